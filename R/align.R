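# Pairwise global protein alignment. Stands in for the by-eye multiple
# alignments a curator would use: all comparisons in the shuffling
# analysis reduce to Needleman-Wunsch identities with explicit thresholds.

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with BLOSUM62 scoring and affine gap
#' penalties: a gap of length L costs `gap_open + L * gap_extend`
#' (defaults 10 and 0.5). End gaps are penalised. Residues outside the 20
#' standard amino acids are treated as X and scored via the BLOSUM62 X
#' column. Identity is the number of identical aligned residue pairs
#' divided by the full alignment length, so gaps count against identity —
#' length differences between variants are treated as evidence of
#' divergence, not ignored.
#'
#' @param a,b non-empty amino-acid strings.
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return object of class `pairwise_alignment`: list with `aligned_a`,
#'   `aligned_b` (equal-length gapped strings), `score`, `identity`.
#' @export
global_align <- function(a, b, gap_open = 10, gap_extend = 0.5) {
  if (!is_scalar_string(a) || !is_scalar_string(b) || !nzchar(a) || !nzchar(b))
    stopf("global_align requires two non-empty sequences")
  a2 <- sanitize_aa(a); b2 <- sanitize_aa(b)
  # canonical orientation: co-optimal tracebacks can differ in match count
  # when pattern and subject swap, so align the lexicographically smaller
  # sequence as pattern and identity(a, b) == identity(b, a) holds exactly
  swapped <- a2 > b2
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(if (swapped) b2 else a2),
    Biostrings::AAString(if (swapped) a2 else b2),
    substitutionMatrix = blosum62(), gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  alp <- as.character(Biostrings::alignedPattern(pa))
  als <- as.character(Biostrings::alignedSubject(pa))
  ala <- if (swapped) als else alp
  alb <- if (swapped) alp else als
  structure(list(aligned_a = ala, aligned_b = alb,
                 score = Biostrings::score(pa),
                 identity = alignment_identity(ala, alb)),
            class = "pairwise_alignment")
}

# cached BLOSUM62 lookup (data set shipped with Biostrings)
blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

alignment_identity <- function(ala, alb) {
  ca <- strsplit(ala, "")[[1]]
  cb <- strsplit(alb, "")[[1]]
  sum(ca == cb & ca != "-") / length(ca)
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> score %.1f, identity %.3f\n",
              x$score, x$identity))
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

#' Pairwise identity between two sequences
#'
#' Convenience wrapper returning only the identity of the global
#' alignment of `a` and `b`.
#'
#' @inheritParams global_align
#' @return identity in `[0, 1]`.
#' @export
seq_identity <- function(a, b) global_align(a, b)$identity

# identities of many patterns against one subject in a single DP batch
identity_to_subject <- function(patterns, subject, gap_open = 10,
                                gap_extend = 0.5) {
  if (!length(patterns)) return(numeric(0))
  pats <- sanitize_aa(patterns)
  subj <- sanitize_aa(subject)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(pats), Biostrings::AAString(subj),
    substitutionMatrix = blosum62(), gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  nm <- Biostrings::nmatch(pa)
  # global alignment length = len_a + len_b - aligned (non-gap) columns
  nm / (nchar(pats) + nchar(subj) - nm - Biostrings::nmismatch(pa))
}

# identities of each seqs[i] vs ref in the canonical orientation used by
# global_align (lexicographically smaller sequence as pattern)
canonical_identities <- function(seqs, ref) {
  seqs <- unlist(seqs)
  out <- numeric(length(seqs))
  lo <- seqs <= ref
  if (any(lo)) out[lo] <- identity_to_subject(seqs[lo], ref)
  for (i in which(!lo)) out[i] <- identity_to_subject(ref, seqs[[i]])
  out
}

# all-pairs identity matrix for a named character vector of sequences;
# every pair is aligned once, in the canonical orientation, so the matrix
# is symmetric and consistent with seq_identity()
pairwise_identity_matrix <- function(seqs) {
  seqs <- unlist(seqs)
  n <- length(seqs)
  m <- diag(1, n)
  dimnames(m) <- list(names(seqs), names(seqs))
  if (n < 2) return(m)
  for (j in seq_len(n)) {
    # pairs whose lexicographic maximum is seqs[j] (ties broken by index)
    smaller <- which(seqs < seqs[j] | (seqs == seqs[j] & seq_len(n) < j))
    if (!length(smaller)) next
    ids <- identity_to_subject(seqs[smaller], seqs[j])
    m[smaller, j] <- ids
    m[j, smaller] <- ids
  }
  m
}
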