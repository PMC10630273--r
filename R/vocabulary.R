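# Controlled vocabulary mapping Pfam signature accessions to the canonical
# lysis-related domain names used throughout the package.

#' Default domain vocabulary
#'
#' Maps Pfam signature accessions onto canonical domain names and
#' categories. The default set covers the holin families, catalytic
#' peptidoglycan-hydrolase domains and cell-wall-binding (CWB) domains
#' observed in lytic cassettes of enterococcal bacteriophages, plus the
#' XhlA hemolysin-like holin-associated domain. Extensible via
#' [extend_vocabulary()] or [read_vocabulary()].
#'
#' @return data.frame with columns `accession`, `canonical_name`,
#'   `category` (one of `catalytic`, `cwb`, `holin`, `holin_like`,
#'   `other_lytic`).
#' @export
default_vocabulary <- function() {
  v <- rbind(
    c("PF05105", "Phage_holin_4_1", "holin"),
    c("PF10960", "Holin_BhlA",      "holin"),
    c("PF04531", "Phage_holin_1",   "holin"),
    c("PF16938", "Phage_holin_Dp1", "holin"),
    c("PF10746", "Phage_holin_2_2", "holin"),
    c("PF16079", "Phage_holin_5_2", "holin"),
    c("PF04688", "Holin_SPP1",      "holin"),
    c("PF10779", "XhlA",            "holin_like"),
    c("PF01510", "Amidase_2",       "catalytic"),
    c("PF05257", "CHAP",            "catalytic"),
    c("PF01183", "Glyco_hydro_25",  "catalytic"),
    c("PF05382", "Amidase_5",       "catalytic"),
    c("PF01551", "Peptidase_M23",   "catalytic"),
    c("PF01832", "Glucosaminidase", "catalytic"),
    c("PF16775", "ZoocinA",         "cwb"),
    c("PF08239", "SH3_3",           "cwb"),
    c("PF08460", "SH3_5",           "cwb"),
    c("PF01476", "LysM",            "cwb"))
  data.frame(accession = v[, 1], canonical_name = v[, 2], category = v[, 3],
             stringsAsFactors = FALSE)
}

VOCAB_CATEGORIES <- c("catalytic", "cwb", "holin", "holin_like", "other_lytic")

#' Extend a domain vocabulary
#'
#' @param vocab vocabulary data.frame (see [default_vocabulary()]).
#' @param accession,canonical_name,category entries to add; existing
#'   accessions are overridden.
#' @return extended vocabulary data.frame.
#' @export
extend_vocabulary <- function(vocab, accession, canonical_name, category) {
  if (!all(category %in% VOCAB_CATEGORIES))
    stopf("category must be one of: %s", paste(VOCAB_CATEGORIES, collapse = ", "))
  vocab <- vocab[!vocab$accession %in% accession, , drop = FALSE]
  rbind(vocab, data.frame(accession = accession,
                          canonical_name = canonical_name,
                          category = category, stringsAsFactors = FALSE))
}

#' Read a vocabulary override file
#'
#' Two-column whitespace-separated text: accession and
#' `canonical_name:category`. Lines starting with `#` are ignored.
#' Entries are added on top of (and may override) the default vocabulary.
#'
#' @param path path to the override file.
#' @param base vocabulary to extend (default [default_vocabulary()]).
#' @return vocabulary data.frame.
#' @export
read_vocabulary <- function(path, base = default_vocabulary()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  for (ln in lines) {
    parts <- strsplit(ln, "\\s+")[[1]]
    if (length(parts) != 2 || !grepl(":", parts[2]))
      stopf("vocabulary line not in 'accession name:category' form: '%s'", ln)
    nc <- strsplit(parts[2], ":", fixed = TRUE)[[1]]
    base <- extend_vocabulary(base, parts[1], nc[1], nc[2])
  }
  base
}

#' Look up a signature accession in the vocabulary
#'
#' Version suffixes (e.g. `PF01510.25`) are stripped before the exact
#' lookup.
#'
#' @param accession signature accession.
#' @param vocab vocabulary data.frame.
#' @return list with `canonical_name` and `category`, or `NULL` when the
#'   accession is not in the vocabulary.
#' @export
map_signature <- function(accession, vocab = default_vocabulary()) {
  acc <- sub("\\.\\d+$", "", accession)
  i <- match(acc, vocab$accession)
  if (is.na(i)) return(NULL)
  list(canonical_name = vocab$canonical_name[i], category = vocab$category[i])
}
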