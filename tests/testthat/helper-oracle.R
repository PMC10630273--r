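# Independent oracles and fixture builders shared across tests.

BLOSUM62_M <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Exhaustive maximum over every gapped global alignment (affine gaps:
# a gap of length L costs open + L * ext; end gaps penalised). Pure
# enumeration, independent of any dynamic-programming code path; only
# practical for sequences of length <= 8.
brute_force_align_score <- function(a, b, open = 10, ext = 0.5) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  m <- length(ca); n <- length(cb)
  S <- BLOSUM62_M[ca, cb, drop = FALSE]
  best <- -Inf
  rec <- function(i, j, sc, last) {
    if (i > m && j > n) {
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (i <= m && j <= n) rec(i + 1L, j + 1L, sc + S[i, j], 0L)
    if (i <= m) rec(i + 1L, j, sc - ext - if (last != 1L) open else 0, 1L)
    if (j <= n) rec(i, j + 1L, sc - ext - if (last != 2L) open else 0, 2L)
  }
  rec(1L, 1L, 0, 0L)
  best
}

random_aa <- function(n)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, TRUE),
        collapse = "")

# mutate k positions of a protein to different residues
mutate_aa <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(ch), k)
  alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (p in pos) ch[p] <- sample(setdiff(alpha, ch[p]), 1L)
  paste(ch, collapse = "")
}

# ---- GenBank fixture ---------------------------------------------------
# Record FIXA: metadata-only, 1200 bp, zero CDS.
# Record FIXB: 600 bp with CDS complement(100..399) and no /translation
# qualifier; the expected 99-residue product below was computed once with
# an independent translation tool and frozen.

FIXB_GENOME <- paste0(
  "ccgttgcctaaacctatttgaaggagtctagcagccgcagtaaggcacaatacctcgtccgtgttacca",
  "gaccaaacaagacgtcctcttcaatgtttattaatgacacggcatagattccagatattcattatgcat",
  "cagacgaccacgcagaccccaatgcatcggttgaccccattgaacattatgttcttttttttgtttcgg",
  "atgcatatcaccattaataccacgattttcatatttaacaatccaattcatatcccacggacgatgaac",
  "ttttttatccatattatccagttcacaatgcagaaattgagcatgatacggaccaaaccattcccaagc",
  "aacagtaccttcattagcacgaaaataattccaatcacaaccaccatgagcatcaatgaccctctcgtc",
  "ataaaacctttctactatgtgttccgcaagaatcaacaactacaatggcgcgtcgtgaataacgcgacg",
  "gctgagacgaacggcgcgtgaatgaagcgcttaaacagctcaggagccagtcccctacgtcgcatatcc",
  "tggccactggaggtgaagcgaatggtatcgatacgtaggaggtgtgcc")

FIXB_EXPECTED_PROTEIN <- paste0(
  "DAHGGCDWNYFRANEGTVAWEWFGPYHAQFLHCELDNMDKKVHRPWDMNWIVKYENRGINGDMHPKQK",
  "KEHNVQWGQPMHWGLRGRLMHNEYLESMPCH")

origin_lines <- function(s) {
  starts <- seq(1, nchar(s), 60)
  vapply(starts, function(st) {
    chunk <- substr(s, st, min(st + 59, nchar(s)))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    sprintf("%9d %s", st, paste(tens, collapse = " "))
  }, character(1))
}

write_fixture_genbank <- function(path) {
  lines <- c(
    "LOCUS       FIXA             1200 bp    DNA     linear   PHG",
    "DEFINITION  synthetic fixture record A.",
    "ACCESSION   FIXA",
    "VERSION     FIXA.1",
    "FEATURES             Location/Qualifiers",
    "     source          1..1200",
    "//",
    "LOCUS       FIXB              600 bp    DNA     linear   PHG",
    "DEFINITION  synthetic fixture record B.",
    "ACCESSION   FIXB",
    "VERSION     FIXB.1",
    "FEATURES             Location/Qualifiers",
    "     source          1..600",
    "     CDS             complement(100..399)",
    "                     /product=\"fixture lysis protein\"",
    "                     /protein_id=\"FIXB_p1\"",
    "ORIGIN",
    origin_lines(FIXB_GENOME),
    "//")
  writeLines(lines, path)
  path
}

# minimal architecture / cassette builders for detector tests
make_arch <- function(protein_id, role, domains = NULL, evidence = "domain") {
  if (is.null(domains))
    domains <- data.frame(canonical_name = character(0),
                          category = character(0), start_aa = integer(0),
                          end_aa = integer(0), stringsAsFactors = FALSE)
  structure(list(protein_id = protein_id, role = role, domains = domains,
                 evidence = evidence), class = "protein_architecture")
}

domain_row <- function(name, category, start, end)
  data.frame(canonical_name = name, category = category,
             start_aa = as.integer(start), end_aa = as.integer(end),
             stringsAsFactors = FALSE)

make_cassette <- function(accession, holin, endo_pid,
                          catalytic = "Amidase_2", cwb = "Unknown",
                          has_xhla = FALSE) {
  structure(list(genome_accession = accession, members = list(),
                 member_ids = endo_pid, start_index = 1L,
                 holin_domains = holin,
                 endolysins = list(list(protein_id = endo_pid,
                                        catalytic = catalytic, cwb = cwb)),
                 has_xhla = has_xhla),
            class = "lytic_cassette")
}
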