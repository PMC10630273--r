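test_that("GenBank parsing handles empty records, ordering and complement CDS", {
  path <- write_fixture_genbank(tempfile(fileext = ".gbk"))
  recs <- read_genbank(path)
  expect_length(recs, 2)
  expect_equal(vapply(recs, `[[`, character(1), "accession"),
               c("FIXA.1", "FIXB.1"))

  # metadata-only record: declared length, zero CDS, no sequence
  expect_equal(recs[[1]]$length_bp, 1200L)
  expect_length(recs[[1]]$cds, 0)
  expect_null(recs[[1]]$sequence)

  # complement(100..399) converts to 0-based half-open [99, 399), strand -
  cds <- recs[[2]]$cds[[1]]
  expect_equal(cds$start, 99L)
  expect_equal(cds$end, 399L)
  expect_equal(cds$strand, "-")
  # translation derived from the reverse complement, stop removed;
  # the expected 99-mer was frozen from an independent translation tool
  expect_equal(nchar(cds$translation), 99L)
  expect_equal(cds$translation, FIXB_EXPECTED_PROTEIN)
  expect_false(cds$flagged)
  # simple CDS span is a positive multiple of 3
  expect_equal((cds$end - cds$start) %% 3, 0)
})

test_that("LOCUS length disagreeing with the sequence is an integrity error", {
  path <- tempfile(fileext = ".gbk")
  lines <- readLines(write_fixture_genbank(tempfile(fileext = ".gbk")))
  lines <- sub("LOCUS       FIXB              600 bp",
               "LOCUS       FIXB              601 bp", lines)
  writeLines(lines, path)
  expect_error(read_genbank(path), "disagrees")
})

test_that("non-GenBank input fails with a format error", {
  path <- tempfile()
  writeLines(c(">seq1", "ACGT"), path)
  expect_error(read_genbank(path), "LOCUS")
})

test_that("GenBank round-trip preserves coordinates, strands and translations", {
  set.seed(11)
  pop <- generate_population(simulation_spec(
    seed = 11, n_per_group = c(`1` = 2L), n_gene_swaps = 0L,
    n_cwb_swaps = 0L, n_catalytic_swaps = 0L))
  path <- tempfile(fileext = ".gbk")
  write_genbank(pop$genomes, path)
  back <- read_genbank(path)
  expect_length(back, length(pop$genomes))
  for (i in seq_along(back)) {
    a <- pop$genomes[[i]]; b <- back[[i]]
    expect_equal(b$accession, a$accession)
    expect_equal(b$length_bp, a$length_bp)
    tup <- function(g) lapply(g$cds, function(f)
      list(f$protein_id, f$start, f$end, f$strand, f$translation))
    expect_equal(tup(b), tup(a))
  }
})

test_that("domain scans parse in both TSV dialects and filter by database", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "lys1\t6b2f\t300\tPfam\tPF01510\tAmidase_2\t5\t150\t1.2e-30",
    "lys1\t6b2f\t300\tGene3D\tG3DSA:3.90.1720.10\tendopeptidase\t160\t290\t1e-10",
    "hol1\t9aaa\t80\tPfam\tPF04531\tPhage_holin_1\t3\t78\t5e-20"), path)
  hits <- read_domain_scan(path)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$protein_id[1], "lys1")
  expect_equal(hits$signature_accession[1], "PF01510")
  expect_equal(hits$start_aa[1], 5L)
  expect_equal(hits$end_aa[1], 150L)
  expect_equal(attr(hits, "skip_log"), c(Gene3D = 1L))

  # reduced six-column dialect
  path2 <- tempfile(fileext = ".tsv")
  writeLines("lys1\tPfam\tPF08460\tSH3_5\t200\t260", path2)
  hits2 <- read_domain_scan(path2)
  expect_equal(hits2$signature_accession, "PF08460")
  expect_equal(hits2$end_aa, 260L)

  # widening the accepted set keeps other databases
  hits3 <- read_domain_scan(path, accepted_dbs = c("Pfam", "Gene3D"))
  expect_equal(nrow(hits3), 3)
})

test_that("malformed domain-scan rows are row errors; empty file is empty", {
  p1 <- tempfile(); writeLines("lys1\tPfam\tPF01510\tAmidase_2\tfive\t150", p1)
  expect_error(read_domain_scan(p1), "row 1")
  p2 <- tempfile(); writeLines("lys1\tPfam\tPF01510\tAmidase_2\t200\t100", p2)
  expect_error(read_domain_scan(p2), "start 200 > stop 100")
  p3 <- tempfile(); file.create(p3)
  expect_equal(nrow(read_domain_scan(p3)), 0)
})

test_that("cross-linking reports orphan hits without dropping them", {
  g <- genome_record("G1", length_bp = 1000, cds = list(
    cds_feature("G1_p1", 0, 300, "+", translation = random_aa(99))))
  hits <- data.frame(protein_id = c("G1_p1", "ghost"),
                     signature_db = "Pfam",
                     signature_accession = c("PF01510", "PF05257"),
                     signature_name = c("Amidase_2", "CHAP"),
                     start_aa = c(1L, 1L), end_aa = c(90L, 50L),
                     score = NA_real_)
  expect_warning(out <- cross_link_hits(hits, list(g)), "ghost")
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "orphans"), "ghost")
})

test_that("write_table formats percentages, sorts stably, handles empty input", {
  df <- data.frame(name = c("b", "a", "a"), sub = c("x", "y", "x"),
                   percent = c(32.748538, 11.111, 0.585))
  path <- tempfile(fileext = ".tsv")
  write_table(df, path, key = c("name", "sub"))
  lines <- readLines(path)
  expect_equal(lines[1], "name\tsub\tpercent")
  expect_equal(lines[2], "a\tx\t0.58")   # stable sort by both keys
  expect_equal(lines[3], "a\ty\t11.11")
  expect_equal(lines[4], "b\tx\t32.75")  # half-away-from-zero rounding

  write_table(df[0, ], path)
  expect_equal(readLines(path), "name\tsub\tpercent")

  expect_error(write_table(df, path, key = "nope"), "unknown key")
})

test_that("genome_record validates lengths and sorts CDS stably", {
  expect_error(genome_record("X", length_bp = 0), "positive")
  expect_error(genome_record("X", length_bp = 10, sequence = "acgt"),
               "disagrees")
  f1 <- cds_feature("p1", 500, 800, "+", translation = random_aa(99))
  f2 <- cds_feature("p2", 100, 400, "+", translation = random_aa(99))
  g <- genome_record("X", length_bp = 1000, cds = list(f1, f2))
  expect_equal(vapply(g$cds, `[[`, character(1), "protein_id"), c("p2", "p1"))
  expect_error(cds_feature("p", 10, 10, "+"), "invalid CDS")
  expect_error(cds_feature("p", 10, 20, "*"), "strand")
})
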