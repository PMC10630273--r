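test_that("keyword classification follows the annotation keyword rules", {
  expect_equal(classify_by_keyword("N-acetylmuramoyl-L-alanine amidase"),
               "endolysin")
  expect_equal(classify_by_keyword("putative endolysin"), "endolysin")
  expect_equal(classify_by_keyword("phage lysin"), "endolysin")
  expect_equal(classify_by_keyword("LySiN domain protein"), "endolysin")
  expect_equal(classify_by_keyword("putative holin"), "holin")
  expect_equal(classify_by_keyword("tail fiber protein"), "unknown")
  expect_equal(classify_by_keyword(""), "unknown")
})

test_that("signature mapping is exact, version-tolerant, and closed", {
  expect_equal(map_signature("PF08460"),
               list(canonical_name = "SH3_5", category = "cwb"))
  expect_equal(map_signature("PF10779"),
               list(canonical_name = "XhlA", category = "holin_like"))
  expect_equal(map_signature("PF01510.31")$canonical_name, "Amidase_2")
  expect_null(map_signature("PF99999"))
  # default vocabulary covers all five categories and 18 accessions
  v <- default_vocabulary()
  expect_equal(nrow(v), 18)
  expect_setequal(unique(v$category), c("holin", "holin_like", "catalytic", "cwb"))
})

test_that("vocabulary extension and override files work", {
  v <- extend_vocabulary(default_vocabulary(), "PF09374", "DUF3310",
                         "other_lytic")
  expect_equal(map_signature("PF09374", v)$category, "other_lytic")
  expect_error(extend_vocabulary(default_vocabulary(), "PF1", "x", "bogus"),
               "category")
  path <- tempfile()
  writeLines(c("# extra cassette members", "PF09374 DUF3310:other_lytic"), path)
  v2 <- read_vocabulary(path)
  expect_equal(map_signature("PF09374", v2)$canonical_name, "DUF3310")
})

hit_row <- function(pid, acc, name, s, e)
  data.frame(protein_id = pid, signature_db = "Pfam",
             signature_accession = acc, signature_name = name,
             start_aa = as.integer(s), end_aa = as.integer(e),
             score = NA_real_, stringsAsFactors = FALSE)

test_that("domain evidence outranks keywords with the documented precedence", {
  seq <- random_aa(300)
  f <- function(product) cds_feature("p1", 0, 903, "+", product = product,
                                     translation = seq)
  # XhlA rescues a mislabelled holin-like gene
  a <- annotate_protein(f("hypothetical protein"),
                        hit_row("p1", "PF10779", "XhlA", 5, 80))
  expect_equal(a$role, "holin_like")
  expect_equal(a$evidence, "domain")
  # endolysin with N-terminal catalytic and C-terminal CWB domain
  b <- annotate_protein(f("endolysin"),
                        rbind(hit_row("p1", "PF01510", "Amidase_2", 5, 150),
                              hit_row("p1", "PF08460", "SH3_5", 200, 260)))
  expect_equal(b$role, "endolysin")
  expect_equal(b$evidence, "both")
  expect_equal(b$domains$canonical_name, c("Amidase_2", "SH3_5"))
  # keyword-only holin
  c1 <- annotate_protein(f("holin"))
  expect_equal(c1$role, "holin")
  expect_equal(c1$evidence, "keyword")
  # conflict: holin keyword vs catalytic domain -> the domain wins
  d <- annotate_protein(f("holin"), hit_row("p1", "PF01510", "Amidase_2", 5, 150))
  expect_equal(d$role, "endolysin")
  expect_equal(d$evidence, "domain")
  # CWB-only architecture is an accessory lytic protein
  e <- annotate_protein(f("hypothetical protein"),
                        hit_row("p1", "PF01476", "LysM", 10, 55))
  expect_equal(e$role, "other_lytic")
})

test_that("repeat domains survive merging; same-name overlaps merge", {
  seq <- random_aa(300)
  f <- cds_feature("p1", 0, 903, "+", product = "endolysin",
                   translation = seq)
  # two separate LysM copies survive
  a <- annotate_protein(f, rbind(hit_row("p1", "PF01183", "GH25", 5, 150),
                                 hit_row("p1", "PF01476", "LysM", 200, 240),
                                 hit_row("p1", "PF01476", "LysM", 250, 290)))
  expect_equal(sum(a$domains$canonical_name == "LysM"), 2)
  # overlapping same-name hits merge to the envelope
  b <- annotate_protein(f, rbind(hit_row("p1", "PF01510", "Amidase_2", 5, 100),
                                 hit_row("p1", "PF01510", "Amidase_2", 80, 150)))
  expect_equal(nrow(b$domains), 1)
  expect_equal(b$domains$start_aa, 5L)
  expect_equal(b$domains$end_aa, 150L)
})

test_that("role and architecture are invariant to hit input order", {
  set.seed(5)
  seq <- random_aa(300)
  f <- cds_feature("p1", 0, 903, "+", product = "hypothetical protein",
                   translation = seq)
  hits <- rbind(hit_row("p1", "PF01510", "Amidase_2", 5, 150),
                hit_row("p1", "PF08460", "SH3_5", 200, 260),
                hit_row("p1", "PF04531", "Phage_holin_1", 160, 190))
  ref <- annotate_protein(f, hits)
  for (k in 1:10) {
    perm <- hits[sample.int(nrow(hits)), , drop = FALSE]
    a <- annotate_protein(f, perm)
    expect_equal(a$role, ref$role)
    expect_equal(a$domains, ref$domains)
  }
})

test_that("hits beyond the translation are integrity errors; foreign ids rejected", {
  f <- cds_feature("p1", 0, 303, "+", product = "endolysin",
                   translation = random_aa(100))
  expect_error(annotate_protein(f, hit_row("p1", "PF01510", "Amidase_2", 5, 150)),
               "exceeds")
  expect_error(annotate_protein(f, hit_row("px", "PF01510", "Amidase_2", 5, 50)),
               "foreign")
})

test_that("every CDS of a genome receives exactly one role", {
  pop <- generate_population(simulation_spec(seed = 3,
                                             n_per_group = c(`2` = 3L),
                                             n_gene_swaps = 0L,
                                             n_cwb_swaps = 0L,
                                             n_catalytic_swaps = 0L))
  for (g in pop$genomes) {
    archs <- annotate_genome(g, pop$domain_hits)
    roles <- vapply(archs, `[[`, character(1), "role")
    expect_length(roles, length(g$cds))
    expect_true(all(roles %in% c("endolysin", "holin", "holin_like",
                                 "other_lytic", "unknown")))
    # vocabulary closure: every reported domain name is in the vocabulary
    nm <- unlist(lapply(archs, function(a) a$domains$canonical_name))
    expect_true(all(nm %in% default_vocabulary()$canonical_name))
  }
})
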