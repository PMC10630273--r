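test_that("the block library is deterministic and internally dissimilar", {
  lib1 <- build_library(19)
  lib2 <- build_library(19)
  expect_identical(lib1, lib2)
  expect_true(LINKER_CONSENSUS %in% lib1$linker_blocks)
  # catalytic blocks from different families are unrelated by construction
  blocks <- lib1$catalytic_blocks
  pairs <- utils::combn(seq_len(nrow(blocks)), 2)
  for (k in sample(ncol(pairs), 8)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    expect_lte(seq_identity(blocks$seq[i], blocks$seq[j]), 0.3)
  }
  # within-family mutated copies stay above 0.9 identity at default rate
  set.seed(1)
  s <- blocks$seq[1]
  copy1 <- lyticmine:::mutate_copy(s, 0.03)
  copy2 <- lyticmine:::mutate_copy(s, 0.03)
  expect_gte(seq_identity(copy1, copy2), 0.9)
})

test_that("population generation is deterministic, including on-disk bytes", {
  spec <- simulation_spec(seed = 7, n_per_group = c(`1` = 2L, `2` = 2L),
                          n_gene_swaps = 0L, n_cwb_swaps = 1L,
                          n_catalytic_swaps = 0L)
  p1 <- generate_population(spec)
  p2 <- generate_population(spec)
  expect_identical(p1$proteins, p2$proteins)
  expect_identical(p1$truth, p2$truth)
  expect_identical(p1$domain_hits, p2$domain_hits)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_population(p1, d1); write_population(p2, d2)
  for (f in c("genomes.gbk", "proteins.faa", "domains.tsv", "truth.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("genome lengths respect their size-group ranges", {
  pop <- generate_population(simulation_spec(seed = 23))
  grp <- group_genomes(pop$genomes)
  planted <- as.integer(sub("SYNG(\\d)_.*", "\\1", grp$accession))
  expect_equal(grp$group, planted)
  g2 <- grp$length_bp[planted == 2]
  expect_true(all(g2 >= 20000 & g2 < 50000))
})

test_that("a swap-free specification plants no events", {
  pop <- generate_population(simulation_spec(seed = 31, n_gene_swaps = 0L,
                                             n_cwb_swaps = 0L,
                                             n_catalytic_swaps = 0L))
  expect_length(pop$truth$events, 0)
})

test_that("invalid simulation specifications are rejected", {
  expect_error(simulation_spec(divergence = 0.5), "divergence")
  expect_error(simulation_spec(n_cwb_swaps = -1), "swap counts")
  expect_error(simulation_spec(n_per_group = c(`9` = 3L)), "group labels")
})

test_that("scan rows carry correct per-protein coordinates", {
  pop <- generate_population(simulation_spec(seed = 17,
                                             n_per_group = c(`4` = 3L),
                                             n_gene_swaps = 0L,
                                             n_cwb_swaps = 0L,
                                             n_catalytic_swaps = 0L))
  h <- pop$domain_hits
  expect_true(all(h$end_aa <= nchar(pop$proteins[h$protein_id])))
  expect_true(all(h$start_aa >= 1))
  # the planted SH3_5 hit starts right after catalytic block + linker
  for (cass in pop$truth$cassettes) {
    hit <- h[h$protein_id == cass$endolysin_protein &
               h$signature_name == "SH3_5", ]
    expect_equal(hit$start_aa, cass$linker_end + 1L)
  }
})

test_that("recovery scoring implements the matching convention", {
  ev <- function(cls, parts) list(event_class = cls, participants = parts)
  truth <- list(ev("domain_cwb_swap", c("a", "b")),
                ev("domain_cwb_swap", c("a", "c")),
                ev("gene_holin_swap", "g1"),
                ev("gene_holin_swap", "g2"))
  called <- list(ev("domain_cwb_swap", c("b", "a")),   # order-insensitive
                 ev("gene_holin_swap", "g1"),
                 ev("domain_catalytic_swap", c("a", "b")))  # wrong class
  sc <- score_recovery(truth, called)
  expect_equal(sc$precision, 2 / 3)
  expect_equal(sc$recall, 0.5)
  pc <- sc$per_class
  expect_equal(pc$recall[pc$event_class == "domain_cwb_swap"], 0.5)
  expect_equal(pc$precision[pc$event_class == "domain_catalytic_swap"], 0)
  # truth == called
  sc2 <- score_recovery(truth, truth)
  expect_equal(sc2$precision, 1)
  expect_equal(sc2$recall, 1)
  # empty vs empty scores 1 by convention
  sc3 <- score_recovery(list(), list())
  expect_equal(sc3$precision, 1)
  expect_equal(sc3$recall, 1)
})

test_that("tabulating a swap-free population reproduces template proportions", {
  pop <- generate_population(simulation_spec(seed = 41, n_gene_swaps = 0L,
                                             n_cwb_swaps = 0L,
                                             n_catalytic_swaps = 0L))
  res <- mine_genomes(pop$genomes, pop$domain_hits)
  t1 <- res$table1
  expect_equal(attr(t1, "total"), 30)
  # the UCWB templates of groups 1 and 5 collapse into one Amidase_2/Unknown
  # row of 12; the other three templates keep their 6 genomes each
  expect_equal(t1$count[paste(t1$catalytic, t1$cwb) == "Amidase_2 Unknown"], 12L)
  expect_setequal(paste(t1$catalytic, t1$cwb),
                  c("Amidase_2 Unknown", "Amidase_2 ZoocinA", "CHAP Unknown",
                    "Amidase_2 SH3_5"))
  expect_equal(sum(t1$count), 30)
  # the holin axis separates them again: five rows of six
  t2 <- res$table2
  expect_equal(sort(t2$count), rep(6L, 5))
  expect_equal(t2$percent, rep(20, 5))
})

test_that("planted linkers are recovered within two residues", {
  pop <- generate_population(simulation_spec(seed = 47,
                                             n_per_group = c(`1` = 2L, `2` = 2L,
                                                             `5` = 2L),
                                             n_gene_swaps = 0L, n_cwb_swaps = 0L,
                                             n_catalytic_swaps = 0L))
  res <- run_pipeline(pop)
  for (cass in pop$truth$cassettes) {
    seg <- res$scan$segmentations[[cass$endolysin_protein]]
    expect_false(is.null(seg$linker))
    expect_lte(abs(seg$linker$start_aa - cass$linker_start), 2)
    expect_lte(abs(seg$linker$end_aa - cass$linker_end), 2)
  }
})
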