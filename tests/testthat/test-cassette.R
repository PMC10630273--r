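test_that("size groups partition lengths with lower-inclusive boundaries", {
  expect_equal(assign_size_group(15000), 1L)
  expect_equal(assign_size_group(19999), 1L)
  expect_equal(assign_size_group(20000), 2L)   # boundary goes upward
  expect_equal(assign_size_group(50000), 3L)
  expect_equal(assign_size_group(65000), 4L)
  expect_equal(assign_size_group(100000), 5L)
  expect_equal(assign_size_group(120000), 5L)
  expect_error(assign_size_group(0), "positive")
  expect_error(assign_size_group(-5), "positive")
})

# build a toy genome whose CDS carry the given roles (via products/hits)
roles_genome <- function(roles) {
  n <- length(roles)
  cds <- lapply(seq_len(n), function(i)
    cds_feature(sprintf("p%02d", i), (i - 1) * 1000, (i - 1) * 1000 + 300,
                "+", product = "x", translation = random_aa(99)))
  g <- genome_record("TOY", length_bp = n * 1000 + 10, cds = cds)
  archs <- lapply(seq_len(n), function(i) {
    dom <- switch(roles[i],
      holin = domain_row("Phage_holin_1", "holin", 2, 70),
      endolysin = domain_row("Amidase_2", "catalytic", 1, 90),
      holin_like = domain_row("XhlA", "holin_like", 2, 80),
      other_lytic = domain_row("LysM", "cwb", 5, 50),
      NULL)
    make_arch(sprintf("p%02d", i), roles[i], dom)
  })
  list(genome = g, archs = archs)
}

test_that("cassette neighbourhoods follow the gap rule and trim unknown ends", {
  t1 <- roles_genome(c("unknown", "holin", "endolysin", "unknown"))
  cs <- find_cassettes(t1$genome, t1$archs)
  expect_length(cs, 1)
  expect_equal(cs[[1]]$member_ids, c("p02", "p03"))

  # a gap of three unknowns exceeds max_gap_genes = 2: two cassettes
  t2 <- roles_genome(c("holin", "unknown", "unknown", "unknown", "endolysin"))
  cs2 <- find_cassettes(t2$genome, t2$archs, max_gap_genes = 2)
  expect_length(cs2, 2)
  expect_equal(cs2[[1]]$member_ids, "p01")
  expect_equal(cs2[[2]]$member_ids, "p05")
  # ... but a wider allowance bridges them into one
  cs2b <- find_cassettes(t2$genome, t2$archs, max_gap_genes = 3)
  expect_length(cs2b, 1)
  expect_equal(length(cs2b[[1]]$member_ids), 5)  # interior unknowns kept

  # holin-like neighbour joins the cassette and sets the XhlA flag
  t3 <- roles_genome(c("holin_like", "holin", "endolysin"))
  cs3 <- find_cassettes(t3$genome, t3$archs)
  expect_length(cs3, 1)
  expect_true(cs3[[1]]$has_xhla)
  expect_equal(cs3[[1]]$member_ids, c("p01", "p02", "p03"))

  # an accessory-only neighbourhood (no holin/endolysin seed) is not a cassette
  t4 <- roles_genome(c("other_lytic", "unknown", "other_lytic"))
  expect_length(find_cassettes(t4$genome, t4$archs), 0)
})

test_that("cassette typing produces canonical keys", {
  c1 <- make_cassette("G1", "Phage_holin_1", "p1", "Amidase_2", "SH3_5")
  expect_equal(type_cassette(c1), "PH_1|Amidase_2+SH3_5|xhla=0")
  # no CWB hit: Unknown
  c2 <- make_cassette("G2", "Phage_holin_4_1", "p1", "Amidase_2", "Unknown")
  expect_equal(type_cassette(c2), "PH_4_1|Amidase_2+Unknown|xhla=0")
  # multiple CWB domains joined N-to-C
  c3 <- make_cassette("G3", "Phage_holin_5_2", "p1", "Amidase_2",
                      c("SH3_5", "SH3_3"))
  expect_equal(type_cassette(c3), "PH_5_2|Amidase_2+SH3_5 + SH3_3|xhla=0")
  # Glyco_hydro_25 abbreviates to GH_25; XhlA flag recorded
  c4 <- make_cassette("G4", "Phage_holin_Dp1", "p1", "Glyco_hydro_25", "LysM",
                      has_xhla = TRUE)
  expect_equal(type_cassette(c4), "PH_Dp1|GH_25+LysM|xhla=1")
  c5 <- make_cassette("G5", character(0), "p1")
  c5$endolysins <- list()
  expect_error(type_cassette(c5), "neither")
})

test_that("tabulation rounds half-away-from-zero and conserves totals", {
  rows <- data.frame(catalytic = c(rep("A", 56), rep("B", 115)),
                     cwb = "Unknown")
  t1 <- tabulate_combinations(rows, c("catalytic", "cwb"))
  expect_equal(attr(t1, "total"), 171)
  expect_equal(t1$percent[t1$catalytic == "A"], 32.75)
  # single category
  one <- tabulate_combinations(data.frame(catalytic = rep("A", 7),
                                          cwb = "U"), c("catalytic", "cwb"))
  expect_equal(one$percent, 100.00)
  # 19 of 171
  rows2 <- data.frame(catalytic = c(rep("A", 19), rep("B", 152)), cwb = "U")
  t2 <- tabulate_combinations(rows2, c("catalytic", "cwb"))
  expect_equal(t2$percent[t2$catalytic == "A"], 11.11)
  expect_error(tabulate_combinations(rows[0, ], c("catalytic", "cwb")),
               "empty")
  # conservation property on random tables
  set.seed(42)
  for (k in 1:10) {
    n <- sample(50:300, 1)
    rows3 <- data.frame(catalytic = sample(LETTERS[1:6], n, TRUE),
                        cwb = sample(c("U", "V", "W"), n, TRUE))
    tt <- tabulate_combinations(rows3, c("catalytic", "cwb"))
    expect_equal(sum(tt$count), n)
    expect_lte(abs(sum(tt$percent) - 100), 0.01 * nrow(tt))
    expect_true(all(diff(tt$count) <= 0))  # sorted by count descending
  }
})

test_that("size histogram uses left-closed bins and conserves counts", {
  gs <- lapply(c(15000, 35000, 36000), function(L)
    genome_record(paste0("g", L), length_bp = L))
  h <- size_histogram(gs, 10000)
  expect_equal(h$count[h$bin_start == 10000], 1)
  expect_equal(h$count[h$bin_start == 30000], 2)
  expect_equal(sum(h$count), 3)
  expect_equal(nrow(size_histogram(list(), 10000)), 0)
  expect_error(size_histogram(gs, 0), "positive")
  set.seed(9)
  for (k in 1:5) {
    lens <- sample(5000:150000, sample(10:60, 1))
    gs2 <- lapply(seq_along(lens), function(i)
      genome_record(paste0("r", i), length_bp = lens[i]))
    expect_equal(sum(size_histogram(gs2, 7000)$count), length(lens))
  }
})

test_that("mining is idempotent and invariant to CDS input order", {
  pop <- generate_population(simulation_spec(seed = 2,
                                             n_per_group = c(`2` = 3L),
                                             n_gene_swaps = 0L,
                                             n_cwb_swaps = 0L,
                                             n_catalytic_swaps = 0L))
  g <- pop$genomes[[1]]
  archs <- annotate_genome(g, pop$domain_hits)
  a <- find_cassettes(g, archs)
  b <- find_cassettes(g, archs)
  expect_identical(a, b)
  # permute the CDS list: genome_record re-sorts, results identical
  set.seed(1)
  g2 <- genome_record(g$accession, g$name, g$length_bp, g$sequence,
                      g$cds[sample.int(length(g$cds))])
  archs2 <- annotate_genome(g2, pop$domain_hits)
  expect_equal(find_cassettes(g2, archs2), a)
})
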