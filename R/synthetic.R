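# Synthetic phage genome populations with planted lytic cassettes and a
# ground-truth shuffling-event ledger.
#
# Design notes:
# * Blocks (catalytic, CWB, holin) are unrelated random sequences checked
#   to be pairwise <= max_cross_identity by global alignment; every planted
#   copy is mutated at a fixed number of positions, round(divergence * len),
#   so within-block copy identity is bounded below by construction.
# * Interdomain linkers are planted unmutated: they model the highly
#   conserved P/K-rich linker around which shuffling happens.
# * Swaps replace a recipient's block (or holin gene) with a spare block
#   that no template uses, modelling acquisition from an outside lineage.

# sample a random protein sequence of length n (uniform over 20 residues)
random_protein <- function(n) paste(sample(AA_STANDARD, n, TRUE), collapse = "")

# mutate exactly round(rate * len) positions to different residues
mutate_copy <- function(seq, rate) {
  n <- nchar(seq)
  k <- as.integer(round(rate * n))
  if (k == 0L) return(seq)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample.int(n, k)
  for (p in pos) ch[p] <- sample(setdiff(AA_STANDARD, ch[p]), 1L)
  paste(ch, collapse = "")
}

# generate `n` mutually dissimilar random proteins (pairwise identity
# <= max_id by global alignment), lengths drawn from len_range; offending
# members are regenerated until the whole set satisfies the constraint
dissimilar_blocks <- function(n, len_range, max_id = 0.3, max_retries = 50L) {
  gen1 <- function() random_protein(sample(len_range[1]:len_range[2], 1L))
  seqs <- vapply(seq_len(n), function(i) gen1(), character(1))
  tries <- 0L
  repeat {
    m <- pairwise_identity_matrix(stats::setNames(seqs, seq_len(n)))
    diag(m) <- 0
    clash <- which(m > max_id, arr.ind = TRUE)
    bad <- unique(pmax(clash[, 1], clash[, 2]))  # regenerate one per pair
    if (!length(bad)) return(seqs)
    tries <- tries + length(bad)
    if (tries > max_retries)
      stopf("could not generate %d blocks below identity %.2f", n, max_id)
    for (b in bad) seqs[b] <- gen1()
  }
}

# P/K-rich linker variant (about 75% P/K), length in 12..20
random_linker <- function() {
  n <- sample(12:20, 1L)
  paste(sample(c("P", "P", "K", "K", "P", "K", "T", "S"), n, TRUE),
        collapse = "")
}

#' Build the synthetic sequence block library
#'
#' Generates named amino-acid blocks for catalytic domains, CWB domains
#' (including putative UCWB families that no domain scanner would
#' annotate), holin genes and P/K-rich interdomain linkers (including the
#' exact consensus `KPTKPPSKPPPKP`). Distinct blocks are pairwise
#' dissimilar (global-alignment identity <= `max_cross_identity`) by
#' construction, verified with [global_align()] and regenerated on
#' violation. Multiple unrelated variants of the same domain family (e.g.
#' four Amidase_2 variants) model the observation that one family name
#' covers several unrelated sequence lineages.
#'
#' @param seed integer seed; the library is byte-identical for a given
#'   seed.
#' @param max_cross_identity maximum identity tolerated between distinct
#'   blocks (default 0.3).
#' @return object of class `block_library`: list of data.frames
#'   `catalytic_blocks`, `cwb_blocks`, `holin_genes` (columns `block_id`,
#'   `family`, `seq`), character vector `linker_blocks`, string
#'   `xhla_seq`.
#' @export
build_library <- function(seed, max_cross_identity = 0.3) {
  set.seed(seed)
  cat_families <- c("Amidase_2", "Amidase_2", "Amidase_2", "Amidase_2",
                    "CHAP", "Glyco_hydro_25", "Peptidase_M23",
                    "Glucosaminidase")
  cat_ids <- c("Amidase_2.v1", "Amidase_2.v2", "Amidase_2.v3", "Amidase_2.v4",
               "CHAP.v1", "Glyco_hydro_25.v1", "Peptidase_M23.v1",
               "Glucosaminidase.v1")
  cwb_families <- c("ZoocinA", "SH3_5", "UCWB-1", "UCWB-2", "UCWB-3",
                    "LysM", "SH3_3", "ZoocinA")
  cwb_ids <- c("ZoocinA.v1", "SH3_5.v1", "UCWB-1", "UCWB-2", "UCWB-3",
               "LysM.v1", "SH3_3.v1", "ZoocinA.v2")
  holin_families <- c("Phage_holin_4_1", "Holin_BhlA", "Phage_holin_1",
                      "Phage_holin_Dp1", "Phage_holin_2_2", "Phage_holin_5_2",
                      "Holin_SPP1")
  cat_seqs <- dissimilar_blocks(length(cat_ids), c(120L, 160L),
                                max_cross_identity)
  cwb_seqs <- dissimilar_blocks(length(cwb_ids), c(60L, 110L),
                                max_cross_identity)
  holin_seqs <- dissimilar_blocks(length(holin_families), c(70L, 100L),
                                  max_cross_identity)
  xhla_seq <- random_protein(90L)
  linkers <- c(LINKER_CONSENSUS, random_linker(), random_linker())
  structure(list(
    catalytic_blocks = data.frame(block_id = cat_ids, family = cat_families,
                                  seq = cat_seqs, stringsAsFactors = FALSE),
    cwb_blocks = data.frame(block_id = cwb_ids, family = cwb_families,
                            seq = cwb_seqs, stringsAsFactors = FALSE),
    holin_genes = data.frame(block_id = paste0(holin_families, ".v1"),
                             family = holin_families, seq = holin_seqs,
                             stringsAsFactors = FALSE),
    linker_blocks = linkers, xhla_seq = xhla_seq,
    seed = seed), class = "block_library")
}

# default cassette template per size group; block ids refer to the library
default_templates <- function() {
  list(
    `1` = list(holin = "Phage_holin_4_1", catalytic = "Amidase_2.v1",
               linker = 1L, cwb = "UCWB-1", xhla = FALSE),
    `2` = list(holin = "Phage_holin_1", catalytic = "Amidase_2.v2",
               linker = 1L, cwb = "ZoocinA.v1", xhla = TRUE),
    `3` = list(holin = "Phage_holin_5_2", catalytic = "CHAP.v1",
               linker = 1L, cwb = "UCWB-2", xhla = FALSE),
    `4` = list(holin = "Phage_holin_5_2", catalytic = "Amidase_2.v3",
               linker = 1L, cwb = "SH3_5.v1", xhla = FALSE),
    `5` = list(holin = "Holin_SPP1", catalytic = "Amidase_2.v4",
               linker = 1L, cwb = "UCWB-3", xhla = FALSE))
}

# spare blocks (used by no template) that swaps draw replacements from
SPARE_CATALYTIC <- c("Glyco_hydro_25.v1", "Peptidase_M23.v1",
                     "Glucosaminidase.v1")
SPARE_CWB <- c("LysM.v1", "SH3_3.v1", "ZoocinA.v2")

#' Simulation specification
#'
#' @param seed integer seed driving every random choice.
#' @param n_per_group named integer vector: genomes per size group
#'   (default 6 in each of the 5 groups, 30 genomes).
#' @param divergence per-copy substitution rate in `[0, 0.1]`; every
#'   planted block copy is mutated at `round(divergence * length)`
#'   positions (default 0.03).
#' @param n_gene_swaps,n_cwb_swaps,n_catalytic_swaps numbers of planted
#'   shuffling events per class (defaults 3 each).
#' @param templates cassette template per group (default
#'   [default_templates()]).
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1L,
                            n_per_group = c(`1` = 6L, `2` = 6L, `3` = 6L,
                                            `4` = 6L, `5` = 6L),
                            divergence = 0.03,
                            n_gene_swaps = 3L, n_cwb_swaps = 3L,
                            n_catalytic_swaps = 3L,
                            templates = default_templates()) {
  if (divergence < 0 || divergence > 0.1)
    stopf("divergence must be in [0, 0.1]")
  if (any(c(n_gene_swaps, n_cwb_swaps, n_catalytic_swaps) < 0))
    stopf("swap counts must be >= 0")
  if (!all(names(n_per_group) %in% as.character(1:5)))
    stopf("n_per_group must be named by group labels 1..5")
  structure(list(seed = as.integer(seed), n_per_group = n_per_group,
                 divergence = divergence,
                 n_gene_swaps = as.integer(n_gene_swaps),
                 n_cwb_swaps = as.integer(n_cwb_swaps),
                 n_catalytic_swaps = as.integer(n_catalytic_swaps),
                 templates = templates),
            class = "simulation_spec")
}

# genome length ranges sampled per group (bp); group 1 leaves room for the
# planted genes, group 5 is capped for practicality
GROUP_LENGTH_RANGES <- rbind(`1` = c(12000, 19999), `2` = c(20000, 49999),
                             `3` = c(50000, 64999), `4` = c(65000, 99999),
                             `5` = c(100000, 129999))

# uniform reverse translation under genetic code table 11
codon_table_11 <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::getGeneticCode("11")
      tab <<- split(names(gc), unname(gc))
    }
    tab
  }
})

reverse_translate <- function(aa) {
  tab <- codon_table_11()
  ch <- strsplit(aa, "")[[1]]
  codons <- vapply(ch, function(a)
    sample(tab[[a]], 1L), character(1), USE.NAMES = FALSE)
  stop_codon <- sample(tab[["*"]], 1L)
  tolower(paste(c(codons, stop_codon), collapse = ""))
}

revcomp_chr <- function(s)
  tolower(as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))))

FILLER_PRODUCTS <- c("hypothetical protein", "terminase", "portal protein",
                     "tail fiber protein", "major capsid protein",
                     "DNA polymerase")

# Pfam accession for a canonical name (inverse vocabulary lookup)
accession_for <- function(name, vocab = default_vocabulary()) {
  i <- match(name, vocab$canonical_name)
  if (is.na(i)) NA_character_ else vocab$accession[i]
}

#' Generate a synthetic genome population with planted shuffling events
#'
#' Each genome receives a length sampled uniformly within its size
#' group's bp range, filler CDS with neutral products (including the
#' "tail fiber protein" decoy), and one planted cassette — optional XhlA
#' holin-like gene, holin, and an endolysin assembled as catalytic block
#' + linker + CWB block — built from mutated copies of its group's
#' template blocks. Planted swap events replace a recipient genome's
#' holin gene or its endolysin's CWB / catalytic block with a spare block
#' unused by any template. Domain-scan rows with correct coordinates are
#' emitted for every planted block of an annotated family (UCWB blocks,
#' like real unknown domains, yield no rows). The truth ledger records
#' block assignments, cassette and linker coordinates, and every planted
#' event in the same form the detectors report.
#'
#' @param spec a [simulation_spec()].
#' @param lib a [build_library()] result (defaults to
#'   `build_library(spec$seed)`).
#' @return list with `genomes` (list of [genome_record()]),
#'   `domain_hits` (data.frame in the domain-scan layout), `proteins`
#'   (named character vector of all translations), `truth` (the ledger).
#' @export
generate_population <- function(spec, lib = build_library(spec$seed)) {
  stopifnot(inherits(spec, "simulation_spec"), inherits(lib, "block_library"))
  set.seed(spec$seed)
  groups <- names(spec$n_per_group)[spec$n_per_group > 0]
  # genome roster
  roster <- do.call(rbind, lapply(groups, function(g)
    data.frame(group = as.integer(g), idx = seq_len(spec$n_per_group[[g]]))))
  roster$accession <- sprintf("SYNG%d_%03d", roster$group, roster$idx)
  n <- nrow(roster)
  # block assignment: start from the group template
  tpl <- spec$templates
  roster$holin_block <- vapply(roster$group, function(g)
    paste0(tpl[[as.character(g)]]$holin, ".v1"), character(1))
  roster$cat_block <- vapply(roster$group, function(g)
    tpl[[as.character(g)]]$catalytic, character(1))
  roster$cwb_block <- vapply(roster$group, function(g)
    tpl[[as.character(g)]]$cwb, character(1))
  roster$linker_idx <- vapply(roster$group, function(g)
    tpl[[as.character(g)]]$linker, integer(1))
  roster$xhla <- vapply(roster$group, function(g)
    tpl[[as.character(g)]]$xhla, logical(1))
  roster$swap <- "none"

  # ---- plan swaps ------------------------------------------------------
  pick <- function(k, eligible) {
    if (k == 0L) return(integer(0))
    if (length(eligible) < k)
      stopf("not enough unswapped genomes to plant %d more events", k)
    eligible[sample.int(length(eligible), k)]
  }
  grp_sizes <- table(roster$group)
  # gene swaps: distinct groups so the modal holin stays unambiguous
  elig_groups <- as.integer(names(grp_sizes)[grp_sizes >= 3])
  if (spec$n_gene_swaps > length(elig_groups))
    stopf("n_gene_swaps exceeds the number of groups with >= 3 genomes")
  gene_groups <- if (spec$n_gene_swaps)
    elig_groups[sample.int(length(elig_groups), spec$n_gene_swaps)] else integer(0)
  for (g in gene_groups) {
    cand <- which(roster$group == g & roster$swap == "none")
    r <- pick(1L, cand)
    roster$swap[r] <- "gene"
    # replacement: first holin family different from the template's
    families <- lib$holin_genes$family
    repl <- families[families != tpl[[as.character(g)]]$holin][1]
    roster$holin_block[r] <- paste0(repl, ".v1")
    roster$replacement_holin <- roster$replacement_holin %||% NA_character_
    roster$replacement_holin[r] <- repl
  }
  # domain swaps: at most 2 per group so endolysin clusters stay >= 3
  plan_domain <- function(k, kind, spares, col) {
    planted <- 0L; spare_i <- 1L
    while (planted < k) {
      per_group_swapped <- tapply(roster$swap %in% c("cwb", "catalytic"),
                                  roster$group, sum)
      ok_groups <- as.integer(names(per_group_swapped)[per_group_swapped < 2])
      cand <- which(roster$group %in% ok_groups & roster$swap == "none")
      r <- pick(1L, cand)
      roster$swap[r] <<- kind
      roster[[col]][r] <<- spares[spare_i]
      spare_i <- spare_i %% length(spares) + 1L
      planted <- planted + 1L
    }
  }
  plan_domain(spec$n_cwb_swaps, "cwb", SPARE_CWB, "cwb_block")
  plan_domain(spec$n_catalytic_swaps, "catalytic", SPARE_CATALYTIC, "cat_block")

  # ---- assemble genomes ------------------------------------------------
  get_block <- function(df, id) df$seq[match(id, df$block_id)]
  genomes <- vector("list", n)
  hits <- list()
  proteins <- character(0)
  truth_cassettes <- list()
  vocab <- default_vocabulary()
  for (r in seq_len(n)) {
    acc <- roster$accession[r]
    g <- roster$group[r]
    rng <- GROUP_LENGTH_RANGES[as.character(g), ]
    target_len <- sample(rng[1]:rng[2], 1L)
    # planted proteins
    cat_seq <- mutate_copy(get_block(lib$catalytic_blocks, roster$cat_block[r]),
                           spec$divergence)
    cwb_seq <- mutate_copy(get_block(lib$cwb_blocks, roster$cwb_block[r]),
                           spec$divergence)
    linker <- lib$linker_blocks[roster$linker_idx[r]]
    endolysin_seq <- paste0(cat_seq, linker, cwb_seq)
    holin_seq <- mutate_copy(get_block(lib$holin_genes, roster$holin_block[r]),
                             spec$divergence)
    xhla_seq <- if (roster$xhla[r]) mutate_copy(lib$xhla_seq, spec$divergence)
      else NULL
    n_before <- sample(3:5, 1L); n_after <- sample(3:5, 1L)
    filler_seqs <- replicate(n_before + n_after,
                             random_protein(sample(150:250, 1L)))
    filler_products <- sample(FILLER_PRODUCTS, n_before + n_after, TRUE)
    # gene order: fillers, [xhla], holin, endolysin, fillers
    gene_aas <- c(filler_seqs[seq_len(n_before)],
                  if (!is.null(xhla_seq)) xhla_seq,
                  holin_seq, endolysin_seq,
                  filler_seqs[n_before + seq_len(n_after)])
    gene_products <- c(filler_products[seq_len(n_before)],
                       if (!is.null(xhla_seq))
                         sample(c("tail fiber protein", "hypothetical protein"), 1L),
                       sample(c("holin", "hypothetical protein"), 1L),
                       sample(c("endolysin", "N-acetylmuramoyl-L-alanine amidase",
                                "hypothetical protein"), 1L),
                       filler_products[n_before + seq_len(n_after)])
    n_genes <- length(gene_aas)
    pids <- sprintf("%s_p%02d", acc, seq_len(n_genes))
    cassette_pos <- n_before + seq_len(n_genes - n_before - n_after)
    # lay genes on the genome
    seq_parts <- character(0)
    cds <- vector("list", n_genes)
    pos <- sample(80:200, 1L)   # leading intergenic offset
    seq_parts <- paste(sample(c("a", "c", "g", "t"), pos, TRUE), collapse = "")
    for (k in seq_len(n_genes)) {
      nt <- reverse_translate(gene_aas[k])
      strand <- if (k %in% cassette_pos) "+" else sample(c("+", "-"), 1L)
      gene_nt <- if (strand == "-") revcomp_chr(nt) else nt
      cds[[k]] <- cds_feature(protein_id = pids[k], start = pos,
                              end = pos + nchar(gene_nt), strand = strand,
                              product = gene_products[k],
                              translation = gene_aas[k])
      seq_parts <- c(seq_parts, gene_nt)
      pos <- pos + nchar(gene_nt)
      gap <- sample(50:200, 1L)
      seq_parts <- c(seq_parts, paste(sample(c("a", "c", "g", "t"), gap, TRUE),
                                      collapse = ""))
      pos <- pos + gap
    }
    if (pos >= target_len)
      stopf("group %d length range too small for the planted genes", g)
    seq_parts <- c(seq_parts, paste(sample(c("a", "c", "g", "t"),
                                           target_len - pos, TRUE), collapse = ""))
    genome_seq <- paste(seq_parts, collapse = "")
    genomes[[r]] <- genome_record(accession = acc, name = acc,
                                  length_bp = target_len,
                                  sequence = genome_seq, cds = cds)
    proteins[pids] <- gene_aas
    # domain-scan rows for planted blocks of annotated families
    add_hit <- function(pid, name, s, e) {
      accn <- accession_for(name, vocab)
      if (is.na(accn)) return()   # UCWB families: the scanner sees nothing
      hits[[length(hits) + 1L]] <<- data.frame(
        protein_id = pid, signature_db = "Pfam", signature_accession = accn,
        signature_name = name, start_aa = s, end_aa = e, score = NA_real_,
        stringsAsFactors = FALSE)
    }
    ki <- 0L
    if (!is.null(xhla_seq)) {
      ki <- ki + 1L
      add_hit(pids[cassette_pos[ki]], "XhlA", 2L, nchar(xhla_seq) - 1L)
    }
    ki <- ki + 1L
    holin_pid <- pids[cassette_pos[ki]]
    holin_family <- lib$holin_genes$family[
      match(roster$holin_block[r], lib$holin_genes$block_id)]
    add_hit(holin_pid, holin_family, 2L, nchar(holin_seq) - 1L)
    ki <- ki + 1L
    endo_pid <- pids[cassette_pos[ki]]
    cat_family <- lib$catalytic_blocks$family[
      match(roster$cat_block[r], lib$catalytic_blocks$block_id)]
    add_hit(endo_pid, cat_family, 1L, nchar(cat_seq))
    cwb_family <- lib$cwb_blocks$family[
      match(roster$cwb_block[r], lib$cwb_blocks$block_id)]
    cwb_start <- nchar(cat_seq) + nchar(linker) + 1L
    add_hit(endo_pid, cwb_family, cwb_start, nchar(endolysin_seq))
    truth_cassettes[[acc]] <- list(
      genome = acc, group = g,
      member_ids = pids[cassette_pos],
      holin_protein = holin_pid, endolysin_protein = endo_pid,
      holin_family = holin_family,
      catalytic_block = roster$cat_block[r], cwb_block = roster$cwb_block[r],
      linker_start = nchar(cat_seq) + 1L,
      linker_end = nchar(cat_seq) + nchar(linker),
      has_xhla = roster$xhla[r], swap = roster$swap[r])
    roster$endo_pid[r] <- endo_pid
  }

  # ---- truth events ----------------------------------------------------
  events <- list()
  # gene swaps: the minority cassette in its template cluster
  for (r in which(roster$swap == "gene")) {
    g <- roster$group[r]
    modal <- tpl[[as.character(g)]]$holin
    events[[length(events) + 1L]] <- list(
      event_class = "gene_holin_swap",
      participants = roster$accession[r],
      minority_holin = roster$replacement_holin[r], modal_holin = modal)
  }
  # domain swaps: every endolysin pair sharing one block but not the other
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_cat <- roster$cat_block[i] == roster$cat_block[j]
    same_cwb <- roster$cwb_block[i] == roster$cwb_block[j]
    cls <- if (same_cat && !same_cwb) "domain_cwb_swap" else
      if (!same_cat && same_cwb) "domain_catalytic_swap" else NA_character_
    if (is.na(cls)) next
    events[[length(events) + 1L]] <- list(
      event_class = cls,
      participants = sort(c(roster$endo_pid[i], roster$endo_pid[j])))
  }
  truth <- list(seed = spec$seed, divergence = spec$divergence,
                n_genomes = n, cassettes = truth_cassettes, events = events)
  domain_hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(protein_id = character(0), signature_db = character(0),
               signature_accession = character(0),
               signature_name = character(0), start_aa = integer(0),
               end_aa = integer(0), score = numeric(0))
  list(genomes = genomes, domain_hits = domain_hits,
       proteins = proteins, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a generated population to disk
#'
#' Emits `genomes.gbk` (GenBank flat file), `proteins.faa` (protein
#' FASTA), `domains.tsv` (full InterProScan TSV layout) and `truth.json`
#' (the ground-truth ledger).
#'
#' @param population result of [generate_population()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_population <- function(population, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("genomes.gbk", "proteins.faa", "domains.tsv",
                            "truth.json"))
  write_genbank(population$genomes, paths[1])
  aa <- Biostrings::AAStringSet(population$proteins)
  Biostrings::writeXStringSet(aa, paths[2])
  h <- population$domain_hits
  full <- data.frame(protein_id = h$protein_id, md5 = "-",
                     len = nchar(population$proteins[h$protein_id]),
                     analysis = h$signature_db,
                     accession = h$signature_accession,
                     description = h$signature_name,
                     start = h$start_aa, stop = h$end_aa,
                     score = ifelse(is.na(h$score), "-", h$score))
  write.table(full, paths[3], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(population$truth, paths[4], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Score called shuffling events against a truth ledger
#'
#' An event matches when its class and its unordered participant set
#' agree with a planted event. Precision is matched calls over all
#' calls, recall is matched truths over all truths; the empty-vs-empty
#' case scores 1.0 for both by convention.
#'
#' @param truth ledger from [generate_population()] (or its `events`
#'   list).
#' @param called list of `shuffling_event` from the detectors.
#' @return list with `precision`, `recall` and `per_class` (data.frame
#'   `event_class`, `n_truth`, `n_called`, `n_matched`, `precision`,
#'   `recall`).
#' @export
score_recovery <- function(truth, called) {
  truth_events <- if (!is.null(truth$events)) truth$events else truth
  key <- function(e) paste0(e$event_class, "::",
                            paste(sort(unlist(e$participants)), collapse = "+"))
  tk <- vapply(truth_events, key, character(1))
  ck <- vapply(called, key, character(1))
  classes <- sort(unique(c(
    vapply(truth_events, `[[`, character(1), "event_class"),
    vapply(called, `[[`, character(1), "event_class"))))
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    tkc <- tk[startsWith(tk, paste0(cl, "::"))]
    ckc <- ck[startsWith(ck, paste0(cl, "::"))]
    nm <- sum(ckc %in% tkc)
    data.frame(event_class = cl, n_truth = length(tkc), n_called = length(ckc),
               n_matched = nm,
               precision = if (length(ckc)) nm / length(ckc) else 1,
               recall = if (length(tkc)) nm / length(tkc) else 1,
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_class))
    per_class <- data.frame(event_class = character(0), n_truth = integer(0),
                            n_called = integer(0), n_matched = integer(0),
                            precision = numeric(0), recall = numeric(0))
  n_matched <- sum(ck %in% tk)
  list(precision = if (length(ck)) n_matched / length(ck) else 1,
       recall = if (length(tk)) n_matched / length(tk) else 1,
       per_class = per_class)
}
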