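# End-to-end orchestration: mine cassettes, scan for shuffling, report.

#' Run configuration
#'
#' Collects every tunable threshold of the pipeline with its default.
#' Unknown keys are rejected; values outside their documented ranges
#' raise an error.
#'
#' @param ... named overrides of the defaults.
#' @return object of class `run_config` (a validated named list).
#' @export
run_config <- function(...) {
  defaults <- list(
    max_gap_genes = 2L,          # unknown-role genes bridged in a cassette
    high_id = 0.9,               # near-identity threshold for swaps
    low_id = 0.5,                # unrelatedness threshold for swaps
    min_ucwb_len = 40L,          # minimum putative UCWB length (aa)
    linker_pk_threshold = 0.5,   # P+K fraction for a composition call
    linker_motif_tol = 3L,       # max edit distance to the consensus
    linker_span = 80L,           # linker search span after the catalytic end
    endolysin_cluster_id = 0.9,  # cassette clustering identity (gene swaps)
    ucwb_identity = 0.8,         # UCWB family clustering identity
    all_cassettes = FALSE,       # keep all cassettes, not one per genome
    vocab_path = NULL)           # optional vocabulary override file
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over, keep.null = TRUE)
  chk01 <- c("high_id", "low_id", "endolysin_cluster_id", "ucwb_identity",
             "linker_pk_threshold")
  for (k in chk01)
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0 || cfg[[k]] > 1)
      stopf("config %s must be in [0, 1]", k)
  if (cfg$high_id < cfg$low_id) stopf("high_id must be >= low_id")
  for (k in c("max_gap_genes", "min_ucwb_len", "linker_motif_tol", "linker_span"))
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0)
      stopf("config %s must be a non-negative number", k)
  if (!is.logical(cfg$all_cassettes)) stopf("all_cassettes must be logical")
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return for `read_config`, a [run_config()]; `write_config` returns
#'   the path invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname read_config
#' @param config a [run_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' @param config a [run_config()].
#' @return md5 hex string of the canonical YAML serialisation.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Mine lytic cassettes from a genome set
#'
#' Annotates every CDS (keywords + domain hits), extracts cassettes,
#' reduces to one primary cassette per genome (unless
#' `config$all_cassettes`), and builds the combination tables, size
#' histogram and group assignments.
#'
#' @param genomes list of [genome_record()] objects.
#' @param hits data.frame of domain hits (may be `NULL`).
#' @param config a [run_config()].
#' @param vocab vocabulary; defaults to `config$vocab_path` when set,
#'   else [default_vocabulary()].
#' @return list with `cassettes`, `rows` (per-cassette data.frame incl.
#'   size group), `table1` (catalytic x CWB), `table2` (holin x
#'   catalytic x CWB), `histogram`, `groups`, `architectures` (per
#'   genome).
#' @export
mine_genomes <- function(genomes, hits = NULL, config = run_config(),
                         vocab = NULL) {
  if (is.null(vocab))
    vocab <- if (!is.null(config$vocab_path))
      read_vocabulary(config$vocab_path) else default_vocabulary()
  archs <- lapply(genomes, annotate_genome, hits = hits, vocab = vocab)
  names(archs) <- vapply(genomes, `[[`, character(1), "accession")
  cassettes <- list()
  for (i in seq_along(genomes)) {
    cs <- find_cassettes(genomes[[i]], archs[[i]],
                         max_gap_genes = config$max_gap_genes)
    if (!isTRUE(config$all_cassettes)) cs <- primary_cassette(cs)
    cassettes <- c(cassettes, cs)
  }
  rows <- cassette_rows(cassettes)
  grp <- group_genomes(genomes)
  rows$group <- grp$group[match(rows$genome_accession, grp$accession)]
  list(cassettes = cassettes, rows = rows,
       table1 = if (nrow(rows)) tabulate_combinations(rows, c("catalytic", "cwb")) else NULL,
       table2 = if (nrow(rows)) tabulate_combinations(rows, c("holin", "catalytic", "cwb")) else NULL,
       histogram = size_histogram(genomes),
       groups = grp, architectures = archs)
}

#' Scan mined cassettes for gene- and domain-shuffling
#'
#' Segments every cassette endolysin (catalytic / linker / CWB), calls
#' domain-shuffling events from region-wise identities, gene-shuffling
#' events from holin minorities within endolysin clusters, and clusters
#' putative UCWB regions into numbered families.
#'
#' @param cassettes list of `lytic_cassette` (see [mine_genomes()]).
#' @param proteins named character vector of protein sequences.
#' @param config a [run_config()].
#' @return list with `segmentations`, `events` (domain + gene events),
#'   `ucwb_labels` (named character vector protein id -> UCWB family).
#' @export
shuffle_scan <- function(cassettes, proteins, config = run_config()) {
  endo_archs <- list()
  for (c in cassettes) for (m in c$members)
    if (m$role == "endolysin") endo_archs[[m$protein_id]] <- m
  segmentations <- lapply(endo_archs, function(a) {
    if (!a$protein_id %in% names(proteins))
      stopf("no sequence available for endolysin %s", a$protein_id)
    segment_endolysin(a, proteins[[a$protein_id]],
                      min_ucwb_len = config$min_ucwb_len)
  })
  domain_events <- detect_domain_shuffling(unname(segmentations),
                                           high_id = config$high_id,
                                           low_id = config$low_id)
  gene_events <- detect_gene_shuffling(cassettes, proteins,
                                       endolysin_cluster_id = config$endolysin_cluster_id)
  # cluster putative UCWB regions into families
  put <- Filter(function(s) !s$failed && !is.null(s$cwb_region) &&
                  isTRUE(s$cwb_region$putative), segmentations)
  ucwb_labels <- character(0)
  if (length(put)) {
    regions <- vapply(put, function(s)
      substr(s$sequence, s$cwb_region$start_aa, s$cwb_region$end_aa),
      character(1))
    names(regions) <- vapply(put, `[[`, character(1), "protein_id")
    ucwb_labels <- cluster_regions(regions,
                                   identity_threshold = config$ucwb_identity)
  }
  list(segmentations = segmentations,
       events = c(domain_events, gene_events),
       ucwb_labels = ucwb_labels)
}

#' Write mining results to a directory
#'
#' Emits `cassettes.tsv`, `groups.tsv`, `histogram.tsv`, `table1.tsv`
#' and `table2.tsv`.
#'
#' @param mined result of [mine_genomes()].
#' @param dir output directory (created if needed).
#' @return invisibly, the file paths.
#' @export
write_mine_results <- function(mined, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(mined$rows, file.path(dir, "cassettes.tsv"),
              key = "genome_accession")
  write_table(mined$groups, file.path(dir, "groups.tsv"), key = "accession")
  write_table(mined$histogram, file.path(dir, "histogram.tsv"))
  if (!is.null(mined$table1))
    write_table(mined$table1, file.path(dir, "table1.tsv"))
  if (!is.null(mined$table2))
    write_table(mined$table2, file.path(dir, "table2.tsv"))
  invisible(file.path(dir, c("cassettes.tsv", "groups.tsv", "histogram.tsv",
                             "table1.tsv", "table2.tsv")))
}

#' Write shuffling-scan results to a directory
#'
#' Emits `events.json` and `events.tsv`.
#'
#' @param scan result of [shuffle_scan()].
#' @param dir output directory (created if needed).
#' @return invisibly, the file paths.
#' @export
write_scan_results <- function(scan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev <- lapply(scan$events, function(e)
    list(event_class = e$event_class, participants = as.list(e$participants),
         evidence = as.list(e$evidence),
         minority_holin = e$minority_holin, modal_holin = e$modal_holin,
         context = e$context))
  jsonlite::write_json(ev, file.path(dir, "events.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  write_table(events_table(scan$events), file.path(dir, "events.tsv"))
  invisible(file.path(dir, c("events.json", "events.tsv")))
}

#' Collect a run report
#'
#' Verifies that the mining and shuffling outputs are present in
#' `dir`, recomputes the combination tables from `cassettes.tsv`,
#' normalises the events to `events.tsv`, and writes a run manifest
#' (package version, configuration hash, input checksums). Outputs are
#' byte-identical across reruns on identical inputs.
#'
#' Exit-code contract (`status` in the return value, used by the CLI):
#' 0 success; 2 missing/invalid input; 3 internal invariant violation.
#'
#' @param dir directory holding `cassettes.tsv`, `groups.tsv` and
#'   `events.json`.
#' @param out_dir where to write the report files (default `dir`).
#' @param config a [run_config()].
#' @return list with `status` (integer), `missing` (character), and on
#'   success `paths` of the five report files.
#' @export
run_report <- function(dir, out_dir = dir, config = run_config()) {
  needed <- c("cassettes.tsv", "groups.tsv", "events.json")
  missing <- needed[!file.exists(file.path(dir, needed))]
  if (length(missing))
    return(list(status = 2L,
                missing = missing,
                message = sprintf("missing input file(s): %s",
                                  paste(missing, collapse = ", "))))
  rows <- utils::read.delim(file.path(dir, "cassettes.tsv"),
                            stringsAsFactors = FALSE,
                            colClasses = "character")
  groups <- utils::read.delim(file.path(dir, "groups.tsv"),
                              stringsAsFactors = FALSE)
  events <- jsonlite::read_json(file.path(dir, "events.json"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t1 <- tabulate_combinations(rows, c("catalytic", "cwb"))
  t2 <- tabulate_combinations(rows, c("holin", "catalytic", "cwb"))
  if (abs(sum(t1$percent) - 100) > 0.01 * nrow(t1) ||
      abs(sum(t2$percent) - 100) > 0.01 * nrow(t2))
    return(list(status = 3L, missing = character(0),
                message = "table percentages do not sum to 100"))
  write_table(t1, file.path(out_dir, "table1.tsv"))
  write_table(t2, file.path(out_dir, "table2.tsv"))
  hist_df <- {
    lens <- groups$length_bp
    bin <- floor(lens / 10000) * 10000
    tab <- table(bin)
    data.frame(bin_start = as.integer(names(tab)),
               bin_end = as.integer(names(tab)) + 10000L,
               count = as.integer(tab))
  }
  write_table(hist_df, file.path(out_dir, "histogram.tsv"))
  ev_objects <- lapply(events, function(e)
    structure(list(event_class = e$event_class,
                   participants = unlist(e$participants),
                   evidence = if (length(e$evidence))
                     unlist(e$evidence) else NULL,
                   minority_holin = e$minority_holin,
                   modal_holin = e$modal_holin,
                   context = e$context), class = "shuffling_event"))
  write_table(events_table(ev_objects), file.path(out_dir, "events.tsv"))
  manifest <- list(
    package = "lyticmine",
    version = as.character(utils::packageVersion("lyticmine")),
    config_hash = config_hash(config),
    inputs = as.list(unname(tools::md5sum(file.path(dir, needed)))),
    n_cassettes = nrow(rows), n_events = length(events))
  names(manifest$inputs) <- needed
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(status = 0L, missing = character(0),
       paths = file.path(out_dir, c("table1.tsv", "table2.tsv",
                                    "histogram.tsv", "events.tsv",
                                    "manifest.json")))
}

#' Run the full pipeline on an in-memory population
#'
#' Convenience wrapper: mine, scan, score against a truth ledger when
#' one is supplied.
#'
#' @param population result of [generate_population()], or a list with
#'   `genomes`, `domain_hits`, `proteins` (and optionally `truth`).
#' @param config a [run_config()].
#' @return list with `mined`, `scan` and (when truth is present)
#'   `recovery` from [score_recovery()].
#' @export
run_pipeline <- function(population, config = run_config()) {
  mined <- mine_genomes(population$genomes, population$domain_hits, config)
  scan <- shuffle_scan(mined$cassettes, population$proteins, config)
  out <- list(mined = mined, scan = scan)
  if (!is.null(population$truth))
    out$recovery <- score_recovery(population$truth, scan$events)
  out
}
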