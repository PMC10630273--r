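# Calling gene- and domain-shuffling events from region-wise pairwise
# identities, and clustering putative unknown CWB regions.

new_shuffling_event <- function(event_class, participants, evidence = NULL,
                                context = NA_character_, details = list()) {
  structure(c(list(event_class = event_class,
                   participants = sort(as.character(participants)),
                   evidence = evidence, context = context), details),
            class = "shuffling_event")
}

#' @export
print.shuffling_event <- function(x, ...) {
  ev <- if (is.null(x$evidence)) "" else
    paste0(" [", paste(sprintf("%s=%.2f", names(x$evidence), x$evidence),
                       collapse = ", "), "]")
  cat(sprintf("<shuffling_event> %s: %s%s\n", x$event_class,
              paste(x$participants, collapse = " ~ "), ev))
  invisible(x)
}

#' Single-linkage clustering of sequence regions by identity
#'
#' Clusters sequences with single linkage at a global-alignment identity
#' threshold: two sequences land in the same cluster when they are
#' connected by a chain of pairs with identity >= `identity_threshold`.
#' Cluster labels (`"UCWB-1"`, `"UCWB-2"`, ...) are assigned by
#' descending cluster size, ties broken by the lexicographically smallest
#' member id, so labels are stable under input permutation.
#'
#' @param regions named character vector of non-empty amino-acid strings
#'   (names are the region/protein ids).
#' @param identity_threshold linking identity (default 0.8).
#' @param label_prefix prefix for cluster labels (default `"UCWB"`).
#' @return named character vector mapping each id to its cluster label.
#' @export
cluster_regions <- function(regions, identity_threshold = 0.8,
                            label_prefix = "UCWB") {
  if (is.list(regions)) regions <- unlist(regions)
  if (!length(regions)) return(character(0))
  if (is.null(names(regions)) || anyDuplicated(names(regions)))
    stopf("regions must have unique names")
  if (any(!nzchar(regions))) stopf("regions must be non-empty")
  ids <- names(regions)
  if (length(regions) == 1L) {
    out <- paste0(label_prefix, "-1"); names(out) <- ids
    return(out)
  }
  m <- pairwise_identity_matrix(regions)
  hc <- stats::hclust(stats::as.dist(1 - m), method = "single")
  cl <- stats::cutree(hc, h = 1 - identity_threshold + 1e-9)
  # deterministic relabelling: size desc, then smallest member id
  sizes <- table(cl)
  first_id <- vapply(names(sizes), function(k) min(ids[cl == as.integer(k)]),
                     character(1))
  ord <- order(-as.integer(sizes), first_id)
  new_label <- setNames(paste0(label_prefix, "-", seq_along(ord)),
                        names(sizes)[ord])
  out <- new_label[as.character(cl)]
  names(out) <- ids
  out
}

# comparison region C-terminal of the linker (or of the catalytic domain
# when no linker was found); "" when nothing lies downstream
post_linker_region <- function(seg) {
  if (seg$failed || is.na(seg$post_linker_start)) return("")
  if (seg$post_linker_start > nchar(seg$sequence)) return("")
  substr(seg$sequence, seg$post_linker_start, nchar(seg$sequence))
}

catalytic_region_seq <- function(seg) {
  cr <- seg$catalytic_region
  if (is.null(cr)) return("")
  substr(seg$sequence, cr$start_aa, cr$end_aa)
}

#' Detect domain-shuffling events among segmented endolysins
#'
#' For every pair of segmented endolysins the catalytic-region identity
#' and the CWB-region identity (the region C-terminal of the linker) are
#' computed by global alignment. A pair whose catalytic regions are
#' near-identical (identity >= `high_id`) but whose CWB regions are
#' unrelated (identity <= `low_id`) is called a CWB-domain swap; the
#' converse pattern is a catalytic-domain swap. Pairs in which either
#' region is absent are skipped.
#'
#' @param segmented list of `endolysin_segmentation` objects (with
#'   sequences, as produced by [segment_endolysin()]).
#' @param high_id near-identity threshold (default 0.9).
#' @param low_id unrelatedness threshold (default 0.5).
#' @return list of `shuffling_event` with classes `domain_cwb_swap` /
#'   `domain_catalytic_swap`; each event's `evidence` carries both
#'   identities.
#' @export
detect_domain_shuffling <- function(segmented, high_id = 0.9, low_id = 0.5) {
  if (length(segmented) < 2) return(list())
  cat_seqs <- vapply(segmented, catalytic_region_seq, character(1))
  cwb_seqs <- vapply(segmented, post_linker_region, character(1))
  ids <- vapply(segmented, `[[`, character(1), "protein_id")
  usable <- nzchar(cat_seqs) & nzchar(cwb_seqs)
  ui <- which(usable)
  if (length(ui) < 2) return(list())
  names(cat_seqs) <- names(cwb_seqs) <- ids
  m_cat <- pairwise_identity_matrix(cat_seqs[ui])
  m_cwb <- pairwise_identity_matrix(cwb_seqs[ui])
  events <- list()
  for (a in seq_len(length(ui) - 1)) for (b in (a + 1):length(ui)) {
    i <- ui[a]; j <- ui[b]
    id_cat <- m_cat[a, b]
    id_cwb <- m_cwb[a, b]
    cls <- if (id_cat >= high_id && id_cwb <= low_id) "domain_cwb_swap" else
      if (id_cat <= low_id && id_cwb >= high_id) "domain_catalytic_swap" else
        NA_character_
    if (is.na(cls)) next
    events[[length(events) + 1L]] <- new_shuffling_event(
      cls, c(ids[i], ids[j]),
      evidence = c(catalytic = id_cat, cwb = id_cwb))
  }
  events
}

# one full-length representative endolysin sequence per cassette (the
# first endolysin in genomic order), or NA when the cassette has none or
# its sequence is unavailable
cassette_endolysin_seq <- function(cassette, protein_seqs) {
  if (!length(cassette$endolysins)) return(NA_character_)
  pid <- cassette$endolysins[[1]]$protein_id
  if (!pid %in% names(protein_seqs)) return(NA_character_)
  s <- protein_seqs[[pid]]
  if (!nzchar(s)) NA_character_ else s
}

cassette_holin_name <- function(cassette) {
  paste(cassette$holin_domains, collapse = "+")
}

#' Detect gene-shuffling (holin replacement) events
#'
#' Cassettes are clustered by full-length identity of their endolysins
#' (single linkage at `endolysin_cluster_id`). Within every cluster of at
#' least three cassettes the modal holin family is determined; each
#' cassette carrying a different holin is called a `gene_holin_swap`
#' event naming the minority and modal holins.
#'
#' @param cassettes list of `lytic_cassette`.
#' @param protein_seqs named character vector mapping protein ids to
#'   amino-acid sequences (must cover the cassettes' endolysins).
#' @param endolysin_cluster_id identity threshold for cassette clustering
#'   (default 0.9).
#' @return list of `shuffling_event` with class `gene_holin_swap`;
#'   participants are the genome accessions of the minority cassettes;
#'   `minority_holin` / `modal_holin` name the swap.
#' @export
detect_gene_shuffling <- function(cassettes, protein_seqs,
                                  endolysin_cluster_id = 0.9) {
  if (length(cassettes) < 3) return(list())
  endo <- vapply(cassettes, cassette_endolysin_seq, character(1),
                 protein_seqs = protein_seqs)
  keep <- which(!is.na(endo) & vapply(cassettes, function(c)
    length(c$holin_domains) > 0 && !identical(c$holin_domains, "Unknown"),
    logical(1)))
  if (length(keep) < 3) return(list())
  seqs <- endo[keep]
  names(seqs) <- vapply(cassettes[keep], `[[`, character(1), "genome_accession")
  labels <- cluster_regions(seqs, identity_threshold = endolysin_cluster_id,
                            label_prefix = "ENDO")
  events <- list()
  for (lab in unique(labels)) {
    members <- keep[labels == lab]
    if (length(members) < 3) next
    holins <- vapply(cassettes[members], cassette_holin_name, character(1))
    tab <- sort(table(holins), decreasing = TRUE)
    modal <- names(tab)[tab == max(tab)]
    modal <- sort(modal)[1]                        # deterministic on ties
    for (k in members[holins != modal]) {
      events[[length(events) + 1L]] <- new_shuffling_event(
        "gene_holin_swap", cassettes[[k]]$genome_accession,
        context = lab,
        details = list(minority_holin = cassette_holin_name(cassettes[[k]]),
                       modal_holin = modal))
    }
  }
  events
}

#' Flatten shuffling events to a data.frame
#'
#' @param events list of `shuffling_event`.
#' @return data.frame with one row per event.
#' @export
events_table <- function(events) {
  if (!length(events))
    return(data.frame(event_class = character(0), participants = character(0),
                      catalytic_identity = numeric(0), cwb_identity = numeric(0),
                      minority_holin = character(0), modal_holin = character(0),
                      context = character(0), stringsAsFactors = FALSE))
  rows <- lapply(events, function(e) {
    data.frame(event_class = e$event_class,
               participants = paste(e$participants, collapse = ","),
               catalytic_identity = if (!is.null(e$evidence))
                 unname(e$evidence["catalytic"]) else NA_real_,
               cwb_identity = if (!is.null(e$evidence))
                 unname(e$evidence["cwb"]) else NA_real_,
               minority_holin = if (!is.null(e$minority_holin))
                 e$minority_holin else NA_character_,
               modal_holin = if (!is.null(e$modal_holin))
                 e$modal_holin else NA_character_,
               context = if (is.null(e$context)) NA_character_ else e$context,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$event_class, out$participants), , drop = FALSE]
}
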