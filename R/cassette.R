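# Lytic-cassette extraction, genome size groups, cassette typing and the
# combination tables.

#' The five genome size groups
#'
#' Phage genome lengths fall into a multimodal distribution that is
#' stratified into five half-open, lower-inclusive classes:
#' Group 1 < 20 kbp, Group 2 20-50 kbp, Group 3 50-65 kbp,
#' Group 4 65-100 kbp, Group 5 >= 100 kbp.
#'
#' @return data.frame with columns `label`, `lower_bp` (inclusive),
#'   `upper_bp` (exclusive; `Inf` for Group 5).
#' @export
size_groups <- function() {
  data.frame(label = 1:5,
             lower_bp = c(0, 20000, 50000, 65000, 100000),
             upper_bp = c(20000, 50000, 65000, 100000, Inf))
}

#' Assign a genome length to its size group
#'
#' Boundaries are half-open and lower-inclusive: a genome of exactly
#' 20,000 bp belongs to Group 2.
#'
#' @param length_bp positive genome length(s) in bp (vectorised).
#' @return integer group label(s) in 1..5.
#' @export
assign_size_group <- function(length_bp) {
  if (any(!is.finite(length_bp) | length_bp <= 0))
    stopf("length_bp must be positive")
  g <- size_groups()
  findInterval(length_bp, g$lower_bp)
}

# canonical holin abbreviations used in Table-2-style output
HOLIN_ALIASES <- c(Phage_holin_1 = "PH_1", Phage_holin_Dp1 = "PH_Dp1",
                   Phage_holin_4_1 = "PH_4_1", Phage_holin_5_2 = "PH_5_2",
                   Phage_holin_2_2 = "PH_2_2", Holin_SPP1 = "Holin_SPP1",
                   Holin_BhlA = "HolinBhlA")
CATALYTIC_ALIASES <- c(Glyco_hydro_25 = "GH_25")

holin_alias <- function(x) ifelse(x %in% names(HOLIN_ALIASES), HOLIN_ALIASES[x], x)
catalytic_alias <- function(x) ifelse(x %in% names(CATALYTIC_ALIASES),
                                      CATALYTIC_ALIASES[x], x)

# summarize one endolysin architecture: first catalytic domain (N-most) and
# the N-to-C list of CWB domains ("Unknown" when none is annotated)
endolysin_summary <- function(arch) {
  dom <- arch$domains
  cat_dom <- dom[dom$category == "catalytic", , drop = FALSE]
  cwb_dom <- dom[dom$category == "cwb", , drop = FALSE]
  list(protein_id = arch$protein_id,
       catalytic = if (nrow(cat_dom)) cat_dom$canonical_name[1] else "Unknown",
       cwb = if (nrow(cwb_dom)) cwb_dom$canonical_name else "Unknown")
}

#' Find lytic cassettes in an annotated genome
#'
#' A cassette is a gene neighbourhood seeded on every holin or endolysin
#' and extended over neighbouring genes of any annotated lytic role on
#' either strand. At most `max_gap_genes` consecutive unknown-role genes
#' are tolerated inside a cassette; unknown-role genes are trimmed from
#' the ends. Overlapping seeds merge into one cassette.
#'
#' @param genome a [genome_record()].
#' @param architectures list of `protein_architecture`, one per CDS of the
#'   genome, in genomic order (see [annotate_genome()]).
#' @param max_gap_genes maximum run of unknown-role genes bridged inside a
#'   cassette (default 2).
#' @return list of `lytic_cassette` objects: list with `genome_accession`,
#'   `members` (protein architectures in genomic order, interior
#'   unknown-role genes included), `member_ids`, `start_index`,
#'   `holin_domains`, `endolysins` (list of `list(protein_id, catalytic,
#'   cwb)`), `has_xhla`.
#' @export
find_cassettes <- function(genome, architectures, max_gap_genes = 2L) {
  n <- length(architectures)
  if (n != length(genome$cds))
    stopf("architectures must cover all %d CDS of %s", length(genome$cds),
          genome$accession)
  if (!n) return(list())
  roles <- vapply(architectures, `[[`, character(1), "role")
  lytic <- which(roles != "unknown")
  if (!length(lytic)) return(list())
  # group annotated genes separated by at most max_gap_genes unknowns
  grp <- cumsum(c(1L, diff(lytic) - 1L > max_gap_genes))
  out <- list()
  for (gid in unique(grp)) {
    idx <- lytic[grp == gid]
    member_idx <- seq(min(idx), max(idx))        # interior unknowns included
    members <- architectures[member_idx]
    mroles <- roles[member_idx]
    if (!any(mroles %in% c("holin", "endolysin"))) next  # no seed
    holins <- unlist(lapply(members[mroles == "holin"], function(a) {
      hd <- a$domains$canonical_name[a$domains$category == "holin"]
      if (length(hd)) hd else "Unknown"
    }))
    endos <- lapply(members[mroles == "endolysin"], endolysin_summary)
    has_xhla <- any(vapply(members, function(a)
      "XhlA" %in% a$domains$canonical_name, logical(1)))
    out[[length(out) + 1L]] <- structure(
      list(genome_accession = genome$accession,
           members = members,
           member_ids = vapply(members, `[[`, character(1), "protein_id"),
           start_index = min(member_idx),
           holin_domains = sort(unique(holins)),
           endolysins = endos,
           has_xhla = has_xhla),
      class = "lytic_cassette")
  }
  out
}

#' Reduce to one primary cassette per genome
#'
#' When a genome yields several cassettes, the one with the largest member
#' count (ties broken by leftmost genomic position) is kept, so that a set
#' of n genomes contributes n cassettes to the combination tables.
#'
#' @param cassettes list of `lytic_cassette` from one genome.
#' @return list with at most one cassette.
#' @export
primary_cassette <- function(cassettes) {
  if (length(cassettes) <= 1L) return(cassettes)
  sizes <- vapply(cassettes, function(c) length(c$member_ids), integer(1))
  starts <- vapply(cassettes, `[[`, integer(1), "start_index")
  cassettes[order(-sizes, starts)][1]
}

# endolysin "catalytic+CWB" string, CWB domains joined N-to-C with " + "
endolysin_combo_string <- function(e) {
  paste0(catalytic_alias(e$catalytic), "+", paste(e$cwb, collapse = " + "))
}

#' Abstract a cassette into its canonical type key
#'
#' The key is deterministic: sorted abbreviated holin names, the sorted
#' per-endolysin "catalytic+CWB" strings (multiple CWB domains joined
#' N-to-C with " + "; `Unknown` when no CWB domain is annotated), and the
#' XhlA flag.
#'
#' @param cassette a `lytic_cassette`.
#' @return character key, e.g. `"PH_1|Amidase_2+SH3_5|xhla=1"`.
#' @export
type_cassette <- function(cassette) {
  has_endo <- length(cassette$endolysins) > 0
  has_holin <- length(cassette$holin_domains) > 0
  if (!has_endo && !has_holin)
    stopf("cassette in %s has neither holin nor endolysin",
          cassette$genome_accession)
  holin_key <- paste(sort(holin_alias(cassette$holin_domains)), collapse = "+")
  endo_key <- paste(sort(vapply(cassette$endolysins, endolysin_combo_string,
                                character(1))), collapse = ";")
  sprintf("%s|%s|xhla=%d", holin_key, endo_key, as.integer(cassette$has_xhla))
}

#' Per-cassette combination rows
#'
#' Flattens cassettes into one row each, using the first (N-most in the
#' genome) endolysin as the cassette's primary endolysin for tabulation.
#'
#' @param cassettes list of `lytic_cassette`.
#' @return data.frame with columns `genome_accession`, `holin`,
#'   `catalytic`, `cwb`, `has_xhla`, `type_key`.
#' @export
cassette_rows <- function(cassettes) {
  rows <- lapply(cassettes, function(c) {
    e <- if (length(c$endolysins)) c$endolysins[[1]] else
      list(catalytic = "Unknown", cwb = "Unknown")
    data.frame(genome_accession = c$genome_accession,
               holin = paste(holin_alias(c$holin_domains), collapse = "+"),
               catalytic = catalytic_alias(e$catalytic),
               cwb = paste(e$cwb, collapse = " + "),
               has_xhla = c$has_xhla,
               type_key = type_cassette(c),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(genome_accession = character(0),
                                      holin = character(0),
                                      catalytic = character(0),
                                      cwb = character(0),
                                      has_xhla = logical(0),
                                      type_key = character(0))
  out$holin[!nzchar(out$holin)] <- "Unknown"
  out
}

#' Tabulate cassette combinations
#'
#' Groups cassette rows by the requested axes — `c("catalytic", "cwb")`
#' for a Table-1-style catalytic x CWB table, `c("holin", "catalytic",
#' "cwb")` for a Table-2-style holin-endolysin pair table — and reports
#' counts and percentages. Percentages are `100 * count / total` rounded
#' half-away-from-zero to two decimals. Rows are sorted by count
#' descending, then by key.
#'
#' @param rows data.frame with one row per cassette (see
#'   [cassette_rows()]), or any data.frame containing the axis columns.
#' @param axes character vector of grouping columns.
#' @return data.frame with the axis columns plus `count` and `percent`;
#'   attribute `total` carries the cassette total.
#' @export
tabulate_combinations <- function(rows, axes = c("catalytic", "cwb")) {
  stopifnot(is.data.frame(rows))
  if (!nrow(rows)) stopf("cannot tabulate an empty cassette set")
  missing_ax <- setdiff(axes, names(rows))
  if (length(missing_ax))
    stopf("axis column(s) not present: %s", paste(missing_ax, collapse = ", "))
  key <- interaction(rows[axes], drop = TRUE, sep = "\r")
  counts <- table(key)
  parts <- strsplit(names(counts), "\r", fixed = TRUE)
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- axes
  out$count <- as.integer(counts)
  total <- sum(out$count)
  out$percent <- round_half_up2(100 * out$count / total)
  ord <- do.call(order, c(list(-out$count), out[axes]))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total") <- total
  out
}

#' Genome size histogram
#'
#' Left-closed bins of fixed width starting at 0; only populated bins are
#' returned, so counts always sum to the number of genomes.
#'
#' @param genomes list of [genome_record()] objects.
#' @param bin_width_bp positive bin width in bp (default 10000).
#' @return data.frame with columns `bin_start`, `bin_end`, `count`.
#' @export
size_histogram <- function(genomes, bin_width_bp = 10000L) {
  if (bin_width_bp <= 0) stopf("bin_width_bp must be positive")
  lens <- vapply(genomes, `[[`, integer(1), "length_bp")
  if (!length(lens))
    return(data.frame(bin_start = integer(0), bin_end = integer(0),
                      count = integer(0)))
  bin <- floor(lens / bin_width_bp)
  tab <- table(bin)
  starts <- as.integer(names(tab)) * bin_width_bp
  data.frame(bin_start = starts, bin_end = starts + bin_width_bp,
             count = as.integer(tab))
}

#' Assign every genome to its size group
#'
#' @param genomes list of [genome_record()] objects.
#' @return data.frame with columns `accession`, `length_bp`, `group`.
#' @export
group_genomes <- function(genomes) {
  data.frame(accession = vapply(genomes, `[[`, character(1), "accession"),
             length_bp = vapply(genomes, `[[`, integer(1), "length_bp"),
             group = assign_size_group(
               vapply(genomes, `[[`, integer(1), "length_bp")))
}
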