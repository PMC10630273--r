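# Segmentation of endolysins into catalytic region, interdomain linker
# and (known or putative) cell-wall-binding region.

#' Segment an endolysin into catalytic / linker / CWB regions
#'
#' The catalytic region is the first (N-most) catalytic domain span from
#' the protein's architecture. The linker is searched downstream of the
#' catalytic region with [detect_linker()]. The CWB region is the first
#' annotated CWB domain span when one exists; otherwise the unannotated
#' stretch from the linker end (or catalytic end when no linker was
#' found) to the sequence end is reported as a putative unknown CWB
#' (UCWB) candidate when it is at least `min_ucwb_len` residues long.
#' When a known CWB domain exists but lies `min_ucwb_len` or more
#' residues downstream of the linker end, the intervening stretch is
#' additionally reported as a UCWB candidate (`extra_ucwb`).
#'
#' @param arch a `protein_architecture` with role `endolysin`.
#' @param seq the protein's amino-acid sequence.
#' @param min_ucwb_len minimum length for a putative UCWB region
#'   (default 40 aa).
#' @return object of class `endolysin_segmentation`: list with
#'   `protein_id`, `sequence`, `catalytic_region` (list `name`, `start_aa`,
#'   `end_aa`), `linker` (`linker_call` or `NULL`), `cwb_region` (list
#'   `label`, `start_aa`, `end_aa`, `putative`; `NULL` when absent),
#'   `extra_ucwb` (list span or `NULL`), `post_linker_start` (1-based
#'   start of the region C-terminal of the linker, used for CWB-region
#'   comparisons) and `failed` (TRUE for the segmentation-failed marker).
#' @export
segment_endolysin <- function(arch, seq, min_ucwb_len = 40L) {
  if (!inherits(arch, "protein_architecture") || arch$role != "endolysin")
    stopf("segment_endolysin expects an endolysin protein_architecture")
  seq <- sanitize_aa(seq)
  n <- nchar(seq)
  failed <- structure(list(protein_id = arch$protein_id, sequence = seq,
                           catalytic_region = NULL, linker = NULL,
                           cwb_region = NULL, extra_ucwb = NULL,
                           post_linker_start = NA_integer_, failed = TRUE),
                      class = "endolysin_segmentation")
  cat_dom <- arch$domains[arch$domains$category == "catalytic", , drop = FALSE]
  if (!nrow(cat_dom)) {
    # no catalytic anchor: a linker anywhere still permits a partial call
    lk <- detect_linker(seq, 1L, span = max(0L, n - 1L))
    if (is.null(lk)) return(failed)
    catalytic <- NULL
    search_from <- lk$end_aa + 1L
  } else {
    catalytic <- list(name = cat_dom$canonical_name[1],
                      start_aa = cat_dom$start_aa[1],
                      end_aa = cat_dom$end_aa[1])
    lk <- if (catalytic$end_aa < n)
      detect_linker(seq, catalytic$end_aa + 1L) else NULL
    search_from <- if (!is.null(lk)) lk$end_aa + 1L else catalytic$end_aa + 1L
  }
  post_linker_start <- search_from

  cwb_dom <- arch$domains[arch$domains$category == "cwb", , drop = FALSE]
  cwb_region <- NULL; extra_ucwb <- NULL
  if (nrow(cwb_dom)) {
    cwb_region <- list(label = cwb_dom$canonical_name[1],
                       start_aa = cwb_dom$start_aa[1],
                       end_aa = cwb_dom$end_aa[1], putative = FALSE)
    gap <- cwb_region$start_aa - post_linker_start
    if (gap >= min_ucwb_len)
      extra_ucwb <- list(label = "UCWB-candidate",
                         start_aa = post_linker_start,
                         end_aa = cwb_region$start_aa - 1L, putative = TRUE)
  } else if (n - post_linker_start + 1L >= min_ucwb_len) {
    cwb_region <- list(label = "UCWB-candidate", start_aa = post_linker_start,
                       end_aa = n, putative = TRUE)
  }
  structure(list(protein_id = arch$protein_id, sequence = seq,
                 catalytic_region = catalytic, linker = lk,
                 cwb_region = cwb_region, extra_ucwb = extra_ucwb,
                 post_linker_start = post_linker_start, failed = FALSE),
            class = "endolysin_segmentation")
}

#' @export
print.endolysin_segmentation <- function(x, ...) {
  if (x$failed) {
    cat(sprintf("<endolysin_segmentation> %s: segmentation failed\n",
                x$protein_id))
    return(invisible(x))
  }
  catp <- if (is.null(x$catalytic_region)) "absent" else
    sprintf("%s [%d-%d]", x$catalytic_region$name,
            x$catalytic_region$start_aa, x$catalytic_region$end_aa)
  lkp <- if (is.null(x$linker)) "absent" else
    sprintf("[%d-%d] (PK %.2f, d=%d)", x$linker$start_aa, x$linker$end_aa,
            x$linker$pk_fraction, x$linker$motif_distance)
  cwbp <- if (is.null(x$cwb_region)) "absent" else
    sprintf("%s [%d-%d]%s", x$cwb_region$label, x$cwb_region$start_aa,
            x$cwb_region$end_aa, if (x$cwb_region$putative) " (putative)" else "")
  cat(sprintf("<endolysin_segmentation> %s: catalytic %s | linker %s | CWB %s\n",
              x$protein_id, catp, lkp, cwbp))
  invisible(x)
}
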