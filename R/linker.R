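# Detection of the proline/lysine-rich interdomain linker that joins the
# catalytic and cell-wall-binding modules of gram-positive endolysins.

#' Interdomain linker consensus
#'
#' The conserved P/K-rich linker consensus observed between the catalytic
#' and CWB modules of Amidase_2 endolysins.
#' @export
LINKER_CONSENSUS <- "KPTKPPSKPPPKP"

pk_fraction <- function(window) {
  ch <- strsplit(window, "")[[1]]
  mean(ch %in% c("P", "K"))
}

#' Detect a P/K-rich interdomain linker
#'
#' Two complementary criteria are evaluated over windows whose start lies
#' in `[search_start, search_start + span]`:
#' composition — windows of length 12-16 with a proline+lysine fraction
#' >= `pk_threshold`, the best window extended maximally through
#' contiguous P/K flanks (so the fraction never drops below threshold);
#' and
#' motif — any substring of length 10-16 within edit distance
#' <= `motif_tol` of the consensus `KPTKPPSKPPPKP`. Each criterion scores
#' its candidate (composition: the P/K fraction; motif:
#' `(13 - distance) / 13`) and the higher-scoring call is reported, the
#' motif winning ties as the more specific evidence.
#'
#' @param seq amino-acid string.
#' @param search_start 1-based position from which windows may start.
#' @param span how far beyond `search_start` window starts may lie
#'   (default 80 residues).
#' @param pk_threshold minimum P+K fraction for a composition call
#'   (default 0.5).
#' @param motif_tol maximum edit distance to the consensus (default 3).
#' @return `NULL` when no window qualifies, else a `linker_call`: list
#'   with `start_aa`, `end_aa` (1-based inclusive), `pk_fraction`,
#'   `motif_distance` (edit distance of the called window to the
#'   consensus).
#' @export
detect_linker <- function(seq, search_start = 1L, span = 80L,
                          pk_threshold = 0.5, motif_tol = 3L) {
  seq <- sanitize_aa(seq)
  n <- nchar(seq)
  if (search_start < 1L || search_start > n)
    stopf("search_start %d outside sequence of length %d", search_start, n)
  last_start <- min(n, search_start + span)
  starts <- seq.int(search_start, last_start)

  # --- composition criterion -------------------------------------------
  best_pk <- NULL
  for (s in starts) {
    for (w in 12:16) {
      e <- s + w - 1L
      if (e > n) next
      f <- pk_fraction(substr(seq, s, e))
      if (f >= pk_threshold &&
          (is.null(best_pk) || f > best_pk$f + 1e-12)) best_pk <- list(s = s, e = e, f = f)
    }
  }
  if (!is.null(best_pk)) {
    # extend through contiguous P/K flanks; only residues that keep the
    # window at or above the threshold (i.e. P/K themselves) are absorbed,
    # so the call never dilutes into the neighbouring domain
    s <- best_pk$s; e <- best_pk$e
    while (e < n && substr(seq, e + 1L, e + 1L) %in% c("P", "K")) e <- e + 1L
    while (s > 1L && substr(seq, s - 1L, s - 1L) %in% c("P", "K")) s <- s - 1L
    best_pk <- list(s = s, e = e, f = pk_fraction(substr(seq, s, e)))
  }

  # --- motif criterion --------------------------------------------------
  best_motif <- NULL
  for (s in starts) {
    for (w in 10:16) {
      e <- s + w - 1L
      if (e > n) next
      d <- utils::adist(substr(seq, s, e), LINKER_CONSENSUS)[1, 1]
      if (d <= motif_tol &&
          (is.null(best_motif) || d < best_motif$d)) best_motif <- list(s = s, e = e, d = d)
    }
  }

  score_pk <- if (is.null(best_pk)) -Inf else best_pk$f
  score_motif <- if (is.null(best_motif)) -Inf else
    (nchar(LINKER_CONSENSUS) - best_motif$d) / nchar(LINKER_CONSENSUS)
  if (!is.finite(score_pk) && !is.finite(score_motif)) return(NULL)

  if (score_motif >= score_pk) {
    call <- list(start_aa = best_motif$s, end_aa = best_motif$e,
                 pk_fraction = pk_fraction(substr(seq, best_motif$s, best_motif$e)),
                 motif_distance = as.integer(best_motif$d))
  } else {
    win <- substr(seq, best_pk$s, best_pk$e)
    call <- list(start_aa = best_pk$s, end_aa = best_pk$e,
                 pk_fraction = best_pk$f,
                 motif_distance = as.integer(utils::adist(win, LINKER_CONSENSUS)[1, 1]))
  }
  structure(call, class = "linker_call")
}
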