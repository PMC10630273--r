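# shared internal helpers

AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Round half away from zero to two decimals
#'
#' Percentages in report tables are rounded half-away-from-zero, the
#' convention under which 32.748538... prints as 32.75. `base::round`
#' rounds half to even and is not suitable for table output.
#'
#' @param x numeric vector.
#' @return numeric vector rounded to two decimals.
#' @keywords internal
round_half_up2 <- function(x) {
  # tiny epsilon guards against representation error just below .xx5
  sign(x) * floor(abs(x) * 100 + 0.5 + 1e-9) / 100
}

# replace residues outside the 20 standard amino acids (plus X) with X
sanitize_aa <- function(seq) {
  toupper(gsub(sprintf("[^%sX]", paste(AA_STANDARD, collapse = "")), "X",
               toupper(seq)))
}

is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
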