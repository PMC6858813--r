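#' Round half away from zero
#'
#' Commercial ("half-up") rounding at a fixed number of decimal digits, with
#' ties carried away from zero, so that `6.75 -> 6.8` and `-121.8 -> -122`.
#' This is the reporting rule used for compaction ratios (1 decimal) and mean
#' free energies (integer kJ/mole); base [round()] uses IEEE round-half-even
#' and would disagree on exact ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep.
#' @return numeric vector of the same length as `x`.
#' @examples
#' round_half_up(6.75, 1)
#' round_half_up(-110.5)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# levels of the transcript-region factor, 5' to 3'
region_levels <- function() c("5UTR", "CDS", "3UTR")

as_region <- function(x) {
  x <- toupper(as.character(x))
  x[x %in% c("UTR5", "5'UTR", "5UTR")] <- "5UTR"
  x[x %in% c("UTR3", "3'UTR", "3UTR")] <- "3UTR"
  bad <- setdiff(unique(x), region_levels())
  if (length(bad) > 0) {
    abort(sprintf("unknown region label(s): %s", paste(bad, collapse = ", ")))
  }
  factor(x, levels = region_levels())
}

stopifnot_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi))
  }
  invisible(x)
}
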