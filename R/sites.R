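# Binding-site representation and the grouped ("(n)  a / b") notation used
# by printed site tables: a run of n equally spaced starts is written once
# with its multiplicity and the start/energy/ratio endpoints.

#' Expand a grouped site row into individual starts
#'
#' A group `(n) start_lo / start_hi` denotes `n` sites whose starts form an
#' arithmetic progression from `start_lo` to `start_hi`. When the span is
#' not divisible by `n - 1` no exact integer step exists; by default the
#' starts are then placed evenly and rounded to integers (endpoints kept
#' exact) with a warning, while `strict = TRUE` raises a format error.
#'
#' @param n multiplicity (>= 1).
#' @param start_lo,start_hi first and last start (nt); equal when `n == 1`.
#' @param strict error on a non-integral step instead of rounding.
#' @param label group label used in messages.
#' @return integer vector of `n` starts.
#' @examples
#' expand_group(6, 1190, 1200)
#' expand_group(9, 1896, 1920)
#' @export
expand_group <- function(n, start_lo, start_hi, strict = FALSE, label = NULL) {
  n <- as.integer(n)
  if (n < 1) abort("group multiplicity must be >= 1")
  if (n == 1) {
    if (start_lo != start_hi) abort("single-site group with a start range")
    return(as.integer(start_lo))
  }
  if (start_hi <= start_lo) abort("group start range must increase")
  d <- (start_hi - start_lo) / (n - 1)
  if (d != floor(d)) {
    msg <- sprintf(
      "group %s: span %d over %d sites has no integer step; spacing evenly",
      label %||% sprintf("(%d) %d / %d", n, start_lo, start_hi),
      start_hi - start_lo, n
    )
    if (strict) abort(msg)
    warn(msg)
    return(as.integer(round(seq(start_lo, start_hi, length.out = n))))
  }
  as.integer(seq(start_lo, start_hi, by = d))
}

#' Compress equally spaced starts into groups
#'
#' Inverse of [expand_group()]: a greedy left-to-right scan over sorted
#' starts extends the current run while the consecutive difference stays
#' constant, so maximal equal-step runs become one group each and
#' `group_starts(expand_group(...))` recovers the original group.
#'
#' @param starts integer vector of site starts (one miRNA, one table block).
#' @return tibble with one row per group: `group`, `n`, `start_lo`,
#'   `start_hi`, `step` (NA for singletons), and `idx` (list column of
#'   positions into the sorted starts).
#' @examples
#' group_starts(c(16, 19, 22, 25))
#' group_starts(c(10, 12, 15))
#' @export
group_starts <- function(starts) {
  s <- sort(as.integer(starts))
  n <- length(s)
  groups <- list()
  i <- 1L
  while (i <= n) {
    if (i == n) {
      groups[[length(groups) + 1L]] <- list(idx = i, step = NA_integer_)
      break
    }
    d <- s[i + 1L] - s[i]
    j <- i + 1L
    while (j < n && s[j + 1L] - s[j] == d) j <- j + 1L
    if (j - i >= 1L && d > 0L) {
      groups[[length(groups) + 1L]] <- list(idx = i:j, step = d)
      i <- j + 1L
    } else {
      # duplicate starts never merge into one printed group
      groups[[length(groups) + 1L]] <- list(idx = i, step = NA_integer_)
      i <- i + 1L
    }
  }
  tibble(
    group = seq_along(groups),
    n = vapply(groups, function(g) length(g$idx), integer(1)),
    start_lo = vapply(groups, function(g) s[g$idx[1]], integer(1)),
    start_hi = vapply(groups, function(g) s[g$idx[length(g$idx)]], integer(1)),
    step = vapply(groups, function(g) if (length(g$idx) > 1) g$step else NA_integer_, integer(1)),
    idx = lapply(groups, function(g) g$idx)
  )
}

#' Assign mRNA regions to scanned sites
#'
#' Labels each site with the region (`5UTR`, `CDS`, `3UTR`) containing its
#' start nucleotide; a site straddling a region boundary is assigned by its
#' start.
#'
#' @param sites tibble with `transcript_id` and `start`.
#' @param transcripts tibble with `transcript_id` and region lengths
#'   (`utr5_len`, `cds_len`, `utr3_len`).
#' @return `sites` with its `region` column (re)computed.
#' @export
annotate_sites <- function(sites, transcripts) {
  ann <- select(transcripts, "transcript_id", "utr5_len", "cds_len", "utr3_len")
  miss <- setdiff(unique(sites$transcript_id), ann$transcript_id)
  if (length(miss) > 0) {
    abort(sprintf("no region annotation for transcript(s): %s", paste(miss, collapse = ", ")))
  }
  out <- sites
  out$region <- NULL
  out <- out |>
    left_join(ann, by = "transcript_id") |>
    mutate(region = position_region(
      .data$start, .data$utr5_len, .data$cds_len, .data$utr3_len
    )) |>
    select(-"utr5_len", -"cds_len", -"utr3_len")
  class(out) <- class(sites)
  out
}
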