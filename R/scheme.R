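# Text rendering of duplex interaction schemes: the mRNA window on top
# (5'->3'), the miRNA beneath written 3'->5' so paired bases align, and a
# marker line between them ('|' canonical pair, ':' one-bond non-canonical
# pair, ' ' unpaired).

#' Render a duplex alignment as a text scheme
#'
#' @param a a `mir_duplex` object from [align_at()], or a one-row
#'   [scan_sites()] tibble together with `mirnas`/`transcripts` to rebuild
#'   the alignment.
#' @param region optional region label shown in the header.
#' @return character vector of lines (header, mRNA strand, marker line,
#'   miRNA strand).
#' @examples
#' cat(render_scheme(align_at("UGG", "CCG", 1)), sep = "\n")
#' @export
render_scheme <- function(a, region = NULL) {
  stopifnot(inherits(a, "mir_duplex"))
  marker <- vapply(a$bond_vector, function(b) {
    if (b >= 2L) "|" else if (b == 1L) ":" else " "
  }, character(1))
  header <- sprintf(
    "%s  region=%s  start=%d  dG=%d kJ/mole  dG/dGm=%d%%  length=%d nt",
    a$mirna_id, if (is.null(region) || is.na(region)) "NA" else as.character(region),
    a$start, as.integer(round_half_up(a$delta_g)), a$ratio_pct, a$length
  )
  c(
    header,
    sprintf("5' %s 3'  mRNA (%s)", a$window, a$transcript_id),
    sprintf("   %s", paste(marker, collapse = "")),
    sprintf("3' %s 5'  miRNA", paste(rev(strsplit(a$mirna, "")[[1]]), collapse = ""))
  )
}

#' Parse a rendered scheme header back into its fields
#'
#' Round-trip companion of [render_scheme()]; recovers the miRNA id, region,
#' start, reported free energy, ratio and length from the header line.
#'
#' @param lines character vector as returned by [render_scheme()].
#' @return one-row tibble with `mirna_id`, `region`, `start`, `delta_g`,
#'   `ratio_pct`, `length`.
#' @export
parse_scheme <- function(lines) {
  h <- lines[1]
  m <- regmatches(h, regexec(
    "^(\\S+)  region=(\\S+)  start=(-?\\d+)  dG=(-?\\d+) kJ/mole  dG/dGm=(\\d+)%  length=(\\d+) nt$",
    h
  ))[[1]]
  if (length(m) == 0) abort("not a rendered duplex scheme header")
  tibble(
    mirna_id = m[2],
    region = if (m[3] == "NA") NA_character_ else m[3],
    start = as.integer(m[4]),
    delta_g = as.numeric(m[5]),
    ratio_pct = as.integer(m[6]),
    length = as.integer(m[7])
  )
}

#' Render schemes for scanned sites
#'
#' Rebuilds each site's alignment from the sequences and renders it with
#' [render_scheme()].
#'
#' @param sites tibble from [scan_sites()] (or any tibble with `mirna_id`,
#'   `transcript_id`, `start`, `region`).
#' @param mirnas,transcripts sequence tibbles as given to [scan_sites()].
#' @param em an [energy_model()].
#' @return character vector of lines, schemes separated by blank lines.
#' @export
render_site_schemes <- function(sites, mirnas, transcripts, em = energy_model()) {
  out <- purrr::pmap(
    list(sites$mirna_id, sites$transcript_id, sites$start, as.character(sites$region)),
    function(mid, tid, start, region) {
      mi <- mirnas$sequence[match(mid, mirnas$mirna_id)]
      tx <- transcripts$sequence[match(tid, transcripts$transcript_id)]
      if (is.na(mi) || is.na(tx)) abort(sprintf("unknown sequence for %s / %s", mid, tid))
      c(render_scheme(
        align_at(mi, tx, start, em = em, mirna_id = mid, transcript_id = tid),
        region = region
      ), "")
    }
  )
  unlist(out)
}
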