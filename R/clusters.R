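# Cluster detection and compaction statistics. A cluster is a maximal set of
# binding sites whose occupied intervals [start, start+length-1] overlap
# transitively (connected components of the interval-overlap graph); sites
# that merely abut (gap 0, no shared nucleotide) do not cluster. The span
# convention last = max(start + length), span = last - first + 1 is the one
# that reproduces published cluster sizes (e.g. sites from 16 nt with final
# coverage through 54 nt are reported as a 16-55 nt cluster of size 40).

#' Group binding sites into overlap clusters
#'
#' Finds connected components of the interval-overlap graph within each
#' transcript (and region, matching how site tables are organized per
#' region block) and labels each site with a cluster id. Overlap requires
#' at least one shared nucleotide; the result does not depend on input
#' order (clusters are numbered by leftmost start).
#'
#' @param sites a `mir_sites` tibble (expanded: one row per site) with
#'   `transcript_id`, `region`, `start`, `length`.
#' @param by columns that delimit clustering groups; defaults to transcript
#'   and region.
#' @return `sites` with columns `cluster_id` (integer, unique within `by`
#'   group) and `singleton` (logical).
#' @export
find_clusters <- function(sites, by = c("transcript_id", "region")) {
  by <- intersect(by, names(sites))
  if (nrow(sites) == 0) {
    out <- sites
    out$cluster_id <- integer(0)
    out$singleton <- logical(0)
    return(out)
  }
  key <- do.call(paste, c(lapply(by, function(col) as.character(sites[[col]])), sep = "\r"))
  out <- sites
  out$cluster_id <- NA_integer_
  for (k in unique(key)) {
    idx <- which(key == k)
    ir <- IRanges::IRanges(start = sites$start[idx], width = sites$length[idx])
    merged <- IRanges::reduce(ir, min.gapwidth = 0L)  # merge only true overlaps
    hits <- IRanges::findOverlaps(ir, merged, minoverlap = 1L)
    out$cluster_id[idx] <- S4Vectors::subjectHits(hits)
  }
  out |>
    group_by(dplyr::across(dplyr::all_of(by)), .data$cluster_id) |>
    mutate(singleton = n() == 1L) |>
    ungroup()
}

#' Compaction statistics per cluster
#'
#' For every cluster: the number of sites and distinct miRNAs, the total
#' site length (summed with multiplicity, nt), the first start and
#' `last = max(start + length)`, the span `last - first + 1` (nt), the
#' compaction ratio `total / span` (how many times overlapping shrinks the
#' footprint; 1 decimal, half away from zero) and the mean per-site free
#' energy (integer kJ/mole, half away from zero; sites expanded from ranged
#' table rows carry their endpoint mean). Span, compaction and mean energy
#' are reported only for proper clusters; singletons keep their total
#' length and are flagged.
#'
#' @param sites output of [find_clusters()]; columns `delta_g` and
#'   `mirna_id` are used when present.
#' @param by grouping columns, as in [find_clusters()].
#' @return tibble of class `mir_cluster_stats`, one row per cluster, with
#'   `gene` (if present), `by` columns, `cluster_id`, `n_sites`,
#'   `n_mirnas`, `first`, `last`, `span`, `total_len`, `compaction`,
#'   `mean_dg`, `singleton`.
#' @export
cluster_stats <- function(sites, by = c("transcript_id", "region")) {
  by <- intersect(by, names(sites))
  if (!"cluster_id" %in% names(sites)) sites <- find_clusters(sites, by = by)
  extra <- intersect("gene", setdiff(names(sites), by))
  if (nrow(sites) == 0) {
    out <- as_tibble(sites)[, c(extra, by)]
    out$cluster_id <- integer(0)
    out$n_sites <- integer(0)
    out$n_mirnas <- integer(0)
    out$first <- integer(0)
    out$last <- integer(0)
    out$span <- integer(0)
    out$total_len <- integer(0)
    out$compaction <- numeric(0)
    out$mean_dg <- numeric(0)
    out$mean_dg_raw <- numeric(0)
    out$singleton <- logical(0)
    out <- out[, c(
      extra, by, "cluster_id", "n_sites", "n_mirnas", "first", "last",
      "span", "total_len", "compaction", "mean_dg", "mean_dg_raw", "singleton"
    )]
    class(out) <- c("mir_cluster_stats", class(out))
    return(out)
  }
  out <- sites |>
    group_by(dplyr::across(dplyr::all_of(c(extra, by))), .data$cluster_id) |>
    summarise(
      n_sites = n(),
      n_mirnas = if ("mirna_id" %in% names(sites)) n_distinct(.data$mirna_id) else NA_integer_,
      first = min(.data$start),
      last = max(.data$start + .data$length),
      total_len = sum(.data$length),
      mean_dg_raw = if ("delta_g" %in% names(sites)) mean(.data$delta_g) else NA_real_,
      .groups = "drop"
    ) |>
    mutate(
      singleton = .data$n_sites == 1L,
      span = ifelse(.data$singleton, NA_integer_, .data$last - .data$first + 1L),
      compaction = ifelse(
        .data$singleton, NA_real_,
        round_half_up(.data$total_len / .data$span, 1)
      ),
      mean_dg = ifelse(.data$singleton, NA_real_, round_half_up(.data$mean_dg_raw))
    ) |>
    select(
      dplyr::all_of(c(extra, by)), "cluster_id", "n_sites", "n_mirnas",
      "first", "last", "span", "total_len", "compaction", "mean_dg",
      "mean_dg_raw", "singleton"
    ) |>
    arrange(dplyr::across(dplyr::all_of(c(extra, by))), .data$first)
  class(out) <- c("mir_cluster_stats", class(out))
  out
}

#' Per-region binding-site footprint summary
#'
#' Aggregates cluster statistics per transcript region: the footprint
#' actually occupied by binding (sum of cluster spans; singletons contribute
#' their site length), the total summed site length, their ratio (overall
#' compaction, 1 decimal), and counts of clusters, sites and miRNAs. When
#' region lengths are supplied the footprint is also expressed as a
#' fraction of the region.
#'
#' @param sites output of [find_clusters()] (cluster ids are computed if
#'   missing).
#' @param region_lengths optional tibble with `gene` (or `transcript_id`),
#'   `region` and `region_len` (nt).
#' @param by grouping columns shared by sites in one region block.
#' @return tibble with one row per (group, region): `n_clusters`,
#'   `n_sites`, `n_mirnas`, `footprint`, `total_len`, `compaction`,
#'   `region_len`, `footprint_frac`.
#' @export
region_summary <- function(sites, region_lengths = NULL, by = c("transcript_id", "region")) {
  stats <- cluster_stats(sites, by = by)
  grp <- intersect(c("gene", by), names(stats))
  out <- stats |>
    group_by(dplyr::across(dplyr::all_of(grp))) |>
    summarise(
      n_clusters = n(),
      mean_dg = round_half_up(
        sum(.data$mean_dg_raw * .data$n_sites) / sum(.data$n_sites)
      ),
      n_sites = sum(.data$n_sites),
      n_mirnas = sum(.data$n_mirnas),
      footprint = sum(ifelse(.data$singleton, .data$total_len, .data$span)),
      total_len = sum(.data$total_len),
      .groups = "drop"
    ) |>
    mutate(compaction = round_half_up(.data$total_len / .data$footprint, 1))
  if (!is.null(region_lengths)) {
    join_by <- intersect(c("gene", "transcript_id", "region"), intersect(names(out), names(region_lengths)))
    out <- out |>
      left_join(
        mutate(region_lengths, region = as_region(.data$region)),
        by = join_by
      ) |>
      mutate(footprint_frac = .data$footprint / .data$region_len)
    bad <- !is.na(out$region_len) & out$region_len == 0 & out$n_sites > 0
    if (any(bad)) {
      abort(sprintf(
        "sites fall in a zero-length region: %s",
        paste(out$gene[bad] %||% out$transcript_id[bad], collapse = ", ")
      ))
    }
  }
  out
}

#' Full cluster analysis of a site list
#'
#' Convenience wrapper running [find_clusters()], [cluster_stats()] and
#' [region_summary()] and keeping the pieces together; [tidy()] returns the
#' per-cluster table, [glance()] a one-row summary and [autoplot()] the
#' site/cluster map.
#'
#' @param sites a `mir_sites` tibble (expanded sites).
#' @param region_lengths optional, see [region_summary()].
#' @param by clustering group columns.
#' @return object of class `mir_cluster_analysis`: list with `sites`
#'   (cluster-labelled), `clusters`, `regions`.
#' @export
cluster_analysis <- function(sites, region_lengths = NULL, by = c("transcript_id", "region")) {
  labelled <- find_clusters(sites, by = by)
  structure(list(
    sites = labelled,
    clusters = cluster_stats(labelled, by = by),
    regions = region_summary(labelled, region_lengths = region_lengths, by = by)
  ), class = "mir_cluster_analysis")
}

#' @export
print.mir_cluster_analysis <- function(x, ...) {
  cat(sprintf(
    "miRNA binding-site cluster analysis: %d sites, %d clusters (%d singletons)\n",
    nrow(x$sites), nrow(x$clusters), sum(x$clusters$singleton)
  ))
  print(as_tibble(x$clusters), ...)
  invisible(x)
}

#' @rdname cluster_analysis
#' @param x a `mir_cluster_analysis` object.
#' @param ... unused.
#' @export
tidy.mir_cluster_analysis <- function(x, ...) as_tibble(x$clusters)

#' @rdname cluster_analysis
#' @export
glance.mir_cluster_analysis <- function(x, ...) {
  proper <- filter(x$clusters, !.data$singleton)
  tibble(
    n_sites = nrow(x$sites),
    n_mirnas = n_distinct(x$sites$mirna_id),
    n_clusters = nrow(x$clusters),
    n_singletons = sum(x$clusters$singleton),
    total_len = sum(x$clusters$total_len),
    footprint = sum(ifelse(x$clusters$singleton, x$clusters$total_len, x$clusters$span)),
    mean_compaction = if (nrow(proper) > 0) round_half_up(mean(proper$compaction), 1) else NA_real_
  )
}

#' Monospace map of a cluster
#'
#' Draws one text row per site (dashes over its occupied interval) above a
#' coordinate ruler, the text analogue of the published cluster location
#' diagrams.
#'
#' @param sites cluster-labelled sites (one cluster's rows are selected via
#'   `cluster` and the `by` columns of the first row, or pass a pre-filtered
#'   tibble and leave `cluster` NULL).
#' @param cluster optional cluster id to select.
#' @param width total character width of the map.
#' @return character vector of lines.
#' @export
render_cluster_map <- function(sites, cluster = NULL, width = 72) {
  x <- sites
  if (!is.null(cluster)) x <- filter(x, .data$cluster_id == cluster)
  if (nrow(x) == 0) abort("no sites to draw")
  lo <- min(x$start)
  hi <- max(x$start + x$length - 1)
  scale <- (hi - lo + 1) / width
  col <- function(pos) pmax(1L, pmin(width, as.integer(ceiling((pos - lo + 1) / scale))))
  label_w <- max(nchar(x$mirna_id)) + 2L
  lines <- purrr::pmap_chr(
    list(x$mirna_id, x$start, x$length),
    function(id, s, len) {
      c1 <- col(s)
      c2 <- col(s + len - 1L)
      bar <- strrep(" ", c1 - 1L)
      bar <- paste0(bar, strrep("-", c2 - c1 + 1L))
      sprintf("%-*s %s", label_w, id, bar)
    }
  )
  ruler <- sprintf(
    "%-*s %s", label_w, "",
    paste0(lo, strrep(".", max(1L, width - nchar(lo) - nchar(hi))), hi)
  )
  c(lines, ruler)
}

#' Plot scanned sites and their clusters
#'
#' @param object a `mir_cluster_analysis`.
#' @param ... unused.
#' @return a ggplot: one horizontal segment per site over transcript
#'   coordinates, coloured by miRNA, faceted by transcript/region, with
#'   cluster spans shaded.
#' @export
autoplot.mir_cluster_analysis <- function(object, ...) {
  x <- object$sites |>
    mutate(.site = factor(row_number()))
  spans <- filter(object$clusters, !.data$singleton)
  p <- ggplot2::ggplot(x)
  if (nrow(spans) > 0) {
    p <- p + ggplot2::geom_rect(
      data = spans,
      ggplot2::aes(xmin = .data$first, xmax = .data$last, ymin = -Inf, ymax = Inf),
      fill = "grey85", alpha = 0.6
    )
  }
  p +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$start, xend = .data$start + .data$length - 1,
        y = .data$.site, yend = .data$.site, colour = .data$mirna_id
      ),
      linewidth = 2
    ) +
    ggplot2::facet_wrap(
      intersect(c("transcript_id", "region"), names(x)),
      scales = "free", labeller = ggplot2::label_both
    ) +
    ggplot2::labs(
      x = "transcript position (nt)", y = NULL, colour = "miRNA",
      title = "miRNA binding sites and overlap clusters"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot the dG/dGm profile of one miRNA along a transcript
#'
#' @param mirna_seq,transcript_seq sequences (RNA, 5'->3').
#' @param threshold_pct horizontal reference line (default 87).
#' @return a ggplot of the exact ratio at every start.
#' @export
plot_ratio_profile <- function(mirna_seq, transcript_seq, threshold_pct = 87) {
  mi <- encode_bases(normalize_rna(mirna_seq))
  tx <- encode_bases(normalize_rna(transcript_seq))
  totals <- scan_bond_totals(mi, tx)
  df <- tibble(start = seq_along(totals), ratio = 100 * totals / max_bonds(mirna_seq))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start, y = .data$ratio)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_hline(yintercept = threshold_pct, linetype = 2, colour = "firebrick") +
    ggplot2::labs(
      x = "window start (nt)", y = "dG/dGm (%)",
      title = "Duplex energy ratio along the transcript"
    ) +
    ggplot2::theme_minimal()
}
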