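# Bundled example site tables: characteristics of predicted miRNA binding
# sites in mRNAs of breast-cancer subtype candidate genes (triple-negative,
# luminal A/B, HER2), in the printed-table dialect. They exercise the whole
# table -> sites -> clusters pipeline without any sequence data.

#' Paths to the bundled breast-cancer site tables
#'
#' @param subtype one of `"triple_negative"`, `"luminal_ab"`, `"her2"`.
#' @return path to the packaged TSV.
#' @export
bc_table_path <- function(subtype = c("triple_negative", "luminal_ab", "her2")) {
  subtype <- match.arg(subtype)
  f <- c(
    triple_negative = "sites_triple_negative.tsv",
    luminal_ab = "sites_luminal_ab.tsv",
    her2 = "sites_her2.tsv"
  )[[subtype]]
  system.file("extdata", f, package = "mirclust", mustWork = TRUE)
}

#' Load a bundled breast-cancer site table as expanded sites
#'
#' @inheritParams bc_table_path
#' @param ... passed to [read_site_table()].
#' @return expanded `mir_sites` tibble.
#' @export
bc_sites <- function(subtype = c("triple_negative", "luminal_ab", "her2"), ...) {
  suppressWarnings(read_site_table(bc_table_path(subtype), ...))
}

#' Region lengths quoted for the bundled tables
#'
#' The 5'UTR/CDS/3'UTR lengths that are known for the genes in the bundled
#' tables (e.g. a 142-nt 5'UTR for CBL, a 498-nt 3'UTR for SFN, no 5'UTR
#' for ITGB1), for use with [region_summary()].
#'
#' @return tibble with `gene`, `region`, `region_len`.
#' @export
bc_region_lengths <- function() {
  readr::read_tsv(
    system.file("extdata", "bc_region_lengths.tsv", package = "mirclust", mustWork = TRUE),
    show_col_types = FALSE, progress = FALSE
  ) |>
    mutate(region = as_region(.data$region))
}

# table-oddity spelling variants -> canonical miRNA ids, for cross-reference
# between table rows and running-text mentions
.mirna_id_aliases <- c(
  "D00436.3p-miR" = "ID00436.3p-miR",
  "D00915.3p-miR" = "ID00915.3p-miR",
  "ID0296.3p-miR" = "ID00296.3p-miR"
)

#' Normalize miRNA identifier spelling variants
#'
#' Printed tables contain a few identifier variants (a dropped "I" or "0");
#' this maps them to their canonical form while leaving all other ids
#' untouched. Parsing keeps table spellings verbatim; apply this only when
#' cross-referencing.
#'
#' @param id character vector of miRNA ids.
#' @return character vector with known variants replaced.
#' @export
normalize_mirna_id <- function(id) {
  hit <- id %in% names(.mirna_id_aliases)
  id[hit] <- .mirna_id_aliases[id[hit]]
  id
}

#' Recompute cluster statistics from a printed-style site table
#'
#' Runs the full cluster pipeline on table-derived sites, per (gene, region)
#' block: clusters, spans, total site lengths, compaction ratios and mean
#' free energies, plus a per-region footprint summary.
#'
#' @param sites expanded sites from [read_site_table()] / [bc_sites()].
#' @param region_lengths optional tibble (`gene`, `region`, `region_len`).
#' @return a `mir_cluster_analysis` object (see [cluster_analysis()]).
#' @export
recompute_table_stats <- function(sites, region_lengths = NULL) {
  cluster_analysis(sites, region_lengths = region_lengths, by = c("gene", "region"))
}

#' Human-readable prose-statistics block for a table
#'
#' @param analysis a `mir_cluster_analysis` from [recompute_table_stats()].
#' @return character vector of report lines (one per cluster and one per
#'   region).
#' @export
format_table_report <- function(analysis) {
  cl <- analysis$clusters
  cl_lines <- purrr::pmap_chr(
    as.list(cl[c("gene", "region", "cluster_id", "n_sites", "n_mirnas",
                 "first", "last", "span", "total_len", "compaction", "mean_dg",
                 "singleton")]),
    function(gene, region, cluster_id, n_sites, n_mirnas, first, last, span,
             total_len, compaction, mean_dg, singleton) {
      if (singleton) {
        sprintf(
          "%s %s cluster %d: singleton site at %d nt, length %d nt",
          gene, region, cluster_id, first, total_len
        )
      } else {
        sprintf(
          "%s %s cluster %d: %d sites of %d miRNAs from %d nt to %d nt; span %d nt, total site length %d nt, compaction %.1f, mean dG %d kJ/mole",
          gene, region, cluster_id, n_sites, n_mirnas, first, last, span,
          total_len, compaction, as.integer(mean_dg)
        )
      }
    }
  )
  rg <- analysis$regions
  rg_lines <- purrr::pmap_chr(
    as.list(rg[c("gene", "region", "n_clusters", "n_sites", "footprint",
                 "total_len", "compaction")]),
    function(gene, region, n_clusters, n_sites, footprint, total_len, compaction) {
      sprintf(
        "%s %s: %d cluster(s), %d sites; footprint %d nt, total site length %d nt, overall compaction %.1f",
        gene, region, n_clusters, n_sites, footprint, total_len, compaction
      )
    }
  )
  c(cl_lines, "", rg_lines)
}
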