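# Printed-style site tables: a TSV dialect mirroring published site tables.
# Columns: gene, rpkm, region, mirna, start_spec, dg_spec, ratio_spec,
# length. gene/rpkm/region are stated once per block and carried down;
# "mirna (n)" marks a group of n sites; "a ÷ b" gives the first/last value
# of a parameter over the group. Thousands separators ("1,190") and the
# typographic minus are accepted on input and never emitted.

# "a ÷ b" | "a" -> c(lo, hi); accepts "−", commas, and missing spaces
parse_spec_range <- function(x) {
  x <- gsub(",", "", gsub("−", "-", trimws(x)))
  parts <- trimws(strsplit(x, "÷", fixed = TRUE)[[1]])
  if (!length(parts) %in% c(1, 2) || anyNA(suppressWarnings(as.numeric(parts)))) {
    abort(sprintf("cannot parse range specification '%s'", x))
  }
  v <- as.numeric(parts)
  c(v[1], v[length(v)])
}

format_spec_range <- function(lo, hi, digits = 0) {
  f <- function(v) format(round(v, digits), scientific = FALSE, trim = TRUE)
  ifelse(lo == hi, f(lo), paste0(f(lo), " ÷ ", f(hi)))
}

#' Parse a printed-style site table into expanded sites
#'
#' Reads the block-structured TSV dialect described above and expands every
#' grouped row via [expand_group()], so the result has one row per binding
#' site. Ranged free energies and ratios contribute their endpoint mean to
#' every expanded site (`delta_g`, `ratio`); the endpoints themselves are
#' kept (`dg_lo`, `dg_hi`, `ratio_lo`, `ratio_hi`) so the table can be
#' written back without loss.
#'
#' @param path TSV path with header
#'   `gene rpkm region mirna start_spec dg_spec ratio_spec length`.
#' @param strict passed to [expand_group()].
#' @return tibble of class `mir_sites`, one row per site, with columns
#'   `gene`, `rpkm`, `region`, `mirna_id`, `transcript_id` (= gene),
#'   `start`, `length`, `delta_g`, `ratio`, `ratio_pct`, plus group
#'   bookkeeping (`block`, `group_id`, `group_n`, `start_lo`, `start_hi`,
#'   `dg_lo`, `dg_hi`, `ratio_lo`, `ratio_hi`, `rpkm_spec`).
#' @export
read_site_table <- function(path, strict = FALSE) {
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  need <- c("gene", "rpkm", "region", "mirna", "start_spec", "dg_spec", "ratio_spec", "length")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(sprintf("site table %s lacks column(s): %s", path, paste(miss, collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    return(empty_parsed_sites())
  }
  blank <- function(x) is.na(x) | trimws(x) == ""
  # carry gene/rpkm/region down from block headers; a non-blank gene cell
  # starts a new block, and rpkm never leaks across block boundaries (a
  # block may genuinely have no expression value)
  gene <- raw$gene
  rpkm_spec <- raw$rpkm
  region <- raw$region
  is_start <- !blank(gene)
  if (!is_start[1]) abort(sprintf("site table %s: first row lacks a block header", path))
  if (any(is_start & blank(region))) {
    abort(sprintf("site table %s: block header row without a region label", path))
  }
  block <- cumsum(is_start)
  for (i in seq_len(nrow(raw))[-1]) {
    if (!is_start[i]) {
      gene[i] <- gene[i - 1]
      if (blank(rpkm_spec[i])) rpkm_spec[i] <- rpkm_spec[i - 1]
      if (blank(region[i])) region[i] <- region[i - 1]
    }
  }

  rows <- purrr::map(seq_len(nrow(raw)), function(i) {
    mirna_cell <- trimws(raw$mirna[i])
    m <- regmatches(mirna_cell, regexec("^(.*?)\\s*\\((\\d+)\\)$", mirna_cell))[[1]]
    if (length(m) == 3) {
      mirna_id <- m[2]
      n <- as.integer(m[3])
    } else {
      mirna_id <- mirna_cell
      n <- 1L
    }
    sr <- tryCatch(parse_spec_range(raw$start_spec[i]),
      error = function(e) abort(sprintf("row %d of %s: %s", i, path, conditionMessage(e)))
    )
    dg <- parse_spec_range(raw$dg_spec[i])
    rr <- parse_spec_range(raw$ratio_spec[i])
    len <- suppressWarnings(as.integer(raw$length[i]))
    if (is.na(len) || len < 1) abort(sprintf("row %d of %s: bad length '%s'", i, path, raw$length[i]))
    starts <- tryCatch(
      expand_group(n, as.integer(sr[1]), as.integer(sr[2]), strict = strict,
                   label = sprintf("%s row %d", mirna_id, i)),
      error = function(e) abort(sprintf("row %d of %s: %s", i, path, conditionMessage(e)))
    )
    tibble(
      gene = gene[i],
      rpkm_spec = if (blank(rpkm_spec[i])) NA_character_ else trimws(rpkm_spec[i]),
      region_chr = region[i],
      mirna_id = mirna_id,
      block = block[i],
      group_id = i,
      group_n = n,
      start = starts,
      length = len,
      start_lo = as.integer(sr[1]), start_hi = as.integer(sr[2]),
      dg_lo = dg[1], dg_hi = dg[2],
      ratio_lo = rr[1], ratio_hi = rr[2]
    )
  })
  out <- bind_rows(rows) |>
    mutate(
      region = as_region(.data$region_chr),
      rpkm = suppressWarnings(as.numeric(.data$rpkm_spec)),
      transcript_id = .data$gene,
      delta_g = (.data$dg_lo + .data$dg_hi) / 2,
      ratio = (.data$ratio_lo + .data$ratio_hi) / 2,
      ratio_pct = as.integer(round_half_up(.data$ratio))
    ) |>
    select(
      "gene", "rpkm", "region", "mirna_id", "transcript_id", "start", "length",
      "delta_g", "ratio", "ratio_pct", "block", "group_id", "group_n",
      "start_lo", "start_hi", "dg_lo", "dg_hi", "ratio_lo", "ratio_hi", "rpkm_spec"
    )
  class(out) <- c("mir_sites", class(out))
  out
}

empty_parsed_sites <- function() {
  out <- tibble(
    gene = character(), rpkm = numeric(),
    region = factor(character(), levels = region_levels()),
    mirna_id = character(), transcript_id = character(),
    start = integer(), length = integer(),
    delta_g = numeric(), ratio = numeric(), ratio_pct = integer(),
    block = integer(), group_id = integer(), group_n = integer(),
    start_lo = integer(), start_hi = integer(),
    dg_lo = numeric(), dg_hi = numeric(),
    ratio_lo = numeric(), ratio_hi = numeric(), rpkm_spec = character()
  )
  class(out) <- c("mir_sites", class(out))
  out
}

#' Write sites in the printed-table dialect
#'
#' Inverse of [read_site_table()]. Sites parsed from a table keep their
#' group bookkeeping and are written back to the same rows (without
#' thousands separators). Sites from [scan_sites()] are compressed with
#' [group_starts()] per (gene, region, miRNA, length); within a compressed
#' run the energy/ratio cells record the first and last site's values.
#'
#' @param sites a `mir_sites` tibble.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  if (nrow(sites) == 0) {
    readr::write_tsv(
      tibble(
        gene = character(), rpkm = character(), region = character(),
        mirna = character(), start_spec = character(), dg_spec = character(),
        ratio_spec = character(), length = integer()
      ),
      path, progress = FALSE
    )
    return(invisible(path))
  }
  x <- as_tibble(sites)
  if (!"group_id" %in% names(x)) {
    x <- regroup_engine_sites(x)
  }
  if (!"rpkm" %in% names(x)) x$rpkm <- NA_real_
  if (!"rpkm_spec" %in% names(x)) {
    x$rpkm_spec <- ifelse(is.na(x$rpkm), NA_character_, format(x$rpkm, trim = TRUE))
  }
  rows <- x |>
    group_by(.data$group_id) |>
    summarise(
      gene = .data$gene[1],
      rpkm_spec = .data$rpkm_spec[1],
      region = as.character(.data$region[1]),
      mirna = if (n() > 1) sprintf("%s (%d)", .data$mirna_id[1], n()) else .data$mirna_id[1],
      start_spec = format_spec_range(min(.data$start), max(.data$start)),
      dg_spec = format_spec_range(.data$dg_lo[1], .data$dg_hi[1]),
      ratio_spec = format_spec_range(.data$ratio_lo[1], .data$ratio_hi[1]),
      length = .data$length[1],
      .groups = "drop"
    ) |>
    arrange(.data$group_id)
  # blank out carried-down block cells
  same_block <- c(FALSE, rows$gene[-1] == rows$gene[-nrow(rows)] &
    rows$region[-1] == rows$region[-nrow(rows)])
  out <- rows |>
    mutate(
      rpkm = ifelse(same_block | is.na(.data$rpkm_spec), "", .data$rpkm_spec),
      gene = ifelse(same_block, "", .data$gene),
      region = ifelse(same_block, "", .data$region)
    ) |>
    select("gene", "rpkm", "region", "mirna", "start_spec", "dg_spec", "ratio_spec", "length")
  readr::write_tsv(out, path, progress = FALSE, na = "")
  invisible(path)
}

# add group bookkeeping to engine output so it can be written in the dialect
regroup_engine_sites <- function(x) {
  x <- x |>
    mutate(.row = row_number()) |>
    arrange(.data$gene, .data$region, .data$mirna_id, .data$length, .data$start)
  key <- paste(x$gene, x$region, x$mirna_id, x$length, sep = "\r")
  pieces <- split(seq_len(nrow(x)), factor(key, levels = unique(key)))
  next_gid <- 0L
  out <- lapply(pieces, function(idx) {
    g <- group_starts(x$start[idx])
    part <- x[idx, ]
    gid <- integer(length(idx))
    for (k in seq_len(nrow(g))) gid[g$idx[[k]]] <- next_gid + k
    next_gid <<- next_gid + nrow(g)
    part$group_id <- gid
    part |>
      group_by(.data$group_id) |>
      mutate(
        group_n = n(),
        start_lo = min(.data$start), start_hi = max(.data$start),
        dg_lo = .data$delta_g[1], dg_hi = .data$delta_g[n()],
        ratio_lo = .data$ratio_pct[1], ratio_hi = .data$ratio_pct[n()]
      ) |>
      ungroup()
  })
  bind_rows(out) |>
    arrange(.data$.row) |>
    select(-".row") |>
    mutate(
      dg_lo = round_half_up(.data$dg_lo), dg_hi = round_half_up(.data$dg_hi),
      group_id = match(.data$group_id, unique(.data$group_id))
    )
}
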