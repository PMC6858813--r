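# Hydrogen-bond duplex model.
#
# A candidate site is a gapless, antiparallel pairing of a whole miRNA
# (5'->3') against an equal-length mRNA window (5'->3'): window position j
# pairs with miRNA position L - j + 1. Each base pair contributes a fixed
# number of hydrogen bonds: G-C 3, A-U 2, and the non-canonical G-U and A-C
# pairs 1 each; every other combination (including anything involving N)
# contributes 0 but stays in register (no bulges). The duplex free energy is
# modeled as dG = -k_hb * (total bonds), so the selection statistic
# 100 * dG / dGm equals 100 * bonds / max_bonds and does not depend on k_hb.

.BASES <- c("A", "C", "G", "U", "N")

.bond_matrix <- local({
  m <- matrix(0L, 5, 5, dimnames = list(.BASES, .BASES))
  m["G", "C"] <- m["C", "G"] <- 3L
  m["A", "U"] <- m["U", "A"] <- 2L
  m["G", "U"] <- m["U", "G"] <- 1L
  m["A", "C"] <- m["C", "A"] <- 1L
  m
})

# canonical-complement bond contribution per miRNA base (N pairs nothing)
.max_bond_per_base <- c(A = 2L, C = 3L, G = 3L, U = 2L, N = 0L)

encode_bases <- function(seq) {
  code <- match(strsplit(seq, "", fixed = TRUE)[[1]], .BASES)
  if (anyNA(code)) abort("sequence contains a base outside {A,C,G,U,N}")
  code
}

#' Hydrogen bonds formed by one base pair
#'
#' @param mi_base,m_base single bases (miRNA side, mRNA side), vectors
#'   recycled to common length; alphabet `A,C,G,U,N`.
#' @return integer vector of hydrogen-bond counts (0-3): 3 for G-C, 2 for
#'   A-U, 1 for the non-canonical G-U and A-C pairs, 0 otherwise.
#' @examples
#' bond_count("G", "C")
#' bond_count(c("A", "A", "A"), c("U", "C", "G"))
#' @export
bond_count <- function(mi_base, m_base) {
  i <- match(toupper(mi_base), .BASES)
  j <- match(toupper(m_base), .BASES)
  if (anyNA(i) || anyNA(j)) abort("base outside {A,C,G,U,N}")
  .bond_matrix[cbind(i, j)]
}

#' Maximal hydrogen bonds of a miRNA
#'
#' Bond total of the miRNA paired with its exact canonical complement: each
#' G or C contributes 3 bonds, each A or U contributes 2 (N contributes 0).
#' `-k_hb * max_bonds` is the miRNA's maximal free energy dGm, the
#' normalizer of the dG/dGm selection ratio.
#'
#' @param sequence character vector of miRNA sequences (RNA, 5'->3').
#' @return integer vector of maximal bond counts.
#' @examples
#' max_bonds("GGGG")
#' max_bonds(c("AAAA", "UGGAC"))
#' @export
max_bonds <- function(sequence) {
  vapply(sequence, function(s) {
    sum(.max_bond_per_base[strsplit(normalize_rna(s), "", fixed = TRUE)[[1]]])
  }, integer(1), USE.NAMES = FALSE)
}

#' Energy model configuration
#'
#' @param k_hb free-energy magnitude per hydrogen bond, kJ/mole per bond
#'   (positive). The default 2.11 is a calibration constant: printed site
#'   energies divided by their printed dG/dGm ratios imply roughly 2.1
#'   kJ/mole per bond for GC-rich miRNAs of known composition. The selection
#'   ratio is invariant to `k_hb`; only reported kJ/mole values scale.
#' @return a list of class `mir_energy_model`.
#' @seealso [fit_khb()]
#' @export
energy_model <- function(k_hb = 2.11) {
  stopifnot_scalar_number(k_hb, "k_hb", lo = 1e-9)
  structure(list(k_hb = k_hb), class = "mir_energy_model")
}

#' Least-squares calibration of the per-bond energy constant
#'
#' Fits `k_hb` from reported site energies: given printed dG (kJ/mole,
#' negative), printed dG/dGm percentages and the maximal bond counts of the
#' corresponding miRNAs, each row implies `dGm = dg / (ratio/100)` and the
#' model `dGm = -k_hb * max_bonds`; the least-squares slope through the
#' origin is returned.
#'
#' @param dg numeric, printed site free energies (negative kJ/mole).
#' @param ratio_pct numeric, printed dG/dGm percentages.
#' @param max_bonds integer, [max_bonds()] of the matching miRNAs.
#' @return fitted `k_hb` (positive scalar, kJ/mole per bond).
#' @export
fit_khb <- function(dg, ratio_pct, max_bonds) {
  dgm <- dg / (ratio_pct / 100)
  stats::lm.fit(x = cbind(-as.numeric(max_bonds)), y = dgm)$coefficients[[1]]
}

#' Score one miRNA/mRNA duplex at a fixed start
#'
#' Pairs the miRNA (reversed, i.e. antiparallel) against the transcript
#' window `[start, start + L - 1]` without gaps and counts hydrogen bonds at
#' every position.
#'
#' @param mirna_seq miRNA sequence (RNA, 5'->3').
#' @param transcript_seq transcript sequence (RNA, 5'->3').
#' @param start 1-based window start on the transcript.
#' @param em an [energy_model()].
#' @param mirna_id,transcript_id optional identifiers carried into the result.
#' @return object of class `mir_duplex`: a list with `mirna_id`,
#'   `transcript_id`, `start`, `length`, `window` (mRNA window 5'->3'),
#'   `mirna` (5'->3'), `bond_vector` (per mRNA-window position),
#'   `bonds_total`, `max_bonds`, `delta_g`, `delta_g_max`, `ratio` (exact
#'   percentage), `ratio_pct` (integer percent, half-up), `unpaired`.
#' @examples
#' align_at("UGG", "ACCAG", start = 2)
#' @export
align_at <- function(mirna_seq, transcript_seq, start, em = energy_model(),
                     mirna_id = "miRNA", transcript_id = "mRNA") {
  mirna_seq <- normalize_rna(mirna_seq)
  transcript_seq <- normalize_rna(transcript_seq)
  L <- nchar(mirna_seq)
  if (start < 1 || start + L - 1 > nchar(transcript_seq)) {
    abort(sprintf(
      "window [%d, %d] out of transcript bounds [1, %d]",
      start, start + L - 1, nchar(transcript_seq)
    ))
  }
  window <- substr(transcript_seq, start, start + L - 1)
  mi_rev <- rev(encode_bases(mirna_seq))
  w <- encode_bases(window)
  bonds <- .bond_matrix[cbind(mi_rev, w)]
  mb <- max_bonds(mirna_seq)
  total <- sum(bonds)
  structure(list(
    mirna_id = mirna_id, transcript_id = transcript_id,
    start = as.integer(start), length = L,
    window = window, mirna = mirna_seq,
    bond_vector = bonds, bonds_total = total, max_bonds = mb,
    delta_g = -em$k_hb * total, delta_g_max = -em$k_hb * mb,
    ratio = 100 * total / mb,
    ratio_pct = as.integer(round_half_up(100 * total / mb)),
    unpaired = sum(bonds == 0L)
  ), class = "mir_duplex")
}

#' @export
print.mir_duplex <- function(x, ...) {
  cat(render_scheme(x), sep = "\n")
  invisible(x)
}

# bond totals for every window start of one miRNA against one transcript;
# returns integer vector over starts 1 .. N - L + 1 (empty when L > N)
scan_bond_totals <- function(mirna_codes, transcript_codes) {
  L <- length(mirna_codes)
  n_start <- length(transcript_codes) - L + 1
  if (n_start < 1) return(integer(0))
  mi_rev <- rev(mirna_codes)
  totals <- integer(n_start)
  for (j in seq_len(L)) {
    totals <- totals + .bond_matrix[mi_rev[j], transcript_codes[j:(j + n_start - 1)]]
  }
  totals
}

#' Scan transcripts for miRNA binding sites
#'
#' Slides each miRNA along each transcript (every 1-based start), scores the
#' gapless antiparallel duplex by hydrogen-bond counting, and keeps the
#' starts whose exact dG/dGm ratio reaches `threshold_pct`. Adjacent
#' qualifying starts are reported as separate sites (tandem repeats yield
#' runs of sites); within one miRNA/transcript pair the output is sorted by
#' start.
#'
#' @param mirnas tibble with `mirna_id` and `sequence` (e.g. from
#'   [read_mirna_fasta()]).
#' @param transcripts tibble with `transcript_id` and `sequence`, and
#'   optionally `gene`, `rpkm` and region lengths (`utr5_len`, `cds_len`,
#'   `utr3_len`) as produced by [build_transcripts()]; when region lengths
#'   are present each site is localized to `5UTR`/`CDS`/`3UTR` by its start
#'   nucleotide.
#' @param threshold_pct minimal dG/dGm percentage, in (0, 100]; default 87,
#'   the selection level used for reported sites. The unrounded ratio is
#'   compared against the threshold.
#' @param em an [energy_model()].
#' @return tibble of class `mir_sites`, one row per qualifying site:
#'   `mirna_id`, `transcript_id`, `gene`, `region` (factor or NA), `start`,
#'   `length`, `bonds_total`, `max_bonds`, `delta_g`, `delta_g_max`, `ratio`
#'   (exact), `ratio_pct` (integer, half-up), `unpaired`. A miRNA longer
#'   than a transcript contributes no rows and raises a warning.
#' @examples
#' mi <- tibble::tibble(mirna_id = "mir1", sequence = "UGG")
#' tx <- tibble::tibble(transcript_id = "tx1", sequence = "ACCAGCCA")
#' scan_sites(mi, tx, threshold_pct = 87)
#' @export
scan_sites <- function(mirnas, transcripts, threshold_pct = 87, em = energy_model()) {
  stopifnot_scalar_number(threshold_pct, "threshold_pct", lo = 1e-9, hi = 100)
  if (!all(c("mirna_id", "sequence") %in% names(mirnas))) {
    abort("`mirnas` needs columns mirna_id, sequence")
  }
  if (!all(c("transcript_id", "sequence") %in% names(transcripts))) {
    abort("`transcripts` needs columns transcript_id, sequence")
  }
  has_regions <- all(c("utr5_len", "cds_len", "utr3_len") %in% names(transcripts))
  mi_codes <- lapply(normalize_rna(mirnas$sequence, mirnas$mirna_id), encode_bases)
  mi_max <- max_bonds(mirnas$sequence)

  res <- vector("list", nrow(mirnas) * nrow(transcripts))
  k <- 0L
  for (ti in seq_len(nrow(transcripts))) {
    tx <- transcripts[ti, ]
    t_codes <- encode_bases(normalize_rna(tx$sequence, tx$transcript_id))
    for (mi in seq_len(nrow(mirnas))) {
      L <- length(mi_codes[[mi]])
      if (L > length(t_codes)) {
        warn(sprintf(
          "miRNA %s (%d nt) longer than transcript %s (%d nt); no sites",
          mirnas$mirna_id[mi], L, tx$transcript_id, length(t_codes)
        ))
        next
      }
      totals <- scan_bond_totals(mi_codes[[mi]], t_codes)
      hit <- which(100 * totals / mi_max[mi] >= threshold_pct)
      if (length(hit) == 0) next
      k <- k + 1L
      res[[k]] <- tibble(
        mirna_id = mirnas$mirna_id[mi],
        transcript_id = tx$transcript_id,
        gene = if ("gene" %in% names(tx)) tx$gene else tx$transcript_id,
        start = as.integer(hit),
        length = L,
        bonds_total = as.integer(totals[hit]),
        max_bonds = mi_max[mi]
      )
    }
  }
  out <- if (k == 0) {
    tibble(
      mirna_id = character(), transcript_id = character(), gene = character(),
      start = integer(), length = integer(),
      bonds_total = integer(), max_bonds = integer()
    )
  } else {
    bind_rows(res[seq_len(k)])
  }
  out <- out |>
    mutate(
      delta_g = -em$k_hb * .data$bonds_total,
      delta_g_max = -em$k_hb * .data$max_bonds,
      ratio = 100 * .data$bonds_total / .data$max_bonds,
      ratio_pct = as.integer(round_half_up(.data$ratio)),
      unpaired = NA_integer_
    )
  if (has_regions) {
    ann <- transcripts |>
      select("transcript_id", "utr5_len", "cds_len", "utr3_len")
    out <- out |>
      left_join(ann, by = "transcript_id") |>
      mutate(region = position_region(
        .data$start, .data$utr5_len, .data$cds_len, .data$utr3_len
      )) |>
      select(-"utr5_len", -"cds_len", -"utr3_len")
  } else {
    out$region <- factor(NA_character_, levels = region_levels())
  }
  out <- select(
    out, "mirna_id", "transcript_id", "gene", "region", "start", "length",
    "bonds_total", "max_bonds", "delta_g", "delta_g_max",
    "ratio", "ratio_pct", "unpaired"
  )
  class(out) <- c("mir_sites", class(out))
  out
}

#' Write a scanned site list as TSV
#'
#' One row per site; free energies are reported rounded to the nearest
#' integer kJ/mole (half away from zero) and ratios to integer percent, the
#' precision used in printed site tables.
#'
#' @param sites tibble from [scan_sites()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(sites, path) {
  sites |>
    mutate(
      region = as.character(.data$region),
      delta_g = round_half_up(.data$delta_g)
    ) |>
    select(
      "gene", "region", "mirna_id", "start", "length", "delta_g", "ratio_pct"
    ) |>
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}
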