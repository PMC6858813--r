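# Seeded synthetic fixtures: random-background transcripts with planted
# complementary windows, optionally corrupted by wobble pairs (G-U / A-C),
# zero-bond mismatches, or repeated in tandem at a fixed step, together with
# the a-priori expected bond total and dG/dGm ratio of every planted start.
# The generator emulates the site structures seen in real site tables
# (near-complementary duplexes at 87-100%, dinucleotide/trinucleotide repeat
# regions carrying runs of equally spaced sites); it makes no attempt to
# model real transcript composition or expression.

rand_rna <- function(n, base_freq) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE, prob = base_freq), collapse = "")
}

# reverse complement (RNA): the window a miRNA binds with 100% ratio
revcomp_rna <- function(seq) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", seq), "")[[1]]), collapse = "")
}

# wobble partner of the mRNA base facing miRNA base `b`, and the bonds lost
.wobble_base <- c(G = "U", C = "A", A = "C", U = "G")
.wobble_loss <- c(G = 2L, C = 2L, A = 1L, U = 1L)
# a zero-bond mRNA base for miRNA base `b`, and the bonds lost
.mismatch_base <- c(G = "A", C = "U", A = "G", U = "C")
.mismatch_loss <- c(G = 3L, C = 3L, A = 2L, U = 2L)

#' Configuration for the synthetic generator
#'
#' The defaults build three transcripts (with 5'UTR/CDS/3'UTR splits,
#' including one transcript without a 5'UTR) and six miRNAs of tabulated
#' lengths (18-24 nt), and plant: a perfect site, a one-wobble site, a
#' two-wobble site, a four-mismatch site (which for the fixed 21-nt miRNA
#' used is guaranteed to fall below the 87% threshold: at most
#' 43/51 = 84.3%), and two tandem runs (6 sites at step 2 and 9 sites at
#' step 3, the patterns repeat regions produce).
#'
#' @param mirnas tibble with `mirna_id` and either `sequence` or `length`
#'   (sequences are drawn at random; a `period` column forces a periodic
#'   sequence, required for tandem plants).
#' @param transcripts tibble with `transcript_id`, `utr5_len`, `cds_len`,
#'   `utr3_len` and optionally `rpkm`.
#' @param plants tibble with `mirna_id`, `transcript_id`, `position`
#'   (1-based start of the planted window), `n_wobble`, `n_mismatch`,
#'   `tandem_n`, `tandem_step`.
#' @param base_freq background base frequencies for `A,C,G,U` (uniform by
#'   default; raise G/C to probe false-positive behaviour of the threshold).
#' @return a list of class `mir_synth_config`.
#' @export
synth_config <- function(mirnas = NULL, transcripts = NULL, plants = NULL,
                         base_freq = c(0.25, 0.25, 0.25, 0.25)) {
  if (length(base_freq) != 4 || any(base_freq < 0) || sum(base_freq) <= 0) {
    abort("base_freq must be four nonnegative frequencies for A,C,G,U")
  }
  mirnas <- mirnas %||% tibble(
    mirna_id = c("syn-mir-a", "syn-mir-b", "syn-mir-c", "syn-mir-d",
                 "syn-mir-rep2", "syn-mir-rep3"),
    length = c(22L, 24L, 21L, 18L, 22L, 21L),
    # syn-mir-c is fixed (9 G/C, max_bonds 51) so four mismatches always
    # push the planted site below an 87% threshold
    sequence = c(NA, NA, "AGCUUGACUGAAUCGGAUACU", NA, NA, NA),
    period = c(NA, NA, NA, NA, 2L, 3L)
  )
  transcripts <- transcripts %||% tibble(
    transcript_id = c("syn-tx-1", "syn-tx-2", "syn-tx-3"),
    utr5_len = c(150L, 0L, 120L),
    cds_len = c(900L, 600L, 720L),
    utr3_len = c(450L, 300L, 360L),
    rpkm = c(3.9, 63.6, 9.4)
  )
  plants <- plants %||% tibble(
    mirna_id = c("syn-mir-a", "syn-mir-b", "syn-mir-c", "syn-mir-d",
                 "syn-mir-rep2", "syn-mir-rep3"),
    transcript_id = c("syn-tx-1", "syn-tx-1", "syn-tx-2", "syn-tx-3",
                      "syn-tx-1", "syn-tx-3"),
    position = c(301L, 701L, 201L, 31L, 1101L, 601L),
    n_wobble = c(0L, 1L, 0L, 2L, 0L, 0L),
    n_mismatch = c(0L, 0L, 4L, 0L, 0L, 0L),
    tandem_n = c(1L, 1L, 1L, 1L, 6L, 9L),
    tandem_step = c(NA_integer_, NA, NA, NA, 2L, 3L)
  )
  structure(
    list(mirnas = mirnas, transcripts = transcripts, plants = plants,
         base_freq = base_freq / sum(base_freq)),
    class = "mir_synth_config"
  )
}

#' Generate a seeded synthetic fixture bundle
#'
#' Deterministic for a given `(config, seed)` pair down to the emitted
#' bytes. Planted windows equal the reverse complement of their miRNA with
#' exactly the requested corruptions; the background is i.i.d. with the
#' configured base frequencies. Tandem plants write a periodically extended
#' complement so that `tandem_n` starts at `tandem_step` spacing each carry
#' a perfect (100%) site.
#'
#' @param config a [synth_config()].
#' @param seed integer RNG seed (recorded in the FASTA headers).
#' @return list of class `mir_synth` with `mirnas`, `transcripts` (tibbles
#'   in the formats used by [scan_sites()]), `truth` (one row per expected
#'   site: `mirna_id`, `transcript_id`, `start`, `expected_bonds`,
#'   `expected_ratio`, `plant` id) and `seed`.
#' @export
synth_generate <- function(config = synth_config(), seed = 17) {
  stopifnot(inherits(config, "mir_synth_config"))
  withr::local_seed(as.integer(seed))

  mirnas <- config$mirnas
  if (!"sequence" %in% names(mirnas)) mirnas$sequence <- NA_character_
  if (!"period" %in% names(mirnas)) mirnas$period <- NA_integer_
  for (i in seq_len(nrow(mirnas))) {
    if (!is.na(mirnas$sequence[i])) next
    L <- mirnas$length[i]
    if (!is.na(mirnas$period[i])) {
      motif <- rand_rna(mirnas$period[i], config$base_freq)
      mirnas$sequence[i] <- substr(strrep(motif, ceiling(L / nchar(motif))), 1, L)
    } else {
      mirnas$sequence[i] <- rand_rna(L, config$base_freq)
    }
  }
  mirnas$length <- nchar(mirnas$sequence)

  transcripts <- config$transcripts
  transcripts$length <- transcripts$utr5_len + transcripts$cds_len + transcripts$utr3_len
  if (!"rpkm" %in% names(transcripts)) transcripts$rpkm <- NA_real_
  if (!"gene" %in% names(transcripts)) transcripts$gene <- transcripts$transcript_id
  seqs <- lapply(transcripts$length, function(n) {
    strsplit(rand_rna(n, config$base_freq), "")[[1]]
  })
  names(seqs) <- transcripts$transcript_id

  truth <- vector("list", nrow(config$plants))
  occupied <- stats::setNames(
    lapply(transcripts$transcript_id, function(...) integer(0)),
    transcripts$transcript_id
  )
  for (p in seq_len(nrow(config$plants))) {
    pl <- config$plants[p, ]
    mi <- match(pl$mirna_id, mirnas$mirna_id)
    ti <- match(pl$transcript_id, transcripts$transcript_id)
    if (is.na(mi) || is.na(ti)) abort(sprintf("plant %d references unknown ids", p))
    mseq <- mirnas$sequence[mi]
    L <- nchar(mseq)
    scalar_or <- function(v, default) {
      if (is.null(v) || length(v) == 0 || is.na(v)) default else v
    }
    tandem_n <- scalar_or(pl$tandem_n, 1L)
    n_wobble <- scalar_or(pl$n_wobble, 0L)
    n_mismatch <- scalar_or(pl$n_mismatch, 0L)
    step <- pl$tandem_step
    if (tandem_n > 1) {
      if (is.na(step) || step < 1) abort(sprintf("plant %d: tandem requires a step", p))
      period_ok <- mseq == substr(strrep(substr(mseq, 1, step), ceiling(L / step)), 1, L)
      if (!period_ok) {
        abort(sprintf("plant %d: tandem step %d needs a miRNA with period %d", p, step, step))
      }
      if (n_wobble > 0 || n_mismatch > 0) {
        abort(sprintf("plant %d: tandem plants must be uncorrupted", p))
      }
    }
    span_len <- L + (tandem_n - 1L) * ifelse(tandem_n > 1, step, 0L)
    span <- pl$position:(pl$position + span_len - 1L)
    if (pl$position < 1 || max(span) > transcripts$length[ti]) {
      abort(sprintf("plant %d exceeds transcript bounds", p))
    }
    if (length(intersect(span, occupied[[pl$transcript_id]])) > 0) {
      abort(sprintf("plant %d overlaps an earlier plant", p))
    }
    occupied[[pl$transcript_id]] <- c(occupied[[pl$transcript_id]], span)

    window <- strsplit(revcomp_rna(mseq), "")[[1]]
    mb <- max_bonds(mseq)
    if (tandem_n > 1) {
      # periodic extension: every start position, position+step, ... is a
      # perfect complement of the (periodic) miRNA
      motif <- window[seq_len(step)]
      filled <- rep(motif, length.out = span_len)
      seqs[[pl$transcript_id]][span] <- filled
      starts <- pl$position + step * (seq_len(tandem_n) - 1L)
      truth[[p]] <- tibble(
        plant = p, mirna_id = pl$mirna_id, transcript_id = pl$transcript_id,
        start = as.integer(starts), expected_bonds = mb,
        expected_ratio = 100
      )
    } else {
      n_corrupt <- n_wobble + n_mismatch
      if (n_corrupt > L) abort(sprintf("plant %d: more corruptions than positions", p))
      pos <- if (n_corrupt > 0) sample.int(L, n_corrupt) else integer(0)
      wob <- pos[seq_len(n_wobble)]
      mis <- setdiff(pos, wob)
      loss <- 0L
      for (j in wob) {
        b <- substr(mseq, L - j + 1L, L - j + 1L)  # miRNA base facing window pos j
        window[j] <- .wobble_base[[b]]
        loss <- loss + .wobble_loss[[b]]
      }
      for (j in mis) {
        b <- substr(mseq, L - j + 1L, L - j + 1L)
        window[j] <- .mismatch_base[[b]]
        loss <- loss + .mismatch_loss[[b]]
      }
      seqs[[pl$transcript_id]][span] <- window
      truth[[p]] <- tibble(
        plant = p, mirna_id = pl$mirna_id, transcript_id = pl$transcript_id,
        start = as.integer(pl$position),
        expected_bonds = mb - loss,
        expected_ratio = 100 * (mb - loss) / mb
      )
    }
  }
  transcripts$sequence <- vapply(
    transcripts$transcript_id, function(id) paste(seqs[[id]], collapse = ""), character(1)
  )
  structure(list(
    mirnas = select(mirnas, "mirna_id", "sequence", "length"),
    transcripts = select(
      transcripts, "transcript_id", "gene", "sequence", "length",
      "utr5_len", "cds_len", "utr3_len", "rpkm"
    ),
    truth = bind_rows(truth),
    seed = as.integer(seed)
  ), class = "mir_synth")
}

#' Write a synthetic bundle to disk
#'
#' Emits the formats the package consumes: miRNA FASTA, transcript FASTA,
#' regions TSV and the ground truth as JSON. FASTA headers record the seed.
#'
#' @param bundle a `mir_synth` from [synth_generate()].
#' @param dir output directory (created if needed).
#' @return named character vector of the four file paths, invisibly.
#' @export
write_synth_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tag <- sprintf(" synth seed=%d", bundle$seed)
  paths <- c(
    mirnas = file.path(dir, "mirnas.fasta"),
    transcripts = file.path(dir, "transcripts.fasta"),
    regions = file.path(dir, "regions.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_fasta(
    mutate(bundle$mirnas, mirna_id = paste0(.data$mirna_id, tag)),
    paths[["mirnas"]]
  )
  write_fasta(
    mutate(bundle$transcripts, transcript_id = paste0(.data$transcript_id, tag)),
    paths[["transcripts"]]
  )
  readr::write_tsv(
    select(bundle$transcripts, "transcript_id", "utr5_len", "cds_len", "utr3_len", "rpkm"),
    paths[["regions"]], progress = FALSE
  )
  jsonlite::write_json(bundle$truth, paths[["truth"]], digits = NA)
  invisible(paths)
}

#' Compare a scan against the generator's ground truth
#'
#' Completeness: every planted start whose expected ratio reaches the
#' threshold must be recovered at its exact position. Soundness: every
#' reported site's bond total must equal an independent per-position
#' recount of the sequences (incidental background hits are allowed and
#' recounted, not penalized).
#'
#' @param bundle a `mir_synth`.
#' @param scan result of [scan_sites()] on the bundle's sequences.
#' @param threshold_pct the threshold used for the scan.
#' @return one-row tibble: `n_expected`, `n_recovered`, `completeness`,
#'   `n_reported`, `n_recount_ok`, `soundness`, `n_expected_miss`
#'   (plants legitimately below threshold), `n_incidental`.
#' @export
recovery_report <- function(bundle, scan, threshold_pct = 87) {
  truth <- bundle$truth
  expected <- filter(truth, .data$expected_ratio >= threshold_pct)
  key <- function(d) paste(d$mirna_id, d$transcript_id, d$start)
  recovered <- key(expected) %in% key(scan)
  # independent recount of every reported site
  recount <- purrr::pmap_int(
    list(scan$mirna_id, scan$transcript_id, scan$start),
    function(mid, tid, s) {
      mi <- bundle$mirnas$sequence[match(mid, bundle$mirnas$mirna_id)]
      tx <- bundle$transcripts$sequence[match(tid, bundle$transcripts$transcript_id)]
      L <- nchar(mi)
      sum(bond_count(
        rev(strsplit(mi, "")[[1]]),
        strsplit(substr(tx, s, s + L - 1L), "")[[1]]
      ))
    }
  )
  tibble(
    n_expected = nrow(expected),
    n_recovered = sum(recovered),
    completeness = if (nrow(expected) > 0) mean(recovered) else 1,
    n_reported = nrow(scan),
    n_recount_ok = sum(recount == scan$bonds_total),
    soundness = if (nrow(scan) > 0) mean(recount == scan$bonds_total) else 1,
    n_expected_miss = nrow(truth) - nrow(expected),
    n_incidental = sum(!key(scan) %in% key(truth))
  )
}
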