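#' Read and normalize a FASTA file of RNA or DNA sequences
#'
#' Reads a multi-record FASTA file (via Biostrings), uppercases the sequences
#' and normalizes the DNA alphabet to RNA (`T -> U`), so GenBank-style mRNA
#' records and miRBase-style miRNA records can be mixed freely. Record ids are
#' the FASTA header up to the first whitespace and must be unique.
#'
#' @param path path to a FASTA file.
#' @param id_col name of the identifier column in the returned tibble.
#' @return a tibble with columns `<id_col>` (character), `sequence`
#'   (RNA, 5'->3') and `length` (nt), in file order. An empty file yields a
#'   zero-row tibble.
#' @details Characters outside `A,C,G,T,U,N` (after uppercasing) are a
#'   validation error naming the record and offending position; `N` is kept
#'   and later scores zero hydrogen bonds.
#' @seealso [read_mirna_fasta()], [read_transcript_fasta()], [write_fasta()]
#' @export
read_fasta <- function(path, id_col = "id") {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(sprintf("malformed FASTA in %s: %s", path, conditionMessage(e)))
  )
  if (length(set) == 0) {
    out <- tibble(id = character(), sequence = character(), length = integer())
    names(out)[1] <- id_col
    return(out)
  }
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate FASTA id(s) in %s: %s", path, paste(dup, collapse = ", ")))
  }
  seqs <- normalize_rna(unname(as.character(set)), ids)
  out <- tibble(id = ids, sequence = seqs, length = nchar(seqs))
  names(out)[1] <- id_col
  out
}

#' @rdname read_fasta
#' @export
read_mirna_fasta <- function(path) {
  out <- read_fasta(path, id_col = "mirna_id")
  if (any(out$length < 1)) abort("zero-length miRNA record")
  out
}

#' @rdname read_fasta
#' @export
read_transcript_fasta <- function(path) {
  read_fasta(path, id_col = "transcript_id")
}

# uppercase, T->U, validate alphabet; `ids` used for error messages
normalize_rna <- function(seqs, ids = seq_along(seqs)) {
  seqs <- chartr("t", "T", toupper(seqs))
  seqs <- chartr("T", "U", seqs)
  ok <- grepl("^[ACGUN]*$", seqs)
  if (!all(ok)) {
    i <- which(!ok)[1]
    pos <- regexpr("[^ACGUN]", seqs[i])
    abort(sprintf(
      "invalid character '%s' at position %d of record %s (alphabet A,C,G,T,U,N)",
      substr(seqs[i], pos, pos), pos, ids[i]
    ))
  }
  seqs
}

#' Write sequence records to FASTA
#'
#' Inverse of [read_fasta()] on normalized records: writing then reading
#' returns the same tibble.
#'
#' @param x tibble with an id column (first column or `mirna_id`/
#'   `transcript_id`) and a `sequence` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  id_col <- intersect(c("mirna_id", "transcript_id", "id"), names(x))[1]
  if (is.na(id_col)) id_col <- names(x)[1]
  set <- Biostrings::BStringSet(x$sequence)
  names(set) <- x[[id_col]]
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a transcript region-annotation table
#'
#' Reads a sidecar TSV giving, for each transcript, the lengths of its 5'UTR,
#' CDS and 3'UTR (nt) and optionally an expression value (RPKM, carried as
#' metadata only) and a gene symbol.
#'
#' @param path TSV with header columns `transcript_id`, `utr5_len`,
#'   `cds_len`, `utr3_len`, and optionally `rpkm` and `gene`.
#' @return tibble with columns `transcript_id`, `gene`, `utr5_len`, `cds_len`,
#'   `utr3_len`, `rpkm` (NA when absent).
#' @export
read_region_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("transcript_id", "utr5_len", "cds_len", "utr3_len")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("region table %s lacks column(s): %s", path, paste(miss, collapse = ", ")))
  }
  if (!"rpkm" %in% names(x)) x$rpkm <- NA_real_
  if (!"gene" %in% names(x)) x$gene <- x$transcript_id
  lens <- as.matrix(x[c("utr5_len", "cds_len", "utr3_len")])
  if (any(is.na(lens)) || any(lens < 0) || any(lens != floor(lens))) {
    abort(sprintf("region table %s: region lengths must be nonnegative integers", path))
  }
  if (any(!is.na(x$rpkm) & x$rpkm < 0)) abort("rpkm must be nonnegative")
  x |>
    mutate(
      utr5_len = as.integer(.data$utr5_len),
      cds_len = as.integer(.data$cds_len),
      utr3_len = as.integer(.data$utr3_len),
      rpkm = as.numeric(.data$rpkm)
    ) |>
    select("transcript_id", "gene", "utr5_len", "cds_len", "utr3_len", "rpkm")
}

#' Assemble annotated transcripts from sequences and region lengths
#'
#' Joins transcript sequences with their region annotation and checks that
#' `utr5_len + cds_len + utr3_len` equals the sequence length. A transcript
#' with `utr5_len = 0` simply begins with its CDS.
#'
#' @param seqs tibble from [read_transcript_fasta()].
#' @param regions tibble from [read_region_table()].
#' @return tibble with columns `transcript_id`, `gene`, `sequence`, `length`,
#'   `utr5_len`, `cds_len`, `utr3_len`, `rpkm`.
#' @export
build_transcripts <- function(seqs, regions) {
  miss <- setdiff(seqs$transcript_id, regions$transcript_id)
  if (length(miss) > 0) {
    abort(sprintf("no region annotation for transcript(s): %s", paste(miss, collapse = ", ")))
  }
  x <- left_join(seqs, regions, by = "transcript_id")
  bad <- x$utr5_len + x$cds_len + x$utr3_len != x$length
  if (any(bad)) {
    abort(sprintf(
      "region lengths do not sum to sequence length for: %s",
      paste(x$transcript_id[bad], collapse = ", ")
    ))
  }
  select(
    x, "transcript_id", "gene", "sequence", "length",
    "utr5_len", "cds_len", "utr3_len", "rpkm"
  )
}

#' Map transcript positions to mRNA regions
#'
#' Positions are 1-based and counted from the first nucleotide of the 5'UTR
#' (the first transcript nucleotide), the same convention used for reported
#' binding-site starts. The three region labels partition `[1, length]`:
#' positions `<= utr5_len` are `5UTR`, the next `cds_len` are `CDS`, the rest
#' `3UTR`.
#'
#' @param pos integer vector of 1-based transcript positions.
#' @param utr5_len,cds_len,utr3_len region lengths (nt), recycled against
#'   `pos`.
#' @return factor with levels `5UTR`, `CDS`, `3UTR`.
#' @examples
#' position_region(c(30, 142, 143), utr5_len = 142, cds_len = 1000, utr3_len = 200)
#' @export
position_region <- function(pos, utr5_len, cds_len, utr3_len) {
  total <- utr5_len + cds_len + utr3_len
  if (any(pos < 1 | pos > total)) {
    abort(sprintf(
      "position out of range: %s (transcript length %s)",
      paste(pos[pos < 1 | pos > total], collapse = ", "), paste(unique(total), collapse = "/")
    ))
  }
  lab <- ifelse(pos <= utr5_len, "5UTR", ifelse(pos <= utr5_len + cds_len, "CDS", "3UTR"))
  factor(lab, levels = region_levels())
}
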