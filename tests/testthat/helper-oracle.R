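# Independent brute-force oracle for duplex scoring, deliberately written
# without reusing any of the package's internals: pair bonds come from a
# flat pair-string lookup and every window is rescored position by position.

oracle_pair_bonds <- c(
  "GC" = 3, "CG" = 3, "AU" = 2, "UA" = 2,
  "GU" = 1, "UG" = 1, "AC" = 1, "CA" = 1
)

# bonds of miRNA (5'->3') against transcript window starting at `start`
oracle_bonds_at <- function(mirna, transcript, start) {
  L <- nchar(mirna)
  mi <- rev(strsplit(mirna, "")[[1]])
  win <- strsplit(substr(transcript, start, start + L - 1), "")[[1]]
  total <- 0
  for (j in seq_len(L)) {
    b <- unname(oracle_pair_bonds[paste0(mi[j], win[j])])
    total <- total + ifelse(is.na(b), 0, b)
  }
  total
}

oracle_max_bonds <- function(mirna) {
  chars <- strsplit(mirna, "")[[1]]
  sum(ifelse(chars %in% c("G", "C"), 3, ifelse(chars %in% c("A", "U"), 2, 0)))
}

# exhaustive scan: all qualifying starts with exact ratios
oracle_scan <- function(mirna, transcript, threshold_pct) {
  L <- nchar(mirna)
  n <- nchar(transcript) - L + 1
  if (n < 1) {
    return(data.frame(start = integer(0), bonds = numeric(0)))
  }
  bonds <- vapply(seq_len(n), function(s) oracle_bonds_at(mirna, transcript, s), numeric(1))
  keep <- which(100 * bonds / oracle_max_bonds(mirna) >= threshold_pct)
  data.frame(start = keep, bonds = bonds[keep])
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")

# reverse complement used to plant perfect sites in tests
rc_rna <- function(seq) paste(rev(strsplit(chartr("ACGU", "UGCA", seq), "")[[1]]), collapse = "")
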