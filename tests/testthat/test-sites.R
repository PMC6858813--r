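test_that("group expansion produces arithmetic progressions of starts", {
  expect_equal(expand_group(6, 1190, 1200), seq(1190L, 1200L, by = 2L))
  expect_equal(expand_group(9, 1896, 1920), seq(1896L, 1920L, by = 3L))
  expect_equal(expand_group(4, 16, 25), c(16L, 19L, 22L, 25L))
  expect_equal(expand_group(1, 28, 28), 28L)
  expect_error(expand_group(1, 28, 30), "start range")
})

test_that("non-integral steps error in strict mode and space evenly otherwise", {
  expect_error(expand_group(4, 2060, 2095, strict = TRUE), "no integer step")
  expect_warning(s <- expand_group(4, 2060, 2095), "no integer step")
  expect_length(s, 4)
  expect_equal(s[c(1, 4)], c(2060L, 2095L))
  expect_true(all(diff(s) > 0))
})

test_that("grouping compresses maximal equal-step runs and round-trips", {
  g <- group_starts(c(16, 19, 22, 25))
  expect_equal(nrow(g), 1)
  expect_equal(g$n, 4L)
  expect_equal(c(g$start_lo, g$start_hi, g$step), c(16L, 25L, 3L))

  single <- group_starts(42)
  expect_equal(single$n, 1L)
  expect_true(is.na(single$step))

  # unequal spacing: greedy left-to-right keeps the first run, then restarts
  g2 <- group_starts(c(10, 12, 15))
  expect_equal(g2$n, c(2L, 1L))
  expect_equal(g2$start_lo, c(10L, 15L))

  # round-trip property over random groups
  withr::local_seed(31)
  for (i in 1:25) {
    n <- sample(2:10, 1)
    lo <- sample(1:2000, 1)
    step <- sample(1:5, 1)
    starts <- expand_group(n, lo, lo + step * (n - 1))
    g <- group_starts(starts)
    expect_equal(nrow(g), 1)
    expect_equal(expand_group(g$n, g$start_lo, g$start_hi), starts)
  }
})

test_that("sites are annotated by the region of their start nucleotide", {
  tx <- tibble::tibble(
    transcript_id = "CBL_tx", utr5_len = 142L, cds_len = 7000L, utr3_len = 1000L
  )
  sites <- tibble::tibble(
    transcript_id = "CBL_tx",
    start = c(16L, 142L, 143L, 7727L),
    length = 23L
  )
  ann <- annotate_sites(sites, tx)
  expect_equal(as.character(ann$region), c("5UTR", "5UTR", "CDS", "3UTR"))
  expect_error(
    annotate_sites(dplyr::mutate(sites, transcript_id = "nope"), tx),
    "no region annotation"
  )
})

test_that("the printed-table dialect parses blocks, multiplicities and ranges", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "gene\trpkm\tregion\tmirna\tstart_spec\tdg_spec\tratio_spec\tlength",
    "CBL\t3.9\t5UTR\tID03332.3p-miR (4)\t16 ÷ 25\t-134 ÷ -140\t90 ÷ 94\t24",
    "\t\t\tmiR-1908-3p\t30\t-121\t92\t21",
    "SMAD3\t\t3UTR\tmiR-6089 (2)\t2,073 ÷ 2,078\t−132 ÷ −136\t89 ÷ 91\t24"
  ), f)
  s <- read_site_table(f)
  expect_equal(nrow(s), 7)
  expect_equal(s$start[s$mirna_id == "ID03332.3p-miR"], c(16L, 19L, 22L, 25L))
  # carried-down block values
  expect_equal(s$gene[s$mirna_id == "miR-1908-3p"], "CBL")
  expect_equal(s$rpkm[s$mirna_id == "miR-1908-3p"], 3.9)
  # rpkm does not leak across block boundaries
  expect_true(all(is.na(s$rpkm[s$gene == "SMAD3"])))
  # typographic minus and thousands separators are accepted
  expect_equal(s$start[s$gene == "SMAD3"], c(2073L, 2078L))
  expect_equal(unique(s$delta_g[s$gene == "SMAD3"]), -134)
  # ranged energies contribute their endpoint mean
  expect_equal(unique(s$delta_g[s$mirna_id == "ID03332.3p-miR"]), -137)
})

test_that("dialect parser reports malformed rows by number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "gene\trpkm\tregion\tmirna\tstart_spec\tdg_spec\tratio_spec\tlength",
    "G1\t1\t5UTR\tm1\tnot-a-number\t-100\t90\t20"
  ), f)
  expect_error(read_site_table(f), "row 1")
  writeLines(c(
    "gene\trpkm\tregion\tmirna\tstart_spec\tdg_spec\tratio_spec\tlength",
    "\t\t\tm1\t10\t-100\t90\t20"
  ), f)
  expect_error(read_site_table(f), "block header")
})

test_that("engine output can be written in the dialect and re-read", {
  withr::local_seed(59)
  m <- random_rna(20)
  t <- paste0(random_rna(50), rc_rna(m), random_rna(50))
  sites <- scan_sites(
    tibble::tibble(mirna_id = "mirX", sequence = m),
    tibble::tibble(
      transcript_id = "tx1", gene = "GENE1", sequence = t,
      utr5_len = 30L, cds_len = 60L, utr3_len = nchar(t) - 90L
    )
  )
  f <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(sites, f)
  back <- read_site_table(f)
  expect_equal(sort(back$start), sort(sites$start))
  expect_equal(back$length, sites$length)
  expect_equal(as.character(back$region), as.character(sites$region[order(sites$start)]))
})
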