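test_that("pair bond counts follow the 3/2/1/1 scheme with N scoring zero", {
  expect_equal(bond_count("G", "C"), 3L)
  expect_equal(bond_count("C", "G"), 3L)
  expect_equal(bond_count("A", "U"), 2L)
  expect_equal(bond_count("G", "U"), 1L)
  expect_equal(bond_count("U", "G"), 1L)
  expect_equal(bond_count("A", "C"), 1L)
  expect_equal(bond_count("A", "G"), 0L)
  expect_equal(bond_count("A", "A"), 0L)
  expect_equal(bond_count(c("N", "G"), c("C", "N")), c(0L, 0L))
  expect_error(bond_count("B", "C"), "outside")
})

test_that("max_bonds counts 3 per G/C and 2 per A/U", {
  expect_equal(max_bonds("GGGG"), 12L)
  expect_equal(max_bonds("AAAA"), 8L)
  expect_equal(max_bonds(paste0(strrep("G", 11), strrep("A", 11))), 55L)
  expect_equal(max_bonds("ANU"), 4L)
  # oracle agreement on random miRNAs
  withr::local_seed(3)
  for (i in 1:25) {
    m <- random_rna(sample(18:25, 1))
    expect_equal(max_bonds(m), oracle_max_bonds(m))
  }
})

test_that("align_at pairs antiparallel without gaps and scores exactly", {
  a <- align_at("UGG", "CCA", 1)
  expect_equal(a$bond_vector, c(3L, 3L, 2L))
  expect_equal(a$bonds_total, 8L)
  expect_equal(a$ratio, 100)
  expect_equal(a$unpaired, 0L)

  b <- align_at("UGG", "CCG", 1)
  expect_equal(b$bond_vector, c(3L, 3L, 1L))
  expect_equal(b$bonds_total, 7L)
  expect_equal(b$ratio, 87.5)

  expect_error(align_at("UGG", "CC", 1), "out of transcript bounds")
  expect_error(align_at("UGG", "CCAA", 3), "out of transcript bounds")
})

test_that("alignment scores match the brute-force recount on random instances", {
  withr::local_seed(41)
  for (i in 1:30) {
    m <- random_rna(22)
    t <- random_rna(200)
    s <- sample(200 - 22 + 1, 1)
    expect_equal(align_at(m, t, s)$bonds_total, oracle_bonds_at(m, t, s))
  }
})

test_that("ratio is invariant to the energy constant and bounded by the maximum", {
  withr::local_seed(5)
  m <- random_rna(21)
  t <- random_rna(100)
  a1 <- align_at(m, t, 10, em = energy_model(2.11))
  a2 <- align_at(m, t, 10, em = energy_model(5))
  expect_equal(a1$ratio, a2$ratio)
  expect_equal(a2$delta_g / a1$delta_g, 5 / 2.11)
  for (s in seq(1, 80, by = 7)) {
    a <- align_at(m, t, s)
    expect_gte(a$bonds_total, 0)
    expect_lte(a$bonds_total, a$max_bonds)
  }
  # equality holds exactly at the canonical complement
  perfect <- align_at(m, rc_rna(m), 1)
  expect_equal(perfect$bonds_total, perfect$max_bonds)
  expect_equal(perfect$ratio, 100)
})

test_that("corrupting a paired position never increases the ratio", {
  withr::local_seed(19)
  for (i in 1:15) {
    m <- random_rna(20)
    win <- rc_rna(m)
    a0 <- align_at(m, win, 1)
    j <- sample(20, 1)
    cur <- substr(win, j, j)
    for (repl in setdiff(c("A", "C", "G", "U"), cur)) {
      win2 <- win
      substr(win2, j, j) <- repl
      a1 <- align_at(m, win2, 1)
      if (a1$bond_vector[j] <= a0$bond_vector[j]) {
        expect_lte(a1$ratio, a0$ratio)
      }
    }
  }
})

test_that("scan_sites equals exhaustive per-start brute force scoring", {
  withr::local_seed(23)
  for (i in 1:20) {
    L <- sample(18:25, 1)
    m <- random_rna(L)
    tlen <- sample(200:1000, 1)
    t <- random_rna(tlen)
    # plant one perfect complement so the scan always has a guaranteed hit
    pos <- sample(tlen - L + 1, 1)
    substr(t, pos, pos + L - 1) <- rc_rna(m)
    got <- scan_sites(
      tibble::tibble(mirna_id = "m", sequence = m),
      tibble::tibble(transcript_id = "t", sequence = t),
      threshold_pct = 87
    )
    want <- oracle_scan(m, t, 87)
    expect_equal(got$start, want$start)
    expect_equal(got$bonds_total, as.integer(want$bonds))
    expect_true(pos %in% got$start)
    expect_false(is.unsorted(got$start))
  }
})

test_that("scan handles miRNA longer than transcript with a warning, not an error", {
  mi <- tibble::tibble(mirna_id = "long", sequence = strrep("G", 30))
  tx <- tibble::tibble(transcript_id = "short", sequence = "ACGU")
  expect_warning(res <- scan_sites(mi, tx), "longer than transcript")
  expect_equal(nrow(res), 0)
  expect_error(scan_sites(mi, tx, threshold_pct = 120), "threshold_pct")
})

test_that("tandem repeat complements yield stepped qualifying starts", {
  withr::local_seed(29)
  m <- strrep("UG", 11) # period-2 miRNA, 22 nt
  t <- paste0(random_rna(40), strrep("CA", 16), random_rna(40))
  got <- scan_sites(
    tibble::tibble(mirna_id = "rep", sequence = m),
    tibble::tibble(transcript_id = "t", sequence = t),
    threshold_pct = 87
  )
  want <- oracle_scan(m, t, 87)
  expect_equal(got$start, want$start)
  runs <- got$start[got$ratio == 100]
  expect_true(length(runs) >= 2)
  expect_true(all(diff(runs) == 2))
})

test_that("rendered schemes mark canonical and non-canonical pairs and round-trip", {
  a <- align_at("UGG", "CCA", 1, mirna_id = "mirX")
  lines <- render_scheme(a, region = "5UTR")
  expect_match(lines[3], "^   \\|\\|\\|$")
  expect_equal(lines[4], "3' GGU 5'  miRNA")

  b <- align_at("UGG", "CCG", 1, mirna_id = "mirX")
  expect_match(render_scheme(b)[3], ":$")

  parsed <- parse_scheme(render_scheme(b, region = "CDS"))
  expect_equal(parsed$start, 1L)
  expect_equal(parsed$ratio_pct, 88L)
  expect_equal(parsed$region, "CDS")
  expect_equal(parsed$delta_g, round_half_up(b$delta_g))
})
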