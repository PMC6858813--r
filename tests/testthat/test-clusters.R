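# small builder for hand-specified site lists
mk_sites <- function(start, length, mirna = paste0("m", seq_along(start)),
                     dg = -100, gene = "G", region = "3UTR") {
  tibble::tibble(
    mirna_id = mirna, gene = gene, transcript_id = gene,
    region = factor(region, levels = c("5UTR", "CDS", "3UTR")),
    start = as.integer(start), length = as.integer(length),
    delta_g = dg
  )
}

test_that("overlap requires a shared nucleotide; abutting sites stay apart", {
  # [1,10] and [11,20] abut but do not overlap; [1,10] and [10,19] overlap
  s <- mk_sites(c(1, 11), c(10, 10))
  cl <- find_clusters(s, by = c("gene", "region"))
  expect_equal(length(unique(cl$cluster_id)), 2)
  expect_true(all(cl$singleton))

  s2 <- mk_sites(c(1, 10), c(10, 10))
  cl2 <- find_clusters(s2, by = c("gene", "region"))
  expect_equal(length(unique(cl2$cluster_id)), 1)
})

test_that("clusters are transitive-overlap components, invariant to input order", {
  # chain: a-b overlap, b-c overlap, a-c do not; still one cluster
  s <- mk_sites(c(1, 8, 15), c(10, 10, 10))
  cl <- find_clusters(s, by = c("gene", "region"))
  expect_equal(length(unique(cl$cluster_id)), 1)

  withr::local_seed(13)
  for (i in 1:20) {
    n <- sample(3:25, 1)
    s <- mk_sites(sample(1:300, n, replace = TRUE), sample(18:25, n, replace = TRUE))
    a <- find_clusters(s, by = c("gene", "region"))
    perm <- sample(n)
    b <- find_clusters(s[perm, ], by = c("gene", "region"))
    # same partition regardless of order
    pa <- split(seq_len(n), a$cluster_id)
    pb <- split(perm, b$cluster_id)
    norm <- function(p) unname(lapply(p[order(vapply(p, min, 1))], sort))
    expect_equal(norm(pa), norm(pb))
    # oracle: within a cluster every site overlaps some other member;
    # across clusters no pair overlaps (maximality)
    ends <- s$start + s$length - 1L
    overlap <- outer(s$start, ends, "<=") & outer(ends, s$start, ">=")
    diag(overlap) <- FALSE
    for (ci in unique(a$cluster_id)) {
      idx <- which(a$cluster_id == ci)
      if (length(idx) > 1) {
        expect_true(all(rowSums(overlap[idx, idx, drop = FALSE]) > 0))
      }
      expect_false(any(overlap[idx, setdiff(seq_len(n), idx)]))
    }
  }
})

test_that("cluster statistics reproduce worked examples and stacking identity", {
  # six miRNAs, 12 sites in a 5'UTR: total 270 nt, span 40 nt,
  # compaction 6.8, mean energy -127 kJ/mole
  cbl <- dplyr::filter(bc_sites("triple_negative"), gene == "CBL", region == "5UTR")
  st <- cluster_stats(cbl, by = c("gene", "region"))
  expect_equal(nrow(st), 1)
  expect_equal(st$n_sites, 12L)
  expect_equal(st$n_mirnas, 6L)
  expect_equal(st$total_len, 270L)
  expect_equal(st$span, 40L)
  expect_equal(st$first, 16L)
  expect_equal(st$last, 55L)
  expect_equal(st$compaction, 6.8)
  expect_equal(st$mean_dg, -127)

  # identical stacked sites: compaction = n * length / span
  stack <- mk_sites(rep(1, 5), rep(20, 5), mirna = paste0("m", 1:5))
  st2 <- cluster_stats(stack, by = c("gene", "region"))
  expect_equal(st2$span, 21L)
  expect_equal(st2$compaction, round_half_up(5 * 20 / 21, 1))

  # singletons report total length only
  lone <- mk_sites(100, 22)
  st3 <- cluster_stats(lone, by = c("gene", "region"))
  expect_true(st3$singleton)
  expect_equal(st3$total_len, 22L)
  expect_true(is.na(st3$span) && is.na(st3$compaction))
})

test_that("two separated site groups give two clusters with the printed totals", {
  rab5a <- dplyr::filter(bc_sites("triple_negative"), gene == "RAB5A")
  st <- cluster_stats(rab5a, by = c("gene", "region"))
  expect_equal(nrow(st), 2)
  expect_equal(st$n_sites, c(3L, 3L))
  expect_equal(st$total_len[1], 71L)
  expect_equal(st$span[1], 31L)
  expect_equal(st$first, c(184L, 325L))
})

test_that("region summary aggregates footprint, totals and site-weighted mean energy", {
  sfn <- dplyr::filter(bc_sites("triple_negative"), gene == "SFN")
  rs <- region_summary(
    sfn,
    region_lengths = bc_region_lengths(),
    by = c("gene", "region")
  )
  expect_equal(rs$n_clusters, 2L)
  expect_equal(rs$n_sites, 27L)
  expect_equal(rs$footprint, 89L)
  expect_equal(rs$total_len, 619L)
  expect_equal(rs$mean_dg, -108)
  expect_equal(rs$compaction, 7.0)
  expect_equal(rs$region_len, 498)

  empty <- region_summary(
    bc_sites("triple_negative")[0, ],
    by = c("gene", "region")
  )
  expect_equal(nrow(empty), 0)
})

test_that("tidy/glance/autoplot and the text map work on an analysis object", {
  an <- cluster_analysis(bc_sites("triple_negative"), by = c("gene", "region"))
  td <- tidy(an)
  expect_s3_class(td, "tbl_df")
  expect_equal(sum(td$n_sites), 72)
  gl <- glance(an)
  expect_equal(gl$n_sites, 72L)
  expect_equal(gl$n_clusters, nrow(td))
  p <- autoplot(an)
  expect_s3_class(p, "ggplot")

  cbl <- dplyr::filter(an$sites, gene == "CBL", region == "5UTR")
  map <- render_cluster_map(cbl)
  expect_length(map, nrow(cbl) + 1)
  expect_match(map[1], "^ID03332.3p-miR\\s+-+")
})
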