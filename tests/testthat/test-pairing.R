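g300 <- binned_genome(c(chrA = 3e6, chrB = 3e6), 10000)  # 300 bins each

test_that("pairs_from_bedpe applies separation band and edge policy", {
  pr <- tibble(chrom = "chrA",
               start1 = 0, end1 = 1, start2 = 0, end2 = 1,
               center_bin1 = c(100L, 5L, 100L), center_bin2 = c(140L, 40L, 105L),
               name = c("in_band", "edge", "close"))
  w <- pairs_from_bedpe(pr, g300, flank_bp = 200e3, min_sep = 105e3)
  expect_equal(nrow(w), 1L)
  expect_equal(w$source1, "in_band")   # sep 400 kb >= 105 kb, inside chrom
  dr <- window_drops(w)
  expect_equal(dr$n[dr$reason == "chromosome_edge"], 1L)
  expect_equal(dr$n[dr$reason == "separation_below_min"], 1L)

  # 100 kb flank at 5 kb resolution -> 20 bins, 41x41 window
  g5 <- binned_genome(c(chr1 = 5e6), 5000)
  pr2 <- tibble(chrom = "chr1", start1 = 0, end1 = 1, start2 = 0, end2 = 1,
                center_bin1 = 300L, center_bin2 = 400L, name = "l")
  w2 <- pairs_from_bedpe(pr2, g5, flank_bp = 100e3)
  expect_equal(w2$flank, 20L)

  expect_error(pairs_from_bedpe(pr2, g5, flank_bp = 100e3, min_sep = 1e9),
               class = "hicpileup_no_windows")
})

test_that("separation filter equals post-hoc filtering of the unfiltered stream", {
  set.seed(42)
  pr <- tibble(chrom = sample(c("chrA", "chrB"), 60, TRUE),
               start1 = 0, end1 = 1, start2 = 0, end2 = 1,
               center_bin1 = sample(20:250, 60, TRUE),
               name = paste0("p", 1:60))
  pr$center_bin2 <- pmin(pr$center_bin1 + sample(1:120, 60, TRUE), 299L)
  all_w <- pairs_from_bedpe(pr, g300, flank_bp = 50e3)
  sub_w <- tryCatch(
    pairs_from_bedpe(pr, g300, flank_bp = 50e3, min_sep = 3e5, max_sep = 8e5),
    error = function(e) NULL)
  sep <- (all_w$bin_j - all_w$bin_i) * 10000
  manual <- all_w[sep >= 3e5 & sep <= 8e5, ]
  expect_equal(nrow(sub_w), nrow(manual))
  expect_equal(sub_w$bin_i, manual$bin_i)
  expect_equal(sub_w$bin_j, manual$bin_j)
})

test_that("combinations emit the brute-force pair count, intra-chromosomal only", {
  r <- make_regions(g300, rep(c("chrA", "chrB"), c(4, 3)),
                    start = c(50, 90, 130, 170, 60, 100, 140) * 1e4,
                    end = c(51, 91, 131, 171, 61, 101, 141) * 1e4)
  w <- combinations_from_regions(r, g300, flank_bp = 50e3)
  expect_equal(nrow(w), choose(4, 2) + choose(3, 2))
  expect_true(all(w$bin_i <= w$bin_j))
  # no pair spans chromosomes: every emitted pair's sources share a chromosome
  expect_true(all(w$chrom %in% c("chrA", "chrB")))

  # brute force: all unordered in-band in-range pairs, counted independently
  cnt <- 0L
  for (cn in c("chrA", "chrB")) {
    cb <- r$center_bin[r$chrom == cn]
    for (i in seq_along(cb)) for (j in seq_along(cb)) {
      if (i < j) cnt <- cnt + 1L
    }
  }
  expect_equal(nrow(w), cnt)
})

test_that("cross_pairs matches A x B counts and collapses to combinations when A == B", {
  a <- make_regions(g300, rep("chrA", 2), c(50, 90) * 1e4, c(51, 91) * 1e4,
                    name = c("a1", "a2"))
  b <- make_regions(g300, rep("chrA", 3), c(130, 170, 210) * 1e4,
                    c(131, 171, 211) * 1e4, name = c("b1", "b2", "b3"))
  w <- cross_pairs(a, b, g300, flank_bp = 50e3)
  expect_equal(nrow(w), 6L)

  r <- make_regions(g300, rep("chrA", 4), c(50, 90, 130, 170) * 1e4,
                    c(51, 91, 131, 171) * 1e4)
  w_cross <- cross_pairs(r, r, g300, flank_bp = 50e3)
  w_comb <- combinations_from_regions(r, g300, flank_bp = 50e3)
  key <- function(w) sort(paste(w$chrom, w$bin_i, w$bin_j))
  expect_equal(key(w_cross), key(w_comb))  # self-pairs excluded either way

  expect_error(cross_pairs(a, b, g300, flank_bp = 50e3, min_sep = 1e9),
               class = "hicpileup_no_windows")
})

test_that("local windows sit on the diagonal and drop edges, conserving count", {
  r <- make_regions(g300, rep("chrA", 3), c(5, 50, 200) * 1e4 + 1e4,
                    c(5, 50, 200) * 1e4 + 2e4)
  w <- local_windows(r, g300, flank_bp = 400e3)  # flank 40 bins
  expect_true(all(w$bin_i == w$bin_j))
  expect_equal(nrow(w), 2L)  # the region at bin ~6 is dropped at the edge
  expect_equal(window_drops(w)$n, 1L)
})

test_that("rescaled windows expand extents by pad_fraction and drop by rule", {
  g5 <- binned_genome(c(chr1 = 10e6), 5000)
  r <- make_regions(g5, "chr1", 4e6, 4.6e6)        # 600 kb TAD = 120 bins
  w <- rescaled_windows(r, g5, pad_fraction = 1.0)
  expect_equal(w$ei - w$si + 1L, 360L)             # 3x feature length
  expect_equal(w$ej - w$sj + 1L, 360L)

  # mixed sizes map to the same output shape after rescale
  r2 <- make_regions(g5, c("chr1", "chr1"), c(3e6, 6e6), c(3.3e6, 6.9e6))
  w2 <- rescaled_windows(r2, g5, pad_fraction = 1.0)
  sim <- small_sim(seed = 3L)
  # (shape equality asserted via rescale_window in pileup-core tests)
  expect_equal(nrow(w2), 2L)
  expect_false(w2$ei[1] - w2$si[1] == w2$ei[2] - w2$si[2])

  # features beyond the length cutoff are excluded
  w3 <- rescaled_windows(r2, g5, pad_fraction = 1.0, max_len_bp = 500e3)
  expect_equal(nrow(w3), 1L)
  expect_equal(window_drops(w3)$reason, "too_long")
})

test_that("anchored windows always place the anchor on the row axis", {
  others <- make_regions(g300, rep("chrA", 4), c(30, 60, 200, 250) * 1e4,
                         c(31, 61, 201, 251) * 1e4,
                         name = c("p1", "p2", "p3", "p4"))
  anchor <- make_regions(g300, "chrA", 120e4, 121e4, name = "anchor")
  w <- anchored_pairs(anchor, others, g300, flank_bp = 50e3)
  expect_equal(nrow(w), 4L)
  expect_true(all(w$source1 == "anchor"))
  # partners upstream of the anchor are marked for transposition
  expect_equal(w$flip, others$center_bin < anchor$center_bin)

  # anchor excluded from its own partners; empty stream is not an error
  w0 <- anchored_pairs(anchor, anchor, g300, flank_bp = 50e3)
  expect_equal(nrow(w0), 0L)
})

test_that("subset sampling is deterministic, uniform and a no-op when n >= total", {
  w <- make_windows("chrA", 10:109, 150:249, flank = 5L)
  expect_identical(subset_sample(w, 200, seed = 4)$bin_i, w$bin_i)
  s1 <- subset_sample(w, 20, seed = 4)
  s2 <- subset_sample(w, 20, seed = 4)
  expect_identical(s1$bin_i, s2$bin_i)
  expect_equal(nrow(s1), 20L)

  # inclusion is uniform: chi-square over many seeds
  hits <- integer(100)
  for (s in 1:400) {
    idx <- subset_sample(w, 20, seed = s)$bin_i - 9L
    hits[idx] <- hits[idx] + 1L
  }
  expdct <- 400 * 20 / 100
  chi <- sum((hits - expdct)^2 / expdct)
  expect_lt(chi, qchisq(0.999, df = 99))
})

test_that("every emitted window lies fully inside its chromosome", {
  set.seed(7)
  r <- make_regions(g300, sample(c("chrA", "chrB"), 200, TRUE),
                    start = sample.int(295, 200, TRUE) * 1e4,
                    end = sample.int(295, 200, TRUE) * 1e4 + 2e4)
  w <- combinations_from_regions(r, g300, flank_bp = 150e3)
  f <- w$flank[1]
  nb <- n_bins(g300)[w$chrom]
  expect_true(all(w$bin_i - f >= 0))
  expect_true(all(w$bin_j + f <= nb - 1L))
})
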