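test_that("expected profile: constant diagonals, invalid bins, dense oracle", {
  g <- binned_genome(c(c1 = 30000), 10000)  # 3 bins
  px <- tibble(bin1 = c(0L, 0L, 0L, 1L, 1L, 2L),
               bin2 = c(0L, 1L, 2L, 1L, 2L, 2L),
               count = c(4, 2, 1, 4, 2, 4))
  x <- contact_matrix(g, list(c1 = px))
  expect_equal(compute_expected(x)$c1, c(4, 2, 1))

  # against the dense oracle on a noisy fixture, raw and balanced
  sim <- small_sim(seed = 31L, bias_sd = 0.3)
  e_raw <- compute_expected(sim$matrix, balanced = FALSE)
  e_bal <- compute_expected(sim$matrix, balanced = TRUE)
  for (cn in c("chrA", "chrB")) {
    expect_equal(e_raw[[cn]], oracle_expected(sim, cn), tolerance = 1e-12)
    expect_equal(e_bal[[cn]], oracle_expected(sim, cn, balanced = TRUE),
                 tolerance = 1e-12)
  }

  # an invalid bin: its pairs leave both numerator and denominator
  w <- rep(1, 3); w[2] <- NA
  xb <- contact_matrix(g, list(c1 = px), weights = list(c1 = w))
  eb <- compute_expected(xb, balanced = TRUE)
  expect_equal(eb$c1[1], 4)        # (4 + 4) / 2, bin 1 excluded
  expect_true(is.na(eb$c1[2]))     # no valid pair at offset 1
  expect_equal(eb$c1[3], 1)
})

test_that("simulated pure power-law decay is recovered with log-log slope -1", {
  spec <- synthetic_spec(c(c1 = 4e6), 10000, alpha = 1, diagonal_value = 800,
                         seed = 32L)
  sim <- simulate_contacts(spec, weights = "none", keep_dense = FALSE)
  d <- compute_expected(sim$matrix)$c1
  k <- 2:60
  fit <- lm(log(d[k + 1]) ~ log(k))
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.05)
})

test_that("expected windows are Toeplitz and match hand-built matrices", {
  prof <- structure(list(c1 = c(4, 2, 1, 0.5, 0.25, 0.1, 0.05, 0.02, 0.01, 0.005)),
                    class = "expected_profile")
  on_diag <- tibble(chrom = "c1", bin_i = 1L, bin_j = 1L, flank = 1L,
                    kind = "local", flip = FALSE)
  expect_identical(expected_window(prof, on_diag),
                   rbind(c(4, 2, 1), c(2, 4, 2), c(1, 2, 4)))

  off <- tibble(chrom = "c1", bin_i = 2L, bin_j = 7L, flank = 2L,
                kind = "pair", flip = FALSE)
  E <- expected_window(prof, off)
  # index-arithmetic oracle: E[a, b] = d(|row_bin - col_bin|)
  for (a in 1:5) for (b in 1:5) {
    expect_identical(E[a, b], prof$c1[abs((a - 1 + 0) - (b - 1 + 5)) + 1])
  }
  # diagonal-constant identity, everywhere in range, exactly
  expect_identical(E[-5, -5], E[-1, -1])
})

test_that("expected normalizer is the ratio-of-averages over the same stream", {
  prof <- structure(list(c1 = seq(100, 1, length.out = 100)),
                    class = "expected_profile")
  w1 <- make_windows("c1", 10, 30, flank = 2L)
  n1 <- expected_normalizer(prof, w1)
  expect_equal(n1$matrix, expected_window(prof, w1[1, ]))

  # hand enumeration on 3 mixed-distance specs: pixel (0,0) is the plain
  # mean of the three d values at the corner separations
  w3 <- make_windows("c1", c(10, 20, 30), c(30, 60, 90), flank = 2L)
  n3 <- expected_normalizer(prof, w3)
  seps <- (w3$bin_j - w3$bin_i)  # corner (1,1) sits at the same separation
  expect_equal(n3$matrix[3, 3], mean(prof$c1[seps + 1]))
  expect_equal(n3$matrix[1, 1], mean(prof$c1[seps + 1]))
  expect_equal(n3$matrix[1, 5], mean(prof$c1[seps + 4 + 1]))
})

test_that("shifted controls preserve separation, count, and determinism", {
  g <- binned_genome(c(c1 = 5e6), 10000)  # 500 bins
  w <- make_windows("c1", c(100, 200, 300), c(150, 260, 380), flank = 10L)
  ctl <- shifted_controls(w, g, n_shifts = 10, seed = 99)
  expect_equal(nrow(ctl), 30L)
  expect_equal(ctl$bin_j - ctl$bin_i, rep(w$bin_j - w$bin_i, each = 10))
  expect_true(all(ctl$kind == "control"))
  # controls stay inside the chromosome and off the source window
  expect_true(all(ctl$bin_i - 10 >= 0 & ctl$bin_j + 10 <= 499))
  src_i <- rep(w$bin_i, each = 10)
  expect_true(all(abs(ctl$bin_i - src_i) >= 21))
  ctl2 <- shifted_controls(w, g, n_shifts = 10, seed = 99)
  expect_identical(ctl$bin_i, ctl2$bin_i)
  ctl3 <- shifted_controls(w, g, n_shifts = 10, seed = 100)
  expect_false(identical(ctl$bin_i, ctl3$bin_i))

  # a window too large to move anywhere contributes no controls, tallied
  gw <- binned_genome(c(c1 = 1e6), 10000)  # 100 bins
  wbig <- make_windows("c1", 40, 60, flank = 30L)
  ctl0 <- shifted_controls(wbig, gw, n_shifts = 5, seed = 1)
  expect_equal(nrow(ctl0), 0L)
  expect_equal(window_drops(ctl0)$n, 1L)
})

test_that("coverage normalization: no-op on uniform coverage, guards on misuse", {
  # uniform synthetic map -> flat coverage -> profiles all 1 -> unchanged
  g <- binned_genome(c(c1 = 2e6), 10000)
  nb <- 200L
  idx <- which(upper.tri(matrix(0, nb, nb), diag = TRUE), arr.ind = TRUE)
  px <- tibble(bin1 = idx[, 1] - 1L, bin2 = idx[, 2] - 1L, count = 2)
  x <- contact_matrix(g, list(c1 = px))
  w <- make_windows("c1", c(50, 100), c(90, 150), flank = 5L)
  p_cov <- pileup(x, w, balanced = FALSE, normalization = "none", coverage = TRUE)
  p_raw <- pileup(x, w, balanced = FALSE, normalization = "none")
  # edge bins have smaller marginals; interior windows see constant coverage
  expect_equal(p_cov$matrix, p_raw$matrix, tolerance = 1e-12)

  expect_error(coverage_normalize(p_raw), "not recorded")
})

test_that("coverage normalization of biased data approximates balancing", {
  # separations start at one window width so no pixel touches the diagonal
  # (a same-bin pixel has E[b^2] != E[b]^2 and coverage cannot correct it)
  lens <- setNames(rep(1e7, 4), paste0("chr", 1:4))
  spec <- synthetic_spec(lens, 10000, alpha = 1, diagonal_value = 2000,
                         bias_sd = 0.3, seed = 33L)
  sim <- simulate_contacts(spec, weights = "true", keep_dense = FALSE)
  x <- sim$matrix
  set.seed(2)
  n <- 1000
  w <- make_windows(sample(paste0("chr", 1:4), n, TRUE),
                    bi <- sample(10:920, n, TRUE),
                    bi + sample(15:60, n, TRUE), flank = 6L)
  p_bal <- pileup(x, w, balanced = TRUE, normalization = "none")
  p_cov <- suppressWarnings(
    pileup(x, w, balanced = FALSE, normalization = "none", coverage = TRUE))
  r_bal <- p_bal$matrix / mean(p_bal$matrix)
  r_cov <- p_cov$matrix / mean(p_cov$matrix)
  expect_lt(max(abs(r_cov / r_bal - 1)), 0.10)
})

test_that("apply_normalizer divides element-wise with guards", {
  p <- fake_pileup(matrix(2, 5, 5), n_windows = 3L)
  expect_equal(apply_normalizer(p, matrix(1, 5, 5))$matrix, p$matrix)
  expect_equal(apply_normalizer(p, p)$matrix, matrix(1, 5, 5))

  nm <- matrix(2, 5, 5); nm[3, 3] <- 0; nm[1, 2] <- NA
  expect_warning(out <- apply_normalizer(p, nm), "zero")
  expect_true(is.na(out$matrix[3, 3]))
  expect_true(is.na(out$matrix[1, 2]))
  expect_equal(out$matrix[5, 5], 1)

  expect_error(apply_normalizer(p, matrix(1, 3, 3)), "shape")
})

test_that("an expected profile and shifted controls are mutually exclusive", {
  sim <- small_sim(seed = 34L)
  w <- make_windows("chrA", 40, 80, flank = 5L)
  prof <- compute_expected(sim$matrix)
  expect_error(pileup(sim$matrix, w, expected = prof, normalization = "shifts"),
               "mutually exclusive")
})
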