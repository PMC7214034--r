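# Shared fixtures and independent brute-force oracles.
#
# The oracles deliberately avoid the package's sparse-extraction /
# accumulator code path: they densify whole chromosomes and compute means
# with plain loops, so agreement is a genuine two-route check.

library(tibble)

# small 2-chromosome simulation with dense ground-truth counts kept
small_sim <- function(seed = 101L, bias_sd = 0, loops = NULL, domains = NULL,
                      n_bins = 120L, resolution = 10000L, alpha = 1,
                      diagonal_value = 300, weights = "true") {
  lens <- setNames(rep(n_bins * resolution, 2L), c("chrA", "chrB"))
  spec <- synthetic_spec(lens, resolution, alpha = alpha,
                         diagonal_value = diagonal_value,
                         bias_sd = bias_sd, seed = seed)
  if (!is.null(loops)) spec <- plant_loops(spec, loops)
  if (!is.null(domains)) spec <- plant_tads(spec, domains)
  simulate_contacts(spec, weights = weights, keep_dense = TRUE)
}

# dense balanced matrix from truth record (NA rows/cols for invalid bins)
dense_balanced <- function(sim, chrom) {
  d <- sim$truth$dense_counts[[chrom]]
  w <- sim$matrix$weights[[chrom]]
  if (is.null(w)) return(d)
  w[!is.finite(w)] <- NA_real_
  d * outer(w, w)
}

# brute-force mean pile-up: densify, slice, average per pixel with plain R
oracle_pileup <- function(sim, windows, balanced = FALSE) {
  stopifnot(nrow(windows) > 0)
  f <- windows$flank[1]
  size <- 2L * f + 1L
  s <- matrix(0, size, size)
  cnt <- matrix(0, size, size)
  for (r in seq_len(nrow(windows))) {
    cn <- windows$chrom[r]
    d <- if (balanced) dense_balanced(sim, cn) else sim$truth$dense_counts[[cn]]
    ri <- (windows$bin_i[r] - f):(windows$bin_i[r] + f) + 1L
    ci <- (windows$bin_j[r] - f):(windows$bin_j[r] + f) + 1L
    w <- d[ri, ci, drop = FALSE]
    if (isTRUE(windows$flip[r])) w <- t(w)
    ok <- is.finite(w)
    s[ok] <- s[ok] + w[ok]
    cnt <- cnt + ok
  }
  out <- s / cnt
  out[cnt == 0] <- NA_real_
  out
}

# brute-force per-diagonal expected from the dense matrix
oracle_expected <- function(sim, chrom, balanced = FALSE) {
  d <- if (balanced) dense_balanced(sim, chrom) else sim$truth$dense_counts[[chrom]]
  nb <- nrow(d)
  vapply(0:(nb - 1L), function(k) {
    v <- d[cbind(seq_len(nb - k), seq_len(nb - k) + k)]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
}

# ad-hoc window stream straight from bin coordinates
make_windows <- function(chrom, bin_i, bin_j, flank, kind = "pair",
                         flip = FALSE) {
  tb <- tibble(chrom = chrom, bin_i = as.integer(bin_i),
               bin_j = as.integer(bin_j), flank = as.integer(flank),
               kind = kind, si = NA_integer_, ei = NA_integer_,
               sj = NA_integer_, ej = NA_integer_, flip = flip,
               source1 = "s", source2 = "s")
  hicpileup:::new_windows(tb, hicpileup:::drop_tally())
}

# region_set straight from bp coordinates
make_regions <- function(genome, chrom, start, end,
                         name = paste0("r", seq_along(chrom))) {
  tb <- tibble(chrom = chrom, start = start, end = end, name = name)
  tb$center_bin <- as.integer(floor(((start + end) %/% 2) / genome$resolution))
  hicpileup:::as_region_set(tb)
}

# synthetic pileup object around a given matrix
fake_pileup <- function(m, n_windows = 1L) {
  hicpileup:::new_pileup(m, n_windows = n_windows, meta = list(resolution = 1L))
}

# vector with exact target coefficient of variation (mean 1, sample sd = cv)
vector_with_cv <- function(n, cv, seed = 1) {
  u <- withr::with_seed(seed, rnorm(n))
  z <- (u - mean(u)) / sd(u)
  1 + cv * z
}
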