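#' Recipe for a synthetic Hi-C contact map
#'
#' Describes a multi-chromosome contact map with power-law distance decay,
#' optional planted loop foci and enriched domains, multiplicative per-bin
#' biases and Poisson-sampled counts — the ground-truth fixture every other
#' module is validated against. The expected (Poisson mean) count is
#'
#' `lambda(i, j) = depth_scale * b_i * b_j * decay(|i - j|) *
#'   loop_factor(i, j) * domain_factor(i, j)`
#'
#' with `decay(k) = diagonal_value * k^(-alpha)` for `k >= 1` and
#' `decay(0) = 2 * decay(1)` (the self-interaction diagonal, excluded from
#' off-diagonal analyses anyway).
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param resolution Bin size (bp).
#' @param alpha Decay exponent (contact probability ~ separation^-alpha).
#' @param diagonal_value Expected count at 1-bin separation (before bias
#'   and depth scaling).
#' @param depth_scale Global sequencing-depth multiplier.
#' @param bias_sd SD of log-normal per-bin biases (`0` = no bias;
#'   `exp(rnorm(0, bias_sd))`, so biases have median 1).
#' @param seed Integer seed; the same recipe and seed give a byte-identical
#'   pixel table.
#' @return A `synthetic_spec` to pass to [plant_loops()], [plant_tads()]
#'   and [simulate_contacts()].
#' @export
synthetic_spec <- function(chrom_lengths, resolution, alpha = 1.0,
                           diagonal_value = 100, depth_scale = 1.0,
                           bias_sd = 0, seed = 1L) {
  stopifnot(alpha > 0, diagonal_value > 0, depth_scale >= 0, bias_sd >= 0)
  structure(list(
    genome = binned_genome(chrom_lengths, resolution),
    alpha = alpha, diagonal_value = diagonal_value,
    depth_scale = depth_scale, bias_sd = bias_sd, seed = as.integer(seed),
    loops = tibble(chrom = character(), bin_i = integer(), bin_j = integer(),
                   fold = numeric(), footprint = integer(), sigma = numeric()),
    domains = tibble(chrom = character(), start_bin = integer(),
                     end_bin = integer(), fold = numeric())
  ), class = "synthetic_spec")
}

#' Plant loop foci in a synthetic recipe
#'
#' Each loop multiplies the Poisson mean by `fold` on a `footprint`-square
#' block centered at `(bin_i, bin_j)`; with `sigma > 0` the factor decays as
#' a Gaussian from the center instead (`1 + (fold - 1) * exp(-r^2 / (2
#' sigma^2))`), preserving `fold` exactly at the central pixel. Overlapping
#' features stack multiplicatively.
#'
#' @param spec A [synthetic_spec()].
#' @param loops Tibble with `chrom`, `bin_i`, `bin_j` (0-based bins,
#'   `bin_i <= bin_j`), `fold`, optional `footprint` (default 1) and
#'   `sigma` (default 0 = hard block).
#' @return The augmented `synthetic_spec`.
#' @export
plant_loops <- function(spec, loops) {
  stopifnot(inherits(spec, "synthetic_spec"))
  loops <- as_tibble(loops)
  if (!"footprint" %in% names(loops)) loops$footprint <- 1L
  if (!"sigma" %in% names(loops)) loops$sigma <- 0
  stopifnot(all(loops$fold > 0), all(loops$footprint >= 1L))
  nb <- n_bins(spec$genome)[loops$chrom]
  if (anyNA(nb) || any(loops$bin_i < 0) || any(loops$bin_j >= nb)) {
    abort("planted loops must lie inside their chromosome.")
  }
  if (any(loops$bin_i > loops$bin_j)) abort("planted loops need bin_i <= bin_j.")
  spec$loops <- dplyr::bind_rows(spec$loops, loops)
  spec
}

#' Plant enriched domains (TAD-like blocks) in a synthetic recipe
#'
#' Each domain multiplies the Poisson mean by `fold` on the square block
#' `[start_bin, end_bin]^2` (both ends inclusive, 0-based bins).
#'
#' @param spec A [synthetic_spec()].
#' @param domains Tibble with `chrom`, `start_bin`, `end_bin`, `fold`.
#' @return The augmented `synthetic_spec`.
#' @export
plant_tads <- function(spec, domains) {
  stopifnot(inherits(spec, "synthetic_spec"))
  domains <- as_tibble(domains)
  stopifnot(all(domains$fold > 0), all(domains$start_bin <= domains$end_bin))
  nb <- n_bins(spec$genome)[domains$chrom]
  if (anyNA(nb) || any(domains$start_bin < 0) || any(domains$end_bin >= nb)) {
    abort("planted domains must lie inside their chromosome.")
  }
  spec$domains <- dplyr::bind_rows(spec$domains, domains)
  spec
}

# Poisson-mean matrix of one chromosome (dense upper triangle as full
# matrix); the ground truth all recovery checks are computed from.
lambda_matrix <- function(spec, chrom, bias) {
  nb <- n_bins(spec$genome, chrom)
  k <- abs(outer(0:(nb - 1L), 0:(nb - 1L), `-`))
  dec <- c(2 * spec$diagonal_value, spec$diagonal_value * (1:(nb - 1L))^(-spec$alpha))
  lam <- matrix(dec[k + 1L], nb, nb)
  lam <- lam * outer(bias, bias) * spec$depth_scale
  lp <- spec$loops[spec$loops$chrom == chrom, , drop = FALSE]
  for (r in seq_len(nrow(lp))) {
    h <- (lp$footprint[r] - 1L) %/% 2L
    ri <- pmax(0L, lp$bin_i[r] - h):pmin(nb - 1L, lp$bin_i[r] + h)
    ci <- pmax(0L, lp$bin_j[r] - h):pmin(nb - 1L, lp$bin_j[r] + h)
    if (lp$sigma[r] > 0) {
      # Gaussian focal peak over a wider support
      s <- lp$sigma[r]
      ext <- ceiling(3 * s)
      ri <- pmax(0L, lp$bin_i[r] - ext):pmin(nb - 1L, lp$bin_i[r] + ext)
      ci <- pmax(0L, lp$bin_j[r] - ext):pmin(nb - 1L, lp$bin_j[r] + ext)
      d2 <- outer((ri - lp$bin_i[r])^2, (ci - lp$bin_j[r])^2, `+`)
      fac <- 1 + (lp$fold[r] - 1) * exp(-d2 / (2 * s^2))
    } else {
      fac <- matrix(lp$fold[r], length(ri), length(ci))
    }
    lam[ri + 1L, ci + 1L] <- lam[ri + 1L, ci + 1L] * fac
    lam[ci + 1L, ri + 1L] <- lam[ci + 1L, ri + 1L] * t(fac)  # keep symmetry
  }
  dm <- spec$domains[spec$domains$chrom == chrom, , drop = FALSE]
  for (r in seq_len(nrow(dm))) {
    ri <- (dm$start_bin[r]:dm$end_bin[r]) + 1L
    lam[ri, ri] <- lam[ri, ri] * dm$fold[r]
  }
  lam
}

#' Simulate a contact matrix from a synthetic recipe
#'
#' Draws Poisson counts for the upper triangle of every chromosome and
#' returns an in-memory [contact_matrix()] plus a ground-truth record:
#' per-chromosome biases, the planted features, the decay parameters, the
#' balancing weights used and (for small genomes) the dense sampled count
#' matrices for brute-force oracles.
#'
#' @param spec A [synthetic_spec()].
#' @param weights How to attach balancing weights: `"true"` (exact
#'   `1 / b_i`), `"ic"` (iterative correction on the sampled counts to
#'   tolerance 1e-6), or `"none"`.
#' @param keep_dense Keep dense per-chromosome count matrices in the truth
#'   record (default: only when every chromosome has <= 600 bins).
#' @return A list with `matrix` (the `contact_matrix`) and `truth`.
#' @export
simulate_contacts <- function(spec, weights = c("true", "ic", "none"),
                              keep_dense = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  weights <- match.arg(weights)
  genome <- spec$genome
  cn <- chrom_names(genome)
  if (is.null(keep_dense)) keep_dense <- max(genome$chroms$n_bins) <= 600L

  out <- with_local_seed(spec$seed, {
    pixels <- list(); wlist <- list(); blist <- list(); dense <- list()
    for (ch in cn) {
      nb <- n_bins(genome, ch)
      bias <- if (spec$bias_sd > 0) exp(rnorm(nb, 0, spec$bias_sd)) else rep(1, nb)
      lam <- lambda_matrix(spec, ch, bias)
      up <- which(upper.tri(lam, diag = TRUE), arr.ind = TRUE)
      counts <- rpois(nrow(up), lam[up])
      nz <- counts > 0
      pixels[[ch]] <- tibble(bin1 = up[nz, 1L] - 1L, bin2 = up[nz, 2L] - 1L,
                             count = as.numeric(counts[nz]))
      blist[[ch]] <- bias
      if (keep_dense) {
        dm <- matrix(0, nb, nb)
        dm[up] <- counts
        dm <- dm + t(dm) - diag(diag(dm))
        dense[[ch]] <- dm
      }
      wlist[[ch]] <- switch(weights,
        true = 1 / bias,
        ic = NULL,  # filled below from the sampled counts
        none = NULL)
    }
    list(pixels = pixels, weights = wlist, bias = blist, dense = dense)
  })

  w <- if (weights == "none") NULL else out$weights
  cmat <- contact_matrix(genome, out$pixels,
                         weights = if (weights == "true") w else NULL)
  if (weights == "ic") {
    wic <- lapply(setNames(cn, cn), function(ch) {
      ic_weights(chrom_sparse(cmat, ch))
    })
    cmat <- contact_matrix(genome, out$pixels, weights = wic)
  }

  list(
    matrix = cmat,
    truth = list(
      spec = spec, bias = out$bias,
      weights_mode = weights,
      weights = if (weights == "none") NULL else cmat$weights,
      dense_counts = if (keep_dense) out$dense else NULL
    )
  )
}

# Iterative correction: multiplicative per-bin weights equalizing marginal
# sums of the symmetric matrix, to relative tolerance `tol`. Bins with zero
# marginal get a non-finite (invalid) weight.
ic_weights <- function(sym, tol = 1e-6, max_iter = 500L) {
  nb <- nrow(sym)
  w <- rep(1, nb)
  marg0 <- as.numeric(Matrix::colSums(sym))
  dead <- marg0 == 0
  for (it in seq_len(max_iter)) {
    D <- Diagonal(nb, ifelse(dead, 0, w))
    marg <- as.numeric(Matrix::colSums(D %*% sym %*% D))
    m <- marg[!dead]
    if (length(m) == 0L) break
    target <- mean(m)
    if (max(abs(m / target - 1)) < tol) break
    adj <- sqrt(marg / target)
    adj[dead | adj == 0] <- 1
    w <- w / adj
  }
  # scale so the balanced matrix keeps the raw matrix's mean visibility
  w[dead] <- NA_real_
  w
}

#' Write a synthetic fixture as a cooler file with ground truth
#'
#' Convenience wrapper: simulates the recipe, writes the `.cool` file (and
#' a JSON sidecar with the recipe and planted features) and returns the
#' simulation result.
#'
#' @param spec A [synthetic_spec()].
#' @param path Output `.cool` path; the sidecar is `<path>.truth.json`.
#' @param weights Passed to [simulate_contacts()].
#' @return The [simulate_contacts()] result, invisibly.
#' @export
write_cool_fixture <- function(spec, path, weights = "true") {
  sim <- simulate_contacts(spec, weights = weights)
  write_cool(sim$matrix, path, weights = !is.null(sim$truth$weights))
  sidecar <- list(
    resolution = spec$genome$resolution,
    chrom_lengths = setNames(as.list(spec$genome$chroms$length),
                             spec$genome$chroms$chrom),
    alpha = spec$alpha, diagonal_value = spec$diagonal_value,
    depth_scale = spec$depth_scale, bias_sd = spec$bias_sd,
    seed = spec$seed, weights_mode = weights,
    loops = spec$loops, domains = spec$domains
  )
  jsonlite::write_json(sidecar, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sim)
}
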