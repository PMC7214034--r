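#' Central enrichment of a pile-up
#'
#' Mean of the central `size` x `size` pixel block (default 3 x 3, the
#' dataset-level enrichment statistic; `size = 1` gives the bare central
#' pixel used for per-region loop-ability). Missing pixels are excluded;
#' the score is missing if the whole block is.
#'
#' @param pileup A `pileup` or bare matrix with odd side length >= `size`.
#' @param size Odd block size.
#' @return Scalar mean, or `NA` if the block is entirely missing.
#' @export
central_enrichment <- function(pileup, size = 3L) {
  m <- if (inherits(pileup, "pileup")) pileup$matrix else pileup
  n <- nrow(m)
  stopifnot(n == ncol(m), n %% 2L == 1L, size %% 2L == 1L, n >= size)
  c0 <- (n + 1L) %/% 2L
  h <- (size - 1L) %/% 2L
  blk <- m[(c0 - h):(c0 + h), (c0 - h):(c0 + h)]
  if (all(is.na(blk))) NA_real_ else mean(blk, na.rm = TRUE)
}

corner_blocks <- function(m, size, which = c("tl", "br", "bl", "tr")) {
  n <- nrow(m)
  lapply(setNames(which, which), function(w) {
    switch(w,
      tl = m[seq_len(size), seq_len(size)],
      br = m[(n - size + 1L):n, (n - size + 1L):n],
      bl = m[(n - size + 1L):n, seq_len(size)],
      tr = m[seq_len(size), (n - size + 1L):n])
  })
}

#' Corner-normalize a pile-up for display
#'
#' Divides the matrix by the mean of its top-left and bottom-right corner
#' blocks (default a single pixel each), bringing pile-ups computed on
#' different scales to a common one for side-by-side display.
#'
#' @param pileup A `pileup`.
#' @param corner_size Corner block side (default 1 pixel).
#' @return The rescaled `pileup`.
#' @export
corner_normalize <- function(pileup, corner_size = 1L) {
  m <- pileup$matrix
  cb <- corner_blocks(m, corner_size, c("tl", "br"))
  ref <- mean(c(cb$tl, cb$br), na.rm = TRUE)
  if (!is.finite(ref) || ref <= 0) {
    abort("cannot corner-normalize: corner mean is missing or <= 0.")
  }
  out <- pileup
  out$matrix <- m / ref
  out$meta$corner_normalized <- TRUE
  out
}

#' Mean of the lower-left corner block
#'
#' Enrichment of the lower-left corner, the region of the pile-up where
#' contacts inside the loop (between the anchors) accumulate — elevated for
#' extrusion-associated loops.
#'
#' @inheritParams corner_normalize
#' @param corner_size Corner block side.
#' @return Scalar mean (missing-aware).
#' @export
lower_left_mean <- function(pileup, corner_size = 1L) {
  m <- if (inherits(pileup, "pileup")) pileup$matrix else pileup
  mean(corner_blocks(m, corner_size, "bl")$bl, na.rm = TRUE)
}

#' Coefficient of variation of the pile-up corners
#'
#' Sample standard deviation over mean of the 5 x 5 upper-left and
#' lower-right corner blocks — a noise statistic for quality control of
#' single-cell pile-ups. The window must be at least 13 x 13 so the corners
#' cannot touch the central 3 x 3. A corner with more than half its pixels
#' missing yields an undefined (`NA`) CV.
#'
#' @param pileup A `pileup` or matrix.
#' @param corner_size Corner block side (default 5).
#' @return Named numeric vector `c(cv_tl, cv_br)`.
#' @export
corner_cv <- function(pileup, corner_size = 5L) {
  m <- if (inherits(pileup, "pileup")) pileup$matrix else pileup
  n <- nrow(m)
  if (n < 2L * corner_size + 3L) {
    abort(sprintf(
      "pile-up is %dx%d but corner CV with %dx%d corners needs at least %dx%d (corners must not touch the central 3x3).",
      n, n, corner_size, corner_size, 2L * corner_size + 3L, 2L * corner_size + 3L))
  }
  cb <- corner_blocks(m, corner_size, c("tl", "br"))
  cv1 <- function(v) {
    if (mean(is.na(v)) > 0.5) return(NA_real_)
    mu <- mean(v, na.rm = TRUE)
    if (!is.finite(mu) || mu == 0) return(NA_real_)
    stats::sd(v, na.rm = TRUE) / mu
  }
  c(cv_tl = cv1(cb$tl), cv_br = cv1(cb$br))
}

#' Corner-CV noise filter
#'
#' A pile-up fails (is "too noisy") iff the larger of its two corner CVs is
#' greater than or equal to `threshold` (default 0.5; the boundary is
#' inclusive on the failing side). An undefined CV fails conservatively.
#'
#' @inheritParams corner_cv
#' @param threshold Inclusive failure threshold.
#' @return `TRUE` if the pile-up passes.
#' @export
cv_filter <- function(pileup, threshold = 0.5, corner_size = 5L) {
  cv <- corner_cv(pileup, corner_size)
  if (any(is.na(cv))) return(FALSE)
  max(cv) < threshold
}

#' Summary scores of a pile-up
#'
#' @param pileup A `pileup` (window >= 13 x 13 for the CV fields, otherwise
#'   they are `NA`).
#' @return A one-row tibble: `central3x3`, `central_pixel`,
#'   `corner_mean_tl_br`, `lower_left_mean`, `cv_tl`, `cv_br`, `passed_cv`,
#'   `n_windows`.
#' @export
pileup_scores <- function(pileup) {
  m <- pileup$matrix
  cb <- corner_blocks(m, 1L, c("tl", "br"))
  cv <- if (nrow(m) >= 13L) corner_cv(pileup) else c(cv_tl = NA_real_, cv_br = NA_real_)
  tibble(
    central3x3 = central_enrichment(pileup, 3L),
    central_pixel = central_enrichment(pileup, 1L),
    corner_mean_tl_br = mean(c(cb$tl, cb$br), na.rm = TRUE),
    lower_left_mean = lower_left_mean(pileup),
    cv_tl = cv[["cv_tl"]], cv_br = cv[["cv_br"]],
    passed_cv = if (nrow(m) >= 13L) cv_filter(pileup) else NA,
    n_windows = pileup$n_windows
  )
}
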