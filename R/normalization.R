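#' Chromosome-wide expected profile (mean value per diagonal)
#'
#' For each chromosome, `d(k)` is the mean contact value over all pairs of
#' valid bins at separation `k` bins — including structural zeros between
#' valid bins, since the expected value is a mean over the map, not over
#' stored pixels. In balanced mode, pairs involving an invalid-weight bin
#' are excluded from both numerator and denominator.
#'
#' @param x A [contact_matrix()].
#' @param balanced Compute on balanced values?
#' @return An `expected_profile`: named list of numeric vectors, entry
#'   `k + 1` = `d(k)`.
#' @export
compute_expected <- function(x, balanced = FALSE) {
  prof <- lapply(setNames(chrom_names(x$genome), chrom_names(x$genome)), function(cn) {
    nb <- n_bins(x$genome, cn)
    px <- chrom_pixels(x, cn)
    if (balanced) {
      w <- chrom_weights(x, cn)
      if (is.null(w)) abort("balanced expected requested but no weights present.")
      valid <- is.finite(w)
    } else {
      w <- rep(1, nb)
      valid <- rep(TRUE, nb)
    }
    if (sum(valid) < 2L) {
      warn(paste0("chromosome ", cn, " has < 2 valid bins; expected profile is all-missing."))
      return(rep(NA_real_, nb))
    }
    # pairs of valid bins per diagonal offset
    v <- as.numeric(valid)
    npairs <- vapply(0:(nb - 1L), function(k) {
      sum(v[seq_len(nb - k)] * v[seq_len(nb - k) + k])
    }, numeric(1))
    val <- px$count * w[px$bin1 + 1L] * w[px$bin2 + 1L]
    off <- px$bin2 - px$bin1
    keep <- is.finite(val)
    sums <- numeric(nb)
    if (any(keep)) {
      agg <- rowsum(val[keep], off[keep])
      sums[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
    }
    d <- sums / npairs
    d[npairs == 0] <- NA_real_
    d
  })
  structure(prof, class = "expected_profile", value_col = "computed")
}

#' Toeplitz expected window
#'
#' Under the distance-only model the whole-chromosome expected matrix is
#' diagonal-constant (`A[i, j] == A[i+1, j+1] == d(i - j)`), so the expected
#' values of any window follow from index arithmetic on the profile alone —
#' only the window footprint is ever allocated.
#'
#' @param profile An `expected_profile` ([compute_expected()] /
#'   [read_expected()]).
#' @param spec One window-stream row.
#' @return Dense matrix of expected values matching the window shape.
#' @export
expected_window <- function(profile, spec) {
  d <- profile[[spec$chrom]]
  if (is.null(d)) abort(paste0("expected profile has no chromosome ", spec$chrom))
  if (is_rescaled_spec(spec)) {
    rows <- spec$si:spec$ei
    cols <- spec$sj:spec$ej
  } else {
    f <- spec$flank
    rows <- (spec$bin_i - f):(spec$bin_i + f)
    cols <- (spec$bin_j - f):(spec$bin_j + f)
  }
  off <- abs(outer(rows, cols, `-`))
  E <- matrix(d[off + 1L], nrow = length(rows))
  if (isTRUE(spec$flip)) E <- t(E)
  E
}

#' Average expected windows into a normalizing matrix
#'
#' Element-wise mean of [expected_window()] over exactly the window stream
#' used for the observed pile-up (ratio of averages, per the pile-up
#' procedure's order of operations — the observed average is later divided
#' by this average, never averaged as per-window ratios).
#'
#' @param profile An `expected_profile`.
#' @param windows A window stream tibble.
#' @param target_size Target size when the stream is in rescale mode.
#' @return A `pileup` object serving as the normalizer (provenance
#'   `"expected"`).
#' @export
expected_normalizer <- function(profile, windows, target_size = NULL) {
  rescaled <- nrow(windows) > 0L && identical(windows$kind[1], "rescaled")
  size <- if (rescaled) target_size else 2L * windows$flank[1] + 1L
  acc <- new_accumulator(size, coverage = FALSE, rescaled = rescaled)
  for (r in seq_len(nrow(windows))) {
    E <- expected_window(profile, windows[r, ])
    if (rescaled) E <- rescale_window(E, target_size)
    acc <- accumulate(acc, E)
  }
  finalize_mean(acc, meta = list(normalizer = "expected"))
}

#' Randomly shifted control windows
#'
#' For each source window, `n_shifts` controls are drawn by sliding the
#' whole window along the diagonal by one shared random offset, preserving
#' the anchor separation exactly. Offsets are drawn uniformly over the
#' positions that keep the control inside the chromosome and at least a
#' minimum shift away from the source — one full window width for
#' fixed-flank windows, a third of the span (one feature length at the
#' default padding) for rescaled windows — so controls never sample the
#' signal they normalize. A window with no admissible offset contributes no
#' controls (tallied). Deterministic for a given seed.
#'
#' @param windows A window stream tibble.
#' @param genome A [binned_genome()].
#' @param n_shifts Controls per source window (>= 1).
#' @param seed Integer seed.
#' @return A window stream of control windows (`kind == "control"` retains
#'   spans/flanks of its sources).
#' @export
shifted_controls <- function(windows, genome, n_shifts, seed) {
  stopifnot(n_shifts >= 1L)
  nbv <- n_bins(genome)
  out <- with_local_seed(seed, {
    rows <- vector("list", nrow(windows))
    for (r in seq_len(nrow(windows))) {
      sp <- windows[r, ]
      nb <- nbv[[sp$chrom]]
      if (is_rescaled_spec(sp)) {
        lo_i <- sp$si; hi_i <- sp$ei; lo_j <- sp$sj; hi_j <- sp$ej
        # a rescaled window is mostly padding; shifting by a third of the
        # span clears the central feature block while staying placeable
        minshift <- as.integer(ceiling((max(hi_i - lo_i, hi_j - lo_j) + 1L) / 3))
      } else {
        f <- sp$flank
        lo_i <- sp$bin_i - f; hi_i <- sp$bin_i + f
        lo_j <- sp$bin_j - f; hi_j <- sp$bin_j + f
        minshift <- 2L * f + 1L
      }
      # admissible shared offsets: window stays inside [0, nb) and moves by
      # at least the minimum shift for its kind
      off_lo <- -min(lo_i, lo_j)
      off_hi <- nb - 1L - max(hi_i, hi_j)
      cand <- c(seq2(off_lo, -minshift), seq2(minshift, off_hi))
      if (length(cand) == 0L) next
      offs <- cand[sample.int(length(cand), n_shifts, replace = TRUE)]
      ctl <- sp[rep(1L, n_shifts), ]
      ctl$bin_i <- sp$bin_i + offs
      ctl$bin_j <- sp$bin_j + offs
      if (is_rescaled_spec(sp)) {
        ctl$si <- sp$si + offs; ctl$ei <- sp$ei + offs
        ctl$sj <- sp$sj + offs; ctl$ej <- sp$ej + offs
      }
      ctl$kind <- "control"
      rows[[r]] <- ctl
    }
    dplyr::bind_rows(rows)
  })
  n_placed <- if (is.null(out) || nrow(out) == 0L) 0L else nrow(out) / n_shifts
  drops <- drop_tally(no_control_position = nrow(windows) - n_placed)
  new_windows(out %||% window_cols(), drops[drops$n > 0, ])
}

seq2 <- function(from, to) if (from > to) integer() else seq.int(from, to)

#' Coverage-normalize a pile-up
#'
#' Divides the pile-up element-wise by the outer product of its mean flank
#' coverage profiles (each scaled to unit mean). Mitigates per-bin
#' visibility biases when balancing weights are unavailable (e.g.
#' single-cell data); intended for unbalanced pile-ups — a warning is
#' raised if the pile-up was built from balanced values. No correction for
#' the method's slight residual over-correction is applied.
#'
#' @param pileup A `pileup` built with coverage recording enabled.
#' @return The normalized `pileup`.
#' @export
coverage_normalize <- function(pileup) {
  if (is.null(pileup$coverage)) {
    abort("coverage was not recorded for this pile-up; rerun with coverage = TRUE.")
  }
  if (isTRUE(pileup$meta$balanced)) {
    warn("coverage normalization is intended for unbalanced data; applying anyway.")
  }
  r <- pileup$coverage$row
  cc <- pileup$coverage$col
  if (mean(r) <= 0 || mean(cc) <= 0) {
    abort("cannot coverage-normalize: zero mean coverage.")
  }
  r <- r / mean(r)
  cc <- cc / mean(cc)
  denom <- outer(r, cc)
  bad <- denom <= 0
  m <- pileup$matrix / denom
  m[bad] <- NA_real_
  out <- pileup
  out$matrix <- m
  out$meta$coverage_normalized <- TRUE
  out
}

#' Divide a pile-up by its normalizing matrix
#'
#' Element-wise ratio; pixels missing in either operand (or zero in the
#' normalizer) are missing in the result.
#'
#' @param pileup Observed `pileup`.
#' @param normalizer A `pileup` (expected- or control-derived) of the same
#'   shape, or a bare matrix.
#' @return The normalized `pileup`, with normalizer provenance recorded.
#' @export
apply_normalizer <- function(pileup, normalizer) {
  nm <- if (inherits(normalizer, "pileup")) normalizer$matrix else normalizer
  if (!all(dim(pileup$matrix) == dim(nm))) {
    abort("pile-up and normalizer shapes differ.")
  }
  zero <- !is.na(nm) & nm == 0
  if (any(zero & !is.na(pileup$matrix))) {
    warn(sprintf("%d pixel(s) had a zero normalizer value; set to missing.", sum(zero)))
  }
  nm[zero] <- NA_real_
  out <- pileup
  out$matrix <- pileup$matrix / nm
  out$meta$normalized_by <- if (inherits(normalizer, "pileup")) {
    normalizer$meta$normalizer %||% "matrix"
  } else "matrix"
  out
}
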