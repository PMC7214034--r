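#' Extract one 2D window from the contact map
#'
#' Returns the dense sub-matrix for one window specification. Pixels not
#' stored in the sparse map are 0 when both bins are valid; in balanced mode
#' any pixel touching an invalid-weight bin is `NA`. On-diagonal windows
#' reflect the symmetry of the map. Anchored windows flagged `flip` are
#' transposed so the anchor occupies the row axis.
#'
#' @param x A [contact_matrix()].
#' @param spec One row of a window stream ([window-streams]).
#' @param balanced Use balancing weights?
#' @return A dense numeric matrix: `(2 * flank + 1)` square for fixed-flank
#'   windows, span-shaped for rescale-mode windows.
#' @export
extract_window <- function(x, spec, balanced = FALSE) {
  if (is_rescaled_spec(spec)) {
    rows <- spec$si:spec$ei
    cols <- spec$sj:spec$ej
  } else {
    f <- spec$flank
    rows <- (spec$bin_i - f):(spec$bin_i + f)
    cols <- (spec$bin_j - f):(spec$bin_j + f)
  }
  nb <- n_bins(x$genome, spec$chrom)
  stopifnot(rows[1] >= 0L, cols[1] >= 0L,
            rows[length(rows)] < nb, cols[length(cols)] < nb)
  w <- contact_values(x, spec$chrom, rows, cols, balanced = balanced)
  if (isTRUE(spec$flip)) w <- t(w)
  w
}

# A window spec is in rescale mode iff it carries bin spans (controls
# derived from rescaled sources keep the spans but change `kind`).
is_rescaled_spec <- function(spec) {
  "si" %in% names(spec) && length(spec[["si"]]) == 1L && !is.na(spec[["si"]])
}

# Fractional-overlap weight matrix mapping n input cells onto t output cells
# (rows: output). Each row sums to 1/t; `t^2 * O %*% m %*% t(O)` is the
# area-weighted (conservative) resampling of m, exactly the block mean when
# n is a multiple of t and the identity when n == t.
overlap_weights <- function(n, t) {
  inb <- seq(0, 1, length.out = n + 1L)
  outb <- seq(0, 1, length.out = t + 1L)
  lo <- pmax(outer(outb[-(t + 1L)], inb[-(n + 1L)], function(a, b) pmax(a, b)), 0)
  hi <- outer(outb[-1L], inb[-1L], function(a, b) pmin(a, b))
  O <- pmax(hi - lo, 0)
  O
}

#' Rescale a window to a fixed target size
#'
#' Area-weighted (conservative) resampling: every output pixel is the
#' overlap-weighted mean of the input pixels it covers, so constant inputs
#' are preserved exactly and block structure maps to block means. Missing
#' input pixels are imputed with the mean of their matrix diagonal (the
#' natural sharing axis for distance-decaying contact data) before
#' resampling; output pixels drawing more than half their weight from
#' missing inputs are re-masked.
#'
#' @param window Dense numeric matrix (may contain `NA`).
#' @param target_size Odd integer >= 3: output is `target_size` square.
#' @return A `target_size` x `target_size` numeric matrix.
#' @export
rescale_window <- function(window, target_size) {
  stopifnot(target_size >= 3L, target_size %% 2L == 1L)
  nr <- nrow(window); nc <- ncol(window)
  miss <- is.na(window)
  filled <- window
  if (any(miss)) {
    dg <- row(window) - col(window)
    dmeans <- tapply(window, dg, function(v) mean(v, na.rm = TRUE))
    fill <- dmeans[as.character(dg[miss])]
    fill[!is.finite(fill)] <- mean(window, na.rm = TRUE)
    fill[!is.finite(fill)] <- 0
    filled[miss] <- fill
  }
  Or <- overlap_weights(nr, target_size)
  Oc <- overlap_weights(nc, target_size)
  out <- (Or %*% filled %*% t(Oc)) * (target_size^2)
  if (any(miss)) {
    frac <- (Or %*% (miss * 1) %*% t(Oc)) * (target_size^2)
    out[frac > 0.5] <- NA_real_
  }
  unname(out)
}

# 1D conservative resampling (coverage vectors of rescaled windows).
rescale_vector <- function(v, target_size) {
  O <- overlap_weights(length(v), target_size)
  as.numeric(O %*% v) * target_size
}

#' Running pile-up accumulator
#'
#' Holds the per-pixel running sum of finite window values, the per-pixel
#' count of finite contributions, the window tally, and (optionally) running
#' sums of per-bin chromosome coverage across the window flanks. Shapes are
#' fixed at construction.
#'
#' @param size Window side length in bins (2 * flank + 1, or `target_size`).
#' @param coverage Record flank coverage profiles?
#' @param rescaled Will windows be rescaled to `size`?
#' @return A `pileup_accumulator`.
#' @export
new_accumulator <- function(size, coverage = FALSE, rescaled = FALSE) {
  structure(list(
    sum = matrix(0, size, size),
    cnt = matrix(0L, size, size),
    n = 0L,
    cov_row = numeric(size), cov_col = numeric(size),
    coverage = coverage, rescaled = rescaled, size = as.integer(size)
  ), class = "pileup_accumulator")
}

#' Add one window to an accumulator
#'
#' Finite pixels are added to the running sum and counted; the window tally
#' increments by one. When coverage recording is active the chromosome-wide
#' coverage of the window's row and column bins is accumulated.
#'
#' @param acc A [new_accumulator()].
#' @param window Dense matrix matching the accumulator shape.
#' @param cov_row,cov_col Optional per-bin coverage vectors for the window's
#'   row/column flanks (required when `acc$coverage`).
#' @return The updated accumulator.
#' @export
accumulate <- function(acc, window, cov_row = NULL, cov_col = NULL) {
  stopifnot(nrow(window) == acc$size, ncol(window) == acc$size)
  fin <- is.finite(window)
  if (any(fin)) acc$sum[fin] <- acc$sum[fin] + window[fin]
  acc$cnt <- acc$cnt + fin
  acc$n <- acc$n + 1L
  if (acc$coverage) {
    if (is.null(cov_row) || is.null(cov_col)) {
      abort("coverage recording is active but no coverage vectors supplied.")
    }
    cr <- ifelse(is.finite(cov_row), cov_row, 0)
    cc <- ifelse(is.finite(cov_col), cov_col, 0)
    acc$cov_row <- acc$cov_row + cr
    acc$cov_col <- acc$cov_col + cc
  }
  acc
}

#' Merge per-chromosome accumulators
#'
#' Field-wise sum of accumulators of identical shape and mode; the basis of
#' per-chromosome parallelism. Merging is associative, with the empty
#' accumulator as identity; merged and serial results agree to float
#' summation order (<= 1e-12 relative).
#'
#' @param accs List of `pileup_accumulator`s.
#' @return A single merged accumulator.
#' @export
merge_accumulators <- function(accs) {
  stopifnot(length(accs) >= 1L)
  out <- accs[[1L]]
  for (a in accs[-1L]) {
    if (a$size != out$size || !identical(a$coverage, out$coverage) ||
        !identical(a$rescaled, out$rescaled)) {
      abort("cannot merge accumulators with mismatched shapes or modes.")
    }
    out$sum <- out$sum + a$sum
    out$cnt <- out$cnt + a$cnt
    out$n <- out$n + a$n
    out$cov_row <- out$cov_row + a$cov_row
    out$cov_col <- out$cov_col + a$cov_col
  }
  out
}

#' Finalize an accumulator into a mean pile-up
#'
#' Each pixel becomes `sum / count` over its finite contributions; pixels
#' with zero contributions are missing. When no bin is invalid this equals
#' the paper-style division by the total window tally (the per-pixel count
#' then equals `n_windows` everywhere); the per-pixel denominator only
#' matters when balancing marks bins invalid.
#'
#' @param acc A `pileup_accumulator`.
#' @param meta Named list of metadata stamped on the result.
#' @return A `pileup` object: `matrix`, `n_windows`, `meta`, and (when
#'   recorded) the mean coverage profiles.
#' @export
finalize_mean <- function(acc, meta = list()) {
  if (acc$n == 0L) abort("no usable windows were accumulated.",
                         class = "hicpileup_no_windows")
  m <- acc$sum / acc$cnt
  m[acc$cnt == 0L] <- NA_real_
  cov <- if (acc$coverage) {
    list(row = acc$cov_row / acc$n, col = acc$cov_col / acc$n)
  } else NULL
  new_pileup(m, n_windows = acc$n, meta = meta, coverage = cov)
}

new_pileup <- function(matrix, n_windows, meta = list(), coverage = NULL) {
  structure(list(matrix = unname(matrix), n_windows = n_windows,
                 meta = meta, coverage = coverage),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %dx%d, %d window(s)%s\n",
              nrow(x$matrix), ncol(x$matrix), x$n_windows,
              if (length(x$meta)) paste0(" | ",
                paste(names(x$meta), unlist(lapply(x$meta, paste, collapse = ",")),
                      sep = "=", collapse = " ")) else ""))
  invisible(x)
}

#' @export
dim.pileup <- function(x) dim(x$matrix)

#' @export
as.matrix.pileup <- function(x, ...) x$matrix
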