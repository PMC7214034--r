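#' Window streams: turning annotations into 2D windows
#'
#' Every pile-up variant reduces to a stream of *window specifications*: a
#' chromosome, a pair of center bins (`bin_i <= bin_j`; equal for local
#' pile-ups), and either a fixed flank in bins or, in rescale mode, explicit
#' bin spans along each axis. Streams are tibbles so they can be inspected,
#' filtered and combined with ordinary data-frame tools; the tally of
#' windows dropped per reason is attached as the `"drops"` attribute
#' ([window_drops()]).
#'
#' Windows that would cross a chromosome end are dropped entirely (never
#' padded), so every accumulated window has the same shape and per-pixel
#' window counts stay equal. Separation bounds `min_sep`/`max_sep` are
#' inclusive bounds on center-to-center distance in bp.
#'
#' @name window-streams
NULL

window_cols <- function() {
  tibble(chrom = character(), bin_i = integer(), bin_j = integer(),
         flank = integer(), kind = character(),
         si = integer(), ei = integer(), sj = integer(), ej = integer(),
         flip = logical(), source1 = character(), source2 = character())
}

new_windows <- function(tb, drops) {
  out <- dplyr::bind_rows(window_cols(), tb)
  attr(out, "drops") <- drops
  class(out) <- c("window_stream", class(out))
  out
}

#' @rdname window-streams
#' @param windows A window stream tibble.
#' @return `window_drops()`: a tibble with columns `reason` and `n`.
#' @export
window_drops <- function(windows) {
  attr(windows, "drops") %||% tibble(reason = character(), n = integer())
}

drop_tally <- function(...) {
  v <- c(...)
  tibble(reason = names(v), n = as.integer(v))
}

flank_to_bins <- function(flank_bp, resolution) {
  fb <- flank_bp / resolution
  f <- as.integer(ceiling(fb))
  if (f != fb) {
    inform(sprintf("flank %g bp is not a multiple of the %d bp resolution; rounded up to %d bins.",
                   flank_bp, resolution, f))
  }
  f
}

check_nonempty <- function(tb, drops) {
  if (nrow(tb) == 0L) {
    msg <- if (nrow(drops) == 0L || sum(drops$n) == 0L) {
      "no usable windows: the input stream was empty."
    } else {
      paste0("no usable windows; dropped — ",
             paste(sprintf("%s: %d", drops$reason, drops$n), collapse = ", "))
    }
    abort(msg, class = "hicpileup_no_windows")
  }
  invisible(tb)
}

# shared edge/separation filter for fixed-flank center-pair windows
filter_center_pairs <- function(tb, genome, flank, min_sep, max_sep) {
  res <- genome$resolution
  nb <- n_bins(genome)[tb$chrom]
  sep <- (tb$bin_j - tb$bin_i) * res
  too_close <- sep < min_sep
  too_far <- sep > max_sep
  edge <- (tb$bin_i - flank < 0L) | (tb$bin_j + flank > nb - 1L)
  keep <- !(too_close | too_far | edge)
  drops <- drop_tally(
    separation_below_min = sum(too_close & !edge),
    separation_above_max = sum(too_far & !edge),
    chromosome_edge = sum(edge)
  )
  list(tb = tb[keep, , drop = FALSE], drops = drops[drops$n > 0, ])
}

#' Windows from explicit anchor pairs (aggregate loops)
#'
#' @param pairs A `pair_set` from [read_pairs()] (or a tibble with `chrom`,
#'   `center_bin1`, `center_bin2`, `name`).
#' @param genome A [binned_genome()].
#' @param flank_bp Padding on each side of the central pixel, in bp
#'   (rounded up to whole bins); the window is `(2 * flank + 1)` bins square.
#' @param min_sep,max_sep Inclusive bp bounds on anchor separation.
#' @param deduplicate Collapse pairs that map to the same bin pair at this
#'   resolution? Default keeps duplicates (each annotation contributes one
#'   window).
#' @return A window stream tibble ([window-streams]).
#' @export
pairs_from_bedpe <- function(pairs, genome, flank_bp, min_sep = 0,
                             max_sep = Inf, deduplicate = FALSE) {
  f <- flank_to_bins(flank_bp, genome$resolution)
  tb <- tibble(chrom = pairs$chrom,
               bin_i = pmin(pairs$center_bin1, pairs$center_bin2),
               bin_j = pmax(pairs$center_bin1, pairs$center_bin2),
               flank = f, kind = "pair", flip = FALSE,
               source1 = pairs$name, source2 = pairs$name)
  dup_drop <- 0L
  if (deduplicate) {
    before <- nrow(tb)
    tb <- dplyr::distinct(tb, chrom, bin_i, bin_j, .keep_all = TRUE)
    dup_drop <- before - nrow(tb)
  }
  fl <- filter_center_pairs(tb, genome, f, min_sep, max_sep)
  drops <- dplyr::bind_rows(fl$drops,
                            if (dup_drop > 0) drop_tally(duplicate_bin_pair = dup_drop))
  check_nonempty(fl$tb, drops)
  new_windows(fl$tb, drops)
}

#' Windows from all pairwise combinations of one region set
#'
#' Emits every unordered intra-chromosomal pair of regions whose
#' center-to-center separation lies inside `[min_sep, max_sep]`.
#' Self-pairs (a region against itself) are excluded — they sit on the
#' diagonal and would contaminate the off-diagonal average.
#'
#' @param regions A `region_set` from [read_regions()].
#' @inheritParams pairs_from_bedpe
#' @return A window stream tibble.
#' @export
combinations_from_regions <- function(regions, genome, flank_bp,
                                      min_sep = 0, max_sep = Inf) {
  f <- flank_to_bins(flank_bp, genome$resolution)
  per_chrom <- lapply(split(seq_len(nrow(regions)), regions$chrom), function(idx) {
    if (length(idx) < 2L) return(NULL)
    cmb <- utils::combn(idx, 2L)
    a <- cmb[1, ]; b <- cmb[2, ]
    tibble(chrom = regions$chrom[a],
           bin_i = pmin(regions$center_bin[a], regions$center_bin[b]),
           bin_j = pmax(regions$center_bin[a], regions$center_bin[b]),
           flank = f, kind = "pair", flip = FALSE,
           source1 = regions$name[pmin(a, b)],
           source2 = regions$name[pmax(a, b)])
  })
  tb <- dplyr::bind_rows(per_chrom)
  fl <- filter_center_pairs(tb, genome, f, min_sep, max_sep)
  check_nonempty(fl$tb, fl$drops)
  new_windows(fl$tb, fl$drops)
}

#' Windows between two region sets
#'
#' Every intra-chromosomal pair `(a, b)` with `a` from `set_a` and `b` from
#' `set_b` inside the separation band, canonically oriented. Pairs whose two
#' members have identical coordinates (self-pairs when the sets overlap) are
#' excluded; unordered duplicates arising when the same pair is seen from
#' both directions are emitted once.
#'
#' @param set_a,set_b `region_set` tibbles.
#' @inheritParams pairs_from_bedpe
#' @return A window stream tibble.
#' @export
cross_pairs <- function(set_a, set_b, genome, flank_bp,
                        min_sep = 0, max_sep = Inf) {
  f <- flank_to_bins(flank_bp, genome$resolution)
  per_chrom <- lapply(intersect(unique(set_a$chrom), unique(set_b$chrom)), function(cn) {
    ia <- which(set_a$chrom == cn)
    ib <- which(set_b$chrom == cn)
    g <- expand.grid(a = ia, b = ib)
    same <- set_a$start[g$a] == set_b$start[g$b] &
      set_a$end[g$a] == set_b$end[g$b]
    g <- g[!same, , drop = FALSE]
    if (nrow(g) == 0L) return(NULL)
    ca <- set_a$center_bin[g$a]
    cb <- set_b$center_bin[g$b]
    tb <- tibble(chrom = cn,
                 bin_i = pmin(ca, cb), bin_j = pmax(ca, cb),
                 flank = f, kind = "pair", flip = FALSE,
                 source1 = ifelse(ca <= cb, set_a$name[g$a], set_b$name[g$b]),
                 source2 = ifelse(ca <= cb, set_b$name[g$b], set_a$name[g$a]))
    dplyr::distinct(tb, chrom, bin_i, bin_j, source1, source2, .keep_all = TRUE)
  })
  tb <- dplyr::bind_rows(per_chrom)
  fl <- filter_center_pairs(tb, genome, f, min_sep, max_sep)
  check_nonempty(fl$tb, fl$drops)
  new_windows(fl$tb, fl$drops)
}

#' On-diagonal (local) windows
#'
#' One window per region, centered on the diagonal at the region's center
#' bin. Windows crossing a chromosome end are dropped.
#'
#' @inheritParams combinations_from_regions
#' @return A window stream tibble with `kind == "local"`.
#' @export
local_windows <- function(regions, genome, flank_bp) {
  f <- flank_to_bins(flank_bp, genome$resolution)
  tb <- tibble(chrom = regions$chrom, bin_i = regions$center_bin,
               bin_j = regions$center_bin, flank = f, kind = "local",
               flip = FALSE, source1 = regions$name, source2 = regions$name)
  nb <- n_bins(genome)[tb$chrom]
  edge <- (tb$bin_i - f < 0L) | (tb$bin_j + f > nb - 1L)
  drops <- drop_tally(chromosome_edge = sum(edge))
  tb <- tb[!edge, , drop = FALSE]
  check_nonempty(tb, drops[drops$n > 0, ])
  new_windows(tb, drops[drops$n > 0, ])
}

#' Variable-span windows for rescaled pile-ups
#'
#' Each record contributes a window spanning its full extent expanded by
#' `pad_fraction` of its own binned length on each side; windows are later
#' resampled to a common `target_size` ([rescale_window()]). For a
#' `region_set` the window is on-diagonal (local rescaled, e.g. average
#' TADs); for a `pair_set` each axis spans one anchor's extent.
#'
#' @param x A `region_set` or `pair_set`.
#' @param genome A [binned_genome()].
#' @param pad_fraction Padding as a fraction of the (binned) feature length,
#'   each side. Default 1.0: a feature of length L yields a 3L-wide window.
#' @param max_len_bp Optional upper length cutoff in bp; longer features are
#'   dropped (counted as `too_long`).
#' @return A window stream tibble with `kind == "rescaled"` carrying bin
#'   spans `si:ei` x `sj:ej`.
#' @export
rescaled_windows <- function(x, genome, pad_fraction = 1.0, max_len_bp = Inf) {
  res <- genome$resolution
  span_of <- function(start, end) {
    sbin <- bin_of(genome, start)
    ebin <- bin_of(genome, pmax(start, end - 1))
    len <- ebin - sbin + 1L
    pad <- as.integer(round(pad_fraction * len))
    list(si = sbin - pad, ei = ebin + pad, len = len)
  }
  if (inherits(x, "pair_set")) {
    s1 <- span_of(x$start1, x$end1)
    s2 <- span_of(x$start2, x$end2)
    tb <- tibble(chrom = x$chrom,
                 bin_i = as.integer((s1$si + s1$ei) %/% 2L),
                 bin_j = as.integer((s2$si + s2$ei) %/% 2L),
                 flank = NA_integer_, kind = "rescaled", flip = FALSE,
                 si = s1$si, ei = s1$ei, sj = s2$si, ej = s2$ei,
                 source1 = x$name, source2 = x$name)
    lens <- pmax(s1$len, s2$len)
  } else {
    s1 <- span_of(x$start, x$end)
    tb <- tibble(chrom = x$chrom,
                 bin_i = as.integer((s1$si + s1$ei) %/% 2L),
                 bin_j = as.integer((s1$si + s1$ei) %/% 2L),
                 flank = NA_integer_, kind = "rescaled", flip = FALSE,
                 si = s1$si, ei = s1$ei, sj = s1$si, ej = s1$ei,
                 source1 = x$name, source2 = x$name)
    lens <- s1$len
  }
  nb <- n_bins(genome)[tb$chrom]
  too_long <- (lens * res) > max_len_bp
  too_short <- lens < 1L
  edge <- tb$si < 0L | tb$sj < 0L | tb$ei > nb - 1L | tb$ej > nb - 1L
  keep <- !(too_long | too_short | edge)
  drops <- drop_tally(too_long = sum(too_long),
                      shorter_than_one_bin = sum(too_short & !too_long),
                      chromosome_edge = sum(edge & !too_long & !too_short))
  tb <- tb[keep, , drop = FALSE]
  check_nonempty(tb, drops[drops$n > 0, ])
  new_windows(tb, drops[drops$n > 0, ])
}

#' Windows of one anchor region against a set of partners
#'
#' Pairs a single anchor with every in-band partner. Windows are oriented so
#' the anchor always occupies the row axis of the pile-up (windows with the
#' anchor downstream are flagged for transposition at extraction), matching
#' the convention of showing the anchored region on one fixed side.
#'
#' @param anchor A single-row `region_set` (the anchored region).
#' @param others A `region_set` of candidate partners; a record identical to
#'   the anchor is excluded from its own partners.
#' @inheritParams pairs_from_bedpe
#' @return A window stream tibble (possibly empty: an anchor with no in-band
#'   partners yields zero windows, not an error — callers record a missing
#'   score).
#' @export
anchored_pairs <- function(anchor, others, genome, flank_bp,
                           min_sep = 0, max_sep = Inf) {
  stopifnot(nrow(anchor) == 1L)
  f <- flank_to_bins(flank_bp, genome$resolution)
  part <- others[others$chrom == anchor$chrom, , drop = FALSE]
  self <- part$start == anchor$start & part$end == anchor$end
  part <- part[!self, , drop = FALSE]
  if (nrow(part) == 0L) return(new_windows(window_cols(), drop_tally()))
  ca <- anchor$center_bin
  cb <- part$center_bin
  tb <- tibble(chrom = anchor$chrom,
               bin_i = pmin(ca, cb), bin_j = pmax(ca, cb),
               flank = f, kind = "pair",
               flip = cb < ca,   # anchor downstream -> transpose on extract
               source1 = anchor$name, source2 = part$name)
  fl <- filter_center_pairs(tb, genome, f, min_sep, max_sep)
  new_windows(fl$tb, fl$drops)
}

#' Deterministic random subset of a window stream
#'
#' @param windows A window stream tibble.
#' @param n Number of windows to keep (`min(n, total)` are kept).
#' @param seed Integer seed; the same seed always selects the same subset.
#' @return A window stream tibble in original order.
#' @export
subset_sample <- function(windows, n, seed) {
  total <- nrow(windows)
  if (n >= total) return(windows)
  idx <- with_local_seed(seed, sample.int(total, n))
  out <- windows[sort(idx), , drop = FALSE]
  attr(out, "drops") <- window_drops(windows)
  class(out) <- class(windows)
  out
}
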