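#' Pile up a window stream over a contact matrix
#'
#' The core engine: extracts every window of the stream from the sparse
#' map (optionally rescaling to a common size), accumulates them into a
#' mean pile-up per chromosome, merges chromosomes, applies coverage
#' normalization if requested, and divides by the chosen normalizing
#' matrix (chromosome-wide Toeplitz expected, or a pile-up of randomly
#' shifted matched-separation controls). Controls inherit every active
#' option (balancing, coverage normalization, rescaling) so numerator and
#' denominator are exchangeable.
#'
#' @param x A [contact_matrix()].
#' @param windows A window stream tibble ([window-streams]).
#' @param balanced Use balancing weights? Defaults to using them when
#'   present.
#' @param normalization `"expected"`, `"shifts"` or `"none"`.
#' @param expected Optional precomputed `expected_profile`; when `NULL` and
#'   `normalization == "expected"`, computed from `x` in the active data
#'   mode ([compute_expected()]).
#' @param n_shifts Controls per window for `"shifts"` normalization.
#' @param coverage Record flank coverage and coverage-normalize the
#'   pile-up(s)?
#' @param target_size Odd output size for rescale-mode streams.
#' @param seed Integer seed driving control placement (per-chromosome child
#'   streams are derived deterministically, so parallel == serial).
#' @param n_cores Worker processes across chromosomes.
#' @return A `pileup` with metadata (`n_windows`, mode, normalization,
#'   seed, drop tallies).
#' @export
pileup <- function(x, windows,
                   balanced = has_weights(x),
                   normalization = c("expected", "shifts", "none"),
                   expected = NULL, n_shifts = 10L,
                   coverage = FALSE, target_size = NULL,
                   seed = 1L, n_cores = 1L) {
  normalization <- match.arg(normalization)
  if (!is.null(expected) && normalization == "shifts") {
    abort("an expected profile and shifted controls are mutually exclusive; choose one normalization.")
  }
  check_nonempty(windows, window_drops(windows))
  rescaled <- identical(windows$kind[1], "rescaled")
  if (rescaled && is.null(target_size)) {
    abort("rescale-mode windows need a `target_size` (odd, >= 3).")
  }
  size <- if (rescaled) as.integer(target_size) else 2L * windows$flank[1] + 1L
  if (!rescaled && !all(windows$flank == windows$flank[1])) {
    abort("all fixed-flank windows in one pile-up must share the same flank.")
  }

  if (normalization == "expected" && is.null(expected)) {
    expected <- compute_expected(x, balanced = balanced)
  }

  chroms <- intersect(chrom_names(x$genome), unique(windows$chrom))
  worker <- function(cn) {
    wc <- windows[windows$chrom == cn, , drop = FALSE]
    obs <- accumulate_windows(x, wc, balanced = balanced, coverage = coverage,
                              target_size = target_size, size = size,
                              rescaled = rescaled)
    ctl <- NULL
    ctl_drops <- 0L
    if (normalization == "shifts") {
      cw <- shifted_controls(wc, x$genome, n_shifts,
                             seed = child_seed(seed, cn))
      ctl_drops <- sum(window_drops(cw)$n)
      ctl <- accumulate_windows(x, cw, balanced = balanced, coverage = coverage,
                                target_size = target_size, size = size,
                                rescaled = rescaled)
    }
    list(obs = obs, ctl = ctl, ctl_drops = ctl_drops)
  }
  parts <- if (n_cores > 1L) {
    parallel::mclapply(chroms, worker, mc.cores = n_cores, mc.preschedule = TRUE)
  } else {
    lapply(chroms, worker)
  }
  for (p in parts) {
    if (inherits(p, "try-error") || is.null(p$obs)) {
      abort("a chromosome worker failed during pile-up accumulation.")
    }
  }

  meta <- list(
    resolution = x$genome$resolution,
    mode = windows$kind[1],
    size = size,
    flank_bins = if (rescaled) NA_integer_ else windows$flank[1],
    balanced = balanced,
    normalization = normalization,
    n_shifts = if (normalization == "shifts") n_shifts else NA_integer_,
    seed = seed
  )
  obs <- finalize_mean(merge_accumulators(lapply(parts, `[[`, "obs")), meta = meta)
  if (coverage) obs <- coverage_normalize(obs)

  if (normalization == "expected") {
    norm <- expected_normalizer(expected, windows, target_size = target_size)
    obs <- apply_normalizer(obs, norm)
  } else if (normalization == "shifts") {
    ctl <- finalize_mean(merge_accumulators(lapply(parts, `[[`, "ctl")),
                         meta = list(normalizer = "shifted_controls"))
    if (coverage) ctl <- suppressWarnings(coverage_normalize(ctl))
    obs$meta$n_control_windows <- ctl$n_windows
    obs$meta$controls_dropped <- sum(vapply(parts, `[[`, 0L, "ctl_drops"))
    obs <- apply_normalizer(obs, ctl)
  }
  obs$meta$drops <- window_drops(windows)
  obs
}

# Accumulate one chromosome's windows (already filtered to that chromosome).
accumulate_windows <- function(x, windows, balanced, coverage, target_size,
                               size, rescaled) {
  acc <- new_accumulator(size, coverage = coverage, rescaled = rescaled)
  if (nrow(windows) == 0L) return(acc)
  cn <- windows$chrom[1]
  cov <- if (coverage) chrom_coverage(x, cn, balanced = FALSE) else NULL
  for (r in seq_len(nrow(windows))) {
    sp <- windows[r, ]
    w <- extract_window(x, sp, balanced = balanced)
    cr <- ccv <- NULL
    if (coverage) {
      if (rescaled) {
        ri <- (sp$si:sp$ei) + 1L; ci <- (sp$sj:sp$ej) + 1L
      } else {
        ri <- (sp$bin_i - sp$flank):(sp$bin_i + sp$flank) + 1L
        ci <- (sp$bin_j - sp$flank):(sp$bin_j + sp$flank) + 1L
      }
      cr <- cov[ri]; ccv <- cov[ci]
      if (isTRUE(sp$flip)) { tmp <- cr; cr <- ccv; ccv <- tmp }
    }
    if (rescaled) {
      w <- rescale_window(w, target_size)
      if (coverage) {
        cr <- rescale_vector(cr, target_size)
        ccv <- rescale_vector(ccv, target_size)
      }
    }
    acc <- accumulate(acc, w, cov_row = cr, cov_col = ccv)
  }
  acc
}

#' One-call pile-up from files
#'
#' Thin orchestration over the reader, window-stream builders and
#' [pileup()]: the function behind the command-line `pileup` subcommand.
#'
#' @param cool Path to a `.cool` file, or a [contact_matrix()].
#' @param features Path to a BED (`local`, `rescaled`, `combinations`) or
#'   BEDPE (`pairs`) file, or an already-read `region_set` / `pair_set`;
#'   `"-"` reads from standard input.
#' @param mode One of `"pairs"`, `"combinations"`, `"cross"`, `"local"`,
#'   `"rescaled"`.
#' @param features2 Second region set for `mode = "cross"`.
#' @param flank_bp Window padding in bp (fixed-flank modes).
#' @param pad_fraction,target_size Rescale-mode geometry
#'   ([rescaled_windows()]).
#' @param min_sep,max_sep Inclusive separation band in bp.
#' @param subset Keep at most this many windows (random, seed-determined);
#'   `Inf` keeps all.
#' @param chroms Optional chromosome include-list.
#' @param out Optional output path for [write_pileup_text()].
#' @inheritParams pileup
#' @return The finalized `pileup`, invisibly when `out` is given.
#' @export
run_pileup <- function(cool, features, mode = c("pairs", "combinations",
                                                "cross", "local", "rescaled"),
                       features2 = NULL,
                       flank_bp = 100e3, pad_fraction = 1.0, target_size = 33L,
                       min_sep = 0, max_sep = Inf, subset = Inf,
                       chroms = NULL, balanced = NULL,
                       normalization = c("expected", "shifts", "none"),
                       expected = NULL, n_shifts = 10L, coverage = FALSE,
                       seed = 1L, n_cores = 1L, out = NULL) {
  mode <- match.arg(mode)
  normalization <- match.arg(normalization)
  x <- if (inherits(cool, "contact_matrix")) cool else read_cool(cool)
  if (is.null(balanced)) balanced <- has_weights(x)
  genome <- x$genome

  load_regions <- function(f) {
    if (inherits(f, "region_set")) f else read_regions(f, genome)
  }
  windows <- switch(mode,
    pairs = {
      p <- if (inherits(features, "pair_set")) features else read_pairs(features, genome)
      pairs_from_bedpe(p, genome, flank_bp, min_sep, max_sep)
    },
    combinations = combinations_from_regions(load_regions(features), genome,
                                             flank_bp, min_sep, max_sep),
    cross = {
      if (is.null(features2)) abort("mode 'cross' needs `features2`.")
      cross_pairs(load_regions(features), load_regions(features2), genome,
                  flank_bp, min_sep, max_sep)
    },
    local = local_windows(load_regions(features), genome, flank_bp),
    rescaled = {
      f <- if (inherits(features, c("region_set", "pair_set"))) features
           else read_regions(features, genome)
      rescaled_windows(f, genome, pad_fraction)
    }
  )
  if (!is.null(chroms)) {
    keep <- windows$chrom %in% chroms
    drops <- dplyr::bind_rows(window_drops(windows),
                              drop_tally(chromosome_excluded = sum(!keep)))
    windows <- new_windows(windows[keep, , drop = FALSE], drops[drops$n > 0, ])
    check_nonempty(windows, window_drops(windows))
  }
  if (is.finite(subset)) windows <- subset_sample(windows, subset, seed)

  p <- pileup(x, windows, balanced = balanced, normalization = normalization,
              expected = expected, n_shifts = n_shifts, coverage = coverage,
              target_size = if (mode == "rescaled") target_size else NULL,
              seed = seed, n_cores = n_cores)
  dr <- p$meta$drops
  inform(sprintf("pile-up of %d window(s) [%s, %s normalization]%s",
                 p$n_windows, mode, normalization,
                 if (!is.null(dr) && nrow(dr)) paste0("; dropped — ",
                   paste(sprintf("%s: %d", dr$reason, dr$n), collapse = ", "))
                 else ""))
  if (!is.null(out)) {
    write_pileup_text(p, out)
    return(invisible(p))
  }
  p
}
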