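#' Per-region loop-ability scores
#'
#' For each region in a set, piles up that region (the *anchor*) against
#' every other in-band region of the set and extracts the central value of
#' the normalized anchored pile-up — its "loop-ability". Unlike a
#' set-level pile-up, this retains locus-specific information: the score of
#' a region reflects how strongly *it* interacts with its partners on
#' average. Regions failing the corner-CV noise filter are flagged, never
#' silently dropped; regions with no in-band partner get a missing score.
#'
#' The central statistic defaults to the bare central pixel (the
#' loop-ability convention); `central = "3x3"` switches to the 3 x 3 block
#' mean used for dataset-level enrichment.
#'
#' @param x A [contact_matrix()].
#' @param regions A `region_set` ([read_regions()]).
#' @param flank_bp Window padding in bp.
#' @param min_sep,max_sep Inclusive separation band in bp.
#' @param central `"pixel"` (default) or `"3x3"`.
#' @param cv_threshold Corner-CV failure threshold (inclusive).
#' @inheritParams pileup
#' @return A tibble with one row per region: `name`, `chrom`, `start`,
#'   `end`, `n_windows`, `score`, `cv_tl`, `cv_br`, `pass`.
#' @export
loopability <- function(x, regions, flank_bp, min_sep = 0, max_sep = Inf,
                        balanced = has_weights(x),
                        normalization = c("expected", "shifts", "none"),
                        expected = NULL, n_shifts = 10L, coverage = FALSE,
                        central = c("pixel", "3x3"), cv_threshold = 0.5,
                        seed = 1L, n_cores = 1L) {
  normalization <- match.arg(normalization)
  central <- match.arg(central)
  if (nrow(regions) == 0L) abort("no regions supplied.", class = "hicpileup_no_windows")
  if (normalization == "expected" && is.null(expected)) {
    expected <- compute_expected(x, balanced = balanced)
  }

  score_one <- function(i) {
    anchor <- regions[i, , drop = FALSE]
    w <- anchored_pairs(anchor, regions, x$genome, flank_bp, min_sep, max_sep)
    if (nrow(w) == 0L) {
      return(tibble(name = anchor$name, chrom = anchor$chrom,
                    start = anchor$start, end = anchor$end,
                    n_windows = 0L, score = NA_real_,
                    cv_tl = NA_real_, cv_br = NA_real_, pass = NA))
    }
    p <- pileup(x, w, balanced = balanced, normalization = normalization,
                expected = expected, n_shifts = n_shifts, coverage = coverage,
                seed = child_seed(seed, anchor$name, salt = i), n_cores = 1L)
    cv <- if (nrow(p$matrix) >= 13L) corner_cv(p) else c(cv_tl = NA_real_, cv_br = NA_real_)
    tibble(name = anchor$name, chrom = anchor$chrom,
           start = anchor$start, end = anchor$end,
           n_windows = p$n_windows,
           score = central_enrichment(p, if (central == "pixel") 1L else 3L),
           cv_tl = cv[["cv_tl"]], cv_br = cv[["cv_br"]],
           pass = if (all(is.na(cv))) NA else !any(cv >= cv_threshold, na.rm = TRUE) &&
             !any(is.na(cv)))
  }
  idx <- seq_len(nrow(regions))
  rows <- if (n_cores > 1L) {
    parallel::mclapply(idx, score_one, mc.cores = n_cores)
  } else {
    lapply(idx, score_one)
  }
  dplyr::bind_rows(rows)
}

#' Write a loop-ability table as TSV
#'
#' @param tab Result of [loopability()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loopability <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
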