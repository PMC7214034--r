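#' In-memory / file-backed sparse contact matrix
#'
#' A `contact_matrix` holds, per chromosome, the upper-triangular sparse
#' counts of a single-resolution Hi-C map plus optional per-bin balancing
#' weights. Chromosomes are loaded lazily (one bulk read per chromosome for
#' file-backed objects) and cached. Queries are symmetric: `value(i, j) ==
#' value(j, i)` even though only `i <= j` is stored. A bin whose balancing
#' weight is non-finite is *invalid*: every balanced value in its row and
#' column is missing (`NA`), which is distinct from a zero count.
#'
#' @param genome A [binned_genome()].
#' @param pixels Named list of per-chromosome triplet data frames with
#'   0-based local columns `bin1`, `bin2` (`bin1 <= bin2`) and `count`.
#' @param weights Optional named list of per-chromosome numeric weight
#'   vectors (length `n_bins`); non-finite entries mark invalid bins.
#' @return A `contact_matrix` object.
#' @export
contact_matrix <- function(genome, pixels, weights = NULL) {
  stopifnot(inherits(genome, "binned_genome"))
  store <- new.env(parent = emptyenv())
  for (cn in names(pixels)) {
    px <- pixels[[cn]]
    stopifnot(all(c("bin1", "bin2", "count") %in% names(px)))
    if (any(px$bin1 > px$bin2)) abort("pixels must satisfy bin1 <= bin2.")
    if (any(px$count < 0)) abort("counts must be non-negative.")
    nb <- n_bins(genome, cn)
    if (nrow(px) && max(px$bin2) >= nb) abort("pixel bin out of range.")
    assign(cn, px, envir = store)
  }
  if (!is.null(weights)) {
    for (cn in names(weights)) {
      if (length(weights[[cn]]) != n_bins(genome, cn)) {
        abort(paste0("weights for ", cn, " have wrong length."))
      }
    }
  }
  new_contact_matrix(genome, store, weights, source = NULL)
}

new_contact_matrix <- function(genome, store, weights, source) {
  cache <- new.env(parent = emptyenv())
  counters <- new.env(parent = emptyenv())
  counters$fetches <- 0L
  structure(
    list(genome = genome, store = store, weights = weights,
         source = source, cache = cache, counters = counters),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  src <- if (is.null(x$source)) "in-memory" else x$source$path
  cat(sprintf("<contact_matrix> %s | %d chromosome(s) @ %d bp%s\n",
              src, nrow(x$genome$chroms), x$genome$resolution,
              if (has_weights(x)) " | balancing weights" else ""))
  invisible(x)
}

#' @rdname contact_matrix
#' @param x A `contact_matrix`.
#' @export
has_weights <- function(x) !is.null(x$weights)

#' Balancing weights of one chromosome
#' @param x A `contact_matrix`.
#' @param chrom Chromosome name.
#' @return Numeric vector (length `n_bins`), `NA`/non-finite = invalid bin,
#'   or `NULL` when the matrix carries no weights.
#' @export
chrom_weights <- function(x, chrom) {
  if (!has_weights(x)) return(NULL)
  x$weights[[chrom]]
}

# Raw triplets of one chromosome (0-based local bins), loading from the
# backing file at most once per chromosome.
chrom_pixels <- function(x, chrom) {
  if (!chrom %in% chrom_names(x$genome)) {
    abort(paste0("unknown chromosome: ", chrom))
  }
  if (exists(chrom, envir = x$store, inherits = FALSE)) {
    return(get(chrom, envir = x$store, inherits = FALSE))
  }
  if (is.null(x$source)) {
    px <- tibble(bin1 = integer(), bin2 = integer(), count = numeric())
  } else {
    px <- cool_fetch_chrom(x$source, x$genome, chrom)
    x$counters$fetches <- x$counters$fetches + 1L
  }
  assign(chrom, px, envir = x$store)
  px
}

#' Number of per-chromosome bulk reads performed so far
#' @param x A `contact_matrix`.
#' @return Integer fetch count (0 for fully in-memory objects).
#' @export
fetch_count <- function(x) x$counters$fetches

# Symmetric sparse count matrix of a chromosome (1-based dgCMatrix), cached.
chrom_sparse <- function(x, chrom) {
  key <- paste0("sym:", chrom)
  if (exists(key, envir = x$cache, inherits = FALSE)) {
    return(get(key, envir = x$cache, inherits = FALSE))
  }
  px <- chrom_pixels(x, chrom)
  nb <- n_bins(x$genome, chrom)
  up <- sparseMatrix(i = px$bin1 + 1L, j = px$bin2 + 1L, x = as.numeric(px$count),
                     dims = c(nb, nb))
  sym <- up + Matrix::t(up)
  d <- Matrix::diag(up)
  if (any(d != 0)) sym <- sym - Diagonal(nb, d)
  sym <- methods::as(sym, "CsparseMatrix")
  assign(key, sym, envir = x$cache)
  sym
}

# Per-bin chromosome-wide coverage: total contacts of each bin (marginal sum
# of the symmetric matrix, diagonal counted once).
chrom_coverage <- function(x, chrom, balanced = FALSE) {
  key <- paste0("cov:", chrom, ":", balanced)
  if (exists(key, envir = x$cache, inherits = FALSE)) {
    return(get(key, envir = x$cache, inherits = FALSE))
  }
  sym <- chrom_sparse(x, chrom)
  if (balanced) {
    w <- chrom_weights(x, chrom)
    if (is.null(w)) abort("balanced coverage requested but no weights present.")
    w2 <- ifelse(is.finite(w), w, NA_real_)
    cov <- as.numeric(Matrix::colSums(Diagonal(length(w2), ifelse(is.na(w2), 0, w2)) %*%
                                        sym %*%
                                        Diagonal(length(w2), ifelse(is.na(w2), 0, w2))))
    cov[!is.finite(w)] <- NA_real_
  } else {
    cov <- as.numeric(Matrix::colSums(sym))
  }
  assign(key, cov, envir = x$cache)
  cov
}

#' Query contact values of a chromosome region
#'
#' Returns a dense sub-matrix of the symmetric contact map. In balanced mode
#' each value is `count * w_i * w_j`; rows/columns of invalid-weight bins are
#' `NA` throughout.
#'
#' @param x A `contact_matrix`.
#' @param chrom Chromosome name.
#' @param rows,cols 0-based bin index vectors (must lie inside the
#'   chromosome).
#' @param balanced Apply balancing weights?
#' @return A dense `length(rows)` x `length(cols)` numeric matrix.
#' @export
contact_values <- function(x, chrom, rows, cols, balanced = FALSE) {
  nb <- n_bins(x$genome, chrom)
  stopifnot(all(rows >= 0L), all(rows < nb), all(cols >= 0L), all(cols < nb))
  sym <- chrom_sparse(x, chrom)
  m <- as.matrix(sym[rows + 1L, cols + 1L, drop = FALSE])
  if (balanced) {
    w <- chrom_weights(x, chrom)
    if (is.null(w)) abort("balanced values requested but no weight column loaded.")
    wr <- w[rows + 1L]
    wc <- w[cols + 1L]
    wr[!is.finite(wr)] <- NA_real_
    wc[!is.finite(wc)] <- NA_real_
    m <- m * outer(wr, wc)
  }
  dimnames(m) <- NULL
  m
}

# Dense full-chromosome matrix; intended for tests/oracles on small fixtures.
chrom_dense <- function(x, chrom, balanced = FALSE) {
  nb <- n_bins(x$genome, chrom)
  contact_values(x, chrom, 0:(nb - 1L), 0:(nb - 1L), balanced = balanced)
}
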