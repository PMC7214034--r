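#' Define a binned genome
#'
#' A binned genome fixes the coordinate system every other object in the
#' package uses: an ordered set of chromosomes, their lengths in base pairs,
#' and a single bin size (resolution). Bin `k` (0-based) on a chromosome
#' covers `[k * resolution, min((k + 1) * resolution, length))` in 0-based
#' half-open coordinates, so the last bin may be short.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp;
#'   names are the chromosome identifiers, order is preserved.
#' @param resolution Bin size in bp (positive integer).
#' @return An object of class `binned_genome` with a `chroms` tibble
#'   (`chrom`, `length`, `n_bins`, `bin_offset`) and the `resolution`.
#' @examples
#' g <- binned_genome(c(chrA = 1e6, chrB = 5e5), resolution = 10000)
#' n_bins(g, "chrA")
#' @export
binned_genome <- function(chrom_lengths, resolution) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    abort("`chrom_lengths` must be a named vector of chromosome lengths.")
  }
  if (anyDuplicated(names(chrom_lengths))) {
    abort("duplicated chromosome names in `chrom_lengths`.")
  }
  resolution <- as.integer(resolution)
  if (length(resolution) != 1L || is.na(resolution) || resolution <= 0L) {
    abort("`resolution` must be a single positive integer (bp).")
  }
  if (any(chrom_lengths < 1)) abort("chromosome lengths must be >= 1 bp.")
  nb <- as.integer(ceiling(chrom_lengths / resolution))
  chroms <- tibble(
    chrom = names(chrom_lengths),
    length = as.numeric(chrom_lengths),
    n_bins = nb,
    bin_offset = cumsum(c(0L, nb[-length(nb)]))
  )
  structure(list(chroms = chroms, resolution = resolution),
            class = "binned_genome")
}

#' @export
print.binned_genome <- function(x, ...) {
  cat(sprintf("<binned_genome> %d chromosome(s), %d bp bins, %d bins total\n",
              nrow(x$chroms), x$resolution, sum(x$chroms$n_bins)))
  print(x$chroms)
  invisible(x)
}

#' Number of bins on a chromosome
#'
#' @param genome A [binned_genome()].
#' @param chrom Chromosome name (scalar). If missing, returns the named
#'   vector for all chromosomes.
#' @return Integer bin count(s).
#' @export
n_bins <- function(genome, chrom) {
  stopifnot(inherits(genome, "binned_genome"))
  v <- setNames(genome$chroms$n_bins, genome$chroms$chrom)
  if (missing(chrom)) return(v)
  if (!chrom %in% names(v)) abort(paste0("unknown chromosome: ", chrom))
  v[[chrom]]
}

#' @rdname n_bins
#' @export
chrom_names <- function(genome) {
  stopifnot(inherits(genome, "binned_genome"))
  genome$chroms$chrom
}

# 0-based bin holding a bp position (0-based coordinate).
bin_of <- function(genome, pos) as.integer(floor(pos / genome$resolution))

# Representative bin of a region: the bin holding the midpoint.
center_bin_of <- function(genome, start, end) {
  bin_of(genome, floor((start + end) / 2))
}

# Global cooler bin id range (0-based, half-open) of a chromosome.
global_bin_range <- function(genome, chrom) {
  i <- match(chrom, genome$chroms$chrom)
  if (is.na(i)) abort(paste0("unknown chromosome: ", chrom))
  off <- genome$chroms$bin_offset[i]
  c(off, off + genome$chroms$n_bins[i])
}
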