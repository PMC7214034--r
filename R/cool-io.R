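#' Read a single-resolution cooler (.cool) contact matrix
#'
#' Opens an HDF5 file following the single-resolution cooler schema
#' (`chroms`, `bins`, `pixels`, `indexes` tables) and returns a lazily
#' loading [contact_matrix()]. The bin table and indexes are read up front;
#' the pixel table of a chromosome is fetched in one bulk read the first
#' time that chromosome is touched, then cached, so a full pass over the
#' genome performs exactly one read per chromosome.
#'
#' @param path Path to the `.cool` file.
#' @param use_weights Load a balancing-weight column? (default `TRUE` when
#'   present; an explicit `TRUE` with no such column is an error).
#' @param weight_col Name of the weight column in `bins` (default
#'   `"weight"`, the cooler convention).
#' @return A [contact_matrix()].
#' @export
read_cool <- function(path, use_weights = NULL, weight_col = "weight") {
  if (!file.exists(path)) abort(paste0("cooler file not found: ", path))
  contents <- rhdf5::h5ls(path, recursive = FALSE)
  top <- contents$name
  if (!"pixels" %in% top) {
    if ("resolutions" %in% top) {
      abort(paste0(
        "file looks like a multi-resolution container (has /resolutions ",
        "but no root /pixels); single-resolution cooler input is required — ",
        "extract one resolution first."))
    }
    abort(paste0("not a cooler file (no /pixels table): ", path))
  }

  chroms <- rhdf5::h5read(path, "chroms")
  cnames <- as.character(chroms$name)
  clen <- as.numeric(chroms$length)
  attrs <- rhdf5::h5readAttributes(path, "/")
  bins_ls <- rhdf5::h5ls(path)
  bin_cols <- bins_ls$name[bins_ls$group == "/bins"]
  bin_start <- as.numeric(rhdf5::h5read(path, "bins/start"))
  bin_end <- as.numeric(rhdf5::h5read(path, "bins/end"))
  res <- if (!is.null(attrs[["bin-size"]]) && is.finite(as.numeric(attrs[["bin-size"]]))) {
    as.integer(attrs[["bin-size"]])
  } else {
    as.integer(max(bin_end - bin_start))
  }
  genome <- binned_genome(setNames(clen, cnames), res)
  nb_total <- sum(genome$chroms$n_bins)
  if (length(bin_start) != nb_total) {
    abort(sprintf("bin table length (%d) does not match chrom lengths (%d bins expected).",
                  length(bin_start), nb_total))
  }

  if (is.null(use_weights)) use_weights <- weight_col %in% bin_cols
  weights <- NULL
  if (isTRUE(use_weights)) {
    if (!weight_col %in% bin_cols) {
      abort(paste0("balancing requested but bins table has no '", weight_col,
                   "' column (columns: ", paste(bin_cols, collapse = ", "), ")."))
    }
    wall <- as.numeric(rhdf5::h5read(path, paste0("bins/", weight_col)))
    weights <- lapply(setNames(cnames, cnames), function(cn) {
      r <- global_bin_range(genome, cn)
      wall[(r[1] + 1L):r[2]]
    })
  }

  bin1_offset <- as.numeric(rhdf5::h5read(path, "indexes/bin1_offset"))
  source <- list(path = path, bin1_offset = bin1_offset)
  store <- new.env(parent = emptyenv())
  new_contact_matrix(genome, store, weights, source = source)
}

# One bulk pixel fetch for a chromosome: rows whose bin1 lies in the
# chromosome's global bin range; trans pixels (bin2 on another chromosome)
# are dropped.
cool_fetch_chrom <- function(source, genome, chrom) {
  r <- global_bin_range(genome, chrom)  # [lo, hi) global 0-based
  off <- source$bin1_offset
  from <- off[r[1] + 1L] + 1L           # 1-based row range in /pixels
  to <- off[r[2] + 1L]
  if (to < from) {
    return(tibble(bin1 = integer(), bin2 = integer(), count = numeric()))
  }
  idx <- list(from:to)
  b1 <- as.integer(rhdf5::h5read(source$path, "pixels/bin1_id", index = idx))
  b2 <- as.integer(rhdf5::h5read(source$path, "pixels/bin2_id", index = idx))
  ct <- as.numeric(rhdf5::h5read(source$path, "pixels/count", index = idx))
  keep <- b2 >= r[1] & b2 < r[2]
  tibble(bin1 = b1[keep] - r[1], bin2 = b2[keep] - r[1], count = ct[keep])
}

#' Write a contact matrix as a single-resolution cooler file
#'
#' Writes the cooler HDF5 layout (`chroms`, `bins`, `pixels`, `indexes`
#' plus root attributes) so the file round-trips through [read_cool()] and
#' is readable by generic HDF5 tooling. `bins/chrom` is stored as a 0-based
#' integer chromosome code (the `chroms/name` table gives the mapping).
#'
#' @param x A [contact_matrix()].
#' @param path Output path (overwritten).
#' @param weights Write the balancing-weight column (if the object has one)?
#' @return `path`, invisibly.
#' @export
write_cool <- function(x, path, weights = has_weights(x)) {
  stopifnot(inherits(x, "contact_matrix"))
  genome <- x$genome
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)

  cn <- chrom_names(genome)
  nbv <- genome$chroms$n_bins
  res <- genome$resolution

  rhdf5::h5createGroup(path, "chroms")
  rhdf5::h5write(cn, path, "chroms/name")
  rhdf5::h5write(as.integer(genome$chroms$length), path, "chroms/length")

  # bin table
  bin_chrom <- rep(seq_along(cn) - 1L, nbv)
  bin_start <- unlist(lapply(seq_along(cn), function(i) (0:(nbv[i] - 1L)) * res))
  bin_end <- unlist(lapply(seq_along(cn), function(i) {
    pmin((1:nbv[i]) * res, genome$chroms$length[i])
  }))
  rhdf5::h5createGroup(path, "bins")
  rhdf5::h5write(as.integer(bin_chrom), path, "bins/chrom")
  rhdf5::h5write(as.integer(bin_start), path, "bins/start")
  rhdf5::h5write(as.integer(bin_end), path, "bins/end")
  if (isTRUE(weights)) {
    if (!has_weights(x)) abort("no weights present to write.")
    wall <- unlist(lapply(cn, function(ch) {
      w <- chrom_weights(x, ch)
      w[!is.finite(w)] <- NaN
      w
    }), use.names = FALSE)
    rhdf5::h5write(wall, path, "bins/weight")
  }

  # pixel table: global 0-based bin ids, bin1 <= bin2, sorted
  px <- dplyr::bind_rows(lapply(cn, function(ch) {
    p <- chrom_pixels(x, ch)
    off <- global_bin_range(genome, ch)[1]
    tibble(bin1_id = p$bin1 + off, bin2_id = p$bin2 + off, count = p$count)
  }))
  px <- px[px$count != 0, , drop = FALSE]
  px <- px[order(px$bin1_id, px$bin2_id), , drop = FALSE]
  rhdf5::h5createGroup(path, "pixels")
  chunk <- max(1L, min(nrow(px), 262144L))
  for (col in c("bin1_id", "bin2_id", "count")) {
    ds <- paste0("pixels/", col)
    rhdf5::h5createDataset(path, ds, dims = nrow(px), storage.mode = "integer",
                           chunk = chunk, level = 4L)
    v <- if (col == "count") as.integer(round(px$count)) else as.integer(px[[col]])
    rhdf5::h5write(v, path, ds)
  }

  # indexes
  nb_total <- sum(nbv)
  bin1_offset <- c(0L, cumsum(tabulate(px$bin1_id + 1L, nbins = nb_total)))
  chrom_offset <- c(0L, cumsum(nbv))
  rhdf5::h5createGroup(path, "indexes")
  rhdf5::h5write(as.integer(bin1_offset), path, "indexes/bin1_offset")
  rhdf5::h5write(as.integer(chrom_offset), path, "indexes/chrom_offset")

  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute("HDF5::Cooler", fid, "format")
  rhdf5::h5writeAttribute(3L, fid, "format-version")
  rhdf5::h5writeAttribute("fixed", fid, "bin-type")
  rhdf5::h5writeAttribute(as.integer(res), fid, "bin-size")
  rhdf5::h5writeAttribute(as.integer(nb_total), fid, "nbins")
  rhdf5::h5writeAttribute(length(cn), fid, "nchroms")
  rhdf5::h5writeAttribute(nrow(px), fid, "nnz")
  rhdf5::h5writeAttribute("hicpileup", fid, "generated-by")
  rhdf5::H5Fclose(fid)
  invisible(path)
}
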