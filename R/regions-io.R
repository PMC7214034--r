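#' Read a BED-like region file
#'
#' Whitespace-delimited, >= 3 columns (`chrom start end [name]`), 0-based
#' half-open coordinates. Lines starting with `#`, `track` or `browser` are
#' skipped. Records on chromosomes absent from `genome` are dropped (count
#' reported via a message); records with `start >= end` are dropped with a
#' warning. Each record gets a `center_bin`: the 0-based bin holding the
#' region midpoint, `floor(((start + end) %/% 2) / resolution)`.
#'
#' @param path File path, or `"-"` to read from standard input.
#' @param genome A [binned_genome()] used to bin and to filter chromosomes.
#' @return A tibble (`chrom`, `start`, `end`, `name`, `center_bin`) of class
#'   `region_set`.
#' @export
read_regions <- function(path, genome) {
  lines <- read_feature_lines(path)
  if (length(lines) == 0L) {
    return(as_region_set(tibble(chrom = character(), start = numeric(),
                                end = numeric(), name = character(),
                                center_bin = integer())))
  }
  fields <- strsplit(trimws(lines$text), "[ \t]+")
  nfield <- lengths(fields)
  bad <- which(nfield < 3L)
  if (length(bad)) {
    abort(sprintf("cannot parse region line %d ('%s'): need >= 3 columns.",
                  lines$lineno[bad[1]], lines$text[bad[1]]))
  }
  chromv <- vapply(fields, `[[`, "", 1L)
  startv <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  endv <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(startv) || anyNA(endv)) {
    i <- which(is.na(startv) | is.na(endv))[1]
    abort(sprintf("non-numeric coordinates on line %d: '%s'",
                  lines$lineno[i], lines$text[i]))
  }
  namev <- ifelse(nfield >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""),
                  paste0("region_", seq_along(fields)))
  tb <- tibble(chrom = chromv, start = startv, end = endv, name = namev)

  inv <- tb$start >= tb$end
  if (any(inv)) {
    warn(sprintf("dropped %d record(s) with start >= end.", sum(inv)))
    tb <- tb[!inv, , drop = FALSE]
  }
  unk <- !tb$chrom %in% chrom_names(genome)
  if (any(unk)) {
    inform(sprintf("dropped %d record(s) on chromosome(s) absent from the genome: %s",
                   sum(unk), paste(unique(tb$chrom[unk]), collapse = ", ")))
    tb <- tb[!unk, , drop = FALSE]
  }
  tb$center_bin <- center_bin_of(genome, tb$start, tb$end)
  as_region_set(tb)
}

as_region_set <- function(tb) {
  class(tb) <- c("region_set", class(tb))
  tb
}

#' Read a BEDPE region-pair file
#'
#' Whitespace-delimited, >= 6 columns (`chrom1 start1 end1 chrom2 start2
#' end2`). Inter-chromosomal rows are dropped (count reported); anchors are
#' swapped where needed so that `center_bin1 <= center_bin2`.
#'
#' @inheritParams read_regions
#' @return A tibble of class `pair_set` with columns `chrom`, `start1`,
#'   `end1`, `start2`, `end2`, `center_bin1`, `center_bin2`, `name`.
#' @export
read_pairs <- function(path, genome) {
  lines <- read_feature_lines(path)
  empty <- tibble(chrom = character(), start1 = numeric(), end1 = numeric(),
                  start2 = numeric(), end2 = numeric(),
                  center_bin1 = integer(), center_bin2 = integer(),
                  name = character())
  if (length(lines) == 0L || nrow(lines) == 0L) {
    return(structure(empty, class = c("pair_set", class(empty))))
  }
  fields <- strsplit(trimws(lines$text), "[ \t]+")
  nfield <- lengths(fields)
  bad <- which(nfield < 6L)
  if (length(bad)) {
    abort(sprintf("cannot parse pair line %d ('%s'): need >= 6 columns.",
                  lines$lineno[bad[1]], lines$text[bad[1]]))
  }
  get <- function(k) vapply(fields, `[[`, "", k)
  num <- function(k) {
    v <- suppressWarnings(as.numeric(get(k)))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      abort(sprintf("non-numeric coordinate on line %d: '%s'",
                    lines$lineno[i], lines$text[i]))
    }
    v
  }
  tb <- tibble(chrom1 = get(1), start1 = num(2), end1 = num(3),
               chrom2 = get(4), start2 = num(5), end2 = num(6),
               name = paste0("pair_", seq_along(fields)))

  inv <- tb$start1 >= tb$end1 | tb$start2 >= tb$end2
  if (any(inv)) {
    warn(sprintf("dropped %d pair(s) with start >= end.", sum(inv)))
    tb <- tb[!inv, , drop = FALSE]
  }
  trans <- tb$chrom1 != tb$chrom2
  if (any(trans)) {
    inform(sprintf("dropped %d inter-chromosomal pair(s).", sum(trans)))
    tb <- tb[!trans, , drop = FALSE]
  }
  unk <- !tb$chrom1 %in% chrom_names(genome)
  if (any(unk)) {
    inform(sprintf("dropped %d pair(s) on chromosome(s) absent from the genome: %s",
                   sum(unk), paste(unique(tb$chrom1[unk]), collapse = ", ")))
    tb <- tb[!unk, , drop = FALSE]
  }

  cb1 <- center_bin_of(genome, tb$start1, tb$end1)
  cb2 <- center_bin_of(genome, tb$start2, tb$end2)
  swap <- cb1 > cb2
  out <- tibble(
    chrom = tb$chrom1,
    start1 = ifelse(swap, tb$start2, tb$start1),
    end1 = ifelse(swap, tb$end2, tb$end1),
    start2 = ifelse(swap, tb$start1, tb$start2),
    end2 = ifelse(swap, tb$end1, tb$end2),
    center_bin1 = as.integer(ifelse(swap, cb2, cb1)),
    center_bin2 = as.integer(ifelse(swap, cb1, cb2)),
    name = tb$name
  )
  structure(out, class = c("pair_set", class(out)))
}

read_feature_lines <- function(path) {
  raw <- if (identical(path, "-")) {
    readLines(file("stdin"))
  } else {
    if (!file.exists(path)) abort(paste0("file not found: ", path))
    readLines(path)
  }
  keep <- !grepl("^\\s*(#|track\\b|browser\\b|$)", raw)
  tibble(text = raw[keep], lineno = which(keep))
}

#' Read a per-diagonal expected-value table
#'
#' Long-format TSV with one row per (chromosome, diagonal) giving the mean
#' contact value at that separation — the layout written by the usual
#' expected-computation tools for cooler files. Column names are
#' configurable; diagonals absent from the table are missing (`NA`) in the
#' profile. Chromosome names must match the genome exactly (no silent
#' `chr`-prefix reconciliation).
#'
#' @param path TSV path.
#' @param genome A [binned_genome()].
#' @param chrom_col,diag_col,value_col Column names (defaults follow the
#'   cooltools convention: `region`/`chrom`, `diag`, `balanced.avg`).
#' @return An `expected_profile`: a named list of per-chromosome numeric
#'   vectors, entry `k + 1` = mean value at diagonal offset `k`.
#' @export
read_expected <- function(path, genome, chrom_col = NULL, diag_col = "diag",
                          value_col = "balanced.avg") {
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(chrom_col)) {
    chrom_col <- intersect(c("chrom", "region", "region1", "chromosome"), names(tb))[1]
    if (is.na(chrom_col)) abort("no chromosome column found in expected table.")
  }
  for (cc in c(chrom_col, diag_col, value_col)) {
    if (!cc %in% names(tb)) {
      abort(paste0("expected table lacks column '", cc, "' (has: ",
                   paste(names(tb), collapse = ", "), ")."))
    }
  }
  tab_chroms <- unique(as.character(tb[[chrom_col]]))
  unmatched <- setdiff(tab_chroms, chrom_names(genome))
  missing_g <- setdiff(chrom_names(genome), tab_chroms)
  if (length(unmatched)) {
    abort(paste0(
      "chromosome names in the expected table do not match the genome ",
      "(table: ", paste(unmatched, collapse = ", "),
      "; genome: ", paste(chrom_names(genome), collapse = ", "),
      "). Exact string match is required."))
  }
  if (length(missing_g)) {
    warn(paste0("expected table has no rows for: ",
                paste(missing_g, collapse = ", ")))
  }
  prof <- lapply(setNames(chrom_names(genome), chrom_names(genome)), function(cn) {
    d <- rep(NA_real_, n_bins(genome, cn))
    rows <- tb[[chrom_col]] == cn
    k <- as.integer(tb[[diag_col]][rows])
    v <- as.numeric(tb[[value_col]][rows])
    ok <- k >= 0 & k < length(d)
    d[k[ok] + 1L] <- v[ok]
    d
  })
  structure(prof, class = "expected_profile", value_col = value_col)
}

#' Write / read a pile-up as plain text
#'
#' The matrix is written one row per line, whitespace-delimited, missing
#' pixels as `nan`, preceded by `#`-prefixed metadata lines (window tally,
#' resolution, flank or target size, normalization mode, seed, ...).
#' `read_pileup_text()` restores the matrix and metadata.
#'
#' @param pileup A `pileup` object (see [finalize_mean()]).
#' @param path Output path.
#' @return `path` invisibly; for the reader, a `pileup` object.
#' @export
write_pileup_text <- function(pileup, path) {
  stopifnot(inherits(pileup, "pileup"))
  meta <- pileup$meta
  meta$n_windows <- pileup$n_windows
  hdr <- vapply(names(meta), function(k) {
    v <- meta[[k]]
    sprintf("# %s: %s", k, paste(format(v, trim = TRUE), collapse = ","))
  }, "")
  m <- pileup$matrix
  body <- apply(m, 1L, function(r) {
    paste(ifelse(is.na(r), "nan", formatC(r, digits = 17, format = "g")),
          collapse = " ")
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' @rdname write_pileup_text
#' @export
read_pileup_text <- function(path) {
  raw <- readLines(path)
  is_meta <- grepl("^#", raw)
  meta <- list()
  for (ln in raw[is_meta]) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:\\s*", "", kv))
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (!is.na(num)) num else val
  }
  rows <- strsplit(trimws(raw[!is_meta]), "\\s+")
  m <- do.call(rbind, lapply(rows, function(r) {
    v <- suppressWarnings(as.numeric(r))
    v[r %in% c("nan", "NaN", "NA")] <- NA_real_
    v
  }))
  nw <- meta$n_windows %||% NA_integer_
  meta$n_windows <- NULL
  new_pileup(m, n_windows = nw, meta = meta)
}
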