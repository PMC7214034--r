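#' Tidy a pile-up into long form
#'
#' One row per pixel with offsets relative to the central pixel (in bins),
#' ready for ggplot2 or dplyr summaries.
#'
#' @param x A `pileup`.
#' @param ... Unused.
#' @return A tibble with `row_off`, `col_off`, `value`.
#' @importFrom generics tidy
#' @export tidy
#' @export
#' @method tidy pileup
tidy.pileup <- function(x, ...) {
  m <- x$matrix
  n <- nrow(m)
  h <- (n - 1L) %/% 2L
  tibble(
    row_off = rep(-h:h, times = n),
    col_off = rep(-h:h, each = n),
    value = as.vector(m)
  )
}

#' One-row summary of a pile-up
#'
#' @param x A `pileup`.
#' @param ... Unused.
#' @return A one-row tibble: the [pileup_scores()] columns plus the key
#'   metadata (mode, normalization, resolution).
#' @importFrom generics glance
#' @export glance
#' @export
#' @method glance pileup
glance.pileup <- function(x, ...) {
  sc <- pileup_scores(x)
  dplyr::bind_cols(sc, tibble(
    mode = x$meta$mode %||% NA_character_,
    normalization = x$meta$normalization %||% NA_character_,
    resolution = x$meta$resolution %||% NA_integer_
  ))
}

#' Heatmap of a pile-up
#'
#' Log2-scaled fill centered on 1 (no enrichment), missing pixels in grey,
#' central score annotated in the top-left corner.
#'
#' @param object A `pileup`.
#' @param annotate Print the central-pixel score on the panel?
#' @param corner_normalized Divide by the corner mean first
#'   ([corner_normalize()])?
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pileup <- function(object, annotate = TRUE,
                            corner_normalized = FALSE, ...) {
  if (corner_normalized) object <- corner_normalize(object)
  df <- tidy(object)
  res <- object$meta$resolution %||% 1L
  g <- ggplot2::ggplot(df, ggplot2::aes(x = col_off, y = row_off, fill = value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(
      trans = "log2", low = "#313695", mid = "#ffffbf", high = "#a50026",
      midpoint = 0, na.value = "grey80", name = "obs/exp"
    ) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = sprintf("offset (bins of %s bp)", format(res, big.mark = ",")),
                  y = NULL) +
    ggplot2::theme_minimal()
  if (annotate) {
    sc <- central_enrichment(object, 1L)
    g <- g + ggplot2::annotate(
      "text", x = min(df$col_off), y = min(df$row_off),
      label = sprintf("%.3g", sc), hjust = 0, vjust = 1, fontface = "bold")
  }
  g
}

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot

#' Render a pile-up heatmap to an image file
#'
#' The command-line `plot` subcommand: reads a text pile-up if given a
#' path, draws [autoplot.pileup()] and writes the image.
#'
#' @param pileup A `pileup` or a path to a [write_pileup_text()] file.
#' @param file Output image path (format from extension, e.g. `.png`).
#' @param width,height Device size in inches.
#' @inheritParams autoplot.pileup
#' @return `file`, invisibly.
#' @export
plot_pileup <- function(pileup, file, annotate = TRUE,
                        corner_normalized = FALSE, width = 4, height = 4) {
  if (is.character(pileup)) pileup <- read_pileup_text(pileup)
  g <- autoplot(pileup, annotate = annotate,
                corner_normalized = corner_normalized)
  ggplot2::ggsave(file, g, width = width, height = height, dpi = 150)
  invisible(file)
}
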