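# broom-style tidiers and ggplot2 autoplot methods for the package's
# result types.

#' Tidy a fragment match report
#'
#' @param x A `fragment_match`.
#' @param ... Unused.
#' @return Tibble of matched fragments (type, index, z, theoretical and
#'   observed m/z, delta ppm, cleavage site).
#' @export
tidy.fragment_match <- function(x, ...) {
  x$matches
}

#' One-row summary of a fragment match report
#'
#' @param x A `fragment_match`.
#' @param ... Unused.
#' @return Tibble with `coverage`, `n_matched`, `n_theoretical`,
#'   `sequence_length`, `tol_ppm`.
#' @export
glance.fragment_match <- function(x, ...) {
  tibble::tibble(coverage = x$coverage, n_matched = nrow(x$matches),
                 n_theoretical = x$n_theoretical,
                 sequence_length = x$sequence_length,
                 tol_ppm = x$tol_ppm)
}

#' Tidy a tissue phantom into its ground-truth map
#'
#' @param x A `tissue_phantom`.
#' @param ... Unused.
#' @return Long tibble (row, col, species, abundance).
#' @export
tidy.tissue_phantom <- function(x, ...) {
  x$truth
}

#' One-row summary of a tissue phantom
#'
#' @param x A `tissue_phantom`.
#' @param ... Unused.
#' @return Tibble with grid size, region pixel counts, dose time and
#'   seed.
#' @export
glance.tissue_phantom <- function(x, ...) {
  tab <- table(x$pixels$region)
  tibble::tibble(
    n_rows = x$config$n_rows, n_cols = x$config$n_cols,
    n_vessel = as.integer(tab[["vessel"]] %||% 0L),
    n_bulk = as.integer(tab[["bulk"]] %||% 0L),
    n_background = as.integer(tab[["background"]] %||% 0L),
    dose_time = x$config$dose_time, half_life = x$config$half_life,
    seed = x$config$seed)
}

#' Plot a mass spectrum
#'
#' Profile spectra as a line trace; centroid spectra as sticks.
#'
#' @param object An `ms_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ms_spectrum <- function(object, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$mz, y = .data$intensity))
  p <- if (spectrum_mode(object) == "profile") {
    p + ggplot2::geom_line(linewidth = 0.3)
  } else {
    p + ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0))
  }
  p + ggplot2::labs(x = "m/z", y = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot an ion image
#'
#' @param object An `ion_image`.
#' @param ... Unused.
#' @return A ggplot raster; rows increase downwards (scan-line order).
#' @export
autoplot.ion_image <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$col, y = .data$row,
                               fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = attr(object, "species"), fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot a two-channel composite image
#'
#' @param object A `composite_image`.
#' @param ... Unused.
#' @return A ggplot raster with red/blue channel mixing.
#' @export
autoplot.composite_image <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$fill <- grDevices::rgb(d$red, 0, d$blue)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
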