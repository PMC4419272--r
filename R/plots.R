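## ggplot2 views of the main result types.

#' Plot an estimated deformation map
#'
#' Reference lattice (grey), estimated deformed lattice (magenta) and the
#' landmark pairs used for the fit.
#'
#' @param object A `deformation_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deformation_map <- function(object, ...) {
  nodes <- tidy(object)
  seg <- function(df, xcol, ycol) {
    rows <- dplyr::filter(
      tidyr::crossing(row = unique(df$row), col = unique(df$col)),
      .data$col < max(.data$col))
    h <- dplyr::left_join(rows, df, by = c("row", "col"))
    h2 <- dplyr::left_join(dplyr::mutate(rows, col = .data$col + 1), df,
                           by = c("row", "col"))
    tibble::tibble(x = h[[xcol]], y = h[[ycol]], xend = h2[[xcol]], yend = h2[[ycol]])
  }
  grid_layer <- function(df, xcol, ycol, colour) {
    horiz <- seg(df, xcol, ycol)
    swapped <- dplyr::rename(df, row = "col", col = "row")
    vert <- seg(swapped, xcol, ycol)
    ggplot2::geom_segment(
      data = dplyr::bind_rows(horiz, vert),
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      colour = colour, linewidth = 0.3)
  }
  lmk <- object$landmarks
  ggplot2::ggplot() +
    grid_layer(nodes, "ref_pd", "ref_ap", "grey70") +
    grid_layer(nodes, "est_pd", "est_ap", "magenta3") +
    ggplot2::geom_point(data = lmk, ggplot2::aes(x = .data$X_pd, y = .data$X_ap),
                        colour = "grey40", size = 0.8) +
    ggplot2::geom_point(data = lmk, ggplot2::aes(x = .data$x_pd, y = .data$x_ap),
                        colour = "seagreen", size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "PD position (um)", y = "AP position (um)",
                  title = sprintf("Deformation map, %s", object$interval_id))
}

#' Plot a per-cell deformation field
#'
#' Growth-rate heat map with deformation-anisotropy axes drawn as
#' double-headed segments scaled by magnitude (reference frame).
#'
#' @param object A `deformation_field`.
#' @param what `"growth_rate"` or `"aniso_mag"` for the fill.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deformation_field <- function(object, what = "growth_rate", ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$supported, .data$ok)
  sp <- attr(object, "spacing")
  len <- 0.4 * sp * pmin((df$aniso_mag - 1) / 0.5, 1)
  arrows <- tibble::tibble(
    x = df$center_pd - len * df$aniso_pd, xend = df$center_pd + len * df$aniso_pd,
    y = df$center_ap - len * df$aniso_ap, yend = df$center_ap + len * df$aniso_ap)
  ggplot2::ggplot(df) +
    ggplot2::geom_tile(ggplot2::aes(x = .data$center_pd, y = .data$center_ap,
                                    fill = .data[[what]]),
                       width = sp, height = sp) +
    ggplot2::geom_segment(data = arrows,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          linewidth = 0.5, colour = "black") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "PD position (um)", y = "AP position (um)", fill = what)
}

#' Plot a vertex tissue
#'
#' @param object A `vertex_tissue`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vertex_tissue <- function(object, ...) {
  flat <- object$flat
  df <- tibble::tibble(
    cell = flat$cell,
    pd = object$V[flat$v, 1], ap = object$V[flat$v, 2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pd, y = .data$ap,
                                   group = .data$cell)) +
    ggplot2::geom_polygon(fill = "grey90", colour = "grey30", linewidth = 0.2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "PD position (um)", y = "AP position (um)")
}

#' Plot the outline trajectory of a simulated scenario
#'
#' @param object A `tissue_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tissue_trajectory <- function(object, ...) {
  df <- purrr::map_dfr(seq_along(object$outlines), function(i) {
    o <- object$outlines[[i]]
    tibble::tibble(step = i - 1L, pd = o[, 1], ap = o[, 2])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pd, y = .data$ap,
                                   group = .data$step, colour = .data$step)) +
    ggplot2::geom_polygon(fill = NA, linewidth = 0.4) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "PD position (um)", y = "AP position (um)",
                  colour = "step",
                  title = sprintf("Scenario %s", object$scenario))
}
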