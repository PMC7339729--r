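#' Map a gridded field or surface
#'
#' Raster map of one day's field (simulated CTM or predicted surface).
#'
#' @param field Field tibble (`pm25` column) or `ds_surface`
#'   (`pm25_mean`).
#' @param date Day to plot; defaults to the first date present.
#' @param stat For surfaces, `"mean"` or `"se"`.
#' @param sites Optional site tibble overplotted as points by network.
#' @return A ggplot object.
#' @export
plot_surface <- function(field, date = NULL, stat = c("mean", "se"),
                         sites = NULL) {
  stat <- match.arg(stat)
  date <- as.Date(date %||% min(field$date))
  d <- field[field$date == date, , drop = FALSE]
  val <- if ("pm25" %in% names(d)) d$pm25 else
    if (stat == "mean") d$pm25_mean else d$pm25_se
  lab <- if (stat == "se" && !"pm25" %in% names(d))
    "PM2.5 SE (µg/m³)" else "PM2.5 (µg/m³)"
  p <- ggplot2::ggplot(dplyr::mutate(d, value = val),
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)", title = format(date)) +
    ggplot2::theme_minimal()
  if (!is.null(sites))
    p <- p + ggplot2::geom_point(
      data = sites, inherit.aes = FALSE,
      ggplot2::aes(x = .data$x, y = .data$y, shape = .data$network),
      colour = "white", size = 2)
  p
}

#' @method autoplot ds_surface
#' @export
autoplot.ds_surface <- function(object, ...) plot_surface(object, ...)

#' Map an aggregate difference surface
#'
#' Diverging-colour map of augmented-minus-baseline differences for one
#' aggregate statistic.
#'
#' @param diff Output of [difference_surface()].
#' @param stat One of `"annual_mean"`, `"p98"`, `"q1"`..`"q4"`,
#'   `"se_mean"`.
#' @return A ggplot object.
#' @export
plot_difference <- function(diff, stat = "annual_mean") {
  stopifnot(stat %in% names(diff))
  ggplot2::ggplot(diff, ggplot2::aes(x = .data$x, y = .data$y,
                                     fill = .data[[stat]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(
      name = bquote(Delta ~ .(stat) ~ "(µg/m³)"),
      low = "#2166ac", mid = "white", high = "#b2182b") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)",
                  title = "augmented − baseline") +
    ggplot2::theme_minimal()
}

#' Posterior densities of a daily fit
#'
#' @param object A `ds_fit`.
#' @param ... Unused.
#' @return A ggplot object with one density panel per scalar parameter.
#' @method autoplot ds_fit
#' @export
autoplot.ds_fit <- function(object, ...) {
  d <- object$draws
  long <- dplyr::bind_rows(
    tibble::tibble(term = "beta0", value = d$beta0),
    tibble::tibble(term = "beta1", value = d$beta1),
    tibble::tibble(term = "sigma2", value = d$sigma2),
    tibble::tibble(term = "tau2", value = d$tau2))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior density",
                  title = format(object$date)) +
    ggplot2::theme_minimal()
}

#' Case-study time series plot
#'
#' Observed vs. baseline and augmented predictions at the focus sites of
#' [extract_case_study()].
#'
#' @param series The `series` tibble from [extract_case_study()].
#' @return A ggplot object, one panel per site.
#' @export
plot_case_study <- function(series) {
  long <- tidyr::pivot_longer(series, c("observed", "baseline", "augmented"),
                              names_to = "source", values_to = "pm25")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$date, y = .data$pm25,
                                     colour = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~site_id, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "PM2.5 (µg/m³)", colour = NULL) +
    ggplot2::theme_minimal()
}
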