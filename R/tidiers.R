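# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a 2D spectrum into a long tibble
#'
#' @param x A `spectrum2d`.
#' @param ... Unused.
#' @return A tibble with `direct_ppm`, `dq_ppm`, `intensity`.
#' @method tidy spectrum2d
#' @export
tidy.spectrum2d <- function(x, ...) {
  tibble::tibble(
    direct_ppm = rep(x$direct_ppm, each = length(x$dq_ppm)),
    dq_ppm = rep(x$dq_ppm, times = length(x$direct_ppm)),
    intensity = as.vector(x$intensity)
  )
}

#' Tidy a 1D spectrum
#'
#' @param x A `spectrum1d`.
#' @param ... Unused.
#' @return A tibble with `ppm`, `intensity`.
#' @method tidy spectrum1d
#' @export
tidy.spectrum1d <- function(x, ...) {
  tibble::tibble(ppm = x$ppm, intensity = x$intensity)
}

#' Tidy a network set: one row per network peak
#'
#' @param x An `inadnet_networks` object.
#' @param ... Unused.
#' @return The per-peak tibble with network membership.
#' @method tidy inadnet_networks
#' @export
tidy.inadnet_networks <- function(x, ...) x$peaks

#' One-row summary of a network set
#'
#' @param x An `inadnet_networks` object.
#' @param ... Unused.
#' @return A tibble: `n_networks`, `n_peaks`, `n_pairs`, `n_links`,
#'   `max_size`.
#' @method glance inadnet_networks
#' @export
glance.inadnet_networks <- function(x, ...) {
  st <- network_stats(x)
  tibble::tibble(n_networks = st$total, n_peaks = nrow(x$peaks),
                 n_pairs = nrow(x$pairs), n_links = nrow(x$links),
                 max_size = st$max_size)
}

#' Plot a 2D spectrum as an intensity raster
#'
#' @param object A `spectrum2d`.
#' @param trans Intensity transform before plotting (default `"sqrt"` of the
#'   positive part, which compresses the dynamic range).
#' @param ... Unused.
#' @return A ggplot object; ppm axes are reversed per NMR convention.
#' @method autoplot spectrum2d
#' @export
autoplot.spectrum2d <- function(object, trans = c("sqrt", "identity"),
                                ...) {
  trans <- match.arg(trans)
  d <- tidy.spectrum2d(object)
  if (trans == "sqrt") d$intensity <- sqrt(pmax(d$intensity, 0))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$direct_ppm, y = .data$dq_ppm,
                                  fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "direct 13C shift (ppm)",
                  y = "double-quantum shift (ppm)",
                  fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot a 1D spectrum or projection
#'
#' @param object A `spectrum1d`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spectrum1d
#' @export
autoplot.spectrum1d <- function(object, ...) {
  d <- tidy.spectrum1d(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ppm, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "13C shift (ppm)", y = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot INADEQUATE networks: peaks, horizontal pairs, vertical links
#'
#' @param object An `inadnet_networks` object.
#' @param ... Unused.
#' @return A ggplot object with pair segments, link segments and peak
#'   points coloured by network; the Y = 2X diagonal is drawn for
#'   orientation.
#' @method autoplot inadnet_networks
#' @export
autoplot.inadnet_networks <- function(object, ...) {
  pk <- object$peaks
  pk$network <- factor(pk$network_id)
  pr <- object$pairs
  seg <- tibble::tibble(
    x = pr$cs_direct_left, xend = pr$cs_direct_right,
    y = pr$dq_value, yend = pr$dq_value,
    network = factor(pr$network_id))
  lk <- object$links
  link_seg <- NULL
  if (nrow(lk) > 0) {
    a <- match(lk$peak_a, pk$peak_id); b <- match(lk$peak_b, pk$peak_id)
    link_seg <- tibble::tibble(
      x = pk$cs_direct[a], xend = pk$cs_direct[b],
      y = pk$cs_dq[a], yend = pk$cs_dq[b],
      network = factor(lk$network_id))
  }
  g <- ggplot2::ggplot() +
    ggplot2::geom_abline(slope = 2, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend,
                                       colour = .data$network))
  if (!is.null(link_seg) && nrow(link_seg) > 0) {
    g <- g + ggplot2::geom_segment(
      data = link_seg,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                   yend = .data$yend, colour = .data$network),
      linetype = "dashed")
  }
  g + ggplot2::geom_point(
    data = pk, ggplot2::aes(x = .data$cs_direct, y = .data$cs_dq,
                            colour = .data$network)) +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "direct 13C shift (ppm)",
                  y = "double-quantum shift (ppm)", colour = "network") +
    ggplot2::theme_minimal()
}
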