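#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted slide transform
#'
#' One row per estimated parameter, broom style.
#'
#' @param x A `wsi_transform`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `unit`.
#' @export
tidy.wsi_transform <- function(x, ...) {
  tibble(term = c("dx0", "dy0", "theta", "slope_m"),
         estimate = c(x$dx0, x$dy0, x$theta, x$slope_m),
         unit = c("level-0 px", "level-0 px", "degrees", "dy/dx"))
}

#' One-row summary of a fitted slide transform
#'
#' @param x A `wsi_transform`.
#' @param ... Unused.
#' @return One-row tibble: offsets, rotation, slope, sample counts, mean
#'   residual RMS and quality flag.
#' @export
glance.wsi_transform <- function(x, ...) {
  tibble(dx0 = x$dx0, dy0 = x$dy0, theta = x$theta, slope_m = x$slope_m,
         n_samples_used = x$n_samples_used,
         mean_residual_rms = if (nrow(x$per_level_residuals))
           mean(x$per_level_residuals$rms) else NA_real_,
         quality = x$quality)
}

#' Diagnostic plot of a fitted slide transform
#'
#' Scatter of the level-0-scaled patch offsets coloured by KDE confidence
#' weight and shaped by source level, with the fitted cross-level direction
#' through the origin and the final point estimate.
#'
#' @param object A `wsi_transform`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wsi_transform <- function(object, ...) {
  s <- object$samples
  est <- tibble(dx = object$dx0 - object$initial[1],
                dy = object$dy0 - object$initial[2])
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$dx, y = .data$dy)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$weight,
                                     shape = factor(.data$source_level)),
                        size = 2) +
    ggplot2::geom_point(data = est, shape = 3, size = 4, colour = "red",
                        stroke = 1.2) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "level-0 dx (px)", y = "level-0 dy (px)",
                  colour = "KDE weight", shape = "level",
                  title = "Patch offsets, KDE weights and fitted direction") +
    ggplot2::theme_minimal()
  if (is.finite(object$slope_m)) {
    p <- p + ggplot2::geom_abline(slope = object$slope_m, intercept = 0,
                                  linetype = 2, colour = "grey40")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter of a weighted offset pool
#'
#' Mirrors the standard diagnostic of patch-registration consistency:
#' offsets in the plane, coloured by confidence (KDE weight when present,
#' otherwise similarity score).
#'
#' @param samples OffsetSample tibble (optionally with a `weight` column).
#' @return A ggplot object.
#' @export
plot_offset_pool <- function(samples) {
  samples <- as_tibble(samples)
  colour_col <- if ("weight" %in% names(samples)) "weight" else "score"
  ggplot2::ggplot(samples,
                  ggplot2::aes(x = .data$dx, y = .data$dy,
                               colour = .data[[colour_col]])) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "dx (px)", y = "dy (px)", colour = colour_col) +
    ggplot2::theme_minimal()
}
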