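#' Cross-level resolution ratios
#'
#' Ratio `R_l` of each level's resolution to the next-higher-resolution
#' level (for a 1:4:16:32 pyramid and the three lowest-resolution levels,
#' `R_l` is 0.25, 0.25, 0.5). Level 0 has no higher-resolution neighbour and
#' gets the ratio to its lower-resolution neighbour.
#'
#' @param downsamples Per-level downsample factors, level 0 first.
#' @return Tibble with `level`, `downsample`, `ratio`.
#' @export
level_ratios <- function(downsamples) {
  L <- length(downsamples)
  stopifnot(L >= 2)
  ratio <- c(downsamples[1] / downsamples[2],
             downsamples[seq_len(L - 1)] / downsamples[-1])
  tibble(level = 0:(L - 1), downsample = as.numeric(downsamples),
         ratio = ratio)
}

#' Scale level-local offsets to the level-0 frame
#'
#' A shift of `(dx, dy)` pixels observed at a level with downsample `D`
#' corresponds to `(D * dx, D * dy)` level-0 pixels. The `level` column is
#' set to 0 after scaling; the originating level is preserved in
#' `source_level` so the cross-level regression can apply its per-level
#' resolution ratios.
#'
#' @param samples OffsetSample tibble with columns `level`, `dx`, `dy`.
#' @param downsamples Per-level downsample factors, level 0 first.
#' @return `samples` with `dx`, `dy` in level-0 pixels, `level = 0`, and
#'   `source_level`, `downsample` columns.
#' @export
scale_offsets_to_level0 <- function(samples, downsamples) {
  samples <- as_tibble(samples)
  if (any(samples$level < 0 | samples$level >= length(downsamples))) {
    abort("scale_offsets_to_level0: sample level outside the pyramid")
  }
  ds <- downsamples[samples$level + 1]
  samples$source_level <- samples$level
  samples$downsample <- ds
  samples$dx <- samples$dx * ds
  samples$dy <- samples$dy * ds
  samples$level <- 0L
  samples
}

#' Weighted regression through the origin across pyramid levels
#'
#' In an ideal pyramid every level-0-scaled offset lies on one line through
#' the origin whose slope is the direction of the true shift. The slope is
#' obtained by minimizing the weighted squared residual
#' `sum R_l * f_l * (y - m x)^2` over the pool, which has the closed form
#' `m = sum(w x y) / sum(w x^2)` with `w = R_l * f_l` (resolution ratio
#' times KDE confidence).
#'
#' @param points Data frame with columns `x`, `y`: level-0 offsets.
#' @param weights Nonnegative weights (KDE confidences), recycled to
#'   `nrow(points)`; default all 1.
#' @param ratios Per-point resolution ratios `R_l`, multiplied into the
#'   weights; default all 1.
#' @return The fitted slope `m` (a scalar).
#' @export
fit_weighted_slope <- function(points, weights = NULL, ratios = NULL) {
  points <- as_tibble(points)
  n <- nrow(points)
  if (n < 1) abort("fit_weighted_slope: no points")
  w <- if (is.null(weights)) rep(1, n) else rep_len(weights, n)
  if (!is.null(ratios)) w <- w * rep_len(ratios, n)
  if (all(w == 0)) abort("fit_weighted_slope: all weights zero")
  sxx <- sum(w * points$x^2)
  if (sxx == 0) {
    abort(class = "slidealign_degenerate_axis",
          message = "fit_weighted_slope: sum(w * x^2) is zero (vertical line); swap axes")
  }
  sum(w * points$x * points$y) / sxx
}

#' Combine weighted offsets from all levels into the final transform
#'
#' The full hierarchical estimator: scale all per-patch offsets to level 0,
#' weight the pooled offsets by KDE confidence (see [kde_weights()]),
#' fit the cross-level slope through the origin ([fit_weighted_slope()]),
#' project every weighted offset onto the fitted direction, and take the
#' weighted mean position along it. The initial thumbnail offset (which the
#' per-patch offsets exclude) is added back at the end.
#'
#' @param samples OffsetSample tibble (columns `level`, `dx`, `dy`, `theta`,
#'   `score`, `success`); offsets level-local, excluding the initial offset.
#' @param downsamples Per-level downsample factors of the pyramid.
#' @param initial Numeric `(dx, dy)` initial level-0 offset from thumbnail
#'   alignment.
#' @param config A [reg_config()]; `weighting`, `regression`,
#'   `kde_include_failures`, `kde_pooled`, `kde_diagonal` and `rotation`
#'   are honoured.
#' @return A `wsi_transform` object: final `dx0`, `dy0`, `theta`,
#'   `slope_m`, diagnostics, and the weighted sample pool.
#' @export
estimate_global_transform <- function(samples, downsamples,
                                      initial = c(0, 0),
                                      config = reg_config()) {
  samples <- as_tibble(samples)
  pool <- if (config$kde_include_failures) samples
          else samples[samples$success, , drop = FALSE]
  if (nrow(pool) == 0) {
    warn("no successful patch registrations; falling back to the initial offset")
    return(new_wsi_transform(dx0 = initial[1], dy0 = initial[2], theta = 0,
                             slope_m = NA_real_, n = 0L,
                             residuals = tibble(level = integer(),
                                                rms = numeric(),
                                                n = integer()),
                             initial = initial, samples = samples,
                             quality = "degraded", config = config))
  }
  scaled <- scale_offsets_to_level0(pool, downsamples)
  rat <- level_ratios(downsamples)
  scaled$ratio <- rat$ratio[match(scaled$source_level, rat$level)]

  base_w <- switch(config$weighting,
    kde = {
      if (config$kde_pooled || length(unique(scaled$source_level)) == 1) {
        kde_weights(scaled, use_theta = config$rotation,
                    diagonal = config$kde_diagonal)$weight
      } else {
        wt <- numeric(nrow(scaled))
        for (i in split(seq_len(nrow(scaled)), scaled$source_level)) {
          wt[i] <- kde_weights(scaled[i, ], use_theta = config$rotation,
                               diagonal = config$kde_diagonal)$weight
        }
        wt
      }
    },
    score = if (max(scaled$score) > 0) scaled$score / max(scaled$score)
            else rep(1, nrow(scaled)),
    uniform = rep(1, nrow(scaled))
  )
  scaled$weight <- base_w
  w <- base_w * scaled$ratio
  X <- cbind(scaled$dx, scaled$dy)

  sxx <- sum(w * X[, 1]^2); syy <- sum(w * X[, 2]^2)
  if (sxx + syy == 0) {
    # all residual offsets exactly zero: the initial offset already aligns
    u <- c(1, 0); slope_m <- 0; est <- c(0, 0)
  } else if (sxx >= syy) {
    m <- fit_weighted_slope(tibble(x = X[, 1], y = X[, 2]), weights = w)
    u <- c(1, m) / sqrt(1 + m^2); slope_m <- m
  } else {
    # near-vertical trend: use y as the abscissa and invert the fit
    m2 <- fit_weighted_slope(tibble(x = X[, 2], y = X[, 1]), weights = w)
    u <- c(m2, 1) / sqrt(1 + m2^2)
    slope_m <- if (m2 != 0) 1 / m2 else Inf
  }
  if (sxx + syy > 0) {
    s <- drop(X %*% u)
    est <- if (config$regression == "projection") {
      (sum(w * s) / sum(w)) * u
    } else {
      c(sum(w * X[, 1]), sum(w * X[, 2])) / sum(w)
    }
  }

  theta <- 0
  if (config$rotation) {
    theta <- atan2(sum(w * sin(scaled$theta * pi / 180)),
                   sum(w * cos(scaled$theta * pi / 180))) * 180 / pi
  }

  perp <- abs(X[, 1] * u[2] - X[, 2] * u[1])     # distance to the fitted line
  res <- dplyr::summarise(
    dplyr::group_by(tibble(level = scaled$source_level, w = w, perp = perp),
                    .data$level),
    rms = sqrt(sum(.data$w * .data$perp^2) / sum(.data$w)),
    n = dplyr::n(), .groups = "drop")

  new_wsi_transform(dx0 = est[1] + initial[1], dy0 = est[2] + initial[2],
                    theta = theta, slope_m = slope_m, n = nrow(scaled),
                    residuals = res, initial = initial, samples = scaled,
                    quality = "ok", config = config)
}

new_wsi_transform <- function(dx0, dy0, theta, slope_m, n, residuals,
                              initial, samples, quality, config) {
  structure(list(dx0 = unname(dx0), dy0 = unname(dy0), theta = unname(theta),
                 slope_m = slope_m, n_samples_used = n,
                 per_level_residuals = residuals,
                 initial = unname(initial), samples = samples,
                 quality = quality, config = config),
            class = "wsi_transform")
}

#' @export
print.wsi_transform <- function(x, ...) {
  cat("<wsi_transform>\n")
  cat(sprintf("  level-0 offset : (%.3f, %.3f) px\n", x$dx0, x$dy0))
  cat(sprintf("  rotation       : %.3f deg\n", x$theta))
  cat(sprintf("  slope m        : %s\n", format(x$slope_m, digits = 4)))
  cat(sprintf("  samples used   : %d  (quality: %s)\n",
              x$n_samples_used, x$quality))
  invisible(x)
}

#' Euclidean registration error against a ground-truth transform
#'
#' @param estimate,truth `wsi_transform` objects, or numeric `(dx0, dy0)`
#'   pairs in level-0 pixels.
#' @return One-row tibble: `euclidean_px`, `err_x`, `err_y`.
#' @export
evaluate_error <- function(estimate, truth) {
  p <- as_offset_pair(estimate); q <- as_offset_pair(truth)
  ex <- p[1] - q[1]; ey <- p[2] - q[2]
  tibble(euclidean_px = sqrt(ex^2 + ey^2), err_x = ex, err_y = ey)
}

as_offset_pair <- function(x) {
  if (inherits(x, "wsi_transform")) c(x$dx0, x$dy0)
  else if (is.list(x) && !is.null(x$dx0)) c(x$dx0, x$dy0)
  else as.numeric(x[1:2])
}
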