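#' Scott's-rule bandwidth factor
#'
#' The dimensionless Scott factor `n^(-1/(d+4))` for a kernel density
#' estimate on `n` points in `d` dimensions. The same factor is used on
#' every axis (no prior knowledge about the offset distribution favours a
#' direction).
#'
#' @param n Sample count (>= 1).
#' @param d Dimensionality of each data point.
#' @return The bandwidth factor `h`.
#' @export
scott_bandwidth <- function(n, d = 2) {
  if (length(n) != 1 || is.na(n) || n < 1) abort("scott_bandwidth: need n >= 1")
  if (d < 1) abort("scott_bandwidth: need d >= 1")
  n^(-1 / (d + 4))
}

# bandwidth matrix H = h^2 * Sigma-hat (or the equal-bandwidth diagonal
# h^2 * sigma^2 * I), with a degeneracy guard. Returns NULL when the pool
# carries no disagreement to resolve (all points identical / n == 1).
kde_bandwidth_matrix <- function(X, diagonal = FALSE) {
  n <- nrow(X); d <- ncol(X)
  if (n < 2) return(NULL)
  h <- scott_bandwidth(n, d)
  S <- stats::cov(X)
  if (diagonal) S <- diag(rep(mean(diag(S)), d), d)
  if (all(diag(S) < 1e-24)) return(NULL)
  # collinear but non-identical pools: ridge the covariance to keep H SPD
  if (det(S) <= 1e-12 * max(diag(S))^d) {
    S <- S + diag(rep(1e-6 * max(diag(S)) + 1e-12, d), d)
  }
  h^2 * S
}

# Gaussian-kernel density of each row of X under bandwidth matrix H:
# f(x) = 1 / (n * 2 * pi * sqrt(det H)) * sum_j exp(-(x - X_j)' H^-1 (x - X_j) / 2)
kde_density_at <- function(X, H, eval = X) {
  n <- nrow(X); d <- ncol(X)
  cst <- 1 / (n * (2 * pi)^(d / 2) * sqrt(det(H)))
  L <- chol(solve(H))                     # mahalanobis via whitening
  Z <- X %*% t(L)                         # n x d
  E <- eval %*% t(L)
  d2 <- outer(rowSums(E^2), rowSums(Z^2), "+") - 2 * E %*% t(Z)
  d2[d2 < 0] <- 0
  cst * rowSums(exp(-0.5 * d2))
}

#' KDE confidence weights for a pool of registration offsets
#'
#' Evaluates a bivariate Gaussian kernel density estimate at every offset in
#' the pool, with bandwidth matrix `H = h^2 * Sigma-hat` where `h` is the
#' Scott factor [scott_bandwidth()] and `Sigma-hat` the sample covariance of
#' the offsets. Densities are normalized by their maximum, giving each
#' sample a confidence weight in `[0, 1]`: offsets consistent with the bulk
#' of the pool get weight near 1, stray registrations get small weights.
#' This replaces the registration methods' own similarity scores, which do
#' not reliably reflect success on re-stained material.
#'
#' Offsets must be expressed in a common frame (scale per-level offsets to
#' level 0 with [scale_offsets_to_level0()] before pooling).
#'
#' @param samples Data frame with numeric columns `dx`, `dy` (and `theta`
#'   when `use_theta`), one registration offset per row.
#' @param use_theta Also weight by a separable 1-D KDE over the rotation
#'   angles (multiplied into the translation weight).
#' @param diagonal Equal-bandwidth diagonal kernel instead of the full
#'   sample covariance.
#' @return `samples` with columns `density` and `weight` appended;
#'   `max(weight) == 1` on any nonempty pool.
#' @export
kde_weights <- function(samples, use_theta = FALSE, diagonal = FALSE) {
  samples <- as_tibble(samples)
  n <- nrow(samples)
  if (n == 0) abort("kde_weights: empty pool")
  X <- cbind(samples$dx, samples$dy)
  H <- kde_bandwidth_matrix(X, diagonal = diagonal)
  if (is.null(H)) {
    dens <- rep(NA_real_, n); wt <- rep(1, n)   # degenerate: no disagreement
  } else {
    dens <- kde_density_at(X, H)
    wt <- dens / max(dens)
  }
  if (use_theta && n >= 2) {
    th <- samples$theta
    s <- stats::sd(th)
    if (s > 0) {
      bw <- scott_bandwidth(n, 1) * s
      dth <- vapply(th, function(t) mean(stats::dnorm(t, th, bw)), numeric(1))
      wt <- wt * dth / max(dth)
      wt <- wt / max(wt)
    }
  }
  samples$density <- dens
  samples$weight <- wt
  samples
}

#' Mode of the offset density surface
#'
#' Argmax of the pooled KDE over a regular grid spanning the sample bounding
#' box (expanded by one bandwidth). A diagnostic: the final registration
#' estimate comes from the cross-level regression, not from this mode.
#'
#' @param samples Data frame with columns `dx`, `dy`.
#' @param grid_resolution Grid points per axis.
#' @param diagonal See [kde_weights()].
#' @return Named numeric `c(dx, dy)` at the density maximum.
#' @export
kde_mode <- function(samples, grid_resolution = 101, diagonal = FALSE) {
  samples <- as_tibble(samples)
  if (nrow(samples) == 0) abort("kde_mode: empty pool")
  X <- cbind(samples$dx, samples$dy)
  H <- kde_bandwidth_matrix(X, diagonal = diagonal)
  if (is.null(H)) return(c(dx = mean(X[, 1]), dy = mean(X[, 2])))
  mar <- sqrt(diag(H))
  gx <- seq(min(X[, 1]) - mar[1], max(X[, 1]) + mar[1],
            length.out = grid_resolution)
  gy <- seq(min(X[, 2]) - mar[2], max(X[, 2]) + mar[2],
            length.out = grid_resolution)
  grid <- cbind(rep(gx, times = grid_resolution),
                rep(gy, each = grid_resolution))
  dens <- kde_density_at(X, H, eval = grid)
  best <- which.max(dens)
  c(dx = grid[best, 1], dy = grid[best, 2])
}
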