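# Independent oracles used to freeze expected values. Each deliberately
# avoids the code path it checks.

# brute-force spatial (not Fourier) cross-correlation: returns the integer
# lag (dx, dy) maximizing the overlap correlation of mean-removed images
brute_force_xcorr <- function(fixed, floating, max_lag) {
  f <- fixed - mean(fixed); g <- floating - mean(floating)
  h <- nrow(f); w <- ncol(f)
  best <- c(0, 0); best_v <- -Inf
  for (dy in -max_lag:max_lag) {
    for (dx in -max_lag:max_lag) {
      rs <- max(1, 1 + dy):min(h, h + dy)
      cs <- max(1, 1 + dx):min(w, w + dx)
      a <- f[rs - dy, cs - dx]; b <- g[rs, cs]
      v <- sum(a * b) / sqrt(sum(a^2) * sum(b^2) + 1e-30)
      if (v > best_v) { best_v <- v; best <- c(dx, dy) }
    }
  }
  list(dx = best[1], dy = best[2], score = best_v)
}

# naive double-loop bivariate Gaussian KDE with H = h^2 * Sigma-hat,
# f(x_i) = 1/(n 2 pi sqrt(det H)) sum_j exp(-(d' H^-1 d)/2)
naive_kde_density <- function(dx, dy) {
  X <- cbind(dx, dy)
  n <- nrow(X)
  h <- n^(-1 / 6)
  H <- h^2 * stats::cov(X)
  Hinv <- solve(H)
  cst <- 1 / (n * 2 * pi * sqrt(det(H)))
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) {
      d <- X[i, ] - X[j, ]
      s <- s + exp(-0.5 * drop(t(d) %*% Hinv %*% d))
    }
    out[i] <- cst * s
  }
  out
}

# grid-search minimizer of the weighted squared through-origin cost
# sum w (y - m x)^2 over m in [-10, 10] step 1e-4, by explicit summation
grid_search_slope <- function(x, y, w, step = 1e-4) {
  ms <- seq(-10, 10, by = step)
  cost <- vapply(ms, function(m) sum(w * (y - m * x)^2), numeric(1))
  ms[which.min(cost)]
}

# circular shift by pure index arithmetic: out[r, c] = M[r - dy, c - dx]
roll_oracle <- function(M, dy, dx) {
  h <- nrow(M); w <- ncol(M)
  M[((seq_len(h) - 1 - dy) %% h) + 1, ((seq_len(w) - 1 - dx) %% w) + 1]
}

# rotation construction by direct nearest-of-four resampling about the
# centre (independent of the package's resampler)
rotate_oracle <- function(M, theta_deg) {
  h <- nrow(M); w <- ncol(M)
  th <- theta_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  out <- matrix(mean(M), h, w)
  for (r in seq_len(h)) {
    cc <- seq_len(w) - cx
    rr <- r - cy
    ci <- cos(th) * cc + sin(th) * rr + cx
    ri <- -sin(th) * cc + cos(th) * rr + cy
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    ri <- pmin(pmax(ri, 1), h); ci <- pmin(pmax(ci, 1), w)
    r0 <- pmin(floor(ri), h - 1); c0 <- pmin(floor(ci), w - 1)
    fr <- ri - r0; fc <- ci - c0
    v <- (1 - fr) * ((1 - fc) * M[cbind(r0, c0)] + fc * M[cbind(r0, c0 + 1)]) +
      fr * ((1 - fc) * M[cbind(r0 + 1, c0)] + fc * M[cbind(r0 + 1, c0 + 1)])
    out[r, ok] <- v[ok]
  }
  out
}

# naive loop implementation of f x f block averaging
block_mean_oracle <- function(M, f) {
  h <- nrow(M) / f; w <- ncol(M) / f
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      out[i, j] <- mean(M[((i - 1) * f + 1):(i * f), ((j - 1) * f + 1):(j * f)])
    }
  }
  out
}

# mildly blurred white-noise texture patch in [0, 255] (band-limited enough
# for rotation/subpixel constructions, rich enough for phase correlation)
textured_patch <- function(n, seed = 1, sigma = 1.5) {
  withr::with_seed(seed, {
    M <- matrix(stats::rnorm(n * n), n, n)
    f <- c(0:(n / 2), (n / 2 - 1):1)
    H <- exp(-2 * pi^2 * sigma^2 * outer(f^2, f^2, "+") / n^2)
    M <- Re(stats::fft(stats::fft(M) * H, inverse = TRUE)) / n^2
    (M - min(M)) / (max(M) - min(M)) * 255
  })
}

# spectral (exact, band-limited) subpixel circular shift of a matrix
spectral_shift <- function(M, dx, dy) {
  h <- nrow(M); w <- ncol(M)
  fy <- c(0:floor((h - 1) / 2), -(ceiling((h - 1) / 2):1)) / h
  fx <- c(0:floor((w - 1) / 2), -(ceiling((w - 1) / 2):1)) / w
  Ph <- exp(-2i * pi * (outer(fy * dy, fx * dx, "+")))
  Re(stats::fft(stats::fft(M) * Ph, inverse = TRUE)) / (h * w)
}

# simulated per-patch offset pool around a level-0 truth, with optional
# nested uniform outliers in [-200, 200]^2 (level-0 frame); mirrors the
# tibble produced by the patch-registration loop
sim_offset_pool <- function(seed, truth = c(100, -40),
                            downsamples = c(1, 4, 16, 32), levels = 1:3,
                            n_per_level = 30, noise_sd = 2,
                            outlier_frac = 0) {
  withr::with_seed(seed, {
    rows <- lapply(levels, function(lv) {
      ds <- downsamples[lv + 1]
      tibble::tibble(level = lv,
                     dx = truth[1] / ds + stats::rnorm(n_per_level, 0, noise_sd),
                     dy = truth[2] / ds + stats::rnorm(n_per_level, 0, noise_sd),
                     theta = 0,
                     score = stats::runif(n_per_level, 0.2, 0.9),
                     success = TRUE)
    })
    pool <- dplyr::bind_rows(rows)
    n <- nrow(pool)
    ord <- sample.int(n)
    out_x <- stats::runif(n, -200, 200)
    out_y <- stats::runif(n, -200, 200)
    k <- round(outlier_frac * n)
    if (k > 0) {
      idx <- ord[seq_len(k)]
      ds <- downsamples[pool$level[idx] + 1]
      pool$dx[idx] <- out_x[seq_len(k)] / ds
      pool$dy[idx] <- out_y[seq_len(k)] / ds
    }
    pool
  })
}
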