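test_that("level ratios reproduce the canonical pyramid's values", {
  r <- level_ratios(c(1, 4, 16, 32))
  expect_equal(r$ratio[r$level %in% 1:3], c(0.25, 0.25, 0.5))
})

test_that("offsets scale to level 0 by the downsample factor", {
  s <- tibble::tibble(level = c(2L, 0L, 3L), dx = c(3, 7, 1.5),
                      dy = c(-2, 7, 0), theta = 0, score = 1, success = TRUE)
  out <- scale_offsets_to_level0(s, c(1, 4, 16, 32))
  expect_equal(out$dx, c(48, 7, 48))
  expect_equal(out$dy, c(-32, 7, 0))
  expect_equal(out$level, c(0L, 0L, 0L))
  expect_equal(out$source_level, c(2L, 0L, 3L))
  expect_error(scale_offsets_to_level0(dplyr::mutate(s, level = 9L),
                                       c(1, 4)), "outside")
})

test_that("weighted slope has the closed form sum(wxy)/sum(wx2)", {
  pts <- tibble::tibble(x = c(1, 2, 5), y = c(2, 4, 10))
  expect_equal(fit_weighted_slope(pts, weights = c(3, 1, 7)), 2)
  pts2 <- tibble::tibble(x = c(1, 1), y = c(1, 3))
  expect_equal(fit_weighted_slope(pts2, weights = c(3, 1)), 1.5)
  expect_error(fit_weighted_slope(tibble::tibble(x = c(0, 0), y = c(1, 2))),
               class = "slidealign_degenerate_axis")
})

test_that("closed-form slope matches grid-search minimization", {
  withr::with_seed(42, {
    for (trial in 1:20) {
      n <- sample(5:40, 1)
      m_true <- runif(1, -2, 2)
      x <- runif(n, -5, 5)
      y <- m_true * x + rnorm(n, 0, 0.5)
      w <- runif(n, 0.05, 1)
      m_closed <- fit_weighted_slope(tibble::tibble(x = x, y = y), weights = w)
      m_grid <- grid_search_slope(x, y, w)
      expect_lt(abs(m_closed - m_grid), 1e-4 + 1e-9)
    }
  })
})

test_that("noise-free consistent samples recover the truth exactly", {
  ds <- c(1, 4, 16, 32)
  truth <- c(100, -40)
  pool <- dplyr::bind_rows(lapply(1:3, function(lv) {
    tibble::tibble(level = lv, dx = rep(truth[1] / ds[lv + 1], 10),
                   dy = rep(truth[2] / ds[lv + 1], 10),
                   theta = 0, score = 0.8, success = TRUE)
  }))
  fit <- estimate_global_transform(pool, ds)
  expect_equal(fit$dx0, 100, tolerance = 1e-12)
  expect_equal(fit$dy0, -40, tolerance = 1e-12)
  expect_equal(fit$slope_m, -0.4, tolerance = 1e-12)
  expect_equal(fit$per_level_residuals$rms, rep(0, 3), tolerance = 1e-12)

  # scale equivariance: doubling all downsample factors doubles the estimate
  fit3 <- estimate_global_transform(pool, ds * 2)
  expect_equal(c(fit3$dx0, fit3$dy0), 2 * c(fit$dx0, fit$dy0),
               tolerance = 1e-12)
})

test_that("vertical trends trigger the axis swap, not a failure", {
  pool <- tibble::tibble(level = rep(1L, 8), dx = rep(0, 8),
                         dy = (-25) / 4 + c(-.1, .1, 0, 0, 0, 0, -.05, .05),
                         theta = 0, score = 0.8, success = TRUE)
  fit <- estimate_global_transform(pool, c(1, 4, 16, 32))
  expect_equal(fit$dx0, 0, tolerance = 0.2)
  expect_equal(fit$dy0, -25, tolerance = 0.5)
})

test_that("no successful samples falls back to the initial offset", {
  pool <- tibble::tibble(level = 1L, dx = 0, dy = 0, theta = 0, score = 0,
                         success = FALSE)
  expect_warning(
    fit <- estimate_global_transform(pool, c(1, 4, 16, 32),
                                     initial = c(12, -7)),
    "falling back")
  expect_equal(c(fit$dx0, fit$dy0), c(12, -7))
  expect_equal(fit$quality, "degraded")
})

test_that("Euclidean evaluation follows the 3-4-5 rule", {
  expect_equal(evaluate_error(c(3, 4), c(0, 0))$euclidean_px, 5)
  expect_equal(evaluate_error(c(10, 2), c(10, 2))$euclidean_px, 0)
  e <- evaluate_error(c(1, -2), c(4, 2))
  expect_equal(c(e$err_x, e$err_y), c(-3, -4))
})

test_that("median recovery error under patch noise stays small", {
  errs <- vapply(1:60, function(seed) {
    pool <- sim_offset_pool(seed, truth = c(100, -40), noise_sd = 2)
    fit <- estimate_global_transform(pool, c(1, 4, 16, 32))
    evaluate_error(fit, c(100, -40))$euclidean_px
  }, numeric(1))
  expect_lt(stats::median(errs), 6)
})

test_that("tidiers and plots expose the fit", {
  pool <- sim_offset_pool(1)
  fit <- estimate_global_transform(pool, c(1, 4, 16, 32))
  td <- tidy(fit)
  expect_equal(td$term, c("dx0", "dy0", "theta", "slope_m"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$dx0, fit$dx0)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_offset_pool(fit$samples), "ggplot")
})
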