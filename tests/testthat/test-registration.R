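test_that("grayscale conversion uses Rec. 601 luminance", {
  white <- array(1, c(4, 4, 3))
  expect_equal(to_grayscale(white), matrix(255, 4, 4))
  red <- array(0, c(4, 4, 3)); red[, , 1] <- 1
  expect_equal(to_grayscale(red), matrix(0.299 * 255, 4, 4))
  g <- matrix(runif(16), 4, 4) * 255
  expect_equal(to_grayscale(g), g)   # grayscale passes through
})

test_that("phase correlation recovers circular integer shifts exactly", {
  M <- textured_patch(128, seed = 4)
  pc0 <- phase_correlate(M, M)
  expect_equal(c(pc0$dx_int, pc0$dy_int), c(0, 0))
  expect_true(pc0$success)

  withr::with_seed(21, {
    for (i in 1:20) {
      s <- sample(-31:31, 2)
      Mb <- roll_oracle(M, s[2], s[1])
      pc <- phase_correlate(M, Mb)
      expect_equal(c(pc$dx_int, pc$dy_int), s)
    }
  })
})

test_that("degenerate and mismatched inputs are handled", {
  expect_error(phase_correlate(matrix(0, 8, 8), matrix(0, 8, 16)), "shape")
  flat <- matrix(5, 32, 32)
  pc <- phase_correlate(flat, flat)
  expect_false(pc$success)
  expect_equal(pc$score, 0)
})

test_that("phase correlation is antisymmetric", {
  A <- textured_patch(96, seed = 7)
  B <- spectral_shift(A, 3.3, -1.7)
  ab <- phase_correlate(A, B)
  ba <- phase_correlate(B, A)
  expect_equal(ab$dx, -ba$dx, tolerance = 0.05)
  expect_equal(ab$dy, -ba$dy, tolerance = 0.05)
})

test_that("subpixel refinement resolves a 2.5 px band-limited shift", {
  M <- textured_patch(128, seed = 12)
  Mb <- spectral_shift(M, 2.5, 0)
  pc <- phase_correlate(M, Mb)
  expect_gte(pc$dx, 2.25); expect_lte(pc$dx, 2.75)
  expect_lt(abs(pc$dy), 0.25)
})

test_that("score never improves with added noise (median over seeds)", {
  M <- textured_patch(96, seed = 3)
  med_score <- vapply(c(0, 20, 60, 150), function(s) {
    stats::median(vapply(1:20, function(k) {
      N <- withr::with_seed(1000 + k, matrix(stats::rnorm(96 * 96, 0, s), 96, 96))
      phase_correlate(M, M + N)$score
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_score) <= 1e-9))
})

test_that("independent noise pairs fall below the default score floor", {
  peaks <- vapply(1:40, function(k) {
    withr::with_seed(500 + k, {
      a <- matrix(stats::rnorm(256 * 256), 256, 256)
      b <- matrix(stats::rnorm(256 * 256), 256, 256)
    })
    phase_correlate(a, b)$score
  }, numeric(1))
  expect_lt(max(peaks), 0.05)           # the default floor separates cleanly
  expect_false(any(peaks >= reg_config()$score_floor))
})

test_that("rotation estimation recovers small constructed rotations", {
  M <- textured_patch(256, seed = 5)
  r0 <- estimate_rotation(M, M)
  expect_lt(abs(r0$theta), 0.1)
  r3 <- estimate_rotation(M, rotate_oracle(M, 3))
  expect_lt(abs(r3$theta - 3), 0.5)
  rm2 <- estimate_rotation(M, rotate_oracle(M, -2))
  expect_lt(abs(rm2$theta + 2), 0.5)
})

test_that("register_patch_pair recovers generator residuals", {
  p <- small_pair()
  # read the same tissue location from both images with no pre-shift: the
  # full truth becomes the residual, scaled by the level downsample
  mk <- tissue_mask(get_thumbnail(p$fixed_img))
  plan <- sample_patch_locations(mk, p$fixed_img, patches_per_level = 6,
                                 levels = 1, patch_size = 128, seed = 3)
  ds <- 2
  ok <- 0
  for (i in seq_len(nrow(plan))) {
    pf <- read_region(p$fixed_img, c(plan$origin_x[i], plan$origin_y[i]), 1,
                      c(128, 128))
    pm <- read_region(p$floating_img, c(plan$origin_x[i], plan$origin_y[i]), 1,
                      c(128, 128))
    s <- register_patch_pair(pf, pm)
    if (s$success) {
      expect_lt(abs(s$dx - 20 / ds), 0.5)
      expect_lt(abs(s$dy - (-14) / ds), 0.5)
      ok <- ok + 1
    }
  }
  expect_gte(ok, 3)
})

test_that("blank-glass patches fail cleanly and rotation config is honoured", {
  glass <- structure(list(pixels = array(1, c(64, 64, 3)), level = 1L,
                          downsample = 2, origin_l0 = c(x = 0, y = 0),
                          size = c(w = 64L, h = 64L), padded = FALSE),
                     class = "wsi_patch")
  s <- register_patch_pair(glass, glass)
  expect_false(s$success)

  # rotation disabled (default): theta is exactly 0
  p <- small_pair()
  pf <- read_region(p$fixed_img, c(128, 128), 0, c(128, 128))
  pm <- read_region(p$floating_img, c(148, 114), 0, c(128, 128))
  s0 <- register_patch_pair(pf, pm)
  expect_identical(s0$theta, 0)
})

test_that("rotation-enabled registration derotates before translating", {
  M <- textured_patch(192, seed = 8)
  Mrot <- rotate_oracle(roll_oracle(M, -4, 7), 2)
  as_patch <- function(m) {
    px <- array(rep(m / 255, 3), c(nrow(m), ncol(m), 3))
    structure(list(pixels = px, level = 0L, downsample = 1,
                   origin_l0 = c(x = 0, y = 0),
                   size = c(w = ncol(m), h = nrow(m)), padded = FALSE),
              class = "wsi_patch")
  }
  s <- register_patch_pair(as_patch(M), as_patch(Mrot),
                           reg_config(rotation = TRUE))
  expect_lt(abs(s$theta - 2), 0.5)
  expect_lt(abs(s$dx - 7), 1)
  expect_lt(abs(s$dy - (-4)), 1)
})

test_that("slope filter keeps parallel match lines and drops outliers", {
  m0 <- tibble::tibble(fixed_x = numeric(), fixed_y = numeric(),
                       float_x = numeric(), float_y = numeric())
  expect_equal(nrow(filter_matches_by_slope(m0)), 0)

  withr::with_seed(2, {
    base <- tibble::tibble(fixed_x = runif(10, 0, 100),
                           fixed_y = runif(10, 0, 100))
  })
  same <- dplyr::mutate(base, float_x = fixed_x + 12, float_y = fixed_y - 5)
  expect_equal(nrow(filter_matches_by_slope(same, tolerance = 5)), 10)

  # 9 parallel pairs + 1 whose line sits ~40 degrees off the mode
  off <- same
  w <- 100  # frame offset used by the angle computation
  ang40 <- (atan2(-5, w + 12) * 180 / pi) + 40
  off$float_x[10] <- off$fixed_x[10] + 150 * cos(ang40 * pi / 180) - w
  off$float_y[10] <- off$fixed_y[10] + 150 * sin(ang40 * pi / 180)
  kept <- filter_matches_by_slope(off, tolerance = 5, frame_offset = w)
  expect_equal(nrow(kept), 9)
  expect_true(all(kept$fixed_x %in% off$fixed_x[1:9]))
})
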