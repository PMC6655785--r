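test_that("brightness thresholding separates tissue from glass", {
  white <- array(1, c(40, 40, 3))
  expect_warning(mk <- tissue_mask(white, threshold = 200), "empty mask")
  expect_equal(mk$coverage, 0)

  # one dark 10x10 square on a 40x40 white field, fixed threshold
  img <- array(1, c(40, 40, 3))
  img[11:20, 6:15, ] <- 0.3
  mk2 <- tissue_mask(img, threshold = 200)
  expect_equal(mk2$coverage, 100 / 1600)
  expect_true(all(mk2$mask[11:20, 6:15]))
  expect_equal(sum(mk2$mask), 100)
})

test_that("auto threshold recovers the generator's tissue fraction", {
  p <- small_pair()   # nominal tissue fraction 0.65
  mk <- tissue_mask(get_thumbnail(p$fixed_img))
  expect_gt(mk$coverage, 0.65 * 0.8)
  expect_lt(mk$coverage, 0.65 * 1.2)
})

test_that("patch sampling is seed-deterministic and mask-respecting", {
  p <- small_pair()
  img <- p$fixed_img
  mk <- tissue_mask(get_thumbnail(img))
  a <- sample_patch_locations(mk, img, patches_per_level = 8,
                              patch_size = 64, seed = 11)
  b <- sample_patch_locations(mk, img, patches_per_level = 8,
                              patch_size = 64, seed = 11)
  expect_equal(as.data.frame(a), as.data.frame(b))
  c_ <- sample_patch_locations(mk, img, patches_per_level = 8,
                               patch_size = 64, seed = 12)
  expect_false(identical(as.data.frame(a), as.data.frame(c_)))

  # every footprint at least half inside the mask
  sat <- slidealign:::mask_sat(mk$mask)
  f <- a$downsample / mk$downsample
  frac <- slidealign:::mask_fraction(
    sat,
    r0 = floor(a$origin_y / a$downsample * f),
    r1 = ceiling((a$origin_y / a$downsample + a$patch_h) * f),
    c0 = floor(a$origin_x / a$downsample * f),
    c1 = ceiling((a$origin_x / a$downsample + a$patch_w) * f))
  expect_true(all(frac >= 0.5))

  # default levels are the three lowest-resolution ones
  d <- sample_patch_locations(mk, img, patches_per_level = 2,
                              patch_size = 16, seed = 1)
  expect_setequal(unique(d$level), 0:2)
})

test_that("scarce candidates return everything with a warning", {
  mask <- matrix(FALSE, 32, 32)
  mask[10:13, 10:13] <- TRUE    # room for very few 64 px footprints
  mk <- structure(list(mask = mask, threshold = 200, coverage = mean(mask),
                       downsample = 16),
                  class = "tissue_mask")
  lv0 <- array(0.5, c(512, 512, 3))
  img <- new_pyramid(list(lv0, array(0.5, c(256, 256, 3)),
                          array(0.5, c(32, 32, 3))))
  expect_warning(
    plan <- sample_patch_locations(mk, img, patches_per_level = 30,
                                   levels = 0, patch_size = 64, seed = 2),
    "candidate origins")
  expect_lt(nrow(plan), 30)
  expect_gt(nrow(plan), 0)

  empty <- structure(list(mask = matrix(FALSE, 8, 8), threshold = 200,
                          coverage = 0, downsample = 16),
                     class = "tissue_mask")
  expect_error(sample_patch_locations(empty, img), "empty")
})

test_that("sample plans serialize to JSON and back", {
  p <- small_pair()
  mk <- tissue_mask(get_thumbnail(p$fixed_img))
  plan <- sample_patch_locations(mk, p$fixed_img, patches_per_level = 4,
                                 patch_size = 64, seed = 3)
  f <- tempfile(fileext = ".json")
  write_sample_plan(plan, f)
  back <- read_sample_plan(f)
  expect_equal(as.data.frame(back), as.data.frame(plan))
  expect_equal(attr(back, "seed"), 3L)
})

test_that("thumbnail alignment yields the initial offset", {
  p <- small_pair()
  same <- initial_offset(p$fixed_img, p$fixed_img)
  expect_equal(c(same$dx, same$dy), c(0, 0), tolerance = 1e-6)

  io <- initial_offset(p$fixed_img, p$floating_img)
  # truth (20, -14); one thumbnail pixel = 4 level-0 px
  expect_lte(abs(io$dx - 20), 4)
  expect_lte(abs(io$dy + 14), 4)

  p4 <- pyramid_pair()
  io4 <- initial_offset(p4$fixed_img, p4$floating_img)
  expect_lte(abs(io4$dx - 96), 32)
  expect_lte(abs(io4$dy + 64), 32)

  # independent noise pyramids: no credible thumbnail alignment
  mk_noise <- function(seed) {
    withr::with_seed(seed, {
      l0 <- array(runif(128 * 128 * 3), c(128, 128, 3))
    })
    new_pyramid(list(l0, array(0.5, c(64, 64, 3)) +
                       array(runif(64 * 64 * 3, -0.3, 0.3), c(64, 64, 3))))
  }
  expect_warning(z <- initial_offset(mk_noise(1), mk_noise(99)),
                 "zero offset")
  expect_equal(c(z$dx, z$dy), c(0, 0))
})
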