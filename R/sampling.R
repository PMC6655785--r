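#' Locate content-rich tissue by brightness thresholding
#'
#' Brightfield slide background (blank glass) is near-white while tissue is
#' darker, so a grayscale intensity threshold on the thumbnail separates the
#' two and the histogram is strongly bimodal. With `threshold = "auto"` the
#' threshold is chosen by Otsu's bimodal-histogram criterion, falling back
#' to a fixed 220/255 when the criterion degenerates (all-tissue or
#' all-glass thumbnails). Connected components smaller than 0.1% of the
#' thumbnail are removed as debris.
#'
#' @param thumb A `wsi_patch` (see [get_thumbnail()]) or an image array.
#' @param threshold Grayscale level in `[0, 255]`, or `"auto"`.
#' @return A `tissue_mask`: list with `mask` (logical matrix), `threshold`,
#'   `coverage` (fraction of tissue pixels), `downsample` of the thumbnail.
#' @export
tissue_mask <- function(thumb, threshold = "auto") {
  ds <- if (inherits(thumb, "wsi_patch")) thumb$downsample else 1
  g <- to_grayscale(thumb)                      # [0, 255]
  if (identical(threshold, "auto")) {
    thr <- tryCatch(255 * EBImage::otsu(EBImage::Image(g / 255)),
                    error = function(e) 220)
    cov0 <- mean(g < thr)
    if (cov0 == 0 || cov0 == 1) thr <- 220      # degenerate histogram
  } else {
    thr <- threshold
  }
  mask <- g < thr
  min_px <- ceiling(0.001 * length(mask))
  if (any(mask) && min_px > 1) {
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    sizes <- tabulate(as.integer(lab))
    keep <- which(sizes >= min_px)
    mask <- matrix(as.integer(lab) %in% keep, nrow(mask), ncol(mask))
  }
  cov <- mean(mask)
  if (cov == 0) warn("tissue_mask: empty mask (no tissue below threshold)")
  structure(list(mask = mask, threshold = thr, coverage = cov,
                 downsample = ds),
            class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("<tissue_mask> %dx%d, threshold %.1f, coverage %.1f%%\n",
              ncol(x$mask), nrow(x$mask), x$threshold, 100 * x$coverage))
  invisible(x)
}

# summed-area table of a logical mask, for O(1) footprint coverage queries
mask_sat <- function(mask) {
  S <- apply(apply(mask, 2, cumsum), 1, cumsum)   # transposed SAT
  rbind(0, cbind(0, t(S)))
}

# fraction of mask TRUE inside the half-open rectangle rows [r0, r1) cols
# [c0, c1) in mask coordinates (0-based, clipped)
mask_fraction <- function(sat, r0, r1, c0, c1) {
  H <- nrow(sat) - 1; W <- ncol(sat) - 1
  area <- pmax(r1 - r0, 0) * pmax(c1 - c0, 0)
  r0c <- pmin(pmax(r0, 0), H); r1c <- pmin(pmax(r1, 0), H)
  c0c <- pmin(pmax(c0, 0), W); c1c <- pmin(pmax(c1, 0), W)
  inside <- sat[cbind(r1c + 1, c1c + 1)] - sat[cbind(r0c + 1, c1c + 1)] -
    sat[cbind(r1c + 1, c0c + 1)] + sat[cbind(r0c + 1, c0c + 1)]
  ifelse(area > 0, inside / area, 0)
}

#' Sample patch locations inside the tissue mask
#'
#' Draws `patches_per_level` patch origins per level, uniformly without
#' replacement from a grid of candidate origins whose footprint is at least
#' half inside the tissue mask. Sampling is deterministic given `seed`; each
#' level uses its own RNG stream keyed by `(seed, level)`, so changing the
#' draw at one level cannot perturb another's.
#'
#' @param mask A [tissue_mask()] computed from the thumbnail.
#' @param img The `wsi_pyramid` being sampled.
#' @param patches_per_level Patches per level.
#' @param levels Level indices to sample; `NULL` = the three
#'   lowest-resolution levels.
#' @param patch_size Patch side, level-local pixels (clamped per level).
#' @param seed Integer seed.
#' @return A `sample_plan` tibble: `level`, `downsample`, `origin_x`,
#'   `origin_y` (level-0 px), `patch_w`, `patch_h`; attributes `seed`,
#'   `patch_size`.
#' @export
sample_patch_locations <- function(mask, img, patches_per_level = 30,
                                   levels = NULL, patch_size = 256,
                                   seed = 1L) {
  stopifnot(inherits(mask, "tissue_mask"), inherits(img, "wsi_pyramid"),
            patches_per_level >= 1)
  if (mask$coverage == 0) abort("sample_patch_locations: empty tissue mask")
  nl <- length(img$levels)
  if (is.null(levels)) levels <- seq.int(max(nl - 3, 0), nl - 1)
  sat <- mask_sat(mask$mask)
  ds_thumb <- mask$downsample
  rows <- list()
  for (lv in levels) {
    ds <- img$downsamples[lv + 1]
    d <- dim(img$levels[[lv + 1]])
    psz <- min(patch_size, d[1], d[2])
    stride <- max(1, psz %/% 4)
    xs <- seq(0, d[2] - psz, by = stride)
    ys <- seq(0, d[1] - psz, by = stride)
    cand <- expand.grid(x = xs, y = ys)
    # candidate footprints in thumbnail coordinates
    f <- ds / ds_thumb
    frac <- mask_fraction(sat,
                          r0 = floor(cand$y * f), r1 = ceiling((cand$y + psz) * f),
                          c0 = floor(cand$x * f), c1 = ceiling((cand$x + psz) * f))
    cand <- cand[frac >= 0.5, , drop = FALSE]
    if (nrow(cand) == 0) next
    k <- min(patches_per_level, nrow(cand))
    if (k < patches_per_level) {
      warn(sprintf("level %d: only %d candidate origins for %d requested patches",
                   lv, nrow(cand), patches_per_level))
    }
    pick <- withr::with_seed(sub_seed(seed, lv),
                             sample.int(nrow(cand), k))
    rows[[length(rows) + 1]] <-
      tibble(level = as.integer(lv), downsample = ds,
             origin_x = cand$x[pick] * ds, origin_y = cand$y[pick] * ds,
             patch_w = as.integer(psz), patch_h = as.integer(psz))
  }
  if (length(rows) == 0) abort("sample_patch_locations: no valid candidates at any level")
  plan <- dplyr::bind_rows(rows)
  attr(plan, "seed") <- as.integer(seed)
  attr(plan, "patch_size") <- as.integer(patch_size)
  class(plan) <- c("sample_plan", class(plan))
  plan
}

#' Serialize / restore a sample plan
#'
#' @param plan A `sample_plan`.
#' @param path JSON file path.
#' @return `path` (write) or the restored plan (read).
#' @export
write_sample_plan <- function(plan, path) {
  jsonlite::write_json(list(seed = attr(plan, "seed"),
                            patch_size = attr(plan, "patch_size"),
                            locations = as.data.frame(plan)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sample_plan
#' @export
read_sample_plan <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  plan <- as_tibble(j$locations)
  attr(plan, "seed") <- as.integer(j$seed)
  attr(plan, "patch_size") <- as.integer(j$patch_size)
  class(plan) <- c("sample_plan", class(plan))
  plan
}

#' Initial coarse offset from thumbnail alignment
#'
#' Phase-correlates the two slide thumbnails and scales the recovered shift
#' to level-0 pixels. This coarse offset pre-shifts all floating-image patch
#' reads so that the per-patch phase correlations only resolve a small
#' residual, well inside the wrap-around-safe range.
#'
#' @param fixed,floating `wsi_pyramid` objects.
#' @param score_floor Minimum correlation peak; below it a zero offset is
#'   returned with a warning.
#' @return One-row OffsetSample tibble with `dx`, `dy` in level-0 pixels
#'   (`level = 0`).
#' @export
initial_offset <- function(fixed, floating, score_floor = 0.05) {
  t1 <- get_thumbnail(fixed); t2 <- get_thumbnail(floating)
  d <- pmin(dim(t1$pixels)[1:2], dim(t2$pixels)[1:2])
  g1 <- to_grayscale(t1)[seq_len(d[1]), seq_len(d[2])]
  g2 <- to_grayscale(t2)[seq_len(d[1]), seq_len(d[2])]
  pc <- phase_correlate(g1, g2, score_floor = score_floor)
  ds <- t1$downsample
  if (!pc$success) {
    warn("initial_offset: thumbnail registration failed; using zero offset")
    return(offset_sample(dx = 0, dy = 0, score = pc$score, level = 0L,
                         success = FALSE))
  }
  offset_sample(dx = pc$dx * ds, dy = pc$dy * ds, dx_int = pc$dx_int * ds,
                dy_int = pc$dy_int * ds, score = pc$score, level = 0L,
                success = TRUE)
}
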