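#' Registration run configuration
#'
#' Collects every tunable of the patch-based registration pipeline in one
#' validated list, so a run is fully reproducible from (inputs, config, seed).
#'
#' @param patch_size Patch side in level-local pixels (clamped to the level
#'   dimensions where a level is smaller).
#' @param patches_per_level Number of patches sampled at each level.
#' @param levels Pyramid levels to sample; `NULL` = the three
#'   lowest-resolution levels.
#' @param score_floor Minimum phase-correlation peak for a patch
#'   registration to count as a success.
#' @param rotation Estimate a small per-patch rotation (off by default:
#'   re-stained slides keep a fixed position on the glass, so rotation is
#'   minimal).
#' @param max_rotation Rotation search half-range, degrees.
#' @param kde_include_failures Keep failed registrations in the KDE pool.
#' @param weighting `"kde"`, `"score"` or `"uniform"`.
#' @param regression `"projection"` (project weighted offsets on the fitted
#'   cross-level direction) or `"weighted_mean"`.
#' @param kde_pooled Single KDE over all levels after scaling to level 0
#'   (`TRUE`, default) or one KDE per level.
#' @param kde_diagonal Use the equal-bandwidth diagonal kernel
#'   `h^2 * sigma^2 * I` instead of `h^2 * Sigma-hat`.
#' @param seed Integer seed driving patch sampling.
#' @return A `reg_config` list.
#' @export
reg_config <- function(patch_size = 256, patches_per_level = 30, levels = NULL,
                       score_floor = 0.05, rotation = FALSE, max_rotation = 5,
                       kde_include_failures = FALSE,
                       weighting = c("kde", "score", "uniform"),
                       regression = c("projection", "weighted_mean"),
                       kde_pooled = TRUE, kde_diagonal = FALSE, seed = 1L) {
  weighting <- match.arg(weighting)
  regression <- match.arg(regression)
  stopifnot(patch_size > 0, patches_per_level >= 1, score_floor >= 0,
            max_rotation > 0)
  structure(list(patch_size = as.integer(patch_size),
                 patches_per_level = as.integer(patches_per_level),
                 levels = levels, score_floor = score_floor,
                 rotation = isTRUE(rotation), max_rotation = max_rotation,
                 kde_include_failures = isTRUE(kde_include_failures),
                 weighting = weighting, regression = regression,
                 kde_pooled = isTRUE(kde_pooled),
                 kde_diagonal = isTRUE(kde_diagonal),
                 seed = as.integer(seed)),
            class = "reg_config")
}

#' Convert a patch to a luminance image
#'
#' Standard Rec. 601 luminance, `0.299 R + 0.587 G + 0.114 B`, returned as a
#' float matrix in `[0, 255]`.
#'
#' @param patch A `wsi_patch`, an `H x W x 3` array in `[0, 1]`, or an
#'   already-grayscale matrix (passed through, rescaled to `[0, 255]` if
#'   needed).
#' @return Numeric matrix in `[0, 255]`.
#' @export
to_grayscale <- function(patch) {
  x <- if (inherits(patch, "wsi_patch")) patch$pixels else patch
  if (is.matrix(x)) {
    return(if (max(x) <= 1) x * 255 else x)
  }
  stopifnot(length(dim(x)) == 3)
  255 * (0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3])
}

# one-row OffsetSample tibble; the common currency of the pipeline
offset_sample <- function(dx = 0, dy = 0, theta = 0, score = 0, level = NA_integer_,
                          origin_x = NA_real_, origin_y = NA_real_,
                          success = FALSE, dx_int = NA_real_, dy_int = NA_real_) {
  tibble(level = as.integer(level), origin_x = origin_x, origin_y = origin_y,
         dx = dx, dy = dy, dx_int = dx_int, dy_int = dy_int,
         theta = theta, score = score, success = success)
}

#' Phase correlation of two equally sized grayscale images
#'
#' Registers `floating` against `fixed` through the normalized cross-power
#' spectrum `conj(F1) * F2 / |F1 * conj(F2)|`: its inverse transform is an
#' impulse at the displacement between the images. Both inputs are
#' mean-removed and Hann-tapered first; the integer peak is then refined to
#' subpixel precision with a locally upsampled discrete Fourier transform.
#'
#' Sign convention: the returned `(dx, dy)` is the position of floating
#' content relative to fixed content, i.e. `floating(x, y) = fixed(x - dx,
#' y - dy)`. Shifts are reported in the signed interval `[-N/2, N/2)`.
#'
#' Success requires the peak to clear both `score_floor` and the
#' noise-peak ceiling `2.5 * sqrt(2 * log(N) / N)` for `N` pixels — the
#' scale of the largest peak that two completely unrelated images of this
#' size produce, so texture-poor patches cannot masquerade as matches at
#' any patch size.
#'
#' @param fixed,floating Numeric matrices of identical dimensions.
#' @param score_floor Success threshold on the correlation peak (combined
#'   with the size-dependent noise ceiling described above).
#' @param subpixel Refine the integer peak (default `TRUE`).
#' @param window Apply the Hann taper (default `TRUE`).
#' @return One-row tibble: `dx`, `dy` (subpixel), `dx_int`, `dy_int`
#'   (integer stage), `score` in `[0, 1]`, `success`.
#' @export
phase_correlate <- function(fixed, floating, score_floor = 0.05,
                            subpixel = TRUE, window = TRUE) {
  if (!all(dim(fixed) == dim(floating))) {
    abort("phase_correlate: images must have identical shapes")
  }
  h <- nrow(fixed); w <- ncol(fixed)
  if (stats::sd(fixed) == 0 || stats::sd(floating) == 0) {
    return(offset_sample(score = 0, success = FALSE, dx_int = 0, dy_int = 0))
  }
  win <- if (window) outer(hann_window(h), hann_window(w)) else 1
  F1 <- stats::fft((fixed - mean(fixed)) * win)
  F2 <- stats::fft((floating - mean(floating)) * win)
  R <- Conj(F1) * F2
  mag <- Mod(R)
  mmax <- max(mag)
  if (mmax == 0) {
    return(offset_sample(score = 0, success = FALSE, dx_int = 0, dy_int = 0))
  }
  R <- R / (mag + 1e-15 * mmax)
  surf <- Re(stats::fft(R, inverse = TRUE)) / (h * w)
  pk <- arrayInd(which.max(surf), dim(surf))
  score <- min(max(surf[pk]), 1)
  dy_i <- pk[1] - 1; dx_i <- pk[2] - 1
  if (dy_i >= h / 2) dy_i <- dy_i - h
  if (dx_i >= w / 2) dx_i <- dx_i - w
  dx <- dx_i; dy <- dy_i
  if (subpixel) {
    ref <- refine_peak_dft(R, dy_i, dx_i, h, w)
    dy <- ref[1]; dx <- ref[2]
  }
  floor_eff <- max(score_floor, noise_peak_ceiling(h * w))
  offset_sample(dx = dx, dy = dy, dx_int = dx_i, dy_int = dy_i,
                score = score, success = score >= floor_eff)
}

# largest correlation peak expected between unrelated images of n pixels
# (extreme-value scale of ~n weakly dependent normalized terms, with margin)
noise_peak_ceiling <- function(n) 2.5 * sqrt(2 * log(n) / n)

# evaluate the correlation surface on fine grids around the integer peak by
# direct (matrix-product) DFT with signed frequencies; two zoom stages give
# ~2e-3 px resolution
refine_peak_dft <- function(R, dy_i, dx_i, h, w) {
  fy <- 0:(h - 1); fy[fy >= h / 2] <- fy[fy >= h / 2] - h
  fx <- 0:(w - 1); fx[fx >= w / 2] <- fx[fx >= w / 2] - w
  eval_grid <- function(us, vs) {
    Ey <- exp(2i * pi * outer(fy, us) / h)    # h x nu
    Ex <- exp(2i * pi * outer(fx, vs) / w)    # w x nv
    Re(crossprod(Ey, R %*% Ex)) / (h * w)     # nu x nv
  }
  ctr <- c(dy_i, dx_i); half <- 1; step <- 0.1
  for (stage in 1:2) {
    us <- seq(ctr[1] - half, ctr[1] + half, by = step)
    vs <- seq(ctr[2] - half, ctr[2] + half, by = step)
    S <- eval_grid(us, vs)
    pk <- arrayInd(which.max(S), dim(S))
    ctr <- c(us[pk[1]], vs[pk[2]])
    half <- step; step <- step / 50
  }
  ctr
}

#' Estimate a small rotation between two patches
#'
#' The magnitude of the Fourier spectrum is invariant to translation and
#' co-rotates with the image, so rotation is recovered by resampling both
#' log-magnitude spectra on a polar grid and circularly correlating their
#' angular signatures (the scale channel of the classical log-polar method
#' is fixed at 1: re-staining implies no scale change). The search is
#' restricted to a small angular window because re-stained slides exhibit
#' minimal rotation.
#'
#' @param fixed,floating Equal-size square grayscale matrices.
#' @param max_angle Search half-range in degrees.
#' @param nphi Angular bins over 180 degrees.
#' @return List with `theta` (degrees; rotating `floating` by `-theta`
#'   aligns it to `fixed`) and `score` (normalized angular correlation).
#' @export
estimate_rotation <- function(fixed, floating, max_angle = 5, nphi = 720) {
  if (!all(dim(fixed) == dim(floating))) {
    abort("estimate_rotation: images must have identical shapes")
  }
  h <- nrow(fixed); w <- ncol(fixed)
  win <- outer(hann_window(h), hann_window(w))
  sig <- function(M) {
    G <- Mod(stats::fft((M - mean(M)) * win))
    G <- fftshift2(G)
    cy <- floor(h / 2) + 1; cx <- floor(w / 2) + 1
    rmax <- min(h, w) / 2 - 2
    radii <- seq(4, rmax, length.out = 96)
    phi <- (0:(nphi - 1)) * pi / nphi            # spectrum has 180-deg symmetry
    ri <- outer(radii, phi, function(r, p) cy + r * sin(p))
    ci <- outer(radii, phi, function(r, p) cx + r * cos(p))
    colSums(log1p(matrix(bilinear_lookup(G, as.vector(ri), as.vector(ci)),
                         length(radii), nphi)))
  }
  m1 <- sig(fixed) ; m1 <- m1 - mean(m1)
  m2 <- sig(floating); m2 <- m2 - mean(m2)
  n1 <- sqrt(sum(m1^2)); n2 <- sqrt(sum(m2^2))
  if (n1 == 0 || n2 == 0) return(list(theta = 0, score = 0))
  cc <- Re(stats::fft(Conj(stats::fft(m1)) * stats::fft(m2), inverse = TRUE)) /
    (nphi * n1 * n2)
  lag <- 0:(nphi - 1); lag[lag >= nphi / 2] <- lag[lag >= nphi / 2] - nphi
  ang <- lag * 180 / nphi
  ok <- abs(ang) <= max_angle
  best <- which(ok)[which.max(cc[ok])]
  theta <- ang[best]
  # parabolic sub-bin interpolation on the circular correlation
  im1 <- ((best - 2) %% nphi) + 1; ip1 <- (best %% nphi) + 1
  y0 <- cc[im1]; y1 <- cc[best]; y2 <- cc[ip1]
  den <- y0 - 2 * y1 + y2
  if (den < 0) theta <- theta + 0.5 * (y0 - y2) / den * 180 / nphi
  list(theta = theta, score = min(max(cc[best], 0), 1))
}

fftshift2 <- function(M) {
  h <- nrow(M); w <- ncol(M)
  M[c((floor(h / 2) + 1):h, 1:floor(h / 2)),
    c((floor(w / 2) + 1):w, 1:floor(w / 2))]
}

#' Register one fixed/floating patch pair
#'
#' Grayscale conversion, optional rotation estimation and derotation of the
#' floating patch, then phase correlation. The returned offsets are
#' level-local and exclude any global pre-shift applied when the patches
#' were read (the caller recombines). Failures (blank glass, texture-poor
#' patches) come back with `success = FALSE` and stay in the pool — the KDE
#' stage down-weights them.
#'
#' @param fixed,floating `wsi_patch` objects of the same level and size.
#' @param config A [reg_config()].
#' @return One-row OffsetSample tibble (columns `level`, `origin_x`,
#'   `origin_y`, `dx`, `dy`, `dx_int`, `dy_int`, `theta`, `score`,
#'   `success`).
#' @export
register_patch_pair <- function(fixed, floating, config = reg_config()) {
  stopifnot(inherits(fixed, "wsi_patch"), inherits(floating, "wsi_patch"))
  if (fixed$level != floating$level || !all(fixed$size == floating$size)) {
    abort("register_patch_pair: patches must share level and size")
  }
  g1 <- to_grayscale(fixed)
  g2 <- to_grayscale(floating)
  theta <- 0; rot_score <- 1
  if (config$rotation) {
    rot <- estimate_rotation(g1, g2, max_angle = config$max_rotation)
    theta <- rot$theta; rot_score <- rot$score
    if (theta != 0) g2 <- rotate_bilinear(g2, -theta)
  }
  pc <- phase_correlate(g1, g2, score_floor = config$score_floor)
  pc$level <- fixed$level
  pc$origin_x <- unname(fixed$origin_l0[1])
  pc$origin_y <- unname(fixed$origin_l0[2])
  pc$theta <- theta
  pc
}

#' Parallelism filter for matched keypoint pairs
#'
#' Keypoint matchers on re-stained pairs produce spurious matches; under a
#' rigid shift all true match lines drawn between the fixed image and a
#' floating image placed to its right must be parallel. The filter computes
#' each pair's line angle, finds the modal angle with a 1-D Gaussian KDE
#' (Scott's-rule bandwidth), and keeps pairs within `tolerance` degrees of
#' the mode.
#'
#' @param matches Data frame with columns `fixed_x`, `fixed_y`, `float_x`,
#'   `float_y` (one matched pair per row; any extra columns are preserved).
#' @param tolerance Angular tolerance, degrees.
#' @param frame_offset Horizontal offset (pixels) applied to the floating
#'   frame for angle computation; defaults to the fixed-point x-range.
#' @return The kept rows, as a tibble.
#' @export
filter_matches_by_slope <- function(matches, tolerance = 5,
                                    frame_offset = NULL) {
  matches <- as_tibble(matches)
  if (nrow(matches) == 0) return(matches)
  if (is.null(frame_offset)) {
    frame_offset <- max(matches$fixed_x) - min(matches$fixed_x) + 1
  }
  ang <- atan2(matches$float_y - matches$fixed_y,
               matches$float_x + frame_offset - matches$fixed_x) * 180 / pi
  if (nrow(matches) == 1) return(matches)
  # wrap-aware mode of the angle distribution
  ang3 <- c(ang - 360, ang, ang + 360)
  bw <- max(scott_bandwidth(length(ang), 1) * stats::sd(ang3), 1e-6)
  grid <- seq(-180, 180, by = 0.1)
  dens <- vapply(grid, function(g) sum(stats::dnorm(g, ang3, bw)), numeric(1))
  mode_ang <- grid[which.max(dens)]
  dev <- abs(((ang - mode_ang + 180) %% 360) - 180)
  matches[dev <= tolerance, , drop = FALSE]
}
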