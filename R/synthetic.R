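#' Specification for a synthetic re-stained WSI pair
#'
#' Describes one simulated tissue section scanned twice: once with dense
#' dual-colour H&E-like staining (the fixed image) and once with sparse
#' IHC-like staining (the floating image), related by a known global
#' translation and optional small rotation. Both renditions share one cell
#' field — nuclei sit at identical tissue positions, as they do on a
#' re-stained slide — while hue, contrast and local detail differ.
#'
#' @param level0_size `(W, H)` level-0 size in pixels (rounded up to a
#'   multiple of the largest downsample).
#' @param downsamples Per-level downsample factors, starting at 1, strictly
#'   increasing. Default `c(1, 4, 16, 32)`, a four-level clinical scanner
#'   layout.
#' @param true_dx0,true_dy0 Ground-truth level-0 translation of the floating
#'   image (pixels; floating content appears at fixed position + shift).
#' @param true_theta Ground-truth rotation, degrees, about the image centre.
#' @param cell_density Nuclei per 1e4 px^2 of tissue.
#' @param ihc_positive_fraction Fraction of nuclei rendered DAB-positive in
#'   the floating image.
#' @param tissue_fraction Fraction of the field covered by tissue.
#' @param blank_region_fraction Fraction of tissue rendered texture-poor
#'   (uniform colour, no nuclei) to provoke patch-registration failures.
#' @param noise_sigma Additive Gaussian noise, 8-bit intensity units.
#' @param seed Integer seed; fully determines the pair.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(level0_size = c(2048, 2048),
                           downsamples = c(1, 4, 16, 32),
                           true_dx0 = 0, true_dy0 = 0, true_theta = 0,
                           cell_density = 2, ihc_positive_fraction = 0.2,
                           tissue_fraction = 0.65,
                           blank_region_fraction = 0.2,
                           noise_sigma = 5, seed = 1L) {
  if (downsamples[1] != 1 || any(diff(downsamples) <= 0)) {
    abort("downsamples must start at 1 and strictly increase")
  }
  fr <- c(ihc_positive_fraction, tissue_fraction, blank_region_fraction)
  if (any(fr < 0 | fr > 1)) abort("fractions must lie in [0, 1]")
  if (noise_sigma < 0 || cell_density < 0) {
    abort("noise_sigma and cell_density must be nonnegative")
  }
  f <- max(downsamples)
  level0_size <- as.integer(ceiling(level0_size / f) * f)
  structure(list(level0_size = level0_size,
                 downsamples = as.numeric(downsamples),
                 true_dx0 = true_dx0, true_dy0 = true_dy0,
                 true_theta = true_theta, cell_density = cell_density,
                 ihc_positive_fraction = ihc_positive_fraction,
                 tissue_fraction = tissue_fraction,
                 blank_region_fraction = blank_region_fraction,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# ---- continuous shared cell field -----------------------------------------

# value-noise layer: coarse i.i.d. N(0,1) grid, bilinearly interpolated at
# arbitrary (possibly transformed) coordinates -> an exactly shiftable field
noise_layer <- function(W, H, cell) {
  nr <- ceiling(H / cell) + 3
  nc <- ceiling(W / cell) + 3
  list(G = matrix(stats::rnorm(nr * nc), nr, nc), cell = cell)
}

layer_eval <- function(layer, x, y) {
  bilinear_lookup(layer$G, y / layer$cell + 2, x / layer$cell + 2)
}

build_cell_field <- function(spec) {
  W <- spec$level0_size[1]; H <- spec$level0_size[2]
  s <- min(W, H)
  tissue_l <- list(noise_layer(W, H, s / 8), noise_layer(W, H, s / 32))
  # blank (texture-poor) regions are rendered at a physical scale large
  # enough to engulf whole registration patches
  bs <- max(s / 8, 256)
  blank_l <- list(noise_layer(W, H, bs), noise_layer(W, H, bs / 4))
  tex_l <- list(noise_layer(W, H, 256), noise_layer(W, H, 64),
                noise_layer(W, H, 16))
  tex_w <- c(1, 0.6, 0.35)
  eval_raw <- function(layers, wts, x, y) {
    v <- 0
    for (i in seq_along(layers)) v <- v + wts[i] * layer_eval(layers[[i]], x, y)
    v
  }
  # calibrate thresholds on a fixed-frame subsample
  gx <- seq(0, W - 1, length.out = 160); gy <- seq(0, H - 1, length.out = 160)
  sx <- rep(gx, times = 160); sy <- rep(gy, each = 160)
  tval <- eval_raw(tissue_l, c(1, 0.4), sx, sy)
  t_thr <- stats::quantile(tval, 1 - spec$tissue_fraction, names = FALSE)
  bval <- eval_raw(blank_l, c(1, 0.5), sx, sy)
  b_thr <- stats::quantile(bval, 1 - spec$blank_region_fraction, names = FALSE)
  if (spec$blank_region_fraction == 0) b_thr <- Inf
  if (spec$tissue_fraction == 1) t_thr <- -Inf

  field <- list(W = W, H = H,
                tissue_l = tissue_l, blank_l = blank_l, tex_l = tex_l,
                tex_w = tex_w, t_thr = t_thr, b_thr = b_thr)
  field$eval <- function(x, y) {
    list(tissue = eval_raw(tissue_l, c(1, 0.4), x, y) > t_thr,
         blank = eval_raw(blank_l, c(1, 0.5), x, y) > b_thr,
         tex = clamp01(0.5 + 0.22 * eval_raw(tex_l, tex_w, x, y) /
                         sqrt(sum(tex_w^2))))
  }

  # nuclei: elliptical, shared between stains, excluded from blank regions
  n_target <- round(spec$cell_density * W * H * spec$tissue_fraction / 1e4)
  nuc <- NULL
  if (n_target > 0) {
    cx <- stats::runif(4 * n_target, 0, W); cy <- stats::runif(4 * n_target, 0, H)
    fv <- field$eval(cx, cy)
    ok <- which(fv$tissue & !fv$blank)
    ok <- ok[seq_len(min(n_target, length(ok)))]
    nn <- length(ok)
    nuc <- tibble(x = cx[ok], y = cy[ok],
                  a = stats::runif(nn, 7, 13), b = stats::runif(nn, 6, 11),
                  phi = stats::runif(nn, 0, pi),
                  shade = stats::runif(nn, -0.06, 0.06),
                  positive = stats::runif(nn) < spec$ihc_positive_fraction)
  }
  field$nuclei <- nuc
  field
}

# ---- rendering ------------------------------------------------------------

stain_palette <- function(stain) {
  if (stain == "he") {
    list(cyto = function(t) list(r = 0.96 - 0.14 * t, g = 0.78 - 0.22 * t,
                                 b = 0.87 - 0.12 * t),
         blank = c(0.93, 0.84, 0.89),
         nucleus = function(pos) c(0.36, 0.21, 0.55))
  } else {
    list(cyto = function(t) list(r = 0.92 - 0.07 * t, g = 0.91 - 0.07 * t,
                                 b = 0.95 - 0.05 * t),
         blank = c(0.92, 0.92, 0.95),
         nucleus = function(pos) if (pos) c(0.47, 0.29, 0.12)
                                 else c(0.76, 0.75, 0.87))
  }
}

# render one full level-0 image (list of 3 channel matrices in [0,1]).
# `fwd` is the forward rigid map applied to the floating field; rendering
# evaluates the continuous field at inverse-mapped output coordinates, so
# subpixel ground truths are exact (no raster resampling).
render_stain <- function(field, spec, stain, transform = NULL,
                         block_rows = 256) {
  W <- field$W; H <- field$H
  pal <- stain_palette(stain)
  inv <- if (is.null(transform)) {
    function(x, y) list(x = x, y = y, valid = TRUE)
  } else {
    th <- transform$theta * pi / 180
    ctr_x <- (W - 1) / 2; ctr_y <- (H - 1) / 2
    function(x, y) {
      ux <- x - transform$dx - ctr_x
      uy <- y - transform$dy - ctr_y
      sx <- cos(th) * ux + sin(th) * uy + ctr_x
      sy <- -sin(th) * ux + cos(th) * uy + ctr_y
      list(x = sx, y = sy, valid = sx >= 0 & sx < W & sy >= 0 & sy < H)
    }
  }
  ch <- array(1, c(H, W, 3))    # filled in place; page 0 of the pyramid
  xs <- 0:(W - 1)
  for (r0 in seq(0, H - 1, by = block_rows)) {
    r1 <- min(r0 + block_rows, H)
    nb <- r1 - r0
    px <- rep(xs, each = nb)
    py <- rep(r0:(r1 - 1), times = W)
    src <- inv(px, py)
    fv <- field$eval(src$x, src$y)
    live <- fv$tissue & src$valid
    flat <- live & fv$blank
    texd <- live & !fv$blank
    cy <- pal$cyto(fv$tex)
    r <- rep(1, nb * W); g <- rep(1, nb * W); b <- rep(1, nb * W)
    r[texd] <- cy$r[texd]; g[texd] <- cy$g[texd]; b[texd] <- cy$b[texd]
    r[flat] <- pal$blank[1]; g[flat] <- pal$blank[2]; b[flat] <- pal$blank[3]
    rows <- (r0 + 1):r1
    ch[rows, , 1] <- matrix(r, nb, W)
    ch[rows, , 2] <- matrix(g, nb, W)
    ch[rows, , 3] <- matrix(b, nb, W)
    rm(px, py, src, fv, live, flat, texd, cy, r, g, b)
    gc(verbose = FALSE)      # the block temporaries dominate the footprint
  }
  # paint nuclei in the output frame (centres forward-mapped for floating)
  nuc <- field$nuclei
  if (!is.null(nuc) && nrow(nuc) > 0) {
    if (!is.null(transform)) {
      th <- transform$theta * pi / 180
      ctr_x <- (W - 1) / 2; ctr_y <- (H - 1) / 2
      nx <- cos(th) * (nuc$x - ctr_x) - sin(th) * (nuc$y - ctr_y) + ctr_x +
        transform$dx
      ny <- sin(th) * (nuc$x - ctr_x) + cos(th) * (nuc$y - ctr_y) + ctr_y +
        transform$dy
      nphi <- nuc$phi + th
    } else {
      nx <- nuc$x; ny <- nuc$y; nphi <- nuc$phi
    }
    for (i in seq_len(nrow(nuc))) {
      rad <- max(nuc$a[i], nuc$b[i]) + 2
      c0 <- max(floor(nx[i] - rad), 0); c1 <- min(ceiling(nx[i] + rad), W - 1)
      rr0 <- max(floor(ny[i] - rad), 0); rr1 <- min(ceiling(ny[i] + rad), H - 1)
      if (c1 < c0 || rr1 < rr0) next
      wx <- c0:c1; wy <- rr0:rr1
      dxm <- outer(rep(1, length(wy)), wx - nx[i])
      dym <- outer(wy - ny[i], rep(1, length(wx)))
      u <- cos(nphi[i]) * dxm + sin(nphi[i]) * dym
      v <- -sin(nphi[i]) * dxm + cos(nphi[i]) * dym
      s <- sqrt((u / nuc$a[i])^2 + (v / nuc$b[i])^2)
      cov <- clamp01((1.075 - s) / 0.15) * 0.92
      if (all(cov == 0)) next
      col <- clamp01(pal$nucleus(nuc$positive[i]) + nuc$shade[i])
      ri <- rr0:rr1 + 1; ci <- c0:c1 + 1
      for (k in 1:3) {
        ch[ri, ci, k] <- ch[ri, ci, k] * (1 - cov) + col[k] * cov
      }
    }
  }
  if (spec$noise_sigma > 0) {
    for (k in 1:3) {                    # blockwise to bound the temporaries
      for (r0 in seq(1, H, by = block_rows)) {
        r1 <- min(r0 + block_rows - 1, H)
        ch[r0:r1, , k] <- clamp01(
          ch[r0:r1, , k] +
            matrix(stats::rnorm((r1 - r0 + 1) * W, 0, spec$noise_sigma / 255),
                   r1 - r0 + 1, W))
      }
      gc(verbose = FALSE)
    }
  }
  ch
}

# block-average the level-0 plane into the full pyramid page list; the
# level-0 page reuses `ch` itself (no gigapixel copy)
channels_to_pages <- function(ch, downsamples) {
  H <- dim(ch)[1]; W <- dim(ch)[2]
  pages <- vector("list", length(downsamples))
  for (li in seq_along(downsamples)) {
    f <- downsamples[li]
    if (f == 1) { pages[[li]] <- ch; next }
    a <- array(0, c(H / f, W / f, 3))
    for (k in 1:3) {
      a[, , k] <- block_mean(ch[, , k], f)
      gc(verbose = FALSE)
    }
    pages[[li]] <- a
  }
  pages
}

#' Generate a synthetic re-stained WSI pair with known ground truth
#'
#' Renders one shared cell field twice — H&E-like (fixed) and IHC-like
#' (floating) — applies the ground-truth rigid transform to the floating
#' rendition in the continuous field (before any rasterization, so subpixel
#' truths are meaningful), injects texture-poor blank regions and additive
#' Gaussian noise, builds each pyramid by block averaging, and writes
#' multi-page TIFFs plus a truth JSON. Identical `spec` (including seed)
#' always produces byte-identical outputs.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Writable output directory (created if absent).
#' @return Named list with `fixed`, `floating`, `truth` file paths
#'   (invisibly also the spec used).
#' @export
generate_pair <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  W <- spec$level0_size[1]; H <- spec$level0_size[2]
  if (abs(spec$true_dx0) > W / 4 || abs(spec$true_dy0) > H / 4) {
    abort("ground-truth shift exceeds 1/4 of the level-0 size")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fixed_path <- file.path(out_dir, "fixed_he.tiff")
  float_path <- file.path(out_dir, "floating_ihc.tiff")
  truth_path <- file.path(out_dir, "truth.json")
  withr::with_seed(spec$seed, {
    field <- build_cell_field(spec)
    ch <- render_stain(field, spec, "he", transform = NULL)
    pages <- channels_to_pages(ch, spec$downsamples)
    rm(ch); gc(verbose = FALSE)
    write_pyramid_tiff(pages, fixed_path)
    rm(pages); gc(verbose = FALSE)
    ch <- render_stain(field, spec, "ihc",
                       transform = list(dx = spec$true_dx0,
                                        dy = spec$true_dy0,
                                        theta = spec$true_theta))
    pages <- channels_to_pages(ch, spec$downsamples)
    rm(ch); gc(verbose = FALSE)
    write_pyramid_tiff(pages, float_path)
    rm(pages); gc(verbose = FALSE)
  })
  jsonlite::write_json(list(dx0 = spec$true_dx0, dy0 = spec$true_dy0,
                            theta_deg = spec$true_theta, seed = spec$seed,
                            level0_size = spec$level0_size,
                            downsamples = spec$downsamples),
                       truth_path, auto_unbox = TRUE, digits = NA)
  invisible(list(fixed = fixed_path, floating = float_path,
                 truth = truth_path, spec = spec))
}

#' Generate a cohort of synthetic pairs over a difficulty grid
#'
#' Emulates a benchmarking cohort: `n_pairs` pairs whose shift, cell
#' density, positive fraction and blank fraction vary over a seeded grid
#' (or over the rows of `difficulty_grid`). Writes one subdirectory per
#' pair plus a manifest CSV consumable by [cmd_evaluate()].
#'
#' @param base_spec A [synthetic_spec()] providing the defaults.
#' @param n_pairs Number of pairs.
#' @param out_dir Output directory.
#' @param difficulty_grid Optional data frame of spec-field overrides, one
#'   row per pair (recycled).
#' @return The manifest tibble (also written to `manifest.csv`).
#' @export
generate_cohort <- function(base_spec, n_pairs = 30, out_dir,
                            difficulty_grid = NULL) {
  stopifnot(inherits(base_spec, "synthetic_spec"), n_pairs >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  W <- base_spec$level0_size[1]; H <- base_spec$level0_size[2]
  if (is.null(difficulty_grid)) {
    difficulty_grid <- withr::with_seed(sub_seed(base_spec$seed, 999), tibble(
      true_dx0 = round(stats::runif(n_pairs, -W / 8, W / 8), 1),
      true_dy0 = round(stats::runif(n_pairs, -H / 8, H / 8), 1),
      cell_density = base_spec$cell_density * stats::runif(n_pairs, 0.5, 1.5),
      ihc_positive_fraction = stats::runif(n_pairs, 0.1, 0.4),
      blank_region_fraction = stats::runif(n_pairs, 0.05, 0.4)
    ))
  }
  rows <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    ov <- as.list(difficulty_grid[((i - 1) %% nrow(difficulty_grid)) + 1, ])
    sp <- base_spec
    for (nm in names(ov)) sp[[nm]] <- ov[[nm]]
    sp$seed <- sub_seed(base_spec$seed, i)
    sp <- do.call(synthetic_spec, sp[setdiff(names(sp), character(0))])
    pid <- sprintf("pair_%03d", i)
    paths <- generate_pair(sp, file.path(out_dir, pid))
    rows[[i]] <- tibble(pair_id = pid, fixed = paths$fixed,
                        floating = paths$floating, truth = paths$truth,
                        true_dx0 = sp$true_dx0, true_dy0 = sp$true_dy0,
                        true_theta = sp$true_theta,
                        cell_density = sp$cell_density,
                        ihc_positive_fraction = sp$ihc_positive_fraction,
                        blank_region_fraction = sp$blank_region_fraction,
                        seed = sp$seed)
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
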