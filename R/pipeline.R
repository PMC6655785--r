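#' Register a re-stained whole-slide image pair end to end
#'
#' The full pipeline: align thumbnails for a coarse initial offset, locate
#' tissue by brightness thresholding, sample patches from the
#' lowest-resolution levels, phase-correlate each fixed/floating patch pair
#' (the floating patch is read pre-shifted by the initial offset, so only a
#' small residual remains), weight the pooled offsets by KDE, and combine
#' them across levels by weighted regression through the origin into one
#' precise level-0 transform.
#'
#' @param fixed,floating `wsi_pyramid` objects or paths readable by
#'   [open_pyramid()]. `fixed` is the stationary image (e.g. H&E),
#'   `floating` the re-stained image to align to it (e.g. IHC).
#' @param config A [reg_config()].
#' @param verbose Print per-level success counts.
#' @return A `wsi_transform` (final level-0 `dx0`, `dy0`, `theta`, fitted
#'   slope, diagnostics) with the per-patch OffsetSample pool attached as
#'   `$samples` and the sample plan as attribute `"plan"`.
#' @export
register_slides <- function(fixed, floating, config = reg_config(),
                            verbose = FALSE) {
  if (is.character(fixed)) fixed <- open_pyramid(fixed)
  if (is.character(floating)) floating <- open_pyramid(floating)
  init <- initial_offset(fixed, floating, score_floor = config$score_floor)
  mask <- tissue_mask(get_thumbnail(fixed))
  plan <- sample_patch_locations(mask, fixed,
                                 patches_per_level = config$patches_per_level,
                                 levels = config$levels,
                                 patch_size = config$patch_size,
                                 seed = config$seed)
  samples <- register_planned_patches(fixed, floating, plan,
                                      initial = c(init$dx, init$dy),
                                      config = config)
  if (verbose) {
    ok <- dplyr::summarise(dplyr::group_by(samples, .data$level),
                           success = sum(.data$success), n = dplyr::n(),
                           .groups = "drop")
    for (i in seq_len(nrow(ok))) {
      message(sprintf("level %d: %d/%d patch registrations succeeded",
                      ok$level[i], ok$success[i], ok$n[i]))
    }
  }
  fit <- estimate_global_transform(samples, fixed$downsamples,
                                   initial = c(init$dx, init$dy),
                                   config = config)
  fit$initial_sample <- init
  attr(fit, "plan") <- plan
  fit
}

# run the per-patch registrations of a sample plan; returned offsets are
# level-local residuals relative to exactly `initial` (the thumbnail offset)
register_planned_patches <- function(fixed, floating, plan, initial = c(0, 0),
                                     config = reg_config()) {
  rows <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    lv <- plan$level[i]; ds <- plan$downsample[i]
    org <- c(plan$origin_x[i], plan$origin_y[i])
    size <- c(plan$patch_w[i], plan$patch_h[i])
    pf <- read_region(fixed, org, lv, size)
    # floating patch pre-shifted by the initial offset, snapped to the grid
    bl <- round((org + initial) / ds)
    pm <- read_region(floating, bl * ds, lv, size)
    s <- register_patch_pair(pf, pm, config)
    # fold the snapping residue back so dx, dy are relative to `initial`
    snap <- (bl * ds - org - initial) / ds
    s$dx <- s$dx + snap[1]
    s$dy <- s$dy + snap[2]
    rows[[i]] <- s
  }
  dplyr::bind_rows(rows)
}
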