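#' Build an in-memory whole-slide pyramid
#'
#' A `wsi_pyramid` is an ordered stack of RGB planes of strictly decreasing
#' resolution, the standard storage layout of whole-slide images (WSIs).
#' Level 0 is the full-resolution plane; level `k` is level 0 reduced by the
#' integer factor `downsamples[k + 1]`. All patch coordinates in the package
#' are expressed in the level-0 frame (the convention of the common WSI
#' reader libraries), 0-based, with `x` = column and `y` = row.
#'
#' @param levels List of numeric `H x W x 3` arrays with values in `[0, 1]`,
#'   ordered from level 0 (largest) to the lowest-resolution level.
#' @param downsamples Optional numeric vector of per-level downsample
#'   factors; derived from the plane widths when omitted.
#' @param pixel_size_um Micrometres per level-0 pixel (optional metadata).
#' @param source Optional provenance string (file path).
#' @return A `wsi_pyramid` object.
#' @export
new_pyramid <- function(levels, downsamples = NULL, pixel_size_um = NULL,
                        source = NULL) {
  if (length(levels) < 2) {
    abort("a pyramid needs at least 2 levels; got a single-level image")
  }
  levels <- lapply(levels, as_rgb_raw)
  dims <- vapply(levels, function(l) dim(l)[1:2], numeric(2))
  if (is.null(downsamples)) {
    downsamples <- round(dims[2, 1] / dims[2, ])
  }
  if (any(diff(downsamples) <= 0) || downsamples[1] != 1) {
    abort("downsample factors must start at 1 and strictly increase")
  }
  for (k in seq_along(levels)) {
    if (abs(dims[2, k] - dims[2, 1] / downsamples[k]) > 1 ||
        abs(dims[1, k] - dims[1, 1] / downsamples[k]) > 1) {
      abort(sprintf("level %d dimensions inconsistent with downsample %g",
                    k - 1, downsamples[k]))
    }
  }
  if (!is.null(pixel_size_um) && pixel_size_um <= 0) {
    abort("pixel_size_um must be > 0")
  }
  structure(
    list(levels = levels, downsamples = as.numeric(downsamples),
         pixel_size_um = pixel_size_um, source = source),
    class = "wsi_pyramid"
  )
}

# store planes as raw (8-bit) arrays to keep gigapixel levels affordable
as_rgb_raw <- function(x) {
  if (is.raw(x)) return(x)
  d <- dim(x)
  if (length(d) == 2) x <- array(rep(x, 3), c(d, 3))
  if (dim(x)[3] > 3) x <- x[, , 1:3, drop = FALSE]
  r <- as.raw(pmin(pmax(round(x * 255), 0), 255))
  dim(r) <- dim(x)
  r
}

raw_to_numeric <- function(x) {
  d <- dim(x)
  y <- as.integer(x) / 255
  dim(y) <- d
  y
}

#' Open a pyramidal (multi-page TIFF) whole-slide image
#'
#' Reads every page of a multi-page TIFF and assembles a [new_pyramid()].
#' Downsample factors are recovered from the page dimensions.
#'
#' @param path Path to a multi-page TIFF written by [generate_pair()] or any
#'   other producer of page-per-level pyramidal TIFFs.
#' @return A `wsi_pyramid`.
#' @export
open_pyramid <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cannot open pyramid: no such file '%s'", path))
  }
  # native (packed-integer) reads keep gigapixel level-0 planes affordable
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, native = TRUE),
                    error = function(e) {
                      abort(sprintf("failed to read '%s': %s", path,
                                    conditionMessage(e)))
                    })
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2) {
    abort(sprintf("'%s' has a single level; not a supported pyramid", path))
  }
  for (k in seq_along(pages)) pages[[k]] <- native_to_raw(pages[[k]])
  ord <- order(vapply(pages, function(p) -dim(p)[2], numeric(1)))
  new_pyramid(pages[ord], source = path)
}

# unpack a nativeRaster (row-major 0xAABBGGRR ints) into an H x W x 3 raw
# array without materializing a double-precision plane
native_to_raw <- function(p) {
  d <- dim(p)                     # c(H, W), data row-major
  iv <- as.integer(unclass(p))
  out <- array(as.raw(0), c(d[1], d[2], 3))
  for (k in 1:3) {
    m <- as.raw(bitwAnd(bitwShiftR(iv, 8L * (k - 1L)), 255L))
    dim(m) <- c(d[2], d[1])
    out[, , k] <- t(m)
    gc(verbose = FALSE)
  }
  out
}

#' Per-level metadata of a pyramid
#'
#' @param img A `wsi_pyramid`.
#' @return A tibble with one row per level: `level`, `width`, `height`,
#'   `downsample`.
#' @export
pyramid_levels <- function(img) {
  stopifnot(inherits(img, "wsi_pyramid"))
  dims <- vapply(img$levels, function(l) dim(l)[1:2], numeric(2))
  tibble(level = seq_along(img$levels) - 1L,
         width = dims[2, ], height = dims[1, ],
         downsample = img$downsamples)
}

#' @export
print.wsi_pyramid <- function(x, ...) {
  cat("<wsi_pyramid>", if (!is.null(x$source)) x$source else "(in memory)", "\n")
  print(pyramid_levels(x))
  invisible(x)
}

#' Read a rectangular patch from a pyramid level
#'
#' The patch origin is given in level-0 pixels (floored to the level grid);
#' the patch size is in level-local pixels. Rectangles are half-open. Reads
#' extending past the slide are padded with white (blank glass) and flagged
#' rather than raising, so random sampling near tissue edges cannot crash a
#' run.
#'
#' @param img A `wsi_pyramid`.
#' @param origin_l0 Numeric `(x, y)` top-left corner, level-0 pixels, 0-based.
#' @param level Pyramid level index (0 = full resolution).
#' @param size Integer `(w, h)` patch size in level-local pixels.
#' @return A `wsi_patch`: list with `pixels` (`h x w x 3` numeric in
#'   `[0, 1]`), `level`, `downsample`, `origin_l0`, `size`, `padded`.
#' @export
read_region <- function(img, origin_l0, level, size) {
  stopifnot(inherits(img, "wsi_pyramid"))
  if (level < 0 || level >= length(img$levels)) {
    abort(sprintf("level %s out of range [0, %d]", level,
                  length(img$levels) - 1L))
  }
  if (any(size <= 0)) abort("patch size must be positive")
  ds <- img$downsamples[level + 1]
  plane <- img$levels[[level + 1]]
  H <- dim(plane)[1]; W <- dim(plane)[2]
  x0 <- floor(origin_l0[1] / ds); y0 <- floor(origin_l0[2] / ds)
  w <- as.integer(size[1]); h <- as.integer(size[2])
  px <- array(1, c(h, w, 3))                       # white background
  rs <- max(y0, 0); re <- min(y0 + h, H)           # source rows [rs, re)
  cs <- max(x0, 0); ce <- min(x0 + w, W)
  padded <- !(rs == y0 && re == y0 + h && cs == x0 && ce == x0 + w)
  if (re > rs && ce > cs) {
    block <- raw_to_numeric(plane[(rs + 1):re, (cs + 1):ce, , drop = FALSE])
    px[(rs - y0 + 1):(re - y0), (cs - x0 + 1):(ce - x0), ] <- block
  } else {
    padded <- TRUE
  }
  structure(list(pixels = px, level = as.integer(level), downsample = ds,
                 origin_l0 = c(x = origin_l0[1], y = origin_l0[2]),
                 size = c(w = w, h = h), padded = padded),
            class = "wsi_patch")
}

#' Whole-image thumbnail (lowest-resolution level)
#'
#' @param img A `wsi_pyramid`.
#' @return A `wsi_patch` spanning the full highest-index level.
#' @export
get_thumbnail <- function(img) {
  stopifnot(inherits(img, "wsi_pyramid"))
  k <- length(img$levels) - 1L
  d <- dim(img$levels[[k + 1]])
  read_region(img, c(0, 0), k, c(d[2], d[1]))
}

#' Write a pyramid to a multi-page TIFF
#'
#' One 8-bit RGB page per level, largest first.
#'
#' @param img A `wsi_pyramid`, or a list of numeric `H x W x 3` arrays.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pyramid_tiff <- function(img, path) {
  planes <- if (inherits(img, "wsi_pyramid")) {
    lapply(img$levels, raw_to_numeric)
  } else {
    img
  }
  tiff::writeTIFF(planes, path, bits.per.sample = 8, compression = "LZW")
  invisible(path)
}
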