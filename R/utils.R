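#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn
#' @import tibble
NULL

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# periodic Hann window of length n (suitable as an FFT taper)
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
}

# mean over f x f blocks; dims of M must be multiples of f
block_mean <- function(M, f) {
  if (f == 1) return(M)
  h <- nrow(M); w <- ncol(M)
  stopifnot(h %% f == 0, w %% f == 0)
  M1 <- colMeans(array(M, c(f, h %/% f, w)), dims = 1)     # (h/f) x w
  M2 <- colMeans(array(t(M1), c(f, w %/% f, h %/% f)), dims = 1)
  t(M2)
}

# bilinear lookup in matrix G at fractional 1-based (row, col) positions,
# clamped to the grid
bilinear_lookup <- function(G, ri, ci) {
  h <- nrow(G); w <- ncol(G)
  ri <- as.numeric(ri); ci <- as.numeric(ci)
  ri[ri < 1] <- 1; ri[ri > h] <- h
  ci[ci < 1] <- 1; ci[ci > w] <- w
  r0 <- floor(ri); r0[r0 > h - 1] <- h - 1
  c0 <- floor(ci); c0[c0 > w - 1] <- w - 1
  fr <- ri - r0; fc <- ci - c0
  i00 <- r0 + (c0 - 1) * h              # linear indices of the 2x2 stencil
  g00 <- G[i00];     g01 <- G[i00 + h]
  g10 <- G[i00 + 1]; g11 <- G[i00 + h + 1]
  (1 - fr) * ((1 - fc) * g00 + fc * g01) + fr * ((1 - fc) * g10 + fc * g11)
}

# rotate a matrix by theta degrees (counter-clockwise in standard x-right,
# y-down image coordinates this is a clockwise visual rotation; the package
# only ever pairs this with its own estimator, which uses the same convention)
# about the patch centre, bilinear resampling, constant background fill
rotate_bilinear <- function(M, theta_deg, bg = mean(M)) {
  if (theta_deg == 0) return(M)
  h <- nrow(M); w <- ncol(M)
  th <- theta_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  # inverse map: output (r, c) -> input coords rotated by -theta
  cc <- matrix(rep(seq_len(w), each = h), h, w) - cx
  rr <- matrix(rep(seq_len(h), times = w), h, w) - cy
  ci <- cos(th) * cc + sin(th) * rr + cx
  ri <- -sin(th) * cc + cos(th) * rr + cy
  out <- bilinear_lookup(M, ri, ci)
  outside <- ri < 1 | ri > h | ci < 1 | ci > w
  out[outside] <- bg
  matrix(out, h, w)
}

# circular shift helper (test oracle counterpart lives in the test helpers)
roll_matrix <- function(M, dy, dx) {
  h <- nrow(M); w <- ncol(M)
  # content moves by (+dy, +dx): out[r, c] = M[r - dy, c - dx]
  M[((seq_len(h) - 1 - dy) %% h) + 1, ((seq_len(w) - 1 - dx) %% w) + 1]
}

# derive a deterministic 32-bit sub-seed from a base seed and a stream index
sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 1103515245 * (stream + 1)) %% 2147483647)
}
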