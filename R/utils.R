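# Internal numeric and RNG helpers shared across the package.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so library calls never perturb user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a parent seed and a stage label, keeping the result
# inside the 32-bit integer range. Distinct labels give independent streams.
derive_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.double(seed) * 7919 + h) %% 2147483647L)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

# Row-wise softmax of a matrix, numerically stabilized.
softmax_rows <- function(x) {
  n <- nrow(x)
  m <- x[cbind(seq_len(n), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  e / .rowSums(e, n, ncol(x))
}

# Truncated-normal draws (resample beyond 2 sd), used for parameter init.
rtruncnorm02 <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Exact separable bilinear resampling of a matrix to out_h x out_w.
# Output pixel centers are mapped to input coordinates by
#   y = (i - 0.5) * H / out_h + 0.5
# (pixel-center alignment); samples outside the grid clamp to the border.
bilinear_resize <- function(mat, out_h, out_w) {
  h <- nrow(mat); w <- ncol(mat)
  yy <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
  xx <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
  y0 <- pmin(pmax(floor(yy), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(xx), 1), w); x1 <- pmin(x0 + 1, w)
  fy <- pmin(pmax(yy - y0, 0), 1)
  fx <- pmin(pmax(xx - x0, 0), 1)
  top <- mat[y0, x0, drop = FALSE] * (1 - fx)[col(matrix(0, out_h, out_w))] +
    mat[y0, x1, drop = FALSE] * fx[col(matrix(0, out_h, out_w))]
  bot <- mat[y1, x0, drop = FALSE] * (1 - fx)[col(matrix(0, out_h, out_w))] +
    mat[y1, x1, drop = FALSE] * fx[col(matrix(0, out_h, out_w))]
  top * (1 - fy) + bot * fy
}

# Sample `mat` at fractional (row, col) coordinates with bilinear weights;
# coordinates outside the grid return `fill`. ys/xs are equal-length vectors.
bilinear_sample <- function(mat, ys, xs, fill = 0) {
  h <- nrow(mat); w <- ncol(mat)
  out <- rep(fill, length(ys))
  inside <- ys >= 1 & ys <= h & xs >= 1 & xs <= w
  if (!any(inside)) return(out)
  y <- ys[inside]; x <- xs[inside]
  y0 <- pmin(floor(y), h - 1L); x0 <- pmin(floor(x), w - 1L)
  y0 <- pmax(y0, 1L); x0 <- pmax(x0, 1L)
  fy <- y - y0; fx <- x - x0
  i00 <- cbind(y0, x0); i01 <- cbind(y0, x0 + 1)
  i10 <- cbind(y0 + 1, x0); i11 <- cbind(y0 + 1, x0 + 1)
  v <- mat[i00] * (1 - fy) * (1 - fx) + mat[i01] * (1 - fy) * fx +
    mat[i10] * fy * (1 - fx) + mat[i11] * fy * fx
  out[inside] <- v
  out
}

# Precompute the bilinear gather (indices + weights) for a rotation
# (degrees, about the frame center) combined with a zoom, on an h x w grid.
# Out-of-bounds samples get weight 0 (i.e. fill with 0).
warp_plan <- function(h, w, angle_deg, zoom) {
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  th <- angle_deg * pi / 180
  dy <- rep(seq_len(h), times = w) - cy
  dx <- rep(seq_len(w), each = h) - cx
  # inverse map: output -> input
  sy <- (cos(th) * dy - sin(th) * dx) / zoom + cy
  sx <- (sin(th) * dy + cos(th) * dx) / zoom + cx
  inside <- sy >= 1 & sy <= h & sx >= 1 & sx <= w
  y0 <- pmax(pmin(floor(sy), h - 1L), 1L)
  x0 <- pmax(pmin(floor(sx), w - 1L), 1L)
  fy <- sy - y0; fx <- sx - x0
  ins <- as.numeric(inside)
  list(i00 = (x0 - 1L) * h + y0, i10 = (x0 - 1L) * h + y0 + 1L,
       i01 = x0 * h + y0, i11 = x0 * h + y0 + 1L,
       w00 = (1 - fy) * (1 - fx) * ins, w10 = fy * (1 - fx) * ins,
       w01 = (1 - fy) * fx * ins, w11 = fy * fx * ins)
}

# Rotate and scale one frame in one bilinear resample; the output grid is
# the input grid, out-of-bounds pixels are 0.
warp_rotate_zoom <- function(mat, angle_deg = 0, zoom = 1) {
  if (angle_deg == 0 && zoom == 1) return(mat)
  p <- warp_plan(nrow(mat), ncol(mat), angle_deg, zoom)
  v <- as.vector(mat)
  matrix(v[p$i00] * p$w00 + v[p$i10] * p$w10 + v[p$i01] * p$w01 + v[p$i11] * p$w11,
         nrow(mat), ncol(mat))
}

# Same warp applied to every frame of a T x H x W clip, with the gather plan
# computed once.
warp_clip <- function(frames, angle_deg, zoom) {
  d <- dim(frames)
  p <- warp_plan(d[2], d[3], angle_deg, zoom)
  fm <- matrix(frames, d[1], d[2] * d[3])
  out <- fm[, p$i00, drop = FALSE] * rep(p$w00, each = d[1]) +
    fm[, p$i10, drop = FALSE] * rep(p$w10, each = d[1]) +
    fm[, p$i01, drop = FALSE] * rep(p$w01, each = d[1]) +
    fm[, p$i11, drop = FALSE] * rep(p$w11, each = d[1])
  array(out, d)
}

# 2-D convolution of a matrix with a small odd-sized kernel, zero padding.
conv2 <- function(mat, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  h <- nrow(mat); w <- ncol(mat)
  padded <- matrix(0, h + 2 * ph, w + 2 * pw)
  padded[(ph + 1):(ph + h), (pw + 1):(pw + w)] <- mat
  out <- matrix(0, h, w)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      k <- kernel[i, j]
      if (k != 0) out <- out + k * padded[i:(i + h - 1), j:(j + w - 1)]
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
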