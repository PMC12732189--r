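#' Preprocessing configuration
#'
#' Parameters of the automated fluoroscopy cleaning pipeline. All values are
#' fixed once (at fit time for `target_hw`, which is the median corpus
#' resolution) and applied identically to training and test clips.
#'
#' @param target_hw target spatial size `(H, W)` after resolution
#'   unification; `NULL` until fitted with [fit_preprocess()].
#' @param prewitt_search_frac fraction of rows scanned at the top and bottom
#'   of the frame for the information-band crop.
#' @param prewitt_floor minimum mean absolute horizontal-Prewitt row response
#'   (normalized intensity units) for a crop to be applied.
#' @param hough_radius_frac radius search range for the targeting artifact,
#'   as a fraction of `min(H, W)`.
#' @param hough_search_frames number of leading frames searched for the
#'   artifact (it appears only early in a recording).
#' @param inpaint_dilation dilation (pixels) of the detected disk before
#'   inpainting.
#' @param bilateral_d,bilateral_sigma_i,bilateral_sigma_s bilateral filter
#'   window diameter (pixels), intensity sigma (fraction of the intensity
#'   range) and spatial sigma (pixels).
#' @param clahe_clip,clahe_tiles CLAHE clip limit and tile grid side.
#' @param fov_margin margin (pixels) subtracted from the inscribed
#'   field-of-view radius.
#' @param min_rows smallest number of rows an information-band crop may leave.
#' @export
preprocess_config <- function(target_hw = NULL, prewitt_search_frac = 0.2,
                              prewitt_floor = 0.1,
                              hough_radius_frac = c(0.05, 0.15),
                              hough_search_frames = 10L, inpaint_dilation = 2,
                              bilateral_d = 5L, bilateral_sigma_i = 0.1,
                              bilateral_sigma_s = 3,
                              clahe_clip = 2, clahe_tiles = 8L,
                              fov_margin = 0, min_rows = 16L) {
  stopifnot(clahe_clip > 0, clahe_tiles >= 1, bilateral_d >= 1)
  if (!is.null(target_hw)) {
    target_hw <- rep(as.integer(target_hw), length.out = 2L)
    stopifnot(all(target_hw > 0))
  }
  structure(list(target_hw = target_hw,
                 prewitt_search_frac = prewitt_search_frac,
                 prewitt_floor = prewitt_floor,
                 hough_radius_frac = hough_radius_frac,
                 hough_search_frames = as.integer(hough_search_frames),
                 inpaint_dilation = inpaint_dilation,
                 bilateral_d = as.integer(bilateral_d),
                 bilateral_sigma_i = bilateral_sigma_i,
                 bilateral_sigma_s = bilateral_sigma_s,
                 clahe_clip = clahe_clip, clahe_tiles = as.integer(clahe_tiles),
                 fov_margin = fov_margin, min_rows = as.integer(min_rows)),
            class = "preprocess_config")
}

#' Fit the resolution target of a preprocessing configuration
#'
#' Records the median height and width over a collection of clips as the
#' unification target, which is then persisted and reused at inference rather
#' than recomputed per clip.
#'
#' @param stacks list of [frame_stack()]s (the training collection).
#' @param config a [preprocess_config()].
#' @return the config with `target_hw` set.
#' @export
fit_preprocess <- function(stacks, config = preprocess_config()) {
  hs <- vapply(stacks, function(s) dim(s$frames)[2], numeric(1))
  ws <- vapply(stacks, function(s) dim(s$frames)[3], numeric(1))
  config$target_hw <- c(as.integer(round(stats::median(hs))),
                        as.integer(round(stats::median(ws))))
  config
}

prewitt_h <- function() rbind(c(-1, -1, -1), c(0, 0, 0), c(1, 1, 1)) / 3

# Mean absolute horizontal-Prewitt response per row of a frame.
row_edge_response <- function(frame) {
  resp <- conv2(frame, prewitt_h())
  rowMeans(abs(resp))
}

#' Crop the patient-information band
#'
#' The static overlay band is located on the temporal-mean frame as the row of
#' maximal mean absolute horizontal-Prewitt response within the top (and
#' bottom) `prewitt_search_frac` of rows; if no response exceeds
#' `prewitt_floor`, no crop is applied on that side.
#'
#' @param stack single-channel [frame_stack()].
#' @param config a [preprocess_config()].
#' @return the cropped stack, with attribute `crop` = `c(top, bottom)` rows
#'   removed.
#' @export
crop_info_window <- function(stack, config = preprocess_config()) {
  fr <- stack$frames
  if (length(dim(fr)) != 3L) stop("crop_info_window expects a single-channel stack")
  h <- dim(fr)[2]
  mean_frame <- apply(fr, c(2, 3), mean)
  resp <- row_edge_response(mean_frame)
  band <- max(2L, floor(config$prewitt_search_frac * h))
  # top: rows 2..band (row 1 is a padding boundary)
  top_rows <- 2:band
  crop_top <- 0L
  if (max(resp[top_rows]) >= config$prewitt_floor) {
    crop_top <- top_rows[which.max(resp[top_rows])]
  }
  bot_rows <- (h - band + 1L):(h - 1L)
  crop_bottom <- 0L
  if (max(resp[bot_rows]) >= config$prewitt_floor) {
    crop_bottom <- h - bot_rows[which.max(resp[bot_rows])] + 1L
  }
  keep <- (crop_top + 1L):(h - crop_bottom)
  if (length(keep) < config$min_rows) {
    stop(sprintf("information-band crop would leave %d rows (< %d)",
                 length(keep), config$min_rows))
  }
  out <- set_frames(stack, fr[, keep, , drop = FALSE])
  attr(out, "crop") <- c(top = crop_top, bottom = crop_bottom)
  out
}

prewitt_gradients <- function(frame) {
  k <- prewitt_h()
  list(gy = conv2(frame, k), gx = conv2(frame, t(k)))
}

#' Detect a circular targeting artifact by Hough voting
#'
#' Gradient-direction circle Hough transform on the mean of the first
#' `n_frames` frames: strong-edge pixels vote for candidate centers along
#' their gradient direction at all radii in range; the radius is then
#' estimated from the distance histogram of edge pixels about the winning
#' center. Detection requires enough edge support on the fitted circle.
#'
#' @param frames `T x H x W` array.
#' @param radius_range numeric length-2, radii in pixels.
#' @param n_frames leading frames to average.
#' @return `NULL` if no circle is found, else a list with `cx`, `cy`, `r`
#'   (pixel coordinates, x = column, y = row) and `support` (edge inliers per
#'   unit perimeter).
#' @export
hough_circle <- function(frames, radius_range, n_frames = 10L) {
  t_use <- seq_len(min(n_frames, dim(frames)[1]))
  a <- apply(frames[t_use, , , drop = FALSE], c(2, 3), mean)
  h <- nrow(a); w <- ncol(a)
  g <- prewitt_gradients(a)
  mag <- sqrt(g$gx^2 + g$gy^2)
  # border gradients are zero-padding artifacts, not structure
  mag[c(1:2, h - 1:0), ] <- 0
  mag[, c(1:2, w - 1:0)] <- 0
  thr <- max(0.3 * max(mag), 0.08)
  idx <- which(mag > thr, arr.ind = TRUE)
  if (nrow(idx) < 8L) return(NULL)
  uy <- g$gy[idx] / mag[idx]
  ux <- g$gx[idx] / mag[idx]
  radii <- seq(floor(radius_range[1]), ceiling(radius_range[2]), by = 1)
  acc <- matrix(0L, h, w)
  for (r in radii) {
    for (s in c(-1, 1)) {
      cy <- round(idx[, 1] + s * r * uy)
      cx <- round(idx[, 2] + s * r * ux)
      ok <- cy >= 1 & cy <= h & cx >= 1 & cx <= w
      if (any(ok)) {
        tab <- cbind(cy[ok], cx[ok])
        acc[tab] <- acc[tab] + 1L
      }
    }
  }
  accs <- conv2(acc, matrix(1, 3, 3))
  peak <- which(accs == max(accs), arr.ind = TRUE)[1, , drop = TRUE]
  cy0 <- peak[1]; cx0 <- peak[2]
  d <- sqrt((idx[, 1] - cy0)^2 + (idx[, 2] - cx0)^2)
  in_range <- d >= radius_range[1] - 1.5 & d <= radius_range[2] + 1.5
  if (sum(in_range) < 8L) return(NULL)
  # the artifact is a thin ring: edge pixels sit on both walls, so center the
  # inlier window on the median distance, then refine by an algebraic
  # least-squares circle fit (two passes to shed outliers)
  r_med <- stats::median(d[in_range])
  sel <- in_range & abs(d - r_med) <= 2.5
  fit <- kasa_circle(idx[sel, 1], idx[sel, 2])
  if (is.null(fit)) return(NULL)
  for (pass in 1:2) {
    d2 <- sqrt((idx[, 1] - fit$cy)^2 + (idx[, 2] - fit$cx)^2)
    sel <- abs(d2 - fit$r) <= 2
    if (sum(sel) < 8L) return(NULL)
    fit <- kasa_circle(idx[sel, 1], idx[sel, 2])
    if (is.null(fit)) return(NULL)
  }
  resid <- sqrt((idx[sel, 1] - fit$cy)^2 + (idx[sel, 2] - fit$cx)^2) - fit$r
  support <- sum(sel) / (2 * pi * fit$r)
  # a genuine ring has inliers all around the circle; straight overlay edges
  # and smeared bolus blobs cover only a limited angular sector
  ang <- atan2(idx[sel, 1] - fit$cy, idx[sel, 2] - fit$cx)
  coverage <- length(unique(floor((ang + pi) / (2 * pi) * 24))) / 24
  # the artifact is an open ring: its wall is brighter than its interior,
  # whereas a filled blob (e.g. the bolus) is brightest inside
  dpix <- sqrt(dist2_field(h, w, fit$cx, fit$cy))
  on_ring <- abs(dpix - fit$r) <= 1.5
  interior <- dpix <= max(fit$r - 2.5, 1)
  ring_contrast <- if (any(interior)) mean(a[on_ring]) - mean(a[interior]) else Inf
  if (support < 0.6 || stats::sd(resid) > 1.5 || coverage < 0.7 ||
      ring_contrast < 0.05 ||
      fit$r < radius_range[1] - 1.5 || fit$r > radius_range[2] + 1.5) {
    return(NULL)
  }
  list(cx = fit$cx, cy = fit$cy, r = fit$r, support = support)
}

# Algebraic (Kasa) least-squares circle fit through points (ys, xs).
kasa_circle <- function(ys, xs) {
  A <- cbind(2 * xs, 2 * ys, 1)
  b <- xs^2 + ys^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  list(cx = sol[1], cy = sol[2], r = sqrt(r2))
}

disk_mask <- function(h, w, cx, cy, r) {
  dist2_field(h, w, cx, cy) <= r^2
}

# Harmonic (diffusion) fill of `frame` over logical `mask`.
inpaint_harmonic <- function(frame, mask, tol = 1e-5, max_iter = 500L) {
  if (!any(mask)) return(frame)
  h <- nrow(frame); w <- ncol(frame)
  boundary <- mask_dilate(mask, 1L) & !mask
  f <- frame
  f[mask] <- mean(frame[boundary])
  up <- function(m) rbind(m[-1, , drop = FALSE], m[h, , drop = FALSE])
  down <- function(m) rbind(m[1, , drop = FALSE], m[-h, , drop = FALSE])
  left <- function(m) cbind(m[, -1, drop = FALSE], m[, w, drop = FALSE])
  right <- function(m) cbind(m[, 1, drop = FALSE], m[, -w, drop = FALSE])
  for (i in seq_len(max_iter)) {
    avg <- (up(f) + down(f) + left(f) + right(f)) / 4
    delta <- max(abs(avg[mask] - f[mask]))
    f[mask] <- avg[mask]
    if (delta < tol) break
  }
  f
}

# Binary dilation by a disk of radius `r` (small radii).
mask_dilate <- function(mask, r) {
  if (r <= 0) return(mask)
  out <- mask
  h <- nrow(mask); w <- ncol(mask)
  for (dy in -ceiling(r):ceiling(r)) {
    for (dx in -ceiling(r):ceiling(r)) {
      if (dy == 0 && dx == 0) next
      if (dy^2 + dx^2 > r^2 + 1e-9) next
      ys <- pmin(pmax(seq_len(h) + dy, 1L), h)
      xs <- pmin(pmax(seq_len(w) + dx, 1L), w)
      out <- out | mask[ys, xs]
    }
  }
  out
}

#' Remove the early-frame targeting artifact
#'
#' A circle Hough transform over the first `hough_search_frames` frames
#' locates the artifact; if found, the detected disk (dilated by
#' `inpaint_dilation`) is harmonically inpainted in every frame where the
#' artifact's edge response persists. Absence of the artifact is not an
#' error: the stack is returned unchanged.
#'
#' @param stack single-channel [frame_stack()].
#' @param config a [preprocess_config()].
#' @return the stack, with attribute `artifact` describing the detection (or
#'   `NULL` if none).
#' @export
remove_targeting_artifact <- function(stack, config = preprocess_config()) {
  fr <- stack$frames
  d <- dim(fr)
  rr <- config$hough_radius_frac * min(d[2], d[3])
  det <- hough_circle(fr, rr, config$hough_search_frames)
  if (is.null(det)) {
    attr(stack, "artifact") <- NULL
    return(stack)
  }
  band <- abs(sqrt(dist2_field(d[2], d[3], det$cx, det$cy)) - det$r) <= 1.5
  edge_strength <- vapply(seq_len(d[1]), function(t) {
    g <- prewitt_gradients(fr[t, , ])
    mean(sqrt(g$gx^2 + g$gy^2)[band])
  }, numeric(1))
  floor_str <- 0.5 * edge_strength[1]
  inmask <- disk_mask(d[2], d[3], det$cx, det$cy, det$r + 1.5)
  inmask <- mask_dilate(inmask, config$inpaint_dilation)
  for (t in which(edge_strength > floor_str)) {
    fr[t, , ] <- inpaint_harmonic(fr[t, , ], inmask)
  }
  out <- set_frames(stack, fr)
  attr(out, "artifact") <- det
  out
}

#' Unify spatial resolution
#'
#' Frames smaller than the target are zero-padded symmetrically; larger
#' frames are center-cropped; mixed cases are handled per axis.
#'
#' @param stack single-channel [frame_stack()].
#' @param target_hw integer length-2 `(H, W)` (a scalar is recycled).
#' @return the resized stack with attribute `offset` = `c(dy, dx)`, the
#'   (possibly negative) row/column shift applied to pixel coordinates.
#' @export
unify_resolution <- function(stack, target_hw) {
  target_hw <- rep(as.integer(target_hw), length.out = 2L)
  fr <- stack$frames
  d <- dim(fr)
  out <- array(0, c(d[1], target_hw))
  place <- function(n_in, n_out) {
    if (n_in <= n_out) {
      off <- (n_out - n_in) %/% 2L
      list(src = seq_len(n_in), dst = off + seq_len(n_in), off = off)
    } else {
      off <- (n_in - n_out) %/% 2L
      list(src = off + seq_len(n_out), dst = seq_len(n_out), off = -off)
    }
  }
  py <- place(d[2], target_hw[1])
  px <- place(d[3], target_hw[2])
  out[, py$dst, px$dst] <- fr[, py$src, px$src]
  res <- set_frames(stack, out)
  attr(res, "offset") <- c(dy = py$off, dx = px$off)
  res
}

#' Circular field-of-view mask
#'
#' True inside the inscribed circle of the frame (minus `margin`), false at
#' the corners.
#'
#' @param h,w frame size in pixels.
#' @param margin pixels subtracted from the inscribed radius.
#' @return an `h x w` logical matrix.
#' @export
make_fov_mask <- function(h, w, margin = 0) {
  r <- min(h, w) / 2 - margin
  dist2_field(h, w, (w + 1) / 2, (h + 1) / 2) <= r^2
}

#' Zero all pixels outside the field of view
#'
#' @param stack single-channel [frame_stack()].
#' @param mask logical matrix matching the frame shape.
#' @export
apply_fov_mask <- function(stack, mask) {
  d <- dim(stack$frames)
  if (!all(dim(mask) == d[2:3])) {
    stop(sprintf("FOV mask shape (%d x %d) does not match frames (%d x %d)",
                 nrow(mask), ncol(mask), d[2], d[3]))
  }
  fr <- stack$frames
  flat <- matrix(fr, d[1], d[2] * d[3])
  flat[, !as.vector(mask)] <- 0
  set_frames(stack, array(flat, d))
}

# Bilateral filter of one frame (window diameter d, intensity sigma as a
# fraction of the [0,1] range, spatial sigma in pixels).
bilateral_frame <- function(f, d = 5L, sigma_i = 0.1, sigma_s = 3) {
  rad <- (d - 1L) %/% 2L
  h <- nrow(f); w <- ncol(f)
  num <- matrix(0, h, w); den <- matrix(0, h, w)
  for (dy in -rad:rad) {
    for (dx in -rad:rad) {
      ws <- exp(-(dy^2 + dx^2) / (2 * sigma_s^2))
      ys <- seq_len(h) + dy; xs <- seq_len(w) + dx
      vy <- ys >= 1 & ys <= h; vx <- xs >= 1 & xs <= w
      if (!any(vy) || !any(vx)) next
      sh <- matrix(0, h, w); valid <- matrix(FALSE, h, w)
      sh[vy, vx] <- f[ys[vy], xs[vx]]
      valid[vy, vx] <- TRUE
      wi <- exp(-(sh - f)^2 / (2 * sigma_i^2)) * ws * valid
      num <- num + wi * sh
      den <- den + wi
    }
  }
  num / den
}

clahe_frame <- function(f, tiles, clip) {
  img <- EBImage::Image(t(clamp01(f)))
  out <- EBImage::clahe(img, nx = tiles, ny = tiles, limit = clip)
  t(EBImage::imageData(out))
}

#' Denoise and equalize a masked stack
#'
#' Per frame: bilateral filter, CLAHE, re-application of the field-of-view
#' mask (CLAHE brightens flat zero regions, so masking must be repeated) and
#' clipping to `[0, 1]`.
#'
#' @param stack masked, resolution-unified [frame_stack()].
#' @param config a [preprocess_config()].
#' @param mask field-of-view mask from [make_fov_mask()].
#' @export
denoise_equalize <- function(stack, config, mask) {
  fr <- stack$frames
  d <- dim(fr)
  for (t in seq_len(d[1])) {
    f <- bilateral_frame(fr[t, , ], config$bilateral_d,
                         config$bilateral_sigma_i, config$bilateral_sigma_s)
    f <- clahe_frame(f, config$clahe_tiles, config$clahe_clip)
    f[!mask] <- 0
    fr[t, , ] <- clamp01(f)
  }
  set_frames(stack, fr)
}

#' Run the full preprocessing pipeline
#'
#' Composition, in order: information-band crop, targeting-artifact removal,
#' resolution unification to `config$target_hw`, field-of-view masking,
#' bilateral denoising + CLAHE + re-masking. The output stack is
#' `target_hw`-sized with intensities in `[0, 1]`, and carries a `geometry`
#' attribute sufficient to map any pixel mask from input to output
#' coordinates (see [transform_mask()]).
#'
#' @param stack eligible single-channel [frame_stack()].
#' @param config a fitted [preprocess_config()] (with `target_hw` set).
#' @export
run_pipeline <- function(stack, config) {
  if (is.null(config$target_hw)) {
    stop("preprocess config has no target_hw; call fit_preprocess() first")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("preprocessing stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  orig_hw <- dim(stack$frames)[2:3]
  s1 <- stage("crop_info_window", crop_info_window(stack, config))
  crop <- attr(s1, "crop")
  s2 <- stage("remove_targeting_artifact", remove_targeting_artifact(s1, config))
  s3 <- stage("unify_resolution", unify_resolution(s2, config$target_hw))
  offset <- attr(s3, "offset")
  mask <- make_fov_mask(config$target_hw[1], config$target_hw[2], config$fov_margin)
  s4 <- stage("apply_fov_mask", apply_fov_mask(s3, mask))
  s5 <- stage("denoise_equalize", denoise_equalize(s4, config, mask))
  attr(s5, "geometry") <- list(orig_hw = orig_hw, crop = crop, offset = offset,
                               target_hw = config$target_hw)
  attr(s5, "artifact") <- attr(s2, "artifact")
  attr(s5, "fov_mask") <- mask
  s5
}

#' Map a pixel mask through the pipeline geometry
#'
#' Applies the information-band crop and resolution-unification offsets
#' recorded by [run_pipeline()] to a binary mask defined in the original
#' frame coordinates, yielding the corresponding mask in pipeline-output
#' coordinates.
#'
#' @param mask logical matrix in original coordinates.
#' @param geometry the `geometry` attribute of a [run_pipeline()] result.
#' @export
transform_mask <- function(mask, geometry) {
  keep <- (geometry$crop[["top"]] + 1L):(nrow(mask) - geometry$crop[["bottom"]])
  m <- mask[keep, , drop = FALSE]
  out <- matrix(FALSE, geometry$target_hw[1], geometry$target_hw[2])
  place <- function(n_in, n_out) {
    if (n_in <= n_out) {
      off <- (n_out - n_in) %/% 2L
      list(src = seq_len(n_in), dst = off + seq_len(n_in))
    } else {
      off <- (n_in - n_out) %/% 2L
      list(src = off + seq_len(n_out), dst = seq_len(n_out))
    }
  }
  py <- place(nrow(m), geometry$target_hw[1])
  px <- place(ncol(m), geometry$target_hw[2])
  out[py$dst, px$dst] <- m[py$src, px$src]
  out
}
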