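#' Collect per-layer, per-head attention matrices
#'
#' One `(N+1) x (N+1)` row-stochastic matrix per (layer, head), taken from a
#' forward pass on the clip.
#'
#' @param params a `vit_params` (or a fitted `vfss_vit`).
#' @param grid a `token_grid`.
#' @return list of `L` layers, each a list of `h` attention matrices.
#' @export
collect_attention <- function(params, grid) {
  if (inherits(params, "vfss_vit")) params <- params$params
  fw <- vit_forward(params, grid, collect_attention = TRUE)
  for (l in seq_along(fw$attn)) {
    for (a in fw$attn[[l]]) {
      if (max(abs(rowSums(a) - 1)) > 1e-5) {
        stop("attention matrix rows do not sum to 1")
      }
    }
  }
  fw$attn
}

# Backward pass of the logit through the encoder that records, for every
# layer and head, the gradient of the logit with respect to the attention
# matrix (d logit / d A). Parameter gradients are not formed.
attention_gradients <- function(params, fwd) {
  cfg <- params$config
  cache <- fwd$cache
  hd <- cache$head
  if (cfg$head_type == "mlp") {
    da2 <- matrix(params$head$Wc[, 1], 1)
    dpre2 <- da2 * (hd$a2 > 0)
    da1 <- dpre2 %*% t(params$head$Wh2)
    dpre1 <- da1 * (hd$a1 > 0)
    dcls <- dpre1 %*% t(params$head$Wh1)
  } else {
    dcls <- matrix(params$head$Wc[, 1], 1)
  }
  dZf <- matrix(0, nrow(cache$Zfinal), cfg$D)
  dZf[1, ] <- dcls
  dZ <- layer_norm_backward(dZf, cache$lnf, params$ln_f_g)$dx
  Dh <- cfg$D %/% cfg$h
  grads <- vector("list", cfg$L)
  for (l in rev(seq_len(cfg$L))) {
    lc <- cache$layers[[l]]
    lp <- params$layers[[l]]
    dZ1 <- dZ
    dU <- (dZ %*% t(lp$W2)) * (lc$U > 0)
    dZ1 <- dZ1 + layer_norm_backward(dU %*% t(lp$W1), lc$ln2, lp$ln2_g)$dx
    att <- lc$att
    dHcat <- dZ1 %*% t(lp$Wo)
    dQ <- matrix(0, nrow(dZ1), cfg$D)
    dK <- matrix(0, nrow(dZ1), cfg$D)
    dV <- matrix(0, nrow(dZ1), cfg$D)
    layer_grads <- vector("list", cfg$h)
    for (i in seq_len(cfg$h)) {
      idx <- ((i - 1) * Dh + 1):(i * Dh)
      A <- t(att$attn_t[[i]])
      dHi <- dHcat[, idx, drop = FALSE]
      Vi <- att$V[, idx, drop = FALSE]
      dA <- tcrossprod(dHi, Vi)
      layer_grads[[i]] <- dA
      dV[, idx] <- crossprod(A, dHi)
      dS <- A * (dA - rowSums(dA * A))
      dQ[, idx] <- dS %*% att$K[, idx, drop = FALSE] / sqrt(Dh)
      dK[, idx] <- crossprod(dS, att$Q[, idx, drop = FALSE]) / sqrt(Dh)
    }
    dZn1 <- dQ %*% t(lp$Wq) + dK %*% t(lp$Wk) + dV %*% t(lp$Wv)
    dZ <- dZ1 + layer_norm_backward(dZn1, lc$ln1, lp$ln1_g)$dx
    grads[[l]] <- layer_grads
  }
  grads
}

#' Attention rollout to a class-token relevance vector
#'
#' Heads are averaged within each layer, the residual path is accounted for
#' by mixing with the identity, rows are re-normalized, and the per-layer
#' matrices are recursively multiplied:
#' `R = A_L ... A_1` with `A_l = normalize(0.5 mean_h(A_l^h) + 0.5 I)`.
#' The class-token row of `R`, restricted to patch tokens and normalized to
#' sum 1, attributes the decision to input patches.
#'
#' @param attn attention record from [collect_attention()].
#' @param attn_grad optional gradient record (one `d logit / d A` matrix per
#'   layer and head): when supplied, the gradient-weighted (relevance
#'   propagation) variant is used, `A_bar_l = normalize(I + mean_h (G
#'   \\* A)^+)`, which suppresses attention edges that do not drive the
#'   abnormality logit.
#' @return relevance vector `r` over the `N` patch tokens (non-negative,
#'   sums to 1).
#' @export
attention_rollout <- function(attn, attn_grad = NULL) {
  n1 <- nrow(attn[[1]][[1]])
  R <- diag(n1)
  for (l in seq_along(attn)) {
    if (is.null(attn_grad)) {
      A_mean <- Reduce(`+`, attn[[l]]) / length(attn[[l]])
      A_bar <- 0.5 * A_mean + 0.5 * diag(n1)
    } else {
      GA <- Reduce(`+`, lapply(seq_along(attn[[l]]), function(i) {
        pmax(attn_grad[[l]][[i]] * attn[[l]][[i]], 0)
      })) / length(attn[[l]])
      A_bar <- diag(n1) + GA
    }
    A_bar <- A_bar / rowSums(A_bar)
    R <- A_bar %*% R
  }
  r <- R[1, -1]
  if (sum(r) < 1e-12) {
    # the class token attended only to itself through every layer: no
    # information reached it from the patches, so attribute uniformly
    return(rep(1 / length(r), length(r)))
  }
  r / sum(r)
}

#' Per-frame saliency maps from a relevance vector
#'
#' The relevance slice of each temporal segment (an `n_h x n_w` patch grid)
#' is bilinearly upsampled to full frame resolution and min-max normalized
#' to `[0, 1]`; every frame within a segment shares that segment's map. A
#' constant slice normalizes to all-zeros (flagged via attribute
#' `flat_segments`) rather than NaN.
#'
#' @param r relevance vector in token order (t, h, w) row-major.
#' @param grid_shape `(n_t, n_h, n_w)`.
#' @param frame_hw output map resolution `(H, W)`.
#' @return list of `n_t` maps (`H x W` matrices), one per temporal segment.
#' @export
frame_maps <- function(r, grid_shape, frame_hw) {
  n_t <- grid_shape[[1]]; n_h <- grid_shape[[2]]; n_w <- grid_shape[[3]]
  stopifnot(length(r) == n_t * n_h * n_w)
  frame_hw <- rep(frame_hw, length.out = 2L)
  flat <- logical(n_t)
  maps <- vector("list", n_t)
  for (s in seq_len(n_t)) {
    slice <- matrix(0, n_h, n_w)
    for (i in seq_len(n_h)) {
      for (j in seq_len(n_w)) {
        slice[i, j] <- r[((s - 1) * n_h + (i - 1)) * n_w + j]
      }
    }
    up <- bilinear_resize(slice, frame_hw[1], frame_hw[2])
    rng <- range(up)
    if (rng[2] - rng[1] < 1e-12) {
      maps[[s]] <- matrix(0, frame_hw[1], frame_hw[2])
      flat[s] <- TRUE
    } else {
      maps[[s]] <- (up - rng[1]) / (rng[2] - rng[1])
    }
  }
  attr(maps, "flat_segments") <- flat
  maps
}

#' Per-frame confidence weights
#'
#' Each `Tp`-frame temporal segment is scored independently by the
#' classifier: the segment is tiled to the clip's full length (so the input
#' stays in-distribution while containing only that segment's content) and
#' the resulting logits are softmax-normalized, broadcast to each segment's
#' frames, and re-normalized over the clip's actual frames so that the
#' weights sum to 1.
#'
#' @param params a `vit_params` (or fitted `vfss_vit`).
#' @param frames `T x H x W` array at model input resolution.
#' @return list with `omega` (length-`T` weights summing to 1) and
#'   `segment_scores` (per-segment abnormality logits).
#' @export
confidence_weights <- function(params, frames) {
  if (inherits(params, "vfss_vit")) params <- params$params
  cfg <- params$config
  t_len <- dim(frames)[1]
  n_t <- ceiling(t_len / cfg$Tp)
  seg_scores <- numeric(n_t)
  for (s in seq_len(n_t)) {
    rows <- ((s - 1) * cfg$Tp + 1):min(s * cfg$Tp, t_len)
    reps <- ceiling(t_len / length(rows))
    tiled <- array(0, c(length(rows) * reps, dim(frames)[2], dim(frames)[3]))
    for (r in seq_len(reps)) {
      tiled[((r - 1) * length(rows) + 1):(r * length(rows)), , ] <-
        frames[rows, , , drop = FALSE]
    }
    tiled <- tiled[seq_len(t_len), , , drop = FALSE]
    seg_scores[s] <- vit_forward(params, extract_patches(tiled, cfg))$logit
  }
  w_seg <- exp(seg_scores - max(seg_scores))
  w_seg <- w_seg / sum(w_seg)
  omega <- numeric(t_len)
  for (s in seq_len(n_t)) {
    rows <- ((s - 1) * cfg$Tp + 1):min(s * cfg$Tp, t_len)
    omega[rows] <- w_seg[s] / cfg$Tp
  }
  omega <- omega / sum(omega)
  list(omega = omega, segment_scores = seg_scores)
}

#' Cumulative contribution map
#'
#' `M(x, y) = sum_t omega_t m_t(x, y)`.
#'
#' @param maps list of per-segment maps from [frame_maps()].
#' @param omega per-frame weights.
#' @param Tp temporal patch length (frame `t` uses segment
#'   `ceiling(t / Tp)`).
#' @export
cumulative_map <- function(maps, omega, Tp) {
  M <- maps[[1]] * 0
  for (t in seq_along(omega)) {
    s <- min((t - 1) %/% Tp + 1, length(maps))
    M <- M + omega[t] * maps[[s]]
  }
  M
}

#' Threshold a saliency map at a percentile of its field-of-view values
#'
#' @param M saliency map.
#' @param fov_mask logical field-of-view mask (percentile computed inside
#'   the FOV only; including the zeroed corners would deflate it).
#' @param percentile percentile in (0, 100), default 90.
#' @return logical mask `Omega` (subset of the FOV); attribute `flat` is
#'   TRUE when `M` is constant inside the FOV (no informative saliency), in
#'   which case the mask is empty.
#' @export
threshold_mask <- function(M, fov_mask, percentile = 90) {
  vals <- M[fov_mask]
  if (max(vals) - min(vals) < 1e-12) {
    out <- fov_mask & FALSE
    attr(out, "flat") <- TRUE
    return(out)
  }
  thr <- stats::quantile(vals, percentile / 100, names = FALSE)
  out <- (M >= thr) & fov_mask
  attr(out, "flat") <- FALSE
  out
}

# Dense Lucas-Kanade optical flow between two frames (5x5 window).
optical_flow <- function(f1, f2) {
  kx <- matrix(c(-0.5, 0, 0.5), 1, 3)
  Ix <- conv2(f1, kx)
  Iy <- conv2(f1, t(kx))
  It <- f2 - f1
  box <- matrix(1, 5, 5)
  sxx <- conv2(Ix * Ix, box); syy <- conv2(Iy * Iy, box)
  sxy <- conv2(Ix * Iy, box)
  sxt <- conv2(Ix * It, box); syt <- conv2(Iy * It, box)
  det <- sxx * syy - sxy^2
  ok <- det > 1e-9
  u <- matrix(0, nrow(f1), ncol(f1))
  v <- matrix(0, nrow(f1), ncol(f1))
  u[ok] <- (-syy[ok] * sxt[ok] + sxy[ok] * syt[ok]) / det[ok]
  v[ok] <- (sxy[ok] * sxt[ok] - sxx[ok] * syt[ok]) / det[ok]
  list(u = u, v = v, mag = sqrt(u^2 + v^2))
}

#' Pick a quiescent (low-motion) frame
#'
#' Dense optical flow is computed between consecutive frames; the first
#' frame whose mean flow magnitude (inside the FOV) falls below
#' `flow_threshold` pixels is returned. If no frame qualifies, the
#' minimum-flow frame is returned with `fallback = TRUE`.
#'
#' @param frames `T x H x W` array, `T >= 2`.
#' @param flow_threshold mean-flow cutoff in pixels (default 0.5).
#' @param fov_mask optional logical mask restricting the flow average.
#' @return list with `index`, `mean_flow` (per frame) and `fallback`.
#' @export
quiescent_frame <- function(frames, flow_threshold = 0.5, fov_mask = NULL) {
  t_len <- dim(frames)[1]
  stopifnot(t_len >= 2)
  if (is.null(fov_mask)) fov_mask <- matrix(TRUE, dim(frames)[2], dim(frames)[3])
  mean_flow <- numeric(t_len)
  for (t in seq_len(t_len - 1)) {
    fl <- optical_flow(frames[t, , ], frames[t + 1, , ])
    mean_flow[t] <- mean(fl$mag[fov_mask])
  }
  mean_flow[t_len] <- mean_flow[t_len - 1]
  idx <- which(mean_flow < flow_threshold)
  if (length(idx) > 0) {
    list(index = idx[1], mean_flow = mean_flow, fallback = FALSE)
  } else {
    list(index = which.min(mean_flow), mean_flow = mean_flow, fallback = TRUE)
  }
}

# Map values in [0,1] through a warm (black-red-yellow) colormap.
warm_colormap <- function(v) {
  r <- pmin(1, 2 * v)
  g <- pmin(1, pmax(0, 2 * v - 1))
  b <- pmax(0, 4 * (v - 0.75))
  list(r = r, g = g, b = b)
}

mask_contour <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  er <- mask
  er[-1, ] <- er[-1, ] & mask[-h, ]
  er[-h, ] <- er[-h, ] & mask[-1, ]
  er[, -1] <- er[, -1] & mask[, -w]
  er[, -w] <- er[, -w] & mask[, -1]
  mask & !er
}

#' Overlay a saliency map on a reference frame
#'
#' Alpha-blends a warm colormap of `M` over the grayscale frame and draws
#' the mask contour; optionally written as PNG.
#'
#' @param M saliency map in `[0, 1]`.
#' @param mask logical mask whose contour is drawn (may be empty).
#' @param frame grayscale reference frame in `[0, 1]` (same shape).
#' @param path optional PNG output path.
#' @param alpha_max maximal overlay opacity.
#' @return `H x W x 3` RGB array (invisibly if written to `path`).
#' @export
overlay_saliency <- function(M, mask, frame, path = NULL, alpha_max = 0.6) {
  if (!all(dim(M) == dim(frame)) || !all(dim(mask) == dim(frame))) {
    stop("saliency map, mask and frame shapes must match")
  }
  cm <- warm_colormap(M)
  a <- alpha_max * M
  rgb <- array(0, c(nrow(frame), ncol(frame), 3))
  rgb[, , 1] <- (1 - a) * frame + a * cm$r
  rgb[, , 2] <- (1 - a) * frame + a * cm$g
  rgb[, , 3] <- (1 - a) * frame + a * cm$b
  if (any(mask)) {
    ct <- mask_contour(mask)
    rgb[, , 1][ct] <- 0
    rgb[, , 2][ct] <- 1
    rgb[, , 3][ct] <- 1
  }
  rgb <- clamp01(rgb)
  if (!is.null(path)) {
    png::writePNG(rgb, path)
    return(invisible(rgb))
  }
  rgb
}

#' End-to-end attention-rollout saliency for one clip
#'
#' Runs the clip through the fitted transformer, rolls the attention out to
#' a patch-relevance vector, builds per-segment maps, weights them by the
#' per-segment classifier confidence, accumulates the cumulative map `M`,
#' thresholds it at the chosen percentile of FOV values, and selects a
#' quiescent backdrop frame.
#'
#' @param fit a fitted `vfss_vit`.
#' @param clip a [frame_stack()] or `T x H x W` array (model-ready, in
#'   `[0, 1]`).
#' @param percentile mask percentile (default 90).
#' @param fov_mask optional logical FOV mask at model resolution; default is
#'   the inscribed circle.
#' @param flow_threshold quiescent-frame cutoff in pixels.
#' @param method `"rollout"` (default) is the head-averaged attention
#'   rollout with residual identity mixing; `"grad"` weights each attention
#'   edge by the gradient of the abnormality logit before rolling out
#'   (a relevance-propagation-style variant).
#' @return a `vfss_saliency` object: `maps` (per segment), `omega`, `M`,
#'   `mask`, `quiescent` and `y_hat`.
#' @export
vfss_saliency <- function(fit, clip, percentile = 90, fov_mask = NULL,
                          flow_threshold = 0.5, method = c("rollout", "grad")) {
  method <- match.arg(method)
  cfg <- fit$config
  frames <- frames_of(clip)
  d <- dim(frames)
  if (d[2] != cfg$input_hw || d[3] != cfg$input_hw) {
    out <- array(0, c(d[1], cfg$input_hw, cfg$input_hw))
    for (t in seq_len(d[1])) {
      out[t, , ] <- clamp01(bilinear_resize(frames[t, , ], cfg$input_hw, cfg$input_hw))
    }
    frames <- out
  }
  if (is.null(fov_mask)) fov_mask <- make_fov_mask(cfg$input_hw, cfg$input_hw)
  grid <- extract_patches(frames, cfg)
  fw <- vit_forward(fit$params, grid, collect_attention = TRUE,
                    keep_cache = (method == "grad"))
  attn <- fw$attn
  r <- if (method == "grad") {
    attention_rollout(attn, attention_gradients(fit$params, fw))
  } else {
    attention_rollout(attn)
  }
  maps <- frame_maps(r, grid$grid_shape, c(cfg$input_hw, cfg$input_hw))
  cw <- confidence_weights(fit$params, frames)
  M <- cumulative_map(maps, cw$omega, cfg$Tp)
  mask <- threshold_mask(M, fov_mask, percentile)
  q <- quiescent_frame(frames, flow_threshold, fov_mask)
  structure(list(maps = maps, omega = cw$omega,
                 segment_scores = cw$segment_scores, relevance = r,
                 M = M, mask = mask, quiescent = q,
                 y_hat = predict(fit, frames), fov_mask = fov_mask,
                 frames = frames),
            class = "vfss_saliency")
}

#' @export
print.vfss_saliency <- function(x, ...) {
  cat(sprintf("<vfss_saliency> %d segments, y_hat %.3f, mask %d px, quiescent frame %d%s\n",
              length(x$maps), x$y_hat, sum(x$mask), x$quiescent$index,
              if (x$quiescent$fallback) " (fallback)" else ""))
  invisible(x)
}

#' @export
plot.vfss_saliency <- function(x, ...) {
  rgb <- overlay_saliency(x$M / max(max(x$M), 1e-12), x$mask,
                          x$frames[x$quiescent$index, , ])
  grid_dim <- dim(rgb)
  graphics::plot(c(0, grid_dim[2]), c(0, grid_dim[1]), type = "n", asp = 1,
                 xlab = "", ylab = "", axes = FALSE, ...)
  graphics::rasterImage(grDevices::as.raster(rgb), 0, 0, grid_dim[2], grid_dim[1])
  invisible(x)
}
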