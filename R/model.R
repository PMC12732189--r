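#' Vision transformer configuration
#'
#' Architectural hyperparameters of the 3D-patch video transformer. The
#' clinical-scale defaults are: 25-frame temporal patches (about one second
#' at 25 fps, so each token spans a complete swallow), 16x16 spatial patches,
#' embedding dimension 64, 8 attention heads, 8 encoder layers, a
#' two-layer MLP classification head of widths 128 and 64, and 256x256 input
#' frames.
#'
#' @param Tp temporal patch length in frames.
#' @param P spatial patch side in pixels.
#' @param D embedding dimension (must be divisible by `h`).
#' @param h number of attention heads.
#' @param L number of encoder layers.
#' @param ffn_dim hidden width of the position-wise feed-forward network
#'   (default `4 * D`, the usual transformer convention).
#' @param head_dims hidden widths of the MLP classification head.
#' @param head_type `"mlp"` (default) routes the class token through the MLP
#'   head; `"linear"` applies a single linear logit layer.
#' @param input_hw input frame side in pixels (must be divisible by `P`).
#' @param stride temporal stride between patch windows (default `Tp`,
#'   i.e. non-overlapping windows).
#' @export
vit_config <- function(Tp = 25L, P = 16L, D = 64L, h = 8L, L = 8L,
                       ffn_dim = NULL, head_dims = c(128L, 64L),
                       head_type = c("mlp", "linear"), input_hw = 256L,
                       stride = NULL) {
  head_type <- match.arg(head_type)
  if (is.null(ffn_dim)) ffn_dim <- 4L * D
  if (is.null(stride)) stride <- Tp
  stopifnot(Tp >= 1, P >= 1, D >= 1, h >= 1, L >= 1, D %% h == 0,
            input_hw %% P == 0, stride >= 1)
  structure(list(Tp = as.integer(Tp), P = as.integer(P), D = as.integer(D),
                 h = as.integer(h), L = as.integer(L),
                 ffn_dim = as.integer(ffn_dim),
                 head_dims = as.integer(head_dims), head_type = head_type,
                 input_hw = as.integer(input_hw), stride = as.integer(stride)),
            class = "vit_config")
}

#' @export
print.vit_config <- function(x, ...) {
  cat(sprintf("<vit_config> Tp=%d P=%d D=%d heads=%d layers=%d ffn=%d head=%s[%s] input=%dpx\n",
              x$Tp, x$P, x$D, x$h, x$L, x$ffn_dim, x$head_type,
              paste(x$head_dims, collapse = ","), x$input_hw))
  invisible(x)
}

#' Isotropically resize a stack for spatial patching
#'
#' Bilinear per-frame resize to `input_hw x input_hw`, clipped to `[0, 1]`.
#' A correctly sized input is returned unchanged.
#'
#' @param stack single-channel [frame_stack()] with square frames.
#' @param input_hw target side in pixels.
#' @export
resize_isotropic <- function(stack, input_hw) {
  d <- dim(stack$frames)
  if (d[2] == input_hw && d[3] == input_hw) return(stack)
  out <- array(0, c(d[1], input_hw, input_hw))
  for (t in seq_len(d[1])) {
    out[t, , ] <- clamp01(bilinear_resize(stack$frames[t, , ], input_hw, input_hw))
  }
  set_frames(stack, out)
}

#' Decompose a video into flattened 3D patches
#'
#' The video is zero-padded at the end to the next multiple of `Tp` frames,
#' then cut into non-overlapping `Tp x P x P` blocks. The total token count is
#' `N = T/Tp * H/P * W/P`. Tokens are enumerated in row-major `(t, h, w)`
#' order (the spatial column index varies fastest, the temporal segment index
#' slowest); within each patch the `Tp * P^2` values are flattened with the
#' spatial column fastest and the frame index slowest. Positional-embedding
#' semantics depend on this fixed order.
#'
#' @param video `T x H x W` array with `H = W = config$input_hw`, values in
#'   `[0, 1]`.
#' @param config a [vit_config()].
#' @return a `token_grid`: list with `tokens` (`N x Tp*P^2` matrix),
#'   `grid_shape` `(n_t, n_h, n_w)` and `pad_frames`.
#' @export
extract_patches <- function(video, config) {
  d <- dim(video)
  if (d[2] %% config$P != 0 || d[3] %% config$P != 0) {
    stop(sprintf("frame size %d x %d is not divisible by patch size %d",
                 d[2], d[3], config$P))
  }
  Tp <- config$Tp
  if (config$stride != Tp) {
    # overlapping windows: enumerate segment starts, duplicate frames
    starts <- seq(1L, max(d[1] - Tp + 1L, 1L), by = config$stride)
    pad_total <- max(utils::tail(starts, 1) + Tp - 1L, d[1]) - d[1]
    padded <- array(0, c(d[1] + pad_total, d[2], d[3]))
    padded[seq_len(d[1]), , ] <- video
    segs <- lapply(starts, function(s) padded[s:(s + Tp - 1L), , , drop = FALSE])
    video <- array(0, c(length(starts) * Tp, d[2], d[3]))
    for (i in seq_along(segs)) video[((i - 1) * Tp + 1):(i * Tp), , ] <- segs[[i]]
    pad <- as.integer(pad_total)
  } else {
    pad <- as.integer((Tp - d[1] %% Tp) %% Tp)
    if (pad > 0) {
      padded <- array(0, c(d[1] + pad, d[2], d[3]))
      padded[seq_len(d[1]), , ] <- video
      video <- padded
    }
  }
  dv <- dim(video)
  n_t <- dv[1] %/% Tp; n_h <- dv[2] %/% config$P; n_w <- dv[3] %/% config$P
  P <- config$P
  # column-major array (t, h, w) -> (tt, t_seg, hh, h_blk, ww, w_blk)
  dim(video) <- c(Tp, n_t, P, n_h, P, n_w)
  # token matrix (dp x N): within-patch (ww, hh, tt), token (w_blk, h_blk, t_seg)
  tok <- aperm(video, c(5, 3, 1, 6, 4, 2))
  dim(tok) <- c(Tp * P * P, n_t * n_h * n_w)
  structure(list(tokens = t(tok), grid_shape = c(n_t = n_t, n_h = n_h, n_w = n_w),
                 pad_frames = pad, Tp = Tp, P = P),
            class = "token_grid")
}

#' Reassemble a video from a token grid
#'
#' Exact inverse of [extract_patches()] for non-overlapping windows; the
#' zero-padded tail frames are dropped when `drop_pad` is true.
#'
#' @param grid a `token_grid`.
#' @param drop_pad drop the `pad_frames` trailing frames.
#' @export
unpatchify <- function(grid, drop_pad = TRUE) {
  gs <- grid$grid_shape
  Tp <- grid$Tp; P <- grid$P
  tok <- t(grid$tokens)
  dim(tok) <- c(gs["n_w"] * 0 + P, P, Tp, gs[["n_w"]], gs[["n_h"]], gs[["n_t"]])
  video <- aperm(tok, c(3, 6, 2, 5, 1, 4))
  dim(video) <- c(Tp * gs[["n_t"]], P * gs[["n_h"]], P * gs[["n_w"]])
  if (drop_pad && grid$pad_frames > 0) {
    video <- video[seq_len(dim(video)[1] - grid$pad_frames), , , drop = FALSE]
  }
  video
}

#' Initialize transformer parameters
#'
#' Fan-in-scaled (LeCun/Xavier-style) truncated-normal initialization for
#' all projection matrices (sd `1/sqrt(fan_in)`), truncated normal sd 0.02
#' for the positional table, zeros for biases and the class token, unit
#' scales for the layer norms. Fan-in scaling keeps attention logits at
#' unit order from the first step, which makes the attention pathway
#' trainable within a small update budget; a fixed small sd leaves the
#' encoder in a long zero-gradient plateau.
#'
#' @param config a [vit_config()].
#' @param n_max_tokens positional-table capacity: the largest patch-token
#'   count the model will ever see (set from the longest training clip;
#'   longer clips at inference raise a capacity error).
#' @param seed integer seed.
#' @return a `vit_params` list of named arrays.
#' @export
vit_init <- function(config, n_max_tokens, seed = 1L) {
  dp <- config$Tp * config$P^2
  D <- config$D
  with_seed(seed, {
    tn <- function(nr, nc) matrix(rtruncnorm02(nr * nc, sd = sqrt(1 / nr)), nr, nc)
    layers <- lapply(seq_len(config$L), function(l) {
      list(ln1_g = rep(1, D), ln1_b = rep(0, D),
           Wq = tn(D, D), bq = rep(0, D), Wk = tn(D, D), bk = rep(0, D),
           Wv = tn(D, D), bv = rep(0, D), Wo = tn(D, D), bo = rep(0, D),
           ln2_g = rep(1, D), ln2_b = rep(0, D),
           W1 = tn(D, config$ffn_dim), b1 = rep(0, config$ffn_dim),
           W2 = tn(config$ffn_dim, D), b2 = rep(0, D))
    })
    head <- if (config$head_type == "mlp") {
      h1 <- config$head_dims[1]; h2 <- config$head_dims[2]
      list(Wh1 = tn(D, h1), bh1 = rep(0, h1),
           Wh2 = tn(h1, h2), bh2 = rep(0, h2),
           Wc = tn(h2, 1L), bc = 0)
    } else {
      list(Wc = tn(D, 1L), bc = 0)
    }
    structure(list(E = tn(dp, D), z_class = matrix(0, 1, D),
                   E_pos = matrix(rtruncnorm02((n_max_tokens + 1L) * D, sd = 0.02),
                                  n_max_tokens + 1L, D),
                   layers = layers, ln_f_g = rep(1, D), ln_f_b = rep(0, D),
                   head = head, config = config,
                   n_max_tokens = as.integer(n_max_tokens)),
              class = "vit_params")
  })
}

#' Count trainable parameters in closed form
#'
#' Embedding `Tp*P^2*D`, class token `D`, positional table
#' `(n_max_tokens+1)*D`, per encoder layer `4(D^2+D) + 4D + D*F + F + F*D + D`
#' (QKV/O projections with biases, two layer norms, the FFN), final layer
#' norm `2D`, and the classification head. Matches the instantiated model's
#' trainable-scalar count exactly.
#'
#' @param config a [vit_config()].
#' @param n_max_tokens positional-table capacity.
#' @export
count_parameters <- function(config, n_max_tokens) {
  dp <- config$Tp * config$P^2
  D <- config$D; F <- config$ffn_dim
  per_layer <- 2 * D + 4 * (D * D + D) + 2 * D + D * F + F + F * D + D
  head <- if (config$head_type == "mlp") {
    h1 <- config$head_dims[1]; h2 <- config$head_dims[2]
    D * h1 + h1 + h1 * h2 + h2 + h2 + 1
  } else {
    D + 1
  }
  dp * D + D + (n_max_tokens + 1) * D + config$L * per_layer + 2 * D + head
}

# Count of scalars actually stored in a vit_params object.
n_params <- function(params) {
  flat <- unlist(params[c("E", "z_class", "E_pos", "layers", "ln_f_g", "ln_f_b", "head")])
  length(flat)
}

## ---- layer primitives ----

layer_norm_forward <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  list(y = sweep(xhat, 2, g, `*`) + rep(b, each = nrow(x)),
       xhat = xhat, inv = inv)
}

layer_norm_backward <- function(dy, cache, g) {
  xhat <- cache$xhat; inv <- cache$inv
  dxhat <- sweep(dy, 2, g, `*`)
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = dg, db = db)
}

add_bias <- function(x, b) x + rep(b, each = nrow(x))

#' Multi-head self-attention
#'
#' Scaled dot-product attention per head (scale `1/sqrt(D/h)`), heads
#' concatenated and projected by the output matrix. Exposed directly so the
#' batched computation can be validated against an independent per-head loop.
#'
#' @param Z `(N+1) x D` input sequence.
#' @param lp layer parameter list (elements `Wq, bq, Wk, bk, Wv, bv, Wo, bo`).
#' @param n_heads number of heads.
#' @param return_cache also return per-head attention matrices and
#'   intermediates (for backprop and saliency).
#' @return `Z'` or, with `return_cache`, a list with `out`, `attn_t` (list
#'   of transposed, column-stochastic attention matrices as cached by the
#'   compiled kernel; transpose for the usual row-stochastic form), `Q`,
#'   `K`, `V`, `Hcat`.
#' @export
mhsa <- function(Z, lp, n_heads, return_cache = FALSE) {
  if (ncol(Z) %% n_heads != 0) stop("embedding dimension not divisible by head count")
  Q <- add_bias(Z %*% lp$Wq, lp$bq)
  K <- add_bias(Z %*% lp$Wk, lp$bk)
  V <- add_bias(Z %*% lp$Wv, lp$bv)
  af <- attention_forward_cpp(Q, K, V, n_heads)
  out <- add_bias(af$Hcat %*% lp$Wo, lp$bo)
  if (return_cache) {
    list(out = out, attn_t = af$attn_t, Q = Q, K = K, V = V, Hcat = af$Hcat)
  } else out
}

#' One pre-norm transformer encoder layer
#'
#' `Z <- Z + MHSA(LN(Z))`, then `Z <- Z + FFN(LN(Z))`, with
#' `FFN(x) = relu(x W1 + b1) W2 + b2`.
#'
#' @param Z `(N+1) x D` sequence.
#' @param lp layer parameter list.
#' @param n_heads number of heads.
#' @param return_cache keep intermediates for backprop.
#' @export
encoder_layer <- function(Z, lp, n_heads, return_cache = FALSE) {
  ln1 <- layer_norm_forward(Z, lp$ln1_g, lp$ln1_b)
  att <- mhsa(ln1$y, lp, n_heads, return_cache = TRUE)
  Z1 <- Z + att$out
  ln2 <- layer_norm_forward(Z1, lp$ln2_g, lp$ln2_b)
  U <- add_bias(ln2$y %*% lp$W1, lp$b1)
  Ur <- relu(U)
  Z2 <- Z1 + add_bias(Ur %*% lp$W2, lp$b2)
  if (!return_cache) return(Z2)
  list(out = Z2, Z = Z, ln1 = ln1, att = att, Z1 = Z1, ln2 = ln2, U = U, Ur = Ur)
}

#' Embed patch tokens and assemble the transformer input sequence
#'
#' Projects each flattened patch by the embedding matrix, prepends the class
#' token and adds positional embeddings: `Z0[1,] = z_class + E_pos[1,]`,
#' `Z0[i+1,] = E' x_i + E_pos[i+1,]`.
#'
#' @param grid a `token_grid` from [extract_patches()].
#' @param params a `vit_params`.
#' @return `(N+1) x D` matrix.
#' @export
embed_and_assemble <- function(grid, params) {
  N <- nrow(grid$tokens)
  if (N > params$n_max_tokens) {
    stop(sprintf("clip produces %d patch tokens but the positional table holds %d; re-fit with a longer capacity",
                 N, params$n_max_tokens))
  }
  Z0 <- rbind(params$z_class, grid$tokens %*% params$E)
  Z0 + params$E_pos[seq_len(N + 1L), , drop = FALSE]
}

head_forward <- function(cls, head, head_type) {
  if (head_type == "mlp") {
    a1 <- relu(add_bias(cls %*% head$Wh1, head$bh1))
    a2 <- relu(add_bias(a1 %*% head$Wh2, head$bh2))
    logit <- drop(a2 %*% head$Wc) + head$bc
    list(logit = logit, a1 = a1, a2 = a2)
  } else {
    list(logit = drop(cls %*% head$Wc) + head$bc)
  }
}

#' Transformer forward pass on one clip
#'
#' @param params a `vit_params`.
#' @param grid a `token_grid` from [extract_patches()].
#' @param collect_attention keep every layer/head attention matrix (for
#'   saliency rollout).
#' @param keep_cache keep all intermediates (for backprop).
#' @return a list with `y_hat` (probability), `logit`, `cls` (final class
#'   embedding), and optionally `attn` and `cache`.
#' @export
vit_forward <- function(params, grid, collect_attention = FALSE, keep_cache = FALSE) {
  cfg <- params$config
  Z <- embed_and_assemble(grid, params)
  caches <- if (keep_cache) vector("list", cfg$L) else NULL
  attn <- if (collect_attention) vector("list", cfg$L) else NULL
  for (l in seq_len(cfg$L)) {
    res <- encoder_layer(Z, params$layers[[l]], cfg$h, return_cache = TRUE)
    if (keep_cache) caches[[l]] <- res
    if (collect_attention) attn[[l]] <- lapply(res$att$attn_t, t)
    Z <- res$out
  }
  lnf <- layer_norm_forward(Z, params$ln_f_g, params$ln_f_b)
  cls <- lnf$y[1, , drop = FALSE]
  hd <- head_forward(cls, params$head, cfg$head_type)
  out <- list(y_hat = sigmoid(hd$logit), logit = hd$logit, cls = drop(cls))
  if (collect_attention) out$attn <- attn
  if (keep_cache) {
    out$cache <- list(layers = caches, lnf = lnf, Zfinal = Z, head = hd,
                      grid = grid)
  }
  out
}

#' Binary cross-entropy loss
#'
#' `-[y log(y_hat) + (1-y) log(1-y_hat)]`, epsilon-clipped. The logit form
#' [bce_loss_logit()] is the numerically stable variant used in training.
#'
#' @param y_hat predicted probability.
#' @param y label in `{0, 1}`.
#' @export
bce_loss <- function(y_hat, y, eps = 1e-12) {
  y_hat <- pmin(pmax(y_hat, eps), 1 - eps)
  -(y * log(y_hat) + (1 - y) * log(1 - y_hat))
}

#' @rdname bce_loss
#' @param logit raw score before the sigmoid.
#' @export
bce_loss_logit <- function(logit, y) {
  pmax(logit, 0) - logit * y + log1p(exp(-abs(logit)))
}

# Zero-filled gradient structure matching a vit_params.
grad_template <- function(params) {
  zero_like <- function(x) if (is.list(x)) lapply(x, zero_like) else x * 0
  g <- list(E = params$E * 0, z_class = params$z_class * 0,
            E_pos = params$E_pos * 0,
            layers = lapply(params$layers, zero_like),
            ln_f_g = params$ln_f_g * 0, ln_f_b = params$ln_f_b * 0,
            head = lapply(params$head, function(x) x * 0))
  g
}

# Backward pass for one clip; dlogit = d(loss)/d(logit) = y_hat - y for BCE.
vit_backward <- function(params, fwd, dlogit) {
  cfg <- params$config
  cache <- fwd$cache
  g <- grad_template(params)
  hd <- cache$head
  # classification head
  if (cfg$head_type == "mlp") {
    da2 <- matrix(dlogit * params$head$Wc[, 1], 1)
    g$head$Wc <- t(hd$a2) * dlogit
    g$head$bc <- dlogit
    dpre2 <- da2 * (hd$a2 > 0)
    g$head$Wh2 <- crossprod(hd$a1, dpre2)
    g$head$bh2 <- drop(dpre2)
    da1 <- dpre2 %*% t(params$head$Wh2)
    dpre1 <- da1 * (hd$a1 > 0)
    cls <- cache$lnf$y[1, , drop = FALSE]
    g$head$Wh1 <- crossprod(cls, dpre1)
    g$head$bh1 <- drop(dpre1)
    dcls <- dpre1 %*% t(params$head$Wh1)
  } else {
    cls <- cache$lnf$y[1, , drop = FALSE]
    g$head$Wc <- t(cls) * dlogit
    g$head$bc <- dlogit
    dcls <- matrix(dlogit * params$head$Wc[, 1], 1)
  }
  dZf <- matrix(0, nrow(cache$Zfinal), cfg$D)
  dZf[1, ] <- dcls
  lb <- layer_norm_backward(dZf, cache$lnf, params$ln_f_g)
  g$ln_f_g <- lb$dg; g$ln_f_b <- lb$db
  dZ <- lb$dx
  for (l in rev(seq_len(cfg$L))) {
    lc <- cache$layers[[l]]
    lp <- params$layers[[l]]
    gl <- g$layers[[l]]
    # FFN block
    dZ1 <- dZ
    dUr <- dZ %*% t(lp$W2)
    gl$W2 <- crossprod(lc$Ur, dZ)
    gl$b2 <- colSums(dZ)
    dU <- dUr * (lc$U > 0)
    gl$W1 <- crossprod(lc$ln2$y, dU)
    gl$b1 <- colSums(dU)
    dZn2 <- dU %*% t(lp$W1)
    lb2 <- layer_norm_backward(dZn2, lc$ln2, lp$ln2_g)
    gl$ln2_g <- lb2$dg; gl$ln2_b <- lb2$db
    dZ1 <- dZ1 + lb2$dx
    # MHSA block
    dM <- dZ1
    att <- lc$att
    dHcat <- dM %*% t(lp$Wo)
    gl$Wo <- crossprod(att$Hcat, dM)
    gl$bo <- colSums(dM)
    ab <- attention_backward_cpp(dHcat, att$Q, att$K, att$V, att$attn_t)
    dQ <- ab$dQ; dK <- ab$dK; dV <- ab$dV
    Zn1 <- lc$ln1$y
    gl$Wq <- crossprod(Zn1, dQ); gl$bq <- colSums(dQ)
    gl$Wk <- crossprod(Zn1, dK); gl$bk <- colSums(dK)
    gl$Wv <- crossprod(Zn1, dV); gl$bv <- colSums(dV)
    dZn1 <- dQ %*% t(lp$Wq) + dK %*% t(lp$Wk) + dV %*% t(lp$Wv)
    lb1 <- layer_norm_backward(dZn1, lc$ln1, lp$ln1_g)
    gl$ln1_g <- lb1$dg; gl$ln1_b <- lb1$db
    dZ <- dZ1 + lb1$dx
    g$layers[[l]] <- gl
  }
  N1 <- nrow(dZ)
  g$E_pos[seq_len(N1), ] <- dZ
  g$z_class <- dZ[1, , drop = FALSE]
  g$E <- crossprod(cache$grid$tokens, dZ[-1, , drop = FALSE])
  g
}
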