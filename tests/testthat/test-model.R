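test_that("token-count law holds for the clinical-scale configuration", {
  cfg <- vit_config(Tp = 25, P = 16, D = 64, h = 8, L = 8, input_hw = 256)
  v <- array(0.5, c(100, 256, 256))
  g <- extract_patches(v, cfg)
  expect_equal(nrow(g$tokens), 1024L)          # 100/25 * 256/16 * 256/16
  expect_equal(ncol(g$tokens), 6400L)          # 25 * 16^2
  expect_equal(unname(g$grid_shape), c(4L, 16L, 16L))
  expect_equal(g$pad_frames, 0L)
})

test_that("temporal end-padding rounds the clip up to a multiple of Tp", {
  cfg <- vit_config(Tp = 25, P = 16, D = 64, h = 8, L = 8, input_hw = 256)
  v <- array(0.5, c(30, 256, 256))
  g <- extract_patches(v, cfg)
  expect_equal(g$pad_frames, 20L)
  expect_equal(unname(g$grid_shape[1]), 2L)
  expect_error(extract_patches(array(0, c(4, 30, 30)), tiny_vit()),
               "not divisible")
})

test_that("patchify/unpatchify is the identity on the unpadded prefix", {
  cfg <- tiny_vit()
  set.seed(4)
  for (t_len in c(1, 2, 3, 7, 8)) {
    v <- array(runif(t_len * 8 * 8), c(t_len, 8, 8))
    g <- extract_patches(v, cfg)
    back <- unpatchify(g)
    expect_identical(back, v)
  }
})

test_that("token enumeration follows the documented (t, h, w) order", {
  cfg <- tiny_vit()  # Tp=2, P=4, input 8 -> n_h = n_w = 2
  v <- array(0, c(2, 8, 8))
  v[1:2, 1:4, 5:8] <- 7  # temporal segment 1, h block 1, w block 2
  g <- extract_patches(v, cfg)
  expect_equal(unname(which(rowSums(g$tokens) > 0)), 2L)
  # within-patch flattening: frame index slowest, column fastest
  v2 <- array(0, c(2, 8, 8))
  v2[2, 1, 3] <- 5  # frame 2, row 1, col 3 of patch (1,1,1)
  g2 <- extract_patches(v2, cfg)
  # index = ((tt-1)*P + (hh-1))*P + ww = ((2-1)*4 + 0)*4 + 3
  expect_equal(unname(which(g2$tokens[1, ] != 0)), (1 * 4 + 0) * 4 + 3)
})

test_that("embedding assembles class token, projections and positions", {
  cfg <- tiny_vit()
  g <- tiny_grid(t_len = 4, cfg)
  p <- vit_init(cfg, nrow(g$tokens), seed = 1)
  Z0 <- embed_and_assemble(g, p)
  expect_equal(nrow(Z0), nrow(g$tokens) + 1L)
  # all-zero patches leave only the positional embeddings
  g0 <- g; g0$tokens <- g$tokens * 0
  Z00 <- embed_and_assemble(g0, p)
  expect_equal(Z00[-1, ], p$E_pos[-1, ][seq_len(nrow(g$tokens)), ], ignore_attr = TRUE)
  expect_equal(Z00[1, ], drop(p$z_class + p$E_pos[1, ]))
  # identity-like embedding: D = Tp*P^2, E = I recovers the raw patches
  cfg_id <- vit_config(Tp = 1, P = 2, D = 4, h = 2, L = 1, ffn_dim = 8,
                       head_dims = c(3, 2), input_hw = 4)
  gid <- extract_patches(array(runif(1 * 4 * 4), c(1, 4, 4)), cfg_id)
  pid <- vit_init(cfg_id, nrow(gid$tokens), seed = 2)
  pid$E <- diag(4)
  Zid <- embed_and_assemble(gid, pid)
  expect_equal(Zid[-1, ] - pid$E_pos[2:(nrow(gid$tokens) + 1), ], gid$tokens,
               ignore_attr = TRUE)
  # capacity overflow is an explicit error
  psmall <- vit_init(cfg, 2, seed = 1)
  expect_error(embed_and_assemble(g, psmall), "positional table")
})

test_that("attention matrices are row-stochastic and match a per-head loop", {
  cfg <- tiny_vit()
  set.seed(9)
  for (case in 1:20) {
    n1 <- sample(2:12, 1)
    Z <- matrix(rnorm(n1 * cfg$D), n1)
    lp <- vit_init(cfg, 4, seed = case)$layers[[1]]
    cache <- mhsa(Z, lp, cfg$h, return_cache = TRUE)
    # independent brute-force oracle: loop over heads in plain R
    n <- nrow(Z)
    Q <- Z %*% lp$Wq + rep(lp$bq, each = n)
    K <- Z %*% lp$Wk + rep(lp$bk, each = n)
    V <- Z %*% lp$Wv + rep(lp$bv, each = n)
    Dh <- cfg$D / cfg$h
    Hcat <- matrix(0, n, cfg$D)
    for (i in seq_len(cfg$h)) {
      idx <- ((i - 1) * Dh + 1):(i * Dh)
      S <- Q[, idx] %*% t(K[, idx]) / sqrt(Dh)
      A <- exp(S - apply(S, 1, max))
      A <- A / rowSums(A)
      expect_lt(max(abs(t(cache$attn_t[[i]]) - A)), 1e-5)
      expect_true(all(abs(rowSums(A) - 1) < 1e-5))
      Hcat[, idx] <- A %*% V[, idx]
    }
    ref <- Hcat %*% lp$Wo + rep(lp$bo, each = n)
    expect_lt(max(abs(cache$out - ref)), 1e-5)
  }
})

test_that("single-token attention is the identity weight", {
  cfg <- tiny_vit()
  Z <- matrix(rnorm(cfg$D), 1)
  lp <- vit_init(cfg, 2, seed = 3)$layers[[1]]
  cache <- mhsa(Z, lp, cfg$h, return_cache = TRUE)
  for (At in cache$attn_t) expect_equal(At, matrix(1, 1, 1))
  V <- Z %*% lp$Wv + rep(lp$bv, each = 1)
  expect_equal(cache$Hcat, V)
})

test_that("an encoder layer with zeroed output projections is the identity", {
  cfg <- tiny_vit()
  lp <- vit_init(cfg, 4, seed = 5)$layers[[1]]
  lp$Wo <- lp$Wo * 0; lp$bo <- lp$bo * 0
  lp$W2 <- lp$W2 * 0; lp$b2 <- lp$b2 * 0
  Z <- matrix(rnorm(6 * cfg$D), 6)
  expect_equal(encoder_layer(Z, lp, cfg$h), Z)
  # shape preservation for any sequence length
  for (n1 in c(1, 3, 9)) {
    Zn <- matrix(rnorm(n1 * cfg$D), n1)
    lp2 <- vit_init(cfg, 4, seed = 6)$layers[[1]]
    expect_equal(dim(encoder_layer(Zn, lp2, cfg$h)), dim(Zn))
  }
})

test_that("one encoder layer matches an independent step-by-step computation", {
  # 3-token sequence, hand-set small weights, recomputed with scalar-level
  # operations independent of the batched implementation
  D <- 4; h <- 2; Dh <- 2
  set.seed(8)
  Z <- matrix(round(rnorm(3 * D), 2), 3)
  lp <- list(ln1_g = c(1, 1.1, 0.9, 1), ln1_b = c(0, 0.1, -0.1, 0),
             Wq = matrix(round(rnorm(16, 0, 0.3), 2), 4),
             bq = c(0.1, 0, -0.1, 0.2),
             Wk = matrix(round(rnorm(16, 0, 0.3), 2), 4), bk = rep(0, 4),
             Wv = matrix(round(rnorm(16, 0, 0.3), 2), 4), bv = rep(0.05, 4),
             Wo = matrix(round(rnorm(16, 0, 0.3), 2), 4), bo = rep(0, 4),
             ln2_g = rep(1, 4), ln2_b = rep(0, 4),
             W1 = matrix(round(rnorm(32, 0, 0.3), 2), 4), b1 = rep(0, 8),
             W2 = matrix(round(rnorm(32, 0, 0.3), 2), 8), b2 = rep(0, 4))
  got <- encoder_layer(Z, lp, h)
  # --- independent recomputation, one scalar at a time ---
  ln <- function(x, g, b) {
    mu <- mean(x); va <- mean((x - mu)^2)
    g * (x - mu) / sqrt(va + 1e-5) + b
  }
  Zn <- t(vapply(1:3, function(i) ln(Z[i, ], lp$ln1_g, lp$ln1_b), numeric(D)))
  Q <- Zn %*% lp$Wq; K <- Zn %*% lp$Wk; V <- Zn %*% lp$Wv
  for (i in 1:3) Q[i, ] <- Q[i, ] + lp$bq
  for (i in 1:3) K[i, ] <- K[i, ] + lp$bk
  for (i in 1:3) V[i, ] <- V[i, ] + lp$bv
  Hc <- matrix(0, 3, D)
  for (head in 1:2) {
    cols <- if (head == 1) 1:2 else 3:4
    for (i in 1:3) {
      s <- numeric(3)
      for (j in 1:3) s[j] <- sum(Q[i, cols] * K[j, cols]) / sqrt(Dh)
      a <- exp(s - max(s)); a <- a / sum(a)
      for (cc in seq_along(cols)) {
        Hc[i, cols[cc]] <- sum(a * V[, cols[cc]])
      }
    }
  }
  Z1 <- Z + Hc %*% lp$Wo
  Zn2 <- t(vapply(1:3, function(i) ln(Z1[i, ], lp$ln2_g, lp$ln2_b), numeric(D)))
  Uq <- pmax(Zn2 %*% lp$W1, 0)
  want <- Z1 + Uq %*% lp$W2
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("the classification head behaves like a sigmoid scorer", {
  cfg <- tiny_vit()
  g <- tiny_grid(4, cfg)
  p <- vit_init(cfg, nrow(g$tokens), seed = 7)
  fw <- vit_forward(p, g)
  expect_equal(fw$y_hat, sigmoid(fw$logit))
  expect_true(fw$y_hat > 0 && fw$y_hat < 1)
  # all-zero head weights with bias b give sigmoid(b)
  p0 <- p
  p0$head <- lapply(p0$head, function(x) x * 0)
  p0$head$bc <- 0.7
  expect_equal(vit_forward(p0, g)$y_hat, sigmoid(0.7))
  # monotonicity in the logit
  expect_true(sigmoid(1.2) > sigmoid(0.3))
  # linear head variant
  cfgl <- tiny_vit(head_type = "linear")
  pl <- vit_init(cfgl, nrow(g$tokens), seed = 7)
  fwl <- vit_forward(pl, g)
  expect_equal(fwl$y_hat, sigmoid(fwl$logit))
})

test_that("BCE matches its closed forms and its logit gradient", {
  expect_equal(bce_loss(0.5, 1), log(2))
  expect_equal(bce_loss(0.5, 0), log(2))
  expect_lt(bce_loss(1 - 1e-9, 1), 1e-6)
  expect_equal(bce_loss_logit(0, 1), log(2))
  # stable and naive forms agree away from saturation
  for (z in c(-3, -0.5, 0.7, 4)) {
    expect_equal(bce_loss_logit(z, 1), bce_loss(sigmoid(z), 1), tolerance = 1e-10)
  }
  # d loss / d logit = y_hat - y, checked by central differences
  set.seed(10)
  for (i in 1:10) {
    z <- rnorm(1, 0, 2); y <- rbinom(1, 1, 0.5)
    eps <- 1e-6
    fd <- (bce_loss_logit(z + eps, y) - bce_loss_logit(z - eps, y)) / (2 * eps)
    expect_equal(fd, sigmoid(z) - y, tolerance = 1e-5)
  }
})

test_that("analytic parameter gradients match central finite differences", {
  cfg <- tiny_vit()
  g <- tiny_grid(4, cfg, seed = 3)
  p <- vit_init(cfg, nrow(g$tokens), seed = 4)
  y <- 1
  fw <- vit_forward(p, g, keep_cache = TRUE)
  gr <- vfssvit:::vit_backward(p, fw, fw$y_hat - y)
  loss_at <- function(pp) bce_loss_logit(vit_forward(pp, g)$logit, y)
  eps <- 1e-5
  set.seed(5)
  check <- function(getter, setter, garr) {
    arr <- getter(p)
    for (j in sample(length(arr), min(3, length(arr)))) {
      pp <- p
      a <- arr; a[j] <- a[j] + eps; pp <- setter(pp, a); l1 <- loss_at(pp)
      a[j] <- arr[j] - eps; pp <- setter(pp, a); l2 <- loss_at(pp)
      expect_equal((l1 - l2) / (2 * eps), garr[j], tolerance = 1e-6)
    }
  }
  check(function(p) p$E, function(p, a) { p$E <- a; p }, gr$E)
  check(function(p) p$E_pos, function(p, a) { p$E_pos <- a; p }, gr$E_pos)
  for (l in 1:2) {
    for (nm in c("Wq", "Wv", "W1", "ln1_g")) {
      check(function(p) p$layers[[l]][[nm]],
            function(p, a) { p$layers[[l]][[nm]] <- a; p },
            gr$layers[[l]][[nm]])
    }
  }
  check(function(p) p$head$Wh1, function(p, a) { p$head$Wh1 <- a; p }, gr$head$Wh1)
})

test_that("parameter count closed form equals the instantiated count", {
  cfg <- tiny_vit()
  p <- vit_init(cfg, 10, seed = 1)
  expect_equal(count_parameters(cfg, 10), vfssvit:::n_params(p))
  # additivity: one extra layer adds exactly the per-layer term
  cfg3 <- tiny_vit(L = 3)
  per_layer <- count_parameters(cfg3, 10) - count_parameters(cfg, 10)
  p3 <- vit_init(cfg3, 10, seed = 1)
  expect_equal(vfssvit:::n_params(p3) - vfssvit:::n_params(p), per_layer)
  # doubling D changes the count by the closed-form difference
  cfgD <- tiny_vit(D = 16, ffn_dim = 32, head_dims = c(6, 4))
  pD <- vit_init(cfgD, 10, seed = 1)
  expect_equal(count_parameters(cfgD, 10) - count_parameters(cfg, 10),
               vfssvit:::n_params(pD) - vfssvit:::n_params(p))
  # linear head variant
  cfgl <- tiny_vit(head_type = "linear")
  expect_equal(count_parameters(cfgl, 10),
               vfssvit:::n_params(vit_init(cfgl, 10, seed = 1)))
})

test_that("model output ignores patch order when positions are zeroed", {
  cfg <- tiny_vit()
  g <- tiny_grid(4, cfg, seed = 6)
  p <- vit_init(cfg, nrow(g$tokens), seed = 8)
  p$E_pos <- p$E_pos * 0
  base <- vit_forward(p, g)$logit
  set.seed(9)
  for (i in 1:20) {
    gp <- g
    gp$tokens <- g$tokens[sample(nrow(g$tokens)), , drop = FALSE]
    expect_equal(vit_forward(p, gp)$logit, base, tolerance = 1e-5)
  }
})

test_that("the forward pass is deterministic", {
  cfg <- tiny_vit()
  g <- tiny_grid(5, cfg, seed = 2)
  p <- vit_init(cfg, nrow(g$tokens), seed = 3)
  a <- vit_forward(p, g, collect_attention = TRUE)
  b <- vit_forward(p, g, collect_attention = TRUE)
  expect_identical(a$logit, b$logit)
  expect_identical(a$attn, b$attn)
})

test_that("isotropic resize is exact on identity and constants, mean-preserving", {
  st <- frame_stack(array(0.3, c(2, 256, 256)))
  expect_identical(resize_isotropic(st, 256)$frames, st$frames)
  out <- resize_isotropic(frame_stack(array(0.42, c(1, 100, 100))), 64)
  expect_equal(range(out$frames), c(0.42, 0.42))
  # 8-px checkerboard, 512 -> 256: mean preserved within 1%
  blk <- matrix(rep(rep(c(0, 1), each = 8), 32), 512, 512)
  board <- blk * 0 + outer(rep(rep(0:1, each = 8), 32), rep(rep(0:1, each = 8), 32),
                           function(a, b) as.numeric(xor(a, b)))
  stb <- frame_stack(array(board, c(1, 512, 512)))
  small <- resize_isotropic(stb, 256)$frames[1, , ]
  expect_lt(abs(mean(small) - mean(board)), 0.01)
})
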