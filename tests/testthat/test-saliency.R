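make_fit_stub <- function(cfg, n_tokens, seed = 1) {
  # a fitted-model shell around freshly initialized parameters, enough for
  # the saliency plumbing
  params <- vit_init(cfg, n_tokens, seed = seed)
  structure(list(params = params, config = cfg,
                 control = train_control(), capacity_tokens = n_tokens),
            class = "vfss_vit")
}

test_that("attention collection yields L x h row-stochastic matrices", {
  cfg <- tiny_vit()
  g <- tiny_grid(4, cfg, seed = 2)
  p <- vit_init(cfg, nrow(g$tokens), seed = 5)
  attn <- collect_attention(p, g)
  expect_length(attn, cfg$L)
  for (l in seq_len(cfg$L)) {
    expect_length(attn[[l]], cfg$h)
    for (A in attn[[l]]) {
      expect_equal(dim(A), rep(nrow(g$tokens) + 1L, 2))
      expect_true(all(abs(rowSums(A) - 1) < 1e-5))
      expect_true(all(A >= 0))
    }
  }
  expect_identical(attn, collect_attention(p, g))
})

test_that("rollout of identity attention is uniform over patch tokens", {
  n <- 6
  eye <- diag(n + 1)
  attn <- list(list(eye, eye), list(eye, eye))
  r <- attention_rollout(attn)
  expect_equal(r, rep(1 / n, n))
})

test_that("rollout always yields a probability vector", {
  cfg <- tiny_vit()
  g <- tiny_grid(4, cfg, seed = 3)
  for (s in 1:5) {
    p <- vit_init(cfg, nrow(g$tokens), seed = s)
    r <- attention_rollout(collect_attention(p, g))
    expect_true(all(r >= 0))
    expect_equal(sum(r), 1)
    expect_length(r, nrow(g$tokens))
  }
})

test_that("single-layer single-head rollout matches the hand computation", {
  A <- rbind(c(0.6, 0.3, 0.1),
             c(0.2, 0.5, 0.3),
             c(0.1, 0.1, 0.8))
  r <- attention_rollout(list(list(A)))
  # by hand: Abar = normalize(0.5 A + 0.5 I); class row = Abar[1, ]
  # row 1 of 0.5A + 0.5I = (0.8, 0.15, 0.05), row sum 1 -> unchanged
  # restrict to patch tokens (0.15, 0.05), normalize -> (0.75, 0.25)
  expect_equal(r, c(0.75, 0.25))
})

test_that("frame maps upsample, normalize and flag flat segments", {
  gs <- c(n_t = 2, n_h = 2, n_w = 2)
  r <- c(0, 0, 0, 1, 0.25, 0.25, 0.25, 0.25)  # seg 1 peaked, seg 2 flat
  maps <- frame_maps(r, gs, c(8, 8))
  expect_length(maps, 2)
  expect_true(all(vapply(maps, function(m) min(m) >= 0 && max(m) <= 1, logical(1))))
  # one-hot at (h=2, w=2): map peaks in the lower-right patch block
  peak <- which(maps[[1]] == max(maps[[1]]), arr.ind = TRUE)
  expect_true(all(peak[, 1] >= 5) && all(peak[, 2] >= 5))
  # flat slice -> all zeros, flagged
  expect_true(all(maps[[2]] == 0))
  expect_equal(attr(maps, "flat_segments"), c(FALSE, TRUE))
})

test_that("bilinear upsampling matches the closed-form interpolation", {
  sl <- matrix(c(0, 1, 2, 3), 2, 2)
  up <- vfssvit:::bilinear_resize(sl, 4, 4)
  # pixel-center alignment: output centers at input coords 0.75, 1.25, 1.75, 2.25
  # hand-computed tensor-product interpolation with border clamping
  want <- outer(c(0, 0.25, 0.75, 1), c(0, 0.5, 1.5, 2), `+`)
  expect_equal(up, want)
})

test_that("confidence weights are a proper distribution over frames", {
  cfg <- tiny_vit()
  fit <- make_fit_stub(cfg, 16)
  set.seed(4)
  # single segment: uniform 1/T
  fr1 <- array(runif(2 * 8 * 8), c(2, 8, 8))
  cw1 <- confidence_weights(fit$params, fr1)
  expect_equal(cw1$omega, rep(0.5, 2))
  # multi-segment: sums to one
  fr3 <- array(runif(6 * 8 * 8), c(6, 8, 8))
  cw3 <- confidence_weights(fit$params, fr3)
  expect_equal(sum(cw3$omega), 1)
  expect_length(cw3$segment_scores, 3)
  # identical segments get identical weights
  fr2 <- array(0, c(4, 8, 8))
  fr2[1:2, , ] <- fr1; fr2[3:4, , ] <- fr1
  cw2 <- confidence_weights(fit$params, fr2)
  expect_equal(cw2$omega, rep(0.25, 4))
})

test_that("the cumulative map is the omega-weighted sum and is linear", {
  m1 <- matrix(runif(16), 4); m2 <- matrix(runif(16), 4)
  maps <- list(m1, m2)
  omega <- c(0.1, 0.2, 0.3, 0.4)  # Tp = 2 -> frames 1:2 seg 1, 3:4 seg 2
  M <- cumulative_map(maps, omega, Tp = 2)
  expect_equal(M, 0.3 * m1 + 0.7 * m2)
  expect_equal(cumulative_map(list(m1), 1, Tp = 1), m1)
  expect_equal(cumulative_map(maps, rep(0, 4), 2), m1 * 0)
  expect_equal(cumulative_map(maps, 2 * omega, 2), 2 * M)
})

test_that("percentile mask selects the top decile inside the FOV", {
  fov <- matrix(FALSE, 10, 12)
  fov[1:10, 1:10] <- TRUE
  M <- matrix(0, 10, 12)
  M[fov] <- seq_len(100)  # linear ramp, all distinct
  omega <- threshold_mask(M, fov, percentile = 90)
  expect_equal(sum(omega), 10)
  expect_true(all(M[omega] > 90))
  expect_true(all(which(omega) %in% which(fov)))
  # raising the percentile shrinks the mask monotonically
  sizes <- vapply(c(50, 75, 90, 95), function(p) sum(threshold_mask(M, fov, p)),
                  numeric(1))
  expect_true(all(diff(sizes) < 0))
  # constant map -> empty mask, flagged
  flat <- threshold_mask(matrix(0.5, 10, 12), fov)
  expect_equal(sum(flat), 0)
  expect_true(attr(flat, "flat"))
})

test_that("mask coverage stays near 10 percent on continuous maps", {
  set.seed(12)
  fov <- make_fov_mask(64, 64)
  for (i in 1:5) {
    M <- matrix(runif(64 * 64), 64)
    frac <- sum(threshold_mask(M, fov)) / sum(fov)
    expect_gte(frac, 0.095)
    expect_lte(frac, 0.105)
  }
})

test_that("quiescent-frame selection finds static episodes", {
  set.seed(13)
  base <- matrix(runif(32 * 32), 32)
  # static clip: zero flow, first frame wins
  static <- array(rep(base, 6), c(32, 32, 6))
  static <- aperm(static, c(3, 1, 2))
  q <- quiescent_frame(static)
  expect_equal(q$index, 1L)
  expect_false(q$fallback)
  expect_true(all(q$mean_flow < 1e-8))
  # globally moving clip (1 px/frame translation), static only in frames
  # 10..14: the mean flow drops below threshold exactly there
  t_len <- 20
  pos <- c(1:9, rep(10, 5), 11:16)
  xs <- seq_len(32)
  smooth <- outer(sin(2 * pi * xs / 16), cos(2 * pi * xs / 11)) +
    0.5 * outer(cos(2 * pi * xs / 7), sin(2 * pi * xs / 23))
  smooth <- (smooth - min(smooth)) / diff(range(smooth))
  fr <- array(0, c(t_len, 32, 32))
  for (t in seq_len(t_len)) {
    shift <- pos[t] %% 32
    fr[t, , ] <- smooth[, c((shift + 1):32, seq_len(shift))]
  }
  q2 <- quiescent_frame(fr, flow_threshold = 0.5)
  expect_true(q2$index >= 10 && q2$index <= 14)
  # all-moving clip falls back to the minimum-flow frame
  fr3 <- array(0, c(5, 32, 32))
  for (t in 1:5) fr3[t, , 1:32] <- matrix(rep(seq_len(32) / 32, each = 32), 32) +
    t * outer(seq_len(32), seq_len(32), function(a, b) a / 40)
  q3 <- quiescent_frame(fr3, flow_threshold = 1e-9)
  expect_true(q3$fallback)
  expect_equal(q3$index, which.min(q3$mean_flow))
})

test_that("overlays have frame geometry and degrade cleanly without a mask", {
  set.seed(14)
  M <- matrix(runif(32 * 32), 32)
  frame <- matrix(runif(32 * 32), 32)
  empty <- matrix(FALSE, 32, 32)
  rgb <- overlay_saliency(M, empty, frame)
  expect_equal(dim(rgb), c(32, 32, 3))
  expect_gte(min(rgb), 0); expect_lte(max(rgb), 1)
  # empty mask: output equals the colormapped blend with no contour pixels
  mask <- threshold_mask(M, matrix(TRUE, 32, 32))
  rgb2 <- overlay_saliency(M, mask, frame)
  contour <- vfssvit:::mask_contour(mask)
  expect_true(all(rgb2[, , 2][contour] == 1))
  expect_equal(rgb2[, , 1][!mask], rgb[, , 1][!mask])
  expect_error(overlay_saliency(M, empty, frame[1:16, 1:16]), "must match")
  # PNG writer round-trip
  path <- tempfile(fileext = ".png")
  overlay_saliency(M, mask, frame, path = path)
  expect_true(file.exists(path))
  back <- png::readPNG(path)
  expect_equal(dim(back), c(32, 32, 3))
})

test_that("end-to-end saliency on a stub model is structurally sound", {
  cfg <- vit_config(Tp = 4, P = 8, D = 16, h = 2, L = 2, ffn_dim = 32,
                    head_dims = c(8, 4), input_hw = 32)
  fit <- make_fit_stub(cfg, 3 * 16)
  st <- tiny_study(n_subjects = 1, clips_per_subject = 1, frame_hw = 32,
                   length_range = c(9, 9), seed = 40)
  sal <- vfss_saliency(fit, st$clips[[1]])
  expect_s3_class(sal, "vfss_saliency")
  expect_equal(sum(sal$omega), 1)
  expect_equal(dim(sal$M), c(32, 32))
  expect_true(all(sal$mask %in% c(TRUE, FALSE)))
  expect_true(sum(sal$mask) <= 0.105 * sum(sal$fov_mask))
  expect_true(sal$quiescent$index >= 1 &&
              sal$quiescent$index <= dim(st$clips[[1]]$frames)[1])
})
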