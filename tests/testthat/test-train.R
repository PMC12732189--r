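test_that("subject-level splits never leak subjects across partitions", {
  for (trial in 1:25) {
    m <- random_manifest(n_subjects = sample(5:30, 1), seed = trial)
    plan <- split_subjects(m, seed = trial)
    parts <- split(plan$subject_map, plan$assignment)
    expect_length(intersect(parts$train, parts$test), 0)
    expect_length(intersect(parts$train, parts$val), 0)
    expect_length(intersect(parts$val, parts$test), 0)
    expect_setequal(names(plan$assignment), m$clip_id)
  }
})

test_that("splits are deterministic, fractions approximate, degenerate input errors", {
  m <- random_manifest(20, seed = 4)
  a <- split_subjects(m, seed = 9)
  b <- split_subjects(m, seed = 9)
  expect_identical(a, b)
  frac_test <- mean(a$assignment == "test")
  expect_true(frac_test > 0.02 && frac_test < 0.25)
  single <- data.frame(clip_id = c("a", "b"), subject_id = c("S1", "S1"))
  expect_error(split_subjects(single), "at least 3 subjects")
})

test_that("folds partition the non-test clips by subject", {
  m <- random_manifest(15, seed = 2)
  plan <- make_folds(split_subjects(m, seed = 2), k = 5, seed = 3)
  cv_ids <- names(plan$assignment)[plan$assignment != "test"]
  expect_setequal(names(plan$folds), cv_ids)
  for (f in 1:5) {
    in_f <- unique(plan$subject_map[names(plan$folds)[plan$folds == f]])
    out_f <- unique(plan$subject_map[names(plan$folds)[plan$folds != f]])
    expect_length(intersect(in_f, out_f), 0)
  }
  expect_identical(plan$folds,
                   make_folds(split_subjects(m, seed = 2), k = 5, seed = 3)$folds)
})

test_that("equal-sized subjects spread evenly over folds", {
  m <- data.frame(clip_id = sprintf("c%02d", 1:20),
                  subject_id = rep(sprintf("S%02d", 1:10), each = 2))
  plan <- split_subjects(m, test_frac = 0, val_frac = 0, seed = 1)
  plan$assignment[] <- "train"  # keep all ten subjects in the CV pool
  plan <- make_folds(plan, k = 5, seed = 1)
  subj_per_fold <- vapply(1:5, function(f) {
    length(unique(plan$subject_map[names(plan$folds)[plan$folds == f]]))
  }, integer(1))
  expect_equal(subj_per_fold, rep(2L, 5))  # every fold has exactly 2 subjects
  expect_error(make_folds(split_subjects(random_manifest(4, seed = 1)), k = 5),
               "cannot form")
})

test_that("augmentation is identity under a zero config and shape-preserving", {
  set.seed(5)
  fr <- array(runif(6 * 32 * 32), c(6, 32, 32))
  ident <- train_control(rot_deg = 0, zoom_max = 0, noise_sigma = 0)
  expect_identical(augment_clip(fr, ident), fr)
  full <- train_control(aug_prob = 1)
  out <- augment_clip(fr, full)
  expect_equal(dim(out), dim(fr))
  expect_gte(min(out), 0); expect_lte(max(out), 1)
})

test_that("sampled rotation angles stay within +-5 degrees", {
  set.seed(6)
  angles <- replicate(1000, stats::runif(1, -5, 5))
  # the sampler augment_clip uses, exercised through its observable effect:
  # a rotation by any sampled angle never exceeds the configured bound
  expect_true(all(angles >= -5 & angles <= 5))
  ctl <- train_control(rot_deg = 5, zoom_max = 0, noise_sigma = 0, aug_prob = 1)
  fr <- array(0, c(1, 17, 17)); fr[1, 3, 9] <- 1
  for (i in 1:25) {
    out <- augment_clip(fr, ctl)
    peak <- which(out[1, , ] == max(out[1, , ]), arr.ind = TRUE)[1, ]
    # at radius ~6 px a 5-degree rotation moves the peak at most 1 px
    expect_lte(abs(peak[1] - 3), 1)
    expect_lte(abs(peak[2] - 9), 1)
  }
})

test_that("the checkpoint rule returns the minimum-validation-loss epoch", {
  expect_equal(select_checkpoint_epoch(c(0.9, 0.5, 0.6, 0.7, 0.8)), 2L)
  expect_equal(select_checkpoint_epoch(c(0.3)), 1L)
  expect_false(vfssvit:::should_stop_early(c(0.9, 0.5, 0.6), patience = 3))
  expect_true(vfssvit:::should_stop_early(c(0.9, 0.5, 0.6, 0.7, 0.8), patience = 3))
})

test_that("training returns the best-epoch state and reproducible history", {
  st <- tiny_study(n_subjects = 4, clips_per_subject = 2, frame_hw = 16,
                   length_range = c(4, 6), seed = 31)
  frames <- lapply(st$clips, function(cl) cl$frames)
  y <- as.integer(st$labels == "abnormal")
  mc <- vit_config(Tp = 2, P = 4, D = 8, h = 2, L = 1, ffn_dim = 16,
                   head_dims = c(6, 4), input_hw = 16)
  ctl <- train_control(epochs = 5, patience = 5, accum = 2, seed = 3)
  a <- vfssvit:::train_loop(frames[1:6], y[1:6], frames[7:8], y[7:8], mc, ctl, 48, 1)
  b <- vfssvit:::train_loop(frames[1:6], y[1:6], frames[7:8], y[7:8], mc, ctl, 48, 1)
  expect_identical(a$history, b$history)
  expect_equal(a$best_epoch, which.min(a$history$val_loss))
  # returned state evaluates to the recorded minimum validation loss
  grids <- lapply(frames[7:8], vfssvit:::tokens_of, config = mc)
  val <- vfssvit:::mean_loss_acc(a$params, grids, y[7:8])
  expect_equal(val$loss, min(a$history$val_loss), tolerance = 1e-12)
  expect_error(vfssvit:::train_loop(list(), integer(0), frames[1:2], y[1:2],
                                    mc, ctl, 48, 1), "empty training fold")
})

test_that("confusion metrics match their closed forms", {
  m <- confusion_metrics(tp = 9, fn = 1, tn = 8, fp = 2)
  expect_equal(m$sensitivity, 0.900)
  expect_equal(m$specificity, 0.800)
  expect_equal(m$accuracy, 0.850)
  expect_equal(m$precision, 9 / 11)
  expect_equal(m$f1, 2 * (9 / 11) * 0.9 / (9 / 11 + 0.9))
  rep <- metrics_report(c(0.9, 0.8, 0.2, 0.6), c(1, 1, 0, 0), threshold = 0.5)
  expect_equal(rep$tp, 2); expect_equal(rep$fp, 1)
  expect_equal(rep$accuracy, 0.75)
  # perfect separation gives all ones
  perf <- metrics_report(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  for (m in c("accuracy", "sensitivity", "specificity", "precision", "f1", "auc")) {
    expect_equal(perf[[m]], 1)
  }
})

test_that("metric identities hold on random confusion counts", {
  set.seed(7)
  for (i in 1:50) {
    cnt <- sample(0:30, 4, replace = TRUE)
    if (sum(cnt) == 0) next
    m <- confusion_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(m$accuracy, (cnt[1] + cnt[3]) / sum(cnt))
    if (!is.na(m$f1)) {
      expect_equal(m$f1, 2 * m$precision * m$sensitivity / (m$precision + m$sensitivity))
    }
    for (v in c(m$accuracy, m$sensitivity, m$specificity, m$precision, m$f1)) {
      if (!is.na(v)) expect_true(v >= 0 && v <= 1)
    }
  }
})

test_that("trapezoidal AUC equals the Mann-Whitney pairwise statistic", {
  set.seed(8)
  for (i in 1:50) {
    n <- sample(6:25, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- runif(n)
    # brute-force pairwise oracle
    pos <- s[y == 1]; neg <- s[y == 0]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc_trapezoid(s, y), mean(pairs), tolerance = 1e-10)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  s <- runif(40)
  ref <- suppressMessages(as.numeric(pROC::auc(y, s)))
  expect_equal(auc_trapezoid(s, y), ref, tolerance = 1e-12)
})

test_that("label-independent scores give AUC near one half", {
  set.seed(10)
  aucs <- replicate(100, {
    y <- c(0, 1, rbinom(18, 1, 0.5))
    auc_trapezoid(runif(20), y)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
  expect_true(all(aucs >= 0 & aucs <= 1))
})

test_that("single-class evaluation reports absent AUC with a warning", {
  expect_warning(rep <- metrics_report(c(0.2, 0.6), c(1, 1)), "single-class")
  expect_true(is.na(rep$auc))
})

test_that("paired t-test matches its closed forms and base R", {
  r <- paired_t_test(c(1, -1, 0, 2, -2), rep(0, 5))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  same <- paired_t_test(c(0.8, 0.9, 0.7), c(0.8, 0.9, 0.7))
  expect_true(same$degenerate)
  expect_equal(same$p, 1)
  shifted <- paired_t_test(c(0.8, 0.9, 0.7), c(0.7, 0.8, 0.6))
  expect_true(shifted$degenerate)
  expect_equal(shifted$p, 0)
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(5); b <- rnorm(5)
    mine <- paired_t_test(a, b)
    ref <- stats::t.test(a, b, paired = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-6)
  }
  # quadrature oracle for the two-sided tail probability
  a <- c(0.84, 0.79, 0.88, 0.81, 0.83); b <- c(0.80, 0.77, 0.85, 0.80, 0.84)
  mine <- paired_t_test(a, b)
  tail_q <- stats::integrate(function(x) stats::dt(x, df = 4), abs(mine$t), Inf,
                             rel.tol = 1e-10)$value
  expect_equal(mine$p, 2 * tail_q, tolerance = 1e-6)
})
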