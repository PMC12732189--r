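norm_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- !labels %in% c("normal", "abnormal")
    if (any(bad)) stop("labels must be 'normal'/'abnormal' (or 0/1)")
    as.integer(labels == "abnormal")
  } else {
    stopifnot(all(labels %in% c(0, 1)))
    as.integer(labels)
  }
}

frames_of <- function(clip) {
  if (inherits(clip, "frame_stack")) clip$frames else clip
}

# Subject-level holdout of roughly `frac` of clips, greedy by clip count.
subject_holdout <- function(subjects, frac, seed) {
  uniq <- unique(subjects)
  if (length(uniq) < 2L) stop("need at least 2 subjects for a validation holdout")
  target <- frac * length(subjects)
  with_seed(seed, {
    ord <- sample(uniq)
    held <- character(0)
    count <- 0
    for (s in ord) {
      if (count >= target) break
      held <- c(held, s)
      count <- count + sum(subjects == s)
    }
    if (length(held) == length(uniq)) held <- held[-length(held)]
    subjects %in% held
  })
}

#' Fit the vision transformer swallow-study classifier
#'
#' Trains the 3D-patch transformer on a collection of preprocessed clips with
#' binary study-level labels. Training uses Adam under binary cross-entropy,
#' per-clip augmentation, and early stopping: the returned parameters are the
#' state at the epoch of minimum validation loss, never the final epoch. The
#' validation set is held out at the subject level (clips of one subject are
#' never split between training and validation).
#'
#' @param clips list of [frame_stack()]s (or bare `T x H x W` arrays) with
#'   intensities in `[0, 1]`; frames are isotropically resized to
#'   `model$input_hw` if needed.
#' @param labels per-clip labels: `"normal"`/`"abnormal"` or 0/1
#'   (1 = abnormal).
#' @param subjects per-clip subject identifiers; defaults to the
#'   `subject_id` fields of `clips`.
#' @param model a [vit_config()].
#' @param control a [train_control()].
#' @param val_frac fraction of clips (by subject) held out for validation
#'   when no explicit validation set is given.
#' @param val_clips,val_labels explicit validation set (overrides
#'   `val_frac`).
#' @param capacity_frames positional-table capacity in frames (defaults to
#'   the longest clip seen here; clips longer than this at prediction time
#'   raise a capacity error rather than being silently truncated).
#' @return an object of class `vfss_vit` with `print`, `summary`, `coef`,
#'   `predict`, `plot`, `residuals`, `fitted` and `simulate` methods.
#' @export
vfss_vit <- function(clips, labels, subjects = NULL, model = vit_config(),
                     control = train_control(), val_frac = 0.2,
                     val_clips = NULL, val_labels = NULL,
                     capacity_frames = NULL) {
  stopifnot(length(clips) == length(labels))
  y <- norm_labels(labels)
  if (is.null(subjects)) {
    subjects <- vapply(clips, function(cl) {
      if (inherits(cl, "frame_stack")) cl$subject_id else NA_character_
    }, character(1))
  }
  frames <- lapply(clips, frames_of)
  if (is.null(val_clips)) {
    is_val <- subject_holdout(subjects, val_frac, derive_seed(control$seed, "valsplit"))
    val_frames <- frames[is_val]; y_val <- y[is_val]
    train_frames <- frames[!is_val]; y_train <- y[!is_val]
  } else {
    val_frames <- lapply(val_clips, frames_of)
    y_val <- norm_labels(val_labels)
    train_frames <- frames; y_train <- y
  }
  if (length(val_frames) == 0L) stop("validation set is empty")
  max_T <- max(vapply(c(train_frames, val_frames), function(f) dim(f)[1], numeric(1)))
  cap_frames <- max(capacity_frames %||% max_T, max_T)
  n_t_max <- ceiling(cap_frames / model$Tp)
  capacity_tokens <- n_t_max * (model$input_hw %/% model$P)^2
  # resize once up front so augmentation operates at model resolution
  pre <- function(f) {
    d <- dim(f)
    if (d[2] == model$input_hw && d[3] == model$input_hw) return(f)
    out <- array(0, c(d[1], model$input_hw, model$input_hw))
    for (t in seq_len(d[1])) {
      out[t, , ] <- clamp01(bilinear_resize(f[t, , ], model$input_hw, model$input_hw))
    }
    out
  }
  train_frames <- lapply(train_frames, pre)
  val_frames <- lapply(val_frames, pre)
  # multi-start: retry (reseeded) when a run never escaped chance level
  res <- NULL
  for (try in 0:control$restarts) {
    ctl_try <- control
    ctl_try$seed <- derive_seed(control$seed, paste0("try", try))
    attempt <- train_loop(train_frames, y_train, val_frames, y_val, model,
                          ctl_try, capacity_tokens,
                          init_seed = derive_seed(ctl_try$seed, "init"))
    attempt$n_restarts <- try
    if (is.null(res) || min(attempt$history$val_loss) < min(res$history$val_loss)) {
      res <- attempt
    }
    if (min(res$history$val_loss) <= control$restart_val_loss) break
  }
  train_grids <- lapply(train_frames, tokens_of, config = model)
  fitted_probs <- vapply(train_grids, function(g) vit_forward(res$params, g)$y_hat,
                         numeric(1))
  structure(list(params = res$params, config = model, control = control,
                 history = res$history, best_epoch = res$best_epoch,
                 best_val_loss = min(res$history$val_loss),
                 n_restarts = res$n_restarts,
                 y = y_train, fitted_values = fitted_probs,
                 subjects = subjects,
                 capacity_tokens = capacity_tokens,
                 n_train = length(train_frames), n_val = length(val_frames),
                 call = match.call()),
            class = "vfss_vit")
}

#' @export
print.vfss_vit <- function(x, ...) {
  cat("Vision transformer VFSS classifier\n")
  cat(sprintf("  %d training / %d validation clips; %s parameters\n",
              x$n_train, x$n_val, format(n_params(x$params), big.mark = ",")))
  print(x$config)
  cat(sprintf("  best epoch %d of %d run (val loss %.4f)\n",
              x$best_epoch, nrow(x$history), x$best_val_loss))
  invisible(x)
}

#' @export
summary.vfss_vit <- function(object, ...) {
  h <- object$history
  best <- h[object$best_epoch, ]
  structure(list(fit = object,
                 n_parameters = n_params(object$params),
                 epochs_run = nrow(h), best = best,
                 train_acc = best$train_acc, val_acc = best$val_acc),
            class = "summary.vfss_vit")
}

#' @export
print.summary.vfss_vit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  at best epoch: train loss %.4f acc %.3f | val loss %.4f acc %.3f\n",
              x$best$train_loss, x$best$train_acc, x$best$val_loss, x$best$val_acc))
  invisible(x)
}

#' @export
coef.vfss_vit <- function(object, ...) {
  trainable_part(object$params)
}

#' Predict on new clips
#'
#' @param object a fitted `vfss_vit`.
#' @param newdata a list of clips ([frame_stack()] or array), or a single
#'   clip.
#' @param type `"prob"` (abnormality probability), `"class"`, or `"logit"`.
#' @param ... unused.
#' @export
predict.vfss_vit <- function(object, newdata,
                             type = c("prob", "class", "logit"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "frame_stack") || is.array(newdata)) newdata <- list(newdata)
  out <- vapply(newdata, function(cl) {
    grid <- tokens_of(frames_of(cl), object$config)
    fw <- vit_forward(object$params, grid)
    if (type == "logit") fw$logit else fw$y_hat
  }, numeric(1))
  if (type == "class") {
    out <- ifelse(out >= object$control$decision_threshold, "abnormal", "normal")
  }
  out
}

#' @export
fitted.vfss_vit <- function(object, ...) object$fitted_values

#' @export
residuals.vfss_vit <- function(object, ...) object$y - object$fitted_values

#' @export
plot.vfss_vit <- function(x, ...) {
  h <- x$history
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "BCE loss",
                 ylim = range(c(h$train_loss, h$val_loss)), ...)
  graphics::lines(h$epoch, h$val_loss, lty = 2)
  graphics::abline(v = x$best_epoch, col = "grey60")
  graphics::legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  graphics::plot(h$epoch, h$train_acc, type = "l", xlab = "epoch", ylab = "accuracy",
                 ylim = c(0, 1), ...)
  graphics::lines(h$epoch, h$val_acc, lty = 2)
  graphics::abline(v = x$best_epoch, col = "grey60")
  invisible(x)
}

#' @export
simulate.vfss_vit <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    p <- object$fitted_values
    out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1, p)))
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}

#' Save / load a fitted model checkpoint
#'
#' The checkpoint is a versioned archive holding the architectural
#' configuration and all named parameter arrays.
#'
#' @param fit a `vfss_vit`.
#' @param path checkpoint file path.
#' @export
write_checkpoint <- function(fit, path) {
  saveRDS(list(schema = "vfssvit-checkpoint-1", fit = fit), path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$schema, "vfssvit-checkpoint-1")) {
    stop(sprintf("'%s' is not a recognized checkpoint (schema '%s')", path,
                 x$schema %||% "missing"))
  }
  x$fit
}

#' Subject-level k-fold cross-validation
#'
#' Reserves a subject-level test partition, splits the remaining subjects
#' into `k` folds, and trains one freshly initialized model per fold (fold
#' `f` is the validation/early-stopping set for model `f`). Reports per-fold
#' validation metrics, their mean and standard deviation, and each fold
#' model's metrics on the untouched test partition.
#'
#' @param clips,labels,subjects as in [vfss_vit()].
#' @param model a [vit_config()].
#' @param control a [train_control()].
#' @param k number of folds.
#' @param test_frac clip fraction reserved for the held-out test partition.
#' @param seed seed for the split and folds.
#' @param keep_models retain the `k` fitted models in the result.
#' @return a `vfss_cv` object.
#' @export
cross_validate <- function(clips, labels, subjects = NULL, model = vit_config(),
                           control = train_control(), k = 5L, test_frac = 0.10,
                           seed = 1L, keep_models = FALSE) {
  y <- norm_labels(labels)
  if (is.null(subjects)) {
    subjects <- vapply(clips, function(cl) cl$subject_id, character(1))
  }
  manifest <- data.frame(clip_id = sprintf("clip%04d", seq_along(clips)),
                         subject_id = subjects, stringsAsFactors = FALSE)
  plan <- split_subjects(manifest, test_frac = test_frac, val_frac = 0,
                         seed = seed)
  plan <- make_folds(plan, k = k, seed = derive_seed(seed, "folds"))
  test_idx <- which(plan$assignment[manifest$clip_id] == "test")
  cv_idx <- which(manifest$clip_id %in% names(plan$folds))
  fold_rows <- NULL
  test_rows <- NULL
  models <- vector("list", k)
  for (f in seq_len(k)) {
    in_fold <- names(plan$folds)[plan$folds == f]
    val_i <- which(manifest$clip_id %in% in_fold)
    train_i <- setdiff(cv_idx, val_i)
    ctl <- control
    ctl$seed <- derive_seed(seed, paste0("fold", f))
    fit <- vfss_vit(clips[train_i], y[train_i], subjects[train_i],
                    model = model, control = ctl,
                    val_clips = clips[val_i], val_labels = y[val_i],
                    capacity_frames = max(vapply(clips, function(cl)
                      dim(frames_of(cl))[1], numeric(1))))
    val_scores <- predict(fit, clips[val_i])
    rep_val <- metrics_report(val_scores, y[val_i], control$decision_threshold)
    fold_rows <- rbind(fold_rows, data.frame(
      fold = f, n = rep_val$n, accuracy = rep_val$accuracy,
      sensitivity = rep_val$sensitivity, specificity = rep_val$specificity,
      precision = rep_val$precision, f1 = rep_val$f1, auc = rep_val$auc))
    if (length(test_idx) > 0) {
      test_scores <- predict(fit, clips[test_idx])
      rep_test <- metrics_report(test_scores, y[test_idx], control$decision_threshold)
      test_rows <- rbind(test_rows, data.frame(
        fold = f, n = rep_test$n, accuracy = rep_test$accuracy,
        sensitivity = rep_test$sensitivity, specificity = rep_test$specificity,
        precision = rep_test$precision, f1 = rep_test$f1, auc = rep_test$auc))
    }
    if (keep_models) models[[f]] <- fit
  }
  metric_cols <- c("accuracy", "sensitivity", "specificity", "precision", "f1", "auc")
  structure(list(fold_metrics = fold_rows,
                 mean = colMeans(fold_rows[metric_cols], na.rm = TRUE),
                 sd = vapply(fold_rows[metric_cols], stats::sd, numeric(1), na.rm = TRUE),
                 test_metrics = test_rows, plan = plan, k = k,
                 models = if (keep_models) models else NULL),
            class = "vfss_cv")
}

#' @export
print.vfss_cv <- function(x, ...) {
  cat(sprintf("<vfss_cv> %d-fold subject-level cross-validation\n", x$k))
  print(x$fold_metrics, row.names = FALSE, digits = 3)
  cat("mean +- sd:\n")
  for (m in names(x$mean)) {
    cat(sprintf("  %-12s %.3f +- %.3f\n", m, x$mean[[m]], x$sd[[m]]))
  }
  invisible(x)
}
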