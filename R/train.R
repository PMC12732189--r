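#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with learning rate `1e-3`,
#' up to 200 epochs, early stopping on the minimum validation loss, and
#' training-set augmentation by per-clip rotation (within +-5 degrees), zoom
#' (up to +10%) and additive Gaussian noise.
#'
#' @param epochs maximum training epochs.
#' @param lr Adam learning rate.
#' @param accum gradient-accumulation length (clips per optimizer step);
#'   clips vary in length, so batching is done by accumulation rather than
#'   padding.
#' @param patience epochs without validation-loss improvement before
#'   stopping.
#' @param min_delta smallest validation-loss decrease that counts as an
#'   improvement for the patience counter (the returned checkpoint always
#'   tracks the true minimum regardless).
#' @param clip_norm global gradient-norm ceiling per optimizer step (`Inf`
#'   disables). Small-batch transformer training produces rare huge
#'   gradients right when the loss starts to drop; clipping prevents a
#'   single step from destroying the emerging solution.
#' @param restarts maximum number of re-initializations when a training run
#'   ends with its best validation loss still at chance level (see
#'   `restart_val_loss`) — the multi-start treatment of a nonconvex fit
#'   whose warm-up occasionally outlasts the patience window.
#' @param restart_val_loss best-validation-loss threshold above which a
#'   finished run is considered never to have escaped warm-up.
#' @param rot_deg,zoom_max,noise_sigma augmentation ranges: rotation limit in
#'   degrees, maximum relative zoom-in, noise standard deviation.
#' @param aug_prob probability that each augmentation is applied to a clip.
#' @param decision_threshold probability cutoff for the abnormal call.
#' @param seed integer seed for initialization, shuffling and augmentation.
#' @param verbose print a line per epoch.
#' @export
train_control <- function(epochs = 200L, lr = 1e-3, accum = 8L, patience = 10L,
                          min_delta = 1e-3, clip_norm = 5, restarts = 3L,
                          restart_val_loss = 0.6, rot_deg = 5,
                          zoom_max = 0.1, noise_sigma = 0.01, aug_prob = 0.5,
                          decision_threshold = 0.5, seed = 1L, verbose = FALSE) {
  stopifnot(lr > 0, patience <= epochs, epochs >= 1, accum >= 1, min_delta >= 0,
            clip_norm > 0, restarts >= 0)
  structure(list(epochs = as.integer(epochs), lr = lr, accum = as.integer(accum),
                 patience = as.integer(patience), min_delta = min_delta,
                 clip_norm = clip_norm, restarts = as.integer(restarts),
                 restart_val_loss = restart_val_loss, rot_deg = rot_deg,
                 zoom_max = zoom_max, noise_sigma = noise_sigma,
                 aug_prob = aug_prob, decision_threshold = decision_threshold,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_control")
}

#' Subject-level train/validation/test split
#'
#' Greedy assignment of whole subjects to partitions so that clip-count
#' fractions approximate the targets; no subject ever spans partitions, which
#' is what prevents identity leakage between training and evaluation.
#'
#' @param manifest data frame with columns `clip_id` and `subject_id`.
#' @param test_frac,val_frac target clip fractions of the test partition and
#'   of the validation part of the remainder (defaults 0.10 and 0.20).
#' @param seed integer seed; same seed, same plan.
#' @return a `split_plan`: list with `assignment` (named character vector
#'   clip_id -> partition), `subject_map`, and empty `folds`.
#' @export
split_subjects <- function(manifest, test_frac = 0.10, val_frac = 0.20, seed = 1L) {
  stopifnot(all(c("clip_id", "subject_id") %in% names(manifest)))
  subjects <- unique(manifest$subject_id)
  if (length(subjects) < 3L) {
    stop("need at least 3 subjects to form train/validation/test partitions")
  }
  n_total <- nrow(manifest)
  targets <- c(test = test_frac * n_total,
               val = (1 - test_frac) * val_frac * n_total,
               train = (1 - test_frac) * (1 - val_frac) * n_total)
  counts <- c(test = 0, val = 0, train = 0)
  assignment_subj <- stats::setNames(character(length(subjects)), subjects)
  with_seed(seed, {
    order_subj <- sample(subjects)
    for (s in order_subj) {
      deficit <- ifelse(targets > 0, (targets - counts) / targets, -Inf)
      part <- names(which.max(deficit))
      assignment_subj[s] <- part
      counts[part] <- counts[part] + sum(manifest$subject_id == s)
    }
  })
  # guarantee every requested partition is non-empty
  for (part in names(targets)[targets > 0]) {
    if (!any(assignment_subj == part)) {
      donor <- names(which.max(table(assignment_subj)))
      victim <- names(assignment_subj)[assignment_subj == donor][1]
      assignment_subj[victim] <- part
    }
  }
  assignment <- stats::setNames(assignment_subj[manifest$subject_id], manifest$clip_id)
  structure(list(assignment = assignment,
                 subject_map = stats::setNames(manifest$subject_id, manifest$clip_id),
                 folds = NULL),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("<split_plan>", paste(sprintf("%s=%d", names(table(x$assignment)),
                                    table(x$assignment)), collapse = " "), "\n")
  if (!is.null(x$folds)) {
    cat("  folds:", paste(sprintf("%d=%d", as.integer(names(table(x$folds))),
                                  table(x$folds)), collapse = " "), "\n")
  }
  invisible(x)
}

#' Subject-level cross-validation folds
#'
#' Partitions the train+validation subjects into `k` folds of near-equal clip
#' counts (longest-processing-time heuristic); fold `f` serves as the
#' validation set when training model `f`.
#'
#' @param plan a `split_plan` from [split_subjects()].
#' @param k number of folds.
#' @param seed integer seed (breaks ties among equal-sized subjects).
#' @return the plan with `folds` filled in (named integer vector, clip_id ->
#'   fold; test clips absent).
#' @export
make_folds <- function(plan, k = 5L, seed = 1L) {
  cv_ids <- names(plan$assignment)[plan$assignment != "test"]
  subjects <- unique(plan$subject_map[cv_ids])
  if (length(subjects) < k) {
    stop(sprintf("cannot form %d folds from %d subjects", k, length(subjects)))
  }
  clip_counts <- table(plan$subject_map[cv_ids])[subjects]
  with_seed(seed, {
    ord <- order(-as.integer(clip_counts), sample(length(subjects)))
  })
  fold_of_subj <- stats::setNames(integer(length(subjects)), subjects)
  fold_sizes <- integer(k)
  for (i in ord) {
    f <- which.min(fold_sizes)
    fold_of_subj[subjects[i]] <- f
    fold_sizes[f] <- fold_sizes[f] + as.integer(clip_counts[i])
  }
  plan$folds <- stats::setNames(fold_of_subj[plan$subject_map[cv_ids]], cv_ids)
  plan
}

#' Augment a training clip
#'
#' One rotation angle in `[-rot_deg, rot_deg]` and one zoom factor in
#' `[1, 1 + zoom_max]` are sampled per clip and applied identically to every
#' frame; Gaussian noise is added per pixel. Each transform is applied
#' independently with probability `aug_prob`. Output is clipped to `[0, 1]`.
#'
#' @param frames `T x H x W` array in `[0, 1]`.
#' @param control a [train_control()] (fields `rot_deg`, `zoom_max`,
#'   `noise_sigma`, `aug_prob`).
#' @return augmented array of the same shape.
#' @export
augment_clip <- function(frames, control) {
  angle <- if (control$rot_deg > 0 && stats::runif(1) < control$aug_prob) {
    stats::runif(1, -control$rot_deg, control$rot_deg)
  } else 0
  zoom <- if (control$zoom_max > 0 && stats::runif(1) < control$aug_prob) {
    stats::runif(1, 1, 1 + control$zoom_max)
  } else 1
  if (angle != 0 || zoom != 1) {
    frames <- warp_clip(frames, angle, zoom)
  }
  if (control$noise_sigma > 0 && stats::runif(1) < control$aug_prob) {
    frames <- frames + stats::rnorm(length(frames), 0, control$noise_sigma)
  }
  clamp01(frames)
}

## ---- Adam over the nested parameter list ----

fmap_params <- function(f, ...) {
  walk <- function(...) {
    args <- list(...)
    if (is.list(args[[1]])) {
      out <- args[[1]]
      for (nm in seq_along(args[[1]])) {
        out[[nm]] <- do.call(walk, lapply(args, `[[`, nm))
      }
      out
    } else {
      do.call(f, args)
    }
  }
  walk(...)
}

trainable_part <- function(params) {
  params[c("E", "z_class", "E_pos", "layers", "ln_f_g", "ln_f_b", "head")]
}

adam_init <- function(params) {
  tp <- trainable_part(params)
  list(m = fmap_params(function(x) x * 0, tp),
       v = fmap_params(function(x) x * 0, tp),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- fmap_params(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- fmap_params(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- fmap_params(function(p, m, v) p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
                     trainable_part(params), state$m, state$v)
  params[names(upd)] <- upd
  list(params = params, state = state)
}

## ---- early stopping ----

#' Epoch selected by the minimum-validation-loss rule
#'
#' @param val_losses numeric vector of per-epoch validation losses.
#' @return the epoch index whose parameter state the training loop returns.
#' @export
select_checkpoint_epoch <- function(val_losses) which.min(val_losses)

# TRUE when `patience` epochs have elapsed since the last validation-loss
# improvement exceeding `min_delta`.
should_stop_early <- function(val_losses, patience, min_delta = 0) {
  best <- Inf
  last_improvement <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best - min_delta) last_improvement <- e
    best <- min(best, val_losses[e])
  }
  length(val_losses) - last_improvement >= patience
}

## ---- the training loop ----

tokens_of <- function(frames, config) {
  d <- dim(frames)
  if (d[2] != config$input_hw || d[3] != config$input_hw) {
    out <- array(0, c(d[1], config$input_hw, config$input_hw))
    for (t in seq_len(d[1])) {
      out[t, , ] <- clamp01(bilinear_resize(frames[t, , ], config$input_hw, config$input_hw))
    }
    frames <- out
  }
  extract_patches(frames, config)
}

mean_loss_acc <- function(params, grids, y, threshold = 0.5) {
  probs <- vapply(grids, function(g) vit_forward(params, g)$y_hat, numeric(1))
  list(loss = mean(bce_loss(probs, y)),
       acc = mean((probs >= threshold) == (y == 1)),
       probs = probs)
}

# Core fitting loop over preprocessed clips. Returns the parameter state at
# the epoch of minimum validation loss, the per-epoch history, and the
# selected epoch.
train_loop <- function(train_frames, y_train, val_frames, y_val,
                       config, control, capacity_tokens, init_seed) {
  if (length(train_frames) == 0L) stop("empty training fold")
  params <- vit_init(config, capacity_tokens, seed = init_seed)
  opt <- adam_init(params)
  val_grids <- lapply(val_frames, tokens_of, config = config)
  history <- data.frame(epoch = integer(), train_loss = double(),
                        train_acc = double(), val_loss = double(),
                        val_acc = double())
  best <- list(val_loss = Inf, params = params, epoch = 0L)
  val_losses <- c()
  n <- length(train_frames)
  for (epoch in seq_len(control$epochs)) {
    ep_seed <- derive_seed(control$seed, paste0("epoch", epoch))
    res <- with_seed(ep_seed, {
      ord <- sample(n)
      losses <- numeric(n)
      accum_grads <- NULL
      n_acc <- 0L
      correct <- 0L
      for (ii in seq_along(ord)) {
        i <- ord[ii]
        fr <- augment_clip(train_frames[[i]], control)
        grid <- extract_patches(fr, config)
        fw <- vit_forward(params, grid, keep_cache = TRUE)
        yi <- y_train[i]
        losses[ii] <- bce_loss_logit(fw$logit, yi)
        correct <- correct + ((fw$y_hat >= control$decision_threshold) == (yi == 1))
        g <- vit_backward(params, fw, fw$y_hat - yi)
        accum_grads <- if (is.null(accum_grads)) g else fmap_params(`+`, accum_grads, g)
        n_acc <- n_acc + 1L
        if (n_acc == control$accum || ii == n) {
          g_avg <- fmap_params(function(x) x / n_acc, accum_grads)
          if (is.finite(control$clip_norm)) {
            gn <- sqrt(sum(unlist(fmap_params(function(x) sum(x^2), g_avg))))
            if (gn > control$clip_norm) {
              sc <- control$clip_norm / gn
              g_avg <- fmap_params(function(x) x * sc, g_avg)
            }
          }
          st <- adam_step(params, g_avg, opt, control$lr)
          params <- st$params; opt <- st$state
          accum_grads <- NULL; n_acc <- 0L
        }
      }
      list(params = params, opt = opt, train_loss = mean(losses),
           train_acc = correct / n)
    })
    params <- res$params; opt <- res$opt
    val <- mean_loss_acc(params, val_grids, y_val, control$decision_threshold)
    val_losses <- c(val_losses, val$loss)
    history <- rbind(history, data.frame(epoch = epoch, train_loss = res$train_loss,
                                         train_acc = res$train_acc,
                                         val_loss = val$loss, val_acc = val$acc))
    if (val$loss < best$val_loss) {
      best <- list(val_loss = val$loss, params = params, epoch = epoch)
    }
    if (control$verbose) {
      message(sprintf("epoch %3d  train %.4f/%.3f  val %.4f/%.3f%s", epoch,
                      res$train_loss, res$train_acc, val$loss, val$acc,
                      if (best$epoch == epoch) " *" else ""))
    }
    if (should_stop_early(val_losses, control$patience, control$min_delta)) break
  }
  stopifnot(best$epoch == select_checkpoint_epoch(val_losses))
  list(params = best$params, best_epoch = best$epoch, history = history)
}
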