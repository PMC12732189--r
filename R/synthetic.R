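#' Configuration for the synthetic fluoroscopy phantom
#'
#' The generator emulates the features of a fluoroscopic swallowing clip that
#' the pipeline must handle: a circular detector field of view with dark
#' corners, a bright patient-information band across the top rows, a circular
#' targeting artifact in the early frames, a radio-opaque bolus blob advancing
#' along a pharyngeal path, and -- for abnormal clips -- bolus material
#' diverted into an anteriorly offset airway region from a sampled onset frame
#' onward, plus additive Gaussian noise. Each subject's anatomy is rigidly
#' jittered once and shared across that subject's clips, so subject-level
#' splitting is meaningful.
#'
#' @param n_subjects number of subjects.
#' @param clips_per_subject clips recorded per subject.
#' @param abnormal_fraction fraction of clips carrying the airway-invasion
#'   signature (default 0.475, matching a roughly balanced clinical mix).
#' @param frame_hw frame side length in pixels (square frames).
#' @param length_range integer range of clip lengths in frames; the lower end
#'   may be set below 25 to exercise the eligibility exclusion.
#' @param bolus_intensity peak grayscale amplitude of the bolus blob in
#'   normalized units.
#' @param invasion_intensity_fraction fraction of the bolus amplitude
#'   deposited in the airway region of abnormal clips, in (0, 1].
#' @param artifact_radius_range radius range (pixels) of the targeting
#'   artifact; default 5--15% of the frame side.
#' @param noise_sigma standard deviation of the additive Gaussian noise in
#'   normalized grayscale units.
#' @param subject_jitter_scale standard deviation (pixels) of the rigid
#'   per-subject anatomical translation.
#' @param fps frame rate attached to generated clips.
#' @param seed integer seed; fixed seed gives byte-identical studies.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_subjects = 40L, clips_per_subject = 5L,
                             abnormal_fraction = 0.475, frame_hw = 64L,
                             length_range = c(30L, 60L),
                             bolus_intensity = 0.8,
                             invasion_intensity_fraction = 0.5,
                             artifact_radius_range = NULL,
                             noise_sigma = 0.03,
                             subject_jitter_scale = 1.5,
                             fps = 25, seed = 1L) {
  stopifnot(n_subjects >= 0, clips_per_subject >= 0,
            abnormal_fraction >= 0, abnormal_fraction <= 1,
            length(length_range) == 2L, length_range[1] <= length_range[2],
            frame_hw >= 16)
  if (is.null(artifact_radius_range)) {
    artifact_radius_range <- c(0.05, 0.15) * frame_hw
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    clips_per_subject = as.integer(clips_per_subject),
    abnormal_fraction = abnormal_fraction,
    frame_hw = as.integer(frame_hw),
    length_range = as.integer(length_range),
    bolus_intensity = bolus_intensity,
    invasion_intensity_fraction = invasion_intensity_fraction,
    artifact_radius_range = artifact_radius_range,
    noise_sigma = noise_sigma,
    subject_jitter_scale = subject_jitter_scale,
    fps = fps,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Phantom anatomy for one subject
#'
#' Defines, in pixel coordinates, the pharyngeal path (a 3-segment polyline
#' from upper-center to lower-center of the field of view), the airway region
#' (a disk offset anteriorly from the path), the inscribed circular field of
#' view, and the height of the patient-information band. `jitter` translates
#' the path and airway rigidly, preserving their relative geometry, so normal
#' clips never receive bolus intensity inside the airway by construction.
#'
#' @param frame_hw frame side in pixels.
#' @param jitter length-2 numeric, rigid (x, y) translation in pixels.
#' @return a `vfss_anatomy` list.
#' @export
vfss_anatomy <- function(frame_hw, jitter = c(0, 0)) {
  s <- frame_hw
  path <- rbind(
    c(0.50, 0.18), c(0.56, 0.42), c(0.46, 0.66), c(0.52, 0.88)
  ) * s
  colnames(path) <- c("x", "y")
  path[, "x"] <- path[, "x"] + jitter[1]
  path[, "y"] <- path[, "y"] + jitter[2]
  airway_center <- c(x = 0.24 * s + jitter[1], y = 0.56 * s + jitter[2])
  structure(list(
    frame_hw = as.integer(s),
    path = path,
    airway_center = airway_center,
    airway_radius = 0.07 * s,
    bolus_sigma = 0.035 * s,
    fov_center = c(x = (s + 1) / 2, y = (s + 1) / 2),
    fov_radius = s / 2,
    band_rows = max(4L, round(0.12 * s)),
    jitter = jitter
  ), class = "vfss_anatomy")
}

# Distance-squared field from every pixel to a point (x, y); rows are y.
dist2_field <- function(h, w, x, y) {
  outer((seq_len(h) - y)^2, (seq_len(w) - x)^2, `+`)
}

# Position (x, y) a fraction u in [0,1] along a polyline by arc length.
polyline_point <- function(path, u) {
  seg <- diff(path)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  target <- u * cum[length(cum)]
  i <- max(which(cum <= target + 1e-12)[sum(cum <= target + 1e-12)], 1L)
  i <- min(i, nrow(seg))
  frac <- if (len[i] > 0) (target - cum[i]) / len[i] else 0
  path[i, ] + frac * seg[i, ]
}

# Logical disk mask of the airway region for an anatomy.
airway_mask <- function(anatomy) {
  s <- anatomy$frame_hw
  d2 <- dist2_field(s, s, anatomy$airway_center["x"], anatomy$airway_center["y"])
  d2 <= anatomy$airway_radius^2
}

fov_disk <- function(anatomy) {
  s <- anatomy$frame_hw
  d2 <- dist2_field(s, s, anatomy$fov_center["x"], anatomy$fov_center["y"])
  d2 <= anatomy$fov_radius^2
}

#' Render one synthetic swallow clip
#'
#' @param anatomy a [vfss_anatomy()].
#' @param label `"normal"` or `"abnormal"`.
#' @param length clip length in frames (>= 1).
#' @param config a [synthetic_config()].
#' @param seed integer seed controlling the clip's random draws (artifact
#'   placement, invasion onset, noise); same inputs and seed give a
#'   byte-identical stack.
#' @return a [frame_stack()]; abnormal clips carry attributes
#'   `invasion_onset` (first frame with airway deposit) and all clips carry
#'   `airway_mask` (the anatomy's airway disk).
#' @export
render_clip <- function(anatomy, label = c("normal", "abnormal"), length,
                        config = synthetic_config(), seed = 1L) {
  label <- match.arg(label)
  stopifnot(length >= 1)
  s <- anatomy$frame_hw
  if (s <= 0) stop("frame dimensions must be positive")
  frac <- config$invasion_intensity_fraction
  if (label == "abnormal" && (frac <= 0 || frac > 1)) {
    stop("invasion_intensity_fraction must be in (0, 1] for abnormal clips")
  }
  with_seed(seed, {
    t_len <- as.integer(length)
    art_r <- stats::runif(1, config$artifact_radius_range[1], config$artifact_radius_range[2])
    art_cx <- stats::runif(1, 0.58, 0.72) * s
    art_cy <- stats::runif(1, 0.25, 0.40) * s
    n_art <- min(8L, t_len)
    onset <- if (label == "abnormal") {
      lo <- max(1L, floor(t_len / 3))
      hi <- max(lo, floor(2 * t_len / 3))
      sample(lo:hi, 1L)
    } else NA_integer_
    fov <- fov_disk(anatomy)
    amask <- airway_mask(anatomy)
    # invasion deposit: soft disk, constant once deposited
    d2a <- dist2_field(s, s, anatomy$airway_center["x"], anatomy$airway_center["y"])
    deposit <- ifelse(amask,
                      frac * config$bolus_intensity *
                        exp(-d2a / (2 * (anatomy$airway_radius / 2)^2)), 0)
    # targeting artifact: a bright ring (1.2 px wall)
    d2r <- dist2_field(s, s, art_cx, art_cy)
    ring <- abs(sqrt(d2r) - art_r) <= 1.2
    trunc2 <- (2.5 * anatomy$bolus_sigma)^2
    frames <- array(0, c(t_len, s, s))
    for (t in seq_len(t_len)) {
      u <- if (t_len > 1) (t - 1) / (t_len - 1) else 0.5
      p <- polyline_point(anatomy$path, u)
      d2b <- dist2_field(s, s, p[1], p[2])
      f <- ifelse(d2b <= trunc2,
                  config$bolus_intensity * exp(-d2b / (2 * anatomy$bolus_sigma^2)), 0)
      if (!is.na(onset) && t >= onset) f <- f + deposit
      f[!fov] <- 0
      f[seq_len(anatomy$band_rows), ] <- 0.95
      if (t <= n_art) f[ring] <- 1
      frames[t, , ] <- f
    }
    if (config$noise_sigma > 0) {
      frames <- frames + stats::rnorm(length(frames), 0, config$noise_sigma)
      frames <- clamp01(frames)
    }
    out <- frame_stack(frames, fps = config$fps, label = label,
                       source_path = "synthetic")
    attr(out, "invasion_onset") <- onset
    attr(out, "airway_mask") <- amask
    attr(out, "artifact") <- c(cx = art_cx, cy = art_cy, r = art_r, n_frames = n_art)
    out
  })
}

#' Simulate a complete synthetic VFSS study collection
#'
#' Generates `n_subjects * clips_per_subject` clips. Each subject's anatomy is
#' jittered once (rigid translation, clamped to three standard deviations) and
#' reused for all of that subject's clips; abnormal labels are assigned to a
#' deterministic-count random subset of clips so the abnormal share matches
#' `abnormal_fraction` as closely as the clip count allows.
#'
#' @param config a [synthetic_config()].
#' @return a `vfss_study` list with elements `clips` (list of
#'   [frame_stack()]), `labels`, `subject_ids`, `invasion_masks` (binary
#'   matrix per clip; all-`FALSE` for normal clips), `airway_masks`, and
#'   `config`.
#' @export
simulate_vfss_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n_clips <- config$n_subjects * config$clips_per_subject
  with_seed(config$seed, {
    jitters <- lapply(seq_len(config$n_subjects), function(i) {
      j <- stats::rnorm(2, 0, config$subject_jitter_scale)
      pmin(pmax(j, -3 * config$subject_jitter_scale), 3 * config$subject_jitter_scale)
    })
    anatomies <- lapply(jitters, function(j) vfss_anatomy(config$frame_hw, j))
    subject_ids <- rep(sprintf("S%03d", seq_len(config$n_subjects)),
                       each = config$clips_per_subject)
    lengths <- sample(config$length_range[1]:config$length_range[2], n_clips,
                      replace = TRUE)
    n_abn <- round(config$abnormal_fraction * n_clips)
    abn_idx <- if (n_abn > 0) sample.int(n_clips, n_abn) else integer(0)
    labels <- rep("normal", n_clips)
    labels[abn_idx] <- "abnormal"
    clip_seeds <- sample.int(2147483646L, max(n_clips, 1L))
    clips <- vector("list", n_clips)
    invasion_masks <- vector("list", n_clips)
    airway_masks <- vector("list", n_clips)
    for (i in seq_len(n_clips)) {
      subj <- (i - 1L) %/% config$clips_per_subject + 1L
      st <- render_clip(anatomies[[subj]], labels[i], lengths[i], config,
                        seed = clip_seeds[i])
      st$subject_id <- subject_ids[i]
      clips[[i]] <- st
      am <- attr(st, "airway_mask")
      airway_masks[[i]] <- am
      invasion_masks[[i]] <- if (labels[i] == "abnormal") am else am & FALSE
    }
    structure(list(clips = clips, labels = labels, subject_ids = subject_ids,
                   invasion_masks = invasion_masks, airway_masks = airway_masks,
                   anatomies = anatomies, config = config),
              class = "vfss_study")
  })
}

#' @export
print.vfss_study <- function(x, ...) {
  cat(sprintf("<vfss_study> %d clips, %d subjects, %d abnormal (%.1f%%), %d x %d px\n",
              length(x$clips), length(unique(x$subject_ids)),
              sum(x$labels == "abnormal"),
              100 * mean(x$labels == "abnormal"),
              x$config$frame_hw, x$config$frame_hw))
  invisible(x)
}

#' Airway pixel-sum oracle score
#'
#' Mean intensity inside the clip's airway disk, averaged over frames. This
#' simple score separates normal from abnormal phantom clips (perfectly in the
#' noise-free case) and serves as an upper bound on attainable classifier
#' performance on the synthetic study.
#'
#' @param study a `vfss_study`.
#' @return numeric vector, one score per clip.
#' @export
airway_score <- function(study) {
  vapply(seq_along(study$clips), function(i) {
    m <- study$airway_masks[[i]]
    fr <- study$clips[[i]]$frames
    mean(apply(fr, 1L, function(f) mean(f[m])))
  }, numeric(1))
}
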