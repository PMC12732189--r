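# Shared fixtures: tiny phantom studies and model configurations sized for
# fast unit tests.

tiny_study <- function(n_subjects = 3, clips_per_subject = 2, noise = 0.02,
                       seed = 7, frame_hw = 64, length_range = c(26, 34), ...) {
  simulate_vfss_study(synthetic_config(
    n_subjects = n_subjects, clips_per_subject = clips_per_subject,
    noise_sigma = noise, frame_hw = frame_hw, length_range = length_range,
    seed = seed, ...))
}

tiny_vit <- function(...) {
  args <- list(Tp = 2, P = 4, D = 8, h = 2, L = 2, ffn_dim = 16,
               head_dims = c(6, 4), input_hw = 8)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(vit_config, args)
}

tiny_grid <- function(t_len = 4, config = tiny_vit(), seed = 1) {
  set.seed(seed)
  extract_patches(array(stats::runif(t_len * config$input_hw^2),
                        c(t_len, config$input_hw, config$input_hw)), config)
}

random_manifest <- function(n_subjects, max_clips = 6, seed = 1) {
  set.seed(seed)
  counts <- sample(max_clips, n_subjects, replace = TRUE)
  data.frame(
    clip_id = sprintf("c%04d", seq_len(sum(counts))),
    subject_id = rep(sprintf("S%03d", seq_len(n_subjects)), counts),
    stringsAsFactors = FALSE
  )
}
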