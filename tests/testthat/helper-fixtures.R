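# Shared fixtures, built in code.

std_arena <- function() arena_geometry(c(400, 400), c(60, 140, 220, 300))

# Constant-colour RGB frame in [0, 1].
const_frame <- function(h, w, rgb) {
  array(rep(rgb, each = h * w), c(h, w, 3))
}

random_frames <- function(n, h, w, seed) {
  withr::with_seed(seed, replicate(n, array(stats::runif(h * w * 3),
                                            c(h, w, 3)), simplify = FALSE))
}

# Rigid track translating along +x at `step` px/frame (7 standard points).
linear_track <- function(n_frames, step = 2, origin = c(100, 100),
                         inter_ear = 20) {
  template <- ethomanifold:::mouse_template(inter_ear)
  coords <- array(0, c(n_frames, nrow(template), 2))
  for (t in seq_len(n_frames))
    coords[t, , ] <- sweep(template, 2,
                           origin + c(step * (t - 1), 0), "+")
  keypoint_track(coords, rownames(template))
}

# Displace every key point of a track by i.i.d. Gaussian noise.
jitter_track <- function(track, sd, seed) {
  withr::with_seed(seed, {
    track$coordinates <- track$coordinates +
      array(stats::rnorm(length(track$coordinates), 0, sd),
            dim(track$coordinates))
  })
  track
}

# Point cloud with an exactly prescribed sample covariance and zero mean.
cloud_with_cov <- function(n, sigma, seed = 1) {
  withr::with_seed(seed,
    MASS::mvrnorm(n, mu = rep(0, ncol(sigma)), Sigma = sigma,
                  empirical = TRUE))
}

# Minimal classifier_report for compare_reports tests.
fake_report <- function(values, n_repeats = length(values)) {
  pr <- data.frame(accuracy = values, precision = values, recall = values,
                   f1 = values)
  structure(list(per_repeat = pr, mean = colMeans(pr),
                 sem = apply(pr, 2, stats::sd) / sqrt(n_repeats),
                 n_repeats = n_repeats, seed = 0L, condition = "original",
                 groups = c("A", "B")),
            class = "classifier_report")
}

# Study-condition cohort: `baseline` uses the generator defaults, `compact`
# raises event rate and shared fraction (see the methods vignette).
study_cohort <- function(cohort_seed, sessions_per_group = 12,
                         n_neurons = 80, n_frames = 4500,
                         compact = list(event_rate = 5,
                                        shared_factor = 0.9)) {
  recs <- list()
  for (s in seq_len(sessions_per_group)) {
    recs[[length(recs) + 1L]] <- generate_calcium(
      synthetic_cohort_config(n_neurons = n_neurons, n_frames = n_frames,
                              group_tag = "baseline",
                              seed = cohort_seed * 1000L + s),
      session_id = sprintf("baseline_s%02d", s))
    recs[[length(recs) + 1L]] <- generate_calcium(
      synthetic_cohort_config(n_neurons = n_neurons, n_frames = n_frames,
                              event_rate = compact$event_rate,
                              shared_factor = compact$shared_factor,
                              group_tag = "compact",
                              seed = cohort_seed * 1000L + 500L + s),
      session_id = sprintf("compact_s%02d", s))
  }
  recs
}
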