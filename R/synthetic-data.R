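# Synthetic cohort generation: calcium traces, behavior tracks, key-point
# trajectories and arena images. Every downstream stage of the package can be
# exercised on these objects without any recorded data.

#' Configuration for a synthetic calcium session
#'
#' Describes one simulated miniscope session: sparse calcium events per neuron
#' drawn as Bernoulli trains at `event_rate`, a fraction `shared_factor` of
#' which is copied from a single population-wide event train (inducing
#' neuron-to-neuron correlation), convolved with a difference-of-exponentials
#' transient kernel and passed through a saturating indicator response before
#' additive Gaussian noise.
#'
#' The kernel is peak-normalized to 1, so fluorescence is in units of a single
#' isolated transient's peak. `f_ceiling` models the finite dynamic range of
#' the indicator: the noiseless drive `x` is mapped to
#' `f_ceiling * (1 - exp(-x / f_ceiling))`, which is linear for small `x` and
#' saturates at `f_ceiling`. `f_ceiling = Inf` gives the purely linear model.
#'
#' @param n_neurons Number of neurons (>= 1).
#' @param n_frames Number of frames (>= 1).
#' @param fps Sampling rate in Hz, default 15.
#' @param event_rate Expected calcium events per second per neuron.
#' @param kernel_rise Transient rise time constant, seconds.
#' @param kernel_decay Transient decay time constant, seconds.
#' @param shared_factor Fraction in \[0, 1\] of each neuron's event train taken
#'   from the population-wide train.
#' @param noise_sd Additive Gaussian noise SD (a.u.).
#' @param f_ceiling Indicator saturation ceiling in units of single-transient
#'   peak amplitude; `Inf` disables saturation.
#' @param group_tag Free-text group label carried into downstream metadata.
#' @param seed Integer seed; all randomness of [generate_calcium()] flows
#'   from it.
#' @return An object of class `synthetic_cohort_config`.
#' @seealso [generate_calcium()]
#' @export
synthetic_cohort_config <- function(n_neurons = 80, n_frames = 4500, fps = 15,
                                    event_rate = 0.1, kernel_rise = 0.07,
                                    kernel_decay = 0.6, shared_factor = 0.6,
                                    noise_sd = 0.05, f_ceiling = 0.3,
                                    group_tag = "WT", seed = 1L) {
  check_scalar_num(n_neurons, "n_neurons", lower = 1, integer = TRUE)
  check_scalar_num(n_frames, "n_frames", lower = 1, integer = TRUE)
  check_scalar_num(fps, "fps", lower = 1e-12)
  check_scalar_num(event_rate, "event_rate", lower = 0)
  check_scalar_num(kernel_rise, "kernel_rise", lower = 1e-12)
  check_scalar_num(kernel_decay, "kernel_decay", lower = 1e-12)
  if (kernel_decay <= kernel_rise)
    abort_input("`kernel_decay` must exceed `kernel_rise`")
  check_scalar_num(shared_factor, "shared_factor", lower = 0, upper = 1)
  check_scalar_num(noise_sd, "noise_sd", lower = 0)
  if (!(is.numeric(f_ceiling) && length(f_ceiling) == 1L && f_ceiling > 0))
    abort_input("`f_ceiling` must be a single positive number (or Inf)")
  stopifnot(is.character(group_tag), length(group_tag) == 1L)
  check_scalar_num(seed, "seed", integer = TRUE)
  structure(list(n_neurons = as.integer(n_neurons),
                 n_frames = as.integer(n_frames), fps = fps,
                 event_rate = event_rate, kernel_rise = kernel_rise,
                 kernel_decay = kernel_decay, shared_factor = shared_factor,
                 noise_sd = noise_sd, f_ceiling = f_ceiling,
                 group_tag = group_tag, seed = as.integer(seed)),
            class = "synthetic_cohort_config")
}

#' Calcium recording container
#'
#' A neurons-by-frames fluorescence matrix with sampling rate and session
#' metadata. Rows are neurons, columns frames.
#'
#' @param fluorescence Numeric matrix \[n_neurons x n_frames\], all finite.
#' @param fps Sampling rate in Hz.
#' @param session_id,mouse_id,group_tag Metadata strings.
#' @return An object of class `calcium_recording`.
#' @export
calcium_recording <- function(fluorescence, fps, session_id = "s1",
                              mouse_id = "m1", group_tag = "WT") {
  if (!is.matrix(fluorescence) || !is.numeric(fluorescence) ||
      nrow(fluorescence) < 1L || ncol(fluorescence) < 1L)
    abort_input("`fluorescence` must be a non-empty numeric matrix")
  if (!all(is.finite(fluorescence)))
    abort_input("`fluorescence` contains non-finite values")
  check_scalar_num(fps, "fps", lower = 1e-12)
  structure(list(fluorescence = fluorescence, fps = fps,
                 session_id = session_id, mouse_id = mouse_id,
                 group_tag = group_tag),
            class = "calcium_recording")
}

#' @export
print.calcium_recording <- function(x, ...) {
  cat(sprintf("<calcium_recording> %d neurons x %d frames @ %g Hz [%s/%s/%s]\n",
              nrow(x$fluorescence), ncol(x$fluorescence), x$fps,
              x$group_tag, x$mouse_id, x$session_id))
  invisible(x)
}

# Difference-of-exponentials transient kernel, peak-normalized to 1.
calcium_kernel <- function(fps, rise, decay) {
  tt <- seq(0, 5 * decay, by = 1 / fps)
  k <- exp(-tt / decay) - exp(-tt / rise)
  k / max(k)
}

saturate <- function(x, ceiling) {
  if (!is.finite(ceiling)) return(x)
  ceiling * (1 - exp(-x / ceiling))
}

#' Generate a synthetic calcium recording
#'
#' Draws one session from the generative model described in
#' [synthetic_cohort_config()]. Deterministic given `config$seed`.
#'
#' @param config A [synthetic_cohort_config()].
#' @param session_id,mouse_id Metadata carried into the recording.
#' @return A [calcium_recording()].
#' @examples
#' rec <- generate_calcium(synthetic_cohort_config(n_neurons = 10,
#'                                                 n_frames = 300, seed = 7))
#' dim(rec$fluorescence)
#' @export
generate_calcium <- function(config, session_id = "s1", mouse_id = "m1") {
  if (!inherits(config, "synthetic_cohort_config"))
    abort_input("`config` must be created by synthetic_cohort_config()")
  with_seed(config$seed, {
    p <- min(1, config$event_rate / config$fps)
    n <- config$n_frames
    shared <- stats::rbinom(n, 1L, p)
    k <- calcium_kernel(config$fps, config$kernel_rise, config$kernel_decay)
    fl <- matrix(0, config$n_neurons, n)
    for (i in seq_len(config$n_neurons)) {
      own <- stats::rbinom(n, 1L, p)
      use_shared <- stats::rbinom(n, 1L, config$shared_factor)
      events <- ifelse(use_shared == 1L, shared, own)
      drive <- stats::convolve(events, rev(k), type = "open")[seq_len(n)]
      # convolution round-off can leave tiny negatives
      drive[drive < 0] <- 0
      fl[i, ] <- saturate(drive, config$f_ceiling) +
        stats::rnorm(n, 0, config$noise_sd)
    }
    calcium_recording(fl, config$fps, session_id = session_id,
                      mouse_id = mouse_id, group_tag = config$group_tag)
  })
}

#' Behavior label track container
#'
#' Per-frame labels over the three-class alphabet of [behavior_classes()],
#' optionally with a per-frame class-probability matrix (rows sum to 1).
#'
#' @param labels Character vector of per-frame labels.
#' @param probabilities Optional numeric matrix \[n_frames x 3\], columns in
#'   [behavior_classes()] order, each row summing to 1.
#' @return An object of class `behavior_label_track`.
#' @export
behavior_label_track <- function(labels, probabilities = NULL) {
  cls <- behavior_classes()
  if (!length(labels) || !all(labels %in% cls))
    abort_input("`labels` must be drawn from: ", paste(cls, collapse = ", "))
  if (!is.null(probabilities)) {
    if (!is.matrix(probabilities) || nrow(probabilities) != length(labels) ||
        ncol(probabilities) != 3L)
      abort_input("`probabilities` must be an n_frames x 3 matrix")
    if (any(abs(rowSums(probabilities) - 1) > 1e-9))
      abort_input("`probabilities` rows must sum to 1")
    colnames(probabilities) <- cls
  }
  structure(list(labels = as.character(labels), probabilities = probabilities),
            class = "behavior_label_track")
}

#' Generate a synthetic behavior label sequence
#'
#' Semi-Markov three-state sequence. State dwell times are geometric (in
#' frames) with the requested means in seconds; on leaving a state the next
#' state is drawn uniformly from the other two. A state with infinite mean
#' dwell is absorbing.
#'
#' @param n_frames Number of frames.
#' @param mean_dwell Named numeric vector of per-class mean dwell times in
#'   seconds (names from [behavior_classes()]); defaults running 2 s,
#'   sitting 4 s, grooming 3 s.
#' @param fps Sampling rate, Hz.
#' @param seed Integer seed.
#' @param start Optional start state; default drawn at random.
#' @return A [behavior_label_track()] (no probabilities).
#' @export
generate_behavior <- function(n_frames,
                              mean_dwell = c(running = 2, sitting = 4,
                                             grooming = 3),
                              fps = 15, seed = 1L, start = NULL) {
  check_scalar_num(n_frames, "n_frames", lower = 1, integer = TRUE)
  cls <- behavior_classes()
  if (is.null(names(mean_dwell))) names(mean_dwell) <- cls
  mean_dwell <- mean_dwell[cls]
  if (any(is.na(mean_dwell)) || any(mean_dwell <= 0))
    abort_input("`mean_dwell` must give a positive dwell for every class")
  if (!is.null(start) && !start %in% cls)
    abort_input("`start` must be one of: ", paste(cls, collapse = ", "))
  with_seed(seed, {
    state <- start %||% sample(cls, 1L)
    labels <- character(0)
    while (length(labels) < n_frames) {
      mean_frames <- mean_dwell[[state]] * fps
      dur <- if (is.finite(mean_frames)) {
        stats::rgeom(1L, 1 / mean_frames) + 1L
      } else {
        n_frames
      }
      labels <- c(labels, rep(state, dur))
      state <- sample(setdiff(cls, state), 1L)
    }
    behavior_label_track(labels[seq_len(n_frames)])
  })
}

#' Add simulated classifier probabilities to a label track
#'
#' Emulates the per-frame class-probability output of a behavior classifier:
#' the true class receives mass `1 - noise` on average, with Dirichlet-like
#' jitter, and a fraction `flip_rate` of frames has its probability mass
#' centred on a wrong class (transient misclassification).
#'
#' @param track A [behavior_label_track()].
#' @param noise Mean probability mass off the true class, in \[0, 1).
#' @param flip_rate Fraction of frames whose mode is flipped to a wrong class.
#' @param seed Integer seed.
#' @return A [behavior_label_track()] with a `probabilities` matrix (labels
#'   are the per-frame argmax of the noisy probabilities).
#' @export
simulate_label_probabilities <- function(track, noise = 0.2, flip_rate = 0.05,
                                         seed = 1L) {
  stopifnot(inherits(track, "behavior_label_track"))
  check_scalar_num(noise, "noise", lower = 0, upper = 1 - 1e-9)
  check_scalar_num(flip_rate, "flip_rate", lower = 0, upper = 1)
  cls <- behavior_classes()
  n <- length(track$labels)
  with_seed(seed, {
    mode_cls <- track$labels
    flip <- stats::runif(n) < flip_rate
    mode_cls[flip] <- vapply(mode_cls[flip],
                             function(s) sample(setdiff(cls, s), 1L), "")
    p <- matrix(stats::rgamma(n * 3L, shape = 1), n, 3L)
    p <- normalize_rows(p) * noise
    p[cbind(seq_len(n), match(mode_cls, cls))] <-
      p[cbind(seq_len(n), match(mode_cls, cls))] + (1 - noise)
    p <- normalize_rows(p)
    behavior_label_track(cls[max.col(p, ties.method = "first")], p)
  })
}

#' Key-point track container
#'
#' Per-frame 2-D pixel coordinates of named body key points. Must contain
#' `left_ear` and `right_ear` exactly once each.
#'
#' @param coordinates Numeric array \[n_frames x K x 2\] (px).
#' @param keypoint_names Character vector of K names.
#' @param confidence Optional \[n_frames x K\] matrix in \[0, 1\].
#' @return An object of class `keypoint_track`.
#' @export
keypoint_track <- function(coordinates, keypoint_names, confidence = NULL) {
  d <- dim(coordinates)
  if (length(d) != 3L || d[3] != 2L)
    abort_input("`coordinates` must be an n_frames x K x 2 array")
  if (length(keypoint_names) != d[2] || d[2] < 2L)
    abort_input("`keypoint_names` must name the K >= 2 key points")
  for (ear in c("left_ear", "right_ear"))
    if (sum(keypoint_names == ear) != 1L)
      abort_input(sprintf("key point `%s` must be present exactly once", ear))
  if (!all(is.finite(coordinates)))
    abort_input("`coordinates` contains non-finite values")
  if (!is.null(confidence)) {
    stopifnot(is.matrix(confidence), dim(confidence)[1] == d[1],
              dim(confidence)[2] == d[2],
              all(confidence >= 0 & confidence <= 1))
  }
  dimnames(coordinates) <- list(NULL, keypoint_names, c("x", "y"))
  structure(list(coordinates = coordinates,
                 keypoint_names = as.character(keypoint_names),
                 confidence = confidence),
            class = "keypoint_track")
}

# Rigid mouse template in units of the inter-ear distance (x forward).
mouse_template <- function(inter_ear_px) {
  pts <- rbind(nose      = c( 0.60,  0.00),
               left_ear  = c( 0.20,  0.50),
               right_ear = c( 0.20, -0.50),
               neck      = c( 0.00,  0.00),
               left_hip  = c(-0.70,  0.45),
               right_hip = c(-0.70, -0.45),
               tail_base = c(-1.10,  0.00))
  pts * inter_ear_px
}

#' Generate a smooth synthetic key-point trajectory
#'
#' A body frame (position + heading) performs a smooth bounded random walk
#' inside the arena's outer radius; seven named key points are rigidly
#' attached to it, so the inter-ear distance is exactly `inter_ear_px` on
#' every frame.
#'
#' @param n_frames Number of frames.
#' @param arena An [arena_geometry()]; only the centre and outer radius are
#'   used for bounding.
#' @param inter_ear_px Inter-ear distance in pixels (> 0).
#' @param seed Integer seed.
#' @return A [keypoint_track()] with 7 key points.
#' @export
generate_keypoints <- function(n_frames, arena, inter_ear_px = 20,
                               seed = 1L) {
  check_scalar_num(n_frames, "n_frames", lower = 1, integer = TRUE)
  stopifnot(inherits(arena, "arena_geometry"))
  check_scalar_num(inter_ear_px, "inter_ear_px", lower = 1e-12)
  template <- mouse_template(inter_ear_px)
  body_extent <- max(sqrt(rowSums(template^2)))
  r_max <- arena$zone_radii[["outer"]] - body_extent - 1
  if (r_max <= 0)
    abort_input("arena outer radius too small for the body template")
  with_seed(seed, {
    pos <- matrix(0, n_frames, 2)
    vel <- c(0, 0)
    pos[1, ] <- arena$center
    theta <- stats::runif(1, 0, 2 * pi)
    thetas <- numeric(n_frames)
    thetas[1] <- theta
    step_sd <- inter_ear_px / 8
    for (t in seq_len(n_frames)[-1]) {
      vel <- 0.9 * vel + stats::rnorm(2, 0, step_sd)
      cand <- pos[t - 1, ] + vel
      off <- cand - arena$center
      r <- sqrt(sum(off^2))
      if (r > r_max) {           # reflect radially off the wall
        cand <- arena$center + off * (2 * r_max / r - 1)
        vel <- -0.5 * vel
      }
      pos[t, ] <- cand
      theta <- theta + stats::rnorm(1, 0, 0.08)
      thetas[t] <- theta
    }
    coords <- array(0, c(n_frames, nrow(template), 2))
    for (t in seq_len(n_frames)) {
      rot <- matrix(c(cos(thetas[t]), sin(thetas[t]),
                      -sin(thetas[t]), cos(thetas[t])), 2, 2)
      coords[t, , ] <- sweep(template %*% t(rot), 2, pos[t, ], "+")
    }
    keypoint_track(coords, rownames(template))
  })
}

#' Render a synthetic circular-arena image
#'
#' Produces a grayscale image (matrix in \[0, 1\], row = y, column = x)
#' containing a high-contrast arena boundary ring and a central marker ring,
#' the fixture consumed by [segment_arena()].
#'
#' @param image_size Side length of the square image in pixels.
#' @param center Numeric `(x, y)` centre in pixels.
#' @param outer_radius Arena boundary radius, px.
#' @param center_marker_radius Central marker radius, px
#'   (< `outer_radius`).
#' @param ring_width Full ring thickness in px.
#' @return Numeric matrix \[image_size x image_size\] in \[0, 1\].
#' @export
generate_arena_image <- function(image_size = 800, center = c(400, 400),
                                 outer_radius = 300,
                                 center_marker_radius = 60, ring_width = 3) {
  check_scalar_num(image_size, "image_size", lower = 16, integer = TRUE)
  stopifnot(length(center) == 2, is.numeric(center))
  check_scalar_num(outer_radius, "outer_radius", lower = 1e-12)
  check_scalar_num(center_marker_radius, "center_marker_radius",
                   lower = 1e-12)
  if (center_marker_radius >= outer_radius)
    abort_input("`center_marker_radius` must be smaller than `outer_radius`")
  pad <- ring_width / 2 + 1
  if (center[1] - outer_radius < pad || center[1] + outer_radius > image_size - pad ||
      center[2] - outer_radius < pad || center[2] + outer_radius > image_size - pad)
    abort_input("arena circle does not fit inside the image")
  xs <- matrix(seq_len(image_size), image_size, image_size, byrow = TRUE)
  ys <- matrix(seq_len(image_size), image_size, image_size)
  r <- sqrt((xs - center[1])^2 + (ys - center[2])^2)
  img <- matrix(0.9, image_size, image_size)
  img[abs(r - outer_radius) <= ring_width / 2] <- 0.05
  img[abs(r - center_marker_radius) <= ring_width / 2] <- 0.05
  img
}

# ---- plain-text / PNG writers -------------------------------------------

#' Write a calcium recording to CSV (neurons as rows)
#' @param recording A [calcium_recording()].
#' @param path Output file path.
#' @export
write_calcium_csv <- function(recording, path) {
  stopifnot(inherits(recording, "calcium_recording"))
  m <- recording$fluorescence
  df <- data.frame(neuron = seq_len(nrow(m)), m)
  colnames(df) <- c("neuron", paste0("f", seq_len(ncol(m))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a calcium recording written by [write_calcium_csv()]
#' @param path CSV path.
#' @param fps Sampling rate of the recording, Hz.
#' @param session_id,mouse_id,group_tag Metadata for the recording.
#' @export
read_calcium_csv <- function(path, fps = 15, session_id = "s1",
                             mouse_id = "m1", group_tag = "WT") {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, setdiff(colnames(df), "neuron"), drop = FALSE])
  dimnames(m) <- NULL
  calcium_recording(m, fps, session_id, mouse_id, group_tag)
}

#' Write a behavior label track to CSV (one row per frame)
#' @param track A [behavior_label_track()].
#' @param path Output file path.
#' @export
write_behavior_csv <- function(track, path) {
  stopifnot(inherits(track, "behavior_label_track"))
  df <- data.frame(frame = seq_along(track$labels), label = track$labels)
  if (!is.null(track$probabilities))
    df <- cbind(df, stats::setNames(as.data.frame(track$probabilities),
                                    paste0("p_", behavior_classes())))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a key-point track to wide CSV (x_name, y_name columns)
#' @param track A [keypoint_track()].
#' @param path Output file path.
#' @export
write_keypoints_csv <- function(track, path) {
  stopifnot(inherits(track, "keypoint_track"))
  nf <- dim(track$coordinates)[1]
  df <- data.frame(frame = seq_len(nf))
  for (kp in track$keypoint_names) {
    df[[paste0("x_", kp)]] <- track$coordinates[, kp, "x"]
    df[[paste0("y_", kp)]] <- track$coordinates[, kp, "y"]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a grayscale image matrix to PNG
#' @param image Numeric matrix in \[0, 1\] (row = y, column = x).
#' @param path Output PNG path.
#' @export
write_image_png <- function(image, path) {
  stopifnot(is.matrix(image))
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}
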