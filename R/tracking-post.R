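# Key-point evaluation (PCK), behavior label denoising and kinematics.

resolve_reference_point <- function(track, reference_point) {
  if (identical(reference_point, "ear_midpoint")) {
    (track$coordinates[, "left_ear", ] + track$coordinates[, "right_ear", ]) / 2
  } else {
    if (!reference_point %in% track$keypoint_names)
      abort_input(sprintf("unknown reference point `%s`", reference_point))
    track$coordinates[, reference_point, ]
  }
}

inter_ear_distance <- function(track) {
  d <- track$coordinates[, "left_ear", ] - track$coordinates[, "right_ear", ]
  sqrt(d[, 1]^2 + d[, 2]^2)
}

#' Percentage of correct key points (PCK)
#'
#' A predicted key point counts as correct on a frame when its Euclidean
#' error does not exceed the confidence radius `d_factor * D`, where `D` is
#' that frame's inter-ear distance in the ground-truth track (PCK@0.25 for
#' the default `d_factor`). Percentages are computed per key point over
#' frames, and the mean over key points is reported.
#'
#' @param predicted,truth [keypoint_track()]s with identical frame counts
#'   and key-point names; `truth` must contain both ears.
#' @param d_factor Dimensionless multiplier of the inter-ear distance
#'   (default 0.25).
#' @return An object of class `pck_result` with fields `d_factor`,
#'   `reference_distance` (per-frame D), `per_keypoint_pct` (named, in
#'   \[0, 100\]) and `mean_pct`.
#' @export
pck <- function(predicted, truth, d_factor = 0.25) {
  stopifnot(inherits(predicted, "keypoint_track"),
            inherits(truth, "keypoint_track"))
  check_scalar_num(d_factor, "d_factor", lower = 1e-12)
  if (dim(predicted$coordinates)[1] != dim(truth$coordinates)[1])
    abort_input("predicted and truth tracks differ in frame count")
  if (!identical(sort(predicted$keypoint_names), sort(truth$keypoint_names)))
    abort_input("predicted and truth tracks must share key-point names")
  d_ref <- inter_ear_distance(truth)
  radius <- d_factor * d_ref
  kp <- truth$keypoint_names
  per_kp <- vapply(kp, function(name) {
    err <- predicted$coordinates[, name, ] - truth$coordinates[, name, ]
    100 * mean(sqrt(err[, 1]^2 + err[, 2]^2) <= radius)
  }, 0)
  structure(list(d_factor = d_factor, reference_distance = d_ref,
                 per_keypoint_pct = per_kp, mean_pct = mean(per_kp)),
            class = "pck_result")
}

#' @export
print.pck_result <- function(x, ...) {
  cat(sprintf("<pck_result> PCK@%g mean %.1f%%\n", x$d_factor, x$mean_pct))
  print(round(x$per_keypoint_pct, 1))
  invisible(x)
}

#' Default behavior transition matrix
#'
#' Row-stochastic 3 x 3 matrix with a common self-transition probability and
#' the remaining mass split evenly over the other classes.
#'
#' @param self Self-transition probability (default 0.9).
#' @return 3 x 3 matrix with rows/columns named by [behavior_classes()].
#' @export
behavior_transition_matrix <- function(self = 0.9) {
  check_scalar_num(self, "self", lower = 0, upper = 1)
  m <- matrix((1 - self) / 2, 3, 3)
  diag(m) <- self
  dimnames(m) <- list(behavior_classes(), behavior_classes())
  m
}

#' Discrete-state forward filter for behavior probabilities
#'
#' The first stage of behavior-stream denoising: a hidden-Markov forward
#' filter whose dynamics are given by a row-stochastic "behavior matrix" `T`
#' redistributing class probability between frames. Per frame, the filter
#' predicts `p' = T' p` (matrix transpose), multiplies element-wise by the
#' observed class probabilities, and renormalizes. The prior for the first
#' frame is uniform. Deterministic.
#'
#' @param probabilities Numeric \[n_frames x k\] matrix of per-frame class
#'   probabilities (rows sum to 1 within 1e-6); `k = 3` for the behavior
#'   alphabet.
#' @param transition_matrix Row-stochastic k x k matrix (default
#'   [behavior_transition_matrix()]).
#' @return An object of class `filtered_behavior_track` with per-frame
#'   argmax `labels`, `raw_probabilities`, `filtered_probabilities` and the
#'   `transition_matrix` used.
#' @export
kalman_label_filter <- function(probabilities,
                                transition_matrix = behavior_transition_matrix()) {
  if (!is.matrix(probabilities) || !is.numeric(probabilities))
    abort_input("`probabilities` must be a numeric matrix")
  k <- ncol(probabilities)
  if (!is.matrix(transition_matrix) || any(dim(transition_matrix) != k))
    abort_input("`transition_matrix` must be ", k, " x ", k)
  if (any(abs(rowSums(probabilities) - 1) > 1e-6))
    abort_input("`probabilities` rows must sum to 1")
  if (any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-6))
    abort_input("`transition_matrix` must be row-stochastic")
  n <- nrow(probabilities)
  filtered <- matrix(0, n, k)
  p <- rep(1 / k, k)
  for (t in seq_len(n)) {
    pred <- drop(crossprod(transition_matrix, p))
    upd <- pred * probabilities[t, ]
    s <- sum(upd)
    if (s <= 0)
      abort_input(sprintf("all-zero posterior at frame %d", t))
    p <- upd / s
    filtered[t, ] <- p
  }
  labels <- if (k == 3L) {
    behavior_classes()[max.col(filtered, ties.method = "first")]
  } else {
    as.character(max.col(filtered, ties.method = "first"))
  }
  structure(list(labels = labels, raw_probabilities = probabilities,
                 filtered_probabilities = filtered,
                 transition_matrix = transition_matrix),
            class = "filtered_behavior_track")
}

block_mode <- function(block) {
  counts <- table(block)
  winners <- names(counts)[counts == max(counts)]
  if (length(winners) == 1L) return(winners)
  central <- block[ceiling(length(block) / 2)]
  if (central %in% winners) central else sort(winners)[1L]
}

#' Mode smoothing of a label sequence
#'
#' The second stage of behavior-stream denoising: the sequence is cut into
#' consecutive non-overlapping blocks of `window` frames and every frame in a
#' block is replaced by the block's modal label. A trailing short block is
#' smoothed with its own mode. Ties are broken by the label of the block's
#' central frame (falling back to alphabetical order if the central label is
#' not among the tied modes).
#'
#' @param labels Character vector of labels.
#' @param window Odd block length, `1 <= window <= length(labels)`
#'   (default 25).
#' @return Character vector of smoothed labels, same length.
#' @export
mode_smooth <- function(labels, window = 25L) {
  check_scalar_num(window, "window", lower = 1, integer = TRUE)
  if (window %% 2 == 0)
    abort_input("`window` must be odd")
  if (window > length(labels))
    abort_input("`window` exceeds the sequence length")
  n <- length(labels)
  out <- labels
  starts <- seq.int(1L, n, by = window)
  for (s in starts) {
    e <- min(s + window - 1L, n)
    out[s:e] <- block_mode(labels[s:e])
  }
  out
}

#' Per-frame velocity of a tracked reference point
#'
#' Raw speed is the frame-to-frame displacement of the reference point times
#' the frame rate (the first frame copies the second); the smoothed series is
#' a Savitzky-Golay filtering of the raw speed, floored at zero.
#'
#' @param track A [keypoint_track()].
#' @param fps Sampling rate, Hz.
#' @param reference_point A key-point name, or `"ear_midpoint"` (default)
#'   for the midpoint of the two ears.
#' @param savgol_window Odd Savitzky-Golay window length in frames
#'   (default 15, i.e. 1 s at 15 Hz).
#' @param savgol_order Polynomial order (< `savgol_window`), default 3.
#' @return An object of class `kinematic_summary` with `velocity_raw`,
#'   `velocity_smooth` (px/s per frame) and `total_distance` (px).
#' @export
compute_velocity <- function(track, fps = 15, reference_point = "ear_midpoint",
                             savgol_window = 15L, savgol_order = 3L) {
  stopifnot(inherits(track, "keypoint_track"))
  check_scalar_num(fps, "fps", lower = 1e-12)
  check_scalar_num(savgol_window, "savgol_window", lower = 1, integer = TRUE)
  check_scalar_num(savgol_order, "savgol_order", lower = 0, integer = TRUE)
  if (savgol_window %% 2 == 0 || savgol_window <= savgol_order)
    abort_input("`savgol_window` must be odd and exceed `savgol_order`")
  pos <- resolve_reference_point(track, reference_point)
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 2)
  step <- sqrt(diff(pos[, 1])^2 + diff(pos[, 2])^2)
  v_raw <- c(if (length(step)) step[1] * fps else 0, step * fps)
  v_smooth <- if (length(v_raw) >= savgol_window) {
    pmax(signal::sgolayfilt(v_raw, p = savgol_order, n = savgol_window), 0)
  } else {
    v_raw
  }
  structure(list(velocity_raw = v_raw, velocity_smooth = v_smooth,
                 total_distance = sum(step), fps = fps,
                 reference_point = reference_point),
            class = "kinematic_summary")
}

#' Zone occupancy, behavior fractions and trajectory tables
#'
#' Classifies the reference point of every frame into an arena zone, tallies
#' seconds per zone and the fraction of frames per behavior class, and
#' returns per-frame tables for ethogram/trajectory plotting plus a binned
#' 2-D position heatmap.
#'
#' @param track A [keypoint_track()].
#' @param labels A [behavior_label_track()] with one label per frame of
#'   `track`.
#' @param arena An [arena_geometry()].
#' @param fps Sampling rate, Hz.
#' @param reference_point As in [compute_velocity()].
#' @param heat_bins Number of bins per axis of the position heatmap.
#' @return A `kinematic_summary` with `zone_occupancy` (named seconds,
#'   summing to the session duration), `behavior_fractions` (named, summing
#'   to 1), `frames` (per-frame data.frame: frame, x, y, zone, behavior) and
#'   `position_heatmap` (counts matrix with break attributes).
#' @export
occupancy_and_ethogram <- function(track, labels, arena, fps = 15,
                                   reference_point = "ear_midpoint",
                                   heat_bins = 25L) {
  stopifnot(inherits(track, "keypoint_track"),
            inherits(labels, "behavior_label_track"),
            inherits(arena, "arena_geometry"))
  nf <- dim(track$coordinates)[1]
  if (length(labels$labels) != nf)
    abort_input("track and labels differ in frame count")
  pos <- resolve_reference_point(track, reference_point)
  zones <- classify_zone(pos, arena)
  zone_names <- c("central", "inner", "middle", "outer", "outside")
  occupancy <- vapply(zone_names, function(z) sum(zones == z), 0L) / fps
  cls <- behavior_classes()
  fractions <- vapply(cls, function(b) mean(labels$labels == b), 0)
  r_out <- arena$zone_radii[["outer"]]
  brk_x <- seq(arena$center[1] - r_out, arena$center[1] + r_out,
               length.out = heat_bins + 1)
  brk_y <- seq(arena$center[2] - r_out, arena$center[2] + r_out,
               length.out = heat_bins + 1)
  hm <- table(cut(pos[, 1], brk_x), cut(pos[, 2], brk_y))
  hm <- matrix(as.integer(hm), heat_bins, heat_bins)
  attr(hm, "breaks_x") <- brk_x
  attr(hm, "breaks_y") <- brk_y
  structure(list(zone_occupancy = occupancy, behavior_fractions = fractions,
                 frames = data.frame(frame = seq_len(nf), x = pos[, 1],
                                     y = pos[, 2], zone = zones,
                                     behavior = labels$labels),
                 position_heatmap = hm, fps = fps),
            class = "kinematic_summary")
}

#' Read a key-point CSV in wide or 3-row-header form
#'
#' Accepts the package's wide dialect (`frame, x_nose, y_nose, ...`) and the
#' DeepLabCut-style dialect with three header rows (scorer / bodyparts /
#' coords) followed by numeric rows.
#'
#' @param path CSV path.
#' @return A [keypoint_track()].
#' @export
read_keypoints_csv <- function(path) {
  first <- utils::read.csv(path, header = FALSE, nrows = 3,
                           colClasses = "character")
  if (tolower(first[1, 1]) == "scorer") {
    body <- as.character(unlist(first[2, -1]))
    coord <- tolower(as.character(unlist(first[3, -1])))
    dat <- utils::read.csv(path, header = FALSE, skip = 3)
    kp <- unique(body)
    nf <- nrow(dat)
    coords <- array(NA_real_, c(nf, length(kp), 2))
    for (j in seq_along(body)) {
      if (!coord[j] %in% c("x", "y")) next
      coords[, match(body[j], kp), match(coord[j], c("x", "y"))] <-
        as.numeric(dat[[j + 1]])
    }
    keypoint_track(coords, kp)
  } else {
    dat <- utils::read.csv(path)
    xcols <- grep("^x_", colnames(dat), value = TRUE)
    kp <- sub("^x_", "", xcols)
    nf <- nrow(dat)
    coords <- array(NA_real_, c(nf, length(kp), 2))
    for (i in seq_along(kp)) {
      coords[, i, 1] <- dat[[paste0("x_", kp[i])]]
      coords[, i, 2] <- dat[[paste0("y_", kp[i])]]
    }
    keypoint_track(coords, kp)
  }
}
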