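# Behavior-epoch assignment of manifold points and covariance-ellipse
# descriptors of the per-behavior sub-clouds.

#' Assign each temporal window its predominant behavior
#'
#' For each window of a [flatten_windows()] result, counts the per-frame
#' behavior labels inside the window and assigns the label with the highest
#' count; ties are broken by the label of the window's central frame.
#'
#' @param windows A [flatten_windows()] result.
#' @param labels A [behavior_label_track()] covering every frame of every
#'   window.
#' @return An object of class `epoch_assignment` with `window_labels` and
#'   `majority_fraction` (fraction of the window's frames carrying the
#'   winning label).
#' @export
assign_epochs <- function(windows, labels) {
  stopifnot(inherits(windows, "window_vector_set"),
            inherits(labels, "behavior_label_track"))
  w <- windows$window_len
  last_needed <- max(windows$window_start_frames) + w - 1L
  if (length(labels$labels) < last_needed)
    abort_input(sprintf("label track does not cover frame %d",
                        length(labels$labels) + 1L))
  res <- vapply(windows$window_start_frames, function(s) {
    block <- labels$labels[s:(s + w - 1L)]
    counts <- table(block)
    winners <- names(counts)[counts == max(counts)]
    win <- if (length(winners) == 1L) winners else {
      central <- block[w %/% 2 + 1L]
      if (central %in% winners) central else sort(winners)[1L]
    }
    c(win, max(counts) / w)
  }, c("", ""))
  structure(list(window_labels = res[1, ],
                 majority_fraction = as.numeric(res[2, ])),
            class = "epoch_assignment")
}

#' Covariance-ellipse descriptor of a 2-D point cloud
#'
#' Estimates the sample covariance (denominator `n - 1`) of the points,
#' takes its eigenvalues `lambda1 >= lambda2`, and summarizes the fitted
#' ellipse by its area and eccentricity. Two conventions are provided:
#'
#' * `"direct"` (default): area `S = pi * lambda1 * lambda2` and
#'   eccentricity `c = sqrt(1 - lambda2^2 / lambda1^2)`, i.e. the formulas
#'   applied directly to the eigenvalues.
#' * `"conf95"`: the textbook 95% confidence ellipse, whose semi-axes are
#'   `sqrt(chi^2_{2,0.95} * lambda_i)`: area
#'   `S = pi * chi^2_{2,0.95} * sqrt(lambda1 * lambda2)` and eccentricity
#'   `c = sqrt(1 - lambda2 / lambda1)` from the squared semi-axes.
#'
#' All group comparisons in this package are relative, so the convention
#' only rescales descriptors; `"direct"` is the default because it is the
#' form the downstream classification analyses are defined on.
#'
#' @param points Numeric matrix \[n x 2\], `n >= 3`.
#' @param behavior Optional behavior label carried into the descriptor.
#' @param convention `"direct"` or `"conf95"`.
#' @return An object of class `ellipse_descriptor` with `lambda1`,
#'   `lambda2`, `area`, `eccentricity`, `behavior`, `n_points`,
#'   `convention`.
#' @export
fit_ellipse <- function(points, behavior = NA_character_,
                        convention = c("direct", "conf95")) {
  convention <- match.arg(convention)
  points <- as.matrix(points)
  if (nrow(points) < 3L)
    abort_input("need at least 3 points to fit an ellipse")
  if (ncol(points) != 2L)
    abort_input("ellipse fitting is defined for 2-D points")
  lam <- sort(eigen(stats::cov(points), symmetric = TRUE,
                    only.values = TRUE)$values, decreasing = TRUE)
  lam[lam < 0 & lam > -1e-12] <- 0   # numerical round-off
  if (lam[1] <= 0)
    abort_input("degenerate geometry: point cloud has zero variance")
  if (convention == "direct") {
    area <- pi * lam[1] * lam[2]
    ecc <- sqrt(1 - lam[2]^2 / lam[1]^2)
  } else {
    q <- stats::qchisq(0.95, df = 2)
    area <- pi * q * sqrt(lam[1] * lam[2])
    ecc <- sqrt(1 - lam[2] / lam[1])
  }
  structure(list(lambda1 = lam[1], lambda2 = lam[2], area = area,
                 eccentricity = ecc, behavior = behavior,
                 n_points = nrow(points), convention = convention),
            class = "ellipse_descriptor")
}

#' @export
print.ellipse_descriptor <- function(x, ...) {
  cat(sprintf(
    "<ellipse_descriptor> %s: lambda (%.3g, %.3g), area %.3g, ecc %.3f (n=%d)\n",
    x$behavior %||% "?", x$lambda1, x$lambda2, x$area, x$eccentricity,
    x$n_points))
  invisible(x)
}

#' Per-behavior ellipse descriptors of an embedding
#'
#' Splits the embedded manifold points by their window behavior labels and
#' fits one covariance ellipse per behavior present with at least
#' `min_points` windows; sparser behaviors are reported absent (with a
#' message), not as errors.
#'
#' @param embedding An [embed_windows()] result (2-D).
#' @param epochs An [assign_epochs()] result aligned with the embedding.
#' @param min_points Minimum windows per behavior (default 3).
#' @param convention Passed to [fit_ellipse()].
#' @return Named list of [fit_ellipse()] descriptors, one per retained
#'   behavior.
#' @export
per_behavior_descriptors <- function(embedding, epochs, min_points = 3L,
                                     convention = c("direct", "conf95")) {
  stopifnot(inherits(embedding, "embedding_result"),
            inherits(epochs, "epoch_assignment"))
  convention <- match.arg(convention)
  if (nrow(embedding$points) != length(epochs$window_labels))
    abort_input("embedding and epoch assignment differ in window count")
  out <- list()
  for (b in behavior_classes()) {
    idx <- which(epochs$window_labels == b)
    if (length(idx) == 0L) next
    if (length(idx) < min_points) {
      message(sprintf(
        "per_behavior_descriptors: `%s` has %d < %d windows; skipped",
        b, length(idx), min_points))
      next
    }
    out[[b]] <- fit_ellipse(embedding$points[idx, , drop = FALSE],
                            behavior = b, convention = convention)
  }
  out
}

#' Tabulate ellipse descriptors
#'
#' @param descriptors List of [fit_ellipse()] results (e.g. from
#'   [per_behavior_descriptors()]).
#' @param session_id,group_tag Metadata columns to prepend.
#' @return data.frame with one row per descriptor.
#' @export
descriptor_table <- function(descriptors, session_id = NA_character_,
                             group_tag = NA_character_) {
  if (!length(descriptors)) {
    return(data.frame(session_id = character(), group = character(),
                      behavior = character(), lambda1 = numeric(),
                      lambda2 = numeric(), area = numeric(),
                      eccentricity = numeric(), n_points = integer()))
  }
  do.call(rbind, lapply(descriptors, function(d)
    data.frame(session_id = session_id, group = group_tag,
               behavior = d$behavior, lambda1 = d$lambda1,
               lambda2 = d$lambda2, area = d$area,
               eccentricity = d$eccentricity, n_points = d$n_points)))
}
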