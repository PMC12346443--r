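# Manifold construction: temporal-window flattening, dimensionality
# reduction, the intracluster-distance metric and temporal shuffles.

#' Flatten a recording into temporal-window population vectors
#'
#' Cuts the session into consecutive non-overlapping windows of `window_len`
#' frames starting at the first frame and concatenates, frame-major, the
#' per-frame population vectors of each window into one row: element
#' `i * N + j` (0-based) of a window vector is neuron `j`'s fluorescence at
#' the window's `i`-th frame. A trailing partial window is dropped (with a
#' message). The default 30 frames corresponds to 2 s at 15 Hz.
#'
#' @param recording A [calcium_recording()].
#' @param window_len Window length in frames (default 30).
#' @return An object of class `window_vector_set` with `vectors`
#'   \[n_windows x (window_len * N)\], `window_len`, `window_start_frames`
#'   (1-based), `n_neurons` and the recording's metadata.
#' @export
flatten_windows <- function(recording, window_len = 30L) {
  stopifnot(inherits(recording, "calcium_recording"))
  check_scalar_num(window_len, "window_len", lower = 1, integer = TRUE)
  window_len <- as.integer(window_len)
  fl <- recording$fluorescence
  n_frames <- ncol(fl)
  if (n_frames < window_len)
    abort_input("recording shorter than one window")
  n_win <- n_frames %/% window_len
  dropped <- n_frames - n_win * window_len
  if (dropped > 0)
    message(sprintf("flatten_windows: %d trailing frames dropped", dropped))
  starts <- (seq_len(n_win) - 1L) * window_len + 1L
  # column-major flattening of the neurons x window block is exactly the
  # frame-major concatenation of per-frame population vectors
  vectors <- t(vapply(starts, function(s)
    as.vector(fl[, s:(s + window_len - 1L), drop = FALSE]),
    numeric(nrow(fl) * window_len)))
  structure(list(vectors = vectors, window_len = as.integer(window_len),
                 window_start_frames = starts, n_neurons = nrow(fl),
                 fps = recording$fps, session_id = recording$session_id,
                 mouse_id = recording$mouse_id,
                 group_tag = recording$group_tag),
            class = "window_vector_set")
}

#' @export
print.window_vector_set <- function(x, ...) {
  cat(sprintf("<window_vector_set> %d windows x %d (W=%d, N=%d) [%s/%s]\n",
              nrow(x$vectors), ncol(x$vectors), x$window_len, x$n_neurons,
              x$group_tag, x$session_id))
  invisible(x)
}

#' Embed window vectors with a dimensionality-reduction method
#'
#' Delegates to established implementations — Rtsne (Barnes-Hut t-SNE),
#' stats::prcomp (PCA), ica::icafast (FastICA), stats::cmdscale (classical
#' MDS) and uwot::umap (UMAP) — under a fixed seed, and records the method
#' parameters actually used. Rows of the result align one-to-one with the
#' window vectors.
#'
#' t-SNE perplexity defaults to 30 and is clamped to `(n_windows - 1) / 3`
#' with a warning when the session is small; UMAP `n_neighbors` is clamped
#' to `n_windows - 1` likewise.
#'
#' @param windows A [flatten_windows()] result, or a plain numeric matrix of
#'   row vectors.
#' @param method One of `"tsne"`, `"pca"`, `"ica"`, `"mds"`, `"umap"`.
#' @param dim Embedding dimension (default 2).
#' @param seed Integer seed controlling all stochastic methods.
#' @param params Named list of method parameters (`perplexity`, `theta`,
#'   `max_iter` for t-SNE; `n_neighbors`, `min_dist` for UMAP; `maxit` for
#'   ICA).
#' @param standardize Standardize each input column to zero mean and, where
#'   the column varies, unit variance before embedding (default FALSE).
#' @return An object of class `embedding_result` with `points`
#'   \[n_windows x dim\], `method`, `dim`, `seed`, `method_params` and the
#'   window metadata.
#' @export
embed_windows <- function(windows, method = c("tsne", "pca", "ica", "mds",
                                              "umap"),
                          dim = 2L, seed = 1L, params = list(),
                          standardize = FALSE) {
  if (is.character(method) && length(method) == 1L &&
      !method %in% c("tsne", "pca", "ica", "mds", "umap"))
    abort_input(sprintf("unknown embedding method `%s`", method))
  method <- match.arg(method)
  check_scalar_num(dim, "dim", lower = 1, integer = TRUE)
  x <- if (inherits(windows, "window_vector_set")) windows$vectors else
    as.matrix(windows)
  n <- nrow(x)
  if (n < dim + 1L)
    abort_input("need at least dim + 1 window vectors to embed")
  if (standardize) {
    x <- scale(x)
    x[, attr(x, "scaled:scale") == 0] <- 0
    attributes(x)[c("scaled:center", "scaled:scale")] <- NULL
  }
  used <- list()
  points <- switch(method,
    pca = {
      p <- stats::prcomp(x, rank. = dim, center = TRUE, scale. = FALSE)
      unname(p$x[, seq_len(dim), drop = FALSE])
    },
    mds = {
      out <- stats::cmdscale(stats::dist(x), k = dim)
      if (ncol(out) < dim)
        abort_input("MDS produced fewer positive-eigenvalue axes than `dim`")
      unname(out)
    },
    tsne = {
      if (dim > 3L)
        abort_input("t-SNE supports dim <= 3; lower `dim` or pick another method")
      perp <- params$perplexity %||% 30
      perp_max <- (n - 1) / 3
      if (perp > perp_max) {
        perp <- floor(perp_max * 100) / 100
        warning(sprintf("perplexity clamped to %.2f for %d windows",
                        perp, n), call. = FALSE)
      }
      if (perp < 1)
        abort_input("too few windows for t-SNE; need n >= 7 (perplexity >= 1)")
      used$perplexity <- perp
      used$theta <- params$theta %||% 0.5
      used$max_iter <- params$max_iter %||% 1000L
      with_seed(seed,
        Rtsne::Rtsne(x, dims = dim, perplexity = perp, theta = used$theta,
                     max_iter = used$max_iter, check_duplicates = FALSE,
                     pca = TRUE, verbose = FALSE)$Y)
    },
    ica = {
      used$maxit <- params$maxit %||% 200L
      with_seed(seed, ica::icafast(x, nc = dim, maxit = used$maxit)$S)
    },
    umap = {
      nn <- min(params$n_neighbors %||% 15L, n - 1L)
      if (nn < 2L)
        abort_input("too few windows for UMAP")
      used$n_neighbors <- nn
      used$min_dist <- params$min_dist %||% 0.1
      with_seed(seed,
        uwot::umap(x, n_components = dim, n_neighbors = nn,
                   min_dist = used$min_dist, n_threads = 1,
                   n_sgd_threads = 1))
    })
  if (!all(is.finite(points)))
    abort_input("embedding produced non-finite coordinates")
  meta <- if (inherits(windows, "window_vector_set")) {
    windows[c("session_id", "mouse_id", "group_tag", "window_start_frames",
              "window_len")]
  } else {
    list()
  }
  structure(c(list(points = points, method = method, dim = as.integer(dim),
                   seed = as.integer(seed), method_params = used), meta),
            class = "embedding_result")
}

#' Intracluster distance of a point cloud
#'
#' The mean pairwise Euclidean distance over all ordered pairs of points,
#' `1 / (n (n - 1)) * sum_i sum_{j != i} ||x_i - x_j||`, which equals the
#' mean over unordered pairs. Lower values indicate a more compact (less
#' variable) manifold.
#'
#' @param points Numeric matrix \[n x dim\] with `n >= 2`, or an
#'   [embed_windows()] result.
#' @return An object of class `cluster_metric` with fields
#'   `intracluster_distance`, `n_points` and, when available, session
#'   metadata.
#' @export
intracluster_distance <- function(points) {
  meta <- list()
  if (inherits(points, "embedding_result")) {
    meta <- points[intersect(c("session_id", "mouse_id", "group_tag",
                               "method"), names(points))]
    points <- points$points
  }
  points <- as.matrix(points)
  if (nrow(points) < 2L)
    abort_input("need at least 2 points")
  structure(c(list(intracluster_distance = mean(stats::dist(points)),
                   n_points = nrow(points)), meta),
            class = "cluster_metric")
}

#' @export
print.cluster_metric <- function(x, ...) {
  cat(sprintf("<cluster_metric> intracluster distance %.4f over %d points\n",
              x$intracluster_distance, x$n_points))
  invisible(x)
}

phase_randomize_vec <- function(v, phases_half) {
  n <- length(v)
  sp <- stats::fft(v)
  half <- seq(2L, floor((n - 1) / 2) + 1L)[seq_along(phases_half)]
  sp[half] <- abs(sp[half]) * exp(1i * phases_half)
  # conjugate symmetry for a real-valued inverse transform
  sp[n + 2L - half] <- Conj(sp[half])
  if (n %% 2 == 0) sp[n / 2 + 1L] <- abs(sp[n / 2 + 1L])
  Re(stats::fft(sp, inverse = TRUE)) / n
}

#' Temporal shuffling controls for a calcium recording
#'
#' `permute_frames` applies an independent random permutation of the time
#' axis to each neuron, destroying cross-neuron temporal coordination while
#' preserving each neuron's value multiset. `phase_randomize` randomizes
#' each neuron's Fourier phases while preserving its amplitude spectrum
#' (surrogate-data control). Deterministic given `seed`.
#'
#' @param recording A [calcium_recording()].
#' @param mode `"permute_frames"` (default) or `"phase_randomize"`.
#' @param seed Integer seed.
#' @return A [calcium_recording()] with shuffled fluorescence and the same
#'   metadata.
#' @export
temporal_shuffle <- function(recording, mode = c("permute_frames",
                                                 "phase_randomize"),
                             seed = 1L) {
  stopifnot(inherits(recording, "calcium_recording"))
  if (is.character(mode) && length(mode) == 1L &&
      !mode %in% c("permute_frames", "phase_randomize"))
    abort_input(sprintf("unknown shuffle mode `%s`", mode))
  mode <- match.arg(mode)
  fl <- recording$fluorescence
  n <- ncol(fl)
  out <- with_seed(seed, {
    if (mode == "permute_frames") {
      t(apply(fl, 1L, function(v) v[sample.int(n)]))
    } else {
      n_half <- length(seq(2L, floor((n - 1) / 2) + 1L))
      t(apply(fl, 1L, function(v)
        phase_randomize_vec(v, stats::runif(n_half, 0, 2 * pi))))
    }
  })
  calcium_recording(out, recording$fps, recording$session_id,
                    recording$mouse_id, recording$group_tag)
}
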