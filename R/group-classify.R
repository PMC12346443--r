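# Encoder-style group classification from manifold descriptors, with
# shuffled-data controls and report comparison.

# Seed for the i-th derived stream: the i-th draw of a master-seeded RNG
# stream. Linear formulas (seed + i * const) are avoided deliberately —
# arithmetic progressions of seeds initialize measurably correlated
# Mersenne-Twister states.
derive_seed <- function(seed, i) {
  i <- as.integer(i)
  withr::with_seed(as.integer(as.numeric(seed) %% 2147483647),
                   sample.int(2147483646L, i)[i])
}

meta_cols <- c("session_id", "mouse_id", "group")

#' Assemble a session feature table
#'
#' @param session_id,mouse_id,group Per-session metadata vectors.
#' @param ... Named numeric feature vectors (e.g.
#'   `intracluster_distance = ...`), one value per session.
#' @return data.frame with metadata and feature columns.
#' @export
feature_table <- function(session_id, group, mouse_id = session_id, ...) {
  feats <- list(...)
  if (!length(feats) || is.null(names(feats)) || any(names(feats) == ""))
    abort_input("supply at least one named feature vector")
  df <- data.frame(session_id = session_id, mouse_id = mouse_id,
                   group = group)
  if (anyNA(group)) abort_input("missing group labels")
  for (nm in names(feats)) df[[nm]] <- feats[[nm]]
  df
}

classifier_metrics <- function(pred, truth, positive) {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(accuracy = mean(pred == truth), precision = precision,
    recall = recall, f1 = f1)
}

# Decision-threshold classifier on one feature: cut at midpoints between
# consecutive sorted training values, direction chosen by training accuracy.
fit_threshold <- function(x, g, positive) {
  xs <- sort(unique(x))
  cuts <- if (length(xs) > 1) (utils::head(xs, -1) + utils::tail(xs, -1)) / 2
          else xs
  best <- list(acc = -1, cut = cuts[1], low_is_positive = TRUE)
  for (cut in cuts) {
    for (low_pos in c(TRUE, FALSE)) {
      pred <- ifelse((x <= cut) == low_pos, positive, "other")
      acc <- mean(pred == ifelse(g == positive, positive, "other"))
      if (acc > best$acc) best <- list(acc = acc, cut = cut,
                                       low_is_positive = low_pos)
    }
  }
  best
}

predict_threshold <- function(fit, x, positive, negative) {
  ifelse((x <= fit$cut) == fit$low_is_positive, positive, negative)
}

#' Train/test encoder classification of sessions
#'
#' Classifies sessions of two groups from manifold-derived features over
#' independent repeats. Each repeat draws a stratified random train/test
#' split (a fraction `test_fraction` of each group's sessions held out).
#' With a single feature a decision threshold is fitted — the cut (midpoint
#' between consecutive sorted training values) and direction maximizing
#' training accuracy; with two or more features a Fisher linear discriminant
#' (via `MASS::lda`) is fitted on the training split. Metrics are computed
#' on the held-out sessions only, with `group_a` as the positive class.
#'
#' @param features A [feature_table()] (or compatible data.frame).
#' @param group_a,group_b Group labels to compare; `group_a` is the positive
#'   class for precision/recall.
#' @param feature_cols Feature column names; default all non-metadata
#'   columns.
#' @param n_repeats Number of independent resplits (default 10).
#' @param test_fraction Held-out fraction per group (default 0.3).
#' @param seed Integer seed; splits are reproducible given it.
#' @param condition Label stored in the report (`"original"` or
#'   `"shuffled"`).
#' @return An object of class `classifier_report`: `per_repeat` data.frame
#'   of accuracy/precision/recall/F1, their `mean` and `sem`
#'   (sd / sqrt(n_repeats)), `n_repeats`, `seed`, `condition`, `groups`.
#' @export
encode_classify <- function(features, group_a, group_b,
                            feature_cols = NULL, n_repeats = 10L,
                            test_fraction = 0.3, seed = 1L,
                            condition = "original") {
  stopifnot(is.data.frame(features))
  check_scalar_num(n_repeats, "n_repeats", lower = 1, integer = TRUE)
  check_scalar_num(test_fraction, "test_fraction", lower = 1e-9,
                   upper = 1 - 1e-9)
  feature_cols <- feature_cols %||% setdiff(colnames(features), meta_cols)
  if (!length(feature_cols))
    abort_input("no feature columns found")
  df <- features[features$group %in% c(group_a, group_b), , drop = FALSE]
  for (g in c(group_a, group_b))
    if (sum(df$group == g) < 3L)
      abort_input(sprintf(
        "group `%s` needs >= 3 sessions (2 train + 1 test) for splitting", g))
  x <- as.matrix(df[, feature_cols, drop = FALSE])
  g <- as.character(df$group)
  per_repeat <- with_seed(seed, {
    reps <- vector("list", n_repeats)
    for (r in seq_len(n_repeats)) {
      test_idx <- NULL
      for (attempt in seq_len(100L)) {
        # iterate groups in sorted order so splits do not depend on which
        # group is named first (label-swap symmetry)
        test_idx <- unlist(lapply(sort(c(group_a, group_b)), function(gg) {
          idx <- which(g == gg)
          sample(idx, max(1L, round(test_fraction * length(idx))))
        }))
        train_g <- g[-test_idx]
        if (all(table(factor(train_g, c(group_a, group_b))) >= 2L)) break
        warning("degenerate split resampled", call. = FALSE)
        if (attempt == 100L)
          abort_input("could not draw a non-degenerate split in 100 attempts")
      }
      xtr <- x[-test_idx, , drop = FALSE]
      gtr <- g[-test_idx]
      xte <- x[test_idx, , drop = FALSE]
      pred <- if (length(feature_cols) == 1L) {
        fit <- fit_threshold(xtr[, 1], gtr, group_a)
        predict_threshold(fit, xte[, 1], group_a, group_b)
      } else {
        fit <- MASS::lda(xtr, grouping = factor(gtr, c(group_a, group_b)))
        as.character(stats::predict(fit, xte)$class)
      }
      reps[[r]] <- classifier_metrics(pred, g[test_idx], group_a)
    }
    as.data.frame(do.call(rbind, reps))
  })
  structure(list(per_repeat = per_repeat,
                 mean = colMeans(per_repeat),
                 sem = apply(per_repeat, 2, stats::sd) / sqrt(n_repeats),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed),
                 condition = condition, groups = c(group_a, group_b),
                 feature_cols = feature_cols),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %s vs %s (%s, %d repeats)\n",
              x$groups[1], x$groups[2], x$condition, x$n_repeats))
  for (m in names(x$mean))
    cat(sprintf("  %-9s %.3f +/- %.3f\n", m, x$mean[[m]], x$sem[[m]]))
  invisible(x)
}

#' Intracluster-distance features for a cohort of recordings
#'
#' Runs the per-session manifold chain (flatten, embed, intracluster
#' distance) over a cohort and assembles a [feature_table()].
#'
#' @param cohort List of [calcium_recording()]s.
#' @param window_len Window length in frames.
#' @param method,dim,params,standardize Passed to [embed_windows()].
#' @param seed Integer seed; session `i` embeds with a seed derived from it,
#'   so original and shuffled runs can reuse identical downstream seeds.
#' @return A [feature_table()] with an `intracluster_distance` column.
#' @export
cohort_icd_features <- function(cohort, window_len = 30L, method = "tsne",
                                dim = 2L, params = list(),
                                standardize = FALSE, seed = 1L) {
  stopifnot(is.list(cohort), length(cohort) >= 2L)
  icd <- numeric(length(cohort))
  for (i in seq_along(cohort)) {
    ws <- flatten_windows(cohort[[i]], window_len)
    emb <- embed_windows(ws, method = method, dim = dim,
                         seed = derive_seed(seed, i), params = params,
                         standardize = standardize)
    icd[i] <- intracluster_distance(emb)$intracluster_distance
  }
  feature_table(
    session_id = vapply(cohort, `[[`, "", "session_id"),
    group = vapply(cohort, `[[`, "", "group_tag"),
    mouse_id = vapply(cohort, `[[`, "", "mouse_id"),
    intracluster_distance = icd)
}

#' Original-versus-shuffled classification control
#'
#' Runs the full chain — window flattening, embedding, intracluster
#' distance, encoder classification — on a cohort twice: on the original
#' recordings and on temporally shuffled copies, reusing identical
#' downstream seeds, and returns both reports.
#'
#' @param cohort List of [calcium_recording()]s spanning >= 2 groups.
#' @param window_len,method,dim,params,standardize Passed to the manifold
#'   chain.
#' @param shuffle_mode Passed to [temporal_shuffle()].
#' @param n_repeats,test_fraction Passed to [encode_classify()].
#' @param seed Integer seed for shuffles, embeddings and splits.
#' @return List with elements `original` and `shuffled` (both
#'   `classifier_report`s) and the two feature tables.
#' @export
shuffled_control_run <- function(cohort, window_len = 30L, method = "tsne",
                                 dim = 2L, params = list(),
                                 standardize = FALSE,
                                 shuffle_mode = "permute_frames",
                                 n_repeats = 10L, test_fraction = 0.3,
                                 seed = 1L) {
  groups <- unique(vapply(cohort, `[[`, "", "group_tag"))
  if (length(groups) < 2L)
    abort_input("cohort must contain at least 2 groups")
  ga <- groups[1]
  gb <- groups[2]
  shuffled <- lapply(seq_along(cohort), function(i)
    temporal_shuffle(cohort[[i]], mode = shuffle_mode,
                     seed = derive_seed(seed, 1000L + i)))
  feat_o <- cohort_icd_features(cohort, window_len, method, dim, params,
                                standardize, seed = seed)
  feat_s <- cohort_icd_features(shuffled, window_len, method, dim, params,
                                standardize, seed = seed)
  list(original = encode_classify(feat_o, ga, gb, n_repeats = n_repeats,
                                  test_fraction = test_fraction, seed = seed,
                                  condition = "original"),
       shuffled = encode_classify(feat_s, ga, gb, n_repeats = n_repeats,
                                  test_fraction = test_fraction, seed = seed,
                                  condition = "shuffled"),
       features_original = feat_o, features_shuffled = feat_s)
}

#' Compare two classifier reports metric by metric
#'
#' Two-sided test per metric (Mann-Whitney by default, or Student's t),
#' with the sign of the mean difference. Identical zero-variance samples
#' yield p = 1 by convention.
#'
#' @param a,b `classifier_report`s with equal `n_repeats`.
#' @param test `"mann_whitney"` or `"t"`.
#' @return data.frame with columns metric, mean_a, mean_b, direction
#'   (sign of mean_a - mean_b) and p_value.
#' @export
compare_reports <- function(a, b, test = c("mann_whitney", "t")) {
  stopifnot(inherits(a, "classifier_report"),
            inherits(b, "classifier_report"))
  test <- match.arg(test)
  if (a$n_repeats != b$n_repeats)
    abort_input("reports have different numbers of repeats")
  metrics <- colnames(a$per_repeat)
  rows <- lapply(metrics, function(m) {
    x <- a$per_repeat[[m]]
    y <- b$per_repeat[[m]]
    p <- if (stats::sd(c(x, y)) == 0) {
      1
    } else if (test == "t" && stats::sd(x) == 0 && stats::sd(y) == 0) {
      # both samples constant but different: the t statistic is degenerate
      if (mean(x) == mean(y)) 1 else 0
    } else if (test == "mann_whitney") {
      suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
    } else {
      stats::t.test(x, y)$p.value
    }
    data.frame(metric = m, mean_a = mean(x), mean_b = mean(y),
               direction = sign(mean(x) - mean(y)), p_value = p)
  })
  do.call(rbind, rows)
}
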