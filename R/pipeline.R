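# One-command end-to-end run: synthetic cohort -> manifolds -> intracluster
# distances and per-behavior ellipses -> original and shuffled classification.

#' Pipeline configuration
#'
#' Describes a two-group synthetic cohort and every downstream analysis
#' setting. Per-group entries override the shared generator defaults; the
#' package defaults encode the study conditions used throughout the
#' documentation: a sparse baseline group with moderate ensemble synchrony
#' and a dense, near-globally synchronous "compact" group whose activity
#' saturates the indicator response.
#'
#' @param groups Named list of per-group generator overrides (fields of
#'   [synthetic_cohort_config()]); exactly two groups.
#' @param sessions_per_group Sessions per group (>= 1; >= 3 for
#'   classification).
#' @param n_neurons,n_frames,fps,noise_sd,f_ceiling,kernel_rise,kernel_decay
#'   Shared generator settings.
#' @param window_len Manifold window length, frames.
#' @param method,dim,embed_params Embedding settings (see
#'   [embed_windows()]).
#' @param ellipse_convention `"direct"` or `"conf95"` (see
#'   [fit_ellipse()]).
#' @param mean_dwell Behavior mean dwell times, seconds.
#' @param shuffle_mode [temporal_shuffle()] mode for the control run.
#' @param n_repeats,test_fraction [encode_classify()] settings.
#' @param seed Master integer seed; every stochastic stage derives its seed
#'   from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(groups = list(
                              baseline = list(event_rate = 0.1,
                                              shared_factor = 0.6),
                              compact = list(event_rate = 5,
                                             shared_factor = 0.9)),
                            sessions_per_group = 12L, n_neurons = 80L,
                            n_frames = 4500L, fps = 15, noise_sd = 0.05,
                            f_ceiling = 0.3, kernel_rise = 0.07,
                            kernel_decay = 0.6, window_len = 30L,
                            method = "tsne", dim = 2L,
                            embed_params = list(),
                            ellipse_convention = "direct",
                            mean_dwell = c(running = 2, sitting = 4,
                                           grooming = 3),
                            shuffle_mode = "permute_frames",
                            n_repeats = 10L, test_fraction = 0.3,
                            seed = 1L) {
  if (!is.list(groups) || length(groups) != 2L || is.null(names(groups)))
    abort_input("`groups` must be a named list of exactly 2 groups")
  check_scalar_num(sessions_per_group, "sessions_per_group", lower = 1,
                   integer = TRUE)
  structure(list(groups = groups,
                 sessions_per_group = as.integer(sessions_per_group),
                 n_neurons = n_neurons, n_frames = n_frames, fps = fps,
                 noise_sd = noise_sd, f_ceiling = f_ceiling,
                 kernel_rise = kernel_rise, kernel_decay = kernel_decay,
                 window_len = as.integer(window_len), method = method,
                 dim = as.integer(dim), embed_params = embed_params,
                 ellipse_convention = ellipse_convention,
                 mean_dwell = mean_dwell, shuffle_mode = shuffle_mode,
                 n_repeats = as.integer(n_repeats),
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON (or YAML)
#'
#' Fields missing from the file fall back to [pipeline_config()] defaults.
#'
#' @param path `.json` (or `.yaml`/`.yml`, requires the yaml package) file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      abort_input("the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$mean_dwell)) raw$mean_dwell <- unlist(raw$mean_dwell)
  if (!is.null(raw$groups)) raw$groups <- lapply(raw$groups, as.list)
  do.call(pipeline_config, raw)
}

#' Generate the synthetic cohort described by a pipeline config
#'
#' @param config A [pipeline_config()].
#' @return List with `recordings` (list of [calcium_recording()]) and
#'   `behavior` (list of [behavior_label_track()]), one per session.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  recordings <- list()
  behavior <- list()
  idx <- 0L
  for (g in names(config$groups)) {
    for (s in seq_len(config$sessions_per_group)) {
      idx <- idx + 1L
      overrides <- config$groups[[g]]
      args <- utils::modifyList(
        list(n_neurons = config$n_neurons, n_frames = config$n_frames,
             fps = config$fps, noise_sd = config$noise_sd,
             f_ceiling = config$f_ceiling, kernel_rise = config$kernel_rise,
             kernel_decay = config$kernel_decay, group_tag = g,
             seed = derive_seed(config$seed, idx)),
        overrides)
      cfg <- do.call(synthetic_cohort_config, args)
      sid <- sprintf("%s_s%02d", g, s)
      recordings[[idx]] <- generate_calcium(cfg, session_id = sid,
                                            mouse_id = sprintf("%s_m%02d",
                                                               g, s))
      behavior[[idx]] <- generate_behavior(
        config$n_frames, mean_dwell = config$mean_dwell, fps = config$fps,
        seed = derive_seed(config$seed, 5000L + idx))
    }
  }
  list(recordings = recordings, behavior = behavior)
}

analyze_sessions <- function(recordings, behavior, config, log) {
  n <- length(recordings)
  icd <- numeric(n)
  desc_rows <- list()
  embeddings <- vector("list", n)
  epochs <- vector("list", n)
  for (i in seq_len(n)) {
    ws <- flatten_windows(recordings[[i]], config$window_len)
    emb <- withCallingHandlers(
      embed_windows(ws, method = config$method, dim = config$dim,
                    seed = derive_seed(config$seed, 200L + i),
                    params = config$embed_params),
      warning = function(w) {
        log(conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    icd[i] <- intracluster_distance(emb)$intracluster_distance
    ep <- assign_epochs(ws, behavior[[i]])
    dd <- withCallingHandlers(
      per_behavior_descriptors(emb, ep,
                               convention = config$ellipse_convention),
      message = function(m) {
        log(conditionMessage(m))
        invokeRestart("muffleMessage")
      })
    desc_rows[[i]] <- descriptor_table(dd,
                                       session_id = ws$session_id,
                                       group_tag = ws$group_tag)
    embeddings[[i]] <- emb
    epochs[[i]] <- ep
  }
  feats <- feature_table(
    session_id = vapply(recordings, `[[`, "", "session_id"),
    group = vapply(recordings, `[[`, "", "group_tag"),
    mouse_id = vapply(recordings, `[[`, "", "mouse_id"),
    intracluster_distance = icd)
  list(features = feats, descriptors = do.call(rbind, desc_rows),
       embeddings = embeddings, epochs = epochs)
}

area_feature_table <- function(descriptors, behavior) {
  d <- descriptors[descriptors$behavior == behavior, , drop = FALSE]
  if (!nrow(d)) return(NULL)
  feature_table(session_id = d$session_id, group = d$group,
                area = d$area, eccentricity = d$eccentricity)
}

report_row <- function(report, comparison, feature) {
  out <- data.frame(comparison = comparison, feature = feature,
                    condition = report$condition)
  for (m in names(report$mean)) {
    out[[m]] <- report$mean[[m]]
    out[[paste0(m, "_sem")]] <- report$sem[[m]]
  }
  out
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Generates the cohort, builds per-session manifolds, computes
#' intracluster distances and per-behavior ellipse descriptors, classifies
#' the two groups from the intracluster distance and from per-behavior
#' ellipse features — each on the original and on temporally shuffled
#' recordings with identical downstream seeds — and writes all tables,
#' figures, a log and a manifest with content hashes into `out_dir`.
#' Idempotent given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return The run manifest (list), invisibly; written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  log <- function(...) log_lines <<- c(log_lines, paste0(...))
  stage <- "generate"
  result <- tryCatch({
    log(sprintf("seed %d; %d sessions/group; window %d; method %s dim %d",
                config$seed, config$sessions_per_group, config$window_len,
                config$method, config$dim))
    cohort <- generate_cohort(config)
    stage <- "analyze_original"
    orig <- analyze_sessions(cohort$recordings, cohort$behavior, config, log)
    stage <- "shuffle"
    shuffled_recs <- lapply(seq_along(cohort$recordings), function(i)
      temporal_shuffle(cohort$recordings[[i]], mode = config$shuffle_mode,
                       seed = derive_seed(config$seed, 3000L + i)))
    log(sprintf("temporal shuffle mode: %s", config$shuffle_mode))
    stage <- "analyze_shuffled"
    shuf <- analyze_sessions(shuffled_recs, cohort$behavior, config, log)
    stage <- "classify"
    ga <- names(config$groups)[1]
    gb <- names(config$groups)[2]
    reports <- list()
    comparisons <- list()
    if (config$sessions_per_group >= 3L) {
      for (cond in c("original", "shuffled")) {
        feats <- if (cond == "original") orig$features else shuf$features
        reports[[paste0("icd_", cond)]] <-
          encode_classify(feats, ga, gb, n_repeats = config$n_repeats,
                          test_fraction = config$test_fraction,
                          seed = config$seed, condition = cond)
      }
      comparisons$icd <- compare_reports(reports$icd_original,
                                         reports$icd_shuffled)
      for (b in behavior_classes()) {
        fo <- area_feature_table(orig$descriptors, b)
        fs <- area_feature_table(shuf$descriptors, b)
        enough <- function(f) !is.null(f) &&
          all(table(factor(f$group, c(ga, gb))) >= 3L)
        if (!enough(fo) || !enough(fs)) {
          log(sprintf("ellipse classifier for `%s` skipped: too few sessions",
                      b))
          next
        }
        reports[[paste0("ellipse_", b, "_original")]] <-
          encode_classify(fo, ga, gb, n_repeats = config$n_repeats,
                          test_fraction = config$test_fraction,
                          seed = config$seed, condition = "original")
        reports[[paste0("ellipse_", b, "_shuffled")]] <-
          encode_classify(fs, ga, gb, n_repeats = config$n_repeats,
                          test_fraction = config$test_fraction,
                          seed = config$seed, condition = "shuffled")
        comparisons[[paste0("ellipse_", b)]] <-
          compare_reports(reports[[paste0("ellipse_", b, "_original")]],
                          reports[[paste0("ellipse_", b, "_shuffled")]])
      }
    } else {
      log("classification skipped: fewer than 3 sessions per group")
    }
    stage <- "write"
    paths <- character()
    wr <- function(name, writer) {
      p <- file.path(out_dir, name)
      writer(p)
      paths <<- c(paths, p)
      p
    }
    wr("features_original.csv",
       function(p) utils::write.csv(orig$features, p, row.names = FALSE))
    wr("features_shuffled.csv",
       function(p) utils::write.csv(shuf$features, p, row.names = FALSE))
    wr("descriptors_original.csv",
       function(p) utils::write.csv(orig$descriptors, p, row.names = FALSE))
    wr("descriptors_shuffled.csv",
       function(p) utils::write.csv(shuf$descriptors, p, row.names = FALSE))
    emb_df <- do.call(rbind, lapply(seq_along(orig$embeddings), function(i) {
      e <- orig$embeddings[[i]]
      data.frame(session_id = e$session_id, group = e$group_tag,
                 window = seq_len(nrow(e$points)), x = e$points[, 1],
                 y = e$points[, 2],
                 behavior = orig$epochs[[i]]$window_labels)
    }))
    wr("embeddings_original.csv",
       function(p) utils::write.csv(emb_df, p, row.names = FALSE))
    if (length(reports)) {
      tab <- do.call(rbind, lapply(names(reports), function(nm) {
        feat <- sub("_(original|shuffled)$", "", nm)
        report_row(reports[[nm]], paste(ga, "vs", gb), feat)
      }))
      wr("classifier_reports.csv",
         function(p) utils::write.csv(tab, p, row.names = FALSE))
      comp_tab <- do.call(rbind, lapply(names(comparisons), function(nm)
        cbind(feature = nm, comparisons[[nm]])))
      wr("classifier_comparisons.csv",
         function(p) utils::write.csv(comp_tab, p, row.names = FALSE))
    }
    group_means <- tapply(orig$features$intracluster_distance,
                          orig$features$group, mean)[names(config$groups)]
    summary <- list(
      groups = names(config$groups),
      mean_intracluster_distance = as.list(group_means),
      second_group_more_compact = unname(group_means[2] < group_means[1]),
      classifier_accuracy = lapply(reports, function(r)
        unname(r$mean[["accuracy"]])))
    wr("summary.json", function(p)
      jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE))
    wr("fig_manifolds.png", function(p)
      plot_group_manifolds(orig$embeddings, orig$epochs,
                           names(config$groups), p,
                           convention = config$ellipse_convention))
    wr("fig_icd.png", function(p)
      plot_icd_groups(orig$features, p))
    wr("run.log", function(p) writeLines(log_lines, p))
    manifest <- list(
      package = "ethomanifold",
      seed = config$seed,
      summary = summary,
      files = data.frame(path = basename(paths),
                         md5 = unname(tools::md5sum(paths))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest
  }, error = function(e) {
    writeLines(c(log_lines, paste("FAILED at stage:", stage),
                 conditionMessage(e)),
               file.path(out_dir, "FAILED.log"))
    stop(sprintf("pipeline stage `%s` failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

behavior_palette <- function() {
  stats::setNames(c("#D55E00", "#0072B2", "#009E73"), behavior_classes())
}

ellipse_outline <- function(points, convention = "direct") {
  mu <- colMeans(points)
  ev <- eigen(stats::cov(points), symmetric = TRUE)
  scale2 <- if (convention == "direct") ev$values else
    stats::qchisq(0.95, 2) * ev$values
  scale2[scale2 < 0] <- 0
  th <- seq(0, 2 * pi, length.out = 120)
  t(mu + ev$vectors %*% rbind(sqrt(scale2[1]) * cos(th),
                              sqrt(scale2[2]) * sin(th)))
}

#' Plot one example manifold per group, colored by behavior
#'
#' @param embeddings,epochs Aligned lists from the per-session analysis.
#' @param groups Character vector of the two group names.
#' @param path Output PNG path.
#' @param convention Ellipse convention for the overlays.
#' @export
plot_group_manifolds <- function(embeddings, epochs, groups, path,
                                 convention = "direct") {
  grDevices::png(path, width = 1200, height = 600, res = 120)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  pal <- behavior_palette()
  for (g in groups) {
    i <- which(vapply(embeddings, `[[`, "", "group_tag") == g)[1]
    e <- embeddings[[i]]
    lab <- epochs[[i]]$window_labels
    graphics::plot(e$points, col = pal[lab], pch = 19, cex = 0.7,
                   xlab = "dim 1", ylab = "dim 2",
                   main = sprintf("%s (%s)", g, e$session_id))
    for (b in behavior_classes()) {
      pts <- e$points[lab == b, , drop = FALSE]
      if (nrow(pts) >= 3)
        graphics::lines(ellipse_outline(pts, convention), col = pal[b],
                        lwd = 2)
    }
    graphics::legend("topright", legend = behavior_classes(),
                     col = pal, pch = 19, cex = 0.8, bty = "n")
  }
  invisible(path)
}

#' Strip plot of per-session intracluster distances by group
#'
#' @param features A [feature_table()] with an `intracluster_distance`
#'   column.
#' @param path Output PNG path.
#' @export
plot_icd_groups <- function(features, path) {
  grDevices::png(path, width = 600, height = 600, res = 120)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, 2, 1))
  f <- factor(features$group, unique(features$group))
  # jitter draws from the RNG; keep the figure byte-deterministic
  with_seed(0L,
    graphics::stripchart(features$intracluster_distance ~ f,
                         vertical = TRUE, method = "jitter", pch = 19,
                         ylab = "intracluster distance",
                         xlab = "group"))
  means <- tapply(features$intracluster_distance, f, mean)
  graphics::points(seq_along(means), means, pch = "-", cex = 3,
                   col = "red")
  invisible(path)
}
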