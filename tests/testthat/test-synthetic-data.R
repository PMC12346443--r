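test_that("calcium generator honours shape, determinism and the silent limit", {
  silent <- synthetic_cohort_config(n_neurons = 12, n_frames = 200,
                                    event_rate = 0, noise_sd = 0, seed = 3)
  expect_true(all(generate_calcium(silent)$fluorescence == 0))

  cfg <- synthetic_cohort_config(n_neurons = 80, n_frames = 4500, seed = 11)
  rec <- generate_calcium(cfg)
  expect_identical(dim(rec$fluorescence), c(80L, 4500L))
  expect_true(all(is.finite(rec$fluorescence)))
  expect_identical(rec$fluorescence, generate_calcium(cfg)$fluorescence)

  expect_error(synthetic_cohort_config(n_neurons = 0), "n_neurons")
  expect_error(synthetic_cohort_config(shared_factor = 1.2), "shared_factor")
  expect_error(synthetic_cohort_config(noise_sd = -1), "noise_sd")
  expect_error(generate_calcium(list()), "synthetic_cohort_config")
})

test_that("shared event trains raise mean pairwise neuron correlation", {
  mean_offdiag_cor <- function(shared, seed) {
    cfg <- synthetic_cohort_config(n_neurons = 15, n_frames = 1500,
                                   event_rate = 0.5, shared_factor = shared,
                                   f_ceiling = Inf, seed = seed)
    cc <- stats::cor(t(generate_calcium(cfg)$fluorescence))
    mean(cc[upper.tri(cc)])
  }
  for (seed in 1:10)
    expect_gt(mean_offdiag_cor(1, seed), mean_offdiag_cor(0, seed))
})

test_that("the transient kernel peaks quickly and decays out", {
  fps <- 15
  k <- ethomanifold:::calcium_kernel(fps, rise = 0.07, decay = 0.6)
  expect_equal(max(k), 1)
  # peak within 3 frames of the rise time
  expect_lte(abs(which.max(k) - 1 - 0.07 * fps), 3)
  # below 10% of peak within 5 decay constants
  expect_lt(k[length(k)], 0.1)
  # saturation preserves silence, peak position and the ceiling
  expect_equal(ethomanifold:::saturate(0, 0.3), 0)
  expect_lt(ethomanifold:::saturate(100, 0.3), 0.3 + 1e-12)
  expect_identical(ethomanifold:::saturate(k, Inf), k)
})

test_that("behavior dwell times match the requested means", {
  track <- generate_behavior(1e5, mean_dwell = c(running = 2, sitting = 4,
                                                 grooming = 3),
                             fps = 15, seed = 21)
  runs <- rle(track$labels)
  for (cls in behavior_classes()) {
    want <- c(running = 2, sitting = 4, grooming = 3)[[cls]] * 15
    got <- mean(runs$lengths[runs$values == cls])
    expect_lt(abs(got - want) / want, 0.15)
  }
})

test_that("behavior generator contracts hold", {
  t1 <- generate_behavior(4500, seed = 5)
  expect_length(t1$labels, 4500)
  expect_true(all(t1$labels %in% behavior_classes()))
  expect_identical(t1$labels, generate_behavior(4500, seed = 5)$labels)
  const <- generate_behavior(600, mean_dwell = c(running = Inf, sitting = 4,
                                                 grooming = 3),
                             seed = 2, start = "running")
  expect_true(all(const$labels == "running"))
  expect_error(generate_behavior(100, mean_dwell = c(running = -1,
                                                     sitting = 4,
                                                     grooming = 3)),
               "dwell")
})

test_that("key-point tracks are rigid, bounded and reproducible", {
  arena <- std_arena()
  kt <- generate_keypoints(500, arena, inter_ear_px = 20.8, seed = 9)
  ears <- kt$coordinates[, "left_ear", ] - kt$coordinates[, "right_ear", ]
  expect_true(all(abs(sqrt(ears[, 1]^2 + ears[, 2]^2) - 20.8) < 1e-6))
  r <- sqrt((kt$coordinates[, , 1] - 400)^2 + (kt$coordinates[, , 2] - 400)^2)
  expect_true(all(r <= 300))
  kt2 <- generate_keypoints(500, arena, inter_ear_px = 20.8, seed = 9)
  expect_identical(kt$coordinates, kt2$coordinates)
})

test_that("PCK decreases monotonically with key-point noise", {
  arena <- std_arena()
  truth <- generate_keypoints(300, arena, inter_ear_px = 20, seed = 4)
  sigmas <- c(0, 2, 5, 10)
  mean_pck <- vapply(sigmas, function(s) {
    mean(vapply(1:5, function(seed)
      pck(jitter_track(truth, s, seed + 100), truth)$mean_pct, 0))
  }, 0)
  expect_equal(mean_pck[1], 100)
  expect_true(all(diff(mean_pck) < 0))
})

test_that("arena image fixture has the advertised geometry and guards", {
  img <- generate_arena_image(800, c(400, 400), 300, 60)
  expect_identical(dim(img), c(800L, 800L))
  expect_lt(img[400, 700], 0.5)   # boundary ring at radius 300
  expect_lt(img[400, 460], 0.5)   # marker ring at radius 60
  expect_gt(img[400, 600], 0.5)   # annulus interior is background
  expect_error(generate_arena_image(800, c(400, 400), 300, 300),
               "smaller")
  expect_error(generate_arena_image(400, c(200, 200), 300, 60), "fit")
})

test_that("CSV writers round-trip recordings and key points", {
  rec <- generate_calcium(synthetic_cohort_config(n_neurons = 5,
                                                  n_frames = 40, seed = 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_calcium_csv(rec, f)
  back <- read_calcium_csv(f, fps = rec$fps)
  expect_equal(back$fluorescence, rec$fluorescence, tolerance = 1e-12)

  kt <- generate_keypoints(25, std_arena(), 20, seed = 1)
  fk <- withr::local_tempfile(fileext = ".csv")
  write_keypoints_csv(kt, fk)
  back_kt <- read_keypoints_csv(fk)
  expect_identical(back_kt$keypoint_names, kt$keypoint_names)
  expect_equal(back_kt$coordinates, kt$coordinates, tolerance = 1e-9,
               ignore_attr = TRUE)

  bt <- generate_behavior(50, seed = 3)
  fb <- withr::local_tempfile(fileext = ".csv")
  write_behavior_csv(bt, fb)
  expect_identical(utils::read.csv(fb)$label, bt$labels)
})

test_that("DeepLabCut-style key-point CSVs are parsed", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("scorer,model,model,model,model",
               "bodyparts,left_ear,left_ear,right_ear,right_ear",
               "coords,x,y,x,y",
               "0,10,20,30,40",
               "1,11,21,31,41"), f)
  kt <- read_keypoints_csv(f)
  expect_identical(kt$keypoint_names, c("left_ear", "right_ear"))
  expect_equal(kt$coordinates[2, "right_ear", "y"], 41, ignore_attr = TRUE)
})
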