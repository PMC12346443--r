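pck_counting_oracle <- function(predicted, truth, d_factor) {
  nf <- dim(truth$coordinates)[1]
  out <- numeric(length(truth$keypoint_names))
  names(out) <- truth$keypoint_names
  for (kp in truth$keypoint_names) {
    n_ok <- 0
    for (t in seq_len(nf)) {
      le <- truth$coordinates[t, "left_ear", ]
      re <- truth$coordinates[t, "right_ear", ]
      radius <- d_factor * sqrt(sum((le - re)^2))
      err <- sqrt(sum((predicted$coordinates[t, kp, ] -
                         truth$coordinates[t, kp, ])^2))
      if (err <= radius) n_ok <- n_ok + 1
    }
    out[kp] <- 100 * n_ok / nf
  }
  out
}

test_that("PCK trivial geometry: identity is 100%, 0.3 D offset is 0%", {
  truth <- linear_track(50, inter_ear = 20)
  res <- pck(truth, truth)
  expect_true(all(res$per_keypoint_pct == 100))
  expect_equal(res$mean_pct, 100)

  off <- truth
  off$coordinates[, , 1] <- off$coordinates[, , 1] + 0.3 * 20  # 0.3 D along x
  expect_true(all(pck(off, truth)$per_keypoint_pct == 0))
})

test_that("PCK equals a per-point counting oracle", {
  truth <- generate_keypoints(200, std_arena(), 20, seed = 13)
  noisy <- jitter_track(truth, 4, seed = 14)
  res <- pck(noisy, truth)
  expect_equal(res$per_keypoint_pct,
               pck_counting_oracle(noisy, truth, 0.25), tolerance = 1e-12)
  expect_equal(res$mean_pct, mean(res$per_keypoint_pct))
})

test_that("PCK is translation invariant and scale equivariant", {
  truth <- generate_keypoints(80, std_arena(), 20, seed = 3)
  noisy <- jitter_track(truth, 3, seed = 4)
  base <- pck(noisy, truth)$per_keypoint_pct

  shift <- function(track, v) {
    track$coordinates[, , 1] <- track$coordinates[, , 1] + v[1]
    track$coordinates[, , 2] <- track$coordinates[, , 2] + v[2]
    track
  }
  expect_equal(pck(shift(noisy, c(55, -20)),
                   shift(truth, c(55, -20)))$per_keypoint_pct, base)

  scale_track <- function(track, a) {
    track$coordinates <- track$coordinates * a
    track
  }
  expect_equal(pck(scale_track(noisy, 3),
                   scale_track(truth, 3))$per_keypoint_pct, base)
})

test_that("PCK input contracts are enforced", {
  t1 <- linear_track(10)
  t2 <- linear_track(12)
  expect_error(pck(t1, t2), "frame count")
  expect_error(keypoint_track(array(0, c(5, 3, 2)),
                              c("nose", "left_ear", "tail")), "right_ear")
})

test_that("forward filter reduces to its identity and uniform limits", {
  # identity dynamics: filtered = renormalized cumulative product of the
  # observation rows
  obs <- withr::with_seed(5, {
    m <- matrix(stats::runif(60, 0.05, 1), 20, 3)
    m / rowSums(m)
  })
  out <- kalman_label_filter(obs, diag(3))
  cp <- apply(obs, 2, cumprod)
  want <- cp / rowSums(cp)
  expect_equal(out$filtered_probabilities, want, tolerance = 1e-9,
               ignore_attr = TRUE)

  # identity dynamics + a consistent one-hot stream keep the input labels
  one_hot <- matrix(rep(c(0, 1, 0), each = 15), 15, 3)
  expect_identical(kalman_label_filter(one_hot, diag(3))$labels,
                   rep("sitting", 15))

  # uniform dynamics make the prediction uninformative
  obs2 <- withr::with_seed(6, {
    m <- matrix(stats::runif(60), 20, 3)
    m / rowSums(m)
  })
  out2 <- kalman_label_filter(obs2, matrix(1 / 3, 3, 3))
  expect_equal(out2$filtered_probabilities, obs2, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("one forward-recursion step matches the hand-computed value", {
  # two-state chain embedded in the 3-class alphabet: start mass on state 1,
  # flat observation; predict T' p = (0.9, 0.1), flat update leaves it
  tm <- rbind(c(0.9, 0.1, 0), c(0.2, 0.8, 0), c(0, 0, 1))
  obs <- rbind(c(1, 0, 0), c(1 / 3, 1 / 3, 1 / 3))
  out <- kalman_label_filter(obs, tm)
  expect_equal(unname(out$filtered_probabilities[2, ]), c(0.9, 0.1, 0),
               tolerance = 1e-12)
})

test_that("forward filter preserves the probability simplex and validates", {
  obs <- withr::with_seed(8, {
    m <- matrix(stats::rgamma(300, 1), 100, 3)
    m / rowSums(m)
  })
  tm <- behavior_transition_matrix(0.8)
  out <- kalman_label_filter(obs, tm)
  expect_true(all(abs(rowSums(out$filtered_probabilities) - 1) < 1e-9))
  expect_true(all(out$filtered_probabilities >= 0))

  expect_error(kalman_label_filter(obs, matrix(1, 3, 3)), "stochastic")
  expect_error(kalman_label_filter(obs * 2, tm), "sum to 1")
  # one-hot stream that contradicts identity dynamics -> zero posterior
  bad <- rbind(c(1, 0, 0), c(0, 0, 1))
  expect_error(kalman_label_filter(bad, diag(3)), "frame 2")
})

test_that("mode smoothing removes blips, keeps constants, is idempotent", {
  expect_identical(mode_smooth(rep("sitting", 50), 25), rep("sitting", 50))

  blip <- c(rep("running", 12), "grooming", rep("running", 12))
  expect_identical(mode_smooth(blip, 25), rep("running", 25))

  lab <- withr::with_seed(11, sample(behavior_classes(), 500, replace = TRUE,
                                     prob = c(0.5, 0.3, 0.2)))
  once <- mode_smooth(lab, 25)
  expect_identical(mode_smooth(once, 25), once)

  expect_error(mode_smooth(lab, 24), "odd")
  expect_error(mode_smooth(lab[1:10], 25), "length")
})

test_that("mode-smoothing ties go to the block's central frame", {
  # counts 10/10/5 with the central (13th) frame sitting
  block <- c(rep("running", 10), rep("sitting", 3), rep("grooming", 5),
             rep("sitting", 7))
  expect_identical(block[13], "sitting")
  expect_identical(mode_smooth(block, 25), rep("sitting", 25))
})

test_that("velocity of simple motions is exact", {
  still <- linear_track(40, step = 0)
  ks <- compute_velocity(still, fps = 15)
  expect_true(all(ks$velocity_raw == 0))
  expect_equal(ks$total_distance, 0)

  line <- linear_track(60, step = 2)
  ks2 <- compute_velocity(line, fps = 15)
  expect_true(all(abs(ks2$velocity_raw - 30) < 1e-9))
  expect_equal(ks2$total_distance, 59 * 2, tolerance = 1e-9)
  expect_error(compute_velocity(line, reference_point = "whisker"),
               "unknown reference")
  expect_error(compute_velocity(line, savgol_window = 14), "odd")
})

test_that("Savitzky-Golay smoothing beats the raw series on noisy motion", {
  for (seed in 1:5) {
    noisy <- jitter_track(linear_track(300, step = 2), 1.5, seed)
    ks <- compute_velocity(noisy, fps = 15)
    rmse <- function(v) sqrt(mean((v - 30)^2))
    expect_lt(rmse(ks$velocity_smooth), rmse(ks$velocity_raw))
  }
})

test_that("total distance is invariant under time reversal", {
  kt <- generate_keypoints(200, std_arena(), 20, seed = 17)
  rev_kt <- kt
  rev_kt$coordinates <- kt$coordinates[dim(kt$coordinates)[1]:1, , ]
  expect_equal(compute_velocity(kt)$total_distance,
               compute_velocity(rev_kt)$total_distance, tolerance = 1e-9)
})

test_that("occupancy and ethogram summaries conserve time and mass", {
  arena <- std_arena()
  centered <- linear_track(45, step = 0, origin = c(400, 400),
                           inter_ear = 10)
  labels <- behavior_label_track(rep("sitting", 45))
  ks <- occupancy_and_ethogram(centered, labels, arena, fps = 15)
  expect_equal(unname(ks$zone_occupancy[["central"]]), 3)
  expect_equal(sum(ks$zone_occupancy), 45 / 15)
  expect_equal(unname(ks$behavior_fractions), c(0, 1, 0))
  expect_identical(nrow(ks$frames), 45L)
  expect_error(occupancy_and_ethogram(centered,
                                      behavior_label_track(rep("sitting", 10)),
                                      arena), "frame count")
})
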