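icd_loop_oracle <- function(points) {
  n <- nrow(points)
  total <- 0
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (i != j) total <- total + sqrt(sum((points[i, ] - points[j, ])^2))
  total / (n * (n - 1))
}

toy_recording <- function(n_neurons, n_frames) {
  # labelled matrix: neuron j at frame t holds 100 t + j
  m <- outer(seq_len(n_neurons), seq_len(n_frames),
             function(j, t) 100 * t + j)
  calcium_recording(m, fps = 15)
}

test_that("window flattening obeys the shape and floor rules", {
  ws <- flatten_windows(toy_recording(3, 90), 30)
  expect_identical(dim(ws$vectors), c(3L, 90L))
  expect_identical(ws$window_start_frames, c(1L, 31L, 61L))

  expect_message(ws2 <- flatten_windows(toy_recording(2, 59), 30),
                 "29 trailing frames dropped")
  expect_identical(nrow(ws2$vectors), 1L)
  expect_error(flatten_windows(toy_recording(2, 20), 30), "shorter")
})

test_that("flattening is frame-major and invertible by index arithmetic", {
  n_neurons <- 4
  w <- 5
  rec <- toy_recording(n_neurons, 17)
  ws <- flatten_windows(rec, w)
  # index oracle: element i * N + j (0-based) of window k is neuron j + 1
  # at frame (k - 1) w + i + 1
  for (k in seq_len(nrow(ws$vectors)))
    for (i in 0:(w - 1))
      for (j in 0:(n_neurons - 1))
        expect_identical(ws$vectors[k, i * n_neurons + j + 1],
                         100 * ((k - 1) * w + i + 1) + (j + 1))
  # un-flatten: reshaping each row recovers the analysed frames
  rebuilt <- do.call(cbind, lapply(seq_len(nrow(ws$vectors)), function(k)
    matrix(ws$vectors[k, ], n_neurons, w)))
  expect_identical(rebuilt, rec$fluorescence[, 1:15])
})

test_that("PCA embedding is lossless on zero-padded planar data", {
  pts <- withr::with_seed(4, matrix(stats::rnorm(20), 10, 2))
  padded <- cbind(pts, matrix(0, 10, 4))
  emb <- embed_windows(padded, "pca", dim = 2, seed = 1)
  expect_equal(as.matrix(stats::dist(emb$points)),
               as.matrix(stats::dist(pts)), tolerance = 1e-9)
})

test_that("classical MDS reproduces a stress-free configuration", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  padded <- cbind(square, matrix(0, 4, 3))
  emb <- embed_windows(padded, "mds", dim = 2, seed = 1)
  expect_equal(as.matrix(stats::dist(emb$points)),
               as.matrix(stats::dist(square)), tolerance = 1e-3)
})

test_that("stochastic embeddings are deterministic given the seed", {
  x <- withr::with_seed(9, matrix(stats::rnorm(40 * 12), 40, 12))
  for (m in c("tsne", "umap", "ica")) {
    e1 <- suppressWarnings(embed_windows(x, m, seed = 7))
    e2 <- suppressWarnings(embed_windows(x, m, seed = 7))
    expect_identical(e1$points, e2$points)
    expect_identical(dim(e1$points), c(40L, 2L))
  }
})

test_that("embedding validates method, size and perplexity constraints", {
  x <- matrix(stats::rnorm(30), 10, 3)
  expect_error(embed_windows(x, "isomap"), "unknown embedding method")
  expect_error(embed_windows(x[1:2, ], "pca", dim = 2), "dim \\+ 1")
  expect_warning(embed_windows(matrix(stats::rnorm(200), 20, 10),
                               "tsne", seed = 1), "perplexity clamped")
  expect_error(suppressWarnings(embed_windows(x[1:3, ], "tsne", dim = 1,
                                              seed = 1)),
               "too few windows")
  expect_error(embed_windows(matrix(stats::rnorm(40), 10, 4), "tsne",
                             dim = 4, seed = 1), "dim <= 3")
})

test_that("embedding rows stay aligned with their windows", {
  rec <- generate_calcium(synthetic_cohort_config(n_neurons = 10,
                                                  n_frames = 600, seed = 2))
  ws <- flatten_windows(rec)
  emb <- embed_windows(ws, "pca", seed = 1)
  expect_identical(nrow(emb$points), nrow(ws$vectors))
  expect_identical(emb$session_id, rec$session_id)
  expect_identical(emb$group_tag, rec$group_tag)
})

test_that("intracluster distance matches closed forms and the loop oracle", {
  expect_equal(intracluster_distance(rbind(c(0, 0),
                                           c(3, 4)))$intracluster_distance, 5)
  tri <- rbind(c(0, 0), c(2, 0), c(1, sqrt(3)))
  expect_equal(intracluster_distance(tri)$intracluster_distance, 2,
               tolerance = 1e-12)
  pts <- withr::with_seed(3, matrix(stats::rnorm(100), 50, 2))
  expect_lt(abs(intracluster_distance(pts)$intracluster_distance -
                  icd_loop_oracle(pts)), 1e-9)
  expect_error(intracluster_distance(rbind(c(1, 1))), "at least 2")
})

test_that("intracluster distance is translation invariant and scales linearly", {
  pts <- withr::with_seed(5, matrix(stats::rnorm(60), 30, 2))
  base <- intracluster_distance(pts)$intracluster_distance
  shifted <- sweep(pts, 2, c(100, -40), "+")
  expect_equal(intracluster_distance(shifted)$intracluster_distance, base,
               tolerance = 1e-12)
  expect_equal(intracluster_distance(2.5 * pts)$intracluster_distance,
               2.5 * base, tolerance = 1e-12)
})

test_that("frame permutation preserves each neuron's value multiset", {
  rec <- generate_calcium(synthetic_cohort_config(n_neurons = 8,
                                                  n_frames = 400, seed = 6))
  sh <- temporal_shuffle(rec, "permute_frames", seed = 3)
  for (i in 1:8)
    expect_identical(sort(sh$fluorescence[i, ]), sort(rec$fluorescence[i, ]))
  sh2 <- temporal_shuffle(rec, "permute_frames", seed = 3)
  expect_identical(sh$fluorescence, sh2$fluorescence)
  expect_error(temporal_shuffle(rec, "bootstrap"), "unknown shuffle mode")
})

test_that("phase randomization preserves the amplitude spectrum", {
  for (n_frames in c(400, 401)) {   # even and odd lengths
    rec <- generate_calcium(synthetic_cohort_config(n_neurons = 4,
                                                    n_frames = n_frames,
                                                    seed = 8))
    sh <- temporal_shuffle(rec, "phase_randomize", seed = 5)
    for (i in 1:4)
      expect_lt(max(abs(Mod(stats::fft(sh$fluorescence[i, ])) -
                          Mod(stats::fft(rec$fluorescence[i, ])))), 1e-8)
  }
})

test_that("shuffling decorrelates perfectly correlated neurons", {
  for (seed in 1:10) {
    base <- withr::with_seed(seed, as.numeric(stats::arima.sim(
      list(ar = 0.9), 4500)))
    rec <- calcium_recording(rbind(base, base), fps = 15)
    sh <- temporal_shuffle(rec, "permute_frames", seed = seed + 50)
    expect_lt(abs(stats::cor(sh$fluorescence[1, ], sh$fluorescence[2, ])),
              0.1)
  }
})
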