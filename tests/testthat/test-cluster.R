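# Hierarchical clustering, silhouette model selection, cluster averages.

test_that("UPGMA merges two tight pairs first, then joins them at the cross distance", {
  D <- matrix(10, 4, 4)
  D[1, 2] <- D[2, 1] <- 1
  D[3, 4] <- D[4, 3] <- 1
  diag(D) <- 0
  rownames(D) <- colnames(D) <- paste0("t", 1:4)
  tree <- behavior_linkage(D, "upgma")
  expect_equal(tree$merges$height, c(1, 1, 10))
  expect_equal(tree$merges$size, c(2L, 2L, 4L))

  D2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  tree2 <- behavior_linkage(D2)
  expect_equal(tree2$merges$height, 3)
})

test_that("UPGMA matches a naive O(n^3) agglomerative oracle on random metric inputs", {
  for (seed in c(5, 19)) {
    D <- random_metric_matrix(6, seed)
    rownames(D) <- colnames(D) <- paste0("t", 1:6)
    tree <- behavior_linkage(D, "upgma")
    got <- hclust_merges(tree$hclust)
    want <- oracle_upgma(D)
    for (i in seq_along(want)) {
      expect_equal(got[[i]]$height, want[[i]]$height, tolerance = 1e-9)
      expect_equal(got[[i]]$members, want[[i]]$members)
    }
  }
})

test_that("UPGMA heights are monotone non-decreasing on metric inputs", {
  for (seed in 1:5) {
    D <- random_metric_matrix(8, seed)
    tree <- behavior_linkage(D, "upgma")
    expect_true(all(diff(tree$merges$height) >= -1e-12))
  }
})

test_that("invalid distance inputs are rejected", {
  M <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(behavior_linkage(M), "symmetric")
  M2 <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(behavior_linkage(M2), "negative")
})

test_that("silhouette hits its closed-form limits and the per-point oracle", {
  D <- matrix(10, 4, 4)
  D[1, 2] <- D[2, 1] <- 0
  D[3, 4] <- D[4, 3] <- 0
  diag(D) <- 0
  expect_equal(silhouette_score(D, c(1, 1, 2, 2)), 1.0)

  E <- matrix(5, 6, 6)
  diag(E) <- 0
  expect_equal(silhouette_score(E, rep(1:2, each = 3)), 0.0)

  D8 <- random_metric_matrix(8, seed = 77)
  labels <- stsmap:::with_seed(78, sample(1:3, 8, replace = TRUE))
  while (length(unique(labels)) < 2) labels <- sample(1:3, 8, replace = TRUE)
  expect_equal(silhouette_score(D8, labels), oracle_silhouette(D8, labels),
               tolerance = 1e-12)

  expect_error(silhouette_score(D8, rep(1, 8)), "single cluster")
  expect_error(silhouette_score(D8, 1:8), "degenerate")
  expect_true(abs(silhouette_score(D8, labels)) <= 1)
})

test_that("silhouette selects the planted cluster count", {
  # two planted groups
  lib <- simulate_library(seed = 1)
  frames <- lapply(lib$trials, function(tr) object_frame_from_scan(tr$scan, tr$sequence))
  rs <- lapply(Map(normalize_sequence, lapply(lib$trials, `[[`, "sequence"),
                   frames), resample_sequence)
  D <- distance_matrix(rs)
  model <- select_k(behavior_linkage(D), D)
  expect_equal(model$selected_k, 2L)
  expect_equal(ari(model$labels, lib$metadata$archetype), 1.0)

  # three far-separated groups
  centers <- c(0, 5, 10)
  lib3 <- unlist(lapply(1:3, function(g) {
    lapply(1:4, function(i) {
      arr <- array(centers[g], dim = c(20, 13, 3)) +
        stsmap:::with_seed(g * 10 + i, array(rnorm(20 * 13 * 3, sd = 0.01),
                                             dim = c(20, 13, 3)))
      skeleton_sequence(sprintf("g%d_%d", g, i), arr, "object")
    })
  }), recursive = FALSE)
  rs3 <- lapply(lib3, resample_sequence, n_out = 100)
  D3 <- distance_matrix(rs3)
  model3 <- select_k(behavior_linkage(D3), D3, k_range = 2:8)
  expect_equal(model3$selected_k, 3L)

  expect_error(select_k(behavior_linkage(D3), D3, k_range = integer(0)), "empty")
  expect_error(select_k(behavior_linkage(D3), D3, k_range = 2:20), "within")
})

test_that("near-duplicates of one behavior share a label at the selected k", {
  base <- tiny_resampled_library(1, seed = 50, n_frames = 30)[[1]]
  dups <- lapply(1:5, function(i) {
    s <- base
    s$trial_id <- paste0("dup", i)
    s$frames <- s$frames + stsmap:::with_seed(60 + i, array(
      rnorm(length(s$frames), sd = 1e-4), dim = dim(s$frames)))
    s
  })
  far <- lapply(1:3, function(i) {
    s <- tiny_resampled_library(1, seed = 70 + i, n_frames = 30)[[1]]
    s$trial_id <- paste0("far", i)
    s$frames <- s$frames + 50
    s
  })
  D <- distance_matrix(c(dups, far))
  model <- select_k(behavior_linkage(D), D, k_range = 2:6)
  expect_equal(length(unique(model$labels[paste0("dup", 1:5)])), 1L)
})

test_that("Ward linkage agrees with UPGMA on the planted two-cluster split", {
  lib <- simulate_library(seed = 2)
  frames <- lapply(lib$trials, function(tr) object_frame_from_scan(tr$scan, tr$sequence))
  rs <- lapply(Map(normalize_sequence, lapply(lib$trials, `[[`, "sequence"),
                   frames), resample_sequence)
  D <- distance_matrix(rs)
  m_upgma <- select_k(behavior_linkage(D, "upgma"), D)
  m_ward <- suppressMessages(select_k(behavior_linkage(D, "ward"), D))
  expect_equal(m_ward$selected_k, 2L)
  expect_equal(ari(m_upgma$labels, m_ward$labels), 1.0)
})

test_that("cluster averages equal the elementwise-mean oracle", {
  one <- tiny_resampled_library(1, seed = 90)[[1]]
  expect_equal(average_behavior(list(one))$frames, one$frames)

  lib <- tiny_resampled_library(2, seed = 91)
  mid <- average_behavior(lib)
  expect_equal(mid$frames, (lib[[1]]$frames + lib[[2]]$frames) / 2,
               tolerance = 1e-12)

  lib5 <- tiny_resampled_library(5, seed = 92)
  av <- average_behavior(lib5, cluster_id = 1L)
  oracle <- array(0, dim = dim(lib5[[1]]$frames))
  for (t in seq_len(dim(oracle)[1])) for (j in 1:13) for (k in 1:3) {
    oracle[t, j, k] <- mean(vapply(lib5, function(s) s$frames[t, j, k], numeric(1)))
  }
  expect_equal(unname(av$frames), oracle, tolerance = 1e-12)
  expect_equal(av$n, 5L)
  expect_error(average_behavior(list()), "empty")
})

test_that("archetype recovery is perfect across seeds", {
  aris <- vapply(1:6, function(s) {
    lib <- simulate_library(seed = s)
    frames <- lapply(lib$trials, function(tr) object_frame_from_scan(tr$scan, tr$sequence))
    rs <- lapply(Map(normalize_sequence, lapply(lib$trials, `[[`, "sequence"),
                     frames), resample_sequence, n_out = 250)
    D <- distance_matrix(rs)
    model <- select_k(behavior_linkage(D), D)
    ari(model$labels, lib$metadata$archetype)
  }, numeric(1))
  expect_equal(stats::median(aris), 1.0)
})
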