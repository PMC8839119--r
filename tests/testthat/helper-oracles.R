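# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Manhattan trajectory distance for one joint: explicit double loop.
oracle_joint_distance <- function(A, B, j) {
  total <- 0
  for (t in seq_len(dim(A$frames)[1])) {
    for (k in 1:3) {
      total <- total + abs(A$frames[t, j, k] - B$frames[t, j, k])
    }
  }
  total
}

oracle_dsum <- function(library) {
  n <- length(library)
  D <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      for (j in 1:13) D[a, b] <- D[a, b] + oracle_joint_distance(library[[a]], library[[b]], j)
    }
  }
  D
}

# Naive O(n^3) UPGMA: returns the merge sequence as a list of
# list(height, members) with members the sorted leaf indices of the newly
# formed cluster. Ties broken by lexicographically smallest index pair.
oracle_upgma <- function(D) {
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL
    for (a in seq_len(length(clusters) - 1L)) {
      for (b in (a + 1L):length(clusters)) {
        d <- mean(D[clusters[[a]], clusters[[b]]])
        if (is.null(best) || d < best$d - 1e-12) best <- list(a = a, b = b, d = d)
      }
    }
    members <- sort(c(clusters[[best$a]], clusters[[best$b]]))
    merges[[length(merges) + 1L]] <- list(height = best$d, members = members)
    clusters[[best$a]] <- members
    clusters[[best$b]] <- NULL
  }
  merges
}

# Extract the same merge representation from an hclust fit.
hclust_merges <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  out <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    grab <- function(x) if (x < 0) -x else sets[[x]]
    sets[[i]] <- sort(c(grab(hc$merge[i, 1]), grab(hc$merge[i, 2])))
    out[[i]] <- list(height = hc$height[i], members = sets[[i]])
  }
  out
}

# Per-point silhouette from the definition.
oracle_silhouette <- function(D, labels) {
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(D[i, labels == cl])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Adjusted Rand index between two labelings.
ari <- function(x, y) {
  tab <- table(x, y)
  comb2 <- function(m) sum(choose(m, 2))
  sum_ij <- comb2(tab)
  sum_i <- comb2(rowSums(tab))
  sum_j <- comb2(colSums(tab))
  expected <- sum_i * sum_j / choose(sum(tab), 2)
  maxidx <- (sum_i + sum_j) / 2
  (sum_ij - expected) / (maxidx - expected)
}

# Random n-point metric distance matrix (Euclidean in R^5).
random_metric_matrix <- function(n, seed) {
  stsmap:::with_seed(seed, {
    X <- matrix(stats::rnorm(n * 5), n)
    as.matrix(stats::dist(X))
  })
}

# A small synthetic resampled library for metric tests.
tiny_resampled_library <- function(n, seed, n_frames = 40) {
  stsmap:::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      arr <- array(stats::rnorm(n_frames * 13 * 3), dim = c(n_frames, 13, 3))
      skeleton_sequence(paste0("trial", i), arr, "object")
    })
  })
}

make_object_sequence <- function(frames, trial_id = "t") {
  skeleton_sequence(trial_id, frames, "object")
}
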