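# Independent oracles used across the suite. Each deliberately takes the
# dumbest correct route (enumeration, literal formula application, brute
# force) so it shares no code path with the implementation it checks.

# Hypergeometric tails by exhaustive enumeration of all C(N, n) draws from a
# universe with K successes.
enum_hyper <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # successes are items 1..K
  c(upper = mean(hits >= k), lower = mean(hits <= k))
}

enum_two_sided <- function(N, K, n, k) {
  t <- enum_hyper(N, K, n, k)
  min(1, 2 * min(t[["upper"]], t[["lower"]]))
}

# Literal counting oracle for the consensus vote.
vote_oracle <- function(calls, min_same, forbid_opposite, fc_min = NULL, fcs = NULL) {
  ok <- character()
  for (d in c("up", "down")) {
    o <- if (d == "up") "down" else "up"
    n_same <- sum(calls == d)
    if (n_same < min_same) next
    if (forbid_opposite && sum(calls == o) > 0) next
    if (!is.null(fc_min)) {
      mags <- pmax(fcs, 1 / fcs)[calls == d]
      if (any(mags < fc_min)) next
    }
    ok <- c(ok, d)
  }
  if (length(ok) == 1) ok else "none"
}

# Literal counting oracle for specificity inclusion given the target call and
# the calls over the other datasets.
specific_oracle <- function(target_dir, others, min_opposite, max_identical) {
  opp <- if (target_dir == "up") "down" else "up"
  sum(others == opp) >= min_opposite && sum(others == target_dir) <= max_identical
}

# Direct application of the Holm step-down formula.
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force agglomeration: at every step recompute the linkage distance of
# every active cluster pair from the ORIGINAL pairwise distance matrix, merge
# the closest pair. Returns the partition merged at each step (as sets of
# leaf indices) and the join height. Assumes tie-free instances.
agglom_oracle <- function(d, linkage = "average") {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  steps <- list()
  while (length(clusters) > 1L) {
    best <- NULL; best_d <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        pairs <- d[clusters[[i]], clusters[[j]], drop = FALSE]
        ld <- switch(linkage, average = mean(pairs), single = min(pairs),
                     complete = max(pairs))
        if (ld < best_d) { best_d <- ld; best <- c(i, j) }
      }
    }
    steps[[length(steps) + 1L]] <- list(
      members = list(sort(clusters[[best[1]]]), sort(clusters[[best[2]]])),
      height = best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  steps
}

# Recover, for each merge step of a cluster_result, the two member sets that
# were joined (as sorted leaf-index vectors).
merge_members <- function(merge) {
  sets <- list()
  expand <- function(id) if (id < 0) -id else sets[[id]]
  lapply(seq_len(nrow(merge)), function(k) {
    a <- expand(merge[k, 1]); b <- expand(merge[k, 2])
    sets[[k]] <<- sort(c(a, b))
    list(sort(a), sort(b))
  })
}

# Pairwise uncentered-correlation distance computed the slow elementwise way.
slow_uncentered_dist <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- 1 - sum(mat[i, ] * mat[j, ]) /
      (sqrt(sum(mat[i, ]^2)) * sqrt(sum(mat[j, ]^2)))
  }
  d
}

f1_of <- function(truth, found) {
  tp <- length(intersect(truth, found))
  2 * tp / (2 * tp + length(setdiff(found, truth)) + length(setdiff(truth, found)))
}

uncentered_dist_for_test <- slow_uncentered_dist

# The two member sets joined at one step, compared as an unordered pair.
expect_setequal_members <- function(got, want) {
  same <- (identical(got[[1]], want[[1]]) && identical(got[[2]], want[[2]])) ||
    (identical(got[[1]], want[[2]]) && identical(got[[2]], want[[1]]))
  testthat::expect_true(same)
}
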