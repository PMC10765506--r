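# Independent brute-force oracles used to cross-check the clustering and
# runs-test code paths. These recompute objectives from scratch at every
# step and share no code with the package internals.

# Greedy Ward agglomeration recomputing the within-cluster ESS increase
# of every candidate merge from the raw coordinates. Heights follow the
# sqrt(2 * delta-ESS) convention (distance scale).
naive_ward <- function(X) {
  n <- nrow(X)
  clusters <- as.list(seq_len(n))
  ess <- function(idx) {
    if (length(idx) == 1L) return(0)
    C <- colMeans(X[idx, , drop = FALSE])
    sum(sweep(X[idx, , drop = FALSE], 2L, C)^2)
  }
  heights <- numeric(n - 1L)
  partitions <- vector("list", n - 1L)
  for (t in seq_len(n - 1L)) {
    m <- length(clusters)
    bestd <- Inf; best <- NULL
    for (i in 1:(m - 1L)) for (j in (i + 1L):m) {
      d <- ess(c(clusters[[i]], clusters[[j]])) -
        ess(clusters[[i]]) - ess(clusters[[j]])
      if (d < bestd - 1e-12) { bestd <- d; best <- c(i, j) }
    }
    heights[t] <- sqrt(2 * bestd)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
    partitions[[t]] <- canonical_partition(clusters)
  }
  list(heights = heights, partitions = partitions)
}

# UPGMA recomputing every inter-cluster average from the original
# distance matrix at each step.
naive_upgma <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  avg <- function(a, b) mean(D[a, b])
  heights <- numeric(n - 1L)
  partitions <- vector("list", n - 1L)
  for (t in seq_len(n - 1L)) {
    m <- length(clusters)
    bestd <- Inf; best <- NULL
    for (i in 1:(m - 1L)) for (j in (i + 1L):m) {
      d <- avg(clusters[[i]], clusters[[j]])
      if (d < bestd - 1e-12) { bestd <- d; best <- c(i, j) }
    }
    heights[t] <- bestd
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
    partitions[[t]] <- canonical_partition(clusters)
  }
  list(heights = heights, partitions = partitions)
}

canonical_partition <- function(sets) {
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, `[`, numeric(1L), 1L))]
}

# partition of 1..n implied by an hclust tree cut into k groups
hclust_partition <- function(hc, k) {
  canonical_partition(unname(split(seq_along(cutree(hc, k)), cutree(hc, k))))
}

# full agreement between an hclust tree and an oracle run
tree_agrees_with_oracle <- function(hc, oracle, tol = 1e-8) {
  n <- length(hc$height) + 1L
  if (max(abs(sort(hc$height) - oracle$heights)) > tol) return(FALSE)
  for (t in seq_len(n - 1L)) {
    if (!identical(hclust_partition(hc, n - t), oracle$partitions[[t]]))
      return(FALSE)
  }
  TRUE
}

# exact runs-test null distribution by enumerating all sign arrangements
runs_dist_enum <- function(n1, n2) {
  n <- n1 + n2
  pos <- utils::combn(n, n1)
  runs <- apply(pos, 2L, function(p) {
    s <- rep(-1L, n); s[p] <- 1L
    1L + sum(diff(s) != 0L)
  })
  table(runs) / ncol(pos)
}

two_sided_runs_p <- function(pmf, r) {
  rv <- as.integer(names(pmf))
  min(1, 2 * min(sum(pmf[rv <= r]), sum(pmf[rv >= r])))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# a +/-1 sequence with n1 pluses, n2 minuses and exactly r runs
sequence_with_runs <- function(n1, n2, r) {
  a <- ceiling(r / 2); b <- floor(r / 2)
  stopifnot(a <= n1, b <= n2)
  plus_sizes <- c(n1 - a + 1L, rep(1L, a - 1L))
  minus_sizes <- c(n2 - b + 1L, rep(1L, b - 1L))
  out <- integer(0)
  for (i in seq_len(max(a, b))) {
    if (i <= a) out <- c(out, rep(1L, plus_sizes[i]))
    if (i <= b) out <- c(out, rep(-1L, minus_sizes[i]))
  }
  out
}

# small well-formed assay panel used by several IO tests
example_panel <- function(killer = "neutral", h2s = c(0, 1, 1),
                          acetic = "producer", so2_top = 500,
                          bglu = "negative") {
  list(killer = killer,
       h2s_scores = setNames(h2s, c(2, 5, 8)),
       acetic = acetic,
       so2_growth = setNames(c(0, 100, 200, 300, 400, 500) <= so2_top,
                             c(0, 100, 200, 300, 400, 500)),
       bglu = bglu)
}
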