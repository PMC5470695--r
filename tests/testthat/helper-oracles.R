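# Independent brute-force oracles used across the clustering tests.
#
# lw_oracle() re-runs the agglomeration from scratch: at every step each
# inter-cluster dissimilarity is recomputed from first principles (min/max/
# mean over member pairs, explicit centroids and recursive midpoints,
# explicit within-cluster sums of squares) rather than by the recurrence
# under test. Tie-breaks mirror the implementation: scan pairs in slot
# order, strict improvement only.

lw_base_matrix <- function(x, method) {
  base <- as.matrix(stats::dist(x))
  switch(method,
         single = , complete = , group_average = , weighted_average = base,
         centroid = , median = base^2,
         ward = base^2 / 2)
}

lw_oracle <- function(x, method) {
  x <- as.matrix(x)                      # objects in rows
  n <- nrow(x)
  base <- as.matrix(stats::dist(x))
  D0 <- lw_base_matrix(x, method)

  sse <- function(members) {
    xm <- x[members, , drop = FALSE]
    sum(sweep(xm, 2L, colMeans(xm))^2)
  }
  midpt <- function(node) {
    if (is.numeric(node)) return(x[node, ])
    (midpt(node$l) + midpt(node$r)) / 2
  }
  wp <- function(n1, n2) {
    if (!is.numeric(n1)) return((wp(n1$l, n2) + wp(n1$r, n2)) / 2)
    if (!is.numeric(n2)) return((wp(n1, n2$l) + wp(n1, n2$r)) / 2)
    D0[n1, n2]
  }
  cluster_dist <- function(a, b) {
    switch(method,
      single = min(base[a$members, b$members]),
      complete = max(base[a$members, b$members]),
      group_average = mean(base[a$members, b$members]),
      weighted_average = wp(a$node, b$node),
      centroid = sum((colMeans(x[a$members, , drop = FALSE]) -
                      colMeans(x[b$members, , drop = FALSE]))^2),
      median = sum((midpt(a$node) - midpt(b$node))^2),
      ward = sse(c(a$members, b$members)) - sse(a$members) - sse(b$members))
  }

  clusters <- lapply(seq_len(n), function(i) list(members = i, node = i))
  heights <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    live <- which(!vapply(clusters, is.null, logical(1L)))
    best <- NULL; bestd <- Inf
    for (ai in seq_along(live)) {
      if (ai == length(live)) break
      for (bi in (ai + 1L):length(live)) {
        i <- live[ai]; j <- live[bi]
        d <- cluster_dist(clusters[[i]], clusters[[j]])
        if (d < bestd) { bestd <- d; best <- c(i, j) }
      }
    }
    i <- best[1L]; j <- best[2L]
    heights[step] <- bestd
    clusters[[i]] <- list(members = c(clusters[[i]]$members, clusters[[j]]$members),
                          node = list(l = clusters[[i]]$node, r = clusters[[j]]$node))
    clusters[j] <- list(NULL)
  }
  heights
}

# run the package implementation on the metric each scheme requires
lw_impl_heights <- function(x, method) {
  metric <- switch(linkage_scheme(method)$required_input,
                   any = "euclidean",
                   squared_euclidean = "squared_euclidean",
                   half_squared_euclidean = "half_squared_euclidean")
  agglomerate(pairwise(t(x), metric = metric), method)$height
}

random_points <- function(n, dim, seed) {
  set.seed(seed)
  matrix(stats::runif(n * dim), n, dim)
}

# partitions from the seven linkages at a k = 2 cut, per required metric
seven_bipartitions <- function(m) {
  lapply(stats::setNames(nm = linkage_methods()), function(meth) {
    metric <- switch(linkage_scheme(meth)$required_input,
                     any = "euclidean",
                     squared_euclidean = "squared_euclidean",
                     half_squared_euclidean = "half_squared_euclidean")
    cut_tree(agglomerate(pairwise(m, metric = metric), meth), 2)
  })
}
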