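#' Lloyd k-means over sample columns
#'
#' Classical Lloyd iterations under squared Euclidean dissimilarity, with
#' multiple random restarts and the best (lowest) within-cluster
#' sum-of-squares solution kept. Deterministic for a given `seed`:
#' initial centroids are drawn as `k` distinct columns, assignment ties go
#' to the lowest cluster index, and an emptied cluster is re-seeded from
#' the point currently farthest from its assigned centroid.
#'
#' @param m Numeric matrix; objects to cluster are the *columns* (samples),
#'   matching the sample-clustering orientation of the rest of the package.
#' @param k Number of clusters, `1 <= k <=` number of columns.
#' @param restarts Number of random restarts (default 25).
#' @param seed Integer seed; the RNG state is restored on exit.
#' @param max_iter Safety cap on Lloyd iterations per restart.
#' @return A [partition()] with the within-cluster sum of squared distances
#'   to centroids in `$objective`.
#' @export
kmeans_lloyd <- function(m, k, restarts = 25L, seed = NULL, max_iter = 100L) {
  x <- if (inherits(m, "abundance_matrix")) unclass_matrix(m) else as.matrix(m)
  x <- t(x)                              # objects in rows
  n <- nrow(x)
  if (k < 1L || k > n) stop("k must be between 1 and the number of columns",
                            call. = FALSE)
  ids <- rownames(x) %||% as.character(seq_len(n))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  best <- NULL
  for (r in seq_len(max(1L, restarts))) {
    centers <- x[sample.int(n, k), , drop = FALSE]
    assign_prev <- rep(0L, n)
    for (it in seq_len(max_iter)) {
      d2 <- sq_dist_to_centers(x, centers)
      assign_cur <- max.col(-d2, ties.method = "first")
      # re-seed emptied clusters from the farthest point
      repeat {
        empty <- setdiff(seq_len(k), unique(assign_cur))
        if (!length(empty)) break
        cur <- d2[cbind(seq_len(n), assign_cur)]
        far <- which.max(cur)
        if (cur[far] <= 0) break   # duplicated points: cluster stays empty
        centers[empty[1L], ] <- x[far, ]
        d2 <- sq_dist_to_centers(x, centers)
        assign_cur <- max.col(-d2, ties.method = "first")
      }
      if (identical(assign_cur, assign_prev)) break
      assign_prev <- assign_cur
      for (c in seq_len(k)) {
        if (any(assign_cur == c)) {
          centers[c, ] <- colMeans(x[assign_cur == c, , drop = FALSE])
        }
      }
    }
    d2 <- sq_dist_to_centers(x, centers)
    obj <- sum(d2[cbind(seq_len(n), assign_cur)])
    if (is.null(best) || obj < best$objective - 1e-12) {
      best <- list(labels = assign_cur, objective = obj)
    }
  }
  partition(ids = ids, labels = best$labels, k = k, objective = best$objective)
}

sq_dist_to_centers <- function(x, centers) {
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  d2 <- outer(xx, cc, `+`) - 2 * x %*% t(centers)
  pmax(d2, 0)
}

#' Agreement between partitions
#'
#' Quantifies how consistently different clustering methods partition the
#' same objects. For each pair of partitions the label-invariant Rand
#' (pair-counting) index is computed; a pair of identical-up-to-relabelling
#' partitions scores exactly 1. The report carries both the mean pairwise
#' Rand index (`overall`) and the fraction of pairs that agree exactly
#' (`frac_identical`). When a reference split is supplied (e.g. the known
#' control/treatment design), each partition is additionally checked for
#' separating the reference groups exactly.
#'
#' @param partitions List of [partition()] objects over identical id sets.
#' @param reference_split Optional named vector mapping id to group label.
#' @return List: `pairwise` (Rand matrix), `overall`, `frac_identical`,
#'   and, given a reference, `matches_reference` (logical per partition)
#'   and `all_match_reference`.
#' @export
agreement <- function(partitions, reference_split = NULL) {
  stopifnot(length(partitions) >= 1L)
  ids <- partitions[[1L]]$ids
  labs <- lapply(partitions, function(p) {
    if (!setequal(p$ids, ids) || length(p$ids) != length(ids)) {
      stop("contract error: partitions are over different id sets", call. = FALSE)
    }
    p$labels[ids]
  })
  np <- length(labs)
  pw <- matrix(1, np, np)
  idn <- names(partitions) %||% as.character(seq_len(np))
  dimnames(pw) <- list(idn, idn)
  if (np > 1L) {
    for (a in seq_len(np - 1L)) {
      for (b in (a + 1L):np) {
        pw[a, b] <- pw[b, a] <- rand_index(labs[[a]], labs[[b]])
      }
    }
  }
  upper <- pw[upper.tri(pw)]
  out <- list(pairwise = pw,
              overall = if (length(upper)) mean(upper) else 1,
              frac_identical = if (length(upper)) mean(upper == 1) else 1)
  if (!is.null(reference_split)) {
    ref <- as.character(reference_split[ids])
    if (anyNA(ref)) {
      stop("contract error: reference split missing some ids", call. = FALSE)
    }
    out$matches_reference <- vapply(labs, function(l) {
      same_partition(l, match(ref, unique(ref)))
    }, logical(1L))
    names(out$matches_reference) <- idn
    out$all_match_reference <- all(out$matches_reference)
  }
  out
}

rand_index <- function(a, b) {
  n <- length(a)
  ct <- table(a, b)
  s_ab <- sum(choose(ct, 2))
  s_a <- sum(choose(rowSums(ct), 2))
  s_b <- sum(choose(colSums(ct), 2))
  tot <- choose(n, 2)
  # agreements = pairs together in both + pairs apart in both
  (tot + 2 * s_ab - s_a - s_b) / tot
}

same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}
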