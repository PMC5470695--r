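#' Lance-Williams coefficient schemes for the seven linkage methods
#'
#' Agglomerative hierarchical clustering can be written as one recurrence:
#' after merging clusters `i` and `j`, the dissimilarity to any other
#' cluster `k` is
#' \deqn{d(C_i \cup C_j, C_k) = \alpha_i d(C_i, C_k) + \alpha_j d(C_j, C_k)
#'   + \beta d(C_i, C_j) + \gamma |d(C_i, C_k) - d(C_j, C_k)|.}
#' The seven classical methods differ only in the coefficients, which may
#' depend on the current cluster sizes `n_i`, `n_j`, `n_k`:
#'
#' | method | alpha_i | alpha_j | beta | gamma | input | monotone |
#' |---|---|---|---|---|---|---|
#' | single | 1/2 | 1/2 | 0 | -1/2 | any | yes |
#' | complete | 1/2 | 1/2 | 0 | 1/2 | any | yes |
#' | group_average | n_i/(n_i+n_j) | n_j/(n_i+n_j) | 0 | 0 | any | yes |
#' | weighted_average | 1/2 | 1/2 | 0 | 0 | any | yes |
#' | centroid | n_i/(n_i+n_j) | n_j/(n_i+n_j) | -n_i n_j/(n_i+n_j)^2 | 0 | squared Euclidean | no |
#' | median | 1/2 | 1/2 | -1/4 | 0 | squared Euclidean | no |
#' | ward | (n_i+n_k)/(n_i+n_j+n_k) | (n_j+n_k)/(n_i+n_j+n_k) | -n_k/(n_i+n_j+n_k) | 0 | half squared Euclidean | yes |
#'
#' On their required inputs, centroid/median merge heights equal squared
#' distances between cluster centroids/recursive midpoints, and Ward merge
#' heights equal the increase in total within-cluster sum of squares.
#' Centroid and median linkage are not monotone: merge heights can invert.
#'
#' @param method One of `"single"`, `"complete"`, `"group_average"`,
#'   `"weighted_average"`, `"centroid"`, `"median"`, `"ward"`.
#' @return A `linkage_scheme` list: `method`, `coef(ni, nj, nk)` returning
#'   `c(alpha_i, alpha_j, beta, gamma)`, `required_input` (`"any"`,
#'   `"squared_euclidean"` or `"half_squared_euclidean"`), and `monotone`.
#' @export
linkage_scheme <- function(method = c("single", "complete", "group_average",
                                      "weighted_average", "centroid",
                                      "median", "ward")) {
  method <- match.arg(method)
  coef <- switch(method,
    single = function(ni, nj, nk) c(0.5, 0.5, 0, -0.5),
    complete = function(ni, nj, nk) c(0.5, 0.5, 0, 0.5),
    group_average = function(ni, nj, nk)
      c(ni / (ni + nj), nj / (ni + nj), 0, 0),
    weighted_average = function(ni, nj, nk) c(0.5, 0.5, 0, 0),
    centroid = function(ni, nj, nk)
      c(ni / (ni + nj), nj / (ni + nj), -ni * nj / (ni + nj)^2, 0),
    median = function(ni, nj, nk) c(0.5, 0.5, -0.25, 0),
    ward = function(ni, nj, nk) {
      s <- ni + nj + nk
      c((ni + nk) / s, (nj + nk) / s, -nk / s, 0)
    })
  required <- switch(method,
                     centroid = , median = "squared_euclidean",
                     ward = "half_squared_euclidean",
                     "any")
  monotone <- !(method %in% c("centroid", "median"))
  structure(list(method = method, coef = coef, required_input = required,
                 monotone = monotone),
            class = "linkage_scheme")
}

#' All seven linkage method names
#' @return Character vector in canonical order.
#' @export
linkage_methods <- function() {
  c("single", "complete", "group_average", "weighted_average",
    "centroid", "median", "ward")
}

#' Agglomerative clustering via the Lance-Williams recurrence
#'
#' Repeatedly merges the globally closest pair of clusters and updates all
#' remaining dissimilarities with the scheme's coefficients. Ties for the
#' closest pair are broken by the lexicographically smallest pair of
#' cluster indices (clusters indexed in creation order: leaves first, then
#' merge products), so results are deterministic across platforms.
#'
#' Methods with a restricted input dissimilarity (centroid/median need
#' squared Euclidean, Ward half squared Euclidean) refuse other
#' `metric_name` tags unless `waiver = TRUE`: the recurrence is only
#' meaningful on the stated dissimilarity. Heights are reported in the
#' input dissimilarity's units; no square root is taken.
#'
#' @param d A [as_dissimilarity()] matrix (or plain square matrix, treated
#'   as `"custom"`).
#' @param method Linkage method name or a [linkage_scheme()].
#' @param waiver Set `TRUE` to override the input-metric contract check.
#' @return A `merge_tree`: list with `n_leaves`, `labels`, `merge`
#'   (`(n-1) x 2`, negative entries = leaves, positive = earlier merge
#'   rows), `height`, `size` (entities per new cluster), `method`,
#'   `metric_name`.
#' @export
agglomerate <- function(d, method = "group_average", waiver = FALSE) {
  scheme <- if (inherits(method, "linkage_scheme")) method
            else linkage_scheme(method)
  if (!inherits(d, "dissimilarity_matrix")) d <- as_dissimilarity(d)
  metric_name <- attr(d, "metric_name")
  if (scheme$required_input != "any" &&
      !identical(metric_name, scheme$required_input) && !waiver) {
    stop(sprintf(
      "contract error: %s linkage requires a %s dissimilarity (got '%s'); pass waiver = TRUE to override",
      scheme$method, scheme$required_input, metric_name), call. = FALSE)
  }
  if (identical(metric_name, "rbf_similarity")) {
    stop("cannot agglomerate a similarity matrix; convert to a dissimilarity first",
         call. = FALSE)
  }
  dm <- unclass_diss(d)
  n <- nrow(dm)
  if (n < 2L) stop("need at least two objects", call. = FALSE)
  labels <- rownames(dm) %||% as.character(seq_len(n))

  # active[s] = hclust-style id of the cluster in slot s (-leaf or +merge row)
  active <- -seq_len(n)
  sizes <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  new_size <- integer(n - 1L)
  D <- dm
  diag(D) <- Inf

  for (step in seq_len(n - 1L)) {
    live <- which(!is.na(active))
    # lexicographically smallest minimising pair over slot order
    best <- c(NA_integer_, NA_integer_); bestd <- Inf
    for (a in seq_along(live)) {
      i <- live[a]
      if (a == length(live)) break
      js <- live[(a + 1L):length(live)]
      row <- D[i, js]
      m <- min(row)
      if (m < bestd) {
        bestd <- m
        best <- c(i, js[which(row == m)[1L]])
      }
    }
    i <- best[1L]; j <- best[2L]
    ni <- sizes[i]; nj <- sizes[j]
    merge[step, ] <- sort(c(active[i], active[j]))
    height[step] <- bestd
    new_size[step] <- ni + nj

    for (k in setdiff(live, c(i, j))) {
      cf <- scheme$coef(ni, nj, sizes[k])
      D[i, k] <- D[k, i] <-
        cf[1L] * D[i, k] + cf[2L] * D[j, k] + cf[3L] * bestd +
        cf[4L] * abs(D[i, k] - D[j, k])
    }
    active[i] <- step
    sizes[i] <- ni + nj
    active[j] <- NA_integer_
    D[j, ] <- D[, j] <- Inf
  }

  structure(list(n_leaves = n, labels = labels, merge = merge,
                 height = height, size = new_size,
                 method = scheme$method, metric_name = metric_name),
            class = "merge_tree")
}

#' @export
print.merge_tree <- function(x, ...) {
  cat(sprintf("merge_tree (%s linkage on %s): %d leaves\n",
              x$method, x$metric_name, x$n_leaves))
  df <- data.frame(a = x$merge[, 1], b = x$merge[, 2],
                   height = x$height, size = x$size)
  print(df)
  invisible(x)
}

#' Convert a merge tree to a base-R hclust object
#'
#' Useful for plotting. Non-monotone trees (centroid/median) plot with the
#' usual reversals.
#'
#' @param x A `merge_tree`.
#' @param ... Ignored.
#' @return An object of class `hclust`.
#' @importFrom stats as.hclust
#' @export
as.hclust.merge_tree <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height,
                 order = leaf_order(x$merge, x$n_leaves),
                 labels = x$labels, method = x$method,
                 call = match.call(), dist.method = x$metric_name),
            class = "hclust")
}

leaf_order <- function(merge, n) {
  expand <- function(id) {
    if (id < 0) return(-id)
    c(expand(merge[id, 1]), expand(merge[id, 2]))
  }
  expand(n - 1L)
}

#' Cut a merge tree into k clusters
#'
#' Undoes the last `k - 1` merges, i.e. keeps the clusters existing just
#' before them. For non-monotone trees (centroid/median) the cut follows
#' merge order, not height, so it is always well defined.
#'
#' @param t A `merge_tree`.
#' @param k Number of clusters, `1 <= k <= n_leaves`.
#' @return A `partition` (see [partition()]): cluster labels `1..k` in
#'   order of first appearance over the leaves.
#' @export
cut_tree <- function(t, k) {
  stopifnot(inherits(t, "merge_tree"))
  n <- t$n_leaves
  if (k < 1L || k > n) stop("k must be between 1 and n_leaves", call. = FALSE)
  comp <- -seq_len(n)                 # cluster id per leaf (hclust convention)
  steps <- seq_len(n - k)
  for (s in steps) {
    members <- comp %in% t$merge[s, ]
    comp[members] <- s
  }
  labels <- match(comp, unique(comp))
  partition(ids = t$labels, labels = labels, k = k)
}

#' Construct a flat partition
#'
#' @param ids Character vector of object ids.
#' @param labels Integer cluster indices (renumbered to `1..k'` in order of
#'   first appearance).
#' @param k Requested number of clusters (defaults to the number used).
#' @param objective Optional k-means within-cluster sum of squares.
#' @return A `partition` list.
#' @export
partition <- function(ids, labels, k = NULL, objective = NULL) {
  labels <- match(labels, unique(labels))
  names(labels) <- ids
  structure(list(ids = as.character(ids), labels = labels,
                 k = k %||% max(labels), objective = objective),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition into %d cluster(s)%s\n", max(x$labels),
              if (!is.null(x$objective))
                sprintf(" (objective %.6g)", x$objective) else ""))
  print(x$labels)
  invisible(x)
}
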