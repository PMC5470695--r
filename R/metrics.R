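#' Pairwise dissimilarities between samples (or entities)
#'
#' Computes the sample-by-sample (default) dissimilarity matrix used to
#' drive agglomerative clustering. Available metrics:
#' \describe{
#'   \item{`euclidean`}{\eqn{\|x - z\|}}
#'   \item{`squared_euclidean`}{\eqn{\|x - z\|^2} (the "E2" input required
#'     by centroid and median linkage)}
#'   \item{`half_squared_euclidean`}{\eqn{\|x - z\|^2 / 2} (the "E2'" input
#'     required by Ward linkage, whose merge heights then equal increases in
#'     within-cluster sum of squares)}
#'   \item{`correlation`}{\eqn{d_{cor}(x, z) = 1 - r_{cor}(x, z)} with
#'     Pearson `r`}
#'   \item{`rbf`}{the radial-basis *similarity*
#'     \eqn{K(x, z) = \exp(-\gamma_K \|x - z\|^2)}; its diagonal is 1 and
#'     larger means closer -- flagged via `metric_name = "rbf_similarity"`}
#' }
#'
#' @param m Numeric matrix ([abundance_matrix()] or `valuation_matrix`
#'   included): entities in rows, samples in columns.
#' @param metric One of `"euclidean"`, `"squared_euclidean"`,
#'   `"half_squared_euclidean"`, `"correlation"`, `"rbf"`.
#' @param gamma RBF bandwidth \eqn{\gamma_K}; defaults to the median
#'   heuristic `1 / median(||x - z||^2)` over distinct pairs.
#' @param on `"samples"` (cluster columns, the default) or `"entities"`.
#' @return A `dissimilarity_matrix`: square symmetric numeric matrix with a
#'   `metric_name` attribute (and `gamma` for the RBF kernel).
#' @export
pairwise <- function(m,
                     metric = c("euclidean", "squared_euclidean",
                                "half_squared_euclidean", "correlation", "rbf"),
                     gamma = NULL, on = c("samples", "entities")) {
  metric <- match.arg(metric)
  on <- match.arg(on)
  x <- if (inherits(m, "abundance_matrix")) unclass_matrix(m) else as.matrix(m)
  if (on == "samples") x <- t(x)
  # from here on: objects in rows
  if (nrow(x) < 2L) stop("need at least two objects", call. = FALSE)
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  sq <- as.matrix(stats::dist(x))^2
  d <- switch(metric,
    euclidean = sqrt(sq),
    squared_euclidean = sq,
    half_squared_euclidean = sq / 2,
    correlation = {
      sds <- apply(x, 1L, stats::sd)
      if (any(sds == 0)) {
        stop("degenerate metric: zero-variance object(s) under correlation: ",
             paste(ids[sds == 0], collapse = ", "), call. = FALSE)
      }
      1 - stats::cor(t(x))
    },
    rbf = {
      if (is.null(gamma)) {
        med <- stats::median(sq[upper.tri(sq)])
        if (med <= 0) med <- 1
        gamma <- 1 / med
      }
      exp(-gamma * sq)
    })
  d <- (d + t(d)) / 2
  diag(d) <- if (metric == "rbf") 1 else 0
  name <- if (metric == "rbf") "rbf_similarity" else metric
  dimnames(d) <- list(ids, ids)
  as_dissimilarity(d, name, gamma = if (metric == "rbf") gamma else NULL)
}

#' Tag a square matrix as a named dissimilarity
#'
#' Linkage methods with a restricted input (centroid, median, Ward) check
#' this tag before running; use `metric_name = "custom"` for externally
#' built matrices.
#'
#' @param d Square symmetric numeric matrix.
#' @param metric_name Metric label, e.g. `"squared_euclidean"`.
#' @param gamma Optional RBF bandwidth to record.
#' @return A `dissimilarity_matrix`.
#' @export
as_dissimilarity <- function(d, metric_name = "custom", gamma = NULL) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8) {
    stop("dissimilarity must be square and symmetric", call. = FALSE)
  }
  structure(d, metric_name = metric_name, gamma = gamma,
            class = c("dissimilarity_matrix", "matrix", "array"))
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  cat(sprintf("dissimilarity_matrix (%s): %d x %d\n",
              attr(x, "metric_name"), nrow(x), ncol(x)))
  print(round(unclass_diss(x), 4))
  invisible(x)
}

unclass_diss <- function(d) {
  v <- as.matrix(d)
  attributes(v) <- list(dim = dim(v), dimnames = dimnames(d))
  v
}

#' Clark-Evans aggregation index for a planar point pattern
#'
#' `ANN = D_O / D_E` with `D_O` the mean observed nearest-neighbour
#' distance and `D_E = 0.5 / sqrt(n / A)` the expectation for a random
#' (Poisson) pattern of `n` points over area `A`. Values below 1 indicate
#' aggregation, above 1 regularity.
#'
#' @param points Two-column numeric matrix of coordinates.
#' @param area Total study area `A` (> 0), in squared coordinate units.
#' @return List with `d_obs` (`D_O`), `d_exp` (`D_E`), `ann`, and the
#'   per-point nearest-neighbour distances `nn_dist`.
#' @export
ann_index <- function(points, area) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) {
    stop("undefined index: nearest-neighbour distances need >= 2 points",
         call. = FALSE)
  }
  if (!is.numeric(area) || length(area) != 1L || area <= 0) {
    stop("area must be a positive scalar", call. = FALSE)
  }
  dm <- as.matrix(stats::dist(points))
  diag(dm) <- Inf
  nn <- apply(dm, 1L, min)
  d_obs <- mean(nn)
  d_exp <- 0.5 / sqrt(nrow(points) / area)
  list(d_obs = d_obs, d_exp = d_exp, ann = d_obs / d_exp, nn_dist = nn)
}
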