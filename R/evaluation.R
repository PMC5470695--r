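#' Per-entity cross-sample variance profile
#'
#' Computes the unbiased (n-1 denominator) variance of each entity across
#' samples and records the descending-variance ordering. Ranked-variance
#' profiles are the package's main diagnostic for comparing the spread of
#' raw values against v values: high-dimensional raw data typically show a
#' few enormous variances (sparse outlying directions), while the
#' valuation compresses them.
#'
#' @param m Numeric entity-by-sample matrix (abundance or valuation).
#' @return A `variance_profile`: list with `entity_ids`, `variance` (named,
#'   input order), `rank_order` (ids by descending variance, ties stable),
#'   `sorted_variance`, and an initially empty `outlier_ids`.
#' @export
variance_profile <- function(m) {
  x <- if (inherits(m, "abundance_matrix")) unclass_matrix(m) else as.matrix(m)
  if (ncol(x) < 2L) {
    stop("undefined variance: need at least two samples", call. = FALSE)
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("entity", seq_len(nrow(x)))
  v <- apply(x, 1L, stats::var)
  ord <- order(-v)                       # stable: ties keep input order
  structure(list(entity_ids = rownames(x),
                 variance = stats::setNames(v, rownames(x)),
                 rank_order = rownames(x)[ord],
                 sorted_variance = unname(v[ord]),
                 outlier_ids = character(0)),
            class = "variance_profile")
}

#' @export
print.variance_profile <- function(x, ...) {
  cat(sprintf("variance_profile: %d entities; top variance %.6g (%s)\n",
              length(x$variance), x$sorted_variance[1], x$rank_order[1]))
  if (length(x$outlier_ids)) {
    cat(sprintf("outliers flagged: %d\n", length(x$outlier_ids)))
  }
  invisible(x)
}

#' Flag rank-wise variance outliers
#'
#' Aligns two variance profiles by descending rank and counts the positions
#' at which the profile under scrutiny exceeds the reference profile's
#' variance *at the same rank*. That many entities are then flagged from
#' the top of the scrutinised profile's own ranking. Applied to a v-value
#' profile with the raw (Euclidean) profile as reference, this is the rule
#' that isolates the transform's few high-rank excess-variance entities.
#'
#' @param v_profile [variance_profile()] under scrutiny (e.g. of v values).
#' @param reference_profile Reference [variance_profile()] (e.g. raw
#'   values), over the same number of entities.
#' @return The `v_profile` with `outlier_ids` filled in; the exceeding rank
#'   positions are attached as attribute `"exceeding_ranks"` for audit.
#' @export
flag_outliers <- function(v_profile, reference_profile) {
  stopifnot(inherits(v_profile, "variance_profile"),
            inherits(reference_profile, "variance_profile"))
  a <- v_profile$sorted_variance
  b <- reference_profile$sorted_variance
  if (length(a) != length(b)) {
    stop("contract error: profiles cover different entity counts", call. = FALSE)
  }
  exceed <- which(a > b)
  v_profile$outlier_ids <- v_profile$rank_order[seq_len(length(exceed))]
  attr(v_profile, "exceeding_ranks") <- exceed
  v_profile
}

#' Welch two-sample t test with per-group confidence intervals
#'
#' Two-sided unequal-variance (Welch-Satterthwaite) test, plus a 95%
#' t-quantile confidence interval for each group mean. Used to compare the
#' variance populations of raw and v-transformed data.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param conf_level Confidence level for the per-group mean CIs.
#' @return A `ttest_result` list: `mean_a`, `mean_b`, `ci95_a`, `ci95_b`
#'   (each `c(lower, upper)`), `t_statistic`, `degrees_of_freedom`,
#'   `p_value`.
#' @export
welch_test <- function(a, b, conf_level = 0.95) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least two observations", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("degenerate input: both groups have zero variance", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  ci <- function(x) {
    n <- length(x)
    half <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1) *
      stats::sd(x) / sqrt(n)
    c(mean(x) - half, mean(x) + half)
  }
  structure(list(mean_a = mean(a), mean_b = mean(b),
                 ci95_a = ci(a), ci95_b = ci(b),
                 t_statistic = unname(ht$statistic),
                 degrees_of_freedom = unname(ht$parameter),
                 p_value = ht$p.value),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("Welch t test: t = %.4g, df = %.2f, p = %.3g\n",
              x$t_statistic, x$degrees_of_freedom, x$p_value))
  cat(sprintf("mean a = %.6g [%.6g, %.6g]\n", x$mean_a, x$ci95_a[1], x$ci95_a[2]))
  cat(sprintf("mean b = %.6g [%.6g, %.6g]\n", x$mean_b, x$ci95_b[1], x$ci95_b[2]))
  invisible(x)
}

#' PCA report with per-sample component correlations
#'
#' Principal components of the column-centered (optionally scaled) matrix
#' with entities as observations and samples as variables, via
#' [stats::prcomp()]. Reports the percentage of total variance explained
#' per component and, in the layout used for sample-level diagnostics, the
#' Pearson correlation of each sample's column with each component's score
#' vector: a failing, dimensionality-dominated dataset shows one component
#' carrying ~90% of variance and correlating highly with *every* sample.
#'
#' @param m Numeric entity-by-sample matrix.
#' @param center,scale Passed to [stats::prcomp()]; default centered,
#'   unscaled.
#' @return A `pca_report`: `explained_pct` (named numeric),
#'   `sample_pc_correlation` (components x samples), `scores`
#'   (entities x components).
#' @export
pca_report <- function(m, center = TRUE, scale = FALSE) {
  x <- if (inherits(m, "abundance_matrix")) unclass_matrix(m) else as.matrix(m)
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("PCA needs at least two entities and two samples", call. = FALSE)
  }
  if (all(abs(scale(x, center = TRUE, scale = FALSE)) < 1e-300)) {
    stop("degenerate input: matrix has rank 0 after centering", call. = FALSE)
  }
  pc <- stats::prcomp(x, center = center, scale. = scale)
  varpct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  names(varpct) <- colnames(pc$x)
  keep_sd <- pc$sdev > 1e-12 * pc$sdev[1]
  cors <- matrix(NA_real_, nrow = ncol(pc$x), ncol = ncol(x),
                 dimnames = list(colnames(pc$x), colnames(x)))
  col_sd <- apply(x, 2L, stats::sd)
  for (j in which(keep_sd)) {
    for (s in seq_len(ncol(x))) {
      cors[j, s] <- if (col_sd[s] > 0) stats::cor(x[, s], pc$x[, j]) else NA_real_
    }
  }
  structure(list(explained_pct = varpct,
                 sample_pc_correlation = cors,
                 scores = pc$x),
            class = "pca_report")
}

#' @export
print.pca_report <- function(x, ...) {
  cat("PCA explained variance (%):\n")
  print(round(x$explained_pct, 2))
  cat("sample-component correlations:\n")
  print(round(x$sample_pc_correlation, 2))
  invisible(x)
}
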