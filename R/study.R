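#' Run the full raw-vs-valuation study on one dataset
#'
#' Reproduces the per-dataset analysis layout used throughout the package:
#' \enumerate{
#'   \item completeness filter, ranking and v transform ([v_pipeline()]);
#'   \item all seven Lance-Williams linkages on the raw values and on the v
#'     values, each method on its required dissimilarity (Euclidean for the
#'     unrestricted methods, squared Euclidean for centroid/median, half
#'     squared Euclidean for Ward), cut into `k_cut` clusters;
#'   \item Lloyd k-means on both representations;
#'   \item cross-method [agreement()] against the sample split;
#'   \item ranked variance profiles of raw and v values over the retained
#'     entities, the rank-wise outlier-exceedance rule, and Welch t tests
#'     of the two variance populations before and after excluding each
#'     profile's own top-variance entities (as many as flagged outliers);
#'   \item [pca_report()] of both representations.
#' }
#'
#' @param raw An [abundance_matrix()].
#' @param groups Optional named sample-to-group vector; defaults to the
#'   matrix's own labels.
#' @param reference_split Optional coarser split (e.g. control vs treated)
#'   used for the agreement check; defaults to `groups`.
#' @param k_cut Clusters to cut each dendrogram into; defaults to the
#'   number of distinct reference groups.
#' @param k_means k for Lloyd k-means; defaults to 5 for an 11-sample
#'   layout, 4 for a 6-sample layout, otherwise the number of groups.
#' @param seed Seed for k-means restarts.
#' @param restarts k-means restarts.
#' @return A `study_report` list; see Details above for its blocks.
#' @export
run_study <- function(raw, groups = NULL, reference_split = NULL,
                      k_cut = NULL, k_means = NULL, seed = 1L,
                      restarts = 25L) {
  stopifnot(inherits(raw, "abundance_matrix"))
  if (!is.null(groups)) raw <- assign_groups(raw, groups = groups)
  groups <- sample_groups(raw)
  reference_split <- reference_split %||% groups
  n_groups <- length(unique(reference_split))
  k_cut <- k_cut %||% max(2L, n_groups)
  k_means <- k_means %||%
    if (ncol(raw) == 11L) 5L else if (ncol(raw) == 6L) 4L else max(2L, n_groups)
  notes <- character(0)
  small <- names(which(table(groups) < 2))
  if (length(small)) {
    notes <- c(notes, paste0("untestable within-group comparison (<2 replicates): ",
                             paste(small, collapse = ", ")))
  }

  filtered <- filter_complete(raw)
  v <- compute_v(filtered)
  retained <- rownames(v)

  cluster_block <- function(x) {
    trees <- lapply(stats::setNames(nm = linkage_methods()), function(meth) {
      metric <- switch(linkage_scheme(meth)$required_input,
                       any = "euclidean",
                       squared_euclidean = "squared_euclidean",
                       half_squared_euclidean = "half_squared_euclidean")
      agglomerate(pairwise(x, metric = metric), meth)
    })
    parts <- lapply(trees, cut_tree, k = k_cut)
    km <- kmeans_lloyd(x, k = k_means, restarts = restarts, seed = seed)
    list(trees = trees, partitions = parts, kmeans = km,
         agreement = agreement(parts, reference_split = reference_split))
  }
  raw_block <- cluster_block(filtered)
  v_block <- cluster_block(v)

  raw_matched <- unclass_matrix(filtered)[retained, , drop = FALSE]
  prof_raw <- variance_profile(raw_matched)
  prof_v <- flag_outliers(variance_profile(v), prof_raw)
  n_excl <- length(prof_v$outlier_ids)
  drop_top <- function(p, n_drop) {
    keep <- setdiff(p$rank_order, p$rank_order[seq_len(n_drop)])
    p$variance[keep]
  }
  welch_before <- try_welch(prof_raw$variance, prof_v$variance)
  welch_after <- try_welch(drop_top(prof_raw, n_excl), drop_top(prof_v, n_excl))
  if (is.null(welch_before) || is.null(welch_after)) {
    notes <- c(notes, "variance comparison degenerate; t test skipped")
  }

  structure(list(
    n_entities_input = nrow(raw),
    n_entities_complete = nrow(filtered),
    n_entities_retained = length(retained),
    excluded_rank1 = excluded_rank1(v),
    dropped_incomplete = attr(filtered, "dropped"),
    valuation = v,
    raw = raw_block,
    v = v_block,
    variance = list(raw_profile = prof_raw, v_profile = prof_v,
                    outlier_ids = prof_v$outlier_ids, n_excluded = n_excl,
                    welch_before = welch_before, welch_after = welch_after),
    pca_raw = pca_report(filtered),
    pca_v = pca_report(v),
    k_cut = k_cut, k_means = k_means, seed = seed,
    groups = groups, reference_split = reference_split,
    notes = notes), class = "study_report")
}

try_welch <- function(a, b) {
  tryCatch(welch_test(a, b), error = function(e) NULL)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("study_report: %d -> %d complete -> %d retained entities (%d rank-1 excluded)\n",
              x$n_entities_input, x$n_entities_complete,
              x$n_entities_retained, length(x$excluded_rank1)))
  cat(sprintf("linkage agreement on the sample split (frac identical pairs): raw %.3f, v %.3f\n",
              x$raw$agreement$frac_identical, x$v$agreement$frac_identical))
  if (!is.null(x$raw$agreement$all_match_reference)) {
    cat(sprintf("all methods match reference split: raw %s, v %s\n",
                x$raw$agreement$all_match_reference,
                x$v$agreement$all_match_reference))
  }
  cat(sprintf("variance outliers (v vs raw, rank-wise): %d\n",
              x$variance$n_excluded))
  if (!is.null(x$variance$welch_after)) {
    wa <- x$variance$welch_after
    cat(sprintf("variance means after exclusion: raw %.4g, v %.4g (p = %.3g)\n",
                wa$mean_a, wa$mean_b, wa$p_value))
  }
  cat(sprintf("PC1 explained: raw %.1f%%, v %.1f%%\n",
              x$pca_raw$explained_pct[1], x$pca_v$explained_pct[1]))
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}
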