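#' Rank entities within each sample
#'
#' Assigns descending ordinal ranks per sample: rank 1 is the largest
#' abundance. Ties are broken by input row order (stable, deterministic),
#' which keeps every rank an integer -- the valuation below uses the rank as
#' a logarithm base, so ranks must stay integral and >= 1.
#'
#' @param m A complete, strictly positive [abundance_matrix()].
#' @return Integer matrix of ranks with the same dimnames as `m`, of class
#'   `rank_assignment`.
#' @export
rank_within_sample <- function(m) {
  v <- if (inherits(m, "abundance_matrix")) unclass_matrix(m) else as.matrix(m)
  if (any(is.na(v)) || any(!is.finite(v)) || any(v <= 0)) {
    stop("matrix must be complete and strictly positive; run filter_complete()",
         call. = FALSE)
  }
  r <- apply(v, 2L, function(col) rank(-col, ties.method = "first"))
  if (!is.matrix(r)) r <- matrix(r, nrow = nrow(v), ncol = ncol(v))
  storage.mode(r) <- "integer"
  dimnames(r) <- dimnames(v)
  class(r) <- c("rank_assignment", "matrix", "array")
  r
}

#' Compute the rank-valuation (v) matrix
#'
#' For entity `i` in sample `s` with within-sample rank `k >= 2`,
#' \deqn{v_{is} = \log(N_{is} / N_{top,s}) / \log(k_{is}),}
#' where `N_top,s` is the sample's rank-1 abundance. The value is the
#' exponent relating an entity's abundance to the sample maximum through its
#' integer rank: data following a power rank-abundance law
#' `N_k = C k^(-alpha)` map exactly to `v = -alpha`, so under the
#' Zipf/log-Boltzmann regime the transform concentrates around -1.
#'
#' Entities attaining rank 1 in *any* sample are removed (the ratio and the
#' log-rank both vanish at `k = 1`); their ids are recorded in the
#' `excluded_rank1` attribute. The result is invariant under per-sample
#' rescaling and under the choice of logarithm base.
#'
#' @param m Complete, strictly positive [abundance_matrix()].
#' @param r Matching [rank_within_sample()] output; recomputed when omitted.
#' @return A `valuation_matrix`: numeric entity-by-sample matrix of v values
#'   with attributes `excluded_rank1` (character) and `groups`.
#' @export
compute_v <- function(m, r = rank_within_sample(m)) {
  v <- if (inherits(m, "abundance_matrix")) unclass_matrix(m) else as.matrix(m)
  r <- as.matrix(r)
  if (!identical(dim(v), dim(r))) {
    stop("rank assignment does not match the matrix", call. = FALSE)
  }
  if (is.null(rownames(v))) rownames(v) <- paste0("entity", seq_len(nrow(v)))
  if (is.null(colnames(v))) colnames(v) <- paste0("sample", seq_len(ncol(v)))
  dimnames(r) <- dimnames(v)
  excluded <- rownames(v)[apply(r == 1L, 1L, any)]
  keep <- setdiff(rownames(v), excluded)
  if (!length(keep)) {
    stop("degenerate input: no entity remains after rank-1 exclusion",
         call. = FALSE)
  }
  top <- v[cbind(apply(r, 2L, which.min), seq_len(ncol(v)))]
  vv <- log(sweep(v[keep, , drop = FALSE], 2L, top, `/`)) /
    log(r[keep, , drop = FALSE])
  structure(vv,
            excluded_rank1 = excluded,
            groups = sample_groups_or_null(m),
            class = c("valuation_matrix", "matrix", "array"))
}

sample_groups_or_null <- function(m) {
  if (inherits(m, "abundance_matrix")) sample_groups(m) else NULL
}

#' @export
print.valuation_matrix <- function(x, ...) {
  cat(sprintf("valuation_matrix: %d entities x %d samples\n", nrow(x), ncol(x)))
  ex <- excluded_rank1(x)
  cat(sprintf("rank-1 entities excluded: %d%s\n", length(ex),
              if (length(ex)) paste0(" (", paste(ex, collapse = ", "), ")") else ""))
  cat(sprintf("v range: [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

#' Entities excluded by the rank-1 rule
#'
#' @param v A `valuation_matrix`.
#' @return Character vector of excluded entity ids.
#' @export
excluded_rank1 <- function(v) as.character(attr(v, "excluded_rank1"))

#' Completeness filter, ranking and valuation in one call
#'
#' Convenience composition `filter_complete` -> `rank_within_sample` ->
#' `compute_v`; errors from any stage propagate.
#'
#' @param m An [abundance_matrix()].
#' @return A `valuation_matrix`; the completeness filter's `"dropped"`
#'   report is carried over as an attribute.
#' @export
v_pipeline <- function(m) {
  mc <- filter_complete(m)
  out <- compute_v(mc, rank_within_sample(mc))
  attr(out, "dropped") <- attr(mc, "dropped")
  out
}
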