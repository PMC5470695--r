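#' Specification for a synthetic Zipf/log-Boltzmann abundance matrix
#'
#' The generator realises the statistical structure the rank-valuation
#' transform presumes: each sample's abundances follow a power
#' rank-abundance (Zipf) baseline `N_i = C * i^(-alpha)` — the discrete
#' face of a neutral logarithmic Boltzmann-type distribution — perturbed by
#' multiplicative lognormal replicate noise, by a group effect applied to a
#' fixed entity subset in every non-control group, and by sparse
#' heavy-tailed multiplicative spikes. The spikes emulate the sparse
#' outlying directions that make raw high-dimensional Euclidean clustering
#' irreproducible, while leaving the rank structure (hence v) largely
#' intact.
#'
#' Defaults mirror an 11-sample LC/MS storage study: three control-like
#' subgroups (3 + 2 + 2 replicates) and two treated ("stored") subgroups
#' (3 + 1). `preset = "array6"` gives the 3 + 3 two-condition microarray
#' layout.
#'
#' @param n_entities Number of entities (default 800).
#' @param groups Named integer vector: replicates per group, in order.
#' @param control Character vector of group labels forming the unaffected
#'   baseline; all other groups receive the same effect on the same entity
#'   subset (a shared treatment signature).
#' @param zipf_exponent Rank-abundance decay `alpha > 0` (default 1).
#' @param top_abundance Baseline scale `C` (default 1e4).
#' @param replicate_noise_sd Log-scale replicate noise sd `sigma`
#'   (default 0.15, i.e. ~15% coefficient of variation).
#' @param effect_fraction Fraction `f` of entities perturbed in non-control
#'   groups (default 0.2).
#' @param effect_size Log-scale shift `delta` added to perturbed entities
#'   in non-control groups (default 2, about a 7.4-fold change).
#' @param spike_prob Per-cell contamination probability `pi` (default 0.02).
#' @param spike_sd Log-scale spike sd `tau` (default 2; occasional
#'   50-fold and larger excursions).
#' @param seed Integer seed making generation fully deterministic.
#' @param preset `"lcms11"`, `"array6"`, or `"custom"` (use the arguments
#'   as given).
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_entities = 800L,
                       groups = c(fresh = 3L, frozen1h = 2L, overnight = 2L,
                                  stored2y = 3L, stored3y = 1L),
                       control = c("fresh", "frozen1h", "overnight"),
                       zipf_exponent = 1,
                       top_abundance = 1e4,
                       replicate_noise_sd = 0.15,
                       effect_fraction = 0.2,
                       effect_size = 2,
                       spike_prob = 0.02,
                       spike_sd = 2,
                       seed = 1L,
                       preset = c("lcms11", "array6", "custom")) {
  preset <- match.arg(preset)
  if (preset == "array6") {
    groups <- c(deficient = 3L, sufficient = 3L)
    control <- "deficient"
  }
  stopifnot(n_entities >= 1, all(groups >= 1), zipf_exponent > 0,
            top_abundance > 0, replicate_noise_sd >= 0,
            effect_fraction >= 0, effect_fraction <= 1, effect_size >= 0,
            spike_prob >= 0, spike_prob <= 1, spike_sd >= 0)
  if (is.null(names(groups)) || !all(control %in% names(groups))) {
    stop("groups must be named and include every control label", call. = FALSE)
  }
  structure(list(n_entities = as.integer(n_entities), groups = groups,
                 control = control, zipf_exponent = zipf_exponent,
                 top_abundance = top_abundance,
                 replicate_noise_sd = replicate_noise_sd,
                 effect_fraction = effect_fraction, effect_size = effect_size,
                 spike_prob = spike_prob, spike_sd = spike_sd,
                 seed = as.integer(seed), preset = preset),
            class = "synth_spec")
}

#' Generate a synthetic abundance matrix with ground truth
#'
#' Draws, per cell, `N_i * exp(eps + delta * perturbed * treated + spike)`
#' with `eps ~ N(0, sigma^2)`, `spike ~ N(0, tau^2)` with probability `pi`
#' (else 0), and the perturbed entity subset fixed across all non-control
#' groups. Values are strictly positive by construction and bit-identical
#' for a given spec (including seed).
#'
#' @param spec A [synth_spec()].
#' @return List: `matrix` (an [abundance_matrix()] with group labels),
#'   `truth` (list: `perturbed` entity ids, `split` named control/treated
#'   vector per sample, `groups`), and the `spec`.
#' @export
generate <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  n <- spec$n_entities
  sample_group <- rep(names(spec$groups), times = spec$groups)
  sample_ids <- unlist(lapply(names(spec$groups), function(g) {
    paste0(g, "_", seq_len(spec$groups[[g]]))
  }))
  ns <- length(sample_ids)
  entity_ids <- sprintf("ent%04d", seq_len(n))

  baseline <- spec$top_abundance * seq_len(n)^(-spec$zipf_exponent)
  n_pert <- round(spec$effect_fraction * n)
  perturbed <- sort(sample.int(n, n_pert))
  treated <- !(sample_group %in% spec$control)

  eps <- matrix(stats::rnorm(n * ns, 0, spec$replicate_noise_sd), n, ns)
  spike <- matrix(0, n, ns)
  hit <- matrix(stats::runif(n * ns) < spec$spike_prob, n, ns)
  spike[hit] <- stats::rnorm(sum(hit), 0, spec$spike_sd)
  shift <- matrix(0, n, ns)
  if (n_pert > 0 && any(treated)) {
    shift[perturbed, treated] <- spec$effect_size
  }
  values <- baseline * exp(eps + shift + spike)

  grp <- stats::setNames(sample_group, sample_ids)
  m <- abundance_matrix(values, entity_ids = entity_ids,
                        sample_ids = sample_ids, groups = grp)
  split <- stats::setNames(ifelse(treated, "treated", "control"), sample_ids)
  list(matrix = m,
       truth = list(perturbed = entity_ids[perturbed], split = split,
                    groups = grp),
       spec = spec)
}
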