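test_that("variance profiles use the unbiased estimator in descending order", {
  m <- rbind(a = c(1, 3), b = c(2, 2), c = c(0, 10))
  p <- variance_profile(m)
  expect_equal(unname(p$variance["a"]), 2)       # ((1-2)^2+(3-2)^2)/1
  expect_equal(unname(p$variance["b"]), 0)
  expect_equal(p$rank_order, c("c", "a", "b"))

  expect_error(variance_profile(matrix(1:3, 3, 1)), "undefined variance")

  set.seed(3)
  x <- matrix(rnorm(24), 6, 4)
  p2 <- variance_profile(x)
  two_pass <- apply(x, 1L, function(r) sum((r - mean(r))^2) / (length(r) - 1))
  expect_equal(unname(p2$variance), unname(two_pass), tolerance = 1e-12)
})

test_that("the rank-wise exceedance rule counts then flags from the top", {
  mk <- function(vars) {
    # build a profile whose sorted variances equal `vars`
    n <- length(vars)
    m <- cbind(-sqrt(vars / 2), sqrt(vars / 2))
    rownames(m) <- paste0("e", seq_len(n))
    variance_profile(m)
  }
  vp <- mk(c(100, 50, 3, 2))
  ref <- mk(c(60, 40, 5, 4))
  out <- flag_outliers(vp, ref)
  expect_equal(length(out$outlier_ids), 2L)
  expect_equal(out$outlier_ids, vp$rank_order[1:2])
  expect_equal(attr(out, "exceeding_ranks"), 1:2)

  below <- flag_outliers(mk(c(1, 1, 1, 1)), mk(c(2, 2, 2, 2)))
  expect_equal(length(below$outlier_ids), 0L)

  samep <- flag_outliers(mk(c(5, 4, 3, 2)), mk(c(5, 4, 3, 2)))
  expect_equal(length(samep$outlier_ids), 0L)

  expect_error(flag_outliers(mk(c(1, 2)), mk(c(1, 2, 3))), "contract error")
})

test_that("welch_test matches the direct Welch-Satterthwaite formulas", {
  tt <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tt$t_statistic, 0)
  expect_equal(tt$p_value, 1)

  a <- c(1, 2, 3, 4, 5); b <- c(2, 4, 6, 8, 10)
  tt2 <- welch_test(a, b)
  se2 <- var(a) / 5 + var(b) / 5
  t_direct <- (mean(a) - mean(b)) / sqrt(se2)
  df_direct <- se2^2 / ((var(a) / 5)^2 / 4 + (var(b) / 5)^2 / 4)
  p_direct <- 2 * pt(-abs(t_direct), df_direct)
  expect_equal(tt2$t_statistic, t_direct, tolerance = 1e-10)
  expect_equal(tt2$degrees_of_freedom, df_direct, tolerance = 1e-10)
  expect_equal(tt2$p_value, p_direct, tolerance = 1e-10)
  expect_equal(tt2$ci95_a,
               mean(a) + c(-1, 1) * qt(0.975, 4) * sd(a) / sqrt(5),
               tolerance = 1e-12)

  # symmetry: swapping the groups negates t, preserves p
  tt3 <- welch_test(b, a)
  expect_equal(tt3$t_statistic, -tt2$t_statistic)
  expect_equal(tt3$p_value, tt2$p_value)

  expect_error(welch_test(c(1), c(1, 2)), "at least two")
  expect_error(welch_test(c(2, 2), c(3, 3)), "degenerate")
})

test_that("pca_report explains variance and correlates samples with scores", {
  # rank-1 matrix: one component carries everything
  base <- c(1, 2, 3, 4, 5)
  m1 <- cbind(s1 = base, s2 = 2 * base, s3 = -0.5 * base)
  p1 <- pca_report(m1)
  expect_equal(unname(p1$explained_pct[1]), 100, tolerance = 1e-9)
  expect_equal(abs(unname(p1$sample_pc_correlation["PC1", ])), rep(1, 3),
               tolerance = 1e-9)

  # orthogonal centered columns of equal norm: 50/50 split
  m2 <- cbind(s1 = c(1, -1, 0), s2 = c(1, 1, -2) / sqrt(3))
  p2 <- pca_report(m2)
  expect_equal(unname(p2$explained_pct), c(50, 50), tolerance = 1e-9)

  set.seed(8)
  m3 <- matrix(rnorm(60), 10, 6)
  expect_equal(sum(pca_report(m3)$explained_pct), 100, tolerance = 1e-9)

  expect_error(pca_report(matrix(5, 3, 3)), "rank 0")
})

test_that("run_study assembles a consistent report on synthetic data", {
  sim <- generate(synth_spec(n_entities = 120, seed = 42))
  rep <- run_study(sim$matrix, reference_split = sim$truth$split, seed = 42)
  expect_s3_class(rep, "study_report")
  expect_equal(rep$n_entities_input, 120)
  expect_equal(rep$n_entities_retained,
               rep$n_entities_complete - length(rep$excluded_rank1))
  expect_length(rep$raw$partitions, 7L)
  expect_length(rep$v$partitions, 7L)
  expect_true(all(c("overall", "frac_identical") %in% names(rep$v$agreement)))
  expect_equal(length(rep$variance$v_profile$variance), rep$n_entities_retained)
  # defaults for the 11-sample layout
  expect_equal(rep$k_means, 5L)
  expect_equal(rep$k_cut, 2L)
  # single-replicate group is flagged as untestable
  expect_true(any(grepl("untestable", rep$notes)))
})
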