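test_that("linkage schemes carry the canonical coefficient table", {
  ward <- linkage_scheme("ward")$coef(2, 3, 4)
  expect_equal(ward, c(6 / 9, 7 / 9, -4 / 9, 0))
  cen <- linkage_scheme("centroid")$coef(2, 3, 5)
  expect_equal(cen, c(2 / 5, 3 / 5, -6 / 25, 0))
  expect_equal(linkage_scheme("single")$coef(1, 1, 1), c(0.5, 0.5, 0, -0.5))
  expect_equal(linkage_scheme("complete")$coef(9, 2, 4), c(0.5, 0.5, 0, 0.5))
  expect_equal(linkage_scheme("group_average")$coef(2, 6, 1),
               c(0.25, 0.75, 0, 0))
  expect_equal(linkage_scheme("median")$coef(5, 5, 5), c(0.5, 0.5, -0.25, 0))
  expect_equal(linkage_scheme("weighted_average")$coef(3, 1, 2),
               c(0.5, 0.5, 0, 0))
  expect_equal(linkage_scheme("ward")$required_input, "half_squared_euclidean")
  expect_equal(linkage_scheme("median")$required_input, "squared_euclidean")
  expect_false(linkage_scheme("centroid")$monotone)
})

test_that("single and complete linkage recover hand-computed merge heights", {
  pts <- matrix(c(0, 1, 3, 7), nrow = 1)       # columns are objects
  d <- pairwise(pts, "euclidean")
  expect_equal(agglomerate(d, "single")$height, c(1, 2, 4))
  expect_equal(agglomerate(d, "complete")$height, c(1, 3, 7))

  p <- cut_tree(agglomerate(d, "single"), 2)
  expect_equal(unname(split(p$ids, p$labels)[["1"]]), c("1", "2", "3"))
  expect_equal(unname(split(p$ids, p$labels)[["2"]]), "4")
})

test_that("restricted-input methods enforce their dissimilarity contract", {
  d_e <- pairwise(matrix(c(0, 1, 3, 7), 1), "euclidean")
  expect_error(agglomerate(d_e, "centroid"), "contract error.*squared_euclidean")
  expect_error(agglomerate(d_e, "ward"), "contract error.*half_squared")
  expect_silent(agglomerate(d_e, "centroid", waiver = TRUE))
  d_sq <- pairwise(matrix(c(0, 1, 3, 7), 1), "squared_euclidean")
  expect_silent(agglomerate(d_sq, "median"))
})

test_that("all seven recurrences reproduce brute-force inter-cluster distances", {
  for (seed in 1:25) {
    n <- sample(4:12, 1)
    dim <- sample(2:8, 1)
    x <- random_points(n, dim, seed)
    for (meth in linkage_methods()) {
      expect_equal(lw_impl_heights(x, meth), lw_oracle(x, meth),
                   tolerance = 1e-10,
                   label = sprintf("%s heights (seed %d)", meth, seed))
    }
  }
})

test_that("heights agree with the reference hclust dialect per method", {
  x <- random_points(10, 4, seed = 99)
  base <- dist(x)
  map <- c(single = "single", complete = "complete",
           group_average = "average", weighted_average = "mcquitty")
  for (meth in names(map)) {
    ours <- agglomerate(pairwise(t(x), "euclidean"), meth)$height
    ref <- stats::hclust(base, method = map[[meth]])$height
    expect_equal(sort(ours), sort(ref), tolerance = 1e-10, label = meth)
  }
  # centroid/median take squared input, ward half-squared, in the same units
  for (meth in c("centroid", "median")) {
    ours <- agglomerate(pairwise(t(x), "squared_euclidean"), meth)$height
    ref <- stats::hclust(base^2, method = meth)$height
    expect_equal(sort(ours), sort(ref), tolerance = 1e-10, label = meth)
  }
  ours <- agglomerate(pairwise(t(x), "half_squared_euclidean"), "ward")$height
  ref <- stats::hclust(base^2 / 2, method = "ward.D")$height
  expect_equal(sort(ours), sort(ref), tolerance = 1e-10)
})

test_that("monotone methods never invert while centroid linkage can", {
  mono <- c("single", "complete", "group_average", "weighted_average", "ward")
  for (seed in 1:10) {
    x <- random_points(9, 3, seed)
    for (meth in mono) {
      h <- lw_impl_heights(x, meth)
      expect_true(all(diff(h) >= -1e-12),
                  label = sprintf("%s monotone (seed %d)", meth, seed))
    }
  }
  # search a small instance with a centroid-linkage height inversion
  found <- FALSE
  for (seed in 1:200) {
    x <- random_points(5, 2, seed)
    h <- lw_impl_heights(x, "centroid")
    if (any(diff(h) < -1e-9)) { found <- TRUE; break }
  }
  expect_true(found)
})

test_that("cut_tree spans singletons to a single cluster", {
  d <- pairwise(random_points(6, 3, 5) |> t(), "euclidean")
  t6 <- agglomerate(d, "group_average")
  expect_equal(max(cut_tree(t6, 6)$labels), 6L)
  expect_equal(max(cut_tree(t6, 1)$labels), 1L)
  expect_error(cut_tree(t6, 0), "between")
  expect_error(cut_tree(t6, 7), "between")
})

test_that("Lloyd k-means finds exact small-case optima deterministically", {
  x <- matrix(c(0, 1, 10, 11), nrow = 1)
  km <- kmeans_lloyd(x, k = 2, seed = 11)
  expect_equal(km$objective, 1.0)                 # exhaustive optimum: {0,1},{10,11}
  expect_equal(km$labels[["1"]], km$labels[["2"]])
  expect_equal(km$labels[["3"]], km$labels[["4"]])

  expect_equal(kmeans_lloyd(x, k = 4, seed = 1)$objective, 0)

  same <- matrix(rep(c(3, 4), 4), nrow = 2)
  expect_equal(kmeans_lloyd(same, k = 2, seed = 2)$objective, 0)

  set.seed(5)
  xx <- matrix(rnorm(40), 4, 10)
  expect_identical(kmeans_lloyd(xx, 3, seed = 9)$labels,
                   kmeans_lloyd(xx, 3, seed = 9)$labels)
})

test_that("Lloyd objective matches the stats::kmeans cross-check", {
  set.seed(123)
  x <- matrix(rnorm(5 * 14), 5, 14)
  ours <- kmeans_lloyd(x, k = 3, restarts = 40, seed = 4)$objective
  ref <- stats::kmeans(t(x), centers = 3, nstart = 40,
                       algorithm = "Lloyd", iter.max = 100)
  expect_equal(ours, ref$tot.withinss, tolerance = 1e-6)
})

test_that("agreement scores identity, near-identity and reference splits", {
  ids <- letters[1:8]
  bip <- function(members2) partition(ids, ifelse(ids %in% members2, 2L, 1L))
  same8 <- replicate(8, bip(c("e", "f", "g", "h")), simplify = FALSE)
  a1 <- agreement(same8)
  expect_equal(a1$overall, 1)
  expect_equal(a1$frac_identical, 1)

  seven_one <- c(same8[1:7], list(bip(c("a", "f", "g", "h"))))
  a2 <- agreement(seven_one)
  expect_equal(a2$frac_identical, 21 / 28)        # fully agreeing pairs
  expect_lt(a2$overall, 1)

  ref_alt <- setNames(rep(c("x", "y"), 4), ids)       # alternating: no match
  a3 <- agreement(same8, reference_split = ref_alt)
  expect_false(any(a3$matches_reference))
  ref_match <- setNames(rep(c("x", "y"), each = 4), ids)
  a4 <- agreement(list(bip(c("e", "f", "g", "h"))), reference_split = ref_match)
  expect_true(a4$all_match_reference)

  other <- partition(LETTERS[1:8], rep(1:2, 4))
  expect_error(agreement(list(same8[[1]], other)), "contract error")
})
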