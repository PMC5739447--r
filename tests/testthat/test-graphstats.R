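# In-degree Gini index and complex-attractor centralities.

test_that("gini coefficient matches the pairwise-difference definition", {
  naiveGini <- function(x) {
    n <- length(x)
    sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
  }
  set.seed(42)
  for (i in 1:10) {
    x <- sample(0:10, 20, replace = TRUE) + 1
    expect_equal(giniCoefficient(x, corrected = FALSE), naiveGini(x))
    expect_equal(giniCoefficient(x, corrected = TRUE),
                 naiveGini(x) * 20 / 19)
    # scale invariance
    expect_equal(giniCoefficient(3 * x), giniCoefficient(x))
  }
  expect_equal(giniCoefficient(rep(4, 10)), 0)
  expect_error(giniCoefficient(c(0, 0)), "all values are zero")
  expect_error(giniCoefficient(c(-1, 2)), "non-negative")
})

test_that("in-degree gini of the catalog STGs matches the reference values", {
  g65 <- vapply(c("CD1965-V1", "CD1965-V2"), function(id) {
    giniIndegree(buildSTG(cdModel(id), "synchronous"))
  }, numeric(1))
  expect_equal(round(unname(g65), 3), c(0.575, 0.575))

  gCD <- vapply(paste0("CD-V", 1:8), function(id) {
    giniIndegree(buildSTG(cdModel(id), "synchronous"))
  }, numeric(1))
  expect_equal(round(unname(gCD), 3),
               c(0.918, 0.908, 0.904, 0.918, 0.908, 0.904, 0.921, 0.921))

  # the present-day landscape is uniformly more funneled than 1965
  expect_true(min(gCD) > max(g65))

  # out-degree-1 conservation: in-degrees sum to 2^n
  stg <- buildSTG(cdModel("CD-V5"), "synchronous")
  expect_equal(sum(stgInDegrees(stg)), 128L)
  # a cyclic permutation STG is perfectly homogeneous
  ring <- booleanNetwork("ring", c("A", "B"), list(A = "B", B = "A"))
  expect_equal(giniIndegree(buildSTG(ring, "synchronous")), 0)
})

test_that("complex-attractor centralities single out the known hub states", {
  aset <- findAttractorsAsync(cdModel("CD-V2"))
  cx <- Filter(function(a) attractorKind(a) == "complex", attractors(aset))[[1]]
  ct <- stateCentralities(cx)
  expect_equal(nrow(ct), 32L)
  expect_true(all(ct$betweenness >= 0))
  expect_true(all(ct$closeness >= 0 & ct$closeness <= 1))
  expect_equal(ct$state[which.max(ct$closeness)], "1111111")
  expect_equal(ct$state[which.max(ct$betweenness)], "1001111")
})

test_that("centrality edge cases: single vertex scores zero, empty errors", {
  g1 <- igraph::make_empty_graph(1, directed = TRUE)
  ct <- stateCentralities(g1)
  expect_equal(ct$betweenness, 0)
  expect_equal(ct$closeness, 0)
  g0 <- igraph::make_empty_graph(0, directed = TRUE)
  expect_error(stateCentralities(g0), "empty")
})
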