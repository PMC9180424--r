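test_that("judgment matrices are validated for shape, sign and reciprocity", {
  bad <- matrix(c(1, 2, 0.4, 1), 2, byrow = TRUE)
  expect_error(judgment_matrix(bad), "reciprocity")
  expect_error(judgment_matrix(matrix(1, 2, 3)), "square")
  expect_error(judgment_matrix(matrix(c(1, -1, -1, 1), 2)), "positive")
  m1 <- judgment_matrix(matrix(1, 1, 1))
  expect_equal(unname(ahp_weights(m1)$weights), 1)
})

test_that("bundled fixtures load with their labels", {
  mats <- load_judgment_matrices()
  expect_named(mats, c("first_level", "ecological_environment",
                       "social_economy", "social_media"))
  expect_equal(dim(mats$first_level), c(3, 3))
  expect_equal(rownames(mats$first_level),
               c("ecological_environment", "social_economy", "social_media"))
  expect_equal(dim(mats$social_economy), c(8, 8))
})

test_that("consistent matrices give exact weight recovery and CR 0", {
  w <- c(0.6, 0.3, 0.1)
  M <- judgment_matrix(outer(w, w, "/"))
  res <- ahp_weights(M)
  expect_equal(unname(res$weights), w, tolerance = 1e-10)
  expect_equal(res$consistency$CR, 0, tolerance = 1e-9)
  expect_equal(res$consistency$lambda_max, 3, tolerance = 1e-9)
})

test_that("order-2 reciprocal matrices are consistent by convention", {
  M <- judgment_matrix(matrix(c(1, 5, 0.2, 1), 2, byrow = TRUE))
  res <- ahp_weights(M)
  expect_equal(res$consistency$RI, 0)
  expect_equal(res$consistency$CR, 0)
})

test_that("the first-level fixture gives the known weights and CR", {
  mats <- load_judgment_matrices()
  res <- ahp_weights(mats$first_level)
  expect_equal(unname(res$weights), c(0.263, 0.079, 0.659), tolerance = 2e-3)
  expect_equal(res$consistency$lambda_max, 3.03, tolerance = 1e-2)
  expect_equal(res$consistency$CR, 0.0279, tolerance = 1e-3)
  expect_lt(res$consistency$CR, 0.1)
})

test_that("power iteration agrees with the dense eigendecomposition oracle", {
  mats <- load_judgment_matrices()
  set.seed(5)
  cases <- c(unname(mats), lapply(c(3, 5, 7, 9), random_reciprocal_matrix))
  for (M in cases) {
    res <- ahp_weights(M)
    orc <- eigen_weights(M)
    expect_equal(unname(res$weights), orc$weights, tolerance = 1e-8)
    expect_equal(res$consistency$lambda_max, orc$lambda_max, tolerance = 1e-8)
  }
})

test_that("RI lookup reproduces the tabulated constants and bounds", {
  expect_equal(ri_lookup(1), 0)
  expect_equal(ri_lookup(3), 0.58)
  expect_equal(ri_lookup(8), 1.41)
  expect_error(ri_lookup(10), "orders 1-9")
  expect_error(ri_lookup(0.5), "integer")
})

test_that("hierarchy composition multiplies layer and group weights", {
  expect_equal(
    compose_hierarchy(c(g = 1), list(g = c(a = 0.4, b = 0.6)))$absolute_weight,
    c(0.4, 0.6)
  )
  out <- compose_hierarchy(
    c(g1 = 0.5, g2 = 0.5),
    list(g1 = c(a = 1), g2 = c(b = 0.4, c = 0.6))
  )
  expect_equal(out$absolute_weight, c(0.5, 0.2, 0.3))
  expect_equal(sum(out$absolute_weight), 1)
  expect_error(
    compose_hierarchy(c(g1 = 1), list(other = c(a = 1))),
    "must match"
  )
})

test_that("the composed topic-index weight lands near its published value", {
  mats <- load_judgment_matrices()
  top <- ahp_weights(mats$first_level)$weights
  sm <- ahp_weights(mats$social_media)$weights
  abs_w <- top[["social_media"]] * sm[["topic_index"]]
  expect_equal(abs_w, 0.249201, tolerance = 0.05)
})

test_that("range standardization handles directions, zeros and constants", {
  panel <- tibble::tibble(a = c(1, 2, 3), b = c(1, 2, 3), k = c(5, 5, 5))
  Y <- standardize_panel(panel, c(a = "benefit", b = "cost", k = "benefit"))
  expect_equal(Y$a, c(0.01, 0.5, 1))
  expect_equal(Y$b, c(1, 0.5, 0.01))
  expect_equal(Y$k, c(1, 1, 1))
  expect_error(standardize_panel(panel[1, ], c(a = "benefit")), "at least 2")
  expect_error(
    standardize_panel(tibble::tibble(a = c("x", "y")), c(a = "benefit")),
    "non-numeric"
  )
})

test_that("entropy weights follow the share-entropy formulas", {
  Y <- tibble::tibble(u = c(1, 1, 1), v = c(0.01, 0.5, 1))
  ew <- entropy_weights(Y)
  expect_equal(unname(ew$entropy["u"]), 1)
  expect_equal(unname(ew$entropy["v"]), 0.6117958, tolerance = 1e-6)
  expect_equal(unname(ew$weights), c(0, 1))
  expect_equal(colSums(ew$P), c(u = 1, v = 1))

  # mirror-image columns share the weight equally
  Y2 <- tibble::tibble(x = c(0.01, 0.5, 1), y = c(1, 0.5, 0.01))
  expect_equal(unname(entropy_weights(Y2)$weights), c(0.5, 0.5))
  expect_error(entropy_weights(tibble::tibble(u = c(1, 1))), "degenerate")
})

test_that("entropy weights are permutation-equivariant", {
  set.seed(9)
  Y <- tibble::as_tibble(matrix(runif(5 * 4, 0.01, 1), 5, 4,
                                dimnames = list(NULL, letters[1:4])))
  base <- entropy_weights(Y)$weights
  rows <- sample(5)
  expect_equal(entropy_weights(Y[rows, ])$weights, base)
  cols <- sample(letters[1:4])
  expect_equal(entropy_weights(Y[, cols])$weights[letters[1:4]], base)
})

test_that("weight combination is the normalized geometric mean", {
  w1 <- c(a = 0.5, b = 0.5)
  expect_equal(combine_weights(w1, w1), w1)
  expect_equal(unname(combine_weights(w1, c(0.8, 0.2))), c(2 / 3, 1 / 3))
  set.seed(2)
  for (i in 1:10) {
    u <- runif(6); u <- u / sum(u)
    v <- runif(6); v <- v / sum(v)
    expect_equal(sum(combine_weights(u, v)), 1, tolerance = 1e-12)
  }
  expect_error(combine_weights(c(1), c(0.5, 0.5)), "length")
})

test_that("composite scores are weighted sums with retained contributions", {
  Y <- tibble::tibble(a = c(1, 0.2), b = c(0, 0.4), c = c(0.5, 0.6))
  one_hot <- c(a = 0, b = 1, c = 0)
  expect_equal(composite_score(one_hot, Y)$z, Y$b)
  all_ones <- tibble::tibble(a = 1, b = 1, c = 1)
  expect_equal(composite_score(c(a = 0.2, b = 0.3, c = 0.5), all_ones)$z, 1)
  out <- composite_score(c(a = 0.2, b = 0.3, c = 0.5), Y[1, ])
  expect_equal(out$z, 0.45)
  expect_equal(out$contrib_a + out$contrib_b + out$contrib_c, out$z)
  expect_error(composite_score(c(zz = 1), Y), "missing indicators")
})
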