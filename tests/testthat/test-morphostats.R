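test_that("t-ratio measures hull filling of the enclosing triangle", {
  tri <- rbind(c(0, 0), c(2, 0), c(0, 2))
  # the three vertices themselves (plus interior points) fill it exactly
  X <- rbind(tri, c(0.5, 0.5), c(0.2, 0.1))
  expect_equal(t_ratio(X, tri), 1, tolerance = 1e-12)
  # unit square inside the (0,0)-(2,0)-(0,2) triangle: hull 1, triangle 2
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(t_ratio(sq, tri), 0.5, tolerance = 1e-12)
  # collinear data have a degenerate hull
  line <- cbind(seq(0, 1, length.out = 10), seq(0, 1, length.out = 10))
  expect_equal(t_ratio(line, tri), 0)
  expect_error(t_ratio(sq, rbind(c(0, 0), c(1, 1), c(2, 2))), "zero-area")
})

test_that("polygonality test separates triangle-filling data from unstructured blobs", {
  tri <- wd_triangle()
  sp <- sample_polytope(polytope(tri, "simplex"), 200, 0.8, 0.01, seed = 11)
  pt <- polygonality_test(sp$points, n_null = 99, seed = 12, restarts = 4)
  expect_gt(pt$statistic, 0.85)
  expect_lte(pt$p_value, 0.05)
  set.seed(13)
  blob <- cbind(rnorm(200), rnorm(200))
  pb <- polygonality_test(blob, n_null = 99, seed = 13, restarts = 4)
  expect_gt(pb$p_value, 0.2)
  expect_error(polygonality_test(sp$points, n_null = 0), "positive")
  expect_error(polygonality_test(sp$points[1:5, ], n_null = 10), "at least 10")
})

test_that("polygonality p-values are roughly uniform under the null", {
  tri <- wd_triangle()
  set.seed(21)
  ps <- vapply(1:12, function(i) {
    sp <- sample_polytope(polytope(tri, "simplex"), 60, 0.8, 0.01,
                          seed = 100 + i)
    # column permutation destroys the joint structure: null-consistent data
    null_data <- apply(sp$points, 2, sample)
    polygonality_test(null_data, n_null = 39, seed = 200 + i,
                      restarts = 1)$p_value
  }, 0)
  expect_gt(mean(ps), 0.2)
  expect_lt(mean(ps), 0.85)
  expect_gt(max(ps), 0.5)
})

test_that("triangle similarity is exact, symmetric, and affine-consistent", {
  A <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(triangle_similarity(A, A), 1)
  B_far <- A + 10
  expect_equal(triangle_similarity(A, B_far), 0)
  B <- A + rep(c(0.5, 0), each = 3)
  # exact clipping: intersection (0.5,0)-(1,0)-(0.5,0.5) has area 1/8,
  # union 7/8, so the ratio is 1/7
  expect_equal(triangle_similarity(A, B), 1 / 7, tolerance = 1e-12)
  expect_equal(triangle_similarity(B, A), triangle_similarity(A, B))
  # common scaling and rotation leave the ratio unchanged
  th <- 0.7; R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  expect_equal(triangle_similarity(3 * A %*% R, 3 * B %*% R),
               triangle_similarity(A, B), tolerance = 1e-12)
  expect_error(triangle_similarity(A, rbind(c(0, 0), c(1, 1), c(2, 2))),
               "degenerate")
})

test_that("triangle similarity matches a Monte-Carlo rejection oracle", {
  A <- rbind(c(0, 0), c(1, 0), c(0, 1))
  B <- A + rep(c(0.5, 0), each = 3)
  expect_lt(abs(triangle_similarity(A, B) - mc_similarity(A, B)), 1e-3)
  set.seed(31)
  C <- matrix(runif(6), 3, 2)
  D <- matrix(runif(6), 3, 2)
  expect_lt(abs(triangle_similarity(C, D) - mc_similarity(C, D)), 1e-3)
})

test_that("similarity null distribution behaves and is rectangle-invariant", {
  st <- similarity_test(0, n_null = 500, seed = 14)
  expect_equal(st$p_value, 1)
  # the similarity ratio does not depend on the sampling rectangle
  s1 <- similarity_test(0.25, n_null = 2000, seed = 6)
  s2 <- similarity_test(0.25, n_null = 2000, seed = 7, rect = c(3, 1))
  expect_lt(abs(s1$p_value - s2$p_value), 0.02)
  expect_error(similarity_test(1.2), "observed_ratio")
})

test_that("distance enrichment recovers planted diameter effects", {
  ds <- make_dataset()
  X <- as.matrix(ds[, c("D", "S", "W")])
  V <- reference_pyramid()$vertices
  # effects (1, 1.8, 1.6, 0.4, 0.5): large shells near vertices 2 and 3,
  # small shells near vertices 4 and 5
  expected <- c("positive", "positive", "negative", "negative")
  for (i in seq_along(expected)) {
    er <- enrichment_by_distance(X, ds$diameter_cm, V[i + 1, ],
                                 n_perm = 499, seed = 20 + i)
    expect_lt(er$p_value, 0.05)
    expect_equal(er$direction, expected[i])
    expect_lte(diff(range(er$bin_counts)), 1)
  }
})

test_that("enrichment handles null, constant, and invalid inputs", {
  ds <- make_dataset(synth_config(diameter_effects = c(1, 1, 1, 1, 1), seed = 8))
  X <- as.matrix(ds[, c("D", "S", "W")])
  er <- enrichment_by_distance(X, ds$diameter_cm,
                               reference_pyramid()$vertices[4, ],
                               n_perm = 499, seed = 9)
  expect_gt(er$p_value, 0.05)
  expect_equal(er$direction, "none")
  er_const <- enrichment_by_distance(X, rep(3, nrow(X)),
                                     reference_pyramid()$vertices[1, ],
                                     n_perm = 99, seed = 10)
  expect_equal(er_const$slope, 0)
  expect_equal(er_const$p_value, 1)
  expect_error(enrichment_by_distance(X[1:5, ], ds$diameter_cm[1:5],
                                      reference_pyramid()$vertices[1, ],
                                      n_bins = 10), "bins")
})
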