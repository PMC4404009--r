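test_that("minimum-volume simplex recovers exact polytope data", {
  tri <- wd_triangle()
  set.seed(5)
  w <- paretoshell:::rdirichlet(60, 3, 1)
  X <- rbind(tri, w %*% tri)          # vertices themselves plus interior
  f <- fit_simplex(X, seed = 4)
  perm <- match_vertices(tri, f$polytope$vertices)
  expect_setequal(unname(perm), 1:3)
  expect_lt(max(abs(tri - f$polytope$vertices[perm, ])), 0.02)
  expect_lt(f$rms_error, 1e-3)
  expect_gte(f$fraction_inside, 0.95)
})

test_that("simplex recovery degrades gracefully with noise and stays enclosing", {
  tri <- wd_triangle()
  errs <- vapply(c(0.005, 0.02, 0.05), function(ns) {
    sp <- sample_polytope(polytope(tri, "simplex"), 500, 0.8, ns, seed = 2)
    f <- fit_simplex(sp$points, seed = 3)
    expect_gte(f$fraction_inside, 0.95)
    perm <- match_vertices(tri, f$polytope$vertices)
    max(abs(tri - f$polytope$vertices[perm, ]))
  }, 0)
  expect_lt(errs[1], 0.1)
  # an enclosing fit overshoots acute corners by the noise scale, not more
  expect_lt(errs[2], 0.2)
  # consistency: recovery error shrinks as noise goes to zero
  expect_lt(errs[1], errs[3])
})

test_that("degenerate (collinear) data are rejected with a diagnostic", {
  X <- cbind(seq(0, 1, length.out = 30), 2 * seq(0, 1, length.out = 30) + 1)
  expect_error(fit_simplex(X, seed = 1), "degenerate|collinear")
  expect_error(fit_simplex(X[1:3, ], seed = 1), "more points")
})

test_that("PCHA reproduces repeated distinct points exactly", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 1))
  X <- pts[rep(1:3, each = 20), ]
  f <- fit_pcha(X, 3, restarts = 2, seed = 1, standardize = FALSE)
  expect_equal(f$rms_error, 0, tolerance = 1e-6)
  perm <- match_vertices(pts, f$polytope$vertices)
  expect_lt(max(abs(pts - f$polytope$vertices[perm, ])), 1e-6)
  expect_error(fit_pcha(X, 100), "exceed")
  expect_error(fit_pcha(X, 1), "at least 2")
})

test_that("PCHA reconstruction error is invariant to rigid motions of the data", {
  sp <- sample_polytope(reference_pyramid(), 200, 0.8, 0.02, seed = 3)
  set.seed(4)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  shift <- c(2, -1, 0.5)
  f1 <- fit_pcha(sp$points, 5, restarts = 3, seed = 5, standardize = FALSE)
  f2 <- fit_pcha(sweep(sp$points %*% Q, 2, shift, "+"), 5, restarts = 3,
                 seed = 5, standardize = FALSE)
  expect_equal(f1$rms_error, f2$rms_error, tolerance = 0.02)
})

test_that("PCHA with delta relaxation recovers the planted pyramid", {
  py <- reference_pyramid()
  sp <- sample_polytope(py, 1000, 0.8, 0.02, seed = 4)
  f <- fit_pcha(sp$points, 5, delta = 0.15, restarts = 5, seed = 5, maxit = 120)
  perm <- match_vertices(py$vertices, f$polytope$vertices)
  expect_setequal(unname(perm), 1:5)
  err <- abs(py$vertices - f$polytope$vertices[perm, ])
  rng <- apply(sp$points, 2, function(x) diff(range(x)))
  expect_lt(max(sweep(err, 2, rng, "/")), 0.1)
  # the four base vertices stay about as coplanar as the generating pyramid's
  base_truth <- py$vertices[c(1, 2, 4, 5), ]
  base_fit <- f$polytope$vertices[perm, ][c(1, 2, 4, 5), ]
  expect_lt(plane_residual(base_fit), 2 * plane_residual(base_truth))
})

test_that("rms profile is non-increasing with elbows at the true vertex count", {
  # exact 5-vertex pyramid data: error collapses at k = 5 and stays small
  sp <- sample_polytope(reference_pyramid(), 150, 0.8, 0, seed = 6)
  prof <- rms_profile(sp$points, k_range = 2:6, restarts = 2, seed = 7,
                      maxit = 60)
  expect_true(all(diff(prof$rms_error) < 1e-6 + 1e-8))
  expect_lt(prof$rms_error[prof$k == 5], 0.1 * prof$rms_error[prof$k == 3])
  expect_lt(prof$rms_error[prof$k == 6], prof$rms_error[prof$k == 4])
  # line-segment (two-task) data: elbow already at k = 2
  seg <- polytope(rbind(c(0, 0, 0), c(1, 2, 0.5)), "general")
  sp2 <- sample_polytope(seg, 120, 1, 0.01, seed = 8)
  prof2 <- rms_profile(sp2$points, k_range = 2:4, restarts = 2, seed = 9,
                       maxit = 60)
  expect_lt(prof2$rms_error[1], 0.05)
  expect_lt((prof2$rms_error[1] - prof2$rms_error[3]) / prof2$rms_error[1], 0.9)
})

test_that("polytope projection merges the paired pyramid vertices in the W-D plane", {
  pr <- project_polytope(reference_pyramid(), c("D", "W"), merge_tol = 0.2,
                         scale = c(1, 4))
  groups <- lapply(pr$merge_map, sort)
  expect_true(list(c(1L, 4L)) %in% groups || any(vapply(groups, identical, TRUE, c(1L, 4L))))
  expect_true(any(vapply(groups, identical, TRUE, c(2L, 5L))))
  expect_true(any(vapply(groups, identical, TRUE, 3L)))
  expect_equal(pr$polytope$k, 3)
  # projection to one axis spans the vertex range
  pr1 <- project_polytope(reference_pyramid(), "W", merge_tol = 0)
  expect_equal(range(pr1$polytope$vertices),
               range(reference_pyramid()$vertices[, "W"]))
  # projected vertices are a subset of the projection of the vertices
  pr2 <- project_polytope(polytope(matrix(rnorm(15), 5, 3)), c(1, 3),
                          merge_tol = 0)
  expect_equal(pr2$polytope$k, 5)
})

test_that("hull membership coefficients reconstruct interior points", {
  V <- rbind(c(0, 0), c(2, 0), c(0, 2))
  X <- rbind(c(0.5, 0.5), c(1, 0.5), c(3, 3))
  hc <- hull_coefficients(X, V)
  expect_lt(max(hc$dist[1:2]), 1e-5)
  expect_gt(hc$dist[3], 1)
  expect_equal(rowSums(hc$coef), rep(1, 3), tolerance = 1e-9)
  expect_true(all(hc$coef >= -1e-12))
})
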