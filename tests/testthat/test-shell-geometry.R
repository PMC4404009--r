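test_that("spiral radius follows the per-whorl expansion law", {
  expect_equal(spiral_radius(shell_model(0.5, 1), 1.3), 1)
  expect_equal(spiral_radius(shell_model(0.003, 4.59), 2 * pi), 4.59)
  expect_equal(spiral_radius(shell_model(0.5, 2), pi), sqrt(2))
  th <- seq(0, 4 * pi, length.out = 50)
  r <- spiral_radius(shell_model(0.2, 1.7), th)
  expect_true(all(diff(r) > 0))
})

test_that("diameter factor is 1 + W^(-1/2), decreasing, and matches a caliper oracle", {
  expect_equal(diameter_factor(shell_model(0.1, 1)), 2)
  expect_equal(diameter_factor(shell_model(0.1, 4)), 1.5)
  W <- c(1, 1.2, 2, 3, 4.44, 6)
  f <- vapply(W, function(w) diameter_factor(shell_model(0.1, w)), 0)
  expect_true(all(diff(f) < 0))
  # brute-force max caliper over a densely sampled spiral outline
  w <- 4.44
  th <- seq(-4 * pi, 0, length.out = 20000)
  r <- w^(th / (2 * pi))
  x <- r * cos(th); y <- r * sin(th)
  # brute-force max caliper of the outline; the axis-chord convention
  # r(theta) + r(theta - pi) underestimates it by O((log W / 2 pi)^2),
  # about 1% at this W
  caliper <- max(vapply(seq(0, pi, length.out = 720), function(a) {
    p <- x * cos(a) + y * sin(a)
    max(p) - min(p)
  }, 0))
  expect_equal(diameter_factor(shell_model(0.1, w)), caliper, tolerance = 0.02)
  expect_lte(diameter_factor(shell_model(0.1, w)), caliper)
})

test_that("whorl overlap obeys the W < 1/D condition", {
  ov <- whorl_overlap(shell_model(0.7, 1.35))
  expect_true(ov$overlap)
  expect_equal(ov$depth, 1 / 1.35 - 0.7)
  ov2 <- whorl_overlap(shell_model(0.5, 2))
  expect_false(ov2$overlap)
  expect_equal(ov2$depth, 0)
  expect_true(whorl_overlap(shell_model(0.003, 4.59))$overlap)
})

test_that("whorl section reduces to circle formulas and matches an arc-length oracle", {
  ws <- whorl_section(shell_model(0, 2, 1))
  expect_equal(ws$area, pi / 4, tolerance = 1e-10)
  expect_equal(ws$total_perimeter, pi, tolerance = 1e-8)
  ws2 <- whorl_section(shell_model(0.5, 3, 1))  # gyroconic: nothing shared
  expect_equal(ws2$area, pi / 16, tolerance = 1e-10)
  expect_equal(ws2$total_perimeter, pi / 2, tolerance = 1e-8)
  expect_equal(ws2$exposed_perimeter, ws2$total_perimeter)
  # S = 0.3, D = 0.2: perimeter against a brute-force polyline oracle
  a <- (1 - 0.2) / 2; b <- 0.3 * a
  ws3 <- whorl_section(shell_model(0.2, 5, 0.3))
  expect_equal(ws3$total_perimeter, polyline_perimeter(a, b),
               tolerance = 1e-6)
  # overlapping shell builds less than its full perimeter
  ws4 <- whorl_section(shell_model(0.5, 1.3, 1))
  expect_lt(ws4$exposed_perimeter, ws4$total_perimeter)
  expect_gt(ws4$exposed_perimeter, 0)
})

test_that("degenerate apertures are rejected", {
  expect_error(shell_model(1, 2), "D")
  expect_error(shell_model(0.9999999999, 2), "D")
  expect_error(shell_model(0.5, 0.9), "W")
  expect_error(shell_model(0.5, 2, S = 0), "S")
})

test_that("volume ratio is constant on the gyroconic region at fixed S", {
  set.seed(7)
  vals <- replicate(25, {
    D <- runif(1, 0.15, 0.9)
    W <- runif(1, 1 / D + 0.05, 1 / D + 6)   # strictly gyroconic
    volume_ratio(shell_model(D, W, 1))
  })
  expect_true(all(abs(vals - vals[1]) < 1e-9))
  # S = 1 gyroconic constant has the closed form 1 / (2 * thickness)
  expect_equal(vals[1], 1 / (2 * 0.077), tolerance = 1e-9)
  # the constant depends on S only
  v_s <- volume_ratio(shell_model(0.4, 6, 0.3))
  v_s2 <- volume_ratio(shell_model(0.8, 9, 0.3))
  expect_equal(v_s, v_s2, tolerance = 1e-9)
})

test_that("volume ratio falls with wall thickness and rises with shallow overlap", {
  tf <- c(0.04, 0.077, 0.15, 0.3)
  v <- vapply(tf, function(t) volume_ratio(shell_model(0.5, 1.8, 1, t)), 0)
  expect_true(all(diff(v) < 0))
  # shallow overlap saves shared wall: beats the gyroconic constant
  gyro <- volume_ratio(shell_model(0.5, 2.5, 1))
  expect_gt(volume_ratio(shell_model(0.55, 1.75, 1)), gyro)
  # counting the full aperture as cavity can only increase the ratio
  sh <- shell_model(0.6, 1.4, 1)
  expect_gt(volume_ratio(sh, area_mode = "full"), volume_ratio(sh))
  # W = 1 is evaluated as a right-limit, not an error
  expect_gte(volume_ratio(shell_model(0.6, 1, 1)), 0)
})

test_that("sphericity index is sphere-minimal and ranks the depressed archetypes as most globular", {
  sphere_min <- (36 * pi)^(1 / 3)
  # b = R exactly: D and S chosen so the axial breadth equals the diameter
  W <- 2.5; D <- 0.3; S <- (1 + W^-0.5) / (1 - D)
  expect_equal(surface_to_volume(shell_model(D, W, S)), sphere_min,
               tolerance = 1e-9)
  expect_gt(surface_to_volume(shell_model(D, W, S * 2)), sphere_min)
  expect_gt(surface_to_volume(shell_model(D, W, S / 3)), sphere_min)
  # the two compact (high-S) archetypes are the most globular of the five
  V <- reference_pyramid()$vertices
  s2v <- vapply(seq_len(nrow(V)), function(i) {
    surface_to_volume(shell_model(V[i, "D"], V[i, "W"], V[i, "S"]))
  }, 0)
  expect_setequal(order(s2v)[1:2], c(4, 5))
  # depressed compact shell more globular than the compressed low-drag shell
  expect_lt(surface_to_volume(shell_model(0.5, 1.6, 3.2)),
            surface_to_volume(shell_model(0.04, 1.55, 0.2)))
})
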