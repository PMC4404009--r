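# Enclosing-polytope fits: minimum-volume simplexes (triangles) and
# principal convex hull / archetypal analysis for general polytopes.

standardize_traits <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[sd < 1e-12] <- 1
  list(Z = sweep(sweep(X, 2L, mu), 2L, sd, "/"), mu = mu, sd = sd)
}

unstandardize <- function(Z, sc) {
  sweep(sweep(as.matrix(Z), 2L, sc$sd, "*"), 2L, sc$mu, "+")
}

fit_report <- function(polytope, rms_error, fraction_inside, converged,
                       iterations, seed, method, extra = list()) {
  structure(c(list(polytope = polytope, rms_error = rms_error,
                   fraction_inside = fraction_inside, converged = converged,
                   iterations = iterations, seed = seed, method = method),
              extra),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("%s fit: %d vertices in %d-D | rms %.4g | %.1f%% inside | %s\n",
              x$method, x$polytope$k, x$polytope$d, x$rms_error,
              100 * x$fraction_inside,
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$polytope$vertices, 4))
  invisible(x)
}

# exact point-to-triangle distances in 2-D (0 inside), vectorised over points
dist_to_triangle <- function(X, V) {
  x <- X[, 1]; y <- X[, 2]
  n <- nrow(X)
  s <- matrix(0, n, 3L)
  dmin <- rep(Inf, n)
  for (i in 1:3) {
    j <- i %% 3L + 1L
    ex <- V[j, 1] - V[i, 1]; ey <- V[j, 2] - V[i, 2]
    px <- x - V[i, 1]; py <- y - V[i, 2]
    s[, i] <- ex * py - ey * px                 # signed side
    t <- pmin(pmax((px * ex + py * ey) / (ex^2 + ey^2), 0), 1)
    dmin <- pmin(dmin, sqrt((px - t * ex)^2 + (py - t * ey)^2))
  }
  inside <- (rowSums(s >= 0) == 3L) | (rowSums(s <= 0) == 3L)
  ifelse(inside, 0, dmin)
}

dist_to_simplex <- function(X, V) {
  if (ncol(X) == 2L && nrow(V) == 3L) return(dist_to_triangle(as.matrix(X), V))
  hull_coefficients(X, V)$dist
}

#' Minimum-volume soft-enclosing simplex
#'
#' Fits a `k = d + 1` vertex simplex that encloses the data as tightly as
#' possible: the objective is the simplex volume plus
#' `outside_penalty` times the summed distance of points lying outside.
#' Traits are standardised before fitting (columns of very different
#' ranges would otherwise dominate the volume) and the vertices are
#' mapped back.  The fit is initialised from an inflated convex-hull
#' simplex and polished by Nelder-Mead with seeded random restarts, so it
#' is deterministic given `seed`.
#'
#' @param X n x d data matrix (or data frame) of traits.
#' @param outside_penalty Weight of the summed hinge distance.
#' @param restarts Number of jittered restarts (first start unjittered).
#' @param seed Integer seed; restart `r` uses `seed + r - 1`.
#' @param standardize Standardise traits before fitting?
#' @param maxit Nelder-Mead iteration budget per start.
#' @return A `fit_report` with the fitted [polytope()], the rms distance
#'   of points to the simplex (0 for interior points), the fraction of
#'   points inside, and convergence details.
#' @export
fit_simplex <- function(X, outside_penalty = 200, restarts = 10L,
                        seed = 1L, standardize = TRUE, maxit = 800L) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  k <- d + 1L
  if (n <= k) stop("need more points than simplex vertices")
  sc <- if (standardize) standardize_traits(X) else
    list(Z = X, mu = rep(0, d), sd = rep(1, d))
  Z <- sc$Z
  if (simplex_volume(init_simplex(Z)) < 1e-10) {
    stop("degenerate data: points are collinear/coplanar, no full-dimensional simplex fits")
  }
  objective <- function(par) {
    V <- matrix(par, k, d)
    vol <- simplex_volume(V)
    dist <- dist_to_simplex(Z, V)
    vol + outside_penalty * sum(dist)
  }
  V0 <- init_simplex(Z)
  best <- NULL
  for (r in seq_len(restarts)) {
    start <- if (r == 1L) V0 else with_seed(seed + r - 1L, {
      V0 + matrix(stats::rnorm(k * d, sd = 0.15), k, d)
    })
    op <- stats::optim(as.vector(start), objective, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-10))
    if (is.null(best) || op$value < best$value) best <- op
  }
  V <- matrix(best$par, k, d)
  dist <- dist_to_simplex(Z, V)
  scale_d <- sqrt(sum(sc$sd^2))
  fit_report(
    polytope = polytope(unstandardize(V, sc), "simplex"),
    rms_error = sqrt(mean((dist * scale_d)^2)),
    fraction_inside = mean(dist < 1e-6),
    converged = best$convergence == 0L,
    iterations = best$counts[["function"]],
    seed = seed, method = "simplex",
    extra = list(objective = best$value, restarts = restarts)
  )
}

# inflated hull-based initial simplex: furthest-point seeding on the data,
# expanded about the centroid so the start roughly encloses the cloud
init_simplex <- function(Z) {
  d <- ncol(Z); k <- d + 1L
  ctr <- colMeans(Z)
  idx <- which.max(rowSums(sweep(Z, 2L, ctr)^2))
  for (j in seq_len(k - 1L)) {
    idx <- c(idx, which.max(min_sqdist(Z, Z[idx, , drop = FALSE])))
  }
  V <- Z[idx, , drop = FALSE]
  ctr <- colMeans(V)
  sweep(sweep(V, 2L, ctr), 2L, ctr, FUN = function(a, b) a * 1.25 + b)
}

#' Principal convex hull (archetypal) analysis
#'
#' PCHA: the `k` archetypes are (optionally `delta`-relaxed) convex
#' combinations of the data points, and each data point is reconstructed
#' as a convex combination of the archetypes.  Both coefficient matrices
#' are fitted by alternating projected-gradient descent on the squared
#' reconstruction error until the relative improvement falls below `tol`.
#' Seeded multi-restart keeps the best solution.
#'
#' @param X n x d data matrix (or data frame).
#' @param k Number of archetypes (`2 <= k <= n`).
#' @param delta Relaxation of the archetype coefficients: column sums may
#'   range over `[1 - delta, 1 + delta]` (0 = archetypes inside the data's
#'   convex hull).
#' @param restarts,seed Seeded restarts; restart `r` uses `seed + r - 1`.
#' @param standardize Standardise traits before fitting?
#' @param maxit,tol Alternating-minimisation controls.
#' @return A `fit_report`; `$polytope` holds the archetypes (original
#'   units), `$rms_error` the root-mean-square reconstruction distance,
#'   and `$coef` the n x k archetype weights of each data point.
#' @export
fit_pcha <- function(X, k, delta = 0, restarts = 5L, seed = 1L,
                     standardize = TRUE, maxit = 500L, tol = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (k > n) stop("k must not exceed the number of points")
  if (k < 2L) stop("k must be at least 2")
  sc <- if (standardize) standardize_traits(X) else
    list(Z = X, mu = rep(0, d), sd = rep(1, d))
  Z <- sc$Z
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- with_seed(seed + r - 1L, pcha_once(Z, k, delta, maxit, tol))
    if (is.null(best) || fit$sse < best$sse) best <- fit
  }
  arch <- unstandardize(best$archetypes, sc)
  resid <- unstandardize(best$fitted, sc) - X
  fit_report(
    polytope = polytope(arch, "general"),
    rms_error = sqrt(mean(rowSums(resid^2))),
    fraction_inside = mean(best$dist < 1e-6),
    converged = best$converged,
    iterations = best$iterations,
    seed = seed, method = "pcha",
    extra = list(coef = best$S, sse = best$sse, restarts = restarts)
  )
}

pcha_once <- function(Z, k, delta, maxit, tol) {
  n <- nrow(Z)
  # furthest-point seeding with a random start point
  idx <- sample.int(n, 1L)
  for (j in seq_len(k - 1L)) {
    idx <- c(idx, which.max(min_sqdist(Z, Z[idx, , drop = FALSE])))
  }
  ZA <- Z[idx, , drop = FALSE]              # k x d archetypes
  S <- hull_coefficients(Z, ZA, maxit = 100L)$coef
  sse <- sum((S %*% ZA - Z)^2)
  converged <- FALSE
  it <- 0L
  mu <- 1
  for (it in seq_len(maxit)) {
    sse_outer <- sse
    # archetype update: backtracked projected-gradient steps on the
    # (delta-inflated) hull constraint - monotone in the objective
    StS <- crossprod(S)
    StZ <- crossprod(S, Z)
    L_S <- max(eigen(StS, symmetric = TRUE, only.values = TRUE)$values, 1e-12)
    mu <- max(mu, 1 / L_S)
    for (inner in 1:3) {
      grad <- StS %*% ZA - StZ
      repeat {
        ZA_try <- ZA - mu * grad
        for (j in seq_len(k)) {
          ZA_try[j, ] <- project_to_hull(ZA_try[j, ], Z, delta)
        }
        sse_try <- sum((S %*% ZA_try - Z)^2)
        if (sse_try <= sse || mu < 1e-12 / L_S) break
        mu <- mu / 2
      }
      if (sse_try <= sse) { ZA <- ZA_try; sse <- sse_try; mu <- mu * 1.5 }
    }
    # S update: points as convex combinations of archetypes
    S <- hull_coefficients(Z, ZA, maxit = 60L, S0 = S)$coef
    sse <- sum((S %*% ZA - Z)^2)
    if (abs(sse_outer - sse) < tol * (sse + 1e-12)) {
      converged <- TRUE
      break
    }
  }
  proj <- hull_coefficients(Z, ZA, maxit = 400L, S0 = S)
  list(archetypes = ZA, S = proj$coef, fitted = proj$fitted,
       dist = proj$dist, sse = sum((proj$fitted - Z)^2),
       converged = converged, iterations = it)
}

# Project point p onto the convex hull of the rows of Z, inflated about
# the origin (the standardised data centroid) by 1 + delta.  Pairwise
# Frank-Wolfe on the hull-membership QP: the linear subproblem over the
# vertex set is a single matrix-vector product per iteration.
project_to_hull <- function(p, Z, delta = 0, maxit = 200L, tol = 1e-10) {
  if (delta > 0) {
    return((1 + delta) * project_to_hull(p / (1 + delta), Z, 0, maxit, tol))
  }
  # active set of data points with weights
  start <- which.max(Z %*% p)
  active <- start
  w <- 1
  x <- Z[start, ]
  for (it in seq_len(maxit)) {
    g <- x - p
    # forward vertex: most improving data point
    fw <- which.min(Z %*% g)
    d_fw <- Z[fw, ] - x
    # away vertex: worst active point
    aw_i <- active[which.max(Z[active, , drop = FALSE] %*% g)]
    d_aw <- x - Z[aw_i, ]
    if (sum(g * d_fw) >= -tol && sum(g * d_aw) >= -tol) break
    if (sum(g * d_fw) <= sum(g * d_aw)) {       # forward step
      gmax <- 1
      dir <- d_fw
      target <- fw
      away <- FALSE
    } else {                                    # away step
      wi <- w[match(aw_i, active)]
      gmax <- wi / (1 - wi + 1e-15)
      dir <- d_aw
      target <- aw_i
      away <- TRUE
    }
    step <- -sum(g * dir) / sum(dir * dir)
    step <- min(max(step, 0), gmax)
    if (step <= 0) break
    x <- x + step * dir
    # maintain weights explicitly
    if (!away) {
      w <- w * (1 - step)
      if (target %in% active) {
        w[match(target, active)] <- w[match(target, active)] + step
      } else {
        active <- c(active, target)
        w <- c(w, step)
      }
    } else {
      w <- w * (1 + step)
      w[match(target, active)] <- w[match(target, active)] - step
    }
    keep <- w > 1e-12
    active <- active[keep]
    w <- w[keep]
    w <- w / sum(w)
  }
  x
}

#' RMS error profile over the number of archetypes
#'
#' Runs [fit_pcha()] for each `k` with a shared restart budget and seed.
#' The profile is non-increasing in `k` (up to solver tolerance); the
#' elbow where additional archetypes stop improving the fit indicates the
#' number of tasks.
#'
#' @inheritParams fit_pcha
#' @param k_range Integer vector of archetype counts.
#' @return Data frame with columns `k` and `rms_error`; attribute `fits`
#'   holds the full `fit_report`s.
#' @export
rms_profile <- function(X, k_range = 2:8, delta = 0, restarts = 5L,
                        seed = 1L, standardize = TRUE, maxit = 500L) {
  fits <- lapply(k_range, function(k) {
    fit_pcha(X, k, delta = delta, restarts = restarts, seed = seed,
             standardize = standardize, maxit = maxit)
  })
  out <- data.frame(k = k_range,
                    rms_error = vapply(fits, `[[`, 0, "rms_error"))
  attr(out, "fits") <- fits
  out
}
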