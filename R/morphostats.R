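# Randomization statistics for polygonality, triangle similarity, and
# distance-to-archetype enrichment.

morpho_test <- function(statistic, p_value, n_null, seed, null_values,
                        extra = list()) {
  ok <- null_values[is.finite(null_values)]
  structure(c(list(
    statistic = statistic, p_value = p_value, n_null = n_null, seed = seed,
    null_summary = list(
      mean = mean(ok), sd = stats::sd(ok),
      quantiles = stats::quantile(ok, c(0.025, 0.5, 0.975, 1), names = TRUE)
    ),
    n_failed = sum(!is.finite(null_values))
  ), extra), class = "morpho_test")
}

#' @export
print.morpho_test <- function(x, ...) {
  p_lab <- if (x$p_value <= 1 / x$n_null) sprintf("< %.3g", 1 / x$n_null)
           else sprintf("= %.4g", x$p_value)
  cat(sprintf("statistic = %.4g, p %s (%d null replicates, seed %d)\n",
              x$statistic, p_lab, x$n_null, x$seed))
  cat(sprintf("null: mean %.4g, sd %.4g\n",
              x$null_summary$mean, x$null_summary$sd))
  if (x$n_failed > 0) cat(sprintf("(%d null fits failed and were excluded)\n",
                                  x$n_failed))
  invisible(x)
}

# p-value with the 1/n resolution floor (never exactly 0)
p_floor <- function(count, n) max(count / n, 1 / n)

#' t-ratio: convex-hull area over enclosing-simplex area
#'
#' How completely the data fill their fitted triangle: the ratio of the
#' area of the convex hull of the points to the area of the simplex.
#' Equals 1 for perfectly polygonal data (points filling the triangle up
#' to its vertices) and is close to 0 for data that occupy only a small
#' part of it.  Collinear data have hull area 0, hence t = 0.
#'
#' @param points n x 2 matrix of trait points.
#' @param simplex A triangle as a [polytope()] (or 3 x 2 matrix).
#' @return Ratio in `[0, 1]` when the simplex encloses the data.
#' @export
t_ratio <- function(points, simplex) {
  points <- as.matrix(points)
  V <- if (inherits(simplex, "polytope")) simplex$vertices else as.matrix(simplex)
  tri_area <- polygon_area(V)
  if (tri_area <= 0) stop("zero-area simplex")
  hull <- grDevices::chull(points)
  if (length(hull) < 3L) return(0)
  polygon_area(points[hull, , drop = FALSE]) / tri_area
}

#' Polygonality randomization test
#'
#' Tests whether the data fill a triangle more completely than expected
#' for traits with the same marginal distributions but no joint
#' structure.  The statistic is the [t_ratio()] of the data under their
#' fitted minimum-volume triangle.  The null randomizes by independently
#' permuting each trait column (preserving marginals exactly), refitting
#' the triangle, and recomputing the t-ratio; the p-value is the fraction
#' of null replicates with a larger t-ratio.
#'
#' @param points n x 2 matrix of trait points (n >= 10).
#' @param n_null Number of null replicates (> 0).
#' @param seed Integer seed.
#' @param refit Refit the simplex for each null replicate (conservative,
#'   default) or reuse the data's simplex.
#' @param restarts,null_restarts Restart budgets for the data fit and the
#'   null fits.
#' @param outside_penalty Passed to [fit_simplex()].
#' @return A `morpho_test`; `$fit` holds the data's triangle fit.
#' @export
polygonality_test <- function(points, n_null = 10000L, seed = 1L,
                              refit = TRUE, restarts = 10L,
                              null_restarts = 1L, outside_penalty = 200) {
  points <- as.matrix(points)
  if (nrow(points) < 10L) stop("need at least 10 points")
  if (n_null < 1L) stop("n_null must be positive")
  fit <- fit_simplex(points, outside_penalty = outside_penalty,
                     restarts = restarts, seed = seed)
  t_obs <- t_ratio(points, fit$polytope)
  null_t <- with_seed(seed, {
    vapply(seq_len(n_null), function(i) {
      perm <- apply(points, 2L, sample)
      tryCatch({
        tri <- if (refit) {
          fit_simplex(perm, outside_penalty = outside_penalty,
                      restarts = null_restarts, seed = seed + i)$polytope
        } else fit$polytope
        t_ratio(perm, tri)
      }, error = function(e) NA_real_)
    }, numeric(1))
  })
  ok <- null_t[is.finite(null_t)]
  morpho_test(t_obs, p_floor(sum(ok > t_obs), length(ok)), n_null, seed,
              null_t, extra = list(fit = fit))
}

# ---- convex polygon clipping ----------------------------------------------

# Sutherland-Hodgman clipping of polygon `subject` by convex polygon
# `clip`, both counter-clockwise n x 2 matrices; returns the intersection
clip_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (is.null(out) || nrow(out) == 0L) return(NULL)
    a <- clip[i, ]; b <- clip[i %% nc + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    inp <- out
    n <- nrow(inp)
    side <- ex * (inp[, 2] - a[2]) - ey * (inp[, 1] - a[1])
    res <- matrix(0, 0, 2L)
    for (j in seq_len(n)) {
      jn <- j %% n + 1L
      p <- inp[j, ]; q <- inp[jn, ]
      sp <- side[j]; sq <- side[jn]
      if (sp >= 0) res <- rbind(res, p)
      if ((sp > 0 && sq < 0) || (sp < 0 && sq > 0)) {
        t <- sp / (sp - sq)
        res <- rbind(res, p + t * (q - p))
      }
    }
    out <- res
  }
  out
}

ccw <- function(poly) {
  if (polygon_signed_area(poly) < 0) poly[rev(seq_len(nrow(poly))), ] else poly
}

polygon_signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

#' Triangle similarity: intersection over union area
#'
#' Exact polygon clipping: `area(A intersect B) / area(A union B)`.
#' Equals 1 iff the triangles coincide and 0 when they are disjoint; the
#' ratio is invariant under any common affine map of both triangles with
#' constant Jacobian (translation, rotation, scaling).
#'
#' @param A,B Triangles as [polytope()]s or 3 x 2 matrices.
#' @return Ratio in `[0, 1]`.
#' @export
triangle_similarity <- function(A, B) {
  va <- if (inherits(A, "polytope")) A$vertices else as.matrix(A)
  vb <- if (inherits(B, "polytope")) B$vertices else as.matrix(B)
  aa <- polygon_area(va); ab <- polygon_area(vb)
  if (aa <= 0 || ab <= 0) stop("degenerate triangle")
  inter <- clip_convex(ccw(va), ccw(vb))
  ai <- if (is.null(inter)) 0 else polygon_area(inter)
  ai / (aa + ab - ai)
}

#' Null distribution test for triangle similarity
#'
#' Compares an observed intersection/union ratio with the similarity of
#' random triangle pairs whose six vertices are drawn i.i.d. uniformly on
#' a rectangle.  The similarity ratio is invariant to the rectangle's
#' scale and aspect, so the default unit square is not a modelling
#' choice.  The p-value is the fraction of random pairs at least as
#' similar as observed.
#'
#' @param observed_ratio Observed intersection/union ratio in `[0, 1]`.
#' @param n_null Number of random triangle pairs.
#' @param seed Integer seed.
#' @param rect `c(width, height)` of the sampling rectangle.
#' @return A `morpho_test`.
#' @export
similarity_test <- function(observed_ratio, n_null = 10000L, seed = 1L,
                            rect = c(1, 1)) {
  stop_if_not_number(observed_ratio, "observed_ratio", 0, 1)
  null_r <- with_seed(seed, {
    vapply(seq_len(n_null), function(i) {
      A <- cbind(stats::runif(3, 0, rect[1]), stats::runif(3, 0, rect[2]))
      B <- cbind(stats::runif(3, 0, rect[1]), stats::runif(3, 0, rect[2]))
      if (polygon_area(A) <= 0 || polygon_area(B) <= 0) return(0)
      triangle_similarity(A, B)
    }, numeric(1))
  })
  morpho_test(observed_ratio,
              p_floor(sum(null_r >= observed_ratio), n_null),
              n_null, seed, null_r)
}

#' Trait-distance enrichment of a covariate
#'
#' Tests whether a per-genus value (e.g. shell diameter) is enriched near
#' a trait-space vertex.  Genera are ranked by Euclidean distance to the
#' vertex (in standardised trait space by default), split into
#' `n_bins` equal-count bins, and a least-squares line is fitted through
#' the bin means.  Significance of the slope is assessed by permuting the
#' values over genera (two-sided).
#'
#' @param points n x d matrix of traits.
#' @param values Numeric vector of length n (positive covariate).
#' @param vertex Trait point (length d).
#' @param n_bins Number of equal-count bins.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param standardize Standardise traits before computing distances?
#' @return An object of class `enrichment_result`: bin means and edges,
#'   slope, permutation p-value, and direction
#'   (`"positive"`, `"negative"`, or `"none"`).
#' @export
enrichment_by_distance <- function(points, values, vertex, n_bins = 10L,
                                   n_perm = 10000L, seed = 1L,
                                   standardize = TRUE) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n_bins > n) stop("more bins than points")
  if (length(values) != n) stop("values must match the number of points")
  if (standardize) {
    sc <- standardize_traits(points)
    points <- sc$Z
    vertex <- (as.numeric(vertex) - sc$mu) / sc$sd
  }
  dist <- sqrt(colSums((t(points) - as.numeric(vertex))^2))
  ord <- order(dist, seq_len(n))          # stable tie-break by index
  bin_id <- integer(n)
  # equal-count bins: counts differ by at most 1
  sizes <- rep(n %/% n_bins, n_bins) + c(rep(1L, n %% n_bins),
                                         rep(0L, n_bins - n %% n_bins))
  bin_id[ord] <- rep(seq_len(n_bins), times = sizes)
  slope_of <- function(v) {
    m <- vapply(seq_len(n_bins), function(b) mean(v[bin_id == b]), 0)
    stats::coef(stats::lm(m ~ seq_len(n_bins)))[2L]
  }
  slope <- slope_of(values)
  if (stats::sd(values) < 1e-12) {
    perm <- rep(0, n_perm)
    p <- 1
  } else {
    perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) slope_of(sample(values)), 0)
    })
    p <- p_floor(sum(abs(perm) >= abs(slope)), n_perm)
  }
  edges <- c(0, vapply(seq_len(n_bins), function(b) max(dist[bin_id == b]), 0))
  structure(list(
    bin_means = vapply(seq_len(n_bins), function(b) mean(values[bin_id == b]), 0),
    bin_edges = edges,
    bin_counts = as.integer(table(bin_id)),
    slope = unname(slope),
    p_value = p,
    n_perm = n_perm,
    seed = seed,
    # direction of the enrichment AT the vertex: values falling off with
    # distance (negative slope) mean the value is enriched near the vertex
    direction = if (p > 0.05) "none" else if (slope < 0) "positive" else "negative"
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("distance enrichment: slope %.4g per bin, p = %.4g (%s)\n",
              x$slope, x$p_value, x$direction))
  cat("bin means:", paste(signif(x$bin_means, 4), collapse = " "), "\n")
  invisible(x)
}
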