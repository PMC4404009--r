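#' Polytope in trait space
#'
#' An ordered set of `k` vertices in `d`-dimensional trait space.  The
#' convex hull of the vertices is the suite of variation predicted by
#' Pareto theory with `k` tasks.
#'
#' @param vertices Numeric matrix, one row per vertex.
#' @param kind `"simplex"` (k = d + 1) or `"general"`.
#' @return An object of class `polytope`.
#' @export
polytope <- function(vertices, kind = c("general", "simplex")) {
  vertices <- as.matrix(vertices)
  kind <- match.arg(kind)
  if (!all(is.finite(vertices))) stop("polytope vertices must be finite")
  if (kind == "simplex" && nrow(vertices) != ncol(vertices) + 1L) {
    stop("a simplex in d dimensions needs d + 1 vertices")
  }
  structure(list(vertices = vertices, d = ncol(vertices), k = nrow(vertices),
                 kind = kind),
            class = "polytope")
}

#' @export
print.polytope <- function(x, ...) {
  cat(sprintf("%s polytope: %d vertices in %d-D\n", x$kind, x$k, x$d))
  print(round(x$vertices, 4))
  invisible(x)
}

# volume of a simplex from its (d+1) x d vertex matrix
simplex_volume <- function(vertices) {
  v <- as.matrix(vertices)
  d <- ncol(v)
  edges <- sweep(v[-1L, , drop = FALSE], 2L, v[1L, ])
  abs(det(edges)) / factorial(d)
}

#' Area or volume of a polytope
#'
#' Simplexes use the determinant formula; planar polygons (ordered
#' vertices) use the shoelace formula; general 3-D polytopes are
#' decomposed into simplexes around their centroid after a convex
#' ordering is not required (hull volume via [hull_coefficients()] is
#' used elsewhere).
#'
#' @param p A [polytope()].
#' @return Scalar area/volume.
#' @export
polytope_volume <- function(p) {
  stopifnot(inherits(p, "polytope"))
  v <- p$vertices
  if (p$kind == "simplex" || p$k == p$d + 1L) return(simplex_volume(v))
  if (p$d == 2L) {
    ord <- order(atan2(v[, 2] - mean(v[, 2]), v[, 1] - mean(v[, 1])))
    return(polygon_area(v[ord, , drop = FALSE]))
  }
  stop("volume of general polytopes is only implemented in 2-D")
}

# shoelace area of an ordered 2-D polygon (n x 2 matrix)
polygon_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3L) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Convex-combination coefficients onto a vertex set
#'
#' For each data point, finds the convex combination of the vertices that
#' is closest in Euclidean norm (the projection onto the convex hull of
#' the vertices), by projected-gradient iteration on the probability
#' simplex.  Used for hull membership, distances, and reconstruction
#' errors.
#'
#' @param X n x d data matrix.
#' @param V k x d vertex matrix.
#' @param maxit,tol Iteration controls.
#' @param S0 Optional warm-start coefficient matrix.
#' @return List with `coef` (n x k), `fitted` (n x d), `dist` (n).
#' @export
hull_coefficients <- function(X, V, maxit = 600L, tol = 1e-10, S0 = NULL) {
  X <- as.matrix(X); V <- as.matrix(V)
  k <- nrow(V)
  Zt <- V                       # k x d
  G <- Zt %*% t(Zt)             # k x k Gram
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values, 1e-12)
  S <- if (is.null(S0)) matrix(1 / k, nrow(X), k) else S0
  XZt <- X %*% t(Zt)            # n x k
  # FISTA (accelerated projected gradient) on the row-simplex constraint
  Y <- S
  t_acc <- 1
  obj_old <- Inf
  for (it in seq_len(maxit)) {
    S_new <- proj_simplex_rows(Y - (Y %*% G - XZt) / L)
    t_new <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
    Y <- S_new + ((t_acc - 1) / t_new) * (S_new - S)
    S <- S_new
    t_acc <- t_new
    if (it %% 10L == 0L) {
      R <- S %*% Zt - X
      obj <- sum(R * R)
      if (abs(obj_old - obj) < tol * (obj + 1e-12)) break
      obj_old <- obj
    }
  }
  fitted <- S %*% Zt
  list(coef = S, fitted = fitted, dist = sqrt(rowSums((X - fitted)^2)))
}

# Euclidean projection of each row onto the probability simplex (Duchi
# et al.).  Row-wise descending sort is done with an odd-even sorting
# network of vectorised pmin/pmax passes - k is small, n can be large.
proj_simplex_rows <- function(M, total = 1) {
  k <- ncol(M)
  n <- nrow(M)
  if (k == 1L) return(matrix(total, n, 1L))
  U <- M
  for (pass in seq_len(k)) {
    start <- if (pass %% 2L) 1L else 2L
    if (start > k - 1L) next
    for (j in seq(start, k - 1L, by = 2L)) {
      hi <- pmax(U[, j], U[, j + 1L])
      U[, j + 1L] <- pmin(U[, j], U[, j + 1L])
      U[, j] <- hi
    }
  }
  css <- U
  for (j in 2:k) css[, j] <- css[, j - 1L] + U[, j]
  css <- css - total
  cond <- U - css / rep(seq_len(k), each = n) > 0
  rho <- rowSums(cond)             # prefix property of the Duchi condition
  theta <- css[cbind(seq_len(n), rho)] / rho
  pmax(M - theta, 0)
}

# squared distance from each row of Z to its nearest row among `chosen`
min_sqdist <- function(Z, chosen) {
  d <- rep(Inf, nrow(Z))
  for (i in seq_len(nrow(chosen))) {
    d <- pmin(d, rowSums(sweep(Z, 2L, chosen[i, ])^2))
  }
  d
}

#' Project a polytope onto a subset of trait axes
#'
#' Drops the other coordinates and merges projected vertices closer than
#' `merge_tol`, reporting which original vertices merged.
#'
#' @param p A [polytope()].
#' @param axes Integer or character indices of the axes to keep.
#' @param merge_tol Distance below which projected vertices merge.
#' @param scale Per-axis divisors applied before measuring merge
#'   distances (e.g. the trait ranges), so axes with very different
#'   spans are weighted comparably.
#' @return List with `polytope` (projected, merged) and `merge_map`
#'   (list of original-vertex index groups, one per merged vertex).
#' @export
project_polytope <- function(p, axes, merge_tol = 0.05, scale = NULL) {
  stopifnot(inherits(p, "polytope"))
  v <- p$vertices[, axes, drop = FALSE]
  k <- nrow(v)
  # single-linkage grouping under merge_tol
  group <- seq_len(k)
  vs <- if (is.null(scale)) v else sweep(v, 2L, scale, "/")
  dmat <- as.matrix(stats::dist(vs))
  repeat {
    merged <- FALSE
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
      if (dmat[i, j] < merge_tol && group[i] != group[j]) {
        group[group == group[j]] <- group[i]
        merged <- TRUE
      }
    }
    if (!merged) break
  }
  ids <- unique(group)
  merged_v <- t(vapply(ids, function(g) {
    colMeans(v[group == g, , drop = FALSE])
  }, numeric(ncol(v))))
  map <- lapply(ids, function(g) which(group == g))
  list(polytope = polytope(merged_v, "general"), merge_map = map)
}
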