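#' Non-dominated (Pareto) filter
#'
#' A point is kept iff no other point is at least as good in every task
#' and strictly better in at least one.  Ties are kept: two identical
#' performance vectors both survive.
#'
#' @param perf Numeric matrix, one row per point, one column per task
#'   (higher is better).
#' @return Logical vector: `TRUE` for non-dominated rows.
#' @export
non_dominated <- function(perf) {
  perf <- as.matrix(perf)
  if (nrow(perf) == 0L) stop("empty performance matrix")
  if (any(!is.finite(perf))) stop("performance values must be finite")
  n <- nrow(perf)
  keep <- rep(TRUE, n)
  # candidate dominators must be at least as good in the first task;
  # sorting by it limits comparisons to earlier rows in the order
  ord <- order(perf[, 1L], decreasing = TRUE)
  sorted <- perf[ord, , drop = FALSE]
  for (i in seq_len(n)) {
    if (i == 1L) next
    x <- sorted[i, ]
    prev <- sorted[seq_len(i - 1L), , drop = FALSE]
    ge <- prev >= rep(x, each = i - 1L)
    gt <- prev > rep(x, each = i - 1L)
    if (any(rowSums(ge) == ncol(perf) & rowSums(gt) > 0L)) {
      keep[ord[i]] <- FALSE
    }
  }
  keep
}

#' Pareto front on a trait grid
#'
#' Evaluates every surface on the grid and keeps the non-dominated points.
#' Every single-task maximiser (archetype) is by construction part of the
#' front.
#'
#' @param surfaces List of [performance_surface()] objects (at least 2).
#' @param grid A [grid_spec()].
#' @return An object of class `front_result`: list with `points` (trait
#'   data frame), `performance` (matrix), `on_front` (logical mask), and
#'   `archetypes` (per-task grid maximisers).
#' @export
front_on_grid <- function(surfaces, grid) {
  stopifnot(is.list(surfaces), length(surfaces) >= 2L)
  lapply(surfaces, function(s) stopifnot(inherits(s, "performance_surface")))
  nms <- vapply(surfaces, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("surface names must be unique")
  for (ax in c("D", "S", "W")) {
    rng <- if (length(grid[[ax]]) == 1L) rep(grid[[ax]], 2) else grid[[ax]][1:2]
    for (s in surfaces) {
      if (rng[1] < s$domain[[ax]][1] - 1e-9 || rng[2] > s$domain[[ax]][2] + 1e-9) {
        stop(sprintf("grid axis `%s` outside domain of surface '%s'", ax, s$name))
      }
    }
  }
  pts <- grid_points(grid)
  perf <- vapply(surfaces, eval_surface, numeric(nrow(pts)), pts = pts)
  colnames(perf) <- nms
  mask <- non_dominated(perf)
  arch <- lapply(seq_along(surfaces), function(j) {
    ord <- order(pts$D, pts$S, pts$W)
    best <- ord[which.max(perf[ord, j])]
    unlist(pts[best, c("D", "S", "W")])
  })
  names(arch) <- nms
  structure(list(points = pts, performance = perf, on_front = mask,
                 archetypes = arch),
            class = "front_result")
}

#' @export
print.front_result <- function(x, ...) {
  cat(sprintf("Pareto front: %d of %d grid points non-dominated (%d tasks)\n",
              sum(x$on_front), nrow(x$points), ncol(x$performance)))
  for (nm in names(x$archetypes)) {
    a <- x$archetypes[[nm]]
    cat(sprintf("  archetype [%s]: D = %.3g, S = %.3g, W = %.3g\n",
                nm, a["D"], a["S"], a["W"]))
  }
  invisible(x)
}

#' @export
#' @importFrom graphics plot points legend
plot.front_result <- function(x, ...) {
  pts <- x$points
  plot(pts$D, pts$W, col = ifelse(x$on_front, "steelblue", "grey85"),
       pch = 16, cex = 0.4, xlab = "D", ylab = "W", ...)
  for (a in x$archetypes) points(a["D"], a["W"], pch = 17, col = "red", cex = 1.2)
  legend("topright", legend = c("front", "dominated", "archetype"),
         col = c("steelblue", "grey85", "red"), pch = c(16, 16, 17), bty = "n")
  invisible(x)
}
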