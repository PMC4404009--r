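#' Performance surfaces over morphospace
#'
#' A performance surface maps trait points `(D, S, W)` to a scalar
#' performance (higher is better) on a box domain.  Surfaces are the input
#' to Pareto-front construction: each surface represents one putative task,
#' and its maximiser is the task's archetype.
#'
#' @param name Label, unique within an analysis.
#' @param evaluator Function taking a data frame with columns `D`, `S`, `W`
#'   and returning a numeric vector of performances.
#' @param domain Named list of `c(min, max)` bounds for `D`, `S`, `W`.
#' @return An object of class `performance_surface`.
#' @export
performance_surface <- function(name, evaluator,
                                domain = list(D = c(0, 0.95),
                                              S = c(0.1, 3.5),
                                              W = c(1 + 1e-6, 6))) {
  stopifnot(is.character(name), length(name) == 1L, is.function(evaluator))
  stopifnot(all(c("D", "S", "W") %in% names(domain)))
  structure(list(name = name, evaluator = evaluator, domain = domain),
            class = "performance_surface")
}

#' @export
print.performance_surface <- function(x, ...) {
  dm <- vapply(x$domain, function(b) sprintf("[%g, %g]", b[1], b[2]), "")
  cat(sprintf("performance surface '%s' on D %s, S %s, W %s\n",
              x$name, dm[["D"]], dm[["S"]], dm[["W"]]))
  invisible(x)
}

eval_surface <- function(surface, pts) {
  stopifnot(inherits(surface, "performance_surface"))
  if (!"S" %in% names(pts)) pts$S <- 1
  surface$evaluator(pts)
}

#' Shell-material economy performance
#'
#' Wraps [volume_ratio()]: the internal-volume to shell-material ratio as a
#' performance surface over `(D, S, W)`.  High values mean much cavity per
#' unit of shell material laid down.
#'
#' @param thickness_fraction Wall thickness relative to the aperture scale.
#' @inheritParams performance_surface
#' @return A `performance_surface`.
#' @export
economy_performance <- function(thickness_fraction = 0.077,
                                domain = list(D = c(0, 0.95),
                                              S = c(0.1, 3.5),
                                              W = c(1 + 1e-6, 5))) {
  performance_surface(
    "economy",
    function(pts) {
      mapply(function(D, S, W) {
        volume_ratio(shell_model(D, W, S, thickness_fraction))
      }, pts$D, pts$S, pts$W)
    },
    domain
  )
}

#' Rapid-growth performance
#'
#' The growth model penalises a shell for the time it spends at small
#' diameters: with shell-material production proportional to body mass,
#' the penalty is `P = W / (Ratio(D, W) log(W) (1 + sqrt(W)))`, where
#' `Ratio` is [volume_ratio()] evaluated at `S = S_eval`.  The penalty
#' diverges as `W -> 1` (the diameter stops growing), so the returned
#' performance is the reciprocal `1/P`, which peaks at evolute,
#' fast-expanding shells.
#'
#' @param S_eval Aperture shape at which the volume ratio is evaluated
#'   (default 1, a circular opening).
#' @param thickness_fraction Wall thickness relative to aperture scale.
#' @inheritParams performance_surface
#' @return A `performance_surface` over `(D, W)` (the `S` coordinate of
#'   evaluation points is ignored; `S_eval` is used instead).
#' @export
growth_performance <- function(S_eval = 1, thickness_fraction = 0.077,
                               domain = list(D = c(0, 0.95),
                                             S = c(0.1, 3.5),
                                             W = c(1 + 1e-6, 6))) {
  stop_if_not_number(S_eval, "S_eval", 1e-9, Inf)
  performance_surface(
    "growth",
    function(pts) {
      if (any(pts$W <= 1)) stop("growth performance requires W > 1")
      mapply(function(D, W) {
        R <- volume_ratio(shell_model(D, W, S_eval, thickness_fraction))
        R * log(W) * (1 + sqrt(W)) / W
      }, pts$D, pts$W)
    },
    domain
  )
}

#' Hydrodynamic-drag performance
#'
#' Higher performance means lower drag.  Measured drag coefficients show
#' drag increasing monotonically with `D` and `W`, with the best
#' hydrodynamics at compressed openings (`S -> 0`).  The default surface
#' is a documented analytic stand-in with exactly that monotone structure,
#' `-(alpha D + beta (W - 1)/(W_ref - 1) + gamma S/S_ref)`, so its argmax
#' on any box is the low-`(D, S, W)` corner.  A measured table with
#' columns `D`, `S`, `W`, `cd` may be supplied instead and is interpolated
#' by inverse-distance weighting (exact at the nodes).
#'
#' @param table Optional data frame of measured drag coefficients.
#' @param alpha,beta,gamma Positive weights of the default stand-in.
#' @param W_ref,S_ref Normalisation constants of the default stand-in.
#' @inheritParams performance_surface
#' @return A `performance_surface`.
#' @export
drag_performance <- function(table = NULL, alpha = 1, beta = 1, gamma = 1,
                             W_ref = 5, S_ref = 3.5,
                             domain = list(D = c(0, 0.95),
                                           S = c(0.1, 3.5),
                                           W = c(1 + 1e-6, 5))) {
  if (is.null(table)) {
    ev <- function(pts) {
      -(alpha * pts$D + beta * (pts$W - 1) / (W_ref - 1) +
          gamma * pts$S / S_ref)
    }
    return(performance_surface("drag", ev, domain))
  }
  stopifnot(is.data.frame(table), all(c("D", "S", "W", "cd") %in% names(table)))
  key <- paste(table$D, table$S, table$W)
  if (anyDuplicated(key)) stop("drag table has duplicate (D, S, W) coordinates")
  nodes <- as.matrix(table[, c("D", "S", "W")])
  cd <- table$cd
  ev <- function(pts) {
    q <- as.matrix(pts[, c("D", "S", "W")])
    out <- numeric(nrow(q))
    for (i in seq_len(nrow(q))) {
      d2 <- colSums((t(nodes) - q[i, ])^2)
      hit <- which(d2 < 1e-18)
      if (length(hit)) {
        out[i] <- -cd[hit[1L]]
      } else {
        w <- 1 / d2
        out[i] <- -sum(w * cd) / sum(w)
      }
    }
    out
  }
  performance_surface("drag", ev, domain)
}

#' Evaluation grid specification
#'
#' @param D,W `c(min, max, n)` triples for the active axes.
#' @param S Either a `c(min, max, n)` triple, or a single number to fix
#'   `S` (a 2-D analysis in the W-D plane).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(D = c(0, 0.95, 101), W = c(1 + 1e-6, 5, 101), S = 1) {
  check_axis <- function(ax, nm) {
    if (length(ax) == 1L) return(ax)
    if (length(ax) != 3L || ax[1] >= ax[2] || ax[3] < 2) {
      stop(sprintf("axis `%s` must be c(min, max, n) with min < max, n >= 2", nm))
    }
    ax
  }
  structure(list(D = check_axis(D, "D"), W = check_axis(W, "W"),
                 S = check_axis(S, "S")),
            class = "grid_spec")
}

grid_points <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  axis_vals <- function(ax) {
    if (length(ax) == 1L) ax else seq(ax[1], ax[2], length.out = ax[3])
  }
  # lexicographic order in (D, S, W): W varies fastest
  g <- expand.grid(W = axis_vals(grid$W), S = axis_vals(grid$S),
                   D = axis_vals(grid$D))
  g[, c("D", "S", "W")]
}

#' Deterministic grid argmax with optional local refinement
#'
#' Scans the surface on the grid; ties are broken towards the
#' lexicographically smallest `(D, S, W)`.  With `refine = TRUE` the grid
#' maximiser is polished by bounded quasi-Newton optimisation inside the
#' surface domain (fixed-`S` grids are refined in the `(D, W)` plane only).
#'
#' @param surface A [performance_surface()].
#' @param grid A [grid_spec()].
#' @param refine Refine the grid maximiser by continuous optimisation?
#' @return List with `par` (named trait point), `value`, and the
#'   unrefined `grid_par`/`grid_value`.
#' @export
argmax_on_grid <- function(surface, grid, refine = TRUE) {
  pts <- grid_points(grid)
  vals <- eval_surface(surface, pts)
  if (all(is.na(vals))) stop("surface is NaN on the whole grid")
  ord <- order(pts$D, pts$S, pts$W)   # lexicographic tie-break
  best <- ord[which.max(vals[ord])]
  par <- unlist(pts[best, c("D", "S", "W")])
  out <- list(grid_par = par, grid_value = vals[best])
  if (refine) {
    fixed_S <- length(grid$S) == 1L
    free <- if (fixed_S) c("D", "W") else c("D", "S", "W")
    lo <- vapply(free, function(nm) surface$domain[[nm]][1], 0)
    hi <- vapply(free, function(nm) surface$domain[[nm]][2], 0)
    fn <- function(p) {
      q <- as.list(par)
      q[free] <- p
      -eval_surface(surface, as.data.frame(q))
    }
    op <- stats::optim(pmin(pmax(par[free], lo), hi), fn,
                       method = "L-BFGS-B", lower = lo, upper = hi,
                       control = list(factr = 1e5))
    refined <- par
    refined[free] <- op$par
    if (-op$value >= out$grid_value) {
      out$par <- refined
      out$value <- -op$value
    } else {
      out$par <- par
      out$value <- out$grid_value
    }
  } else {
    out$par <- par
    out$value <- out$grid_value
  }
  out
}
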