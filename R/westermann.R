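# Westermann-style ternary projection of (D, S, W) morphospace and its
# local distortion.

#' Westermann ternary projection
#'
#' Maps a trait point to barycentric coordinates of a ternary triangle
#' whose corners correspond to umbilical exposure (serpenticone-like,
#' driven by `D`), expansion (oxycone-like, driven by `W`) and inflation
#' (sphericone-like, driven by `S`).  Each trait is first rescaled to a
#' `[0, 1]` score by a documented affine transform (`D` as-is,
#' `(W - 1)/(W_ref - 1)`, `S/S_ref`), then the scores are normalised by
#' their sum.  The projection is scale-consistent: multiplying all three
#' scores by a constant leaves the ternary point unchanged.  Points whose
#' three scores are all (near) zero have no well-defined image - this is
#' the severely warped region of morphospace near the low-drag archetype.
#'
#' @param point Numeric `c(D, S, W)` (or a data frame row with those
#'   columns).
#' @param w_ref,s_ref Normalisation constants of the affine transform.
#' @return An object of class `ternary_point`: barycentric coordinates
#'   `(u_D, u_S, u_W)` summing to 1 plus plane coordinates `xy` for an
#'   equilateral triangle with unit side.
#' @export
to_westermann <- function(point, w_ref = 5, s_ref = 3.5) {
  if (is.data.frame(point)) point <- c(D = point$D[1], S = point$S[1],
                                       W = point$W[1])
  pick <- function(nm, i) {
    if (!is.null(names(point)) && nm %in% names(point)) point[[nm]]
    else point[[i]]
  }
  D <- pick("D", 1L)
  S <- pick("S", 2L)
  W <- pick("W", 3L)
  scores <- c(D = D, S = S / s_ref, W = (W - 1) / (w_ref - 1))
  tot <- sum(scores)
  if (abs(tot) < 1e-12) {
    stop("undefined ternary image: all three scores are zero ",
         "(warped region near the low-D, low-S, low-W corner)")
  }
  bary <- scores / tot
  structure(list(bary = bary, xy = ternary_xy(bary)), class = "ternary_point")
}

# plane coordinates of barycentric (u_D, u_S, u_W) in an equilateral
# triangle: D corner (0,0), S corner (1,0), W corner (1/2, sqrt(3)/2)
ternary_xy <- function(bary) {
  c(x = bary[["S"]] + bary[["W"]] / 2, y = bary[["W"]] * sqrt(3) / 2)
}

#' @export
print.ternary_point <- function(x, ...) {
  cat(sprintf("ternary point: u_D = %.3f, u_S = %.3f, u_W = %.3f\n",
              x$bary[["D"]], x$bary[["S"]], x$bary[["W"]]))
  invisible(x)
}

#' Local distortion of the Westermann projection
#'
#' Samples a small ellipsoid around a trait point (semi-axis along each
#' coordinate = `radius_frac` of that coordinate's total variation,
#' i.e. of the normalisation range), maps every sample to the ternary
#' plane, and summarises the spread of the images.  Large spreads mark
#' regions where the nonlinear projection is severely warped: tiny shape
#' differences map to very different ternary positions.
#'
#' @param point Trait point `c(D, S, W)`.
#' @param radius_frac Ellipsoid semi-axes as a fraction of each
#'   coordinate's range (default 0.05 = 5 percent).
#' @param n_samples Number of samples.
#' @param seed Integer seed.
#' @param w_ref,s_ref Passed to [to_westermann()].
#' @return List with `max_spread` (largest pairwise distance between
#'   mapped samples in the ternary plane), `cov` (2 x 2 covariance of the
#'   mapped points), `n_undefined` (samples without a ternary image), and
#'   the mapped `xy` coordinates.
#' @export
sensitivity_region <- function(point, radius_frac = 0.05, n_samples = 500L,
                               seed = 1L, w_ref = 5, s_ref = 3.5) {
  point <- c(D = unname(point[1]), S = unname(point[2]), W = unname(point[3]))
  ranges <- c(D = 1, S = s_ref, W = w_ref - 1)
  radii <- radius_frac * ranges
  samples <- with_seed(seed, {
    # uniform in the unit ball, scaled per-axis
    u <- matrix(stats::rnorm(3 * n_samples), n_samples, 3)
    u <- u / sqrt(rowSums(u^2))
    r <- stats::runif(n_samples)^(1 / 3)
    sweep(u * r, 2L, radii, "*")
  })
  pts <- sweep(samples, 2L, point, "+")
  xy <- matrix(NA_real_, n_samples, 2L)
  n_undef <- 0L
  for (i in seq_len(n_samples)) {
    tp <- tryCatch(to_westermann(pts[i, ], w_ref, s_ref),
                   error = function(e) NULL)
    if (is.null(tp)) n_undef <- n_undef + 1L else xy[i, ] <- tp$xy
  }
  ok <- stats::complete.cases(xy)
  spread <- if (sum(ok) >= 2L) max(stats::dist(xy[ok, , drop = FALSE])) else 0
  list(max_spread = spread,
       cov = if (sum(ok) >= 2L) stats::cov(xy[ok, , drop = FALSE])
             else matrix(0, 2, 2),
       n_undefined = n_undef,
       xy = xy[ok, , drop = FALSE])
}
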