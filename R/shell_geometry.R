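#' Raup logarithmic-spiral shell model
#'
#' Construct a coiled-shell model in Raup's dimensionless morphospace.  The
#' outer shell margin is a logarithmic spiral whose radius grows by a factor
#' `W` per full revolution; the aperture (generating curve) is an ellipse
#' whose radial height spans the fraction `1 - D` of the outer radius and
#' whose width-to-height ratio is `S`.  Shell wall thickness is a fixed
#' fraction of the aperture scale, so every derived quantity is a pure
#' number: the model has no absolute size.
#'
#' @param D Ratio of inner to outer shell radius (umbilical exposure),
#'   `0 <= D < 1`.
#' @param W Whorl expansion rate per revolution, `W >= 1` (`W = 1` is the
#'   degenerate non-expanding limit and is treated as a right-limit by the
#'   volumetric functions).
#' @param S Aperture shape, width/height of the opening ellipse, `S > 0`.
#'   `S < 1` gives compressed (oblate) openings, `S > 1` depressed ones.
#' @param thickness_fraction Shell wall thickness divided by the aperture
#'   scale radius `sqrt(ab)` (geometric mean of the aperture semi-axes).
#'   Default 0.077, the measured thickness/radius fraction for ammonoids.
#'
#' @return An object of class `shell_model`.
#' @examples
#' sh <- shell_model(D = 0.3, W = 2, S = 1)
#' spiral_radius(sh, 2 * pi)   # one whorl multiplies the radius by W
#' volume_ratio(sh)
#' @export
shell_model <- function(D, W, S = 1, thickness_fraction = 0.077) {
  stop_if_not_number(D, "D", 0, 1 - 1e-9)
  stop_if_not_number(W, "W", 1, Inf)
  stop_if_not_number(S, "S", 1e-9, Inf)
  stop_if_not_number(thickness_fraction, "thickness_fraction", 1e-12, Inf)
  structure(
    list(D = D, W = W, S = S, thickness_fraction = thickness_fraction),
    class = "shell_model"
  )
}

#' @export
print.shell_model <- function(x, ...) {
  ov <- whorl_overlap(x)
  cat(sprintf(
    "Raup shell: D = %.4g, W = %.4g, S = %.4g (thickness %.3g, %s)\n",
    x$D, x$W, x$S, x$thickness_fraction,
    if (ov$overlap) "overlapping whorls" else "gyroconic"
  ))
  invisible(x)
}

as_shell <- function(x) {
  if (inherits(x, "shell_model")) x else do.call(shell_model, as.list(x))
}

#' Spiral radius at a given angle
#'
#' Radius of the outer shell margin at rotation `theta`, in units of the
#' radius at `theta = 0`: `r(theta) = W^(theta / 2 pi)`.
#'
#' @param shell A [shell_model()].
#' @param theta Rotation angle in radians (vectorised).
#' @return Dimensionless radius (vector).
#' @export
spiral_radius <- function(shell, theta) {
  shell <- as_shell(shell)
  shell$W^(theta / (2 * pi))
}

#' Shell diameter in units of the current outer radius
#'
#' The diameter is measured across the coiling axis as
#' `r(theta) + r(theta - pi)`, i.e. the current outer radius plus the
#' radius half a whorl back, giving the factor `1 + W^(-1/2)`.
#'
#' @param shell A [shell_model()].
#' @return The dimensionless factor `diameter / outer radius`.
#' @export
diameter_factor <- function(shell) {
  shell <- as_shell(shell)
  1 + shell$W^(-0.5)
}

#' Whorl overlap test
#'
#' Successive whorls overlap when the previous whorl's outer radius `1/W`
#' (in units of the current outer radius) exceeds the new whorl's inner
#' radius `D`; otherwise the shell is gyroconic (open-coiled).
#'
#' @param shell A [shell_model()].
#' @return A list with `overlap` (logical) and `depth`
#'   (`max(0, 1/W - D)`, radial overlap in outer-radius units).
#' @export
whorl_overlap <- function(shell) {
  shell <- as_shell(shell)
  depth <- max(0, 1 / shell$W - shell$D)
  list(overlap = shell$W < 1 / shell$D, depth = depth)
}

# ---- cross-section geometry ------------------------------------------------
#
# All volumetric quantities are per-angle integrands of the self-similar
# spiral, evaluated in the cross-section plane at unit outer radius:
#   aperture ellipse E:   centre c = (1+D)/2, semi-axes a = (1-D)/2 (radial)
#                         and b = S*a (axial)
#   previous whorl:       E scaled by s = 1/W about the coiling axis.
# When whorls overlap (s > D) the new cavity is E minus the previous whorl's
# section, and the wall that must be built is the part of E's perimeter not
# shared with the previous whorl.  The boundary crossing has the closed form
#   x* = (1 + s) D / (1 + D),
# and deeper whorls never reach above the immediately previous one within
# the exposed band, so the single-previous-whorl formulas equal the full
# multi-whorl union exactly.

# signed area under the upper half of a circle radius a centred at c,
# integrated from x1 to x2 (both within [c - a, c + a])
half_disc_area <- function(x1, x2, c, a) {
  f <- function(x) {
    u <- pmin(pmax((x - c) / a, -1), 1)
    (u * sqrt(pmax(0, 1 - u^2)) + asin(u)) * a^2 / 2
  }
  f(x2) - f(x1)
}

# arc length of the aperture ellipse between parameter angles t1 < t2
# (x = c + a cos t, y = b sin t)
ellipse_arc <- function(t1, t2, a, b, n = 512L) {
  simpson(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2), t1, t2, n)
}

# Core cross-section quantities at unit outer radius.  Returns the cavity
# area added per turn, the exposed (newly built) perimeter, and the full
# ellipse area/perimeter.  `area_mode = "full"` keeps the whole aperture
# area even where it overlaps the previous whorl.
section_quantities <- function(D, W, S, area_mode = c("truncated", "full"),
                               n = 512L) {
  area_mode <- match.arg(area_mode)
  a <- (1 - D) / 2
  b <- S * a
  cc <- (1 + D) / 2
  s <- 1 / W
  total_per <- 2 * ellipse_arc(0, pi, a, b, n)
  full_area <- pi * a * b
  if (s <= D) {  # gyroconic: nothing shared
    return(list(area = full_area, exposed = total_per,
                total_perimeter = total_per, full_area = full_area,
                tstar = pi))
  }
  xstar <- (1 + s) * D / (1 + D)
  tstar <- acos(min(1, max(-1, (xstar - cc) / a)))
  exposed <- 2 * ellipse_arc(0, tstar, a, b, n)
  if (area_mode == "full") {
    area <- full_area
  } else {
    # cavity: E above the previous whorl on (x*, s], all of E on (s, 1]
    a_outer <- 2 * S * half_disc_area(max(xstar, s), 1, cc, a)
    a_band <- 0
    if (s > xstar) {
      a_band <- 2 * S * (half_disc_area(xstar, s, cc, a) -
                           half_disc_area(xstar, s, cc * s, a * s))
    }
    area <- a_band + a_outer
  }
  list(area = area, exposed = exposed, total_perimeter = total_per,
       full_area = full_area, tstar = tstar)
}

#' Whorl cross-section summary
#'
#' Aperture ellipse area and perimeter at unit outer radius, and the part
#' of the perimeter that must actually be built (not shared with the
#' previous whorl when whorls overlap).
#'
#' @param shell A [shell_model()].
#' @param n Number of quadrature subintervals for the arc length.
#' @return An object of class `whorl_section`: list with `area` (full
#'   aperture ellipse area), `total_perimeter`, `exposed_perimeter`.
#' @export
whorl_section <- function(shell, n = 2048L) {
  shell <- as_shell(shell)
  if (shell$D >= 1 - 1e-9) stop("degenerate aperture: D must be < 1")
  q <- section_quantities(shell$D, max(shell$W, 1 + 1e-6), shell$S, n = n)
  structure(
    list(area = q$full_area, total_perimeter = q$total_perimeter,
         exposed_perimeter = q$exposed),
    class = "whorl_section"
  )
}

#' @export
print.whorl_section <- function(x, ...) {
  cat(sprintf(
    "whorl section: area %.6g, perimeter %.6g (exposed %.6g)\n",
    x$area, x$total_perimeter, x$exposed_perimeter
  ))
  invisible(x)
}

#' Internal-volume to shell-material volume ratio
#'
#' The economy of shell construction: cavity volume gained per volume of
#' shell material laid down.  Because the shell is self-similar, the ratio
#' of the per-angle integrands (cavity area added, and built wall length
#' times thickness) is independent of position along the spiral and of
#' overall scale, so no integration along the spiral is needed.  The wall
#' thickness is `thickness_fraction * sqrt(ab)` (aperture scale), which
#' makes the ratio exactly constant over the whole gyroconic region at
#' fixed `S`.  Overlapping whorls save the shared wall but lose the
#' invaded cavity; the default `area_mode = "truncated"` accounts for
#' both, `"full"` counts the whole aperture area as cavity.
#'
#' @param shell A [shell_model()].
#' @param area_mode `"truncated"` (default) or `"full"`, see Details.
#' @param n Quadrature subintervals for arc lengths.
#' @return Dimensionless ratio internal volume / shell-material volume.
#' @export
volume_ratio <- function(shell, area_mode = c("truncated", "full"),
                         n = 512L) {
  shell <- as_shell(shell)
  area_mode <- match.arg(area_mode)
  if (shell$D >= 1 - 1e-9) stop("degenerate aperture: D must be < 1")
  W <- max(shell$W, 1 + 1e-6)  # W = 1 evaluated as a right-limit
  a <- (1 - shell$D) / 2
  b <- shell$S * a
  q <- section_quantities(shell$D, W, shell$S, area_mode, n)
  if (q$exposed <= 0) return(0)
  q$area / (shell$thickness_fraction * sqrt(a * b) * q$exposed)
}

#' Whole-shell surface-to-volume sphericity index
#'
#' Dimensionless globularity measure of the shell's overall form.  The
#' outer envelope is modelled as the spheroid spanned by the shell's two
#' calipers: equatorial semi-axis `R = (1 + W^(-1/2)) / 2` (half the shell
#' diameter across the coiling axis) and polar semi-axis `b = S (1 - D)/2`
#' (half the axial breadth at the final aperture).  The index is
#' `surface / volume^(2/3)` of that spheroid, so it is scale-free, reaches
#' its minimum `(36 pi)^(1/3)` exactly for a sphere (`b = R`), and grows
#' as the shell becomes discus-like (`b << R`, low `S`) or barrel-like
#' (`b >> R`).  Lower values therefore mean a more globular shell: its
#' height is most similar to its width and depth.
#'
#' @param shell A [shell_model()].
#' @return Dimensionless surface/volume^(2/3) index, `>= (36 pi)^(1/3)`.
#' @export
surface_to_volume <- function(shell) {
  shell <- as_shell(shell)
  if (shell$D >= 1 - 1e-9) stop("degenerate aperture: D must be < 1")
  R <- (1 + shell$W^(-0.5)) / 2            # equatorial semi-axis
  b <- shell$S * (1 - shell$D) / 2         # polar (axial) semi-axis
  if (abs(R - b) < 1e-9 * R) {
    area <- 4 * pi * R^2
  } else if (b < R) {                      # oblate (discus-like)
    e <- sqrt(1 - (b / R)^2)
    area <- 2 * pi * R^2 + pi * b^2 / e * log((1 + e) / (1 - e))
  } else {                                 # prolate (barrel-like)
    e <- sqrt(1 - (R / b)^2)
    area <- 2 * pi * R^2 + 2 * pi * R * b / e * asin(e)
  }
  vol <- 4 / 3 * pi * R^2 * b
  area / vol^(2 / 3)
}
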