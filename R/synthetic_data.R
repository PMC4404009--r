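# Synthetic genus tables with known ground truth: points in a specified
# polytope plus noise, era partitions, and diameters enriched near chosen
# vertices.  Every downstream module is testable against these datasets
# without the fossil compilations.

#' Reference archetype pyramid
#'
#' The five-vertex square pyramid used as the default ground-truth
#' polytope of the synthetic generator: vertex coordinates (in `D`, `S`,
#' `W`) of the five suggested ammonoid archetypes, with their putative
#' tasks as row names.
#'
#' @return A [polytope()] with 5 vertices in (D, S, W) space.
#' @export
reference_pyramid <- function() {
  v <- rbind(
    economy          = c(D = 0.65, S = 0.7, W = 1.3),
    hydrodynamics    = c(D = 0.04, S = 0.2, W = 1.55),
    growth           = c(D = 0.00, S = 0.3, W = 4.6),
    compact_economy  = c(D = 0.50, S = 3.2, W = 1.6),
    compact_hydro    = c(D = 0.01, S = 1.8, W = 1.07)
  )
  polytope(v, "general")
}

#' Synthetic-dataset configuration
#'
#' Defaults define the study conditions the generator emulates: the
#' reference 5-vertex pyramid, an era-partitioned genus table with
#' 113/386/392 genera in the three inter-extinction intervals, Dirichlet
#' vertex weights with concentration 0.8 (mass towards the polytope
#' boundary, giving a filled pyramid with visible corners), small
#' isotropic trait noise, and a multiplicative-lognormal diameter model
#' whose per-vertex effects make genera near the two depressed
#' (compact) archetypes small and genera near the drag and growth
#' archetypes large.
#'
#' @param polytope Ground-truth [polytope()] (default [reference_pyramid()]).
#' @param era_counts Named integer vector of genera per era.
#' @param concentration Dirichlet concentration for vertex weights.
#' @param noise_sd Isotropic Gaussian trait noise (trait units).
#' @param diameter_base Baseline shell diameter in cm.
#' @param diameter_effects Per-vertex multiplicative diameter effects
#'   (length = number of vertices; values < 1 shrink diameters near that
#'   vertex).  `NULL` disables diameter generation.
#' @param diameter_sdlog Lognormal noise of the diameter model.
#' @param seed Integer seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(polytope = reference_pyramid(),
                         era_counts = c("FF-DM" = 113L, "DM-PT" = 386L,
                                        "post-PT" = 392L),
                         concentration = 0.8,
                         noise_sd = 0.02,
                         diameter_base = 6,
                         diameter_effects = c(1, 1.8, 1.6, 0.4, 0.5),
                         diameter_sdlog = 0.35,
                         seed = 1L) {
  stopifnot(inherits(polytope, "polytope"), all(era_counts > 0),
            concentration > 0, noise_sd >= 0)
  if (!is.null(diameter_effects) &&
      length(diameter_effects) != polytope$k) {
    stop("diameter_effects must have one entry per polytope vertex")
  }
  structure(list(polytope = polytope, era_counts = era_counts,
                 concentration = concentration, noise_sd = noise_sd,
                 diameter_base = diameter_base,
                 diameter_effects = diameter_effects,
                 diameter_sdlog = diameter_sdlog, seed = seed),
            class = "synth_config")
}

# Dirichlet(alpha, ..., alpha) rows via gamma variates
rdirichlet <- function(n, k, alpha) {
  g <- matrix(stats::rgamma(n * k, shape = alpha), n, k)
  g / rowSums(g)
}

#' Sample points inside a polytope
#'
#' Each point is a Dirichlet-weighted convex combination of the polytope
#' vertices plus isotropic Gaussian noise.  The true weights are
#' returned, enabling parameter-recovery tests.
#'
#' @param polytope A [polytope()].
#' @param n Number of points.
#' @param concentration Dirichlet concentration (small values concentrate
#'   mass at the vertices).
#' @param noise_sd Isotropic Gaussian noise sd (0 keeps all points inside
#'   the polytope).
#' @param seed Integer seed.
#' @return List with `points` (n x d) and `weights` (n x k).
#' @export
sample_polytope <- function(polytope, n, concentration = 0.8,
                            noise_sd = 0.02, seed = 1L) {
  stopifnot(inherits(polytope, "polytope"), n >= 1)
  with_seed(seed, {
    w <- rdirichlet(n, polytope$k, concentration)
    pts <- w %*% polytope$vertices
    if (noise_sd > 0) {
      pts <- pts + matrix(stats::rnorm(n * polytope$d, sd = noise_sd),
                          n, polytope$d)
    }
    colnames(pts) <- colnames(polytope$vertices)
    list(points = pts, weights = w)
  })
}

#' Generate a synthetic genus table
#'
#' Draws each era's genera from the configured polytope, assigns genus
#' ids, and (when diameter effects are configured) a shell diameter per
#' genus: `base * prod(effect_v ^ weight_v) * lognormal noise`, so genera
#' near vertices with effect < 1 are systematically small.  Trait values
#' are clamped to their physical ranges (`0 <= D < 1`, `S > 0`,
#' `W >= 1`).  Fully reproducible from the seed.
#'
#' @param config A [synth_config()].
#' @return A `morpho_dataset` data frame with columns `genus`, `era`,
#'   `D`, `S`, `W` and optionally `diameter_cm`; the true vertex weights
#'   are attached as attribute `weights`.
#' @export
make_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  eras <- names(config$era_counts)
  rows <- list()
  weights <- list()
  for (i in seq_along(eras)) {
    n <- config$era_counts[[i]]
    sp <- sample_polytope(config$polytope, n,
                          concentration = config$concentration,
                          noise_sd = config$noise_sd,
                          seed = config$seed + i)
    pts <- as.data.frame(sp$points)
    names(pts) <- colnames(config$polytope$vertices) %||% c("D", "S", "W")
    pts$era <- eras[i]
    rows[[i]] <- pts
    weights[[i]] <- sp$weights
  }
  out <- do.call(rbind, rows)
  w <- do.call(rbind, weights)
  # clamp traits to their physical ranges
  out$D <- pmin(pmax(out$D, 0), 1 - 1e-6)
  out$S <- pmax(out$S, 1e-3)
  out$W <- pmax(out$W, 1)
  out$genus <- sprintf("genus_%04d", seq_len(nrow(out)))
  if (!is.null(config$diameter_effects)) {
    log_diam <- log(config$diameter_base) +
      w %*% log(config$diameter_effects)
    noise <- with_seed(config$seed + length(eras) + 1L, {
      stats::rnorm(nrow(out), sd = config$diameter_sdlog)
    })
    out$diameter_cm <- exp(as.numeric(log_diam) + noise)
  }
  out <- out[, c("genus", "era", "D", "S", "W",
                 intersect("diameter_cm", names(out)))]
  rownames(out) <- NULL
  attr(out, "weights") <- w
  class(out) <- c("morpho_dataset", "data.frame")
  out
}
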