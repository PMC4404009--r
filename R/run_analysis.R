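#' Full morphospace analysis pipeline
#'
#' Orchestrates the whole workflow on one genus table: per-era triangle
#' fits with polygonality tests and pairwise triangle similarity in the
#' W-D plane; the three performance surfaces and their Pareto front; the
#' PCHA rms-vs-k profile and the 5-vertex pyramid fit in (D, S, W);
#' diameter enrichment at each fitted vertex (when diameters are
#' present); and the Westermann projection of the fitted vertices with
#' sensitivity ellipses.  Stages that do not apply to the input (no `S`
#' column, no diameters) are skipped with a notice; stage failures are
#' isolated and recorded.  A master seed fans out to recorded per-stage
#' seeds, so the whole bundle is reproducible.
#'
#' @param dataset A `morpho_dataset` (see [read_morpho_dataset()] /
#'   [make_dataset()]).
#' @param seed Master seed.
#' @param n_null Replicates for the randomization tests.
#' @param k_range Archetype counts for the rms profile.
#' @param k_pyramid Vertex count of the final polytope fit.
#' @param restarts Restart budget for the polytope fits.
#' @param grid_n Grid points per axis for the Pareto front stage.
#' @return An object of class `analysis_bundle`: named list of stage
#'   results with per-stage seeds, plus `skipped` / `failed` notes.
#' @export
run_full_analysis <- function(dataset, seed = 1L, n_null = 200L,
                              k_range = 2:8, k_pyramid = 5L,
                              restarts = 5L, grid_n = 41L) {
  stopifnot(is.data.frame(dataset))
  has_S <- "S" %in% names(dataset)
  has_diam <- "diameter_cm" %in% names(dataset) &&
    any(is.finite(dataset$diameter_cm))
  stage_seeds <- seed + seq_len(5L) * 1000L
  bundle <- list(seed = seed, stage_seeds = stage_seeds,
                 skipped = character(0), failed = character(0))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      bundle$failed <<- c(bundle$failed, sprintf("%s: %s", name, conditionMessage(e)))
      NULL
    })
  }

  # stage 1: per-era triangles in the W-D plane
  bundle$triangles <- run_stage("triangles", {
    eras <- if ("era" %in% names(dataset)) unique(dataset$era) else "all"
    fits <- list(); tests <- list()
    for (e in eras) {
      sub <- if ("era" %in% names(dataset)) dataset[dataset$era == e, ] else dataset
      pts <- as.matrix(sub[, c("D", "W")])
      tests[[e]] <- polygonality_test(pts, n_null = n_null,
                                      seed = stage_seeds[1L],
                                      restarts = restarts)
      fits[[e]] <- tests[[e]]$fit
    }
    sims <- list()
    if (length(eras) > 1L) {
      for (i in seq_len(length(eras) - 1L)) for (j in seq(i + 1L, length(eras))) {
        key <- paste(eras[i], eras[j], sep = " vs ")
        ratio <- triangle_similarity(fits[[eras[i]]]$polytope,
                                     fits[[eras[j]]]$polytope)
        sims[[key]] <- similarity_test(ratio, n_null = n_null,
                                       seed = stage_seeds[1L] + i * 100L + j)
      }
    }
    list(fits = fits, polygonality = tests, similarity = sims)
  })

  # stage 2: performance surfaces and Pareto front at S = 1
  bundle$pareto <- run_stage("pareto", {
    surfaces <- list(economy_performance(), growth_performance(),
                     drag_performance())
    grid <- grid_spec(D = c(0, 0.95, grid_n), W = c(1 + 1e-3, 5, grid_n), S = 1)
    front_on_grid(surfaces, grid)
  })

  # stage 3: rms profile + pyramid fit in (D, S, W)
  if (has_S) {
    bundle$pyramid <- run_stage("pyramid", {
      X <- as.matrix(dataset[, c("D", "S", "W")])
      prof <- rms_profile(X, k_range = k_range, restarts = restarts,
                          seed = stage_seeds[3L])
      fit <- fit_pcha(X, k = k_pyramid, restarts = restarts,
                      seed = stage_seeds[3L])
      list(profile = prof, fit = fit)
    })
  } else {
    bundle$skipped <- c(bundle$skipped, "pyramid: no S column (2-trait dataset)")
  }

  # stage 4: diameter enrichment at each fitted vertex
  if (has_S && has_diam && !is.null(bundle$pyramid)) {
    bundle$enrichment <- run_stage("enrichment", {
      X <- as.matrix(dataset[, c("D", "S", "W")])
      keep <- is.finite(dataset$diameter_cm)
      V <- bundle$pyramid$fit$polytope$vertices
      lapply(seq_len(nrow(V)), function(i) {
        enrichment_by_distance(X[keep, , drop = FALSE],
                               dataset$diameter_cm[keep], V[i, ],
                               n_perm = n_null, seed = stage_seeds[4L] + i)
      })
    })
  } else if (!has_diam) {
    bundle$skipped <- c(bundle$skipped, "enrichment: no diameter column")
  }

  # stage 5: Westermann projection of the fitted vertices
  if (has_S && !is.null(bundle$pyramid)) {
    bundle$westermann <- run_stage("westermann", {
      V <- bundle$pyramid$fit$polytope$vertices
      lapply(seq_len(nrow(V)), function(i) {
        pt <- c(D = V[i, "D"], S = V[i, "S"], W = V[i, "W"])
        list(
          point = tryCatch(to_westermann(pt), error = function(e) NULL),
          sensitivity = sensitivity_region(pt, seed = stage_seeds[5L] + i)
        )
      })
    })
  }

  class(bundle) <- "analysis_bundle"
  bundle
}

#' @export
print.analysis_bundle <- function(x, ...) {
  stages <- setdiff(names(x), c("seed", "stage_seeds", "skipped", "failed"))
  cat(sprintf("analysis bundle (seed %d): stages %s\n", x$seed,
              paste(stages, collapse = ", ")))
  if (length(x$skipped)) cat("skipped:", paste(x$skipped, collapse = "; "), "\n")
  if (length(x$failed)) cat("FAILED:", paste(x$failed, collapse = "; "), "\n")
  invisible(x)
}
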