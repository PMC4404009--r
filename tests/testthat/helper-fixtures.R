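# Shared fixtures and independent oracles.

# classic W-D triangle used as a planted ground truth
wd_triangle <- function() rbind(c(0, 1), c(0.7, 1.35), c(0, 4.6))

# independent O(n^2) non-domination oracle: explicit loop per point,
# direct definition, no sorting shortcuts
oracle_non_dominated <- function(perf) {
  n <- nrow(perf)
  keep <- logical(n)
  for (i in seq_len(n)) {
    dominated <- FALSE
    for (j in seq_len(n)) {
      if (j == i) next
      if (all(perf[j, ] >= perf[i, ]) && any(perf[j, ] > perf[i, ])) {
        dominated <- TRUE
        break
      }
    }
    keep[i] <- !dominated
  }
  keep
}

# Monte-Carlo rejection oracle for intersection/union of two triangles
mc_similarity <- function(A, B, n = 4e6, seed = 99) {
  pts <- rbind(A, B)
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  set.seed(seed)
  x <- runif(n, lo[1], hi[1]); y <- runif(n, lo[2], hi[2])
  in_tri <- function(V) {
    s1 <- (V[2,1]-V[1,1])*(y-V[1,2]) - (V[2,2]-V[1,2])*(x-V[1,1])
    s2 <- (V[3,1]-V[2,1])*(y-V[2,2]) - (V[3,2]-V[2,2])*(x-V[2,1])
    s3 <- (V[1,1]-V[3,1])*(y-V[3,2]) - (V[1,2]-V[3,2])*(x-V[3,1])
    (s1 >= 0 & s2 >= 0 & s3 >= 0) | (s1 <= 0 & s2 <= 0 & s3 <= 0)
  }
  ia <- in_tri(A); ib <- in_tri(B)
  sum(ia & ib) / sum(ia | ib)
}

# polyline arc-length oracle for the aperture ellipse
polyline_perimeter <- function(a, b, n = 2e5) {
  t <- seq(0, 2 * pi, length.out = n)
  sum(sqrt(diff(a * cos(t))^2 + diff(b * sin(t))^2))
}

# match fitted vertices to truth rows by nearest neighbour
match_vertices <- function(truth, fitted) {
  d <- as.matrix(stats::dist(rbind(truth, fitted)))
  d <- d[seq_len(nrow(truth)), nrow(truth) + seq_len(nrow(fitted)), drop = FALSE]
  apply(d, 1, which.min)
}

# plane-fit rms residual of a set of points (smallest principal direction)
plane_residual <- function(P) {
  sv <- svd(scale(P, scale = FALSE))$d
  sv[length(sv)] / sqrt(nrow(P))
}
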