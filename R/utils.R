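# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards (or removing it if there was none).
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Composite Simpson quadrature of f on [lo, hi] with n subintervals (n even).
simpson <- function(f, lo, hi, n = 512L) {
  if (hi <= lo) return(0)
  n <- as.integer(n)
  if (n %% 2L == 1L) n <- n + 1L
  x <- seq(lo, hi, length.out = n + 1L)
  w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
  sum(w * f(x)) * (hi - lo) / (3 * n)
}

# Locate all roots of f on [lo, hi] by sign-scanning n points then uniroot.
find_roots <- function(f, lo, hi, n = 256L, tol = 1e-12) {
  x <- seq(lo, hi, length.out = n)
  y <- f(x)
  roots <- numeric(0)
  sgn <- sign(y)
  for (i in seq_len(n - 1L)) {
    if (is.na(sgn[i]) || is.na(sgn[i + 1L])) next
    if (sgn[i] == 0) roots <- c(roots, x[i])
    if (sgn[i] * sgn[i + 1L] < 0) {
      r <- stats::uniroot(f, c(x[i], x[i + 1L]), tol = tol)
      roots <- c(roots, r$root)
    }
  }
  if (length(y) && sgn[n] == 0) roots <- c(roots, x[n])
  sort(unique(roots))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a single number in [%g, %g]", name, lo, hi),
         call. = FALSE)
  }
  invisible(x)
}
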