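# Internal numerical helpers shared across modules.

# log(phi(u)/Phi(u)): stable for u << 0 because pnorm(log.p = TRUE) uses an
# asymptotic (Mills-ratio) expansion in the lower tail.
log_mills <- function(u) dnorm(u, log = TRUE) - pnorm(u, log.p = TRUE)

# phi(u)/Phi(u), the inverse Mills ratio.
zeta_ratio <- function(u) exp(log_mills(u))

# Trapezoid integral of y over x (x ordered).
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Cumulative trapezoid integral, anchored at 0 for the first abscissa.
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2))
}

# Composite Simpson integral of a function between consecutive grid points,
# cumulative along the grid; used where trapezoid bias would contaminate
# exponent-recovery checks. f must be vectorized.
cumsimpson_fun <- function(f, x) {
  n <- length(x)
  mid <- (x[-1] + x[-n]) / 2
  fx <- f(x)
  fm <- f(mid)
  h <- x[-1] - x[-n]
  seg <- h / 6 * (fx[-n] + 4 * fm + fx[-1])
  c(0, cumsum(seg))
}

# Central-difference gradient.
num_grad <- function(f, x, h = NULL) {
  d <- length(x)
  if (is.null(h)) h <- pmax(abs(x), 1) * .Machine$double.eps^(1 / 3)
  g <- numeric(d)
  for (j in seq_len(d)) {
    e <- numeric(d); e[j] <- h[j]
    g[j] <- (f(x + e) - f(x - e)) / (2 * h[j])
  }
  g
}

# Central-difference Hessian (symmetrized).
num_hess <- function(f, x, h = NULL) {
  d <- length(x)
  if (is.null(h)) h <- pmax(abs(x), 1) * .Machine$double.eps^(1 / 4)
  H <- matrix(0, d, d)
  f0 <- f(x)
  for (j in seq_len(d)) {
    ej <- numeric(d); ej[j] <- h[j]
    H[j, j] <- (f(x + ej) - 2 * f0 + f(x - ej)) / h[j]^2
    if (j < d) for (k in (j + 1):d) {
      ek <- numeric(d); ek[k] <- h[k]
      H[j, k] <- H[k, j] <-
        (f(x + ej + ek) - f(x + ej - ek) - f(x - ej + ek) + f(x - ej - ek)) /
        (4 * h[j] * h[k])
    }
  }
  H
}

# Third k-statistic: unbiased estimator of the third cumulant.
kstat3 <- function(x) {
  n <- length(x)
  if (n < 3) stop("need at least 3 values for the third k-statistic")
  m3 <- mean((x - mean(x))^3)
  n^2 * m3 / ((n - 1) * (n - 2))
}

# Jackknife standard error of a statistic computed on a vector.
jackknife_se <- function(x, stat) {
  n <- length(x)
  reps <- vapply(seq_len(n), function(i) stat(x[-i]), numeric(1))
  sqrt((n - 1) * mean((reps - mean(reps))^2))
}

# Cubic-spline interpolator of (x, y) returning a function, with constant
# extrapolation outside the node range; used for caching expensive
# correction terms along a psi grid (linear extrapolation of an O(1)
# correction would fabricate growth far from the data).
interp_fun <- function(x, y) {
  sf <- stats::splinefun(x, y, method = "natural")
  lo <- min(x); hi <- max(x)
  function(p) sf(pmin(pmax(p, lo), hi))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
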