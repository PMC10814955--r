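#' Score cumulants at a parameter point
#'
#' First three cumulants of the score (scalar models).  For a genuine score
#' kappa1 = 0 identically; kappa2 is the expected information; kappa3 the
#' third cumulant, obtained in closed form for canonical exponential
#' families, by quadrature for the skew-normal shape, or by Monte Carlo for
#' any simulable family.
#'
#' @param model scalar `parametric_model`.
#' @param theta evaluation point.
#' @param n number of observations the cumulants refer to.
#' @param method "auto" (closed form or quadrature if the model provides a
#'   `cumulant3` evaluator, else Monte Carlo), "closed-form" or
#'   "monte-carlo".
#' @param replicates,seed Monte Carlo settings.
#' @return object of class `score_cumulants` with fields `kappa1`, `kappa2`,
#'   `kappa3`, `method`, and (for Monte Carlo) `mc_se`.
#' @export
cumulants_scalar <- function(model, theta, n, method = "auto",
                             replicates = 20000, seed = NULL) {
  if (model$npar != 1) stop("cumulants_scalar requires a scalar model")
  use_closed <- method %in% c("auto", "closed-form") && !is.null(model$cumulant3)
  if (method == "closed-form" && is.null(model$cumulant3))
    stop("model '", model$family, "' has no closed-form third cumulant")
  if (use_closed) {
    out <- list(kappa1 = 0, kappa2 = expected_info(model, theta, n),
                kappa3 = model$cumulant3(theta, n),
                method = "closed-form", mc_se = NULL)
  } else {
    if (is.null(model$simulate))
      stop("Monte Carlo cumulants need a simulable model")
    if (!is.null(seed)) set.seed(seed)
    u <- vapply(seq_len(replicates), function(r) {
      y <- model$simulate(theta, n)
      score(model, theta, y)
    }, numeric(1))
    out <- list(kappa1 = 0, kappa2 = stats::var(u), kappa3 = kstat3(u),
                method = "monte-carlo",
                mc_se = c(kappa1 = stats::sd(u) / sqrt(replicates),
                          kappa2 = stats::sd((u - mean(u))^2) / sqrt(replicates),
                          kappa3 = sqrt(6 / replicates) * stats::var(u)^1.5))
  }
  if (out$kappa2 <= 0) stop("nonpositive score variance")
  structure(out, class = "score_cumulants")
}

#' Median correction term for a scalar score
#'
#' The O(1) additive adjustment m = kappa3 / (6 kappa2) whose root-shifted
#' score equation produces a median-unbiased (to third order) and
#' reparameterization-equivariant estimator.  For a canonical exponential
#' family this is K'''/(6 K''), the derivative of log i(theta)^{1/6}, so the
#' implied matching prior is i(theta)^{1/6}.
#'
#' @param cum a `score_cumulants` object (kappa1 is ignored: zero for a
#'   genuine score).
#' @param sign_convention "as-examples" (default; certified by the
#'   median-unbiasedness of the resulting estimator) or "as-displayed" for
#'   the opposite sign, retained for auditability.
#' @return scalar correction m.
#' @export
median_correction_scalar <- function(cum, sign_convention = c("as-examples", "as-displayed")) {
  sign_convention <- match.arg(sign_convention)
  if (cum$kappa2 <= 0) stop("invalid cumulants: kappa2 <= 0")
  m <- cum$kappa3 / (6 * cum$kappa2)
  if (sign_convention == "as-displayed") m <- -m
  m
}

#' Firth (mean bias reducing) correction term for a scalar score
#'
#' m_F = (E(l'^3) + E(l'' l')) / (2 i(theta)); in canonical exponential
#' families this is the derivative of log i(theta)^{1/2}, i.e. the Jeffreys
#' prior penalty, and the implied prior is the predictive matching prior.
#'
#' @inheritParams cumulants_scalar
#' @param sign_convention see [median_correction_scalar()].
#' @export
firth_correction_scalar <- function(model, theta, n,
                                    sign_convention = c("as-examples", "as-displayed")) {
  sign_convention <- match.arg(sign_convention)
  if (is.null(model$cumulant3) || is.null(model$mixed_moment))
    stop("model '", model$family,
         "' does not expose E(l'^3) and E(l'' l') needed for the Firth term")
  i <- expected_info(model, theta, n)
  m <- (model$cumulant3(theta, n) + model$mixed_moment(theta, n)) / (2 * i)
  if (sign_convention == "as-displayed") m <- -m
  m
}

correction_fun_scalar <- function(model, kind, n) {
  switch(kind,
    none = , flat = function(theta) 0,
    median = function(theta)
      median_correction_scalar(cumulants_scalar(model, theta, n)),
    firth = , predictive = function(theta)
      firth_correction_scalar(model, theta, n),
    jeffreys = function(theta) {
      # derivative of (1/2) log i(theta), by central differences on log i
      h <- max(abs(theta), 1) * 1e-5
      (log(expected_info(model, theta + h, n)) -
         log(expected_info(model, theta - h, n))) / (4 * h)
    },
    stop("unknown correction kind: ", kind))
}

#' Matching log-prior on a grid (scalar models)
#'
#' Integrates the chosen score correction along the grid (composite Simpson
#' between grid points, anchored at the grid midpoint, additive constant
#' immaterial) to obtain the log prior: `kind = "median"` gives the median
#' matching prior, `kind = "firth"`/"predictive" the predictive matching
#' prior, `kind = "jeffreys"` returns (1/2) log i(theta) directly, and
#' `kind = "none"`/"flat" a zero vector.
#'
#' @param model scalar `parametric_model`.
#' @param kind one of "median", "firth", "predictive", "jeffreys", "none",
#'   "flat".
#' @param grid ordered abscissae inside the support.
#' @param n number of observations (the exponent recovered is free of n:
#'   corrections are ratios of cumulants).
#' @return numeric vector of log-prior values on `grid`.
#' @export
matching_logprior_scalar <- function(model, kind, grid, n = 1) {
  if (is.unsorted(grid)) stop("grid must be increasing")
  if (any(grid <= model$support[1, 1]) || any(grid >= model$support[2, 1]))
    stop("grid outside the model support")
  if (kind %in% c("none", "flat")) return(numeric(length(grid)))
  if (kind == "jeffreys") {
    v <- vapply(grid, function(t) 0.5 * log(expected_info(model, t, n)),
                numeric(1))
    return(v - v[ceiling(length(v) / 2)])
  }
  mfun <- correction_fun_scalar(model, kind, n)
  mv <- Vectorize(mfun)
  lp <- cumsimpson_fun(mv, grid)
  lp - lp[ceiling(length(lp) / 2)]
}

# Expand a bracket around `center` until fn changes sign; errors with the
# direction of divergence if none is found.
expand_bracket <- function(fn, center, half = 1, lower = -Inf, upper = Inf,
                           max_expand = 60) {
  for (k in seq_len(max_expand)) {
    lo <- if (is.finite(lower)) max(center - half, lower + (center - lower) / 2^k)
          else center - half
    hi <- if (is.finite(upper)) min(center + half, upper - (upper - center) / 2^k)
          else center + half
    flo <- fn(lo); fhi <- fn(hi)
    if (is.finite(flo) && is.finite(fhi) && flo * fhi <= 0)
      return(c(lo, hi))
    half <- half * 2
  }
  dir <- if (is.finite(fhi) && fhi > 0) +1 else -1
  stop(structure(class = c("evmatch_divergence", "error", "condition"),
                 list(message = paste0("no sign change in expanding bracket; ",
                                       "estimating equation appears monotone (direction ",
                                       if (dir > 0) "+Inf" else "-Inf", ")"),
                      call = sys.call(-1), direction = dir)))
}

#' Solve a modified score equation (scalar model)
#'
#' Finds the root of t(theta) = l'(theta) + m(theta) by bracket expansion
#' around a crude location followed by Brent refinement.  With
#' `kind = "median"` the root is the median-bias-reduced estimator; with
#' `kind = "firth"` the mean-bias-reduced (Jeffreys-penalized, in canonical
#' families) estimator; `kind = "none"` recovers the MLE.
#'
#' @param model scalar `parametric_model`.
#' @param data observations.
#' @param kind correction kind (see [matching_logprior_scalar()]).
#' @param interval optional starting bracket.
#' @return object of class `bias_reduced_estimate`: `estimate`, `se` (from
#'   expected information at the root), `kind`, `converged`, `t_at_root`.
#' @export
solve_modified_score <- function(model, data, kind = "median",
                                 interval = NULL) {
  n <- if (is.matrix(data)) nrow(data) else length(data)
  mfun <- correction_fun_scalar(model, kind, n)
  tfun <- function(th) score(model, th, data) + mfun(th)
  lo <- model$support[1, 1]; hi <- model$support[2, 1]
  if (is.null(interval)) {
    center <- if (is.finite(lo) && lo == 0) max(mean(abs(as.numeric(data))), 1e-3) else 0
    interval <- expand_bracket(tfun, center, half = max(abs(center), 1) / 2,
                               lower = lo, upper = hi)
  }
  root <- stats::uniroot(tfun, interval, tol = 1e-12)
  est <- root$root
  se <- 1 / sqrt(expected_info(model, est, n))
  structure(list(estimate = est, se = se, kind = kind,
                 converged = abs(tfun(est)) < 1e-6 * max(1, abs(score(model, est, data))) + 1e-6,
                 t_at_root = tfun(est), iterations = root$iter),
            class = "bias_reduced_estimate")
}

#' @export
print.bias_reduced_estimate <- function(x, ...) {
  cat(sprintf("<bias_reduced_estimate> kind=%s  estimate=%.6g  se=%.4g\n",
              x$kind, x$estimate, x$se))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Profile likelihood machinery.

full_theta <- function(model, psi, lambda) {
  th <- numeric(model$npar)
  th[model$interest] <- psi
  th[-model$interest] <- lambda
  th
}

constrained_mle <- function(model, psi, data, start = NULL) {
  if (!is.null(model$constrained_mle))
    return(model$constrained_mle(psi, data, start))
  j <- model$interest
  d <- model$npar
  if (d == 1) return(numeric(0))
  lo <- model$support[1, -j]; hi <- model$support[2, -j]
  obj <- function(lam) -model$loglik(full_theta(model, psi, lam), data)
  if (is.null(start)) start <- pmin(pmax(rep(0.5, d - 1), lo + 0.1), hi - 0.1)
  fit <- stats::nlminb(start, obj, lower = lo + 1e-10, upper = hi - 1e-10)
  if (fit$convergence != 0 && fit$objective > obj(start))
    stop("inner nuisance optimization failed at psi = ", psi)
  fit$par
}

#' Profile log-likelihood
#'
#' l_p(psi) = l(psi, lambda_hat_psi) with the nuisance maximized out;
#' closed-form inner maximizers are used where the family provides them
#' (normal variance, GLS step of the bivariate model, offset logistic
#' refits), general quasi-Newton optimization otherwise.
#'
#' @inheritParams loglik
#' @param psi value of the interest parameter.
#' @param start warm start for the nuisance optimizer.
#' @return list with `value` and `lambda_hat`.
#' @export
profile_loglik <- function(model, psi, data, start = NULL) {
  if (model$npar == 1)
    return(list(value = loglik(model, psi, data), lambda_hat = numeric(0)))
  lam <- constrained_mle(model, psi, data, start)
  list(value = model$loglik(full_theta(model, psi, lam), data),
       lambda_hat = lam)
}

#' Profile score
#'
#' By the envelope identity this equals the interest component of the full
#' score evaluated at (psi, lambda_hat_psi).
#'
#' @inheritParams profile_loglik
#' @export
profile_score <- function(model, psi, data, start = NULL) {
  if (model$npar == 1) return(unname(score(model, psi, data)))
  lam <- constrained_mle(model, psi, data, start)
  unname(score(model, full_theta(model, psi, lam), data)[model$interest])
}

# Observed profile information -d^2 l_p / d psi^2 by central differences.
profile_obs_info <- function(model, psi, data, h = NULL) {
  if (is.null(h)) h <- max(abs(psi), 1) * 1e-4
  # differentiate the profile score (already the first derivative of l_p)
  (profile_score(model, psi - h, data) - profile_score(model, psi + h, data)) /
    (2 * h)
}

# Maximum likelihood for the full parameter; scalar models use the modified
# score solver with a zero correction, vector models quasi-Newton from a
# cheap start.
fit_mle <- function(model, data, start = NULL) {
  if (model$npar == 1) {
    est <- solve_modified_score(model, data, kind = "none")
    return(list(theta = est$estimate, psi = est$estimate,
                lambda = numeric(0), value = loglik(model, est$estimate, data)))
  }
  j <- model$interest
  lo <- model$support[1, ]; hi <- model$support[2, ]
  if (is.null(start)) {
    start <- rep(0, model$npar)
    start[lo == 0 & !is.finite(hi)] <- 1
    start[is.finite(lo) & is.finite(hi)] <- (lo + hi)[is.finite(lo) & is.finite(hi)] / 2
    if (model$family == "logistic-regression")
      start <- rep(0, model$npar)
  }
  fit <- stats::nlminb(start, function(th) -model$loglik(th, data),
                       lower = lo + 1e-9, upper = hi - 1e-9)
  th <- fit$par
  list(theta = th, psi = th[j], lambda = th[-j], value = -fit$objective)
}

#' Cumulants of the profile score at (psi, lambda_hat_psi)
#'
#' Default method is a parametric bootstrap: datasets are simulated from
#' f(y; psi, lambda_hat_psi), the profile score at psi is recomputed on each
#' (with its own inner nuisance optimization), and the sample mean, variance
#' and third k-statistic are returned with jackknife-free standard errors.
#' For scalar models this reduces to [cumulants_scalar()].
#'
#' @inheritParams profile_loglik
#' @param replicates bootstrap replicates.
#' @param seed integer seed for the bootstrap.
#' @param method "auto" (closed form for scalar canonical families, else
#'   Monte Carlo) or "monte-carlo".
#' @return `score_cumulants` with kappa1 generally nonzero (the profile
#'   score is biased).
#' @export
profile_cumulants <- function(model, psi, data, replicates = 2000,
                              seed = NULL, method = "auto") {
  n <- if (is.matrix(data)) nrow(data) else length(data)
  if (model$npar == 1 && method == "auto" && !is.null(model$cumulant3))
    return(cumulants_scalar(model, psi, n))
  if (is.null(model$simulate))
    stop("profile cumulants need a simulable model")
  lam <- constrained_mle(model, psi, data)
  th <- full_theta(model, psi, lam)
  if (!is.null(seed)) set.seed(seed)
  fails <- 0L
  u <- vapply(seq_len(replicates), function(r) {
    yb <- model$simulate(th, n)
    tryCatch(profile_score(model, psi, yb, start = lam),
             error = function(e) NA_real_)
  }, numeric(1))
  fails <- sum(!is.finite(u))
  if (fails > 0.01 * replicates)
    stop("more than 1% of inner optimizations failed while estimating ",
         "profile cumulants (", fails, "/", replicates, ")")
  u <- u[is.finite(u)]
  R <- length(u)
  # saturation guard: when most simulated datasets are themselves separated
  # or otherwise boundary-degenerate, the profile score distribution
  # becomes a point mass plus rare huge outliers and its k-statistics are
  # meaningless; a blown-up sd/MAD ratio is the signature
  mu <- stats::mad(u)
  if (mu == 0 || stats::sd(u) / mu > 10)
    stop("degenerate simulated profile-score distribution at psi = ", psi,
         " (sd/MAD = ", signif(stats::sd(u) / max(mu, 1e-300), 3), ")")
  out <- list(kappa1 = mean(u), kappa2 = stats::var(u), kappa3 = kstat3(u),
              method = "monte-carlo", replicates = R,
              mc_se = c(kappa1 = stats::sd(u) / sqrt(R),
                        kappa2 = stats::sd((u - mean(u))^2) / sqrt(R),
                        kappa3 = sqrt(6 / R) * stats::var(u)^1.5))
  if (out$kappa2 <= 0) stop("nonpositive profile score variance")
  structure(out, class = "score_cumulants")
}

#' Median correction for a profile score
#'
#' m = -kappa1 + kappa3 / (6 kappa2): the profile score is first recentred
#' by its mean, then shifted by the skewness term, reducing to the scalar
#' correction when kappa1 = 0.
#'
#' @param cum `score_cumulants` from [profile_cumulants()].
#' @export
median_correction_profile <- function(cum) {
  if (cum$kappa2 <= 0) stop("invalid cumulants: kappa2 <= 0")
  -cum$kappa1 + cum$kappa3 / (6 * cum$kappa2)
}

# Correction evaluator for the interest parameter of a (possibly nuisance)
# model, cached on a psi grid and cubically interpolated.  For scalar models
# with closed-form cumulants the exact pointwise evaluator is returned.
profile_correction_fun <- function(model, data, kind, replicates = 2000,
                                   seed = NULL, grid = NULL) {
  n <- if (is.matrix(data)) nrow(data) else length(data)
  if (kind %in% c("none", "flat")) return(function(psi) 0)
  if (model$npar == 1) return(correction_fun_scalar(model, kind, n))
  if (kind == "median") {
    if (is.null(grid)) stop("a psi grid is required to cache the profile correction")
    eval_nodes <- function(nodes, off = 0) vapply(seq_along(nodes), function(i) {
      cum <- tryCatch(
        profile_cumulants(model, nodes[i], data, replicates = replicates,
                          seed = if (is.null(seed)) NULL else seed + off + i),
        error = function(e) NULL)
      if (is.null(cum)) NA_real_ else median_correction_profile(cum)
    }, numeric(1))
    vals <- eval_nodes(grid)
    ok <- is.finite(vals)
    # extreme grid nodes can saturate the simulated datasets (e.g. fitted
    # probabilities at 0/1); the correction is interpolated from the rest,
    # densifying inside the healthy window when few nodes survive
    if (sum(ok) >= 2 && sum(ok) < 9) {
      extra <- seq(min(grid[ok]), max(grid[ok]), length.out = 11)
      vextra <- eval_nodes(extra, off = length(grid))
      grid <- c(grid, extra)
      vals <- c(vals, vextra)
      o <- order(grid)
      grid <- grid[o]; vals <- vals[o]
      dup <- duplicated(signif(grid, 12))
      grid <- grid[!dup]; vals <- vals[!dup]
      ok <- is.finite(vals)
    }
    if (sum(ok) < 5)
      stop("profile cumulant estimation failed on most of the psi grid")
    return(interp_fun(grid[ok], vals[ok]))
  }
  if (kind %in% c("firth", "predictive")) {
    # predictive matching with nuisance parameters: the pseudo-posterior is
    # the profile of the Jeffreys-penalized likelihood, so the additive
    # correction is the penalized-profile score minus the profile score
    if (is.null(grid)) stop("a psi grid is required to cache the profile correction")
    vals <- vapply(grid, function(p)
      penalized_profile_score(model, p, data) - profile_score(model, p, data),
      numeric(1))
    return(interp_fun(grid, vals))
  }
  if (kind == "jeffreys") {
    return(function(psi) {
      h <- max(abs(psi), 1) * 1e-4
      ip <- function(p) {
        lam <- constrained_mle(model, p, data)
        I <- expected_info(model, full_theta(model, p, lam), n)
        j <- model$interest
        log(I[j, j] - I[j, -j, drop = FALSE] %*%
              solve(I[-j, -j, drop = FALSE], I[-j, j, drop = FALSE]))
      }
      drop(ip(psi + h) - ip(psi - h)) / (4 * h)
    })
  }
  stop("unknown correction kind: ", kind)
}

# Jeffreys-penalized objective l(theta) + (1/2) log det i(theta).
penalized_objective <- function(model, theta, data, n) {
  I <- model$info(theta, n)
  model$loglik(theta, data) +
    0.5 * as.numeric(determinant(as.matrix(I), logarithm = TRUE)$modulus)
}

# Profile of the Jeffreys-penalized log-likelihood: max over the nuisance of
# l(psi, lambda) + (1/2) log det i(psi, lambda).
penalized_profile_loglik <- function(model, psi, data, start = NULL,
                                     return_lambda = FALSE) {
  n <- if (is.matrix(data)) nrow(data) else length(data)
  j <- model$interest
  obj <- function(lam)
    -penalized_objective(model, full_theta(model, psi, lam), data, n)
  lo <- model$support[1, -j]; hi <- model$support[2, -j]
  if (is.null(start)) start <- constrained_mle(model, psi, data)
  fit <- stats::nlminb(start, obj, lower = lo + 1e-9, upper = hi - 1e-9,
                       control = list(rel.tol = 1e-12, abs.tol = 0))
  if (return_lambda) list(value = -fit$objective, lambda = fit$par)
  else -fit$objective
}

# Derivative of the penalized profile via the envelope identity: the inner
# maximizer is held fixed while only psi moves, so optimizer noise enters
# at second order only.
penalized_profile_score <- function(model, psi, data) {
  n <- if (is.matrix(data)) nrow(data) else length(data)
  fit <- penalized_profile_loglik(model, psi, data, return_lambda = TRUE)
  h <- max(abs(psi), 1) * 1e-5
  g <- function(p) penalized_objective(model, full_theta(model, p, fit$lambda),
                                       data, n)
  (g(psi + h) - g(psi - h)) / (2 * h)
}

#' Solve the modified profile score equation
#'
#' Root of t_p(psi) = l_p'(psi) + m(psi, lambda_hat_psi).  The correction is
#' estimated on a psi grid spanning the MLE (or a finite fallback centre
#' under monotone likelihood) and interpolated inside the root search.
#'
#' @inheritParams profile_loglik
#' @param kind correction kind.
#' @param replicates bootstrap replicates per grid point for the cumulants.
#' @param seed seed for the bootstrap.
#' @param grid_points number of cache points for the correction.
#' @return `bias_reduced_estimate`; the standard error comes from the
#'   observed profile information at the root.
#' @export
solve_modified_profile_score <- function(model, data, kind = "median",
                                         replicates = 2000, seed = NULL,
                                         grid_points = 41) {
  if (model$npar == 1) return(solve_modified_score(model, data, kind))
  j <- model$interest
  mono <- detect_monotone_likelihood(model, data)
  if (!mono$monotone) {
    mle <- fit_mle(model, data)
    centre <- mle$psi
    jp <- profile_obs_info(model, centre, data)
    se <- 1 / sqrt(max(jp, 1e-12))
  } else {
    # divergent MLE: centre the search on the Jeffreys-penalized profile
    # maximizer, which stays finite under monotone likelihood/separation
    pen <- function(p) penalized_profile_loglik(model, p, data)
    B <- 2
    repeat {
      opt <- stats::optimize(pen, c(-B, B), maximum = TRUE)
      if (abs(opt$maximum) < 0.9 * B || B >= 64) break
      B <- B * 2
    }
    centre <- opt$maximum
    h <- max(abs(centre), 1) * 1e-3
    curv <- -(pen(centre + h) - 2 * opt$objective + pen(centre - h)) / h^2
    se <- if (is.finite(curv) && curv > 0) 1 / sqrt(curv) else 1
  }
  lo <- model$support[1, j]; hi <- model$support[2, j]
  glo <- centre - 6 * se
  ghi <- centre + 6 * se
  # stay a few percent of the remaining distance away from finite bounds:
  # cumulant simulation degenerates against the boundary
  if (is.finite(lo)) glo <- max(glo, lo + (centre - lo) * 0.05)
  if (is.finite(hi)) ghi <- min(ghi, hi - (hi - centre) * 0.05)
  br <- NULL
  for (attempt in 1:4) {
    grid <- seq(glo, ghi, length.out = grid_points)
    mfun <- profile_correction_fun(model, data, kind, replicates = replicates,
                                   seed = seed, grid = grid)
    tfun <- function(psi) profile_score(model, psi, data) + mfun(psi)
    br <- tryCatch(expand_bracket(tfun, centre, half = se,
                                  lower = glo, upper = ghi),
                   evmatch_divergence = function(e) e)
    if (!inherits(br, "condition")) break
    if (attempt == 4) stop(br)
    # widen the search window in the direction of the apparent divergence
    span <- ghi - glo
    if ((br$direction %||% 1) > 0) {
      ghi <- if (is.finite(hi)) min(ghi + span, hi - (hi - centre) * 0.02)
             else ghi + span
    } else {
      glo <- if (is.finite(lo)) max(glo - span, lo + (centre - lo) * 0.02)
             else glo - span
    }
  }
  root <- stats::uniroot(tfun, br, tol = 1e-10)
  est <- root$root
  jp_root <- profile_obs_info(model, est, data)
  structure(list(estimate = est, se = 1 / sqrt(max(jp_root, 1e-12)),
                 kind = kind, converged = TRUE, t_at_root = tfun(est),
                 correction = mfun),
            class = "bias_reduced_estimate")
}

#' Firth-penalized logistic regression
#'
#' Joint mode of l(beta) + (1/2) log det i(beta) (the Jeffreys-prior
#' penalty) by Newton iteration with step halving, using the standard
#' hat-diagonal form of the adjusted score; finite under quasi-complete
#' separation.
#'
#' @param X full-rank design matrix (include the intercept column).
#' @param y 0/1 response.
#' @param tol convergence tolerance on the adjusted score norm.
#' @param maxit maximum Newton steps.
#' @return coefficient vector with attributes `se` (from the penalized
#'   information) and `iterations`.
#' @export
firth_logistic_fit <- function(X, y, tol = 1e-8, maxit = 100) {
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank-deficient")
  p <- ncol(X)
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    pr <- stats::plogis(eta)
    w <- pr * (1 - pr)
    XW <- X * w
    I <- crossprod(X, XW)
    # hat diagonal of the weighted design
    U <- chol(I)
    Z <- backsolve(U, t(X * sqrt(w)), transpose = TRUE)
    hdiag <- colSums(Z^2)
    g <- drop(crossprod(X, y - pr + hdiag * (0.5 - pr)))
    if (sqrt(sum(g^2)) < tol) break
    step <- solve(I, g)
    # step halving on the penalized objective
    pen_obj <- function(b) {
      e <- drop(X %*% b)
      prb <- stats::plogis(e)
      ll <- sum(y * e - log1p(exp(-abs(e))) - pmax(e, 0))
      Ib <- crossprod(X, X * (prb * (1 - prb)))
      ll + 0.5 * determinant(Ib, logarithm = TRUE)$modulus
    }
    f0 <- pen_obj(beta)
    lam <- 1
    repeat {
      bnew <- beta + lam * step
      if (is.finite(pen_obj(bnew)) && pen_obj(bnew) >= f0 - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8) break
    }
    beta <- beta + lam * step
  }
  eta <- drop(X %*% beta); pr <- stats::plogis(eta)
  I <- crossprod(X, X * (pr * (1 - pr)))
  structure(beta, se = sqrt(diag(solve(I))), iterations = it,
            names = colnames(X) %||% paste0("beta", seq_len(p) - 1))
}
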