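#' Posterior grid objects
#'
#' A `posterior_grid` is a normalized 1-D density on an ordered grid:
#' abscissae, unnormalized log density, normalized density, normalizing
#' constant, refined mode, cumulative masses and construction metadata.
#'
#' @param x ordered abscissae.
#' @param logdens unnormalized log-density values.
#' @param meta construction metadata list.
#' @keywords internal
new_posterior_grid <- function(x, logdens, meta = list(), refine_fn = NULL) {
  stopifnot(length(x) == length(logdens), !is.unsorted(x))
  keep <- is.finite(logdens)
  if (sum(keep) < 5) stop("fewer than 5 finite log-density points")
  x <- x[keep]; logdens <- logdens[keep]
  ld <- logdens - max(logdens)
  dens <- exp(ld)
  Z <- trapz(x, dens)
  dens <- dens / Z
  # refine the mode around the grid argmax: against the continuous
  # log-kernel when supplied, else a local spline fit
  i0 <- which.max(ld)
  lo <- max(1, i0 - 3); hi <- min(length(x), i0 + 3)
  if (!is.null(refine_fn)) {
    opt <- stats::optimize(refine_fn, c(x[max(1, i0 - 1)],
                                        x[min(length(x), i0 + 1)]),
                           maximum = TRUE, tol = 1e-10)
  } else {
    sf <- stats::splinefun(x[lo:hi], ld[lo:hi], method = "natural")
    opt <- stats::optimize(sf, range(x[lo:hi]), maximum = TRUE)
  }
  g <- list(x = x, logdens = logdens, dens = dens,
            logZ = log(Z) + max(logdens), mode = opt$maximum,
            cdf = cumtrapz(x, dens), meta = meta)
  class(g) <- "posterior_grid"
  g
}

#' @export
print.posterior_grid <- function(x, ...) {
  cat(sprintf("<posterior_grid> %d points on [%.4g, %.4g], mode %.6g\n",
              length(x$x), min(x$x), max(x$x), x$mode))
  invisible(x)
}

# Interpolated normalized density at arbitrary points (linear in log space
# where positive, zero outside the grid).
grid_density_at <- function(grid, psi) {
  out <- numeric(length(psi))
  ok <- psi >= min(grid$x) & psi <= max(grid$x)
  if (any(ok))
    out[ok] <- exp(stats::approx(grid$x, log(pmax(grid$dens, 1e-300)),
                                 xout = psi[ok])$y)
  out
}

# Interpolated cdf.
grid_cdf_at <- function(grid, psi) {
  stats::approx(grid$x, grid$cdf, xout = psi, yleft = 0,
                yright = max(grid$cdf))$y
}

#' Build the median matching (or other) pseudo-posterior on a grid
#'
#' Constructs the scalar pseudo-posterior whose log kernel is the profile
#' log-likelihood plus the integrated score correction,
#' l_p(psi) + int m(psi, lambda_hat_psi) d psi, normalized by quadrature on
#' an adaptive grid.  `prior_kind = "flat"` gives a density proportional to
#' the profile likelihood and raises an improper-posterior error when that
#' likelihood is monotone; `"median"` and `"firth"`/"predictive" remain
#' proper in those cases; `"jeffreys"` uses half the log profile-adapted
#' information.
#'
#' @inheritParams profile_loglik
#' @param prior_kind one of "median", "firth", "predictive", "jeffreys",
#'   "flat".
#' @param grid_points number of grid points (default 801 over +/- 8 SE).
#' @param half_width_se grid half-width in standard errors.
#' @param replicates,seed Monte Carlo settings for profile cumulants
#'   (models with nuisance parameters).
#' @param correction_points number of psi points at which the (expensive)
#'   profile correction is evaluated before interpolation.
#' @return a `posterior_grid`.
#' @export
build_pseudo_posterior <- function(model, data, prior_kind = "median",
                                   grid_points = 801, half_width_se = 8,
                                   replicates = 2000, seed = NULL,
                                   correction_points = 41) {
  j <- model$interest
  mono <- detect_monotone_likelihood(model, data)
  if (mono$monotone && prior_kind %in% c("flat", "none"))
    stop(structure(class = c("evmatch_improper_posterior", "error", "condition"),
                   list(message = paste0(
                     "flat-prior pseudo-posterior is improper: the profile ",
                     "likelihood is monotone (direction ",
                     if (mono$direction > 0) "+Inf" else "-Inf",
                     "); use the median matching prior"),
                     call = sys.call(-1), direction = mono$direction)))
  if (!mono$monotone) {
    mle <- fit_mle(model, data)
    centre <- mle$psi
    jp <- if (model$npar == 1) {
      n <- if (is.matrix(data)) nrow(data) else length(data)
      expected_info(model, centre, n)
    } else profile_obs_info(model, centre, data)
    se <- 1 / sqrt(max(jp, 1e-12))
  } else {
    # divergent MLE: centre the grid on the Jeffreys-penalized profile
    # maximizer (always finite); the posterior mode then emerges from the
    # kernel itself rather than from a separate root search
    if (model$npar == 1) {
      est <- solve_modified_score(model, data, kind = prior_kind)
      centre <- est$estimate
      se <- est$se
    } else {
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
  }
  lo <- model$support[1, j]; hi <- model$support[2, j]
  for (attempt in 1:6) {
    glo <- centre - half_width_se * se
    ghi <- centre + half_width_se * se
    if (is.finite(lo)) glo <- max(glo, lo + (centre - lo) * 1e-4)
    if (is.finite(hi)) ghi <- min(ghi, hi - (hi - centre) * 1e-4)
    x <- seq(glo, ghi, length.out = grid_points)
    lp <- vapply(x, function(p) profile_loglik(model, p, data)$value, numeric(1))
    cgrid <- seq(glo, ghi, length.out = correction_points)
    mfun <- profile_correction_fun(model, data, prior_kind,
                                   replicates = replicates, seed = seed,
                                   grid = cgrid)
    # integrate the correction by cumulative Simpson: trapezoid bias would
    # bleed into the mode when the kernel is nearly flat.  Cheap exact
    # corrections (closed-form cumulants) are evaluated directly -- they can
    # be singular at a support boundary, where a spline cache oscillates;
    # expensive ones (quadrature/Monte Carlo) go through the node cache.
    direct <- model$npar == 1 && !is.null(model$cumulant3) &&
      prior_kind %in% c("median", "firth", "predictive")
    mcache <- if (direct) Vectorize(mfun)
              else interp_fun(cgrid, vapply(cgrid, mfun, numeric(1)))
    logk <- lp + cumsimpson_fun(mcache, x)
    anchor <- x[which.max(logk)]
    logk_fun <- function(p) {
      # composite Simpson of the exact correction over the short refinement
      # interval (the cached spline is only used for the full-grid integral)
      u <- seq(anchor, p, length.out = 9)
      mv <- vapply(u, mfun, numeric(1))
      h <- (p - anchor) / 8
      intm <- if (h == 0) 0 else
        h / 3 * (mv[1] + 4 * sum(mv[c(2, 4, 6, 8)]) +
                   2 * sum(mv[c(3, 5, 7)]) + mv[9])
      profile_loglik(model, p, data)$value + intm
    }
    g <- new_posterior_grid(x, logk, refine_fn = logk_fun,
                            meta = list(prior_kind = prior_kind,
                                        centre = centre, se = se,
                                        seed = seed,
                                        half_width_se = half_width_se))
    # auto-expand when boundary mass is non-negligible
    edge <- 2
    bmass <- (g$cdf[edge] - g$cdf[1]) +
      (g$cdf[length(g$cdf)] - g$cdf[length(g$cdf) - edge + 1])
    at_support <- (is.finite(lo) && glo - lo < 1e-6 * max(1, abs(lo) + 1)) |
      (is.finite(hi) && hi - ghi < 1e-6 * max(1, abs(hi)))
    if (bmass < 1e-4 || half_width_se > 64 || isTRUE(at_support)) return(g)
    half_width_se <- half_width_se * 2
    grid_points <- min(2 * grid_points - 1, 4001)
  }
  g
}

#' Quadratic (Rao score-type) approximation to the pseudo-posterior
#'
#' Density proportional to exp(-s_p(psi)/2) with
#' s_p(psi) = t_p(psi)^2 / j_p(psi), the score-type statistic built from the
#' modified profile score; the curvature j_p is evaluated at psi
#' (`curvature_at = "psi"`, the default) or frozen at the maximum likelihood
#' estimate.
#'
#' @inheritParams build_pseudo_posterior
#' @param kind correction kind entering t_p.
#' @param curvature_at "psi" or "psi-hat".
#' @export
quadratic_pseudo_posterior <- function(model, data, kind = "median",
                                       grid_points = 801, half_width_se = 8,
                                       replicates = 2000, seed = NULL,
                                       curvature_at = c("psi", "psi-hat")) {
  curvature_at <- match.arg(curvature_at)
  j <- model$interest
  mle <- fit_mle(model, data)
  centre <- mle$psi
  n <- if (is.matrix(data)) nrow(data) else length(data)
  jp_hat <- if (model$npar == 1) expected_info(model, centre, n)
            else profile_obs_info(model, centre, data)
  se <- 1 / sqrt(max(jp_hat, 1e-12))
  lo <- model$support[1, j]; hi <- model$support[2, j]
  glo <- centre - half_width_se * se
  ghi <- centre + half_width_se * se
  if (is.finite(lo)) glo <- max(glo, lo + (centre - lo) * 1e-4)
  if (is.finite(hi)) ghi <- min(ghi, hi - (hi - centre) * 1e-4)
  x <- seq(glo, ghi, length.out = grid_points)
  cgrid <- seq(glo, ghi, length.out = 41)
  mfun <- profile_correction_fun(model, data, kind, replicates = replicates,
                                 seed = seed, grid = cgrid)
  tp <- vapply(x, function(p) profile_score(model, p, data) + mfun(p), numeric(1))
  jp <- if (curvature_at == "psi-hat") rep(jp_hat, length(x))
        else vapply(x, function(p) {
          if (model$npar == 1) expected_info(model, p, n)
          else profile_obs_info(model, p, data)
        }, numeric(1))
  ok <- jp > 0
  if (!all(ok)) warning("nonpositive curvature at ", sum(!ok),
                        " grid points; trimmed")
  new_posterior_grid(x[ok], -0.5 * tp[ok]^2 / jp[ok],
                     meta = list(prior_kind = kind, quadratic = TRUE,
                                 curvature_at = curvature_at))
}

#' Highest posterior density interval from a grid density
#'
#' Superlevel-set interval with the requested mass, found by bisection on
#' the density height with linear interpolation at the crossings.  For a
#' multimodal density the union of intervals is returned with a flag.
#'
#' @param grid a `posterior_grid`.
#' @param level target mass.
#' @return numeric vector `c(lower, upper)` (or a 2-column matrix of
#'   components when multimodal, with attribute `multimodal = TRUE`);
#'   attribute `attained` holds the achieved mass.
#' @export
hpd_interval <- function(grid, level = 0.95) {
  stopifnot(level > 0, level < 1)
  f <- grid$dens
  mass_above <- function(h) {
    comp <- superlevel_components(grid$x, f, h)
    if (nrow(comp) == 0) return(list(mass = 0, comp = comp))
    m <- sum(vapply(seq_len(nrow(comp)), function(i)
      region_mass(grid, comp[i, 1], comp[i, 2]), numeric(1)))
    list(mass = m, comp = comp)
  }
  lo_h <- 0; hi_h <- max(f)
  for (it in 1:200) {
    h <- (lo_h + hi_h) / 2
    r <- mass_above(h)
    if (r$mass > level) lo_h <- h else hi_h <- h
    if (hi_h - lo_h < 1e-14 * max(f)) break
  }
  r <- mass_above((lo_h + hi_h) / 2)
  comp <- r$comp
  if (nrow(comp) == 1) {
    out <- c(comp[1, 1], comp[1, 2])
  } else {
    out <- comp
    attr(out, "multimodal") <- TRUE
  }
  attr(out, "attained") <- r$mass
  out
}

# Connected components {x : f(x) > h} of a piecewise-linear density, with
# linearly interpolated crossing points.  Returns a matrix with columns
# lower, upper.
superlevel_components <- function(x, f, h) {
  above <- f > h
  if (!any(above)) return(matrix(numeric(0), 0, 2))
  n <- length(x)
  starts <- which(above & !c(FALSE, above[-n]))
  ends <- which(above & !c(above[-1], FALSE))
  lo <- vapply(starts, function(i) {
    if (i == 1) x[1]
    else x[i - 1] + (h - f[i - 1]) / (f[i] - f[i - 1]) * (x[i] - x[i - 1])
  }, numeric(1))
  hi <- vapply(ends, function(i) {
    if (i == n) x[n]
    else x[i] + (h - f[i]) / (f[i + 1] - f[i]) * (x[i + 1] - x[i])
  }, numeric(1))
  cbind(lo, hi)
}

# Mass of the normalized grid density between a and b, by integrating a
# spline of the density (accurate well past trapezoid order).
region_mass <- function(grid, a, b) {
  sf <- stats::splinefun(grid$x, grid$dens, method = "natural")
  stats::integrate(function(u) pmax(sf(u), 0), a, b,
                   rel.tol = 1e-10, abs.tol = 1e-12,
                   subdivisions = 500L, stop.on.error = FALSE)$value
}
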