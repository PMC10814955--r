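#' e-value results
#'
#' An `evalue_result` records the FBST evidence value in favor of a sharp
#' null, the method that produced it, the tangential-set boundaries where
#' available, the surprise level at the null, and diagnostics.
#' @keywords internal
new_evalue_result <- function(ev, method, psi0, boundaries = NULL,
                              surprise = NULL, diagnostics = list()) {
  structure(list(ev = min(max(ev, 0), 1), method = method, psi0 = psi0,
                 boundaries = boundaries, surprise = surprise,
                 diagnostics = diagnostics),
            class = "evalue_result")
}

#' @export
print.evalue_result <- function(x, ...) {
  cat(sprintf("<evalue> ev = %.4f  (method: %s, H0: psi = %g)\n",
              x$ev, x$method, x$psi0))
  invisible(x)
}

#' Exact 1-D FBST e-value on a density grid
#'
#' Computes the evidence value ev = 1 - posterior mass of the tangential set
#' T = {psi : s(psi) > s(psi0)}, where the surprise function s is the
#' normalized grid density divided by a reference evaluator (flat by
#' default, as appropriate for the matching-prior pseudo-posterior).
#' Crossing points of the level are located by linear interpolation on the
#' grid and the mass integrated by adaptive quadrature on a spline of the
#' density.
#'
#' @param grid a `posterior_grid`.
#' @param psi0 null value.
#' @param reference NULL for a flat reference, or a positive vectorized
#'   function of psi.
#' @return an `evalue_result` with tangential boundaries; `ev = 1` when the
#'   null sits at the mode.  A multimodality flag is set in the diagnostics
#'   when the tangential set has several components.
#' @export
evalue_exact_1d <- function(grid, psi0, reference = NULL) {
  if (psi0 < min(grid$x) || psi0 > max(grid$x))
    stop("psi0 = ", psi0, " lies outside the posterior grid [",
         signif(min(grid$x), 4), ", ", signif(max(grid$x), 4),
         "]; rebuild the grid with a wider half-width")
  if (is.null(reference)) {
    s <- grid$dens
    s0 <- grid_density_at(grid, psi0)
  } else {
    r <- reference(grid$x)
    if (any(!is.finite(r)) || any(r <= 0))
      stop("reference function must be strictly positive on the grid")
    s <- grid$dens / r
    s0 <- grid_density_at(grid, psi0) / reference(psi0)
  }
  comp <- superlevel_components(grid$x, s, s0)
  if (nrow(comp) == 0)
    return(new_evalue_result(1, "exact-grid", psi0, surprise = s0))
  # refine the linearly interpolated crossings on a spline of the surprise
  sf <- stats::splinefun(grid$x, s, method = "natural")
  h <- stats::median(diff(grid$x))
  refine <- function(z) {
    if (z <= min(grid$x) + h || z >= max(grid$x) - h) return(z)
    out <- tryCatch(stats::uniroot(function(u) sf(u) - s0, c(z - h, z + h),
                                   tol = 1e-12)$root, error = function(e) z)
    out
  }
  comp <- apply(comp, 2, function(col) vapply(col, refine, numeric(1)))
  comp <- matrix(comp, ncol = 2)
  mass <- sum(vapply(seq_len(nrow(comp)), function(i) {
    region_mass(grid, comp[i, 1], comp[i, 2])
  }, numeric(1)))
  new_evalue_result(1 - mass, "exact-grid", psi0,
                    boundaries = comp, surprise = s0,
                    diagnostics = list(multimodal = nrow(comp) > 1,
                                       components = nrow(comp)))
}

#' Wald-type first-order e-value
#'
#' ev = 2 (1 - Phi(|psi0 - estimate| * curvature^(1/2))).  With the MLE and
#' the observed profile information this is the classical first-order
#' approximation; with the median-bias-reduced estimator it differs in
#' location only.
#'
#' @param estimate point estimate (MLE or median-bias-reduced).
#' @param curvature information evaluated at the estimate (must be > 0).
#' @param psi0 null value.
#' @param estimator tag recorded in the method field ("mle" or "median").
#' @export
evalue_wald <- function(estimate, curvature, psi0, estimator = "mle") {
  if (!is.finite(curvature) || curvature <= 0)
    stop("curvature must be positive")
  z <- abs(psi0 - estimate) * sqrt(curvature)
  new_evalue_result(2 * stats::pnorm(z, lower.tail = FALSE),
                    paste0("wald-", estimator), psi0,
                    diagnostics = list(z = z))
}

#' Score-type first-order e-value
#'
#' ev = 2 (1 - Phi(|t(psi0)| / i(psi0)^(1/2))) built from the modified
#' (profile) score at the null; since t/sqrt(i) transforms invariantly
#' under monotone reparameterization, so does this e-value.
#'
#' @param t_value modified (profile) score at psi0.
#' @param information (profile) information at psi0 (must be > 0).
#' @param psi0 null value.
#' @param profile logical tag: profile (t_p, j_p) or genuine scalar score.
#' @export
evalue_score <- function(t_value, information, psi0, profile = FALSE) {
  if (!is.finite(information) || information <= 0)
    stop("information must be positive")
  z <- abs(t_value) / sqrt(information)
  new_evalue_result(2 * stats::pnorm(z, lower.tail = FALSE),
                    if (profile) "score-profile" else "score-scalar", psi0,
                    diagnostics = list(z = z))
}

#' Asymptotic null distribution of the e-value
#'
#' V(c) = Q(d - h, Qinv(d, c)) with Q the chi-square cdf: the cumulative
#' distribution function of the e-value under the null, as the sample size
#' grows.  For d = 1, h = 0 this is the identity (e-values are
#' asymptotically uniform).
#'
#' @param c evidence level(s) in 0..1.
#' @param d dimension of the parameter space.
#' @param h dimension of the null set (0 <= h < d).
#' @export
evalue_null_cdf <- function(c, d, h = 0) {
  if (d < 1 || h < 0 || h >= d) stop("require 0 <= h < d, d >= 1")
  if (any(c < 0 | c > 1)) stop("c must lie in [0, 1]")
  stats::pchisq(stats::qchisq(c, df = d), df = d - h)
}

#' Compute an e-value for a sharp hypothesis (dispatcher)
#'
#' Ties the model, data, hypothesis, prior kind and approximation method
#' together: "grid" builds the pseudo-posterior and computes the exact 1-D
#' FBST e-value; "wald" uses the median-bias-reduced (or ML) estimate;
#' "score" the modified (profile) score statistic; "tailarea" the
#' third-order modified likelihood root route.
#'
#' @inheritParams build_pseudo_posterior
#' @param psi0 null value of the interest parameter.
#' @param method "grid", "wald", "score" or "tailarea".
#' @param replicates,seed Monte Carlo settings for profile corrections.
#' @export
evalue_for_hypothesis <- function(model, data, psi0,
                                  method = c("grid", "wald", "score", "tailarea"),
                                  prior_kind = "median",
                                  replicates = 2000, seed = NULL, ...) {
  method <- match.arg(method)
  n <- if (is.matrix(data)) nrow(data) else length(data)
  if (method == "grid") {
    g <- build_pseudo_posterior(model, data, prior_kind = prior_kind,
                                replicates = replicates, seed = seed, ...)
    if (psi0 < min(g$x) || psi0 > max(g$x)) {
      hw <- (g$meta$half_width_se %||% 8) *
        max(2, ceiling(abs(psi0 - g$mode) / max(g$meta$se, 1e-12) / 4))
      g <- build_pseudo_posterior(model, data, prior_kind = prior_kind,
                                  replicates = replicates, seed = seed,
                                  half_width_se = hw, ...)
    }
    return(evalue_exact_1d(g, psi0))
  }
  if (method == "wald") {
    if (prior_kind %in% c("flat", "none")) {
      mle <- fit_mle(model, data)
      jp <- if (model$npar == 1) expected_info(model, mle$psi, n)
            else profile_obs_info(model, mle$psi, data)
      return(evalue_wald(mle$psi, jp, psi0, estimator = "mle"))
    }
    est <- solve_modified_profile_score(model, data, kind = prior_kind,
                                        replicates = replicates, seed = seed)
    info0 <- if (model$npar == 1) expected_info(model, psi0, n)
             else profile_obs_info(model, psi0, data)
    return(evalue_wald(est$estimate, info0, psi0, estimator = prior_kind))
  }
  if (method == "score") {
    if (model$npar == 1) {
      mfun <- correction_fun_scalar(model, prior_kind, n)
      tv <- score(model, psi0, data) + mfun(psi0)
      return(evalue_score(tv, expected_info(model, psi0, n), psi0))
    }
    est <- solve_modified_profile_score(model, data, kind = prior_kind,
                                        replicates = replicates, seed = seed)
    tv <- profile_score(model, psi0, data) + est$correction(psi0)
    jp0 <- profile_obs_info(model, psi0, data)
    return(evalue_score(tv, jp0, psi0, profile = TRUE))
  }
  ctx <- tailarea_context(model, data)
  evalue_tailarea(ctx, psi0)
}
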