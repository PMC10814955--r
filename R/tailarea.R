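#' Tail-area context
#'
#' Collects every ingredient of the higher-order marginal-posterior
#' machinery for a model/data pair: the profile log-likelihood and its
#' constrained nuisance maximizer, the full MLE, the observed profile
#' information at the MLE, the log-determinant of the nuisance information
#' block, and user-supplied log prior and log reference evaluators over
#' (psi, lambda) (both default to flat).
#'
#' @inheritParams profile_loglik
#' @param log_prior,log_reference functions of (psi, lambda) returning log
#'   densities up to constants; NULL means flat.
#' @return object of class `tailarea_context`.
#' @export
tailarea_context <- function(model, data, log_prior = NULL,
                             log_reference = NULL) {
  j <- model$interest
  mle <- fit_mle(model, data)
  lp_fun <- function(psi) profile_loglik(model, psi, data)$value
  lam_fun <- function(psi) constrained_mle(model, psi, data)
  jp_hat <- profile_obs_info(model, mle$psi, data)
  if (jp_hat <= 0) stop("nonpositive profile information at the MLE")
  ldet_jll <- if (model$npar == 1) function(psi, lam) 0 else function(psi, lam) {
    H <- num_hess(function(l) model$loglik(full_theta(model, psi, l), data), lam)
    d <- determinant(as.matrix(-H), logarithm = TRUE)
    if (d$sign <= 0) stop("singular or indefinite nuisance information ",
                          "block at psi = ", psi)
    as.numeric(d$modulus)
  }
  structure(list(model = model, data = data, psi_hat = mle$psi,
                 lam_hat = mle$lambda, lp_hat = mle$value, jp_hat = jp_hat,
                 lp = lp_fun, lam = lam_fun, ldet_jll = ldet_jll,
                 log_prior = log_prior %||% function(psi, lam) 0,
                 log_reference = log_reference %||% function(psi, lam) 0),
            class = "tailarea_context")
}

#' Laplace approximation to the marginal posterior on a grid
#'
#' Log kernel l_p(psi) - l_p(psi_hat)
#' + (1/2) (log det j_ll(psi_hat, lam_hat) - log det j_ll(psi, lam_psi))
#' + log pi(psi, lam_psi) - log pi(psi_hat, lam_hat), renormalized on the
#' grid; accurate to third order in moderate-deviation regions.
#'
#' @param ctx a [tailarea_context()].
#' @param psi_grid ordered evaluation grid.
#' @return a `posterior_grid`.
#' @export
laplace_marginal_posterior <- function(ctx, psi_grid) {
  ld <- vapply(psi_grid, function(p) laplace_log_kernel(ctx, p), numeric(1))
  new_posterior_grid(psi_grid, ld, meta = list(kind = "laplace-marginal"))
}

laplace_log_kernel <- function(ctx, psi, surprise = FALSE) {
  lam <- ctx$lam(psi)
  v <- ctx$lp(psi) - ctx$lp_hat +
    0.5 * (ctx$ldet_jll(ctx$psi_hat, ctx$lam_hat) - ctx$ldet_jll(psi, lam)) +
    ctx$log_prior(psi, lam) - ctx$log_prior(ctx$psi_hat, ctx$lam_hat)
  if (surprise) v <- v - ctx$log_reference(psi, lam)
  v
}

#' Profile likelihood root
#'
#' r_p(psi) = sign(psi_hat - psi) * sqrt(2 (l_p(psi_hat) - l_p(psi))).
#'
#' @param ctx a [tailarea_context()].
#' @param psi evaluation point.
#' @export
profile_likelihood_root <- function(ctx, psi) {
  dl <- ctx$lp_hat - ctx$lp(psi)
  if (dl < -1e-6)
    stop("profile log-likelihood exceeds its maximum at psi = ", psi,
         " (inner optimization inconsistency)")
  sign(ctx$psi_hat - psi) * sqrt(2 * max(dl, 0))
}

#' Bayesian correction factor q_B
#'
#' q_B(psi) = l_p'(psi) * j_p(psi_hat)^(-1/2)
#' * (det j_ll(psi, lam_psi) / det j_ll(psi_hat, lam_hat))^(1/2)
#' * pi(psi_hat, lam_hat) / pi(psi, lam_psi)
#' * r(psi, lam_psi) / r(psi_hat, lam_hat).
#'
#' @inheritParams profile_likelihood_root
#' @export
qB_factor <- function(ctx, psi) {
  lam <- ctx$lam(psi)
  lps <- profile_score(ctx$model, psi, ctx$data)
  lps / sqrt(ctx$jp_hat) *
    exp(0.5 * (ctx$ldet_jll(psi, lam) - ctx$ldet_jll(ctx$psi_hat, ctx$lam_hat)) +
          ctx$log_prior(ctx$psi_hat, ctx$lam_hat) - ctx$log_prior(psi, lam) +
          ctx$log_reference(psi, lam) -
          ctx$log_reference(ctx$psi_hat, ctx$lam_hat))
}

#' Modified likelihood root r_B*
#'
#' r_B*(psi) = r_p + log(q_B / r_p) / r_p; inside the singular window
#' |r_p| < `window` the value is replaced by a cubic interpolation across
#' the window (flagged), keeping the root continuous through psi_hat.
#'
#' @inheritParams profile_likelihood_root
#' @param window half-width of the singular window on the r_p scale.
#' @return list with `rp`, `qB`, `rstar`, `interpolated`.
#' @export
rstar_bayes <- function(ctx, psi, window = 0.05) {
  rp <- profile_likelihood_root(ctx, psi)
  if (abs(rp) >= window) {
    qb <- qB_factor(ctx, psi)
    if (qb / rp <= 0)
      stop("qB/rp = ", signif(qb / rp, 4), " <= 0 at psi = ", psi,
           " (rp = ", signif(rp, 4), ", qB = ", signif(qb, 4), ")")
    return(list(rp = rp, qB = qb, rstar = rp + log(qb / rp) / rp,
                interpolated = FALSE))
  }
  # cubic interpolation through four points flanking the window
  se <- 1 / sqrt(ctx$jp_hat)
  offs <- c(-3, -1.5, 1.5, 3) * max(window, 0.04) * se * 2
  xs <- ctx$psi_hat + offs
  ys <- vapply(xs, function(p) {
    r <- profile_likelihood_root(ctx, p)
    q <- qB_factor(ctx, p)
    r + log(q / r) / r
  }, numeric(1))
  fit <- stats::lm.fit(cbind(1, offs, offs^2, offs^3), ys)
  d <- psi - ctx$psi_hat
  list(rp = rp, qB = NA_real_,
       rstar = drop(c(1, d, d^2, d^3) %*% fit$coefficients),
       interpolated = TRUE)
}

#' Higher-order marginal posterior tail area
#'
#' Phi(r_B*(psi0)) approximates the upper tail integral of the marginal
#' (surprise) posterior beyond psi0 to third order.
#'
#' @inheritParams rstar_bayes
#' @param psi0 tail boundary.
#' @export
tail_area_probability <- function(ctx, psi0, window = 0.05) {
  stats::pnorm(rstar_bayes(ctx, psi0, window = window)$rstar)
}

#' Third-order tail-area e-value
#'
#' Locates psi0*, the point on the opposite side of the marginal-surprise
#' mode with equal surprise density, and returns
#' ev = 1 - Phi(r_B*(lo)) + Phi(r_B*(hi)) for the ordered pair
#' {psi0, psi0*}; for a symmetric marginal this reduces to
#' 2 (1 - Phi(r_B*(psi0))).  Requires a unimodal marginal surprise density.
#'
#' @inheritParams rstar_bayes
#' @param psi0 null value.
#' @export
evalue_tailarea <- function(ctx, psi0, window = 0.05) {
  lk <- function(p) laplace_log_kernel(ctx, p, surprise = TRUE)
  se <- 1 / sqrt(ctx$jp_hat)
  j <- ctx$model$interest
  lo_s <- ctx$model$support[1, j]; hi_s <- ctx$model$support[2, j]
  br <- c(max(ctx$psi_hat - 10 * se, lo_s + 1e-8),
          min(ctx$psi_hat + 10 * se, hi_s - 1e-8))
  mode <- stats::optimize(lk, br, maximum = TRUE, tol = 1e-10)$maximum
  l0 <- lk(psi0)
  if (abs(psi0 - mode) < 1e-8 * max(1, abs(mode)))
    return(new_evalue_result(1, "tail-area", psi0))
  f <- function(p) lk(p) - l0
  # bracket the matching point on the other side of the mode
  dir <- if (psi0 < mode) +1 else -1
  step <- se / 2
  a <- mode
  repeat {
    b <- a + dir * step
    if (b <= lo_s || b >= hi_s) { b <- if (dir > 0) hi_s - 1e-8 else lo_s + 1e-8 }
    if (f(b) <= 0 || b %in% c(lo_s + 1e-8, hi_s - 1e-8)) break
    a <- b
    step <- step * 1.6
  }
  psi_star <- tryCatch(stats::uniroot(f, sort(c(a, b)), tol = 1e-10)$root,
                       error = function(e)
                         stop("could not bracket psi0* with equal marginal ",
                              "surprise density: ", conditionMessage(e)))
  pair <- sort(c(psi0, psi_star))
  ev <- 1 - stats::pnorm(rstar_bayes(ctx, pair[1], window = window)$rstar) +
    stats::pnorm(rstar_bayes(ctx, pair[2], window = window)$rstar)
  new_evalue_result(ev, "tail-area", psi0,
                    boundaries = pair,
                    diagnostics = list(psi0_star = psi_star, mode = mode))
}
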