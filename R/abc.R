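#' Rejection-ABC posterior sample
#'
#' Draws parameter values from a prior sampler, simulates a dataset of the
#' observed size for each, computes a Euclidean distance between
#' standardized summaries of the simulated and observed data, and accepts
#' the draws in the smallest `accept_fraction` quantile of the distances.
#'
#' @param model simulable scalar-interest `parametric_model` (scalar
#'   parameter for the default summaries).
#' @param prior_sampler function of (n_draws) returning parameter draws.
#' @param data observed dataset.
#' @param n_draws number of prior draws.
#' @param accept_fraction fraction of draws kept.
#' @param summary "deciles" (order statistics at the deciles, standardized
#'   by the observed-data scale), "sorted" (full order statistics),
#'   "score-grid" (the per-observation score evaluated at four parameter
#'   points flanking the MLE of the observed data — an estimating-function
#'   summary, nearly sufficient and much sharper than order statistics),
#'   "estimate" (the median-bias-reduced estimate of each dataset), or a
#'   function mapping a dataset to a numeric summary vector.
#' @param seed integer seed.
#' @return object of class `abc_sample`: `draws`, `distances`, `accepted`
#'   (logical), `threshold`, `acceptance_fraction`, `seed`.
#' @export
abc_posterior <- function(model, prior_sampler, data, n_draws = 100000,
                          accept_fraction = 0.05, summary = "deciles",
                          seed = NULL) {
  if (is.null(model$simulate)) stop("ABC requires a simulable model")
  if (!is.null(seed)) set.seed(seed)
  n <- if (is.matrix(data)) nrow(data) else length(data)
  sfun <- if (is.function(summary)) summary else switch(
    summary,
    deciles = function(y) stats::quantile(as.numeric(y),
                                          probs = seq(0.1, 0.9, by = 0.1),
                                          names = FALSE),
    sorted = function(y) sort(as.numeric(y)),
    "score-grid" = {
      ctr <- tryCatch(fit_mle(model, data)$psi, error = function(e)
        solve_modified_score(model, data, kind = "median")$estimate)
      se0 <- 1 / sqrt(expected_info(model, ctr, n))
      tg <- ctr + c(-1.5, -0.5, 0.5, 1.5) * se0
      tg <- tg[tg > model$support[1, model$interest] &
                 tg < model$support[2, model$interest]]
      function(y) vapply(tg, function(t) score(model, t, y) / n, numeric(1))
    },
    estimate = function(y)
      solve_modified_score(model, y, kind = "median")$estimate,
    stop("unknown summary: ", summary))
  s_obs <- sfun(data)
  # order-statistic summaries are standardized by the observed-data scale;
  # estimating-function summaries are already on a common scale
  scale <- if (is.character(summary) && summary %in% c("deciles", "sorted"))
    stats::sd(as.numeric(data)) else 1
  if (!is.finite(scale) || scale <= 0)
    stop("degenerate observed-data summary: zero scale")
  theta <- prior_sampler(n_draws)
  dist <- vapply(theta, function(t) {
    yb <- model$simulate(t, n)
    sqrt(sum(((sfun(yb) - s_obs) / scale)^2))
  }, numeric(1))
  k <- round(accept_fraction * n_draws)
  thr <- sort(dist)[k]
  acc <- dist <= thr
  # resolve ties at the threshold to keep exactly k draws
  if (sum(acc) > k) {
    extra <- which(dist == thr)
    drop_n <- sum(acc) - k
    acc[extra[seq_len(drop_n)]] <- FALSE
  }
  structure(list(draws = theta, distances = dist, accepted = acc,
                 threshold = thr, acceptance_fraction = accept_fraction,
                 n_draws = n_draws, seed = seed),
            class = "abc_sample")
}

#' @export
print.abc_sample <- function(x, ...) {
  cat(sprintf("<abc_sample> %d draws, %d accepted (%.1f%%), threshold %.4g\n",
              x$n_draws, sum(x$accepted), 100 * x$acceptance_fraction,
              x$threshold))
  invisible(x)
}

#' MAP estimate from posterior samples
#'
#' Mode of a Gaussian kernel density estimate (Silverman bandwidth by
#' default) refined by golden-section search on the interpolated KDE;
#' flags multimodality when the KDE has several substantial local maxima.
#'
#' @param samples accepted parameter draws (at least 100).
#' @param bw bandwidth passed to [stats::density()].
#' @return the KDE mode, with attribute `multimodal`.
#' @export
map_from_samples <- function(samples, bw = "nrd0") {
  if (length(unique(samples)) == 1) return(samples[1])
  if (length(samples) < 100)
    stop("need at least 100 samples for a stable KDE mode")
  d <- stats::density(samples, bw = bw, n = 1024)
  i0 <- which.max(d$y)
  sf <- stats::splinefun(d$x, d$y, method = "natural")
  lo <- d$x[max(1, i0 - 2)]; hi <- d$x[min(length(d$x), i0 + 2)]
  opt <- stats::optimize(sf, c(lo, hi), maximum = TRUE)
  ispeak <- which(diff(sign(diff(d$y))) == -2) + 1
  big <- sum(d$y[ispeak] > 0.1 * max(d$y))
  structure(opt$maximum, multimodal = big > 1)
}

#' Prior sampler for a scalar matching prior over a truncation range
#'
#' Normalizes the chosen matching prior on `range` (by quadrature of the
#' integrated correction) and samples by inverse-CDF on a fine grid;
#' improper priors (flat, Jeffreys on unbounded supports) become proper by
#' the truncation, which should comfortably cover the likelihood support.
#'
#' @param model scalar `parametric_model`.
#' @param kind "flat", "median", "firth"/"predictive" or "jeffreys".
#' @param range truncation interval.
#' @param n number of observations the correction refers to (the sampled
#'   prior is free of n for ratio-based corrections).
#' @param grid_points resolution of the inverse-CDF grid.
#' @return function of (n_draws) returning draws.
#' @export
matching_prior_sampler <- function(model, kind, range, n = 1,
                                   grid_points = 2001) {
  x <- seq(range[1], range[2], length.out = grid_points)
  lp <- matching_logprior_scalar(model, kind, x, n = n)
  w <- exp(lp - max(lp))
  cdf <- cumtrapz(x, w)
  cdf <- cdf / cdf[length(cdf)]
  # strictly increasing envelope for inversion
  keep <- c(TRUE, diff(cdf) > 0)
  qf <- stats::approxfun(cdf[keep], x[keep], rule = 2)
  function(n_draws) qf(stats::runif(n_draws))
}

#' Posterior grid from weighted/unweighted ABC draws
#'
#' Kernel density estimate of the accepted draws, wrapped as a
#' `posterior_grid` so the exact-grid FBST machinery applies to
#' simulation-based posteriors.
#'
#' @param abc an `abc_sample`.
#' @param n_grid grid resolution.
#' @export
abc_posterior_grid <- function(abc, n_grid = 512) {
  acc <- abc$draws[abc$accepted]
  d <- stats::density(acc, n = n_grid)
  new_posterior_grid(d$x, log(pmax(d$y, 1e-300)),
                     meta = list(kind = "abc-kde", n_accepted = length(acc),
                                 seed = abc$seed))
}
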