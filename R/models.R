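#' Parametric model objects
#'
#' A `parametric_model` bundles the log-likelihood of one of the supported
#' families together with its analytic derivatives (where available), the
#' expected information, the third score cumulant, and a seeded simulator.
#' All downstream machinery (modified score equations, matching priors,
#' pseudo-posteriors, e-values, tail-area approximations) consumes this
#' object.
#'
#' Data conventions: univariate families take a numeric vector of
#' observations; logistic regression takes a 0/1 response vector (the design
#' matrix lives in the model); the bivariate regression model takes an
#' n x 2 response matrix.
#'
#' @param family character family id.
#' @param par_names parameter labels, in order.
#' @param interest index of the scalar parameter of interest within theta.
#' @param support 2 x d matrix of open interval bounds (lower row, upper row).
#' @param loglik,score functions of (theta, data).
#' @param info function of (theta, n) returning the expected information for
#'   n observations (design-bound families ignore n).
#' @param cumulant3 function of (theta, n): third cumulant of the score.
#' @param mixed_moment function of (theta, n): E(l'' l') for the score.
#' @param simulate function of (theta, n) drawing a dataset.
#' @param constrained_mle function of (psi, data, start) returning the
#'   nuisance maximizer with the interest component fixed (optional).
#' @param caps named logical capability flags.
#' @param extra list of family-specific payload (design matrices etc.).
#' @return an object of class `parametric_model`.
#' @keywords internal
new_parametric_model <- function(family, par_names, interest = 1L, support,
                                 loglik, score = NULL, info = NULL,
                                 cumulant3 = NULL, mixed_moment = NULL,
                                 simulate = NULL, constrained_mle = NULL,
                                 caps = list(), extra = list()) {
  m <- list(family = family, par_names = par_names, interest = interest,
            support = support, loglik = loglik, score = score, info = info,
            cumulant3 = cumulant3, mixed_moment = mixed_moment,
            simulate = simulate, constrained_mle = constrained_mle,
            caps = caps, extra = extra, npar = length(par_names))
  class(m) <- "parametric_model"
  m
}

#' @export
print.parametric_model <- function(x, ...) {
  cat("<parametric_model>", x$family, "\n")
  cat("  parameters:", paste(x$par_names, collapse = ", "),
      " (interest:", x$par_names[x$interest], ")\n")
  invisible(x)
}

check_theta <- function(model, theta) {
  if (length(theta) != model$npar)
    stop("theta has length ", length(theta), " but model '", model$family,
         "' has ", model$npar, " parameters")
  lo <- model$support[1, ]
  hi <- model$support[2, ]
  if (any(theta <= lo) || any(theta >= hi))
    stop("theta outside the open support of model '", model$family, "'")
  invisible(TRUE)
}

#' Log-likelihood of a model at a parameter point
#'
#' Sum of per-observation log densities.
#'
#' @param model a [parametric_model][new_parametric_model].
#' @param theta parameter vector (in the model's declared order).
#' @param data observations in the model's data convention.
#' @return scalar log-likelihood.
#' @export
loglik <- function(model, theta, data) {
  check_theta(model, theta)
  model$loglik(theta, data)
}

#' Score function (gradient of the log-likelihood)
#'
#' Analytic where the family provides it, otherwise central finite
#' differences of [loglik()].
#'
#' @inheritParams loglik
#' @return gradient vector of length `length(theta)`.
#' @export
score <- function(model, theta, data) {
  check_theta(model, theta)
  if (!is.null(model$score)) return(model$score(theta, data))
  num_grad(function(th) model$loglik(th, data), theta)
}

#' Expected (Fisher) information
#'
#' @inheritParams loglik
#' @param n number of observations the information refers to; ignored by
#'   design-bound families (logistic, bivariate regression) whose
#'   information is fixed by the design.
#' @return information matrix (a 1 x 1 matrix collapses to a scalar).
#' @export
expected_info <- function(model, theta, n = 1) {
  check_theta(model, theta)
  if (is.null(model$info))
    stop("model '", model$family, "' has no expected-information evaluator")
  i <- model$info(theta, n)
  if (is.matrix(i) && nrow(i) == 1) i <- drop(i)
  i
}

#' Simulate a dataset from a model
#'
#' Reproducible given `seed`; the returned object follows the model's data
#' convention and carries a `provenance` attribute recording seed and family.
#'
#' @inheritParams loglik
#' @param n number of observations.
#' @param seed integer seed.
#' @return simulated data.
#' @export
simulate_data <- function(model, theta, n, seed = NULL) {
  check_theta(model, theta)
  if (is.null(model$simulate))
    stop("model '", model$family, "' is not simulable")
  if (!is.null(seed)) set.seed(seed)
  y <- model$simulate(theta, n)
  attr(y, "provenance") <- list(source = "synthetic", family = model$family,
                                theta = theta, n = n, seed = seed)
  y
}

# ---------------------------------------------------------------------------
# Canonical one-parameter exponential family f(y; theta) = exp{theta a(y) -
# K(theta)} b(y).  All score cumulants come from derivatives of K.

#' Canonical one-parameter exponential family
#'
#' Built from the cumulant function K and its first three derivatives; the
#' score is `sum(a(y)) - n K'(theta)`, the information `n K''(theta)` and
#' the third score cumulant `n K'''(theta)`.
#'
#' @param K,K1,K2,K3 cumulant function of the canonical parameter and its
#'   first three derivatives (vectorized in theta).
#' @param a sufficient statistic, a function of one observation (vectorized).
#' @param logb log carrier density (vectorized); defaults to 0.
#' @param simulate function of (theta, n) or NULL.
#' @param support open interval for theta, default the whole line.
#' @param family id used in printouts.
#' @return a `parametric_model`.
#' @examples
#' m <- model_exponential_rate()
#' loglik(m, 1, 1)  # -1
#' @export
model_expfam <- function(K, K1, K2, K3, a = identity, logb = function(y) 0,
                         simulate = NULL, support = c(-Inf, Inf),
                         family = "exp-family-canonical") {
  new_parametric_model(
    family = family, par_names = "theta",
    support = matrix(support, 2, 1),
    loglik = function(theta, y) sum(theta * a(y) - K(theta) + logb(y)),
    score = function(theta, y) sum(a(y)) - length(y) * K1(theta),
    info = function(theta, n) n * K2(theta),
    cumulant3 = function(theta, n) n * K3(theta),
    # l'' is non-random in the canonical parameterization, so E(l'' l') = 0
    mixed_moment = function(theta, n) 0,
    simulate = simulate,
    caps = list(closed_form_K = TRUE, closed_form_information = TRUE,
                simulable = !is.null(simulate)),
    extra = list(K = K, K1 = K1, K2 = K2, K3 = K3, a = a))
}

#' Exponential model, canonical rate parameterization
#'
#' Density theta exp(-theta y): a(y) = -y, K(theta) = -log(theta).
#' @export
model_exponential_rate <- function() {
  model_expfam(K = function(t) -log(t), K1 = function(t) -1 / t,
               K2 = function(t) 1 / t^2, K3 = function(t) -2 / t^3,
               a = function(y) -y,
               simulate = function(theta, n) stats::rexp(n, rate = theta),
               support = c(0, Inf), family = "exponential-rate")
}

#' Poisson model, canonical log-mean parameterization
#'
#' K(theta) = exp(theta); the ratio kappa3/kappa2 is 1 for every theta.
#' @export
model_poisson_canonical <- function() {
  model_expfam(K = exp, K1 = exp, K2 = exp, K3 = exp,
               a = identity, logb = function(y) -lgamma(y + 1),
               simulate = function(theta, n) stats::rpois(n, exp(theta)),
               support = c(-Inf, Inf), family = "poisson-canonical")
}

# ---------------------------------------------------------------------------
# Gamma/exponential scale-type models with known shape, mean parameter psi.

#' Gamma model with known shape, parameterized by its mean
#'
#' f(y; psi) = Gamma(shape, rate = shape / psi); `shape = 1` is the
#' exponential scale model of the worked examples.
#'
#' @param shape known shape parameter.
#' @export
model_gamma_mean <- function(shape = 1) {
  k <- shape
  new_parametric_model(
    family = if (k == 1) "exponential-scale" else sprintf("gamma-mean(shape=%g)", k),
    par_names = "psi", support = matrix(c(0, Inf), 2, 1),
    loglik = function(theta, y)
      sum(stats::dgamma(y, shape = k, rate = k / theta, log = TRUE)),
    score = function(theta, y) k * (sum(y) - length(y) * theta) / theta^2,
    info = function(theta, n) n * k / theta^2,
    # third cumulant of the score: per-obs score k(y - psi)/psi^2 with
    # E(y - psi)^3 = 2 psi^3 / k^2
    cumulant3 = function(theta, n) 2 * n * k / theta^3,
    # Cov(l'', l') = -2k/psi^3 per observation (cancels kappa3 in m_F)
    mixed_moment = function(theta, n) -2 * n * k / theta^3,
    simulate = function(theta, n) stats::rgamma(n, shape = k, rate = k / theta),
    caps = list(closed_form_information = TRUE, simulable = TRUE))
}

#' Exponential scale model f(y; theta) = (1/theta) exp(-y/theta)
#' @export
model_exponential_scale <- function() model_gamma_mean(1)

# ---------------------------------------------------------------------------
# Skew-normal shape model f(y; theta) = 2 phi(y) Phi(y theta), location 0 and
# scale 1 fixed.

#' Expectations of powers of the skew-normal score
#'
#' Computes E[(Y phi(Y theta) / Phi(Y theta))^order] under the skew-normal
#' density 2 phi(y) Phi(y theta) by adaptive quadrature split at 0, with the
#' ratio phi/Phi evaluated in log space (asymptotically expanded in the far
#' lower tail by `pnorm(log.p = TRUE)`).  `order = 2` is the per-observation
#' Fisher information for the shape; `order = 3` the per-observation third
#' score cumulant.
#'
#' @param theta shape parameter.
#' @param order integer 2 or 3 (1 returns 0 analytically: the score has
#'   mean zero).
#' @return scalar expectation.
#' @examples
#' skewnorm_score_expectations(0, 2)  # 2/pi
#' @export
skewnorm_score_expectations <- function(theta, order) {
  if (!order %in% c(1, 2, 3)) stop("order must be 1, 2 or 3")
  if (order == 1) return(0)
  if (theta == 0 && order == 3) return(0)   # integrand odd under y -> -y
  integrand <- function(y) {
    u <- y * theta
    lg <- log(2) + dnorm(y, log = TRUE) + pnorm(u, log.p = TRUE) +
      order * log_mills(u)
    y^order * exp(lg)
  }
  skn_quad(integrand, theta)
}

# Quadrature over the real line split at 0 and at +/- 1/(1+|theta|): for
# large |theta| the integrands kink at 0 and concentrate on a 1/theta scale.
skn_quad <- function(integrand, theta) {
  s <- 1 / (1 + abs(theta))
  cuts <- sort(unique(c(-Inf, -1, -s, 0, s, 1, Inf)))
  tot <- 0
  for (i in seq_len(length(cuts) - 1)) {
    part <- stats::integrate(integrand, cuts[i], cuts[i + 1],
                             rel.tol = 1e-10, abs.tol = 1e-13,
                             subdivisions = 400L, stop.on.error = FALSE)
    if (!part$message %in% c("OK", "the integral is probably divergent"))
      stop("quadrature failed on (", cuts[i], ", ", cuts[i + 1],
           ") for theta = ", theta, ": ", part$message)
    tot <- tot + part$value
  }
  tot
}

# E(l'' l') per observation for the skew-normal shape score.
# l'_1 = y zeta(u), l''_1 = -y^2 zeta(u) (u + zeta(u)), u = y theta.
skewnorm_mixed_moment1 <- function(theta) {
  integrand <- function(y) {
    u <- y * theta
    z <- zeta_ratio(u)
    lg <- log(2) + dnorm(y, log = TRUE) + pnorm(u, log.p = TRUE)
    -y^3 * z^2 * (u + z) * exp(lg)
  }
  skn_quad(integrand, theta)
}

#' Skew-normal shape model
#'
#' Density 2 phi(y) Phi(y theta) with location 0, scale 1 fixed; the scalar
#' shape theta is the parameter of interest.  Information and third score
#' cumulant are computed by quadrature ([skewnorm_score_expectations()]).
#' @export
model_skewnorm <- function() {
  new_parametric_model(
    family = "skew-normal-shape", par_names = "theta",
    support = matrix(c(-Inf, Inf), 2, 1),
    loglik = function(theta, y)
      sum(log(2) + dnorm(y, log = TRUE) + pnorm(y * theta, log.p = TRUE)),
    score = function(theta, y) sum(y * zeta_ratio(y * theta)),
    info = function(theta, n) n * skewnorm_score_expectations(theta, 2),
    cumulant3 = function(theta, n) n * skewnorm_score_expectations(theta, 3),
    mixed_moment = function(theta, n) n * skewnorm_mixed_moment1(theta),
    simulate = function(theta, n) {
      d <- theta / sqrt(1 + theta^2)
      d * abs(stats::rnorm(n)) + sqrt(1 - d^2) * stats::rnorm(n)
    },
    caps = list(simulable = TRUE, quadrature_information = TRUE))
}

# ---------------------------------------------------------------------------
# Logistic regression with a fixed design matrix.

#' Logistic regression model
#'
#' The design matrix (including any intercept column) is bound to the model;
#' data are the 0/1 responses.  The coefficient of interest is selected by
#' `interest`.
#'
#' @param X numeric design matrix (n x p, full rank).
#' @param interest column index of the coefficient of interest.
#' @export
model_logistic <- function(X, interest = 1L) {
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank-deficient")
  p <- ncol(X)
  cn <- colnames(X) %||% paste0("beta", seq_len(p) - 1)
  new_parametric_model(
    family = "logistic-regression", par_names = cn, interest = interest,
    support = matrix(rep(c(-Inf, Inf), p), 2, p),
    loglik = function(theta, y) {
      eta <- drop(X %*% theta)
      sum(y * eta - log1p(exp(-abs(eta))) - pmax(eta, 0))
    },
    score = function(theta, y) {
      pr <- stats::plogis(drop(X %*% theta))
      drop(crossprod(X, y - pr))
    },
    info = function(theta, n) {
      pr <- stats::plogis(drop(X %*% theta))
      crossprod(X, X * (pr * (1 - pr)))
    },
    simulate = function(theta, n) {
      pr <- stats::plogis(drop(X %*% theta))
      stats::rbinom(nrow(X), 1, pr)
    },
    constrained_mle = function(psi, y, start = NULL) {
      off <- psi * X[, interest]
      fit <- suppressWarnings(stats::glm.fit(
        X[, -interest, drop = FALSE], y, family = stats::binomial(),
        offset = off,
        control = stats::glm.control(epsilon = 1e-12, maxit = 200)))
      fit$coefficients
    },
    caps = list(closed_form_information = TRUE, simulable = TRUE),
    extra = list(X = X))
}

# ---------------------------------------------------------------------------
# Bivariate regression: Y_ij = b0 + b1 x1_i + b2 x2_i + eps_ij, j = 1, 2,
# eps_i ~ N2(0, sigma2 * R(rho)).  theta = (b0, b1, b2, sigma2, rho),
# interest rho.

#' Bivariate regression model with equicorrelated paired errors
#'
#' Two responses per unit share the same linear predictor; the error pair is
#' bivariate normal with common variance `sigma2` and correlation `rho`
#' (the parameter of interest).  The constrained maximizer of the nuisance
#' (regression coefficients and variance) given rho is closed-form: the
#' coefficient estimate is ordinary least squares on the within-pair mean
#' and does not depend on rho.
#'
#' @param x1,x2 covariate vectors of length n.
#' @export
model_bivariate_regression <- function(x1, x2) {
  X <- cbind(1, x1, x2)
  n <- nrow(X)
  qform <- function(E, rho) sum(E[, 1]^2 - 2 * rho * E[, 1] * E[, 2] + E[, 2]^2)
  ll <- function(theta, Y) {
    b <- theta[1:3]; s2 <- theta[4]; rho <- theta[5]
    mu <- drop(X %*% b)
    E <- Y - mu
    q <- qform(E, rho)
    -n * log(2 * pi) - n * log(s2) - n / 2 * log1p(-rho^2) -
      q / (2 * s2 * (1 - rho^2))
  }
  new_parametric_model(
    family = "bivariate-regression",
    par_names = c("b0", "b1", "b2", "sigma2", "rho"), interest = 5L,
    support = matrix(c(-Inf, Inf, -Inf, Inf, -Inf, Inf, 0, Inf, -1, 1), 2, 5),
    loglik = ll,
    score = function(theta, Y) {
      b <- theta[1:3]; s2 <- theta[4]; rho <- theta[5]
      E <- Y - drop(X %*% b)
      q <- E[, 1]^2 - 2 * rho * E[, 1] * E[, 2] + E[, 2]^2
      gb <- drop(crossprod(X, (E[, 1] + E[, 2]))) / (s2 * (1 + rho))
      gs2 <- -n / s2 + sum(q) / (2 * s2^2 * (1 - rho^2))
      grho <- n * rho / (1 - rho^2) +
        sum(E[, 1] * E[, 2] * (1 - rho^2) - rho * q) / (s2 * (1 - rho^2)^2)
      c(gb, gs2, grho)
    },
    info = function(theta, nn) {
      # expected information at theta; error-independent of data, computed
      # from the Gaussian model in closed blocks
      s2 <- theta[4]; rho <- theta[5]
      Om <- solve(matrix(c(1, rho, rho, 1), 2) * s2)
      Ib <- crossprod(X) * sum(Om)            # both responses share X beta
      d <- 5
      I <- matrix(0, d, d)
      I[1:3, 1:3] <- Ib
      # (sigma2, rho) block for a bivariate normal with Sigma = s2 R(rho)
      I[4, 4] <- n * 2 / (2 * s2^2)           # d vech
      I[4, 5] <- I[5, 4] <- -n * rho / (s2 * (1 - rho^2))
      I[5, 5] <- n * (1 + rho^2) / (1 - rho^2)^2
      I
    },
    simulate = function(theta, nn) {
      b <- theta[1:3]; s2 <- theta[4]; rho <- theta[5]
      mu <- drop(X %*% b)
      z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
      e1 <- sqrt(s2) * z1
      e2 <- sqrt(s2) * (rho * z1 + sqrt(1 - rho^2) * z2)
      cbind(mu + e1, mu + e2)
    },
    constrained_mle = function(rho, Y, start = NULL) {
      bhat <- stats::lm.fit(X, rowMeans(Y))$coefficients
      E <- Y - drop(X %*% bhat)
      s2 <- qform(E, rho) / (2 * n * (1 - rho^2))
      c(bhat, s2)
    },
    caps = list(simulable = TRUE, closed_form_information = TRUE),
    extra = list(X = X))
}

# ---------------------------------------------------------------------------
# Normal toys used throughout tests and vignettes.

#' Normal model with unknown mean (interest) and variance (nuisance)
#' @export
model_normal <- function() {
  new_parametric_model(
    family = "normal-mean-variance", par_names = c("mu", "sigma2"),
    interest = 1L,
    support = matrix(c(-Inf, Inf, 0, Inf), 2, 2),
    loglik = function(theta, y)
      sum(stats::dnorm(y, theta[1], sqrt(theta[2]), log = TRUE)),
    score = function(theta, y) {
      n <- length(y); r <- y - theta[1]
      c(sum(r) / theta[2], -n / (2 * theta[2]) + sum(r^2) / (2 * theta[2]^2))
    },
    info = function(theta, n)
      diag(c(n / theta[2], n / (2 * theta[2]^2))),
    simulate = function(theta, n) stats::rnorm(n, theta[1], sqrt(theta[2])),
    constrained_mle = function(psi, y, start = NULL) mean((y - psi)^2),
    caps = list(closed_form_information = TRUE, simulable = TRUE))
}

#' Normal model with known variance (scalar mean)
#' @param sigma2 known variance.
#' @export
model_normal_known <- function(sigma2 = 1) {
  new_parametric_model(
    family = "normal-mean-known-variance", par_names = "mu",
    support = matrix(c(-Inf, Inf), 2, 1),
    loglik = function(theta, y)
      sum(stats::dnorm(y, theta, sqrt(sigma2), log = TRUE)),
    score = function(theta, y) sum(y - theta) / sigma2,
    info = function(theta, n) n / sigma2,
    cumulant3 = function(theta, n) 0,
    mixed_moment = function(theta, n) 0,
    simulate = function(theta, n) stats::rnorm(n, theta, sqrt(sigma2)),
    caps = list(closed_form_information = TRUE, simulable = TRUE))
}

# ---------------------------------------------------------------------------

#' Reparameterize a scalar model by a monotone transformation
#'
#' Returns the model expressed in eta = g(theta).  Score, information and
#' score cumulants transform exactly by the chain rule, so equivariance
#' properties of the modified score equations can be checked to machine
#' precision.
#'
#' @param model scalar `parametric_model`.
#' @param trans "log" or "reciprocal", or a list with elements
#'   `g`, `ginv`, `dginv` (first derivative of ginv) and `d2ginv`.
#' @export
reparam_model <- function(model, trans = c("log", "reciprocal")) {
  if (model$npar != 1) stop("reparam_model handles scalar models only")
  if (is.character(trans)) {
    trans <- match.arg(trans)
    tr <- switch(trans,
      log = list(g = log, ginv = exp, dginv = exp, d2ginv = exp,
                 name = "log"),
      reciprocal = list(g = function(x) 1 / x, ginv = function(x) 1 / x,
                        dginv = function(x) -1 / x^2,
                        d2ginv = function(x) 2 / x^3, name = "reciprocal"))
  } else tr <- trans
  lo <- model$support[1, 1]; hi <- model$support[2, 1]
  ends <- sort(c(tr$g(max(lo, if (is.finite(lo)) lo else -Inf)),
                 tr$g(hi)))
  ends[!is.finite(ends) & ends < 0] <- -Inf
  ends[!is.finite(ends) & ends > 0] <- Inf
  base <- model
  new_parametric_model(
    family = paste0(model$family, ":", tr$name %||% "reparam"),
    par_names = paste0(tr$name %||% "g", "(", model$par_names, ")"),
    support = matrix(ends, 2, 1),
    loglik = function(eta, y) base$loglik(tr$ginv(eta), y),
    score = if (!is.null(base$score))
      function(eta, y) base$score(tr$ginv(eta), y) * tr$dginv(eta),
    info = if (!is.null(base$info))
      function(eta, n) base$info(tr$ginv(eta), n) * tr$dginv(eta)^2,
    cumulant3 = if (!is.null(base$cumulant3))
      function(eta, n) base$cumulant3(tr$ginv(eta), n) * tr$dginv(eta)^3,
    mixed_moment = if (!is.null(base$mixed_moment) && !is.null(base$info))
      function(eta, n) {
        th <- tr$ginv(eta)
        base$mixed_moment(th, n) * tr$dginv(eta)^3 +
          base$info(th, n) * tr$dginv(eta) * tr$d2ginv(eta)
      },
    simulate = if (!is.null(base$simulate))
      function(eta, n) base$simulate(tr$ginv(eta), n),
    caps = base$caps,
    extra = list(base = base, trans = tr))
}

#' Detect a monotone (profile) likelihood
#'
#' Checks whether the (profile) score for the interest parameter keeps a
#' constant sign over an expanding bracket, the finite-sample signature of a
#' maximum on the boundary (infinite MLE), e.g. a skew-normal sample with
#' all observations positive or a quasi-separated logistic fit.
#'
#' @inheritParams loglik
#' @param data observations.
#' @param max_half_width widest bracket half-width examined (on the scale of
#'   the interest parameter, after mapping positive supports through log).
#' @return list with `monotone` flag and `direction` (+1, -1 or 0).
#' @export
detect_monotone_likelihood <- function(model, data, max_half_width = 1e6) {
  j <- model$interest
  lo <- model$support[1, j]; hi <- model$support[2, j]
  sc <- function(psi) {
    if (model$npar == 1) return(score(model, psi, data))
    lam <- model$constrained_mle(psi, data)
    th <- numeric(model$npar); th[j] <- psi; th[-j] <- lam
    score(model, th, data)[j]
  }
  # probe points sweeping the whole support: log-spaced toward infinite
  # bounds, geometrically toward finite ones
  grid <- if (!is.finite(lo) && !is.finite(hi)) {
    sort(unique(c(-exp(seq(log(1e-3), log(max_half_width), length.out = 20)),
                  0, exp(seq(log(1e-3), log(max_half_width), length.out = 20)))))
  } else if (is.finite(lo) && !is.finite(hi)) {
    lo + exp(seq(log(1e-6 * max(1, abs(lo))), log(max_half_width),
                 length.out = 41))
  } else if (!is.finite(lo) && is.finite(hi)) {
    hi - exp(seq(log(max_half_width), log(1e-6 * max(1, abs(hi))),
                 length.out = 41))
  } else {
    lo + (hi - lo) * stats::plogis(seq(-18, 18, length.out = 41))
  }
  vals <- vapply(grid, function(p) tryCatch(sc(p), error = function(e) NA_real_),
                 numeric(1))
  vals <- vals[is.finite(vals)]
  if (length(vals) < 3) return(list(monotone = FALSE, direction = 0))
  # a score underflowing to exactly 0 in the far tail counts as no sign change
  if (all(vals >= 0) && any(vals > 0)) return(list(monotone = TRUE, direction = +1))
  if (all(vals <= 0) && any(vals < 0)) return(list(monotone = TRUE, direction = -1))
  list(monotone = FALSE, direction = 0)
}
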