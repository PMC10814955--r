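test_that("score cumulants match closed forms", {
  n <- 8
  cum <- cumulants_scalar(model_exponential_rate(), 2, n)
  expect_equal(cum$kappa2, n / 4)
  expect_equal(cum$kappa3, -2 * n / 8)
  # Poisson canonical: kappa3 / kappa2 = 1 for every theta
  for (th in c(-1, 0, 1.7)) {
    cp <- cumulants_scalar(model_poisson_canonical(), th, 5)
    expect_equal(cp$kappa3 / cp$kappa2, 1)
  }
  expect_equal(cumulants_scalar(model_skewnorm(), 0, 10)$kappa3, 0)
  # Monte Carlo path agrees with the closed form
  mc <- cumulants_scalar(model_exponential_scale(), 1, 10,
                         method = "monte-carlo", replicates = 4000, seed = 5)
  expect_lt(abs(mc$kappa2 - 10), 4 * mc$mc_se["kappa2"])
  expect_lt(abs(mc$kappa3 - 20), 4 * mc$mc_se["kappa3"])
})

test_that("median and Firth corrections reproduce the canonical examples", {
  n <- 6
  # canonical exponential rate: m = -1/(3 theta), mF = -1/theta
  cum <- cumulants_scalar(model_exponential_rate(), 2, n)
  expect_equal(median_correction_scalar(cum), -1 / 6)
  expect_equal(firth_correction_scalar(model_exponential_rate(), 2, n), -1 / 2)
  # sign flag flips the convention
  expect_equal(median_correction_scalar(cum, "as-displayed"), 1 / 6)
  # Poisson canonical: m = 1/6 for all theta
  expect_equal(median_correction_scalar(
    cumulants_scalar(model_poisson_canonical(), 0.3, 4)), 1 / 6)
  # scale and variance-type models have vanishing Firth correction
  expect_equal(firth_correction_scalar(model_exponential_scale(), 1.7, 9), 0)
  expect_equal(firth_correction_scalar(model_gamma_mean(3), 1.2, 9), 0)
  # skew-normal at 0 is symmetric
  expect_equal(median_correction_scalar(
    cumulants_scalar(model_skewnorm(), 0, 5)), 0)
})

test_that("matching log-priors recover the canonical exponents", {
  grid <- seq(0.5, 4, length.out = 801)
  m <- model_exponential_rate()
  li <- sapply(grid, function(t) log(expected_info(m, t, 1)))
  lp_med <- matching_logprior_scalar(m, "median", grid)
  expect_lt(diff(range(lp_med - li / 6)), 1e-7)
  lp_fir <- matching_logprior_scalar(m, "firth", grid)
  expect_lt(diff(range(lp_fir - li / 2)), 1e-7)
  # jeffreys kind returns (1/2) log i directly
  lp_j <- matching_logprior_scalar(m, "jeffreys", grid)
  expect_lt(diff(range(lp_j - li / 2)), 1e-12)
  # scale model: median matching prior is theta^(1/3)
  lp_s <- matching_logprior_scalar(model_exponential_scale(), "median", grid)
  expect_equal(unname(coef(lm(lp_s ~ log(grid)))[2]), 1 / 3, tolerance = 1e-8)
  expect_identical(matching_logprior_scalar(m, "none", grid), numeric(801))
})

test_that("modified score equations have the known closed-form roots", {
  y <- exp_sample(10, 2)
  est <- solve_modified_score(model_exponential_scale(), y, "median")
  expect_equal(est$estimate, 60 / 29, tolerance = 1e-9)
  expect_true(est$converged)
  expect_gt(est$se, 0)
  # equivariance: rate = 1/scale
  est_r <- solve_modified_score(model_exponential_rate(), y, "median")
  expect_equal(est_r$estimate, 29 / 60, tolerance = 1e-9)
  # Firth kind: scale MLE unbiased already, rate shrinks to (n-1)/(n ybar)
  expect_equal(solve_modified_score(model_exponential_scale(), y, "firth")$estimate,
               2, tolerance = 1e-9)
  expect_equal(solve_modified_score(model_exponential_rate(), y, "firth")$estimate,
               9 / 20, tolerance = 1e-9)
  # Poisson with zero counts: MLE diverges, median root finite
  est_p <- solve_modified_score(model_poisson_canonical(), rep(0, 5), "median")
  expect_equal(est_p$estimate, log(1 / 30), tolerance = 1e-9)
  expect_error(solve_modified_score(model_poisson_canonical(), rep(0, 5), "none"),
               class = "evmatch_divergence")
})

test_that("median-kind estimation is equivariant under smooth monotone maps", {
  y <- exp_sample(10, 2)
  base <- solve_modified_score(model_exponential_scale(), y, "median")$estimate
  e_log <- solve_modified_score(reparam_model(model_exponential_scale(), "log"),
                                y, "median")$estimate
  expect_equal(exp(e_log), base, tolerance = 1e-6)
  e_rec <- solve_modified_score(reparam_model(model_exponential_scale(), "reciprocal"),
                                y, "median")$estimate
  expect_equal(1 / e_rec, base, tolerance = 1e-6)
  # skew-normal sample, log of a shifted... use rate model instead for reciprocal
  ys <- simulate_data(model_skewnorm(), 3, 25, seed = 21)
  b <- solve_modified_score(model_skewnorm(), ys, "median")$estimate
  # no closed reparam on the real line with log; check Firth-kind too on scale
  bf <- solve_modified_score(model_exponential_scale(), y, "firth")$estimate
  bf_log <- solve_modified_score(reparam_model(model_exponential_scale(), "log"),
                                 y, "firth")$estimate
  # Firth kind is NOT equivariant in general; in this model both corrections
  # vanish only in the original scale, so the transported root differs
  expect_false(isTRUE(all.equal(exp(bf_log), bf, tolerance = 1e-4)))
  expect_true(is.finite(b))
})

test_that("profile operations reduce to closed forms and to scalar cases", {
  set.seed(31)
  y <- rnorm(25, 1, 2)
  mn <- model_normal()
  pl <- profile_loglik(mn, 0.4, y)
  expect_equal(pl$lambda_hat, mean((y - 0.4)^2))
  expect_equal(profile_score(mn, 0.4, y),
               length(y) * (mean(y) - 0.4) / mean((y - 0.4)^2))
  # at the MLE the profile score vanishes
  expect_lt(abs(profile_score(mn, mean(y), y)), 1e-8)
  # logistic: profile value equals an independent constrained refit
  fx <- separated_logistic_fixture()
  X <- cbind(1, NV = fx$NV, PI = fx$PI, EH = fx$EH)
  m3 <- model_logistic(X, interest = 3L)
  pl3 <- profile_loglik(m3, 0.1, fx$HG)
  ref <- nlminb(rep(0, 3), function(lam)
    -m3$loglik(evmatch:::full_theta(m3, 0.1, lam), fx$HG))
  expect_equal(pl3$value, -ref$objective, tolerance = 1e-8)
  # finite-difference agreement of the profile score
  h <- 1e-5
  fd <- (profile_loglik(m3, 0.1 + h, fx$HG)$value -
           profile_loglik(m3, 0.1 - h, fx$HG)$value) / (2 * h)
  expect_equal(profile_score(m3, 0.1, fx$HG), fd, tolerance = 1e-5)
  # scalar model: profile = genuine
  me <- model_exponential_scale()
  ye <- exp_sample(10, 2)
  expect_identical(profile_loglik(me, 1.5, ye)$value, loglik(me, 1.5, ye))
  expect_identical(profile_score(me, 1.5, ye), score(me, 1.5, ye))
})

test_that("profile cumulants: symmetric model, scalar consistency, positivity", {
  set.seed(41)
  y <- rnorm(20, 0, 1.5)
  cum <- profile_cumulants(model_normal(), mean(y), y, replicates = 600, seed = 2)
  expect_lt(abs(cum$kappa1), 4 * cum$mc_se["kappa1"])
  expect_lt(abs(cum$kappa3), 4 * cum$mc_se["kappa3"])
  expect_gt(cum$kappa2, 0)
  # no-nuisance canonical family: MC matches the closed form within 4 SE
  ye <- exp_sample(10, 1)
  mc <- profile_cumulants(model_exponential_scale(), 1, ye,
                          replicates = 3000, seed = 3, method = "monte-carlo")
  cf <- cumulants_scalar(model_exponential_scale(), 1, 10)
  expect_lt(abs(mc$kappa2 - cf$kappa2), 4 * mc$mc_se["kappa2"])
  expect_lt(abs(mc$kappa3 - cf$kappa3), 4 * mc$mc_se["kappa3"])
  # kappa1 = 0 reduces the profile correction to the scalar one
  expect_equal(median_correction_profile(cf), median_correction_scalar(cf))
})

test_that("modified profile score solver: consistency and separated fixtures", {
  # no-nuisance model: coincides with the scalar solver
  ye <- exp_sample(10, 2)
  a <- solve_modified_profile_score(model_exponential_scale(), ye, "median")
  b <- solve_modified_score(model_exponential_scale(), ye, "median")
  expect_equal(a$estimate, b$estimate, tolerance = 1e-6)
  # bivariate regression: median-corrected rho is finite, inside (-1, 1),
  # and larger than the downward-biased MLE on the rho = 0.95 design
  fx <- generate_fixture("bivariate-regression", seed = 11)
  mb <- model_bivariate_regression(fx$x1, fx$x2)
  Y <- as.matrix(fx[, c("y1", "y2")])
  est <- solve_modified_profile_score(mb, Y, "median", replicates = 400, seed = 2)
  mle <- evmatch:::fit_mle(mb, Y)
  expect_true(est$estimate > -1 && est$estimate < 1)
  expect_gt(est$estimate, mle$psi)
  expect_gt(est$se, 0)
})

test_that("Firth-penalized logistic regression is finite under separation", {
  # intercept-only closed form: logit((k + 1/2)/(n + 1))
  b0 <- firth_logistic_fit(matrix(1, 20, 1), rep(c(0, 1), c(15, 5)))
  expect_equal(as.numeric(b0), qlogis(5.5 / 21), tolerance = 1e-8)
  # separated fixture: penalized fit finite while the MLE diverges
  fx <- separated_logistic_fixture()
  X <- cbind(1, NV = fx$NV, PI = fx$PI, EH = fx$EH)
  fb <- firth_logistic_fit(X, fx$HG)
  expect_true(all(is.finite(fb)))
  expect_true(all(is.finite(attr(fb, "se"))))
  expect_true(detect_monotone_likelihood(model_logistic(X, 2L), fx$HG)$monotone)
  # large well-behaved sample: penalized fit approaches the MLE
  set.seed(61)
  Xb <- cbind(1, rnorm(5000))
  yb <- rbinom(5000, 1, plogis(drop(Xb %*% c(-0.3, 0.8))))
  fit_mle <- glm.fit(Xb, yb, family = binomial())$coefficients
  fb2 <- firth_logistic_fit(Xb, yb)
  expect_lt(max(abs(fb2 - fit_mle)), 5e-3)
  expect_error(firth_logistic_fit(cbind(1, 1:5, 2 * (1:5)), rep(0:1, c(2, 3))),
               "rank")
})
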