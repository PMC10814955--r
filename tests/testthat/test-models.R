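test_that("log-likelihoods match closed forms", {
  expect_equal(loglik(model_exponential_rate(), 1, 1.0), -1.0)
  expect_equal(loglik(model_skewnorm(), 0, 0), log(2 * dnorm(0) * 0.5))
  n <- 17
  X <- cbind(1, rnorm(n))
  expect_equal(loglik(model_logistic(X), c(0, 0), rbinom(n, 1, 0.5)),
               -n * log(2))
  expect_error(loglik(model_exponential_rate(), c(1, 2), 1), "length")
  expect_error(loglik(model_exponential_rate(), -1, 1), "support")
})

test_that("analytic scores agree with finite differences at random points", {
  set.seed(101)
  cases <- list(
    list(m = model_exponential_rate(), y = exp_sample(12, 2),
         draw = function() runif(1, 0.2, 4)),
    list(m = model_exponential_scale(), y = exp_sample(12, 2),
         draw = function() runif(1, 0.2, 4)),
    list(m = model_skewnorm(), y = simulate_data(model_skewnorm(), 3, 15, 7),
         draw = function() runif(1, -4, 4)),
    list(m = model_poisson_canonical(), y = rpois(10, 3),
         draw = function() runif(1, -1, 2)))
  for (cs in cases) {
    for (k in 1:20) {
      th <- cs$draw()
      fd <- evmatch:::num_grad(function(t) loglik(cs$m, t, cs$y), th)
      # relative to the score scale, guarded for near-zero scores at the MLE
      expect_lt(abs(score(cs$m, th, cs$y) - fd), 1e-6 * max(1, abs(fd)))
    }
  }
  # vector models
  Xl <- cbind(1, rnorm(12), rbinom(12, 1, 0.4))
  ml <- model_logistic(Xl)
  yl <- rbinom(12, 1, 0.5)
  bl <- rnorm(3, 0, 0.5)
  expect_equal(score(ml, bl, yl),
               evmatch:::num_grad(function(b) loglik(ml, b, yl), bl),
               tolerance = 1e-6, ignore_attr = TRUE)
  fx <- generate_fixture("bivariate-regression", seed = 11)
  mb <- model_bivariate_regression(fx$x1, fx$x2)
  Y <- as.matrix(fx[, c("y1", "y2")])
  thb <- c(1, 2, -1, 1.3, 0.4)
  expect_equal(score(mb, thb, Y),
               evmatch:::num_grad(function(t) loglik(mb, t, Y), thb),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("expected information matches closed forms and is positive definite", {
  expect_equal(expected_info(model_exponential_rate(), 2, 7), 7 / 4)
  expect_equal(expected_info(model_skewnorm(), 0, 1), 2 / pi, tolerance = 1e-9)
  X <- cbind(1, seq(-1, 1, length.out = 10))
  ml <- model_logistic(X)
  b <- c(0.3, -0.7)
  pr <- plogis(drop(X %*% b))
  expect_equal(expected_info(ml, b), crossprod(X, X * (pr * (1 - pr))),
               ignore_attr = TRUE)
  fx <- generate_fixture("bivariate-regression", seed = 11)
  mb <- model_bivariate_regression(fx$x1, fx$x2)
  ev <- eigen(expected_info(mb, c(1, 2, -1, 1.3, 0.4)))$values
  expect_true(all(ev > 0))
})

test_that("skew-normal score expectations: symmetry, closed form and MC oracle", {
  expect_identical(skewnorm_score_expectations(0, 3), 0)
  expect_equal(skewnorm_score_expectations(0, 2), 2 / pi, tolerance = 1e-8)
  # MC oracle at theta = 3
  set.seed(42)
  y <- simulate_data(model_skewnorm(), 3, 1e5)
  u <- y * 3
  z <- exp(dnorm(u, log = TRUE) - pnorm(u, log.p = TRUE))
  mc <- mean((y * z)^2)
  se <- sd((y * z)^2) / sqrt(length(y))
  expect_lt(abs(skewnorm_score_expectations(3, 2) - mc), 3 * se)
})

test_that("simulation is seed-reproducible and moment-consistent", {
  m <- model_skewnorm()
  y1 <- simulate_data(m, 3, 20, seed = 9)
  y2 <- simulate_data(m, 3, 20, seed = 9)
  expect_identical(as.numeric(y1), as.numeric(y2))
  # long-run fraction of negative draws matches the skew-normal cdf at 0
  yy <- simulate_data(m, 3, 2e5, seed = 10)
  expect_lt(abs(mean(yy < 0) - (0.5 - atan(3) / pi)), 0.004)
  # bivariate design: residual correlation near rho
  fx <- generate_fixture("bivariate-regression", seed = 11)
  mb <- model_bivariate_regression(fx$x1, fx$x2)
  YY <- simulate_data(mb, c(1, 2, -1, 1, 0.95), 20, seed = 12)
  E <- YY - drop(mb$extra$X %*% c(1, 2, -1))
  expect_gt(cor(E[, 1], E[, 2]), 0.85)
})

test_that("Bartlett identities hold empirically for simulable models", {
  for (spec in list(list(m = model_exponential_scale(), th = 1.5),
                    list(m = model_skewnorm(), th = 2))) {
    set.seed(77)
    n <- 10
    R <- 3000
    u <- replicate(R, {
      y <- spec$m$simulate(spec$th, n)
      score(spec$m, spec$th, y)
    })
    se1 <- sd(u) / sqrt(R)
    expect_lt(abs(mean(u)), 4 * se1)
    i_th <- expected_info(spec$m, spec$th, n)
    v <- u^2
    expect_lt(abs(mean(v) - i_th), 4 * sd(v) / sqrt(R))
  }
})

test_that("monotone likelihood detection distinguishes the three designs", {
  m <- model_skewnorm()
  fx_pos <- generate_fixture("skewnormal-allpositive", seed = 3)
  r <- detect_monotone_likelihood(m, fx_pos$y)
  expect_true(r$monotone)
  expect_equal(r$direction, +1)
  fx_mix <- generate_fixture("skewnormal-basic", seed = 1)
  expect_false(detect_monotone_likelihood(m, fx_mix$y)$monotone)
  fxl <- separated_logistic_fixture()
  X <- cbind(1, NV = fxl$NV, PI = fxl$PI, EH = fxl$EH)
  expect_true(detect_monotone_likelihood(model_logistic(X, 2L), fxl$HG)$monotone)
  expect_false(detect_monotone_likelihood(model_logistic(X, 3L), fxl$HG)$monotone)
})
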