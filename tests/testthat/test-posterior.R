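test_that("pseudo-posterior grids normalize and agree with the estimator", {
  # exponential scale, no nuisance: mode equals the median-BR root
  ye <- exp_sample(10, 2)
  g <- build_pseudo_posterior(model_exponential_scale(), ye, "median")
  expect_equal(evmatch:::trapz(g$x, g$dens), 1, tolerance = 1e-6)
  expect_equal(g$mode, 60 / 29, tolerance = 1e-6)
  # Simpson cross-check of the normalization
  n <- length(g$x)
  simp <- sum((g$x[seq(3, n, 2)] - g$x[seq(1, n - 2, 2)]) / 6 *
                (g$dens[seq(1, n - 2, 2)] + 4 * g$dens[seq(2, n - 1, 2)] +
                   g$dens[seq(3, n, 2)]))
  expect_equal(simp, 1, tolerance = 1e-5)
  # normal mean with variance nuisance: mode near ybar (symmetric model;
  # tolerance reflects the Monte Carlo correction noise)
  set.seed(71)
  y <- rnorm(30, 1, 2)
  gm <- build_pseudo_posterior(model_normal(), y, "median",
                               replicates = 1500, seed = 4,
                               grid_points = 301, correction_points = 21)
  expect_lt(abs(gm$mode - mean(y)), 0.03)
})

test_that("flat prior fails on a monotone likelihood, matching priors do not", {
  fx <- generate_fixture("skewnormal-allpositive", seed = 3)
  m <- model_skewnorm()
  expect_error(build_pseudo_posterior(m, fx$y, "flat"),
               class = "evmatch_improper_posterior")
  g <- build_pseudo_posterior(m, fx$y, "median", grid_points = 401)
  expect_true(is.finite(g$mode))
  est <- solve_modified_score(m, fx$y, "median")
  expect_equal(g$mode, est$estimate, tolerance = 1e-4)
})

test_that("quadratic pseudo-posterior is exact for the normal location model", {
  set.seed(81)
  y <- rnorm(40, 2, 1)
  mk <- model_normal_known(1)
  g <- quadratic_pseudo_posterior(mk, y, kind = "none", grid_points = 1001)
  exact <- dnorm(g$x, mean(y), sqrt(1 / 40))
  expect_lt(max(abs(g$dens - exact)), 1e-6)
  # mode of the quadratic form sits at the estimating-equation root
  ye <- exp_sample(20, 1)
  gq <- quadratic_pseudo_posterior(model_exponential_scale(), ye, "median",
                                   grid_points = 801)
  root <- solve_modified_score(model_exponential_scale(), ye, "median")$estimate
  expect_lt(abs(gq$mode - root), diff(range(gq$x)) / 800)
  # sup-norm distance to the exact pseudo-posterior shrinks with n
  sup <- sapply(c(20, 50, 200), function(n) {
    yn <- exp_sample(n, 1)
    g1 <- build_pseudo_posterior(model_exponential_scale(), yn, "median",
                                 grid_points = 601)
    g2 <- quadratic_pseudo_posterior(model_exponential_scale(), yn, "median",
                                     grid_points = 601)
    f2 <- approx(g2$x, g2$dens, xout = g1$x, rule = 2)$y
    max(abs(g1$dens - f2)) / max(g1$dens)
  })
  expect_true(all(diff(sup) < 0))
})

test_that("HPD intervals: normal closed form, level limit, transform containment", {
  gn <- normal_grid()
  h <- hpd_interval(gn, 0.95)
  expect_equal(as.numeric(h), c(-1.959964, 1.959964), tolerance = 5e-3)
  expect_equal(attr(h, "attained"), 0.95, tolerance = 1e-4)
  h99 <- hpd_interval(gn, 0.999)
  expect_true(h99[1] < -3 && h99[2] > 3)
  # a log-normal-ish grid: HPD contains the mode after transformation
  x <- seq(0.01, 15, length.out = 3001)
  gl <- evmatch:::new_posterior_grid(x, dlnorm(x, 0.5, 0.4, log = TRUE))
  hl <- hpd_interval(gl, 0.9)
  expect_true(hl[1] < gl$mode && gl$mode < hl[2])
  # bimodal density returns components with a flag
  gb <- evmatch:::new_posterior_grid(
    seq(-8, 8, length.out = 2001),
    log(0.55 * dnorm(seq(-8, 8, length.out = 2001), -2.5, 0.6) +
          0.45 * dnorm(seq(-8, 8, length.out = 2001), 2.5, 0.6)))
  hb <- hpd_interval(gb, 0.9)
  expect_true(isTRUE(attr(hb, "multimodal")))
  expect_true(is.matrix(hb) && nrow(hb) == 2)
})

test_that("rejection ABC: bookkeeping, reproducibility and conjugate oracle", {
  mk <- model_normal_known(1)
  yobs <- simulate_data(mk, 5, 40, seed = 4)
  sampler <- function(n) runif(n, 2, 8)
  abc <- abc_posterior(mk, sampler, yobs, n_draws = 4000,
                       accept_fraction = 0.05, seed = 6)
  expect_equal(sum(abc$accepted), 200)
  expect_equal(abc$threshold,
               sort(abc$distances)[round(0.05 * 4000)])
  # accept everything
  abc1 <- abc_posterior(mk, sampler, yobs, n_draws = 500,
                        accept_fraction = 1, seed = 6)
  expect_true(all(abc1$accepted))
  # identical seeds give identical accepted sets
  abc2 <- abc_posterior(mk, sampler, yobs, n_draws = 4000,
                        accept_fraction = 0.05, seed = 6)
  expect_identical(abc$draws[abc$accepted], abc2$draws[abc2$accepted])
  # conjugate oracle: flat prior => posterior N(ybar, 1/n)
  abc3 <- abc_posterior(mk, sampler, yobs, n_draws = 20000,
                        accept_fraction = 0.02, summary = "score-grid", seed = 8)
  acc <- abc3$draws[abc3$accepted]
  expect_lt(abs(mean(acc) - mean(yobs)), 3 * sd(acc) / sqrt(10)) # conservative
})

test_that("KDE MAP extraction finds modes and flags mixtures", {
  set.seed(91)
  s <- rnorm(1e5, 5, 1)
  # KDE-mode sampling error at n = 1e5 with the Silverman bandwidth is
  # about 0.055; allow three standard errors
  expect_lt(abs(map_from_samples(s) - 5), 0.17)
  expect_identical(as.numeric(map_from_samples(rep(3.3, 500))), 3.3)
  mix <- c(rnorm(7000, 0, 0.5), rnorm(3000, 4, 0.5))
  mm <- map_from_samples(mix)
  expect_lt(abs(mm - 0), 0.2)
  expect_true(isTRUE(attr(mm, "multimodal")))
  expect_error(map_from_samples(rnorm(20)), "at least 100")
})
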