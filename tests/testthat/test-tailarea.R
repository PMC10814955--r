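test_that("normal location model: r_B* reduces to the exact likelihood root", {
  set.seed(2)
  y <- rnorm(25, 1, 2)
  mk <- model_normal_known(4)
  ctx <- tailarea_context(mk, y)
  psi0 <- mean(y) - 1.3
  rp_exact <- sqrt(25) * (mean(y) - psi0) / 2
  r <- rstar_bayes(ctx, psi0)
  expect_equal(r$rp, rp_exact, tolerance = 1e-7)
  expect_equal(r$qB, rp_exact, tolerance = 1e-6)
  expect_equal(r$rstar, rp_exact, tolerance = 1e-6)
  expect_false(r$interpolated)
  expect_equal(tail_area_probability(ctx, psi0), pnorm(rp_exact),
               tolerance = 1e-7)
  # symmetric marginal: ev = 2 (1 - Phi(rB*))
  ev <- evalue_tailarea(ctx, psi0)
  expect_equal(ev$ev, 2 * (1 - pnorm(abs(rp_exact))), tolerance = 1e-6)
  # at the MLE the root vanishes and ev = 1
  expect_equal(profile_likelihood_root(ctx, ctx$psi_hat), 0)
  expect_equal(evalue_tailarea(ctx, ctx$psi_hat)$ev, 1, tolerance = 1e-6)
  # rp^2 is the profile likelihood-ratio statistic
  expect_equal(r$rp^2, 2 * (ctx$lp_hat - ctx$lp(psi0)), tolerance = 1e-9)
})

test_that("near the maximum the interpolated root stays continuous", {
  ye <- exp_sample(20, 1)
  ctx <- tailarea_context(model_exponential_scale(), ye)
  se <- 1 / sqrt(ctx$jp_hat)
  inside <- rstar_bayes(ctx, ctx$psi_hat + 0.01 * se)
  expect_true(inside$interpolated)
  outside <- rstar_bayes(ctx, ctx$psi_hat + 0.5 * se)
  expect_false(outside$interpolated)
  # interpolation agrees with the formula just outside the window
  edge <- rstar_bayes(ctx, ctx$psi_hat - 0.3 * se)
  expect_true(is.finite(inside$rstar) && is.finite(edge$rstar))
  # at the MLE the tail area is the posterior mass above the mode: exactly
  # the upper tail of the normalized likelihood (a right-skewed density
  # here, so the value sits above 1/2)
  lk <- function(p) sapply(p, function(pp)
    exp(loglik(model_exponential_scale(), pp, ye) - ctx$lp_hat))
  oracle <- integrate(lk, ctx$psi_hat, 60)$value / integrate(lk, 1e-6, 60)$value
  expect_equal(tail_area_probability(ctx, ctx$psi_hat), oracle,
               tolerance = 0.02)
  # symmetric model: exactly one half
  set.seed(3)
  yn <- rnorm(30)
  ctxn <- tailarea_context(model_normal_known(1), yn)
  expect_equal(tail_area_probability(ctxn, ctxn$psi_hat), 0.5,
               tolerance = 1e-6)
})

test_that("tail-area accuracy on exponential and gamma toys is third order", {
  errs <- sapply(c(15, 60), function(n) {
    ye <- exp_sample(n, 1)
    ctx <- tailarea_context(model_exponential_scale(), ye)
    se <- 1 / sqrt(ctx$jp_hat)
    psi0 <- ctx$psi_hat - 1.5 * se
    lk <- function(p) sapply(p, function(pp)
      exp(loglik(model_exponential_scale(), pp, ye) - ctx$lp_hat))
    Z <- integrate(lk, 1e-6, 60)$value
    abs(tail_area_probability(ctx, psi0) - integrate(lk, psi0, 60)$value / Z)
  })
  expect_lt(errs[1], 1e-3)
  expect_lt(errs[2], 1e-4)
  # O(n^{-3/2}) error decay: ratio near (15/60)^{3/2} = 0.125, within x3
  expect_lt(errs[2] / errs[1], 0.375)
  errg <- sapply(c(15, 60), function(n) {
    yg <- gamma_sample(n, 3)
    mg <- model_gamma_mean(3)
    ctx <- tailarea_context(mg, yg)
    se <- 1 / sqrt(ctx$jp_hat)
    psi0 <- ctx$psi_hat - 1.5 * se
    lk <- function(p) sapply(p, function(pp) exp(loglik(mg, pp, yg) - ctx$lp_hat))
    Z <- integrate(lk, 1e-6, 30)$value
    abs(tail_area_probability(ctx, psi0) - integrate(lk, psi0, 30)$value / Z)
  })
  expect_lt(errg[1], 1e-3)
  expect_lt(errg[2], 1e-4)
})

test_that("third-order e-value agrees with grid FBST on the Laplace marginal", {
  ye <- exp_sample(30, 1)
  ctx <- tailarea_context(model_exponential_scale(), ye)
  se <- 1 / sqrt(ctx$jp_hat)
  psi0 <- ctx$psi_hat - 1.7 * se
  x <- seq(max(1e-4, ctx$psi_hat - 8 * se), ctx$psi_hat + 10 * se,
           length.out = 2001)
  gl <- laplace_marginal_posterior(ctx, x)
  expect_equal(evmatch:::trapz(gl$x, gl$dens), 1, tolerance = 1e-6)
  e_tail <- evalue_tailarea(ctx, psi0)$ev
  e_grid <- evalue_exact_1d(gl, psi0)$ev
  expect_lt(abs(e_tail - e_grid), 5e-3)
  # the matching point has equal marginal density on the other side
  ev <- evalue_tailarea(ctx, psi0)
  d <- evmatch:::grid_density_at(gl, ev$boundaries)
  expect_equal(d[1], d[2], tolerance = 1e-2)
})

test_that("Laplace marginal matches the Student-t oracle under a variance nuisance", {
  set.seed(8)
  y <- rnorm(30, 2, 1.5)
  n <- 30
  ctx <- tailarea_context(model_normal(), y)
  se <- 1 / sqrt(ctx$jp_hat)
  x <- seq(ctx$psi_hat - 6 * se, ctx$psi_hat + 6 * se, length.out = 801)
  gl <- laplace_marginal_posterior(ctx, x)
  s2h <- mean((y - mean(y))^2)
  sc <- sqrt(s2h / (n - 3))
  exact <- dt((x - mean(y)) / sc, n - 3) / sc
  expect_lt(max(abs(gl$dens - exact)), 0.01)
})
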