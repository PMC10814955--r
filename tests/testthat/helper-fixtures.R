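# Deterministic toy datasets used across the suite.

# exponential sample with exact mean `mean` (plug-in quantile sample)
exp_sample <- function(n, mean = 1) {
  y <- qexp(ppoints(n))
  y * mean / base::mean(y)
}

# gamma(shape) sample with exact mean 1
gamma_sample <- function(n, shape = 3) {
  y <- qgamma(ppoints(n), shape, shape)
  y / base::mean(y)
}

# standard-normal posterior grid (exactly normal density)
normal_grid <- function(mu = 0, sd = 1, half = 9, npts = 2001) {
  x <- seq(mu - half * sd, mu + half * sd, length.out = npts)
  evmatch:::new_posterior_grid(x, dnorm(x, mu, sd, log = TRUE))
}

separated_logistic_fixture <- function(seed = 5) {
  generate_fixture("logistic-separated", seed = seed)
}
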