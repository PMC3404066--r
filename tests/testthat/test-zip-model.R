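test_that("log posterior matches a naive direct summation", {
  set.seed(21)
  md <- raw_model_data(y = c(0L, 3L, 0L, 1L, 7L),
                       C1 = c(1, 0, 0, 1, 0), C2 = c(0, 1, 0, 0, 0),
                       trend = 2:6,
                       container = c(1L, 1L, 2L, 2L, 3L),
                       household = c(1L, 1L, 1L, 2L, 2L))
  cfg <- mcmc_config()
  params <- list(beta = rnorm(4), delta = rnorm(4) * 0.3,
                 u = rnorm(3), v = rnorm(2), w = rnorm(3) * 0.5,
                 z = rnorm(2) * 0.2,
                 var_u = 1.7, var_v = 0.4, var_w = 0.9, var_z = 0.2)
  # independent oracle: term-by-term summation from the model definition
  naive <- 0
  for (r in 1:5) {
    x <- c(1, md$C1[r], md$C2[r], md$trend[r])
    eta0 <- sum(x * params$beta) + params$u[md$container[r]] +
      params$v[md$household[r]]
    etac <- sum(x * params$delta) + params$w[md$container[r]] +
      params$z[md$household[r]]
    pi <- 1 / (1 + exp(-eta0))
    lam <- exp(etac)
    pr <- (1 - pi) * (md$y[r] == 0) +
      pi * exp(-lam) * lam^md$y[r] / factorial(md$y[r])
    naive <- naive + log(pr)
  }
  for (b in c(params$beta, params$delta)) {
    naive <- naive + dnorm(b, 0, sqrt(1 / cfg$prior_precision_fixed),
                           log = TRUE)
  }
  naive <- naive +
    sum(dnorm(params$u, 0, sqrt(params$var_u), log = TRUE)) +
    sum(dnorm(params$v, 0, sqrt(params$var_v), log = TRUE)) +
    sum(dnorm(params$w, 0, sqrt(params$var_w), log = TRUE)) +
    sum(dnorm(params$z, 0, sqrt(params$var_z), log = TRUE)) +
    sum(dgamma(1 / unlist(params[c("var_u", "var_v", "var_w", "var_z")]),
               shape = cfg$re_precision_shape,
               rate = cfg$re_precision_rate, log = TRUE))
  expect_lt(abs(log_posterior(params, md, cfg) - naive), 1e-8)
})

test_that("with zero random effects the posterior reduces to the fixed-effects ZIP", {
  md <- raw_model_data(y = c(0L, 2L, 5L, 0L), trend = 2:5)
  cfg <- mcmc_config()
  zero_re <- list(u = 0, v = 0, w = 0, z = 0,
                  var_u = 1, var_v = 1, var_w = 1, var_z = 1)
  p1 <- c(list(beta = c(0.5, 0, 0, 0.02), delta = c(1, 0, 0, 0)), zero_re)
  p2 <- c(list(beta = c(-0.4, 0, 0, 0.02), delta = c(1.3, 0, 0, 0)), zero_re)
  flat_ll <- function(p) {
    X <- cbind(1, md$C1, md$C2, md$trend)
    eta0 <- drop(X %*% p$beta); etac <- drop(X %*% p$delta)
    sum(zip_log_pmf(md$y, plogis(-eta0), exp(etac))) +
      sum(dnorm(c(p$beta, p$delta), 0, 100, log = TRUE))
  }
  # RE and variance prior terms are equal constants, so differences agree
  expect_equal(log_posterior(p1, md, cfg) - log_posterior(p2, md, cfg),
               flat_ll(p1) - flat_ll(p2), tolerance = 1e-10)
  # finite even when the zero probability saturates
  p3 <- c(list(beta = c(-30, 0, 0, 0), delta = c(1, 0, 0, 0)), zero_re)
  expect_true(is.finite(log_posterior(p3, raw_model_data(0L), cfg)))
})

test_that("identical seed and data give bit-identical draws", {
  set.seed(77)
  md <- raw_model_data(y = rpois(40, 2), container = rep(1:4, each = 10),
                       household = rep(1:2, each = 20), trend = rep(2:11, 4))
  cfg <- mcmc_config(burn_in = 200, n_iter = 600, thin = 3, seed = 5)
  f1 <- fit_zip_mixed(md, cfg)
  f2 <- fit_zip_mixed(md, cfg)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_zip_mixed(md, mcmc_config(burn_in = 200, n_iter = 600, thin = 3,
                                      seed = 6))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("posterior summaries behave on reference chains", {
  set.seed(101)
  x <- matrix(rnorm(10000), ncol = 1, dimnames = list(NULL, "theta"))
  s <- summarize_posterior(x)
  expect_lt(abs(s$lower + 1.96), 0.05)
  expect_lt(abs(s$upper - 1.96), 0.05)
  expect_lt(abs(s$mce_sd - 0.01), 0.01)
  expect_true(s$converged)
  expect_false(s$significant)

  const <- matrix(1, 500, 1, dimnames = list(NULL, "c"))
  sc <- summarize_posterior(const)
  expect_true(sc$degenerate)
  expect_false(sc$converged)

  # strong autocorrelation inflates the Monte Carlo error
  ar <- numeric(10000); ar[1] <- 0
  for (t in 2:10000) ar[t] <- 0.9 * ar[t - 1] + rnorm(1)
  m_ar <- batch_mce(ar)
  m_iid <- batch_mce(rnorm(10000, sd = sd(ar)))
  expect_gt(m_ar, 2 * m_iid)

  expect_error(summarize_posterior(x[1:50, , drop = FALSE]), "100 draws")
  expect_error(batch_mce(rnorm(30), n_batches = 50), "too short")
})

test_that("random-effect significance counts use credible-interval exclusion", {
  set.seed(31)
  n_draws <- 400
  draws <- cbind(
    "u[1]" = rnorm(n_draws, 5, 0.5),    # entirely positive
    "u[2]" = rnorm(n_draws, -4, 0.5),   # entirely negative
    "u[3]" = rnorm(n_draws, 0, 1),      # includes zero
    "v[1]" = rnorm(n_draws, 0, 1),
    "w[1]" = rnorm(n_draws, 3, 0.2),
    "z[1]" = rnorm(n_draws, 0, 1))
  fake <- structure(list(draws = draws), class = "zip_fit")
  sig <- significant_random_effects(fake)
  zc <- sig[sig$component == "zero" & sig$level == "container", ]
  expect_equal(zc$n_above, 1)
  expect_equal(zc$n_below, 1)
  expect_equal(zc$n_total, 3)
  cc <- sig[sig$component == "count" & sig$level == "container", ]
  expect_equal(cc$n_above, 1)
  expect_equal(sig$n_above[sig$level == "household"], c(0, 0))
})

test_that("with the zero state disabled the count posterior matches the Poisson GLM", {
  set.seed(55)
  n <- 400
  C1 <- rbinom(n, 1, 0.3); C2 <- rbinom(n, 1, 0.3) * (1 - C1)
  trend <- rep(2:11, length.out = n)
  lam <- exp(0.8 + 0.6 * C1 - 0.2 * C2 + 0.05 * trend)
  y <- rpois(n, lam)
  md <- raw_model_data(y, C1, C2, trend)
  # presence probability pinned near 1: a plain Poisson regression
  cfg <- mcmc_config(burn_in = 1000, n_iter = 8000, thin = 4, seed = 8,
                     init_beta = c(30, 0, 0, 0), update_beta = FALSE,
                     update_re = FALSE, update_variances = FALSE)
  fit <- fit_zip_mixed(md, cfg)
  post <- colMeans(fit$draws[, 5:8])
  mle <- coef(glm(y ~ C1 + C2 + trend, family = poisson()))
  expect_true(all(abs(post - mle) < 0.05))
})

test_that("the intercept plus mean container effect is identified across seeds", {
  set.seed(66)
  ds <- make_fixture("tiny", seed = 12)
  md <- build_model_data(ds)
  g <- function(seed) {
    fit <- fit_zip_mixed(md, mcmc_config(burn_in = 1000, n_iter = 8000,
                                         thin = 4, seed = seed))
    chain <- fit$draws[, "delta0"] +
      rowMeans(fit$draws[, grep("^w\\[", colnames(fit$draws)), drop = FALSE])
    c(mean(chain), batch_mce(chain))
  }
  a <- g(1); b <- g(2)
  expect_lt(abs(a[1] - b[1]), 5 * sqrt(a[2]^2 + b[2]^2))
})
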