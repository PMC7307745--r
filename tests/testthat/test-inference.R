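test_that("mcmc configuration is validated", {
  expect_error(mcmc_config(n_iter = 100, n_burnin = 100), "smaller")
  expect_error(mcmc_config(seeds = c(1, 1), n_chains = 2), "distinct")
  cfg <- mcmc_config(n_chains = 3, seed = 5)
  expect_equal(length(cfg$seeds), 3L)
  expect_false(anyDuplicated(cfg$seeds) > 0)
})

test_that("identical seeds and config give identical chains", {
  rec <- tiny_records(80)
  g <- chain5()
  cfg <- mcmc_config(n_chains = 2, n_iter = 200, n_burnin = 100,
                     thin = 2, seed = 7)
  f1 <- run_mcmc(rec, graph = g, config = cfg)
  f2 <- run_mcmc(rec, graph = g, config = cfg)
  expect_identical(f1$chains, f2$chains)
})

test_that("with complete data the imputation machinery is inert", {
  rec <- tiny_records(80)
  g <- chain5()
  f1 <- run_mcmc(rec, graph = g,
                 config = mcmc_config(n_chains = 1, n_iter = 150,
                                      n_burnin = 50, thin = 1,
                                      seed = 3, impute = TRUE))
  f2 <- run_mcmc(rec, graph = g,
                 config = mcmc_config(n_chains = 1, n_iter = 150,
                                      n_burnin = 50, thin = 1,
                                      seed = 3, impute = FALSE))
  expect_identical(f1$chains, f2$chains)
})

test_that("the one-parameter aggregated model matches quadrature", {
  oracle <- quadrature_pi_mean(2, 10)
  fit <- run_mcmc(table = toy_table(2, 10), graph = build_graph("A"),
                  model = toy_model(),
                  config = mcmc_config(n_chains = 2, n_iter = 15000,
                                       n_burnin = 3000, thin = 3,
                                       seed = 42))
  pim <- do.call(rbind, lapply(fit$chains, function(ch) ch$draws$pi))
  expect_lt(abs(mean(pim) - oracle), 0.01)
  ## posterior SD sanity: within 10% of the quadrature SD
  m2 <- integrate(function(t) plogis(t)^2 * dbinom(2, 10, plogis(t)) *
                    dnorm(t, 0, 10), -60, 60, rel.tol = 1e-10)$value /
    integrate(function(t) dbinom(2, 10, plogis(t)) * dnorm(t, 0, 10),
              -60, 60, rel.tol = 1e-10)$value
  expect_lt(abs(sd(pim) - sqrt(m2 - oracle^2)) / sqrt(m2 - oracle^2),
            0.10)
})

test_that("an all-zero outcome keeps the chain finite and small", {
  rec <- tiny_records(60)
  rec$dm <- 0L
  g <- chain5()
  fit <- run_mcmc(rec, graph = g,
                  config = mcmc_config(n_chains = 1, n_iter = 300,
                                       n_burnin = 150, thin = 2,
                                       seed = 1))
  pim <- fit$chains[[1]]$draws$pi
  dmcol <- grep(",dm\\]$", colnames(pim))
  expect_true(all(is.finite(pim)))
  expect_lt(mean(pim[, dmcol]), 0.12)
})

test_that("gelman_rubin reproduces its closed-form example", {
  expect_equal(gelman_rubin(list(c(1, 2, 3), c(1, 2, 3))), 1.0)
  expect_equal(gelman_rubin(list(c(1, 2, 3), c(4, 5, 6))),
               sqrt(5.16667 / 1), tolerance = 1e-5)
  expect_warning(rh <- gelman_rubin(list(rep(2, 5), rep(2, 5))),
                 "zero")
  expect_identical(rh, Inf)
  ## a long converged run split in half is near 1
  set.seed(8)
  x <- rnorm(20000)
  expect_lt(gelman_rubin(list(x[1:10000], x[10001:20000])), 1.05)
  expect_error(gelman_rubin(list(1:3)), "two chains")
})

test_that("effective sample size tracks autocorrelation", {
  set.seed(21)
  x <- rnorm(10000)
  expect_gt(effective_sample_size(x), 8000)
  expect_lte(effective_sample_size(x), 12000)
  ar <- as.numeric(arima.sim(list(ar = 0.9), 20000))
  theory <- 20000 * (1 - 0.9) / (1 + 0.9)
  expect_lt(abs(effective_sample_size(ar) - theory) / theory, 0.30)
  expect_warning(e0 <- effective_sample_size(rep(1, 100)), "constant")
  expect_identical(e0, 0)
  expect_error(effective_sample_size(1:5), "at least 10")
})

test_that("diagnostics report covers monitored scalars", {
  rec <- tiny_records(80)
  fit <- run_mcmc(rec, graph = chain5(),
                  config = mcmc_config(n_chains = 2, n_iter = 300,
                                       n_burnin = 100, thin = 2,
                                       seed = 2))
  d <- mcmc_diagnostics(fit)
  expect_true(all(c("param", "rhat", "ess") %in% names(d)))
  expect_true(any(grepl("^national:", d$param)))
  expect_true(all(d$rhat >= 1 - 1e-12))
  expect_true(is.logical(attr(d, "pass")))
})
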