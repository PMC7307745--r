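test_that("the logit link is stable at extreme linear predictors", {
  expect_equal(inv_logit(0), 0.5)
  expect_equal(inv_logit(logit(0.109)), 0.109)
  ## log-scale likelihood stays finite far beyond double underflow
  expect_true(is.finite(bernoulli_loglik(1, -800)))
  expect_true(is.finite(bernoulli_loglik(0, 800)))
  ## y = 1 with eta -> +Inf contributes 0
  expect_equal(bernoulli_loglik(1, 1e4), 0)
  expect_equal(bernoulli_loglik(1, 0), log(0.5))
})

test_that("individual linear predictor assembles its terms", {
  g <- chain5()
  st <- blank_state(g, outcomes = "dm")
  rec <- data.frame(id = 1, province = "N2", age = 56, male = 1,
                    weight = 1.2)
  expect_equal(individual_linpred(rec, st, 1), 0)

  st$beta["(Intercept)", 1] <- 1.2
  expect_equal(individual_linpred(rec, st, 1), 1.2)

  st2 <- blank_state(g, outcomes = "dm")
  st2$age_center <- 46
  st2$beta["age", 1] <- 0.06
  expect_equal(individual_linpred(rec, st2, 1), 0.06 * 10)

  ## area effects enter through the record's province
  st3 <- blank_state(g, outcomes = "dm")
  st3$u[2, 1] <- 0.7
  st3$v[2, 1] <- -0.2
  expect_equal(individual_linpred(rec, st3, 1), 0.5)

  expect_error(individual_linpred(
    data.frame(id = 1, province = "ZZ", age = 40, male = 0,
               weight = 1), st, 1), "unknown")
})

test_that("likelihood terms match closed forms and are additive", {
  g <- chain5()
  st <- blank_state(g, outcomes = "dm")
  rec <- data.frame(id = 1, province = "N1", age = st$age_center,
                    male = 0, weight = 0, dm = 1L)
  expect_equal(loglik_individual(rec, st), log(0.5))

  rec2 <- rbind(rec, data.frame(id = 2, province = "N4",
                                age = st$age_center + 10, male = 1,
                                weight = 2, dm = 0L))
  expect_equal(loglik_individual(rec2, st),
               loglik_individual(rec2[1, ], st) +
                 loglik_individual(rec2[2, ], st))

  ## binomial aggregate: r=5, n=10, pi=0.5
  tab <- toy_table(5, 10)
  sta <- blank_state(build_graph("A"), outcomes = "dm")
  expect_equal(loglik_aggregate(tab, sta),
               lchoose(10, 5) + 10 * log(0.5))
  expect_equal(loglik_aggregate(toy_table(0, 0), sta), 0)
  expect_error(loglik_aggregate(toy_table(8, 5), sta), "exceeds")

  ## the single-area contribution is maximized at pi = r/n
  ll_at <- function(p) {
    s <- sta; s$alpha[1, 1] <- qlogis(p)
    loglik_aggregate(tab, s)
  }
  expect_gt(ll_at(0.5), ll_at(0.4))
  expect_gt(ll_at(0.5), ll_at(0.6))
})

test_that("log-posterior decomposes exactly and responds to data size", {
  g <- chain5()
  md <- model_spec()
  st <- blank_state(g, outcomes = c("dm", "ob"), model = md)
  set.seed(31)
  st$u <- matrix(rnorm(10, 0, 0.3), 5, 2)
  st$u <- sweep(st$u, 2, colMeans(st$u))
  st$U <- -st$u
  st$v <- matrix(rnorm(10, 0, 0.2), 5, 2)
  st$V <- matrix(rnorm(10, 0, 0.2), 5, 2)
  st$beta[1, ] <- c(-1, 0.5)
  pri <- prior_spec(sigma_df = 4, sigma_scale = diag(2))

  rec <- tiny_records(40, g)[, c("id", "province", "age", "male",
                                 "weight", "dm", "ob")]
  tab <- aggregate_provinces(rec, g, outcomes = c("dm", "ob"))
  lp <- log_posterior(rec, tab, st, pri, g)
  expect_equal(lp, loglik_individual(rec, st) +
                 loglik_aggregate(tab, st) + log_prior(st, pri, g))
  expect_true(is.finite(lp))

  ## zero data: the posterior is the prior
  expect_equal(log_posterior(rec[0, ], tab[tab$n < 0, ], st, pri, g),
               log_prior(st, pri, g))

  ## doubling the records doubles the individual likelihood only
  rec2 <- rbind(rec, transform(rec, id = id + 100))
  expect_equal(loglik_individual(rec2, st),
               2 * loglik_individual(rec, st))

  ## monotonicity: raising the intercept raises every probability
  st_hi <- st; st_hi$beta[1, 1] <- st$beta[1, 1] + 0.5
  eta_lo <- individual_linpred(rec, st, 1)
  eta_hi <- individual_linpred(rec, st_hi, 1)
  expect_true(all(inv_logit(eta_hi) > inv_logit(eta_lo)))
})
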