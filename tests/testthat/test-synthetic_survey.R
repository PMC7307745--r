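test_that("default scenario carries the survey's structure", {
  sc <- default_scenario()
  expect_equal(sc$graph$J, 52L)
  expect_equal(sc$n_total, 4800L)
  expect_equal(sc$p_female, 0.60)
  expect_equal(unname(sc$miss_rates["ldl"]), 0.44)
  expect_true(all(sc$miss_rates[c("dm", "ob", "ht")] < 0.05))
  expect_equal(sum(sc$sample_alloc), sc$n_total)
  expect_gt(sum(sc$sample_alloc == 0), 0)      # unsampled provinces
  expect_equal(sc$graph$n_comp, 1L)            # elongated but connected
})

test_that("degenerate scenario collapses to one prevalence per outcome", {
  sc <- default_scenario(n_total = 2000, gradient_slope = rep(0, 4),
                         tau_u = rep(Inf, 4), tau_v = rep(Inf, 4),
                         Sigma_true = matrix(0, 4, 4))
  sim <- simulate_dataset(sc, seed = 5)
  ## no gradient, no random effects: the truth surface is constant
  for (k in 1:4)
    expect_equal(max(sim$truth$pi_star[, k]) -
                   min(sim$truth$pi_star[, k]), 0)
})

test_that("simulation is reproducible and consistent with its truth", {
  sc <- default_scenario(n_total = 1500)
  a <- simulate_dataset(sc, seed = 42)
  b <- simulate_dataset(sc, seed = 42)
  expect_identical(a$records, b$records)
  d <- simulate_dataset(sc, seed = 43)
  expect_false(identical(a$records, d$records))

  ## realized outcome frequencies match the realized Bernoulli means
  ## to binomial precision
  for (k in seq_along(sc$outcomes)) {
    p <- a$truth$realized_prev[k]
    se <- sqrt(p * (1 - p) / nrow(a$records))
    expect_lt(abs(mean(a$records[[sc$outcomes[k]]]) - p), 3.5 * se)
  }
  ## roughly 60% women
  expect_lt(abs(mean(a$records$male == 0) - 0.60), 0.04)
  ## survey weights normalized to mean one
  expect_equal(mean(a$records$weight), 1, tolerance = 1e-12)
})

test_that("intercept calibration hits the national prevalence targets", {
  sc <- default_scenario()
  sim <- simulate_dataset(sc, seed = 7)
  ## national estimand: unweighted mean over provinces of the truth
  ## surface; band covers calibration Monte-Carlo error plus the
  ## realization noise of the area random effects
  est <- colMeans(sim$truth$pi_star)
  expect_true(all(abs(est - sc$prev_targets) < 0.0075),
              info = paste(round(est, 4), collapse = " "))
})

test_that("a planted hotspot raises the true local prevalence", {
  sc <- default_scenario(n_total = 1000, hotspot_plants = data.frame(
    area = "P07", outcome = "ob", bump = 1.0))
  sim <- simulate_dataset(sc, seed = 3)
  expect_gt(sim$truth$pi_star["P07", "ob"],
            median(sim$truth$pi_star[, "ob"]))
  expect_identical(sim$truth$hotspots, "P07")
})

test_that("missingness masking honours its rates and mechanism", {
  sc <- default_scenario(n_total = 4800)
  sim <- simulate_dataset(sc, seed = 9)
  rec0 <- apply_missingness(sim$records, c(ldl = 0), seed = 1)
  expect_false(anyNA(rec0$ldl))
  rec1 <- apply_missingness(sim$records, c(ldl = 1), seed = 1)
  expect_true(all(is.na(rec1$ldl)))
  rec <- apply_missingness(sim$records, c(ldl = 0.44), seed = 1)
  expect_gt(mean(is.na(rec$ldl)), 0.42)
  expect_lt(mean(is.na(rec$ldl)), 0.46)
  expect_error(apply_missingness(sim$records, c(ldl = 1.2)), "rates")

  ## MAR-by-age: older tertiles more often missing, average preserved
  recm <- apply_missingness(sim$records, c(ldl = 0.44), seed = 2,
                            mechanism = "mar_age")
  ter <- cut(sim$records$age,
             quantile(sim$records$age, c(0, 1/3, 2/3, 1)),
             include.lowest = TRUE, labels = FALSE)
  rates <- tapply(is.na(recm$ldl), ter, mean)
  expect_true(rates[1] < rates[3])
  expect_lt(abs(mean(is.na(recm$ldl)) - 0.44), 0.03)
})

test_that("province aggregation counts cases, missing and totals", {
  g <- triangle_graph()
  rec <- data.frame(id = 1:3, province = "A",
                    age = c(30, 40, 50), male = c(0, 1, 0),
                    weight = 1, dm = c(1L, 0L, NA))
  tab <- aggregate_provinces(rec, g, outcomes = "dm")
  expect_equal(tab$n, c(3L, 0L, 0L))
  expect_equal(tab$r_dm, c(1L, 0L, 0L))
  expect_equal(tab$m_dm, c(1L, 0L, 0L))

  ## empty input: an all-zero table over all areas
  tab0 <- aggregate_provinces(rec[0, ], g, outcomes = "dm")
  expect_equal(nrow(tab0), 3L)
  expect_true(all(tab0$n == 0L) && all(tab0$r_dm == 0L))

  expect_error(aggregate_provinces(
    data.frame(id = 1, province = "Z", age = 1, male = 0, weight = 1,
               dm = 0L), g), "Z")

  ## conservation over a larger simulated table
  sc <- default_scenario(n_total = 900)
  sim <- simulate_dataset(sc, seed = 2)
  rec2 <- apply_missingness(sim$records, sc$miss_rates, seed = 3)
  tab2 <- aggregate_provinces(rec2, sc$graph)
  expect_equal(sum(tab2$n), nrow(rec2))
  for (k in sc$outcomes) {
    obs <- sum(!is.na(rec2[[k]]) & rec2[[k]] == 1)
    expect_equal(sum(tab2[[paste0("r_", k)]]), obs)
    expect_equal(sum(tab2[[paste0("m_", k)]]), sum(is.na(rec2[[k]])))
  }
})
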