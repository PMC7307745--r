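## build a fake chainset with prescribed prevalence draws
fake_fit <- function(pi_draws_by_area, outcomes = "dm", nchain = 2) {
  areas <- names(pi_draws_by_area)
  nd <- length(pi_draws_by_area[[1]])
  pim <- do.call(cbind, pi_draws_by_area)
  colnames(pim) <- as.vector(outer(areas, outcomes, function(a, o)
    paste0("pi[", a, ",", o, "]")))
  chains <- replicate(nchain, list(draws = list(
    pi = pim, tau = matrix(1, nd, 1))), simplify = FALSE)
  structure(list(chains = chains, area_ids = areas,
                 outcomes = outcomes,
                 config = mcmc_config(n_iter = 2, n_burnin = 1)),
            class = "cm_chainset")
}

test_that("national prevalence averages areas then summarizes draws", {
  f <- fake_fit(list(A = rep(0.3, 100), B = rep(0.3, 100),
                     C = rep(0.3, 100)))
  np <- national_prevalence(f)
  expect_equal(np$mean, 0.3)
  expect_equal(np$lo95, 0.3)
  expect_equal(np$hi95, 0.3)

  f2 <- fake_fit(list(A = rep(0.2, 100), B = rep(0.4, 100)))
  expect_equal(national_prevalence(f2)$mean, 0.3)

  ## permuting areas leaves the national summary unchanged
  f3 <- fake_fit(list(B = rep(0.4, 100), A = rep(0.2, 100)))
  expect_equal(national_prevalence(f3)$mean,
               national_prevalence(f2)$mean)

  f4 <- fake_fit(list(A = rep(0.2, 10)))
  expect_error(national_prevalence(f4), "100")
})

test_that("thresholds follow their mode", {
  summ <- data.frame(area = c("A", "B", "C"), outcome = "dm",
                     mean = c(0.10, 0.11, 0.12))
  expect_equal(unname(prevalence_thresholds(summ, "median")), 0.11)
  expect_equal(unname(prevalence_thresholds(summ, "national_mean")),
               0.11)
  expect_equal(unname(prevalence_thresholds(summ, "fixed",
                                            values = 0.11)), 0.11)
  expect_error(prevalence_thresholds(summ[0, ]), "empty")
  expect_error(prevalence_thresholds(summ, "fixed"), "values")
})

test_that("exceedance probability is a strict tail fraction", {
  d <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(exceedance_probability(d, 0.25), 0.5)
  expect_equal(exceedance_probability(d, 0), 1.0)
  expect_equal(exceedance_probability(d, 0.4), 0)  # strict inequality
  expect_error(exceedance_probability(numeric(0), 0.5), "draws")
  ## non-increasing in the threshold
  cs <- seq(0, 1, by = 0.05)
  qs <- vapply(cs, function(c) exceedance_probability(d, c), numeric(1))
  expect_true(all(diff(qs) <= 0))
})

test_that("hotspot flags respect the cutoff, ties excluded", {
  set.seed(5)
  f <- fake_fit(list(A = runif(1000) * 0.2 + 0.25,  # high area
                     B = runif(1000) * 0.2 + 0.05,
                     C = runif(1000) * 0.2 + 0.06))
  hs <- detect_hotspots(f, mode = "fixed", values = 0.2, cutoff = 0.95)
  expect_s3_class(hs, "hotspot_table")
  expect_identical(hs$area[hs$hotspot], "A")
  ## cutoff 1: no hotspot can ever be flagged
  hs1 <- detect_hotspots(f, mode = "fixed", values = 0.2, cutoff = 1)
  expect_false(any(hs1$hotspot))
  ## a tie at the cutoff is not flagged
  hs$exceedance[1] <- 0.95
  expect_false(hs$exceedance[1] > 0.95)
  ## flag set shrinks weakly as the cutoff rises
  n_low <- sum(detect_hotspots(f, mode = "fixed", values = 0.2,
                               cutoff = 0.5)$hotspot)
  n_hi <- sum(detect_hotspots(f, mode = "fixed", values = 0.2,
                              cutoff = 0.9)$hotspot)
  expect_gte(n_low, n_hi)
})

test_that("crude descriptives reproduce count arithmetic", {
  rec <- data.frame(dm = c(rep(1L, 506), rep(0L, 4780 - 506)))
  cd <- crude_descriptives(rec, vars = "dm")
  expect_equal(cd$n, 506)
  expect_equal(cd$pct, 11)

  rec2 <- data.frame(female = c(rep(1L, 2865), rep(0L, 4780 - 2865)))
  expect_equal(crude_descriptives(rec2, vars = "female")$pct, 60)

  rec3 <- data.frame(x = c(rep(1L, 0), rep(0L, 10)))
  expect_equal(crude_descriptives(rec3, vars = "x")$pct, 0)

  ## denominator excludes missing values
  rec4 <- data.frame(y = c(1L, 1L, 0L, NA, NA))
  cd4 <- crude_descriptives(rec4, vars = "y", digits = 1)
  expect_equal(cd4$denom, 3)
  expect_equal(cd4$pct, 66.7)

  ## stratified counts
  rec5 <- data.frame(y = c(1L, 0L, 1L, 1L), g = c("m", "m", "f", "f"))
  cd5 <- crude_descriptives(rec5, vars = "y", by = "g")
  expect_equal(cd5$pct[cd5$group == "f"], 100)
  expect_equal(cd5$pct[cd5$group == "m"], 50)
})

test_that("results round-trip through CSV and GeoJSON", {
  set.seed(6)
  f <- fake_fit(list(A = runif(200, 0.2, 0.4), B = runif(200, 0, 0.2)))
  hs <- detect_hotspots(f)
  csv <- tempfile(fileext = ".csv")
  write_results_csv(hs, csv)
  back <- read.csv(csv)
  expect_equal(nrow(back), nrow(hs))
  expect_equal(back$exceedance, hs$exceedance)

  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(NAME = "A"),
         geometry = list(type = "Point", coordinates = c(-70, -33))),
    list(type = "Feature", properties = list(NAME = "B"),
         geometry = list(type = "Point", coordinates = c(-70, -35)))))
  gin <- tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, gin, auto_unbox = TRUE, null = "null")
  gout <- tempfile(fileext = ".geojson")
  write_hotspot_geojson(hs, gin, gout, property = "NAME")
  res <- jsonlite::read_json(gout)
  expect_equal(res$features[[1]]$properties$dm_mean,
               hs$mean[hs$area == "A"], tolerance = 1e-9)
  expect_false(is.null(res$features[[2]]$properties$dm_hotspot))
})
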