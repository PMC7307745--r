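test_that("build_graph collapses edges and finds components", {
  g <- triangle_graph()
  expect_equal(g$J, 3L)
  expect_equal(nrow(g$edges), 2L)
  expect_equal(g$n_comp, 1L)

  ## duplicate and reversed edges collapse to one
  g2 <- build_graph(c("A", "B"), rbind(c("A", "B"), c("B", "A"),
                                       c("A", "B")))
  expect_equal(nrow(g2$edges), 1L)

  ## empty edge set: all singletons
  g3 <- build_graph(c("A", "B", "C"))
  expect_equal(g3$n_comp, 3L)
  expect_equal(nrow(g3$edges), 0L)

  expect_error(build_graph(c("A", "B"), rbind(c("A", "X"))), "X")
  expect_error(build_graph(c("A", "B"), rbind(c("A", "A"))),
               "self-loop")
  expect_error(build_graph(c("A", "A")), "duplicate")
})

test_that("icar_logdensity matches the pairwise-difference form", {
  g2 <- build_graph(c("A", "B"), rbind(c("A", "B")))
  ## all-zero field: log 1 = 0 and the pairwise sum vanishes
  expect_equal(icar_logdensity(rep(0, 3), 1, triangle_graph()), 0)
  ## hand evaluation: (1/2) log 1 - (1/2) (1.0)^2
  expect_equal(icar_logdensity(c(0.5, -0.5), 1, g2), -0.5)
  expect_equal(icar_logdensity(c(0.5, -0.5), 4, g2),
               0.5 * log(4) - 2.0)

  expect_error(icar_logdensity(c(0.5, -0.5), 0, g2), "tau")
  expect_error(icar_logdensity(c(0.5, -0.5), -1, g2), "tau")
  expect_error(icar_logdensity(c(0.5, 0.5), 1, g2), "constraint")
})

test_that("icar_logdensity obeys the closed-form precision scaling", {
  g <- chain5()
  set.seed(4)
  for (rep in 1:5) {
    u <- rnorm(5)
    u <- u - mean(u)
    ss <- sum((u[g$edges[, 1]] - u[g$edges[, 2]])^2)
    for (tau in c(0.3, 1, 2.5, 7)) {
      expect_equal(icar_logdensity(u, tau, g) - icar_logdensity(u, 1, g),
                   ((5 - 1) / 2) * log(tau) - (tau - 1) / 2 * ss)
    }
  }
})

test_that("sample_icar centres per component and is seed-reproducible", {
  g <- build_graph(c("A", "B", "C", "D", "E"),
                   rbind(c("A", "B"), c("B", "C"), c("D", "E")))
  u1 <- sample_icar(g, tau = 2, seed = 11)
  u2 <- sample_icar(g, tau = 2, seed = 11)
  expect_identical(u1, u2)
  expect_lt(abs(sum(u1[1:3])), 1e-12)
  expect_lt(abs(sum(u1[4:5])), 1e-12)
  expect_error(sample_icar(g, tau = 0), "tau")

  ## singleton components are pinned at zero
  gs <- build_graph(c("A", "B", "C"), rbind(c("A", "B")))
  us <- sample_icar(gs, 1, seed = 3)
  expect_identical(unname(us["C"]), 0)
})

test_that("sample_icar covariance matches the eigen-decomposition oracle", {
  g <- chain5()
  tau <- 1.7
  ## oracle: pseudo-covariance from the Laplacian spectrum
  L <- diag(Matrix::rowSums(g$A)) - as.matrix(g$A)
  ev <- eigen(L, symmetric = TRUE)
  pos <- ev$values > 1e-9
  C_or <- ev$vectors[, pos] %*% diag(1 / (tau * ev$values[pos])) %*%
    t(ev$vectors[, pos])
  set.seed(210)
  ndr <- 40000
  draws <- matrix(NA_real_, ndr, 5)
  for (i in seq_len(ndr)) draws[i, ] <- sample_icar(g, tau)
  C_emp <- cov(draws)
  ## entrywise Monte-Carlo standard error of a covariance estimate
  se <- sqrt((outer(diag(C_or), diag(C_or)) + C_or^2) / ndr)
  expect_true(all(abs(C_emp - C_or) < 3.5 * se))
})

test_that("graph TSV round-trips and GeoJSON ids are readable", {
  g <- triangle_graph()
  tf <- tempfile(fileext = ".tsv")
  write_graph(g, tf)
  g2 <- read_graph(tf, area_ids = g$area_ids)
  expect_identical(g2$edges, g$edges)
  expect_identical(g2$area_ids, g$area_ids)

  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(NAME = "A"),
         geometry = NULL),
    list(type = "Feature", properties = list(NAME = "B"),
         geometry = NULL)))
  gjf <- tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, gjf, auto_unbox = TRUE, null = "null")
  expect_identical(geojson_area_ids(gjf, "NAME"), c("A", "B"))
})
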