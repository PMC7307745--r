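## Synthetic survey generator: a stand-in for national health-survey
## microdata with the statistical structure the joint spatial model
## assumes (elongated chain geography, unequal sampling with unsampled
## areas, survey weights, a latitudinal prevalence gradient, four
## correlated binary outcomes, missing values).

#' Default synthetic-survey scenario
#'
#' Emulates a national cardiometabolic survey over 52 provinces on an
#' elongated, chain-like geography: 4,800 individuals, 60\% women, age
#' truncated-normal 46 (18.5) on 15--95 years, centre-heavy sampling
#' with six unsampled provinces, inverse-sampling-fraction survey
#' weights normalized to mean 1, a north-to-south prevalence gradient,
#' and four correlated outcomes (diabetes `dm`, obesity `ob`,
#' hypertension `ht`, high LDL cholesterol `ldl`) whose intercepts are
#' calibrated so the population-average prevalences equal 10.9, 30.0,
#' 36.4 and 13.7\%.  Default missingness is 44\% on `ldl` and 2\%
#' elsewhere.
#'
#' @param n_total number of sampled individuals.
#' @param J number of provinces.
#' @param gradient_slope per-outcome logit change per latitude rank.
#' @param tau_u,tau_v per-outcome precisions of the ICAR and iid spatial
#'   effects (use `Inf` to switch an effect off).
#' @param Sigma_true covariance of the individual-level joint outcome
#'   random effect (K x K, positive semi-definite; all-zero disables it).
#' @param miss_rates named per-variable missingness fractions.
#' @param hotspot_plants optional data frame with columns `area`,
#'   `outcome`, `bump` adding a logit bump to selected province/outcome
#'   cells (for planted-hotspot studies).
#' @param prev_targets per-outcome population-average prevalences used
#'   to calibrate the intercepts.
#' @param calibrate recalibrate intercepts numerically (default TRUE).
#' @return an object of class `cm_scenario`.
#' @export
default_scenario <- function(n_total = 4800L, J = 52L,
                             gradient_slope = c(dm = -0.008, ob = 0.012,
                                                ht = 0.012, ldl = 0.010),
                             tau_u = rep(40, 4), tau_v = rep(12, 4),
                             Sigma_true = NULL,
                             miss_rates = c(dm = 0.02, ob = 0.02,
                                            ht = 0.02, ldl = 0.44),
                             hotspot_plants = NULL,
                             prev_targets = c(dm = 0.109, ob = 0.300,
                                              ht = 0.364, ldl = 0.137),
                             calibrate = TRUE) {
  K <- length(OUTCOMES)
  area_ids <- sprintf("P%02d", seq_len(J))
  rank <- seq_len(J)
  ## elongated geography: latitude chain plus a few fixed chords
  chord_at <- rank[rank %% 9 == 5 & rank + 2 <= J]
  chords <- if (length(chord_at))
    cbind(area_ids[chord_at], area_ids[chord_at + 2]) else NULL
  graph <- chain_graph(area_ids, chords)

  ## centre-heavy population shares; a capital-like peak mid-chain
  popw <- 0.25 + 2.5 * exp(-((rank - 21)^2) / (2 * 6^2)) +
    0.6 * exp(-((rank - 34)^2) / (2 * 4^2))
  unsampled <- if (J >= 52) c(4L, 43L, 46L, 48L, 49L, 52L) else integer(0)
  unsampled <- unsampled[unsampled <= J]
  sw <- popw
  sw[unsampled] <- 0
  ## non-proportional allocation: small sampled strata are oversampled
  ## to a floor of 1.2% of the sample, as complex national surveys do
  share <- sw / sum(sw)
  share[share > 0] <- pmax(share[share > 0], 0.012)
  share <- share / sum(share)
  sw <- share
  alloc <- floor(sw / sum(sw) * n_total)
  rem <- n_total - sum(alloc)
  if (rem > 0) {
    frac <- sw / sum(sw) * n_total - alloc
    alloc[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      alloc[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
  }
  names(alloc) <- area_ids

  if (is.null(Sigma_true))
    Sigma_true <- 0.25 * (0.7 * diag(K) + 0.3)
  true_fixed <- list(
    intercept = qlogis(unname(prev_targets)),  # recalibrated below
    age       = c(0.06, 0.02, 0.12, 0.04),
    male      = c(0, -0.54, 0.40, 0),
    age_male  = c(0, 0.01, 0, 0),
    weight    = c(0, 0, 0, 0))

  sc <- structure(list(
    graph = graph, latitude_rank = rank, n_total = as.integer(n_total),
    sample_alloc = alloc, p_female = 0.60,
    age_mean = 46, age_sd = 18.5, age_lo = 15, age_hi = 95,
    weight_jitter_sdlog = 0.3, pop_weight = popw,
    outcomes = OUTCOMES, prev_targets = prev_targets,
    true_fixed = true_fixed,
    gradient_slope = unname(gradient_slope),
    tau_u = tau_u, tau_v = tau_v, Sigma_true = Sigma_true,
    miss_rates = miss_rates, hotspot_plants = hotspot_plants),
    class = "cm_scenario")
  validate_scenario(sc)
  if (calibrate) sc$true_fixed$intercept <- calibrate_intercepts(sc)
  sc
}

validate_scenario <- function(sc) {
  stopifnot(sum(sc$sample_alloc) == sc$n_total,
            all(sc$miss_rates >= 0), all(sc$miss_rates <= 1),
            sc$p_female >= 0, sc$p_female <= 1)
  S <- sc$Sigma_true
  if (!isSymmetric(unname(S), tol = 1e-10))
    stop("Sigma_true must be symmetric")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10))
    stop("Sigma_true must be positive semi-definite")
  invisible(sc)
}

## marginal ICAR variances (tau = 1) at each area
icar_marginal_var <- function(graph) {
  eg <- icar_eigen(graph)
  if (!ncol(eg$vectors)) return(rep(0, graph$J))
  rowSums(sweep(eg$vectors^2, 2, eg$values, `/`))
}

## scaling constant making the geometric-mean marginal variance of the
## ICAR field equal 1/tau (so tau is interpretable across geographies)
icar_scale_factor <- function(graph) {
  vu <- icar_marginal_var(graph)
  vu <- vu[vu > 0]
  if (!length(vu)) return(1)
  exp(mean(log(vu)))
}

## per-area survey weights: inverse sampling fraction, mean-1 normalized
area_weights <- function(sc) {
  s <- sc$sample_alloc > 0
  f <- sc$sample_alloc[s] / sc$pop_weight[s]
  w <- 1 / f
  w <- w * sum(sc$sample_alloc[s]) / sum(w * sc$sample_alloc[s])
  out <- rep(NA_real_, sc$graph$J)
  out[s] <- w
  names(out) <- sc$graph$area_ids
  out
}

## deterministic covariate/latent quadrature sample used to calibrate
## intercepts.  The national estimand is the unweighted mean over all
## provinces of the province prevalence for a standard (pooled)
## covariate population, so areas enter uniformly here.
calibration_sample <- function(sc, m = 120000L) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(760001L)
  area <- sample(seq_len(sc$graph$J), m, replace = TRUE)
  age <- rtruncnorm(m, sc$age_mean, sc$age_sd, sc$age_lo, sc$age_hi)
  male <- rbinom(m, 1, 1 - sc$p_female)
  waj <- area_weights(sc)
  waj[is.na(waj)] <- mean(waj, na.rm = TRUE)
  w <- waj[area] * exp(rnorm(m, 0, sc$weight_jitter_sdlog))
  w <- w / mean(w)
  z <- rnorm(m)
  list(area = area, age_c = age - sc$age_mean, male = male, w = w, z = z)
}

calibrate_intercepts <- function(sc) {
  cs <- calibration_sample(sc)
  gv <- icar_scale_factor(sc$graph)
  vu <- icar_marginal_var(sc$graph) / gv
  rk <- sc$latitude_rank - mean(sc$latitude_rank)
  tf <- sc$true_fixed
  vapply(seq_along(sc$outcomes), function(k) {
    lat_var <- (if (is.finite(sc$tau_u[k])) vu / sc$tau_u[k]
                else rep(0, sc$graph$J)) +
      (if (is.finite(sc$tau_v[k])) 1 / sc$tau_v[k] else 0) +
      sc$Sigma_true[k, k]
    base <- tf$age[k] * cs$age_c + tf$male[k] * cs$male +
      tf$age_male[k] * cs$age_c * cs$male + tf$weight[k] * cs$w +
      sc$gradient_slope[k] * rk[cs$area] +
      cs$z * sqrt(lat_var[cs$area])
    target <- unname(sc$prev_targets[k])
    stats::uniroot(function(b0) mean(plogis(b0 + base)) - target,
                   c(-12, 12), tol = 1e-9)$root
  }, numeric(1))
}

#' Simulate a synthetic survey dataset
#'
#' Draws spatial fields, covariates, correlated individual random
#' effects and the four binary outcomes under the scenario's generative
#' model, and records the ground truth (parameters, realized per-area
#' prevalences over a standard population, planted hotspots) before any
#' missingness is applied.
#'
#' @param scenario a `cm_scenario`.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return a list with `records` (data frame: `id`, `province`, `age`,
#'   `male`, `weight`, one 0/1 column per outcome) and `truth`
#'   (class `synthetic_truth`).
#' @export
simulate_dataset <- function(scenario, seed = 1L) {
  sc <- validate_scenario(scenario)
  ev <- eigen(sc$Sigma_true, symmetric = TRUE, only.values = TRUE)$values
  set.seed(seed)
  g <- sc$graph; J <- g$J; K <- length(sc$outcomes)
  eg <- icar_eigen(g)
  gv <- icar_scale_factor(g)
  u <- v <- matrix(0, J, K)
  for (k in seq_len(K)) {
    if (is.finite(sc$tau_u[k]) && ncol(eg$vectors)) {
      uk <- as.numeric(eg$vectors %*%
                         (rnorm(length(eg$values)) /
                            sqrt(gv * sc$tau_u[k] * eg$values)))
      cm <- tapply(uk, g$comp, mean)
      u[, k] <- uk - cm[g$comp]
    }
    if (is.finite(sc$tau_v[k]))
      v[, k] <- rnorm(J, 0, 1 / sqrt(sc$tau_v[k]))
  }

  alloc <- sc$sample_alloc
  n <- sum(alloc)
  area_idx <- rep(seq_len(J), alloc)
  age <- rtruncnorm(n, sc$age_mean, sc$age_sd, sc$age_lo, sc$age_hi)
  male <- rbinom(n, 1, 1 - sc$p_female)
  waj <- area_weights(sc)
  w <- waj[area_idx] * exp(rnorm(n, 0, sc$weight_jitter_sdlog))
  w <- w / mean(w)

  b <- matrix(0, n, K)
  if (any(ev > 1e-12)) {
    ch <- chol(sc$Sigma_true + 1e-12 * diag(K))
    b <- matrix(rnorm(n * K), n, K) %*% ch
  }

  rk <- sc$latitude_rank - mean(sc$latitude_rank)
  plant <- matrix(0, J, K)
  if (!is.null(sc$hotspot_plants)) {
    hp <- sc$hotspot_plants
    ai <- match(as.character(hp$area), g$area_ids)
    ki <- if (is.numeric(hp$outcome)) as.integer(hp$outcome)
          else match(as.character(hp$outcome), sc$outcomes)
    if (anyNA(ai) || anyNA(ki)) stop("unknown area/outcome in hotspot_plants")
    plant[cbind(ai, ki)] <- plant[cbind(ai, ki)] + hp$bump
  }

  tf <- sc$true_fixed
  age_c <- age - sc$age_mean
  ## fixed + individual parts, no area terms (reused for truth surface)
  base <- vapply(seq_len(K), function(k)
    tf$intercept[k] + tf$age[k] * age_c + tf$male[k] * male +
      tf$age_male[k] * age_c * male + tf$weight[k] * w + b[, k],
    numeric(n))
  area_part <- u + v + plant + outer(rk, sc$gradient_slope)
  eta <- base + area_part[area_idx, , drop = FALSE]
  p <- plogis(eta)
  Y <- matrix(rbinom(n * K, 1, p), n, K)
  colnames(Y) <- sc$outcomes

  ## realized true area prevalences over the standard (pooled) population
  pi_star <- matrix(NA_real_, J, K,
                    dimnames = list(g$area_ids, sc$outcomes))
  for (k in seq_len(K))
    pi_star[, k] <- vapply(seq_len(J), function(j)
      mean(plogis(base[, k] + area_part[j, k])), numeric(1))

  records <- data.frame(id = seq_len(n),
                        province = g$area_ids[area_idx],
                        age = age, male = male, weight = w,
                        stringsAsFactors = FALSE)
  records <- cbind(records, as.data.frame(Y))

  truth <- structure(list(
    fixed = tf, age_center = sc$age_mean,
    gradient_slope = sc$gradient_slope,
    u = u, v = v, plant = plant, pi_star = pi_star,
    hotspots = if (!is.null(sc$hotspot_plants))
      as.character(sc$hotspot_plants$area) else character(0),
    realized_prev = colMeans(p),
    prev_targets = sc$prev_targets,
    outcomes = sc$outcomes, seed = seed), class = "synthetic_truth")
  list(records = records, truth = truth)
}

#' Apply missingness to survey records
#'
#' Masks each listed variable independently at its rate.  The default
#' mechanism is MCAR; `"mar_age"` makes the rate depend on the observed
#' age tertile (0.7x / 1x / 1.3x of the nominal rate, preserving the
#' average), giving a missing-at-random mechanism for robustness
#' studies.
#'
#' @param records survey data frame.
#' @param miss_rates named vector of per-variable missingness fractions
#'   in `[0, 1]`.
#' @param seed integer seed.
#' @param mechanism `"mcar"` (default) or `"mar_age"`.
#' @return `records` with masked entries set to `NA`.
#' @export
apply_missingness <- function(records, miss_rates, seed = 1L,
                              mechanism = c("mcar", "mar_age")) {
  mechanism <- match.arg(mechanism)
  if (any(miss_rates < 0 | miss_rates > 1))
    stop("missingness rates must lie in [0, 1]")
  set.seed(seed)
  n <- nrow(records)
  for (vn in names(miss_rates)) {
    r <- miss_rates[[vn]]
    if (r == 0 || !vn %in% names(records)) next
    rate_i <- rep(r, n)
    if (mechanism == "mar_age") {
      ter <- cut(records$age,
                 quantile(records$age, c(0, 1 / 3, 2 / 3, 1),
                          na.rm = TRUE),
                 include.lowest = TRUE, labels = FALSE)
      rate_i <- pmin(1, r * c(0.7, 1, 1.3)[ter])
    }
    mask <- runif(n) < rate_i
    records[[vn]][mask] <- NA
  }
  records
}

#' Aggregate survey records to the province level
#'
#' One row per area of the graph (including unsampled areas, which get
#' `n = 0`): sampled count, per-outcome observed case counts `r_*`
#' (missing outcomes excluded) and missing counts `m_*`, mean age,
#' fraction male and mean survey weight.
#'
#' @param records survey data frame with a `province` column.
#' @param graph an `adjacency_graph` covering all provinces.
#' @param outcomes outcome column names (defaults to the intersection of
#'   the canonical four with the columns present).
#' @return a `province_table` data frame.
#' @export
aggregate_provinces <- function(records, graph,
                                outcomes = intersect(OUTCOMES,
                                                     names(records))) {
  idx <- match(records$province, graph$area_ids)
  if (anyNA(idx))
    stop("records reference unknown areas: ",
         paste(unique(records$province[is.na(idx)]), collapse = ", "))
  J <- graph$J
  f <- factor(idx, levels = seq_len(J))
  tab <- data.frame(area = graph$area_ids,
                    n = as.integer(table(f)),
                    mean_age = as.numeric(tapply(records$age, f, mean,
                                                 na.rm = TRUE)),
                    pct_male = as.numeric(tapply(records$male, f, mean,
                                                 na.rm = TRUE)),
                    mean_weight = as.numeric(tapply(records$weight, f,
                                                    mean, na.rm = TRUE)),
                    stringsAsFactors = FALSE)
  zero_fill <- function(x) { x[is.na(x)] <- 0L; as.integer(x) }
  for (k in outcomes) {
    y <- records[[k]]
    tab[[paste0("r_", k)]] <-
      zero_fill(tapply(ifelse(is.na(y), 0L, y), f, sum))
    tab[[paste0("m_", k)]] <-
      zero_fill(tapply(as.integer(is.na(y)), f, sum))
  }
  attr(tab, "outcomes") <- outcomes
  class(tab) <- c("province_table", "data.frame")
  tab
}
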