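## shared fixtures, built in code

triangle_graph <- function() {
  build_graph(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
}

chain5 <- function() {
  chain_graph(paste0("N", 1:5))
}

## one-area province table with r cases out of n (single outcome dm)
toy_table <- function(r, n, area = "A") {
  tab <- data.frame(area = area, n = as.integer(n), mean_age = 50,
                    pct_male = 0.5, mean_weight = 1,
                    r_dm = as.integer(r), m_dm = 0L,
                    stringsAsFactors = FALSE)
  attr(tab, "outcomes") <- "dm"
  class(tab) <- c("province_table", "data.frame")
  tab
}

## aggregated-only intercept model (no covariates, no random effects)
toy_model <- function() {
  model_spec(individual = FALSE, spatial = FALSE, iid = FALSE,
             joint = FALSE, agg_covariates = character(0))
}

## posterior mean of pi for the one-area binomial with alpha0 ~ N(0, sd)
## by adaptive quadrature (the independent oracle)
quadrature_pi_mean <- function(r, n, sd = 10) {
  num <- integrate(function(t) plogis(t) * dbinom(r, n, plogis(t)) *
                     dnorm(t, 0, sd), -60, 60, rel.tol = 1e-10)$value
  den <- integrate(function(t) dbinom(r, n, plogis(t)) *
                     dnorm(t, 0, sd), -60, 60, rel.tol = 1e-10)$value
  num / den
}

## minimal parameter state for the joint-model API functions
blank_state <- function(graph, outcomes = "dm", model = model_spec(),
                        n_cov = NULL, age_center = 46) {
  model$outcomes <- outcomes
  K <- length(outcomes)
  p <- length(model$ind_covariates) + 1L
  pa <- length(model$agg_covariates) + 1L
  J <- graph$J
  list(model = model, outcomes = outcomes, area_ids = graph$area_ids,
       age_center = age_center,
       beta = matrix(0, p, K,
                     dimnames = list(c("(Intercept)",
                                       model$ind_covariates), outcomes)),
       alpha = matrix(0, pa, K,
                      dimnames = list(c("(Intercept)",
                                        model$agg_covariates), outcomes)),
       u = matrix(0, J, K), v = matrix(0, J, K),
       U = matrix(0, J, K), V = matrix(0, J, K),
       tau_u = rep(1, K), tau_v = rep(1, K),
       tau_U = rep(1, K), tau_V = rep(1, K),
       Sigma = diag(K), b = NULL,
       wmiss = numeric(0), wmiss_mean = 1,
       age_imp = numeric(0), male_imp = integer(0),
       miss_age_idx = integer(0), miss_male_idx = integer(0))
}

## small survey records with all covariates, no missingness
tiny_records <- function(n = 60, graph = chain5(), seed = 99) {
  set.seed(seed)
  data.frame(id = seq_len(n),
             province = sample(graph$area_ids, n, replace = TRUE),
             age = runif(n, 20, 80),
             male = rbinom(n, 1, 0.4),
             weight = exp(rnorm(n, 0, 0.2)),
             dm = rbinom(n, 1, 0.2),
             ob = rbinom(n, 1, 0.3),
             ht = rbinom(n, 1, 0.4),
             ldl = rbinom(n, 1, 0.15),
             stringsAsFactors = FALSE)
}
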