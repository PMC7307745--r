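#' Prior specification for the joint model
#'
#' Defaults follow long-standing disease-mapping practice: vague
#' independent normals on fixed effects, diffuse gamma priors on all
#' precisions, an inverse-Wishart prior on the joint-outcome covariance,
#' and a restricted (truncated-normal around the global mean) prior on
#' the mean survey weight of unsampled provinces.
#'
#' @param sd_fixed prior SD of every fixed effect (normal, mean 0).
#' @param tau_shape,tau_rate gamma shape and rate for all precisions.
#' @param sigma_df inverse-Wishart degrees of freedom for the joint
#'   covariance (default `K + 2`, set when the model is prepared).
#' @param sigma_scale inverse-Wishart scale matrix (default identity).
#' @param wmiss_cv coefficient of variation of the truncated-normal
#'   prior on unsampled-area mean weights (SD = `wmiss_cv` x global
#'   mean weight; truncated at 0).
#' @return a list of class `cm_priors`.
#' @export
prior_spec <- function(sd_fixed = 10, tau_shape = 0.5, tau_rate = 5e-4,
                       sigma_df = NULL, sigma_scale = NULL,
                       wmiss_cv = 0.1) {
  structure(list(sd_fixed = sd_fixed, tau_shape = tau_shape,
                 tau_rate = tau_rate, sigma_df = sigma_df,
                 sigma_scale = sigma_scale, wmiss_cv = wmiss_cv),
            class = "cm_priors")
}

#' Model structure switches
#'
#' Controls which components of the joint hierarchical model are
#' active.  The default is the full model: individual-level and
#' province-aggregated submodels co-run in one chain (sharing no
#' parameters), each with BYM spatial effects (ICAR + iid), a joint
#' multivariate-normal individual random effect linking the outcomes,
#' and the standard covariate set (centered age, sex, their
#' interaction, survey weight).
#'
#' @param individual include the individual-level Bernoulli submodel.
#' @param aggregated include the aggregated binomial submodel.
#' @param spatial include ICAR spatially correlated effects (u, U).
#' @param iid include unstructured heterogeneity effects (v, V).
#' @param joint include the correlated individual random effect b.
#' @param ind_covariates,agg_covariates covariate names among
#'   `"age"`, `"male"`, `"age_male"`, `"weight"` (the intercept is
#'   always present).
#' @param outcomes outcome column names (default: those found in the
#'   data among `dm`, `ob`, `ht`, `ldl`).
#' @return a list of class `cm_model`.
#' @export
model_spec <- function(individual = TRUE, aggregated = TRUE,
                       spatial = TRUE, iid = TRUE, joint = TRUE,
                       ind_covariates = c("age", "male", "age_male",
                                          "weight"),
                       agg_covariates = c("age", "male", "age_male",
                                          "weight"),
                       outcomes = NULL) {
  structure(list(individual = individual, aggregated = aggregated,
                 spatial = spatial, iid = iid, joint = joint,
                 ind_covariates = ind_covariates,
                 agg_covariates = agg_covariates,
                 outcomes = outcomes), class = "cm_model")
}

## design matrix for individual records (intercept first)
ind_design <- function(records, covariates, age_center) {
  n <- nrow(records)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  age_c <- records$age - age_center
  cols <- list(age = age_c, male = records$male,
               age_male = age_c * records$male, weight = records$weight)
  for (cv in covariates) X <- cbind(X, cols[[cv]])
  colnames(X) <- c("(Intercept)", covariates)
  X
}

## design matrix for the province table (intercept first); unsampled
## areas get neutral covariates, their mean weight comes from `wmiss`
agg_design <- function(table, covariates, age_center, wmiss = NULL) {
  J <- nrow(table)
  age_c <- table$mean_age - age_center
  pm <- table$pct_male
  mw <- table$mean_weight
  uns <- table$n == 0
  age_c[uns] <- 0
  pm[uns] <- mean(pm[!uns])
  if (any(uns)) {
    mw[uns] <- if (!is.null(wmiss)) wmiss[table$area[uns]]
               else mean(mw[!uns])
  }
  X <- matrix(1, J, 1)
  cols <- list(age = age_c, male = pm, age_male = age_c * pm,
               weight = mw)
  for (cv in covariates) X <- cbind(X, cols[[cv]])
  colnames(X) <- c("(Intercept)", covariates)
  X
}

## fill missing entries of records from the state's imputations
fill_records <- function(records, state) {
  if (length(state$miss_age_idx))
    records$age[state$miss_age_idx] <- state$age_imp
  if (length(state$miss_male_idx))
    records$male[state$miss_male_idx] <- state$male_imp
  if ("weight" %in% names(records) && anyNA(records$weight))
    records$weight[is.na(records$weight)] <- 1
  records
}

state_area_index <- function(records, state) {
  idx <- match(records$province, state$area_ids)
  if (anyNA(idx))
    stop("records reference areas unknown to the model state: ",
         paste(unique(records$province[is.na(idx)]), collapse = ", "))
  idx
}

#' Individual-level linear predictor
#'
#' `eta_ik = beta0k + beta_age (age - abar) + beta_male male +
#' beta_agemale (age - abar) male + beta_w w + u_{j(i)k} + v_{j(i)k} +
#' b_ik`, with `abar` the age-centering constant stored in the state.
#'
#' @param record one-row data frame (or a full records frame).
#' @param state a `cm_state` parameter state.
#' @param k outcome index.
#' @return numeric vector of linear predictors.
#' @export
individual_linpred <- function(record, state, k) {
  record <- fill_records(record, state)
  idx <- state_area_index(record, state)
  X <- ind_design(record, state$model$ind_covariates, state$age_center)
  eta <- as.numeric(X %*% state$beta[, k])
  if (state$model$spatial) eta <- eta + state$u[idx, k]
  if (state$model$iid) eta <- eta + state$v[idx, k]
  if (state$model$joint && !is.null(state$b) &&
      nrow(state$b) == nrow(record))
    eta <- eta + state$b[, k]
  eta
}

#' Aggregated (province-level) linear predictor
#'
#' `logit(pi_jk) = alpha0k + alpha_age (meanAge_j - abar) +
#' alpha_male pctMale_j + alpha_agemale (meanAge_j - abar) pctMale_j +
#' alpha_w meanW_j + U_jk + V_jk`.
#'
#' @param province_row one-row (or full) `province_table`.
#' @param state a `cm_state`.
#' @param k outcome index.
#' @return numeric vector of logit prevalences.
#' @export
aggregate_linpred <- function(province_row, state, k) {
  X <- agg_design(province_row, state$model$agg_covariates,
                  state$age_center, state$wmiss)
  idx <- match(province_row$area, state$area_ids)
  eta <- as.numeric(X %*% state$alpha[, k])
  if (state$model$spatial) eta <- eta + state$U[idx, k]
  if (state$model$iid) eta <- eta + state$V[idx, k]
  eta
}

#' Individual-level log-likelihood
#'
#' Sum over individuals and outcomes of the Bernoulli log-likelihood at
#' the current parameter state; missing outcomes contribute through
#' their current imputed values (they are treated as unknowns of the
#' model).
#'
#' @param records survey data frame.
#' @param state a `cm_state`.
#' @return scalar log-likelihood.
#' @export
loglik_individual <- function(records, state) {
  K <- length(state$outcomes)
  Y <- as.matrix(records[state$outcomes])
  if (!is.null(state$Y_fill)) Y[is.na(Y)] <- state$Y_fill[is.na(Y)]
  if (anyNA(Y))
    stop("missing outcomes present but no imputed values in state")
  ll <- 0
  for (k in seq_len(K)) {
    eta <- individual_linpred(records, state, k)
    ll <- ll + sum(bernoulli_loglik(Y[, k], eta))
  }
  ll
}

#' Aggregated binomial log-likelihood
#'
#' `r_jk ~ Binomial(n_j - m_jk, pi_jk)` over sampled areas; areas with
#' `n_j = 0` contribute nothing (their prevalence is prior-predicted).
#' Includes the binomial combinatorial constant.
#'
#' @param table a `province_table`.
#' @param state a `cm_state`.
#' @return scalar log-likelihood.
#' @export
loglik_aggregate <- function(table, state) {
  ll <- 0
  for (k in seq_along(state$outcomes)) {
    r <- table[[paste0("r_", state$outcomes[k])]]
    m <- table[[paste0("m_", state$outcomes[k])]]
    size <- table$n - m
    if (any(r > size)) stop("r_jk exceeds n_j - m_jk")
    keep <- size > 0
    if (!any(keep)) next
    eta <- aggregate_linpred(table, state, k)[keep]
    ll <- ll + sum(lchoose(size[keep], r[keep]) +
                     r[keep] * eta - size[keep] * log1pexp(eta))
  }
  ll
}

#' Log-prior of the parameter state
#'
#' Sum of: ICAR terms for `u` and `U`; iid-normal terms for `v` and
#' `V`; the multivariate-normal term for the joint random effects `b`
#' given `Sigma`; independent normals on all fixed effects; gamma terms
#' for all active precisions; the inverse-Wishart term for `Sigma`; and
#' truncated-normal terms for unsampled-area mean weights and any
#' missing-covariate imputations.
#'
#' @param state a `cm_state`.
#' @param priors a `cm_priors`.
#' @param graph the `adjacency_graph`.
#' @return scalar log-prior.
#' @export
log_prior <- function(state, priors, graph) {
  md <- state$model
  K <- length(state$outcomes)
  lp <- sum(dnorm(state$beta, 0, priors$sd_fixed, log = TRUE) *
              (md$individual)) +
        sum(dnorm(state$alpha, 0, priors$sd_fixed, log = TRUE) *
              (md$aggregated))
  gam <- function(x) dgamma(x, priors$tau_shape, rate = priors$tau_rate,
                            log = TRUE)
  for (k in seq_len(K)) {
    if (md$spatial) {
      if (md$individual)
        lp <- lp + icar_logdensity(state$u[, k], state$tau_u[k], graph)
      if (md$aggregated)
        lp <- lp + icar_logdensity(state$U[, k], state$tau_U[k], graph)
    }
    if (md$iid) {
      if (md$individual)
        lp <- lp + sum(dnorm(state$v[, k], 0,
                             1 / sqrt(state$tau_v[k]), log = TRUE))
      if (md$aggregated)
        lp <- lp + sum(dnorm(state$V[, k], 0,
                             1 / sqrt(state$tau_V[k]), log = TRUE))
    }
  }
  if (md$spatial) {
    if (md$individual) lp <- lp + sum(gam(state$tau_u))
    if (md$aggregated) lp <- lp + sum(gam(state$tau_U))
  }
  if (md$iid) {
    if (md$individual) lp <- lp + sum(gam(state$tau_v))
    if (md$aggregated) lp <- lp + sum(gam(state$tau_V))
  }
  if (md$joint && md$individual && !is.null(state$b)) {
    S <- state$Sigma
    ch <- chol(S)
    Q <- chol2inv(ch)
    n <- nrow(state$b)
    lp <- lp - n * sum(log(diag(ch))) - n * K / 2 * log(2 * pi) -
      0.5 * sum((state$b %*% Q) * state$b)
    scale <- priors$sigma_scale %||% diag(K)
    df <- priors$sigma_df %||% (K + 2)
    lp <- lp + ldiwish(S, scale, df)
  }
  if (length(state$wmiss)) {
    mu <- state$wmiss_mean
    sdv <- priors$wmiss_cv * mu
    lp <- lp + sum(dnorm(state$wmiss, mu, sdv, log = TRUE) -
                     pnorm(0, mu, sdv, lower.tail = FALSE, log.p = TRUE))
  }
  if (length(state$age_imp)) {
    lo <- state$age_range[1]; hi <- state$age_range[2]
    Z <- pnorm(hi, state$age_mu, state$age_sdv) -
      pnorm(lo, state$age_mu, state$age_sdv)
    lp <- lp + sum(dnorm(state$age_imp, state$age_mu, state$age_sdv,
                         log = TRUE) - log(Z))
  }
  if (length(state$male_imp)) {
    pm <- state$p_male_hat
    lp <- lp + sum(state$male_imp * log(pm) +
                     (1 - state$male_imp) * log(1 - pm))
  }
  lp
}

#' Joint log-posterior
#'
#' Individual plus aggregated log-likelihoods plus [log_prior()]; the
#' decomposition is exact and each term is finite for a valid state.
#'
#' @param records survey data frame (may be `NULL` when the individual
#'   submodel is off).
#' @param table a `province_table` (may be `NULL` when the aggregated
#'   submodel is off).
#' @param state a `cm_state`.
#' @param priors a `cm_priors`.
#' @param graph the `adjacency_graph`.
#' @return scalar log-posterior (up to the fixed constant conventions
#'   of [icar_logdensity()]).
#' @export
log_posterior <- function(records, table, state, priors, graph) {
  ll <- 0
  if (state$model$individual && !is.null(records) && nrow(records))
    ll <- ll + loglik_individual(records, state)
  if (state$model$aggregated && !is.null(table) && nrow(table))
    ll <- ll + loglik_aggregate(table, state)
  ll + log_prior(state, priors, graph)
}
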