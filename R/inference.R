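#' MCMC run configuration
#'
#' @param n_chains number of chains.
#' @param n_iter iterations per chain.
#' @param n_burnin burn-in iterations (must be `< n_iter`); adaptation
#'   of proposal step sizes is frozen at the end of burn-in.
#' @param thin post-burn-in thinning interval.
#' @param seed base integer seed; per-chain seeds are derived from it
#'   unless `seeds` is given.
#' @param seeds optional explicit per-chain seeds (distinct).
#' @param target_accept target acceptance rate of scalar/single-site
#'   random-walk updates (0.44, the classical optimum).
#' @param rhat_threshold convergence threshold on the potential scale
#'   reduction factor.
#' @param adapt adapt proposal step sizes during burn-in
#'   (Robbins-Monro on the log step).
#' @param impute enable in-chain imputation of missing outcomes and
#'   covariates; if `FALSE`, data must be complete.
#' @return a list of class `cm_mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3L, n_iter = 20000L,
                        n_burnin = 10000L, thin = 5L, seed = 1L,
                        seeds = NULL, target_accept = 0.44,
                        rhat_threshold = 1.1, adapt = TRUE,
                        impute = TRUE) {
  if (n_burnin >= n_iter) stop("n_burnin must be smaller than n_iter")
  if (is.null(seeds)) seeds <- as.integer(seed) + 7919L * (seq_len(n_chains) - 1L)
  if (anyDuplicated(seeds)) stop("per-chain seeds must be distinct")
  if (length(seeds) != n_chains) stop("need one seed per chain")
  structure(list(n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seeds = as.integer(seeds), target_accept = target_accept,
                 rhat_threshold = rhat_threshold, adapt = adapt,
                 impute = impute), class = "cm_mcmc_config")
}

## greedy colouring: groups of mutually non-adjacent areas, so that
## single-site ICAR updates within a group are conditionally
## independent and can be vectorized
colour_classes <- function(graph) {
  J <- graph$J
  col <- integer(J)
  nb <- lapply(seq_len(J), function(j)
    c(graph$edges[graph$edges[, 1] == j, 2],
      graph$edges[graph$edges[, 2] == j, 1]))
  for (j in order(graph$deg, decreasing = TRUE)) {
    used <- col[nb[[j]]]
    col[j] <- min(setdiff(seq_len(J), used))
  }
  split(seq_len(J), col)
}

## ---- main entry -----------------------------------------------------

#' Fit the joint Bayesian hierarchical model by MCMC
#'
#' Runs the individual-level Bernoulli submodel and the
#' province-aggregated binomial submodel together in one
#' Metropolis-within-Gibbs chain.  Sweep order: (1) fixed effects by
#' adaptive scalar random-walk Metropolis; (2) ICAR effects by
#' single-site Metropolis over graph-colour classes followed by
#' per-component re-centering (the component mean is transferred into
#' the intercept); (3) unstructured effects by single-site Metropolis;
#' (4) precisions by conjugate gamma Gibbs; (5) joint individual random
#' effects by per-individual blocked Metropolis and their covariance by
#' conjugate inverse-Wishart Gibbs; (6) missing outcomes drawn exactly
#' from their Bernoulli full conditionals; (7) missing covariates by
#' Metropolis (age) / exact Gibbs (sex), and unsampled-area mean
#' weights from their restricted prior.
#'
#' @param records survey data frame (individual submodel); may be
#'   `NULL` if `model$individual` is `FALSE`.
#' @param table a `province_table`; computed from `records` when `NULL`.
#' @param graph the `adjacency_graph`.
#' @param priors a [prior_spec()].
#' @param config an [mcmc_config()].
#' @param model a [model_spec()].
#' @return an object of class `cm_chainset`.
#' @export
run_mcmc <- function(records = NULL, table = NULL, graph,
                     priors = prior_spec(), config = mcmc_config(),
                     model = model_spec()) {
  prep <- mcmc_prepare(records, table, graph, priors, config, model)
  chains <- lapply(config$seeds, function(s) mcmc_chain(prep, s))
  structure(list(chains = chains, area_ids = graph$area_ids,
                 outcomes = prep$outcomes, config = config,
                 model = prep$model, priors = prep$priors,
                 age_center = prep$age_center,
                 n_records = prep$n %||% 0L),
            class = "cm_chainset")
}

#' @export
print.cm_chainset <- function(x, ...) {
  kept <- nrow(x$chains[[1]]$draws$tau)
  cat("cm_chainset:", length(x$chains), "chains x", kept,
      "kept draws;", length(x$outcomes), "outcomes;",
      length(x$area_ids), "areas\n")
  invisible(x)
}

mcmc_prepare <- function(records, table, graph, priors, config, model) {
  if (is.null(model$outcomes)) {
    src <- if (!is.null(records)) names(records) else
      sub("^r_", "", grep("^r_", names(table), value = TRUE))
    model$outcomes <- intersect(OUTCOMES, src)
    if (!length(model$outcomes)) stop("no outcome columns found")
  }
  outc <- model$outcomes
  K <- length(outc)
  classes <- colour_classes(graph)
  ## low-frequency Laplacian eigenvectors: the slow-mixing directions of
  ## an ICAR field, updated by dedicated blocked proposals
  eg <- icar_eigen(graph)
  nlow <- min(3L, length(eg$values))
  low_idx <- order(eg$values)[seq_len(nlow)]
  prep <- list(graph = graph, J = graph$J, K = K, outcomes = outc,
               model = model, priors = priors, config = config,
               classes = classes,
               Acc = lapply(classes, function(cc)
                 as.matrix(graph$A[cc, , drop = FALSE])),
               Elow = eg$vectors[, low_idx, drop = FALSE],
               lam_low = eg$values[low_idx],
               e1 = graph$edges[, 1], e2 = graph$edges[, 2])

  if (model$individual) {
    if (is.null(records)) stop("individual submodel requires records")
    records <- records[order(match(records$province, graph$area_ids)), ,
                       drop = FALSE]
    n <- nrow(records)
    prep$n <- n
    prep$area_idx <- match(records$province, graph$area_ids)
    if (anyNA(prep$area_idx))
      stop("records reference unknown areas: ",
           paste(unique(records$province[is.na(prep$area_idx)]),
                 collapse = ", "))
    prep$age_center <- mean(records$age, na.rm = TRUE)
    w <- records$weight
    w <- w / mean(w, na.rm = TRUE)
    w[is.na(w)] <- 1
    records$weight <- w
    prep$miss_age <- which(is.na(records$age))
    prep$miss_male <- which(is.na(records$male))
    if (!config$impute && (length(prep$miss_age) ||
                           length(prep$miss_male)))
      stop("missing covariates present but imputation is disabled")
    prep$age_mu <- prep$age_center
    prep$age_sdv <- sd(records$age, na.rm = TRUE)
    prep$age_range <- range(records$age, na.rm = TRUE)
    prep$p_male_hat <- min(max(mean(records$male, na.rm = TRUE),
                               0.01), 0.99)
    records$age[prep$miss_age] <- prep$age_mu
    records$male[prep$miss_male] <- 0L
    prep$X <- ind_design(records, model$ind_covariates, prep$age_center)
    prep$male_vec <- records$male
    Y <- as.matrix(records[outc])
    storage.mode(Y) <- "double"
    prep$miss_y <- lapply(seq_len(K), function(k) which(is.na(Y[, k])))
    if (!config$impute && any(lengths(prep$miss_y)))
      stop("missing outcomes present but imputation is disabled")
    prep$Y <- Y
    prep$rows_by_class <- lapply(prep$classes, function(cc)
      which(prep$area_idx %in% cc))
    prep$subidx_by_class <- lapply(seq_along(prep$classes), function(ci) {
      cc <- prep$classes[[ci]]
      match(prep$area_idx[prep$rows_by_class[[ci]]], cc)
    })
    prep$records <- records
  }

  if (model$aggregated) {
    if (is.null(table)) {
      if (is.null(records)) stop("aggregated submodel requires a table")
      table <- aggregate_provinces(records, graph, outc)
    }
    if (!all(table$area == graph$area_ids))
      table <- table[match(graph$area_ids, table$area), , drop = FALSE]
    r <- sapply(outc, function(k) table[[paste0("r_", k)]])
    m <- sapply(outc, function(k) table[[paste0("m_", k)]])
    r <- matrix(r, ncol = K); m <- matrix(m, ncol = K)
    size <- table$n - m
    if (any(r > size)) stop("observed cases exceed effective sample size")
    prep$r <- r; prep$size <- size
    prep$uns <- which(table$n == 0)
    if (is.null(prep$age_center))
      prep$age_center <- sum(table$mean_age * table$n, na.rm = TRUE) /
        sum(table$n)
    mw <- table$mean_weight
    prep$wmiss_mean <- mean(mw[table$n > 0])
    prep$Xa <- agg_design(table, model$agg_covariates, prep$age_center,
                          wmiss = NULL)
    prep$w_col <- match("weight", colnames(prep$Xa))
    prep$table <- table
  }
  prep$priors$sigma_df <- priors$sigma_df %||% (K + 2)
  prep$priors$sigma_scale <- priors$sigma_scale %||% diag(K)
  prep
}

## one chain; `seed` fully determines the trajectory
mcmc_chain <- function(prep, seed) {
  set.seed(seed)
  cfg <- prep$config; md <- prep$model; pri <- prep$priors
  J <- prep$J; K <- prep$K
  ind <- md$individual; agg <- md$aggregated
  t_acc <- cfg$target_accept
  rm_gain <- function(t) min(0.25, 3 / sqrt(t))
  comp <- prep$graph$comp
  n_comp <- prep$graph$n_comp
  rank_def <- (J - n_comp) / 2
  a0 <- pri$tau_shape; b0 <- pri$tau_rate
  sdf <- pri$sd_fixed

  ## pooled starting prevalences
  p0 <- vapply(seq_len(K), function(k) {
    p <- if (agg) sum(prep$r[, k]) / max(1, sum(prep$size[, k]))
         else mean(prep$Y[, k], na.rm = TRUE)
    min(max(p, 0.01), 0.99)
  }, numeric(1))

  ## --- state ---
  if (ind) {
    X <- prep$X; Y <- prep$Y; aidx <- prep$area_idx; n <- prep$n
    p_ind <- ncol(X)
    beta <- matrix(0, p_ind, K,
                   dimnames = list(colnames(X), prep$outcomes))
    beta[1, ] <- qlogis(p0) + rnorm(K, 0, 0.3)
    ## start the area effects at damped empirical-logit residuals so the
    ## first precision draws see realistically sized fields (an all-zero
    ## start makes the conjugate gamma update collapse them)
    nobs <- rowsum(1 - is.na(prep$Y), prep$area_idx)
    robs <- rowsum(ifelse(is.na(prep$Y), 0, prep$Y), prep$area_idx)
    emp <- matrix(0, J, K)
    emp[as.integer(rownames(nobs)), ] <-
      qlogis((robs + 0.5) / (nobs + 1))
    resid <- pmin(pmax(sweep(emp, 2, qlogis(p0)), -2), 2)
    resid[emp == 0] <- 0
    u <- v <- 0.5 * resid
    for (k in seq_len(K)) {
      mc <- tapply(u[, k], comp, mean)
      u[, k] <- u[, k] - mc[comp]
    }
    b <- matrix(0, n, K)
    tau_u <- rep(25, K); tau_v <- rep(25, K)
    Sigma <- diag(K) * 0.25
    for (k in seq_len(K)) {
      mk <- prep$miss_y[[k]]
      if (length(mk)) Y[mk, k] <- rbinom(length(mk), 1, p0[k])
    }
    age_imp <- rep(prep$age_mu, length(prep$miss_age))
    male_imp <- integer(length(prep$miss_male))
    eta <- X %*% beta + u[aidx, , drop = FALSE] + v[aidx, , drop = FALSE] + b
    L <- log1pexp(eta)
    ls_beta <- matrix(log(0.1), p_ind, K)
    ls_u <- rep(log(0.3), K); ls_v <- rep(log(0.3), K)
    ls_ue <- matrix(log(0.3), ncol(prep$Elow), K)
    ls_b <- log(0.5); ls_age <- log(5)
    ls_shv <- rep(log(0.1), K); ls_shb <- rep(log(0.1), K)
    acc_ct <- c(beta = 0, u = 0, v = 0, b = 0)
    att_ct <- c(beta = 0, u = 0, v = 0, b = 0)
  }
  if (agg) {
    Xa <- prep$Xa; r <- prep$r; size <- prep$size
    p_agg <- ncol(Xa)
    alpha <- matrix(0, p_agg, K,
                    dimnames = list(colnames(Xa), prep$outcomes))
    alpha[1, ] <- qlogis(p0) + rnorm(K, 0, 0.3)
    empA <- qlogis((r + 0.5) / (size + 1))
    residA <- pmin(pmax(sweep(empA, 2, qlogis(p0)), -2), 2)
    residA[size == 0] <- 0
    U <- V <- 0.5 * residA
    for (k in seq_len(K)) {
      mc <- tapply(U[, k], comp, mean)
      U[, k] <- U[, k] - mc[comp]
    }
    tau_U <- rep(25, K); tau_V <- rep(25, K)
    wmiss <- if (length(prep$uns) && !is.na(prep$w_col))
      rep(prep$wmiss_mean, length(prep$uns)) else numeric(0)
    if (length(wmiss) && !is.na(prep$w_col))
      Xa[prep$uns, prep$w_col] <- wmiss
    etaA <- Xa %*% alpha + U + V
    LA <- log1pexp(etaA)
    ls_alpha <- matrix(log(0.2), p_agg, K)
    ls_U <- rep(log(0.5), K); ls_V <- rep(log(0.5), K)
    ls_shV <- rep(log(0.2), K)
    ls_Ue <- matrix(log(0.3), ncol(prep$Elow), K)
    acc_ct <- c(if (ind) acc_ct, alpha = 0, U = 0, V = 0)
    att_ct <- c(if (ind) att_ct, alpha = 0, U = 0, V = 0)
  }

  ## sanity: finite starting log-posterior, with the offending term named
  if (ind && !all(is.finite(eta)))
    stop("non-finite individual linear predictor at initialization")
  if (agg && !all(is.finite(etaA)))
    stop("non-finite aggregated linear predictor at initialization")

  n_kept <- (cfg$n_iter - cfg$n_burnin) %/% cfg$thin
  draw_pi <- if (agg)
    matrix(NA_real_, n_kept, J * K,
           dimnames = list(NULL, as.vector(outer(prep$graph$area_ids,
                                                 prep$outcomes,
                                                 function(a, o)
                                                   paste0("pi[", a, ",", o, "]")))))
  draw_beta <- if (ind)
    matrix(NA_real_, n_kept, length(beta),
           dimnames = list(NULL, as.vector(outer(rownames(beta),
                                                 prep$outcomes, paste,
                                                 sep = ":"))))
  draw_alpha <- if (agg)
    matrix(NA_real_, n_kept, length(alpha),
           dimnames = list(NULL, as.vector(outer(rownames(alpha),
                                                 prep$outcomes, paste,
                                                 sep = ":"))))
  draw_tau <- matrix(NA_real_, n_kept, 4 * K,
                     dimnames = list(NULL,
                       as.vector(outer(prep$outcomes,
                                       c("tau_u", "tau_v", "tau_U",
                                         "tau_V"),
                                       function(o, t) paste0(t, ":", o)))))
  lowtri <- which(lower.tri(diag(K), diag = TRUE), arr.ind = TRUE)
  draw_sig <- if (ind && md$joint)
    matrix(NA_real_, n_kept, nrow(lowtri),
           dimnames = list(NULL, paste0("Sigma[", lowtri[, 1], ",",
                                        lowtri[, 2], "]")))
  draw_imp <- if (ind && any(lengths(prep$miss_y)))
    matrix(NA_real_, n_kept, K,
           dimnames = list(NULL, paste0("imp_mean:", prep$outcomes)))
  kept <- 0L

  for (t in seq_len(cfg$n_iter)) {
    adapting <- cfg$adapt && t <= cfg$n_burnin
    g_t <- rm_gain(t)

    ## (1) fixed effects ------------------------------------------------
    if (ind) {
      for (k in seq_len(K)) for (p in seq_len(p_ind)) {
        delta <- rnorm(1, 0, exp(ls_beta[p, k]))
        etan <- eta[, k] + X[, p] * delta
        Ln <- log1pexp(etan)
        d <- sum(Y[, k] * (etan - eta[, k])) - sum(Ln - L[, k]) +
          dnorm(beta[p, k] + delta, 0, sdf, log = TRUE) -
          dnorm(beta[p, k], 0, sdf, log = TRUE)
        acc <- log(runif(1)) < d
        if (acc) { beta[p, k] <- beta[p, k] + delta
                   eta[, k] <- etan; L[, k] <- Ln }
        if (adapting) ls_beta[p, k] <- ls_beta[p, k] +
            g_t * ((acc * 1) - t_acc)
        if (t > cfg$n_burnin) { acc_ct["beta"] <- acc_ct["beta"] + acc
                                att_ct["beta"] <- att_ct["beta"] + 1 }
      }
    }
    if (agg) {
      for (k in seq_len(K)) for (p in seq_len(p_agg)) {
        delta <- rnorm(1, 0, exp(ls_alpha[p, k]))
        etan <- etaA[, k] + Xa[, p] * delta
        Ln <- log1pexp(etan)
        d <- sum(r[, k] * (etan - etaA[, k])) -
          sum(size[, k] * (Ln - LA[, k])) +
          dnorm(alpha[p, k] + delta, 0, sdf, log = TRUE) -
          dnorm(alpha[p, k], 0, sdf, log = TRUE)
        acc <- log(runif(1)) < d
        if (acc) { alpha[p, k] <- alpha[p, k] + delta
                   etaA[, k] <- etan; LA[, k] <- Ln }
        if (adapting) ls_alpha[p, k] <- ls_alpha[p, k] +
            g_t * ((acc * 1) - t_acc)
        if (t > cfg$n_burnin) { acc_ct["alpha"] <- acc_ct["alpha"] + acc
                                att_ct["alpha"] <- att_ct["alpha"] + 1 }
      }
    }

    ## (1b) intercept/random-effect shift moves: eta-invariant
    ## reparameterization proposals that decorrelate the intercept from
    ## the mean of the unstructured (and joint) effects
    if (ind && md$iid) {
      for (k in seq_len(K)) {
        delta <- rnorm(1, 0, exp(ls_shv[k]))
        d <- dnorm(beta[1, k] + delta, 0, sdf, log = TRUE) -
          dnorm(beta[1, k], 0, sdf, log = TRUE) -
          (tau_v[k] / 2) * (-2 * delta * sum(v[, k]) + J * delta^2)
        acc <- log(runif(1)) < d
        if (acc) { beta[1, k] <- beta[1, k] + delta
                   v[, k] <- v[, k] - delta }
        if (adapting) ls_shv[k] <- ls_shv[k] + g_t * ((acc * 1) - t_acc)
      }
    }
    if (ind && md$joint) {
      Qs <- chol2inv(chol(Sigma))
      cb <- colSums(b %*% Qs)
      for (k in seq_len(K)) {
        delta <- rnorm(1, 0, exp(ls_shb[k]))
        d <- dnorm(beta[1, k] + delta, 0, sdf, log = TRUE) -
          dnorm(beta[1, k], 0, sdf, log = TRUE) -
          0.5 * (-2 * delta * cb[k] + n * delta^2 * Qs[k, k])
        acc <- log(runif(1)) < d
        if (acc) { beta[1, k] <- beta[1, k] + delta
                   b[, k] <- b[, k] - delta
                   cb <- cb - delta * n * Qs[, k] }
        if (adapting) ls_shb[k] <- ls_shb[k] + g_t * ((acc * 1) - t_acc)
      }
    }
    if (agg && md$iid) {
      for (k in seq_len(K)) {
        delta <- rnorm(1, 0, exp(ls_shV[k]))
        d <- dnorm(alpha[1, k] + delta, 0, sdf, log = TRUE) -
          dnorm(alpha[1, k], 0, sdf, log = TRUE) -
          (tau_V[k] / 2) * (-2 * delta * sum(V[, k]) + J * delta^2)
        acc <- log(runif(1)) < d
        if (acc) { alpha[1, k] <- alpha[1, k] + delta
                   V[, k] <- V[, k] - delta }
        if (adapting) ls_shV[k] <- ls_shV[k] + g_t * ((acc * 1) - t_acc)
      }
    }

    ## (2) ICAR spatial effects ----------------------------------------
    if (md$spatial && ind) {
      acc_sum <- 0; acc_n <- 0
      for (ci in seq_along(prep$classes)) {
        cc <- prep$classes[[ci]]
        nc <- length(cc)
        s_nb <- prep$Acc[[ci]] %*% u
        prop <- matrix(rnorm(nc * K), nc, K) *
          rep(exp(ls_u), each = nc)
        ucc <- u[cc, , drop = FALSE]
        un <- ucc + prop
        dpri <- -(sweep(prep$graph$deg[cc] * (un^2 - ucc^2) -
                          2 * s_nb * (un - ucc), 2, tau_u / 2, `*`))
        dll <- matrix(0, nc, K)
        rows <- prep$rows_by_class[[ci]]
        if (length(rows)) {
          a_sub <- prep$subidx_by_class[[ci]]
          etao <- eta[rows, , drop = FALSE]
          etan <- etao + prop[a_sub, , drop = FALSE]
          Ln <- log1pexp(etan)
          dmat <- Y[rows, , drop = FALSE] * (etan - etao) -
            (Ln - L[rows, , drop = FALSE])
          ds <- rowsum(dmat, a_sub)
          dll[as.integer(rownames(ds)), ] <- ds
        }
        accm <- matrix(log(runif(nc * K)), nc, K) < dpri + dll
        u[cc, ][accm] <- un[accm]
        if (length(rows)) {
          accrows <- accm[a_sub, , drop = FALSE]
          eo <- eta[rows, , drop = FALSE]
          eo[accrows] <- etan[accrows]
          eta[rows, ] <- eo
          Lo <- L[rows, , drop = FALSE]
          Lo[accrows] <- Ln[accrows]
          L[rows, ] <- Lo
        }
        acc_sum <- acc_sum + colSums(accm); acc_n <- acc_n + nc
      }
      if (adapting) ls_u <- ls_u + g_t * (acc_sum / acc_n - t_acc)
      if (t > cfg$n_burnin) { acc_ct["u"] <- acc_ct["u"] + sum(acc_sum)
                              att_ct["u"] <- att_ct["u"] + acc_n * K }
      ## per-component re-centering; the mean moves into the intercept
      if (n_comp == 1L) {
        mg <- colMeans(u)
        u <- sweep(u, 2, mg)
        beta[1, ] <- beta[1, ] + mg
      } else for (k in seq_len(K)) {
        mc <- tapply(u[, k], comp, mean)
        u[, k] <- u[, k] - mc[comp]
        mg <- mean(mc)
        beta[1, k] <- beta[1, k] + mg
        shift <- mg - mc[comp[aidx]]
        eta[, k] <- eta[, k] + shift
        L[, k] <- log1pexp(eta[, k])
      }
    }
    if (md$spatial && agg) {
      acc_sum <- 0; acc_n <- 0
      for (ci in seq_along(prep$classes)) {
        cc <- prep$classes[[ci]]
        nc <- length(cc)
        s_nb <- prep$Acc[[ci]] %*% U
        prop <- matrix(rnorm(nc * K), nc, K) *
          rep(exp(ls_U), each = nc)
        Ucc <- U[cc, , drop = FALSE]
        Un <- Ucc + prop
        dpri <- -(sweep(prep$graph$deg[cc] * (Un^2 - Ucc^2) -
                          2 * s_nb * (Un - Ucc), 2, tau_U / 2, `*`))
        etao <- etaA[cc, , drop = FALSE]
        etan <- etao + prop
        Ln <- log1pexp(etan)
        dll <- r[cc, , drop = FALSE] * (etan - etao) -
          size[cc, , drop = FALSE] * (Ln - LA[cc, , drop = FALSE])
        accm <- matrix(log(runif(nc * K)), nc, K) < dpri + dll
        U[cc, ][accm] <- Un[accm]
        eo <- etao; eo[accm] <- etan[accm]; etaA[cc, ] <- eo
        Lo <- LA[cc, , drop = FALSE]; Lo[accm] <- Ln[accm]
        LA[cc, ] <- Lo
        acc_sum <- acc_sum + colSums(accm); acc_n <- acc_n + nc
      }
      if (adapting) ls_U <- ls_U + g_t * (acc_sum / acc_n - t_acc)
      if (t > cfg$n_burnin) { acc_ct["U"] <- acc_ct["U"] + sum(acc_sum)
                              att_ct["U"] <- att_ct["U"] + acc_n * K }
      if (n_comp == 1L) {
        mg <- colMeans(U)
        U <- sweep(U, 2, mg)
        alpha[1, ] <- alpha[1, ] + mg
      } else for (k in seq_len(K)) {
        mc <- tapply(U[, k], comp, mean)
        U[, k] <- U[, k] - mc[comp]
        mg <- mean(mc)
        alpha[1, k] <- alpha[1, k] + mg
        etaA[, k] <- etaA[, k] + (mg - mc[comp])
        LA[, k] <- log1pexp(etaA[, k])
      }
    }

    ## (2b) blocked moves along low-frequency Laplacian eigenvectors:
    ## smooth field components that single-site updates mix poorly
    if (md$spatial && ind && ncol(prep$Elow)) {
      for (q in seq_len(ncol(prep$Elow))) {
        ev <- prep$Elow[, q]
        lam <- prep$lam_low[q]
        proj <- colSums(ev * u)
        delta <- rnorm(K, 0, exp(ls_ue[q, ]))
        dpri <- -(tau_u / 2) * (2 * delta * lam * proj +
                                  delta^2 * lam)
        deta <- outer(ev[aidx], delta)
        etan <- eta + deta
        Ln <- log1pexp(etan)
        dll <- colSums(Y * deta - (Ln - L))
        accl <- log(runif(K)) < dpri + dll
        if (any(accl)) {
          u[, accl] <- u[, accl, drop = FALSE] +
            outer(ev, delta[accl])
          eta[, accl] <- etan[, accl, drop = FALSE]
          L[, accl] <- Ln[, accl, drop = FALSE]
        }
        if (adapting) ls_ue[q, ] <- ls_ue[q, ] +
            g_t * ((accl * 1) - t_acc)
      }
    }
    if (md$spatial && agg && ncol(prep$Elow)) {
      for (q in seq_len(ncol(prep$Elow))) {
        ev <- prep$Elow[, q]
        lam <- prep$lam_low[q]
        proj <- colSums(ev * U)
        delta <- rnorm(K, 0, exp(ls_Ue[q, ]))
        dpri <- -(tau_U / 2) * (2 * delta * lam * proj +
                                  delta^2 * lam)
        deta <- outer(ev, delta)
        etan <- etaA + deta
        Ln <- log1pexp(etan)
        dll <- colSums(r * deta - size * (Ln - LA))
        accl <- log(runif(K)) < dpri + dll
        if (any(accl)) {
          U[, accl] <- U[, accl, drop = FALSE] +
            outer(ev, delta[accl])
          etaA[, accl] <- etan[, accl, drop = FALSE]
          LA[, accl] <- Ln[, accl, drop = FALSE]
        }
        if (adapting) ls_Ue[q, ] <- ls_Ue[q, ] +
            g_t * ((accl * 1) - t_acc)
      }
    }

    ## (3) unstructured heterogeneity ----------------------------------
    if (md$iid && ind) {
      prop <- matrix(rnorm(J * K), J, K) * rep(exp(ls_v), each = J)
      vn <- v + prop
      dpri <- sweep(vn^2 - v^2, 2, tau_v / 2, `*`) * -1
      etan <- eta + prop[aidx, , drop = FALSE]
      Ln <- log1pexp(etan)
      dmat <- Y * (etan - eta) - (Ln - L)
      ds <- rowsum(dmat, aidx)
      dll <- matrix(0, J, K)
      dll[as.integer(rownames(ds)), ] <- ds
      accm <- matrix(log(runif(J * K)), J, K) < dpri + dll
      v[accm] <- vn[accm]
      accrows <- accm[aidx, , drop = FALSE]
      eta[accrows] <- etan[accrows]
      L[accrows] <- Ln[accrows]
      if (adapting) ls_v <- ls_v + g_t * (colMeans(accm) - t_acc)
      if (t > cfg$n_burnin) { acc_ct["v"] <- acc_ct["v"] + sum(accm)
                              att_ct["v"] <- att_ct["v"] + J * K }
    }
    if (md$iid && agg) {
      prop <- matrix(rnorm(J * K), J, K) * rep(exp(ls_V), each = J)
      Vn <- V + prop
      dpri <- sweep(Vn^2 - V^2, 2, tau_V / 2, `*`) * -1
      etan <- etaA + prop
      Ln <- log1pexp(etan)
      dll <- r * (etan - etaA) - size * (Ln - LA)
      accm <- matrix(log(runif(J * K)), J, K) < dpri + dll
      V[accm] <- Vn[accm]
      etaA[accm] <- etan[accm]
      LA[accm] <- Ln[accm]
      if (adapting) ls_V <- ls_V + g_t * (colMeans(accm) - t_acc)
      if (t > cfg$n_burnin) { acc_ct["V"] <- acc_ct["V"] + sum(accm)
                              att_ct["V"] <- att_ct["V"] + J * K }
    }

    ## (4) precisions: conjugate gamma Gibbs ---------------------------
    if (md$spatial && ind)
      tau_u <- vapply(seq_len(K), function(k)
        rgamma(1, a0 + rank_def,
               rate = b0 + 0.5 * sum((u[prep$e1, k] - u[prep$e2, k])^2)),
        numeric(1))
    if (md$iid && ind)
      tau_v <- vapply(seq_len(K), function(k)
        rgamma(1, a0 + J / 2, rate = b0 + 0.5 * sum(v[, k]^2)),
        numeric(1))
    if (md$spatial && agg)
      tau_U <- vapply(seq_len(K), function(k)
        rgamma(1, a0 + rank_def,
               rate = b0 + 0.5 * sum((U[prep$e1, k] - U[prep$e2, k])^2)),
        numeric(1))
    if (md$iid && agg)
      tau_V <- vapply(seq_len(K), function(k)
        rgamma(1, a0 + J / 2, rate = b0 + 0.5 * sum(V[, k]^2)),
        numeric(1))

    ## (5) joint individual random effects + covariance ----------------
    if (md$joint && ind) {
      Q <- chol2inv(chol(Sigma))
      prop <- matrix(rnorm(n * K), n, K) * exp(ls_b)
      bn <- b + prop
      dq <- -0.5 * (rowSums((bn %*% Q) * bn) - rowSums((b %*% Q) * b))
      etan <- eta + prop
      Ln <- log1pexp(etan)
      dll <- rowSums(Y * (etan - eta) - (Ln - L))
      accv <- log(runif(n)) < dq + dll
      b[accv, ] <- bn[accv, , drop = FALSE]
      eta[accv, ] <- etan[accv, , drop = FALSE]
      L[accv, ] <- Ln[accv, , drop = FALSE]
      if (adapting) ls_b <- ls_b + g_t * (mean(accv) - t_acc)
      if (t > cfg$n_burnin) { acc_ct["b"] <- acc_ct["b"] + sum(accv)
                              att_ct["b"] <- att_ct["b"] + n }
      Sigma <- riwish(pri$sigma_scale + crossprod(b),
                      pri$sigma_df + n)
    }

    ## (6) missing outcomes: exact Bernoulli draws ---------------------
    if (ind && cfg$impute) {
      for (k in seq_len(K)) {
        mk <- prep$miss_y[[k]]
        if (length(mk))
          Y[mk, k] <- rbinom(length(mk), 1, plogis(eta[mk, k]))
      }
    }

    ## (7) missing covariates and unsampled-area weights ---------------
    if (ind && cfg$impute && length(prep$miss_age)) {
      rows <- prep$miss_age
      dage <- rnorm(length(rows), 0, exp(ls_age))
      newage <- age_imp + dage
      ok <- newage >= prep$age_range[1] & newage <= prep$age_range[2]
      co_age <- if ("age" %in% colnames(X)) beta["age", ] else rep(0, K)
      co_am <- if ("age_male" %in% colnames(X)) beta["age_male", ]
               else rep(0, K)
      deta <- outer(dage, co_age) +
        outer(dage * prep$male_vec[rows], co_am)
      etan <- eta[rows, , drop = FALSE] + deta
      Ln <- log1pexp(etan)
      dll <- rowSums(Y[rows, , drop = FALSE] *
                       (etan - eta[rows, , drop = FALSE]) -
                       (Ln - L[rows, , drop = FALSE]))
      dpri <- dnorm(newage, prep$age_mu, prep$age_sdv, log = TRUE) -
        dnorm(age_imp, prep$age_mu, prep$age_sdv, log = TRUE)
      accv <- ok & (log(runif(length(rows))) < dll + dpri)
      age_imp[accv] <- newage[accv]
      if (any(accv)) {
        rws <- rows[accv]
        if ("age" %in% colnames(X))
          X[rws, "age"] <- age_imp[accv] - prep$age_center
        if ("age_male" %in% colnames(X))
          X[rws, "age_male"] <- (age_imp[accv] - prep$age_center) *
            prep$male_vec[rws]
        eta[rws, ] <- etan[accv, , drop = FALSE]
        L[rws, ] <- Ln[accv, , drop = FALSE]
      }
      if (adapting) ls_age <- ls_age + g_t * (mean(accv) - t_acc)
    }
    if (ind && cfg$impute && length(prep$miss_male)) {
      rows <- prep$miss_male
      co_m <- if ("male" %in% colnames(X)) beta["male", ] else rep(0, K)
      co_am <- if ("age_male" %in% colnames(X)) beta["age_male", ]
               else rep(0, K)
      agec <- if ("age" %in% colnames(X)) X[rows, "age"] else
        rep(0, length(rows))
      d1 <- outer(rep(1, length(rows)), co_m) + outer(agec, co_am)
      eta0 <- eta[rows, , drop = FALSE] - male_imp * d1
      eta1 <- eta0 + d1
      ll1 <- rowSums(Y[rows, , drop = FALSE] * eta1 - log1pexp(eta1))
      ll0 <- rowSums(Y[rows, , drop = FALSE] * eta0 - log1pexp(eta0))
      lo <- ll1 - ll0 + qlogis(prep$p_male_hat)
      male_new <- rbinom(length(rows), 1, plogis(lo))
      chg <- male_new != male_imp
      male_imp <- male_new
      if (any(chg)) {
        rws <- rows[chg]
        prep$male_vec[rws] <- male_new[chg]
        if ("male" %in% colnames(X)) X[rws, "male"] <- male_new[chg]
        if ("age_male" %in% colnames(X))
          X[rws, "age_male"] <- agec[chg] * male_new[chg]
        eta[rws, ] <- (eta0 + male_new * d1)[chg, , drop = FALSE]
        L[rws, ] <- log1pexp(eta[rws, , drop = FALSE])
      }
    }
    if (agg && length(prep$uns) && !is.na(prep$w_col) && cfg$impute) {
      ## restricted prior around the global mean weight, truncated at 0;
      ## no likelihood attaches (unsampled), so this is an exact draw
      wmiss <- rtruncnorm(length(prep$uns), prep$wmiss_mean,
                          pri$wmiss_cv * prep$wmiss_mean, lo = 0)
      dW <- wmiss - Xa[prep$uns, prep$w_col]
      Xa[prep$uns, prep$w_col] <- wmiss
      etaA[prep$uns, ] <- etaA[prep$uns, , drop = FALSE] +
        outer(dW, alpha[prep$w_col, ])
      LA[prep$uns, ] <- log1pexp(etaA[prep$uns, , drop = FALSE])
    }

    ## record ----------------------------------------------------------
    if (t > cfg$n_burnin && (t - cfg$n_burnin) %% cfg$thin == 0L) {
      kept <- kept + 1L
      if (agg) draw_pi[kept, ] <- as.vector(plogis(etaA))
      if (ind) draw_beta[kept, ] <- as.vector(beta)
      if (agg) draw_alpha[kept, ] <- as.vector(alpha)
      tu <- if (ind && md$spatial) tau_u else rep(NA_real_, K)
      tv <- if (ind && md$iid) tau_v else rep(NA_real_, K)
      tU <- if (agg && md$spatial) tau_U else rep(NA_real_, K)
      tV <- if (agg && md$iid) tau_V else rep(NA_real_, K)
      draw_tau[kept, ] <- c(tu, tv, tU, tV)
      if (!is.null(draw_sig))
        draw_sig[kept, ] <- Sigma[lower.tri(Sigma, diag = TRUE)]
      if (!is.null(draw_imp))
        draw_imp[kept, ] <- vapply(seq_len(K), function(k) {
          mk <- prep$miss_y[[k]]
          if (length(mk)) mean(Y[mk, k]) else NA_real_
        }, numeric(1))
    }
  }

  accept <- ifelse(att_ct > 0, acc_ct / att_ct, NA_real_)
  list(draws = list(pi = if (agg) draw_pi,
                    beta = if (ind) draw_beta,
                    alpha = if (agg) draw_alpha,
                    tau = draw_tau, sigma = draw_sig, imp = draw_imp),
       accept = accept, seed = seed)
}
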