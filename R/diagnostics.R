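#' Gelman-Rubin potential scale reduction factor
#'
#' Classical PSRF from between-chain variance `B` and within-chain
#' variance `W`: `var+ = ((n-1)/n) W + B/n`, `Rhat = sqrt(var+/W)`.
#'
#' @param draws a list of equal-length numeric vectors (one per chain)
#'   or a matrix with one column per chain.
#' @return scalar R-hat (`>= 1` up to floating tolerance); `+Inf` with a
#'   warning if the within-chain variance is zero.
#' @export
#' @examples
#' gelman_rubin(list(c(1, 2, 3), c(4, 5, 6)))  # ~2.273
gelman_rubin <- function(draws) {
  if (is.matrix(draws)) draws <- lapply(seq_len(ncol(draws)),
                                        function(j) draws[, j])
  m <- length(draws)
  if (m < 2L) stop("need at least two chains")
  n <- unique(lengths(draws))
  if (length(n) != 1L || n < 2L)
    stop("chains must have equal length >= 2")
  means <- vapply(draws, mean, numeric(1))
  W <- mean(vapply(draws, var, numeric(1)))
  if (W == 0) {
    warning("within-chain variance is zero; R-hat undefined")
    return(Inf)
  }
  B <- n * var(means)
  var_plus <- (n - 1) / n * W + B / n
  ## floored at 1: values below 1 only reflect the small-sample
  ## deflation of the pooled variance estimate
  max(1, sqrt(var_plus / W))
}

#' Effective sample size
#'
#' Autocorrelation-based ESS using Geyer's initial positive sequence:
#' autocovariances are summed in adjacent pairs until the first
#' non-positive pair, and `ESS = n / (1 + 2 * sum(rho))`, capped at `n`.
#'
#' @param draws numeric vector of at least 10 draws.
#' @return scalar ESS in `(0, n]`; a constant chain gives 0 with a
#'   warning.
#' @export
effective_sample_size <- function(draws) {
  n <- length(draws)
  if (n < 10L) stop("need at least 10 draws")
  v <- var(draws)
  if (v == 0) {
    warning("constant chain; ESS undefined, returning 0")
    return(0)
  }
  max_lag <- min(n - 1L, 2000L)
  ac <- stats::acf(draws, lag.max = max_lag, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  rho_sum <- 0
  t <- 1L
  while (t + 1L <= max_lag) {
    pair <- ac[t + 1L] + ac[t + 2L]  # acf[1] is lag 0
    if (!is.finite(pair) || pair <= 0) break
    rho_sum <- rho_sum + pair
    t <- t + 2L
  }
  min(n, n / (1 + 2 * rho_sum))
}

## pull a named scalar's per-chain draws from a chainset
chain_scalar <- function(fit, block, column) {
  lapply(fit$chains, function(ch) ch$draws[[block]][, column])
}

## per-draw national mean prevalence, one matrix (draws x K) per chain
national_draws <- function(fit) {
  J <- length(fit$area_ids)
  K <- length(fit$outcomes)
  lapply(fit$chains, function(ch) {
    pim <- ch$draws$pi
    if (is.null(pim)) stop("no aggregated prevalence draws in chainset")
    out <- sapply(seq_len(K), function(k)
      rowMeans(pim[, (k - 1) * J + seq_len(J), drop = FALSE]))
    colnames(out) <- fit$outcomes
    out
  })
}

#' Convergence diagnostics for a fitted chainset
#'
#' Computes R-hat and total effective sample size for the monitored
#' scalars: per-outcome national mean prevalence, intercepts, and
#' precisions.
#'
#' @param fit a `cm_chainset` from [run_mcmc()].
#' @return a data frame (class `cm_diagnostics`) with columns `param`,
#'   `rhat`, `ess` and an overall `pass` attribute
#'   (all R-hat below the configured threshold).
#' @export
mcmc_diagnostics <- function(fit) {
  rows <- list()
  add <- function(name, perchain) {
    rh <- gelman_rubin(perchain)
    es <- sum(vapply(perchain, function(x)
      suppressWarnings(effective_sample_size(x)), numeric(1)))
    rows[[length(rows) + 1L]] <<- data.frame(param = name, rhat = rh,
                                             ess = es)
  }
  if (!is.null(fit$chains[[1]]$draws$pi)) {
    nat <- national_draws(fit)
    for (k in fit$outcomes)
      add(paste0("national:", k), lapply(nat, function(m) m[, k]))
    for (cn in grep("^\\(Intercept\\)", colnames(
      fit$chains[[1]]$draws$alpha), value = TRUE))
      add(paste0("alpha:", cn), chain_scalar(fit, "alpha", cn))
  }
  if (!is.null(fit$chains[[1]]$draws$beta)) {
    for (cn in grep("^\\(Intercept\\)", colnames(
      fit$chains[[1]]$draws$beta), value = TRUE))
      add(paste0("beta:", cn), chain_scalar(fit, "beta", cn))
  }
  tn <- colnames(fit$chains[[1]]$draws$tau)
  for (cn in tn) {
    pc <- chain_scalar(fit, "tau", cn)
    if (!anyNA(pc[[1]])) add(cn, pc)
  }
  out <- do.call(rbind, rows)
  attr(out, "pass") <- all(out$rhat < fit$config$rhat_threshold)
  class(out) <- c("cm_diagnostics", "data.frame")
  out
}
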