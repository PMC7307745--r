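#' Numerically stable inverse-logit link
#'
#' Maps a linear predictor to a probability.  Values are computed with
#' [stats::plogis()]; log-scale Bernoulli likelihood contributions should
#' use [bernoulli_loglik()], which never underflows to `-Inf` for finite
#' linear predictors.
#'
#' @param x numeric vector of linear-predictor values.
#' @return probabilities in `(0, 1)` (subnormal underflow to 0 can occur
#'   below roughly `-745`; likelihood code works on the log scale and is
#'   unaffected).
#' @seealso [logit()]
#' @export
#' @examples
#' inv_logit(0)            # 0.5
#' inv_logit(logit(0.109)) # 0.109
inv_logit <- function(x) plogis(x)

#' Logit link
#' @param p probabilities in (0, 1).
#' @return log-odds.
#' @export
logit <- function(p) qlogis(p)

## log(1 + exp(x)) without overflow; vectorized
log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Bernoulli log-likelihood on the linear-predictor scale
#'
#' Computes `y * log(p) + (1 - y) * log(1 - p)` with
#' `p = inv_logit(eta)` directly on the log scale, so that extreme
#' linear predictors (e.g. `|eta| = 800`) give finite values.
#'
#' @param y 0/1 responses (vector or matrix).
#' @param eta linear predictors, same shape as `y`.
#' @return log-likelihood contributions, same shape as inputs.
#' @export
bernoulli_loglik <- function(y, eta) y * eta - log1pexp(eta)

## inverse-Wishart log-density (with normalizing constant)
ldiwish <- function(Sigma, S, df) {
  k <- nrow(Sigma)
  chS <- chol(S)
  chSig <- chol(Sigma)
  lgmv <- (k * (k - 1) / 4) * log(pi) + sum(lgamma((df + 1 - seq_len(k)) / 2))
  (df / 2) * 2 * sum(log(diag(chS))) -
    (df * k / 2) * log(2) - lgmv -
    ((df + k + 1) / 2) * 2 * sum(log(diag(chSig))) -
    0.5 * sum(diag(chol2inv(chSig) %*% S))
}

## draw from inverse-Wishart(S, df)
riwish <- function(S, df) {
  W <- rWishart(1, df = df, Sigma = chol2inv(chol(S)))[, , 1]
  chol2inv(chol(W))
}

## truncated-normal draws on [lo, hi] by inverse-cdf
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
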