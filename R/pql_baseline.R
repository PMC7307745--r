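#' Frequentist baseline: logistic GLMM by penalized quasi-likelihood
#'
#' Per-outcome logistic mixed model with a province random intercept,
#' fitted by penalized quasi-likelihood (Breslow-Clayton working-
#' response iteration with a REML variance-component solve, as
#' implemented in \code{MASS::glmmPQL}).  The frequentist arm uses
#' listwise deletion: only complete cases enter, and unsampled
#' provinces receive no prediction.
#'
#' @param records survey data frame.
#' @param outcome outcome column name (or index into the canonical
#'   four).
#' @param covariates covariate names among `age`, `male`, `age_male`,
#'   `weight`.
#' @param max_iter maximum PQL iterations.
#' @param tol convergence tolerance on the working-model coefficients.
#' @return an object of class `pql_fit`: `coefficients` (data frame
#'   with `estimate`, `se`, `lo95`, `hi95` Wald intervals),
#'   `ranef_variance`, `converged`, `n_used`, `n_areas`, `outcome`.
#' @export
pql_fit <- function(records, outcome,
                    covariates = c("age", "male", "age_male", "weight"),
                    max_iter = 25L, tol = 1e-6) {
  if (is.numeric(outcome)) outcome <- OUTCOMES[outcome]
  if (!outcome %in% names(records))
    stop("outcome column not found: ", outcome)
  dat <- data.frame(y = records[[outcome]],
                    age = records$age - mean(records$age, na.rm = TRUE),
                    male = records$male,
                    weight = records$weight,
                    province = records$province,
                    stringsAsFactors = FALSE)
  dat$age_male <- dat$age * dat$male
  keep <- complete.cases(dat[c("y", covariates, "province")])
  dat <- dat[keep, , drop = FALSE]
  n_areas <- length(unique(dat$province))
  form <- stats::as.formula(paste("y ~",
                                  paste(covariates, collapse = " + ")))
  if (n_areas < 2L) {
    warning("fewer than two sampled areas; random-intercept variance ",
            "fixed at its boundary (0)")
    fit <- stats::glm(form, family = stats::binomial(), data = dat)
    sm <- summary(fit)$coefficients
    co <- data.frame(term = rownames(sm), estimate = sm[, 1],
                     se = sm[, 2],
                     lo95 = sm[, 1] - 1.96 * sm[, 2],
                     hi95 = sm[, 1] + 1.96 * sm[, 2],
                     row.names = NULL, stringsAsFactors = FALSE)
    return(structure(list(coefficients = co, ranef_variance = 0,
                          converged = TRUE, n_used = nrow(dat),
                          n_areas = n_areas, outcome = outcome),
                     class = "pql_fit"))
  }
  fit <- tryCatch(
    suppressMessages(do.call(MASS::glmmPQL, list(
      fixed = form, random = ~ 1 | province,
      family = stats::binomial(), data = dat, niter = max_iter,
      verbose = FALSE, control = nlme::lmeControl(tolerance = tol)))),
    error = function(e) e)
  if (inherits(fit, "error")) {
    warning("PQL did not converge: ", conditionMessage(fit))
    return(structure(list(coefficients = NULL, ranef_variance = NA_real_,
                          converged = FALSE, n_used = nrow(dat),
                          n_areas = n_areas, outcome = outcome),
                     class = "pql_fit"))
  }
  tt <- summary(fit)$tTable
  co <- data.frame(term = rownames(tt), estimate = tt[, "Value"],
                   se = tt[, "Std.Error"],
                   lo95 = tt[, "Value"] - 1.96 * tt[, "Std.Error"],
                   hi95 = tt[, "Value"] + 1.96 * tt[, "Std.Error"],
                   row.names = NULL, stringsAsFactors = FALSE)
  vc <- as.numeric(nlme::VarCorr(fit)["(Intercept)", "Variance"])
  structure(list(coefficients = co, ranef_variance = vc,
                 converged = TRUE, n_used = nrow(dat),
                 n_areas = n_areas, outcome = outcome),
            class = "pql_fit")
}

#' @export
print.pql_fit <- function(x, ...) {
  cat("PQL logistic GLMM for outcome '", x$outcome, "' (",
      x$n_used, " complete cases, ", x$n_areas, " areas)\n", sep = "")
  if (!x$converged) { cat("  ** did not converge **\n"); return(invisible(x)) }
  print(x$coefficients, digits = 3)
  cat("Province random-intercept variance:",
      format(x$ranef_variance, digits = 3), "\n")
  invisible(x)
}

#' Write PQL baseline results as CSV
#' @param fits list of `pql_fit` objects.
#' @param path output path.
#' @export
write_pql_csv <- function(fits, path) {
  rows <- do.call(rbind, lapply(fits, function(f) {
    if (!f$converged || is.null(f$coefficients))
      return(data.frame(outcome = f$outcome, term = NA, estimate = NA,
                        se = NA, lo95 = NA, hi95 = NA,
                        ranef_variance = f$ranef_variance,
                        converged = f$converged))
    cbind(outcome = f$outcome, f$coefficients,
          ranef_variance = f$ranef_variance, converged = f$converged)
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
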