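## Posterior summaries, exceedance probabilities and hotspot flags.

pooled_pi <- function(fit) {
  do.call(rbind, lapply(fit$chains, function(ch) ch$draws$pi))
}

#' Province-level posterior prevalence summaries
#'
#' @param fit a `cm_chainset`.
#' @return data frame with one row per (area, outcome): posterior
#'   `mean`, `lo95`, `hi95` (2.5 and 97.5 percentiles).
#' @export
province_posterior <- function(fit) {
  pim <- pooled_pi(fit)
  if (is.null(pim)) stop("chainset has no prevalence draws")
  J <- length(fit$area_ids); K <- length(fit$outcomes)
  out <- data.frame(
    area = rep(fit$area_ids, K),
    outcome = rep(fit$outcomes, each = J),
    mean = colMeans(pim),
    lo95 = apply(pim, 2, quantile, 0.025),
    hi95 = apply(pim, 2, quantile, 0.975),
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' National posterior mean prevalence with 95% credible intervals
#'
#' Per posterior draw, the unweighted mean of the province prevalences
#' over all areas (sampled and predicted); then the mean and 2.5/97.5
#' percentiles over draws.
#'
#' @param fit a `cm_chainset` (needs at least 100 pooled draws).
#' @return data frame with one row per outcome: `mean`, `lo95`, `hi95`.
#' @export
national_prevalence <- function(fit) {
  nat <- do.call(rbind, national_draws(fit))
  if (nrow(nat) < 100L)
    stop("need at least 100 posterior draws for national summaries")
  data.frame(outcome = fit$outcomes,
             mean = colMeans(nat),
             lo95 = apply(nat, 2, quantile, 0.025),
             hi95 = apply(nat, 2, quantile, 0.975),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-outcome exceedance thresholds
#'
#' @param summaries output of [province_posterior()].
#' @param mode `"median"` (default; the median over areas of the
#'   posterior mean prevalence), `"national_mean"` (mean over areas) or
#'   `"fixed"` (user-supplied values).
#' @param values fixed threshold per outcome when `mode = "fixed"`.
#' @return named numeric vector of thresholds `c_k`, one per outcome.
#' @export
prevalence_thresholds <- function(summaries,
                                  mode = c("median", "national_mean",
                                           "fixed"),
                                  values = NULL) {
  mode <- match.arg(mode)
  if (!nrow(summaries)) stop("empty summaries")
  outc <- unique(summaries$outcome)
  if (mode == "fixed") {
    if (is.null(values)) stop("mode='fixed' requires values")
    values <- rep_len(values, length(outc))
    return(stats::setNames(values, outc))
  }
  f <- if (mode == "median") median else mean
  vapply(stats::setNames(outc, outc), function(k)
    f(summaries$mean[summaries$outcome == k]), numeric(1))
}

#' Posterior exceedance probability
#'
#' Fraction of posterior draws strictly greater than the threshold.
#'
#' @param draws numeric vector of prevalence draws for one area/outcome.
#' @param c threshold in (0, 1) (0 and 1 allowed as degenerate bounds).
#' @return probability in `[0, 1]`.
#' @export
exceedance_probability <- function(draws, c) {
  if (!length(draws)) stop("no draws supplied")
  mean(draws > c)
}

#' Detect hotspots from a fitted chainset
#'
#' Computes, per area and outcome, the posterior prevalence summaries,
#' the exceedance probability `q_jk = Pr(pi_jk > c_k | data)` and the
#' hotspot flag `q_jk > cutoff` (ties at the cutoff are not flagged).
#'
#' @param fit a `cm_chainset`.
#' @param mode threshold mode, see [prevalence_thresholds()].
#' @param values fixed thresholds when `mode = "fixed"`.
#' @param cutoff exceedance-probability decision cutoff (default 0.95).
#' @return a `hotspot_table` data frame: `area`, `outcome`, `mean`,
#'   `lo95`, `hi95`, `threshold`, `exceedance`, `hotspot`.
#' @export
detect_hotspots <- function(fit, mode = "median", values = NULL,
                            cutoff = 0.95) {
  summ <- province_posterior(fit)
  ck <- prevalence_thresholds(summ, mode, values)
  pim <- pooled_pi(fit)
  J <- length(fit$area_ids)
  summ$threshold <- ck[summ$outcome]
  summ$exceedance <- vapply(seq_len(nrow(summ)), function(i)
    mean(pim[, i] > summ$threshold[i]), numeric(1))
  summ$hotspot <- summ$exceedance > cutoff
  attr(summ, "cutoff") <- cutoff
  class(summ) <- c("hotspot_table", "data.frame")
  summ
}

#' Crude descriptive statistics
#'
#' Unweighted counts and rounded percentages for binary / categorical
#' variables, with the denominator restricted to non-missing values,
#' optionally stratified by a grouping column.
#'
#' @param records data frame.
#' @param vars variable names to describe (default: all 0/1 and factor
#'   columns other than `id`).
#' @param by optional stratification column name.
#' @param digits rounding for the percentage (default 0, the precision
#'   of a typical descriptive table).
#' @return data frame with columns `variable`, `level`, (`group`,)
#'   `n`, `denom`, `pct`.
#' @export
crude_descriptives <- function(records, vars = NULL, by = NULL,
                               digits = 0) {
  if (is.null(vars)) {
    is_cat <- vapply(records, function(x)
      is.factor(x) || is.character(x) ||
        all(stats::na.omit(x) %in% c(0, 1)), logical(1))
    vars <- setdiff(names(records)[is_cat], c("id", "province", by))
  }
  groups <- if (is.null(by)) list(all = rep(TRUE, nrow(records)))
            else split(seq_len(nrow(records)), records[[by]])
  out <- list()
  for (gn in names(groups)) {
    sel <- groups[[gn]]
    sub <- records[sel, , drop = FALSE]
    for (vn in vars) {
      x <- sub[[vn]]
      denom <- sum(!is.na(x))
      lv <- if (is.factor(x) || is.character(x)) unique(stats::na.omit(x))
            else 1
      for (l in lv) {
        cnt <- sum(x == l, na.rm = TRUE)
        pct <- if (denom > 0) round(100 * cnt / denom, digits) else NA
        out[[length(out) + 1L]] <- data.frame(
          variable = vn, level = as.character(l),
          group = gn, n = cnt, denom = denom, pct = pct,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(by)) res$group <- NULL
  res
}

#' Write posterior results to CSV
#' @param results a `hotspot_table` (or any data frame).
#' @param path output CSV path.
#' @export
write_results_csv <- function(results, path) {
  write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Join posterior summaries onto GeoJSON polygons
#'
#' Adds per-outcome posterior mean, exceedance probability and hotspot
#' flag as feature properties of an existing GeoJSON file (WGS84
#' assumed) and writes the result.
#'
#' @param results a `hotspot_table`.
#' @param geojson_in input GeoJSON path (FeatureCollection).
#' @param path output path.
#' @param property feature property holding the area id (default: the
#'   feature `id`).
#' @export
write_hotspot_geojson <- function(results, geojson_in, path,
                                  property = NULL) {
  gj <- jsonlite::read_json(geojson_in)
  ids <- geojson_area_ids(geojson_in, property)
  for (i in seq_along(gj$features)) {
    rows <- results[results$area == ids[i], , drop = FALSE]
    for (j in seq_len(nrow(rows))) {
      o <- rows$outcome[j]
      gj$features[[i]]$properties[[paste0(o, "_mean")]] <- rows$mean[j]
      gj$features[[i]]$properties[[paste0(o, "_exceedance")]] <-
        rows$exceedance[j]
      gj$features[[i]]$properties[[paste0(o, "_hotspot")]] <-
        rows$hotspot[j]
    }
  }
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
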