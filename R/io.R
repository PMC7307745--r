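## Survey CSV schema: columns id, province, age, male, weight, dm, ob,
## ht, ldl (and optional edu, income); missing values are empty fields.

SURVEY_NUMERIC <- c("age", "weight")
SURVEY_BINARY <- c("male", OUTCOMES)

#' Read survey microdata from CSV
#'
#' Validates the documented schema: `age`/`weight` numeric, `male` and
#' the outcomes coded 0/1, missing values as empty fields.  If a graph
#' is supplied, province labels are checked against it.
#'
#' @param path CSV file path.
#' @param graph optional `adjacency_graph` to validate provinces
#'   against.
#' @return data frame of records.
#' @export
read_survey_csv <- function(path, graph = NULL) {
  rec <- read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                  colClasses = c(province = "character"))
  need <- c("id", "province", "age", "male", "weight")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    stop("survey CSV lacks required columns: ",
         paste(miss, collapse = ", "))
  for (cn in intersect(c(SURVEY_NUMERIC, SURVEY_BINARY), names(rec))) {
    x <- rec[[cn]]
    if (!is.numeric(x)) {
      bad <- which(!is.na(x) & is.na(suppressWarnings(as.numeric(x))))
      if (length(bad))
        stop("non-numeric value in column '", cn, "' at row ", bad[1],
             ": '", x[bad[1]], "'")
      rec[[cn]] <- as.numeric(x)
    }
    if (cn %in% SURVEY_BINARY &&
        !all(rec[[cn]] %in% c(0, 1) | is.na(rec[[cn]])))
      stop("column '", cn, "' must be coded 0/1")
  }
  if (!is.null(graph)) {
    bad <- setdiff(unique(rec$province), graph$area_ids)
    if (length(bad))
      stop("provinces absent from the graph: ",
           paste(bad, collapse = ", "))
  }
  rec
}

#' Write survey microdata to CSV (missing values as empty fields)
#' @param records data frame of records.
#' @param path output path.
#' @export
write_survey_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write the ground-truth sidecar of a synthetic dataset as JSON
#' @param truth a `synthetic_truth`.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  out <- list(outcomes = truth$outcomes,
              fixed = truth$fixed, age_center = truth$age_center,
              gradient_slope = truth$gradient_slope,
              realized_prev = as.list(truth$realized_prev),
              prev_targets = as.list(truth$prev_targets),
              pi_star = as.data.frame(truth$pi_star),
              hotspots = truth$hotspots, seed = truth$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Export chain draws as CSV files (one per chain)
#' @param fit a `cm_chainset`.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_chains_csv <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(fit$chains)) {
    dr <- fit$chains[[i]]$draws
    m <- do.call(cbind, dr[!vapply(dr, is.null, logical(1))])
    p <- file.path(dir, sprintf("chain%02d.csv", i))
    write.csv(as.data.frame(m), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Run configuration with defaults
#'
#' Reads a YAML run configuration, filling defaults for any field not
#' given.  Recognized top-level keys: `paths` (survey, graph, geojson,
#' out_dir), `mcmc` (arguments of [mcmc_config()]), `priors`
#' (arguments of [prior_spec()]), `threshold_mode`, `hotspot_cutoff`,
#' `seed`.
#'
#' @param path YAML file path, or `NULL` for all-defaults.
#' @return a list of class `cm_runconfig`.
#' @export
read_run_config <- function(path = NULL) {
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  cfg <- list(paths = user$paths %||% list(),
              mcmc = user$mcmc %||% list(),
              priors = user$priors %||% list(),
              threshold_mode = user$threshold_mode %||% "median",
              hotspot_cutoff = user$hotspot_cutoff %||% 0.95,
              seed = user$seed %||% 1L)
  for (p in c("survey", "graph")) {
    fp <- cfg$paths[[p]]
    if (!is.null(fp) && !file.exists(fp))
      stop("configured ", p, " path does not exist: ", fp)
  }
  class(cfg) <- "cm_runconfig"
  cfg
}

#' Write a JSON run manifest
#' @param dir output directory.
#' @param config the effective configuration (list).
#' @param extra named list of extra entries (seeds, diagnostics, ...).
#' @export
write_manifest <- function(dir, config, extra = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- c(list(package = "cardiomap",
                version = as.character(utils::packageVersion("cardiomap")),
                timestamp = format(Sys.time(), tz = "UTC"),
                config = config), extra)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(file.path(dir, "manifest.json"))
}
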