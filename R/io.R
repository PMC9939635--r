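#' Read and validate a long exposure table
#'
#' Expects a CSV with columns `subject_id`, `metal`, `medium`, `value`,
#' `lod` (and optionally `censored`; computed as `value < lod` when
#' absent). Metal and medium labels, numeric values, positivity and key
#' uniqueness are validated with row-numbered diagnostics.
#'
#' @param path Path to the CSV file.
#' @return Validated data frame with an added `component` column.
#' @export
read_exposure_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "metal", "medium", "value", "lod")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("exposure table is missing required column(s): ",
         paste(miss, collapse = ", "), " (required: ",
         paste(req, collapse = ", "), ")")
  }
  validate_exposure_table(df)
}

validate_exposure_table <- function(df) {
  bad <- which(!df$metal %in% METALS)
  if (length(bad)) {
    stop("unknown metal label '", df$metal[bad[1]], "' at row ", bad[1])
  }
  bad <- which(!df$medium %in% MEDIA)
  if (length(bad)) {
    stop("unknown medium label '", df$medium[bad[1]], "' at row ", bad[1])
  }
  for (col in c("value", "lod")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop("non-numeric ", col, " '", df[[col]][bad[1]], "' at row ", bad[1])
    }
    df[[col]] <- v
  }
  key <- paste(df$subject_id, df$metal, df$medium)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicated (subject, metal, medium) key: ", key[dup[1]])
  }
  if (!"censored" %in% names(df)) {
    df$censored <- df$value < df$lod
  } else {
    df$censored <- as.logical(df$censored)
  }
  bad <- which(!is.na(df$value) & df$value <= 0 & !df$censored)
  if (length(bad)) {
    stop("non-positive uncensored concentration at row ", bad[1])
  }
  df$component <- component_label(df$metal, df$medium)
  df
}

#' Read a covariates table (subject_id, age, sex)
#' @param path Path to the CSV file.
#' @return Validated data frame.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("subject_id", "age", "sex"), names(df))
  if (length(miss)) {
    stop("covariates table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df$subject_id)) stop("duplicated subject_id in covariates")
  df
}

#' Read a graph-metrics table (subject_id, ge, le_mean)
#' @param path Path to the CSV file.
#' @return Validated data frame.
#' @export
read_metrics_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("subject_id", "ge", "le_mean"), names(df))
  if (length(miss)) {
    stop("metrics table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df$subject_id)) stop("duplicated subject_id in metrics")
  df
}

#' Load and align the pipeline inputs
#'
#' @param exposures_path,covariates_path,metrics_path CSV paths; the
#'   metrics table is optional (time series can be supplied instead).
#' @param timeseries_dir Optional directory of per-subject TSV time series
#'   written by [write_timeseries_tsv()].
#' @return List with `exposures`, `covariates`, `metrics` (or `NULL`) and
#'   `timeseries` (or `NULL`).
#' @export
load_inputs <- function(exposures_path, covariates_path, metrics_path = NULL,
                        timeseries_dir = NULL) {
  list(
    exposures = read_exposure_table(exposures_path),
    covariates = read_covariates(covariates_path),
    metrics = if (!is.null(metrics_path)) read_metrics_table(metrics_path),
    timeseries = if (!is.null(timeseries_dir)) read_timeseries_dir(timeseries_dir)
  )
}

#' Write a ROI time-series set as per-subject TSV files
#'
#' For each subject, `<id>_timeseries.tsv` holds the timepoints x ROI
#' matrix (ROI labels as header) and `<id>_nuisance.tsv` the eight
#' nuisance columns (motion1..motion6, wm, csf).
#'
#' @param ts A `roi_timeseries_set`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_timeseries_tsv <- function(ts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (id in names(ts$subjects)) {
    s <- ts$subjects[[id]]
    utils::write.table(s$data, file.path(dir, paste0(id, "_timeseries.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    nuis <- cbind(s$motion, wm = s$wm, csf = s$csf)
    colnames(nuis) <- c(paste0("motion", 1:6), "wm", "csf")
    utils::write.table(nuis, file.path(dir, paste0(id, "_nuisance.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read a directory of per-subject ROI time-series TSV files
#'
#' Inverse of [write_timeseries_tsv()].
#'
#' @param dir Directory containing `<id>_timeseries.tsv` /
#'   `<id>_nuisance.tsv` pairs.
#' @param tr Repetition time in seconds (metadata).
#' @return A `roi_timeseries_set` (without generator parameters).
#' @export
read_timeseries_dir <- function(dir, tr = 1) {
  files <- list.files(dir, pattern = "_timeseries\\.tsv$")
  if (!length(files)) stop("no *_timeseries.tsv files in ", dir)
  ids <- sub("_timeseries\\.tsv$", "", files)
  subjects <- lapply(ids, function(id) {
    dat <- as.matrix(read.delim(file.path(dir, paste0(id, "_timeseries.tsv"))))
    nf <- file.path(dir, paste0(id, "_nuisance.tsv"))
    if (!file.exists(nf)) stop("missing nuisance file for subject ", id)
    nuis <- as.matrix(read.delim(nf))
    roi_timeseries(dat, nuis[, paste0("motion", 1:6)], nuis[, "wm"],
                   nuis[, "csf"], tr = tr)
  })
  names(subjects) <- ids
  structure(list(subjects = subjects, modules = NULL, params = list(tr = tr)),
            class = "roi_timeseries_set")
}

#' Descriptive statistics of an exposure table
#'
#' Per (metal, medium) cell: the share of values above the LOD, and the
#' geometric mean and geometric SD of the uncensored values
#' (`GM = exp(mean(log x))`, `GSD = exp(sd(log x))`). Cells that are
#' entirely censored get `NA` summaries with a note. Also returns the
#' Pearson correlation matrix of the log concentrations across the 16
#' components (censored values imputed at LOD/sqrt(2)).
#'
#' @param exposures Long exposure table.
#' @return List of class `exposure_summary` with `summary` (data frame)
#'   and `log_correlations` (16 x 16 matrix).
#' @export
describe_exposures <- function(exposures) {
  ex <- as.data.frame(exposures)
  if (!"component" %in% names(ex)) ex$component <- component_label(ex$metal, ex$medium)
  if (length(unique(ex$subject_id)) < 2L) stop("need at least 2 subjects")
  cells <- unique(ex[, c("metal", "medium", "component")])
  cells <- cells[order(match(cells$metal, METALS), match(cells$medium, MEDIA)), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- ex[ex$component == cells$component[i], ]
    unc <- sub$value[!sub$censored]
    data.frame(
      metal = cells$metal[i], medium = cells$medium[i],
      component = cells$component[i], n = nrow(sub),
      pct_above_lod = 100 * mean(!sub$censored),
      gm = if (length(unc)) exp(mean(log(unc))) else NA_real_,
      gsd = if (length(unc) >= 2L) exp(sd(log(unc))) else
        if (length(unc) == 1L) NA_real_ else NA_real_,
      note = if (!length(unc)) "all values below LOD" else "",
      stringsAsFactors = FALSE
    )
  })
  summary <- do.call(rbind, rows)
  # single-value special case: GSD of one repeated value is 1 by convention
  for (i in seq_len(nrow(summary))) {
    sub <- ex[ex$component == summary$component[i], ]
    unc <- sub$value[!sub$censored]
    if (length(unc) >= 2L && length(unique(unc)) == 1L) summary$gsd[i] <- 1
  }
  imput <- ifelse(ex$censored, ex$lod / sqrt(2), ex$value)
  subjects <- unique(ex$subject_id)
  mat <- matrix(NA_real_, length(subjects), nrow(cells),
                dimnames = list(subjects, cells$component))
  mat[cbind(match(ex$subject_id, subjects),
            match(ex$component, cells$component))] <- imput
  keep <- colnames(mat)[apply(mat, 2L, function(v) {
    v <- v[!is.na(v)]
    length(v) >= 2L && var(log(v)) > 0
  })]
  logc <- if (length(keep) >= 2L) {
    cor(log(mat[, keep, drop = FALSE]), use = "pairwise.complete.obs")
  } else {
    matrix(numeric(0), 0L, 0L)
  }
  structure(list(summary = summary, log_correlations = logc),
            class = "exposure_summary")
}

ensemble_to_list <- function(ens) {
  list(
    component_labels = ens$component_labels,
    betas = ens$betas, pvalues = ens$pvalues,
    weights = unname(ens$weights),
    beta_mean = ens$beta_mean, beta_ci = ens$beta_ci,
    weight_summary = ens$weight_summary,
    direction = ens$direction, n_boot = ens$n_boot,
    n_holdouts = ens$n_holdouts, train_fraction = ens$train_fraction,
    seed = ens$seed
  )
}

ensemble_from_list <- function(l) {
  W <- matrix(unlist(l$weights), nrow = l$n_holdouts, byrow = FALSE)
  if (is.matrix(l$weights)) W <- l$weights
  colnames(W) <- l$component_labels
  structure(
    list(betas = as.numeric(l$betas), pvalues = as.numeric(l$pvalues),
         weights = W, beta_mean = l$beta_mean,
         beta_ci = as.numeric(l$beta_ci),
         weight_summary = as.data.frame(l$weight_summary),
         component_labels = l$component_labels, direction = l$direction,
         n_boot = as.integer(l$n_boot), n_holdouts = as.integer(l$n_holdouts),
         train_fraction = l$train_fraction, seed = as.integer(l$seed)),
    class = "wqs_ensemble"
  )
}

#' Serialize an MMB report to JSON
#'
#' Writes the full report — configuration echo, seeds, per-holdout traces
#' and the weight percentile tables — as JSON at full numeric precision so
#' that [read_report()] round-trips it losslessly.
#'
#' @param report An `mmb_report`.
#' @param path Output file path (directory must exist).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "mmb_report"))
  if (length(report$level2$betas) == 0L) {
    stop("refusing to write a report with an empty holdout trace")
  }
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  payload <- list(
    outcome_label = report$outcome_label,
    n_subjects = report$n_subjects,
    subject_id = report$subject_id,
    config = report$config,
    level1 = lapply(report$level1, function(l) {
      list(metal = l$metal, mmb_score = l$mmb_score,
           ensemble = ensemble_to_list(l$ensemble))
    }),
    level2 = ensemble_to_list(report$level2)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an MMB report written by [write_report()]
#' @param path JSON file path.
#' @return An `mmb_report`.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  level1 <- lapply(l$level1, function(x) {
    structure(list(metal = x$metal, ensemble = ensemble_from_list(x$ensemble),
                   mmb_score = as.numeric(x$mmb_score),
                   subject_id = l$subject_id),
              class = "mmb_level1")
  })
  structure(
    list(outcome_label = l$outcome_label, level1 = level1,
         level2 = ensemble_from_list(l$level2),
         subject_id = l$subject_id, n_subjects = l$n_subjects,
         config = l$config),
    class = "mmb_report"
  )
}

#' Write the Fig-style weight percentile tables of a report as CSV
#'
#' One file per WQS model (four level-1 media tables plus the level-2
#' metal table), each with the mean and 10/25/50/75/90th holdout
#' percentiles of every component weight.
#'
#' @param report An `mmb_report`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_weight_tables <- function(report, dir) {
  stopifnot(inherits(report, "mmb_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (m in names(report$level1)) {
    f <- file.path(dir, paste0("weights_level1_", m, "_",
                               report$outcome_label, ".csv"))
    write.csv(report$level1[[m]]$ensemble$weight_summary, f, row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(dir, paste0("weights_level2_", report$outcome_label, ".csv"))
  write.csv(report$level2$weight_summary, f, row.names = FALSE)
  invisible(c(files, f))
}

#' Write a synthetic cohort to CSV/JSON files
#'
#' Emits `exposures.csv`, `covariates.csv` and `truth.json` (the recorded
#' ground truth, including the generator seed) into `dir`.
#'
#' @param cohort A `cohort_bundle`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(cohort$exposures, file.path(dir, "exposures.csv"), row.names = FALSE)
  write.csv(cohort$covariates, file.path(dir, "covariates.csv"), row.names = FALSE)
  tr <- cohort$truth
  jsonlite::write_json(
    list(level1_weights = tr$level1_weights, level2_weights = tr$level2_weights,
         beta_ge = tr$beta_ge, beta_le = tr$beta_le,
         intercept_ge = tr$intercept_ge, intercept_le = tr$intercept_le,
         age_effect = tr$age_effect, sex_effect = tr$sex_effect,
         noise_sd = tr$noise_sd, burden = cohort$burden,
         seed = cohort$config$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
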