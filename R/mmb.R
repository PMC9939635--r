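#' Wide exposure matrix with below-LOD imputation
#'
#' Reshapes a long exposure table into a subjects x components matrix in
#' canonical component order, imputing censored values as LOD/sqrt(2)
#' (`"lod_sqrt2"`, the default) or keeping them as stored (`"as_stored"`,
#' appropriate for synthetic cohorts where the generator records the drawn
#' value).
#'
#' @param exposures Long exposure data frame (`subject_id`, `metal`,
#'   `medium`, `value`, `lod`, `censored`).
#' @param metal Optional single metal; restricts columns to its four media.
#' @param lod_policy `"lod_sqrt2"` or `"as_stored"`.
#' @return Numeric matrix, rownames subject ids, colnames component labels.
#' @export
exposure_matrix <- function(exposures, metal = NULL,
                            lod_policy = c("lod_sqrt2", "as_stored")) {
  lod_policy <- match.arg(lod_policy)
  ex <- as.data.frame(exposures)
  if (!is.null(metal)) {
    if (!metal %in% METALS) stop("unknown metal: ", metal)
    ex <- ex[ex$metal == metal, , drop = FALSE]
    want <- component_label(metal, MEDIA)
  } else {
    want <- component_label(rep(METALS, each = 4L), rep(MEDIA, 4L))
  }
  if (!"component" %in% names(ex)) {
    ex$component <- component_label(ex$metal, ex$medium)
  }
  miss <- setdiff(want, unique(ex$component))
  if (length(miss)) {
    stop("missing exposure components: ", paste(miss, collapse = ", "))
  }
  val <- if (lod_policy == "lod_sqrt2") {
    ifelse(ex$censored, ex$lod / sqrt(2), ex$value)
  } else {
    ex$value
  }
  subjects <- unique(ex$subject_id)
  out <- matrix(NA_real_, length(subjects), length(want),
                dimnames = list(subjects, want))
  out[cbind(match(ex$subject_id, subjects), match(ex$component, want))] <- val
  out
}

#' Level-1 multi-media biomarker: one metal across its four media
#'
#' Decile-scores the metal's blood, urine, hair and saliva concentrations
#' (censored values imputed as LOD/sqrt(2)), runs the repeated-holdout WQS
#' against the outcome, and combines the decile scores with the
#' holdout-mean media weights into a per-subject multi-media biomarker
#' (MMB) score on the 0-9 decile scale.
#'
#' @param exposures Long exposure table covering the metal's four media.
#' @param y Outcome vector aligned with the subjects in `exposures`.
#' @param covariates Data frame of adjustment covariates (age, sex),
#'   aligned with `y`.
#' @param metal One of `"Mn"`, `"Pb"`, `"Cr"`, `"Cu"`.
#' @inheritParams fit_wqs_repeated
#' @param lod_policy Passed to [exposure_matrix()].
#' @return An object of class `mmb_level1`: `metal`, `ensemble`
#'   (a `wqs_ensemble` over the four media), `mmb_score` (per subject, in
#'   `[0, 9]`), `subject_id`.
#' @export
fit_level1_mmb <- function(exposures, y, covariates, metal,
                           direction = "negative", n_boot = 50L,
                           n_holdouts = 100L, train_fraction = 0.6,
                           seed = 1L, lod_policy = "lod_sqrt2") {
  mat <- exposure_matrix(exposures, metal = metal, lod_policy = lod_policy)
  y <- as.numeric(y)
  if (nrow(mat) != length(y)) {
    stop("outcome has ", length(y), " subjects but exposures have ", nrow(mat))
  }
  q <- apply(mat, 2L, decile_transform, warn = FALSE)
  ens <- fit_wqs_repeated(q, y, covariates, direction = direction,
                          n_boot = n_boot, n_holdouts = n_holdouts,
                          train_fraction = train_fraction, seed = seed)
  wbar <- colMeans(ens$weights)
  structure(
    list(metal = metal, ensemble = ens,
         mmb_score = as.numeric(q %*% wbar),
         subject_id = rownames(mat)),
    class = "mmb_level1"
  )
}

#' Level-2 mixture model across the four metal MMBs
#'
#' Re-deciles the four per-subject MMB scores (all exposures enter the
#' models as deciles) and fits the repeated-holdout WQS of the outcome on
#' the cross-metal mixture index, adjusted for the covariates, assembling
#' the full hierarchical report.
#'
#' @param level1 List of four [fit_level1_mmb()] results (one per metal,
#'   same subjects).
#' @inheritParams fit_level1_mmb
#' @param outcome_label Label stored in the report (e.g. `"GE"`, `"LE"`).
#' @return An object of class `mmb_report`: `outcome_label`, `level1`
#'   (named by metal), `level2` (a `wqs_ensemble` over the metals),
#'   `subject_id`, `n_subjects`, `config`.
#' @export
fit_level2_mixture <- function(level1, y, covariates,
                               direction = "negative", n_boot = 50L,
                               n_holdouts = 100L, train_fraction = 0.6,
                               seed = 1L, outcome_label = "GE") {
  if (length(level1) != 4L || !all(vapply(level1, inherits, TRUE, "mmb_level1"))) {
    stop("level1 must be a list of four mmb_level1 results")
  }
  names(level1) <- vapply(level1, `[[`, "", "metal")
  if (!setequal(names(level1), METALS)) {
    stop("level1 results must cover exactly the metals ", paste(METALS, collapse = ", "))
  }
  level1 <- level1[METALS]
  ids <- level1[[1L]]$subject_id
  for (l in level1) {
    if (!identical(l$subject_id, ids)) stop("level-1 results are on misaligned subjects")
  }
  y <- as.numeric(y)
  if (length(y) != length(ids)) stop("outcome is misaligned with the level-1 subjects")
  scores <- vapply(level1, `[[`, numeric(length(ids)), "mmb_score")
  q2 <- apply(scores, 2L, decile_transform, warn = FALSE)
  ens2 <- fit_wqs_repeated(q2, y, covariates, direction = direction,
                           n_boot = n_boot, n_holdouts = n_holdouts,
                           train_fraction = train_fraction, seed = seed)
  structure(
    list(outcome_label = outcome_label, level1 = level1, level2 = ens2,
         subject_id = ids, n_subjects = length(ids),
         config = list(direction = direction, n_boot = as.integer(n_boot),
                       n_holdouts = as.integer(n_holdouts),
                       train_fraction = train_fraction,
                       seed = as.integer(seed))),
    class = "mmb_report"
  )
}

#' Full two-level MMB pipeline
#'
#' Complete-case analysis: subjects missing any of the 16 exposure
#' components, a covariate, or an outcome are dropped (counts reported).
#' If ROI time series are supplied instead of a metrics table, per-subject
#' global and local efficiency are computed first. For each requested
#' outcome, the four level-1 MMB models and the level-2 mixture model are
#' fitted; both outcomes reuse identical seeds for comparability.
#'
#' @param exposures Long exposure table.
#' @param covariates Data frame with `subject_id`, `age`, `sex`.
#' @param metrics Data frame with `subject_id`, `ge`, `le_mean`; computed
#'   from `timeseries` when `NULL`.
#' @param timeseries Optional `roi_timeseries_set` used when `metrics` is
#'   `NULL`.
#' @param outcomes Which outcomes to model (columns of the metrics table).
#' @inheritParams fit_level1_mmb
#' @return An object of class `mmb_run`: `reports` (one `mmb_report` per
#'   outcome), `n_analyzed`, `n_dropped`, `seed`.
#' @export
run_pipeline <- function(exposures, covariates, metrics = NULL,
                         timeseries = NULL, outcomes = c("ge", "le_mean"),
                         direction = "negative", n_boot = 50L,
                         n_holdouts = 100L, train_fraction = 0.6,
                         seed = 1L, lod_policy = "lod_sqrt2") {
  if (is.null(metrics)) {
    if (is.null(timeseries)) stop("supply either metrics or timeseries")
    metrics <- subject_metrics(timeseries)
  }
  miss <- setdiff(outcomes, names(metrics))
  if (length(miss)) stop("metrics table lacks outcome column(s): ", paste(miss, collapse = ", "))
  ex <- as.data.frame(exposures)
  if (!"component" %in% names(ex)) ex$component <- component_label(ex$metal, ex$medium)
  all_subjects <- unique(c(ex$subject_id, covariates$subject_id, metrics$subject_id))
  tab <- table(factor(ex$subject_id[!is.na(ex$value)],
                      levels = all_subjects))
  complete_exp <- names(tab)[tab == 16L]
  cov_ok <- covariates$subject_id[!is.na(covariates$age) & !is.na(covariates$sex)]
  met_ok <- metrics$subject_id[rowSums(is.na(metrics[, outcomes, drop = FALSE])) == 0]
  keep <- intersect(intersect(complete_exp, cov_ok), met_ok)
  keep <- all_subjects[all_subjects %in% keep] # stable order
  n_dropped <- length(all_subjects) - length(keep)
  message("Analyzing ", length(keep), " of ", length(all_subjects),
          " subjects (", n_dropped, " dropped for incomplete data)")
  if (length(keep) < 50L) {
    warning("fewer than 50 complete-case subjects; estimates will be unstable")
  }
  ex <- ex[ex$subject_id %in% keep, , drop = FALSE]
  cov <- covariates[match(keep, covariates$subject_id), c("age", "sex"), drop = FALSE]
  met <- metrics[match(keep, metrics$subject_id), , drop = FALSE]
  seeds <- spawn_seeds(seed, 5L) # 4 metals + level 2; shared across outcomes
  reports <- list()
  for (oc in outcomes) {
    y <- met[[oc]]
    level1 <- lapply(seq_along(METALS), function(i) {
      fit_level1_mmb(ex, y, cov, METALS[i], direction = direction,
                     n_boot = n_boot, n_holdouts = n_holdouts,
                     train_fraction = train_fraction, seed = seeds[i],
                     lod_policy = lod_policy)
    })
    label <- c(ge = "GE", le_mean = "LE")[oc]
    if (is.na(label)) label <- toupper(oc)
    reports[[oc]] <- fit_level2_mixture(
      level1, y, cov, direction = direction, n_boot = n_boot,
      n_holdouts = n_holdouts, train_fraction = train_fraction,
      seed = seeds[5L], outcome_label = unname(label)
    )
  }
  structure(
    list(reports = reports, n_analyzed = length(keep), n_dropped = n_dropped,
         seed = as.integer(seed)),
    class = "mmb_run"
  )
}

#' @export
print.mmb_report <- function(x, ...) {
  cat(sprintf("Two-level MMB WQS report, outcome %s (%d subjects)\n",
              x$outcome_label, x$n_subjects))
  cat(sprintf("  mixture beta = %.4f, 95%% CI (%.4f, %.4f)\n",
              x$level2$beta_mean, x$level2$beta_ci[1], x$level2$beta_ci[2]))
  ws <- colMeans(x$level2$weights)
  cat("  metal weights:",
      paste(sprintf("%s %.3f", names(ws), ws), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.mmb_run <- function(x, ...) {
  cat("MMB pipeline run:", x$n_analyzed, "subjects analyzed,",
      x$n_dropped, "dropped\n")
  for (r in x$reports) print(r)
  invisible(x)
}
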