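#' Default biomarker distribution parameters for the 16 exposure cells
#'
#' Geometric mean (GM), geometric standard deviation (GSD) and limit of
#' detection (LOD) for each of the four metals measured in each of the four
#' biological media, as reported for the adolescent cohort the generator
#' emulates. Units are medium-specific: blood and saliva ng/mL, hair
#' \eqn{\mu}g/g, urine \eqn{\mu}g/mL.
#'
#' @return A data frame with one row per (metal, medium) cell and columns
#'   `metal`, `medium`, `component`, `gm`, `gsd`, `lod`.
#' @examples
#' head(exposure_defaults())
#' @export
exposure_defaults <- function() {
  tbl <- rbind(
    # medium, metal,  gm,     gsd,  lod
    c("saliva", "Pb", 0.19,   3.07, 0.05),
    c("saliva", "Cr", 0.50,   3.69, 0.13),
    c("saliva", "Mn", 3.13,   2.97, 0.08),
    c("saliva", "Cu", 8.63,   2.35, 0.35),
    c("blood",  "Pb", 8.84,   1.56, 0.16),
    c("blood",  "Cr", 0.34,   4.54, 0.19),
    c("blood",  "Mn", 8.45,   1.49, 0.49),
    c("blood",  "Cu", 586.94, 1.30, 1.09),
    c("hair",   "Pb", 0.09,   2.97, 0.003),
    c("hair",   "Cr", 0.04,   2.57, 0.004),
    c("hair",   "Mn", 0.06,   2.58, 0.005),
    c("hair",   "Cu", 9.96,   1.62, 0.04),
    c("urine",  "Pb", 0.36,   2.17, 0.06),
    c("urine",  "Cr", 0.28,   3.07, 0.09),
    c("urine",  "Mn", 0.24,   3.69, 0.11),
    c("urine",  "Cu", 6.01,   1.85, 0.30)
  )
  out <- data.frame(
    metal = tbl[, 2], medium = tbl[, 1],
    gm = as.numeric(tbl[, 3]), gsd = as.numeric(tbl[, 4]),
    lod = as.numeric(tbl[, 5]),
    stringsAsFactors = FALSE
  )
  out$component <- component_label(out$metal, out$medium)
  # canonical order: metal-major, medium-minor
  out <- out[order(match(out$metal, METALS), match(out$medium, MEDIA)), ]
  rownames(out) <- NULL
  out[, c("metal", "medium", "component", "gm", "gsd", "lod")]
}

#' Configuration for the synthetic exposure generator
#'
#' @param params Data frame with columns `metal`, `medium`, `gm`, `gsd`,
#'   `lod` covering all 16 cells; defaults to [exposure_defaults()].
#' @param cross_media_rho Correlation in `[0, 1)` among log-concentrations of
#'   the same metal across media, induced by one latent factor per metal.
#' @param n_subjects Number of subjects to simulate.
#' @param seed Integer seed used by [generate_cohort()] unless overridden.
#' @return An object of class `exposure_config`.
#' @examples
#' cfg <- exposure_config(n_subjects = 50)
#' @export
exposure_config <- function(params = exposure_defaults(), cross_media_rho = 0.3,
                            n_subjects = 193L, seed = 1L) {
  need <- c("metal", "medium", "gm", "gsd", "lod")
  miss <- setdiff(need, names(params))
  if (length(miss)) stop("params is missing columns: ", paste(miss, collapse = ", "))
  key <- paste(params$metal, params$medium)
  want <- paste(rep(METALS, each = 4), rep(MEDIA, 4))
  if (!setequal(key, want) || anyDuplicated(key)) {
    stop("params must contain exactly one row per (metal, medium) cell, 16 in all")
  }
  if (any(params$gm <= 0)) stop("geometric means must be positive")
  if (any(params$gsd < 1)) stop("geometric standard deviations must be >= 1")
  if (any(params$lod < 0)) stop("limits of detection must be nonnegative")
  if (cross_media_rho < 0 || cross_media_rho >= 1) {
    stop("cross_media_rho must lie in [0, 1) for a positive-definite latent correlation")
  }
  if (n_subjects < 1) stop("n_subjects must be positive")
  params <- params[order(match(params$metal, METALS), match(params$medium, MEDIA)), ]
  rownames(params) <- NULL
  params$component <- component_label(params$metal, params$medium)
  structure(
    list(params = params, cross_media_rho = cross_media_rho,
         n_subjects = as.integer(n_subjects), seed = as.integer(seed)),
    class = "exposure_config"
  )
}

#' Ground truth for synthetic cohorts
#'
#' Defines the data-generating effect structure recorded verbatim in every
#' generated cohort so that recovery tests can compare estimates against it:
#' per-metal media weights (level 1), cross-metal mixture weights (level 2),
#' the signed effect of the unit-scaled mixture index on each network
#' outcome, covariate effects and residual noise.
#'
#' Default effect sizes follow the cohort analysis the generator emulates:
#' the mixture lowers global efficiency by 0.076 and local efficiency by
#' 0.048 per unit of the scaled index; lead and chromium carry the largest
#' metal weights and urine the largest media weights.
#'
#' @param level1_weights 4 x 4 matrix (rows metals Mn/Pb/Cr/Cu, columns media
#'   blood/urine/hair/saliva); each row a simplex vector.
#' @param level2_weights Simplex 4-vector over metals (Mn, Pb, Cr, Cu).
#' @param beta_ge,beta_le Signed effect of the unit-scaled mixture index on
#'   global and mean local efficiency.
#' @param intercept_ge,intercept_le Outcome intercepts (efficiency scale, 0-1).
#' @param age_effect Outcome change per year of age (age centered at 20).
#' @param sex_effect Outcome difference for sex code 1 vs 0.
#' @param noise_sd Residual standard deviation of the outcomes; must be >= 0.
#' @return An object of class `ground_truth`.
#' @examples
#' tr <- ground_truth()
#' rowSums(tr$level1_weights)
#' @export
ground_truth <- function(level1_weights = NULL,
                         level2_weights = c(Mn = 0.24, Pb = 0.29, Cr = 0.29, Cu = 0.18),
                         beta_ge = -0.076, beta_le = -0.048,
                         intercept_ge = 0.65, intercept_le = 0.78,
                         age_effect = -0.002, sex_effect = 0.01,
                         noise_sd = 0.02) {
  if (is.null(level1_weights)) {
    level1_weights <- rbind(
      Mn = c(blood = 0.21, urine = 0.51, hair = 0.16, saliva = 0.12),
      Pb = c(blood = 0.24, urine = 0.46, hair = 0.17, saliva = 0.13),
      Cr = c(blood = 0.28, urine = 0.34, hair = 0.22, saliva = 0.16),
      Cu = c(blood = 0.14, urine = 0.68, hair = 0.10, saliva = 0.08)
    )
  }
  level1_weights <- as.matrix(level1_weights)
  if (!identical(dim(level1_weights), c(4L, 4L))) {
    stop("level1_weights must be a 4 x 4 matrix (metals x media)")
  }
  if (is.null(rownames(level1_weights))) rownames(level1_weights) <- METALS
  if (is.null(colnames(level1_weights))) colnames(level1_weights) <- MEDIA
  level1_weights <- level1_weights[METALS, MEDIA]
  for (m in METALS) {
    if (!is_simplex(level1_weights[m, ])) {
      stop("level1 weights for ", m, " must be nonnegative and sum to 1")
    }
  }
  level2_weights <- level2_weights[METALS]
  if (anyNA(level2_weights) || !is_simplex(level2_weights)) {
    stop("level2_weights must be a simplex vector named by the four metals")
  }
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(
    list(level1_weights = level1_weights, level2_weights = level2_weights,
         beta_ge = beta_ge, beta_le = beta_le,
         intercept_ge = intercept_ge, intercept_le = intercept_le,
         age_effect = age_effect, sex_effect = sex_effect,
         noise_sd = noise_sd),
    class = "ground_truth"
  )
}

#' Generate a synthetic exposure cohort
#'
#' Draws, for each subject, concentrations of the 4 metals in the 4 media
#' from log-normal distributions with the configured geometric means and
#' GSDs. Media of the same metal share one latent Gaussian factor so their
#' log-concentrations correlate at `cross_media_rho`. Values below the
#' cell's LOD are flagged censored but stored as drawn (downstream imputation
#' is a modelling step, not a generator step). Covariates are age ~
#' Uniform(15, 25) and sex ~ Bernoulli(0.53). The latent mixture burden of
#' each subject is the level-2-weighted combination of re-deciled
#' level-1-weighted decile scores, rescaled to `[0, 1]`.
#'
#' @param config An [exposure_config()].
#' @param truth A [ground_truth()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return An object of class `cohort_bundle` with elements `exposures`
#'   (long data frame: `subject_id`, `metal`, `medium`, `component`, `value`,
#'   `lod`, `censored`), `covariates` (`subject_id`, `age`, `sex`), `truth`,
#'   `burden` (per-subject latent index in `[0, 1]`) and `config`.
#' @examples
#' cohort <- generate_cohort(exposure_config(n_subjects = 30), seed = 7)
#' nrow(cohort$exposures)  # 30 subjects x 16 components
#' @export
generate_cohort <- function(config, truth = ground_truth(), seed = config$seed) {
  stopifnot(inherits(config, "exposure_config"), inherits(truth, "ground_truth"))
  n <- config$n_subjects
  p <- config$params
  rho <- config$cross_media_rho
  vals <- matrix(NA_real_, n, 16L, dimnames = list(NULL, p$component))
  with_seed(seed, {
    for (m in METALS) {
      z <- rnorm(n) # latent body-burden factor shared by the metal's media
      for (med in MEDIA) {
        row <- p[p$metal == m & p$medium == med, ]
        e <- rnorm(n)
        logx <- log(row$gm) + log(row$gsd) * (sqrt(rho) * z + sqrt(1 - rho) * e)
        vals[, row$component] <- exp(logx)
      }
    }
    age <- runif(n, 15, 25)
    sex <- rbinom(n, 1L, 0.53)
    covariates <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      age = age, sex = sex, stringsAsFactors = FALSE
    )
  })
  subject_id <- covariates$subject_id
  lod <- structure(p$lod, names = p$component)
  censored <- sweep(vals, 2L, lod[colnames(vals)], `<`)
  burden <- latent_burden(vals, truth)
  exposures <- data.frame(
    subject_id = rep(subject_id, times = 16L),
    metal = rep(p$metal, each = n),
    medium = rep(p$medium, each = n),
    component = rep(p$component, each = n),
    value = as.vector(vals),
    lod = rep(p$lod, each = n),
    censored = as.vector(censored),
    stringsAsFactors = FALSE
  )
  structure(
    list(exposures = exposures, covariates = covariates, truth = truth,
         burden = burden, config = config),
    class = "cohort_bundle"
  )
}

# Level-2-weighted combination of level-1-weighted within-subject decile
# scores, on the scale of the fitted mixture index, then rescaled to [0, 1].
latent_burden <- function(vals, truth) {
  n <- nrow(vals)
  q <- apply(vals, 2L, decile_transform, warn = FALSE)
  if (n == 1L) q <- matrix(q, nrow = 1L, dimnames = list(NULL, colnames(vals)))
  metal_idx <- matrix(NA_real_, n, 4L, dimnames = list(NULL, METALS))
  for (m in METALS) {
    comps <- component_label(m, MEDIA)
    metal_idx[, m] <- q[, comps, drop = FALSE] %*% truth$level1_weights[m, MEDIA]
  }
  q2 <- apply(metal_idx, 2L, decile_transform, warn = FALSE)
  if (n == 1L) q2 <- matrix(q2, nrow = 1L, dimnames = list(NULL, METALS))
  as.numeric(q2 %*% truth$level2_weights[METALS]) / 9
}

#' Generate network-efficiency outcomes directly from the latent burden
#'
#' "Direct mode": bypasses time-series simulation and draws per-subject
#' global and mean local efficiency as a linear function of the unit-scaled
#' latent mixture index, age (centered at 20 years), sex, and Gaussian
#' noise, clipped to `[0, 1]`. Useful for statistical recovery tests of the
#' WQS/MMB machinery with an exactly known effect.
#'
#' @param cohort A [generate_cohort()] result.
#' @param seed Integer seed for the outcome noise.
#' @return Data frame with columns `subject_id`, `ge`, `le_mean`.
#' @examples
#' cohort <- generate_cohort(exposure_config(n_subjects = 30), seed = 1)
#' head(generate_direct_outcomes(cohort, seed = 2))
#' @export
generate_direct_outcomes <- function(cohort, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_bundle"))
  tr <- cohort$truth
  if (tr$noise_sd < 0) stop("noise_sd must be nonnegative")
  n <- length(cohort$burden)
  cov <- cohort$covariates
  base <- tr$age_effect * (cov$age - 20) + tr$sex_effect * cov$sex
  with_seed(seed, {
    ge <- tr$intercept_ge + tr$beta_ge * cohort$burden + base +
      rnorm(n, sd = tr$noise_sd)
    le <- tr$intercept_le + tr$beta_le * cohort$burden + base +
      rnorm(n, sd = tr$noise_sd)
  })
  data.frame(
    subject_id = cov$subject_id,
    ge = pmin(pmax(ge, 0), 1),
    le_mean = pmin(pmax(le, 0), 1),
    stringsAsFactors = FALSE
  )
}

# Stationary AR(1) series (T x k), unit marginal variance, innovations iid.
ar1_matrix <- function(n_t, k, phi) {
  e <- matrix(rnorm(n_t * k), n_t, k)
  x <- e
  s <- sqrt(1 - phi^2)
  for (t in seq_len(n_t)[-1]) x[t, ] <- phi * x[t - 1L, ] + s * e[t, ]
  x
}

#' Generate synthetic ROI time series with burden-dependent coupling
#'
#' Per subject, simulates a stationary multivariate AR(1) series whose
#' stationary correlation has a modular block structure: `within_coupling`
#' inside modules and a between-module coupling that decreases linearly in
#' the subject's latent mixture burden,
#' `coupling_base + coupling_slope * burden`. Lowering between-module
#' coupling weakens network integration, so global efficiency of the
#' estimated connectome falls with burden. Synthetic nuisance signals
#' (6 motion parameters, white-matter and CSF averages) are generated and
#' mixed into the ROI data so that confound regression has real work to do.
#'
#' @param cohort A [generate_cohort()] result (supplies the burden).
#' @param n_rois Number of regions; default 111 (whole-brain cortical +
#'   subcortical + brainstem parcellation).
#' @param n_timepoints Number of volumes; default 600 (10 min at TR = 1 s).
#' @param n_modules Number of correlation modules.
#' @param coupling_base,coupling_slope Between-module correlation at zero
#'   burden and its change per unit burden; the realized coupling must stay
#'   in `[0, 1)` and below `within_coupling`.
#' @param within_coupling Within-module correlation.
#' @param ar_phi Temporal lag-1 autocorrelation of every signal.
#' @param nuisance_scale Standard deviation of the random mixing
#'   coefficients of the 8 nuisance signals into the ROI data.
#' @param tr Repetition time in seconds (metadata only).
#' @param seed Integer seed.
#' @return An object of class `roi_timeseries_set`: list with `subjects`
#'   (named list of [roi_timeseries()] objects), `modules` (ROI module
#'   assignment) and `params`.
#' @examples
#' cohort <- generate_cohort(exposure_config(n_subjects = 3), seed = 1)
#' ts <- generate_timeseries(cohort, n_rois = 20, n_timepoints = 80,
#'                           n_modules = 2, seed = 2)
#' dim(ts$subjects[[1]]$data)
#' @export
generate_timeseries <- function(cohort, n_rois = 111L, n_timepoints = 600L,
                                n_modules = 6L, coupling_base = 0.45,
                                coupling_slope = -0.25, within_coupling = 0.65,
                                ar_phi = 0.3, nuisance_scale = 0.4, tr = 1,
                                seed = 1L) {
  stopifnot(inherits(cohort, "cohort_bundle"))
  if (n_modules < 1L || n_rois < n_modules) stop("need n_rois >= n_modules >= 1")
  burden <- cohort$burden
  coupling <- coupling_base + coupling_slope * burden
  if (any(coupling < 0) || any(coupling >= 1)) {
    stop("between-module coupling leaves [0, 1) for some subjects; adjust coupling_base/slope")
  }
  if (any(coupling >= within_coupling)) {
    stop("between-module coupling must stay below within_coupling")
  }
  modules <- sort(rep_len(seq_len(n_modules), n_rois))
  same_module <- outer(modules, modules, `==`)
  roi_labels <- sprintf("ROI%03d", seq_len(n_rois))
  subjects <- vector("list", length(burden))
  names(subjects) <- cohort$covariates$subject_id
  with_seed(seed, {
    for (i in seq_along(burden)) {
      sigma <- matrix(coupling[i], n_rois, n_rois)
      sigma[same_module] <- within_coupling
      diag(sigma) <- 1
      cr <- chol(sigma)
      innov <- matrix(rnorm(n_timepoints * n_rois), n_timepoints, n_rois) %*% cr
      x <- innov
      s <- sqrt(1 - ar_phi^2)
      for (t in seq_len(n_timepoints)[-1]) x[t, ] <- ar_phi * x[t - 1L, ] + s * innov[t, ]
      motion <- ar1_matrix(n_timepoints, 6L, 0.85)
      wm <- ar1_matrix(n_timepoints, 1L, 0.85)[, 1L]
      csf <- ar1_matrix(n_timepoints, 1L, 0.85)[, 1L]
      mix <- matrix(rnorm(8L * n_rois, sd = nuisance_scale), 8L, n_rois)
      data <- x + cbind(motion, wm, csf) %*% mix
      colnames(data) <- roi_labels
      subjects[[i]] <- roi_timeseries(data, motion, wm, csf, tr = tr)
    }
  })
  structure(
    list(subjects = subjects, modules = modules,
         params = list(n_rois = n_rois, n_timepoints = n_timepoints,
                       n_modules = n_modules, coupling_base = coupling_base,
                       coupling_slope = coupling_slope,
                       within_coupling = within_coupling, ar_phi = ar_phi,
                       nuisance_scale = nuisance_scale, tr = tr, seed = seed)),
    class = "roi_timeseries_set"
  )
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("Synthetic exposure cohort:", length(x$burden), "subjects,",
      nrow(x$exposures), "exposure records (16 components each)\n")
  cat(sprintf("  censored below LOD: %.1f%%\n", 100 * mean(x$exposures$censored)))
  cat(sprintf("  latent burden range: [%.3f, %.3f]\n",
              min(x$burden), max(x$burden)))
  invisible(x)
}
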