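#' Decile (quantile) scoring of an exposure column
#'
#' Rank-based assignment into `n_quantiles` bins scored `0 ..
#' n_quantiles - 1`. Ties share the bin of their average rank, which keeps
#' the transform deterministic and invariant under strictly monotone
#' transformations of the input. A constant column maps to all zeros.
#'
#' @param values Numeric vector (censored values already imputed).
#' @param n_quantiles Number of bins; default 10 (deciles).
#' @param warn Warn when fewer observations than bins.
#' @return Integer vector of scores in `0 .. n_quantiles - 1`.
#' @examples
#' decile_transform(1:10)
#' @export
decile_transform <- function(values, n_quantiles = 10L, warn = TRUE) {
  n <- length(values)
  if (n == 0L) stop("cannot quantile-score an empty vector")
  if (anyNA(values)) stop("values must not contain NA")
  if (warn && n < n_quantiles) {
    warning("fewer observations (", n, ") than quantile bins (", n_quantiles, ")")
  }
  if (length(unique(values)) == 1L) return(rep(0L, n))
  r <- rank(values, ties.method = "average")
  as.integer(pmin(floor((r - 1) * n_quantiles / n), n_quantiles - 1L))
}

# Cache of nonempty index subsets of 1..p, used by the exact QP solver.
.subset_cache <- new.env(parent = emptyenv())
nonempty_subsets <- function(p) {
  key <- as.character(p)
  if (is.null(.subset_cache[[key]])) {
    .subset_cache[[key]] <- unlist(
      lapply(seq_len(p), function(k) combn(p, k, simplify = FALSE)),
      recursive = FALSE
    )
  }
  .subset_cache[[key]]
}

# Core sign-constrained WQS least squares.
#
# Minimizing ||y - X b - beta1 (Q w)||^2 over simplex w and sign-constrained
# beta1 is, in theta = beta1 * w, exactly sign-constrained least squares:
# min ||y - X b - Q theta||^2 with dir_sign * theta >= 0. Profiling out the
# unconstrained b (Frisch-Waugh) leaves a convex QP in theta built from the
# crossproduct of [X Q y]. For p <= 8 the optimum is found exactly by
# enumerating supports (on its support the solution is the unconstrained LS
# of that subset and sign-feasible); larger p falls back to Lawson-Hanson
# NNLS. Returns theta, beta1 = sum(theta), w = theta / beta1 (uniform when
# the constraint binds at beta1 = 0), the residual sum of squares, and the
# profiled covariate coefficients.
wqs_solve_core <- function(Q, y, X, dir_sign, method = c("auto", "enum", "nnls")) {
  method <- match.arg(method)
  p <- ncol(Q)
  k <- ncol(X)
  M <- crossprod(cbind(X, Q, y))
  iX <- seq_len(k)
  iQ <- k + seq_len(p)
  iy <- k + p + 1L
  XtX <- M[iX, iX, drop = FALSE]
  B <- M[iX, c(iQ, iy), drop = FALSE]
  A <- tryCatch(solve(XtX, B), error = function(e) NULL)
  if (is.null(A)) stop("covariate design matrix is rank deficient (collinear columns)")
  G <- M[iQ, iQ, drop = FALSE] - crossprod(B[, seq_len(p), drop = FALSE], A[, seq_len(p), drop = FALSE])
  h <- M[iQ, iy] - as.numeric(crossprod(B[, seq_len(p), drop = FALSE], A[, p + 1L]))
  yy <- M[iy, iy] - sum(B[, p + 1L] * A[, p + 1L])
  theta <- numeric(p)
  rss <- yy
  if (method == "nnls" || (method == "auto" && p > 8L)) {
    qrX <- qr(X)
    ry <- qr.resid(qrX, y)
    rq <- qr.resid(qrX, Q)
    u <- pracma::lsqnonneg(dir_sign * rq, ry)$x
    theta <- dir_sign * u
    rss <- sum((ry - rq %*% theta)^2)
  } else {
    for (S in nonempty_subsets(p)) {
      thS <- tryCatch(solve(G[S, S, drop = FALSE], h[S]), error = function(e) NULL)
      if (is.null(thS) || any(!is.finite(thS))) next
      if (any(dir_sign * thS < -1e-10)) next
      thS[dir_sign * thS < 0] <- 0
      rssS <- yy - sum(thS * h[S])
      if (rssS < rss) {
        rss <- rssS
        theta <- numeric(p)
        theta[S] <- thS
      }
    }
  }
  beta1 <- sum(theta)
  w <- if (abs(beta1) > 0) theta / beta1 else rep(1 / p, p)
  b <- as.numeric(A[, p + 1L] - A[, seq_len(p), drop = FALSE] %*% theta)
  list(theta = theta, beta1 = beta1, w = w, rss = max(rss, 0), coef = b)
}

# OLS of y on [X, z]; returns the coefficient, standard error and two-sided
# p-value of z. Used for the validation-split index regression.
lm_index_test <- function(z, y, X) {
  D <- cbind(X, index = z)
  n <- length(y)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    return(list(beta = 0, se = NA_real_, pvalue = 1))
  }
  cf <- qr.coef(qrD, y)
  res <- qr.resid(qrD, y)
  df <- n - ncol(D)
  if (df < 1L) stop("validation split too small for the index regression")
  s2 <- sum(res^2) / df
  xtxi <- chol2inv(chol(crossprod(D)))
  se <- sqrt(s2 * xtxi[ncol(D), ncol(D)])
  tv <- cf[["index"]] / se
  list(beta = cf[["index"]], se = se, pvalue = 2 * pt(-abs(tv), df))
}

build_design <- function(covariates, n) {
  if (is.null(covariates)) {
    return(matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)")))
  }
  cm <- as.matrix(as.data.frame(covariates))
  if (nrow(cm) != n) stop("covariates must have one row per subject")
  if (anyNA(cm)) stop("covariates must not contain NA")
  storage.mode(cm) <- "double"
  cbind("(Intercept)" = 1, cm)
}

as_decile_matrix <- function(q) {
  q <- as.matrix(q)
  if (anyNA(q)) stop("decile matrix must not contain NA")
  if (ncol(q) < 2L) stop("need at least 2 mixture components")
  if (is.null(colnames(q))) colnames(q) <- paste0("C", seq_len(ncol(q)))
  storage.mode(q) <- "double"
  q
}

#' Sign-constrained WQS fit on one data set
#'
#' Minimizes the squared error of
#' `y ~ beta0 + beta1 * (Q w) + covariates` over simplex weights `w` and an
#' index coefficient `beta1` constrained to the requested sign (`beta1 = 0`
#' allowed; the weights then default to uniform). Solved exactly as a
#' convex sign-constrained least-squares problem, so the fit is
#' deterministic.
#'
#' @param q Subject x component matrix of quantile scores
#'   (see [decile_transform()]).
#' @param y Numeric outcome vector.
#' @param covariates Optional data frame / matrix of adjustment covariates.
#' @param direction `"negative"` or `"positive"` constraint on `beta1`.
#' @param method Solver: `"auto"` (exact support enumeration for up to 8
#'   components, NNLS beyond), `"enum"`, or `"nnls"`.
#' @return An object of class `wqs_fit`: `beta1`, named simplex `weights`,
#'   `coefficients` (intercept + covariates), `pvalue` (unconstrained
#'   t-test of the fitted index), and `rss`.
#' @examples
#' q <- cbind(a = decile_transform(rnorm(50)), b = decile_transform(rnorm(50)))
#' fit <- solve_constrained_fit(q, rnorm(50), direction = "negative")
#' sum(fit$weights)
#' @export
solve_constrained_fit <- function(q, y, covariates = NULL,
                                  direction = c("negative", "positive"),
                                  method = c("auto", "enum", "nnls")) {
  direction <- match.arg(direction)
  q <- as_decile_matrix(q)
  y <- as.numeric(y)
  if (nrow(q) != length(y)) stop("q and y must have aligned rows")
  X <- build_design(covariates, length(y))
  dir_sign <- if (direction == "negative") -1 else 1
  fit <- wqs_solve_core(q, y, X, dir_sign, method = match.arg(method))
  pv <- if (fit$beta1 != 0) {
    lm_index_test(as.numeric(q %*% fit$w), y, X)$pvalue
  } else 1
  structure(
    list(beta1 = fit$beta1,
         weights = structure(fit$w, names = colnames(q)),
         coefficients = structure(fit$coef, names = colnames(X)),
         pvalue = pv, rss = fit$rss, direction = direction),
    class = "wqs_fit"
  )
}

weight_percentiles <- function(W) {
  probs <- c(0.10, 0.25, 0.50, 0.75, 0.90)
  qs <- apply(W, 2L, quantile, probs = probs, names = FALSE)
  out <- data.frame(component = colnames(W), mean = colMeans(W),
                    stringsAsFactors = FALSE)
  out[paste0("p", probs * 100)] <- t(qs)
  rownames(out) <- NULL
  out
}

#' Repeated-holdout WQS with bootstrap weight ensembles
#'
#' For each of `n_holdouts` random train/validation partitions: the
#' sign-constrained fit is estimated on `n_boot` bootstrap resamples of the
#' training split and the weight vectors averaged; the mixture index is
#' computed on the validation split with the averaged weights, and a linear
#' model of the outcome on the index and covariates gives that holdout's
#' index coefficient and p-value. The mean of the holdout coefficients is
#' the point estimate and their 2.5th/97.5th percentiles the 95% CI.
#'
#' @inheritParams solve_constrained_fit
#' @param n_boot Bootstrap resamples per holdout (default 50).
#' @param n_holdouts Random partitions (default 100).
#' @param train_fraction Fraction of subjects in the training split
#'   (default 0.6).
#' @param seed Integer seed; the whole resampling lattice is reproducible
#'   from it.
#' @return An object of class `wqs_ensemble` with per-holdout `betas`,
#'   `pvalues` and `weights` (holdouts x components), `beta_mean`,
#'   `beta_ci`, and a `weight_summary` table (mean and
#'   10/25/50/75/90th percentiles per component).
#' @examples
#' set.seed(1)
#' q <- cbind(a = decile_transform(rnorm(80)), b = decile_transform(rnorm(80)))
#' y <- 0.5 - 0.02 * (q %*% c(0.7, 0.3)) + rnorm(80, sd = 0.02)
#' fit <- fit_wqs_repeated(q, y, n_boot = 5, n_holdouts = 10, seed = 1)
#' fit$beta_mean
#' @export
fit_wqs_repeated <- function(q, y, covariates = NULL,
                             direction = c("negative", "positive"),
                             n_boot = 50L, n_holdouts = 100L,
                             train_fraction = 0.6, seed = 1L) {
  direction <- match.arg(direction)
  q <- as_decile_matrix(q)
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(q) != n) stop("q and y must have aligned rows")
  if (n_boot < 1L || n_holdouts < 1L) stop("n_boot and n_holdouts must be >= 1")
  if (train_fraction <= 0 || train_fraction >= 1) stop("train_fraction must be in (0, 1)")
  X <- build_design(covariates, n)
  dir_sign <- if (direction == "negative") -1 else 1
  n_train <- round(train_fraction * n)
  n_val <- n - n_train
  if (n_val < ncol(X) + 2L) {
    stop("validation split (", n_val, " subjects) is smaller than the covariate count + 2")
  }
  p <- ncol(q)
  hseeds <- spawn_seeds(seed, n_holdouts)
  betas <- numeric(n_holdouts)
  pvals <- numeric(n_holdouts)
  W <- matrix(NA_real_, n_holdouts, p, dimnames = list(NULL, colnames(q)))
  with_seed(seed, {
    for (h in seq_len(n_holdouts)) {
      set.seed(hseeds[h])
      train <- sample.int(n, n_train)
      val <- setdiff(seq_len(n), train)
      wb <- matrix(NA_real_, n_boot, p)
      for (b in seq_len(n_boot)) {
        idx <- sample(train, n_train, replace = TRUE)
        wb[b, ] <- wqs_solve_core(q[idx, , drop = FALSE], y[idx],
                                  X[idx, , drop = FALSE], dir_sign)$w
      }
      wbar <- colMeans(wb)
      z <- as.numeric(q[val, , drop = FALSE] %*% wbar)
      fit <- lm_index_test(z, y[val], X[val, , drop = FALSE])
      betas[h] <- fit$beta
      pvals[h] <- fit$pvalue
      W[h, ] <- wbar
    }
  })
  structure(
    list(betas = betas, pvalues = pvals, weights = W,
         beta_mean = mean(betas),
         beta_ci = unname(quantile(betas, c(0.025, 0.975))),
         weight_summary = weight_percentiles(W),
         component_labels = colnames(q), direction = direction,
         n_boot = as.integer(n_boot), n_holdouts = as.integer(n_holdouts),
         train_fraction = train_fraction, seed = as.integer(seed)),
    class = "wqs_ensemble"
  )
}

#' Components with above-threshold mean weights
#'
#' In a mixture of `p` components an uninformative model spreads weight
#' uniformly at `1/p`; components whose mean weight strictly exceeds this
#' (or a supplied) threshold are flagged as driving the association.
#'
#' @param result A [fit_wqs_repeated()] result.
#' @param threshold Weight threshold; defaults to `1 / n_components`.
#' @return Data frame with `component` and `mean_weight`, sorted by
#'   decreasing weight; zero rows when no component exceeds the threshold.
#' @export
significant_components <- function(result, threshold = NULL) {
  stopifnot(inherits(result, "wqs_ensemble"))
  wbar <- colMeans(result$weights)
  if (is.null(threshold)) threshold <- 1 / length(wbar)
  keep <- wbar > threshold
  out <- data.frame(component = names(wbar)[keep],
                    mean_weight = unname(wbar[keep]),
                    stringsAsFactors = FALSE)
  out[order(-out$mean_weight), , drop = FALSE]
}

#' @export
print.wqs_ensemble <- function(x, ...) {
  cat(sprintf("Repeated-holdout WQS (%d holdouts x %d bootstraps, direction %s)\n",
              x$n_holdouts, x$n_boot, x$direction))
  cat(sprintf("  beta = %.4f, 95%% CI (%.4f, %.4f)\n",
              x$beta_mean, x$beta_ci[1], x$beta_ci[2]))
  ws <- x$weight_summary[order(-x$weight_summary$mean), c("component", "mean")]
  cat("  mean weights:",
      paste(sprintf("%s %.3f", ws$component, ws$mean), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.wqs_fit <- function(x, ...) {
  cat(sprintf("Sign-constrained WQS fit (direction %s): beta1 = %.4f\n",
              x$direction, x$beta1))
  cat("  weights:",
      paste(sprintf("%s %.3f", names(x$weights), x$weights), collapse = ", "), "\n")
  invisible(x)
}
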