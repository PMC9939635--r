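test_that("decile scoring follows the rank-based contract", {
  expect_equal(decile_transform(1:10), 0:9)
  expect_equal(decile_transform(10:1), 9:0)
  # 20 distinct values: every bin holds exactly 2
  set.seed(301)
  v <- sample(rnorm(20))
  expect_equal(as.vector(table(decile_transform(v))), rep(2L, 10))
  # constant column maps to all zeros
  expect_equal(decile_transform(rep(3.2, 15)), rep(0L, 15))
  # ties share the average-rank bin
  q <- decile_transform(c(1, 2, 2, 4:20))
  expect_equal(q[2], q[3])
  expect_error(decile_transform(numeric(0)), "empty")
  expect_warning(decile_transform(1:5), "fewer observations")
})

test_that("decile scoring is invariant under strictly monotone transforms", {
  set.seed(302)
  v <- rlnorm(57)
  q <- decile_transform(v)
  expect_identical(decile_transform(log(v)), q)
  expect_identical(decile_transform(1000 * v + 5), q)
  expect_identical(decile_transform(v^3), q)
  # bin counts differ by at most 1 for distinct values
  expect_lte(diff(range(table(q))), 1)
})

test_that("the constrained solver recovers a noiseless mixture exactly", {
  set.seed(303)
  q <- random_decile_matrix(200, 2, c("a", "b"))
  y <- -(0.7 * q[, 1] + 0.3 * q[, 2])
  fit <- solve_constrained_fit(q, y, direction = "negative")
  expect_equal(unname(fit$weights), c(0.7, 0.3), tolerance = 1e-6)
  expect_equal(fit$beta1, -1, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)
})

test_that("the solver matches a dense simplex grid search", {
  set.seed(304)
  for (p in 2:3) {
    q <- random_decile_matrix(150, p)
    cov <- data.frame(age = runif(150, 15, 25), sex = rbinom(150, 1, 0.5))
    w_true <- if (p == 2L) c(0.6, 0.4) else c(0.5, 0.3, 0.2)
    # noiseless, grid-aligned optimum: solver and grid agree to 1e-6
    y0 <- 0.7 - 0.03 * as.numeric(q %*% w_true) - 0.002 * cov$age
    fit0 <- solve_constrained_fit(q, y0, cov, direction = "negative")
    expect_lt(abs(grid_wqs_rss(q, y0, cov, "negative") - fit0$rss), 1e-6)
    # noisy: the exact solver is never beaten by the dense grid
    y <- y0 + rnorm(150, sd = 0.05)
    fit <- solve_constrained_fit(q, y, cov, direction = "negative")
    expect_lte(fit$rss, grid_wqs_rss(q, y, cov, "negative") + 1e-12)
  }
})

test_that("the sign constraint binds on oppositely-signed data", {
  set.seed(305)
  q <- random_decile_matrix(300, 3)
  y <- as.numeric(q %*% c(0.5, 0.3, 0.2)) + rnorm(300, sd = 0.1)
  fit <- solve_constrained_fit(q, y, direction = "negative")
  expect_equal(fit$beta1, 0)
  expect_equal(fit$pvalue, 1)
  # and under the right sign the effect is found
  fit_pos <- solve_constrained_fit(q, y, direction = "positive")
  expect_gt(fit_pos$beta1, 0.9)
})

test_that("the solver returns a near-zero index on independent data", {
  set.seed(306)
  q <- random_decile_matrix(1000, 4)
  y <- rnorm(1000)
  fit <- solve_constrained_fit(q, y, direction = "negative")
  expect_lt(abs(fit$beta1), 0.05)
})

test_that("support enumeration and NNLS solvers agree", {
  set.seed(307)
  q <- random_decile_matrix(200, 5)
  y <- 1 - 0.05 * as.numeric(q %*% c(0.4, 0.3, 0.2, 0.1, 0)) + rnorm(200, sd = 0.1)
  fe <- solve_constrained_fit(q, y, direction = "negative", method = "enum")
  fn <- solve_constrained_fit(q, y, direction = "negative", method = "nnls")
  expect_equal(fe$rss, fn$rss, tolerance = 1e-8)
  expect_equal(fe$weights, fn$weights, tolerance = 1e-5)
})

test_that("every weight vector produced anywhere lies on the simplex", {
  set.seed(308)
  for (rep in 1:10) {
    p <- sample(2:6, 1)
    q <- random_decile_matrix(80, p)
    y <- rnorm(80)
    fit <- solve_constrained_fit(q, y, direction = sample(c("negative", "positive"), 1))
    expect_true(all(fit$weights >= 0))
    expect_equal(sum(fit$weights), 1, tolerance = 1e-8)
  }
  q <- random_decile_matrix(120, 4)
  y <- 0.5 - 0.02 * as.numeric(q %*% rep(0.25, 4)) + rnorm(120, sd = 0.05)
  ens <- fit_wqs_repeated(q, y, n_boot = 10, n_holdouts = 15, seed = 9)
  expect_true(all(abs(rowSums(ens$weights) - 1) < 1e-8))
  expect_equal(sum(colMeans(ens$weights)), 1, tolerance = 1e-8)
})

test_that("repeated-holdout WQS recovers generator weights and is reproducible", {
  set.seed(309)
  n <- 500
  q <- random_decile_matrix(n, 4, c("a", "b", "c", "d"))
  w_true <- c(0.5, 0.3, 0.2, 0.0)
  y <- 0.7 - 0.5 * as.numeric(q %*% w_true) / 9 + rnorm(n, sd = 0.02)
  ens <- fit_wqs_repeated(q, y, n_boot = 20, n_holdouts = 40, seed = 11)
  expect_true(all(abs(colMeans(ens$weights) - w_true) < 0.10))
  expect_lt(ens$beta_ci[2], 0) # CI excludes zero
  # with a real negative effect every holdout coefficient is negative
  expect_true(all(ens$betas <= 0))
  # bit-reproducibility under a fixed seed
  ens2 <- fit_wqs_repeated(q, y, n_boot = 20, n_holdouts = 40, seed = 11)
  expect_identical(ens$betas, ens2$betas)
  expect_identical(ens$weights, ens2$weights)
  # different seed shuffles the resampling lattice
  ens3 <- fit_wqs_repeated(q, y, n_boot = 20, n_holdouts = 40, seed = 12)
  expect_false(identical(ens$betas, ens3$betas))
})

test_that("ensemble summaries and significance screening behave", {
  set.seed(310)
  q <- random_decile_matrix(150, 4, c("w", "x", "y", "z"))
  yv <- 0.6 - 0.04 * as.numeric(q %*% c(0.7, 0.3, 0, 0)) + rnorm(150, sd = 0.05)
  ens <- fit_wqs_repeated(q, yv, n_boot = 10, n_holdouts = 20, seed = 2)
  ws <- ens$weight_summary
  expect_named(ws, c("component", "mean", "p10", "p25", "p50", "p75", "p90"))
  expect_true(all(ws$p10 <= ws$p25 & ws$p25 <= ws$p50 &
                  ws$p50 <= ws$p75 & ws$p75 <= ws$p90))
  expect_gte(ens$beta_mean, ens$beta_ci[1])
  expect_lte(ens$beta_mean, ens$beta_ci[2])
  # screening: strict threshold, descending order
  fake <- structure(list(weights = matrix(rep(c(0.46, 0.30, 0.14, 0.10), each = 5),
                                          5, 4, dimnames = list(NULL, c("a", "b", "c", "d")))),
                    class = "wqs_ensemble")
  hits <- significant_components(fake)
  expect_equal(hits$component, c("a", "b"))
  unif <- structure(list(weights = matrix(0.25, 5, 4,
                                          dimnames = list(NULL, c("a", "b", "c", "d")))),
                    class = "wqs_ensemble")
  expect_equal(nrow(significant_components(unif)), 0L)
  dom <- structure(list(weights = matrix(c(1, 0, 0, 0), 5, 4, byrow = TRUE,
                                         dimnames = list(NULL, c("a", "b", "c", "d")))),
                   class = "wqs_ensemble")
  expect_equal(significant_components(dom)$component, "a")
})

test_that("alignment and split-size errors are reported", {
  q <- random_decile_matrix(30, 3)
  expect_error(fit_wqs_repeated(q, rnorm(29), seed = 1), "aligned")
  expect_error(fit_wqs_repeated(q, rnorm(30), train_fraction = 0.95, seed = 1),
               "validation split")
  expect_error(solve_constrained_fit(q[, 1, drop = FALSE], rnorm(30)),
               "2 mixture components")
  # collinear covariates
  cv <- data.frame(a = 1:30, b = 2 * (1:30))
  expect_error(solve_constrained_fit(q, rnorm(30), cv), "rank deficient")
})
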