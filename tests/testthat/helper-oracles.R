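# Independent brute-force oracles used to validate the implementation.

# Floyd-Warshall all-pairs shortest paths with edge lengths 1/weight.
fw_dists <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[w > 0] <- 1 / w[w > 0]
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

fw_global_efficiency <- function(w) {
  n <- nrow(w)
  d <- fw_dists(w)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

fw_local_efficiency <- function(w) {
  n <- nrow(w)
  sapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2L) return(0)
    fw_global_efficiency(w[nb, nb, drop = FALSE])
  })
}

# Random symmetric weight matrix in [0, 1], zero diagonal.
random_weight_matrix <- function(n, density = 0.6) {
  w <- matrix(0, n, n)
  up <- upper.tri(w)
  vals <- runif(sum(up))
  vals[runif(sum(up)) > density] <- 0
  w[up] <- vals
  w + t(w)
}

# Dense simplex grid search oracle for the sign-constrained WQS fit.
# Profiles beta/covariates by OLS at each grid weight vector; when the
# unconstrained index coefficient has the wrong sign the constrained
# optimum at that w is beta1 = 0, i.e. the covariates-only fit.
grid_wqs_rss <- function(q, y, covariates = NULL, direction = "negative",
                         step = 0.01) {
  p <- ncol(q)
  X <- matrix(1, nrow(q), 1)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(as.data.frame(covariates)))
  qrX <- qr(X)
  rss0 <- sum(qr.resid(qrX, y)^2)
  grid <- seq(0, 1, by = step)
  ws <- if (p == 2L) {
    lapply(grid, function(a) c(a, 1 - a))
  } else if (p == 3L) {
    out <- list()
    for (a in grid) for (b in grid[grid <= 1 - a + 1e-12]) {
      out[[length(out) + 1L]] <- c(a, b, 1 - a - b)
    }
    out
  } else {
    stop("grid oracle implemented for 2-3 components only")
  }
  best <- rss0
  for (w in ws) {
    z <- as.numeric(q %*% w)
    D <- cbind(X, z)
    qrD <- qr(D)
    if (qrD$rank < ncol(D)) next
    b1 <- qr.coef(qrD, y)[ncol(D)]
    ok <- if (direction == "negative") b1 <= 0 else b1 >= 0
    rss <- if (ok) sum(qr.resid(qrD, y)^2) else rss0
    if (rss < best) best <- rss
  }
  best
}

# Small helper: a decile matrix from independent log-normal columns.
random_decile_matrix <- function(n, p, labels = paste0("C", seq_len(p))) {
  q <- sapply(seq_len(p), function(j) decile_transform(exp(rnorm(n)), warn = FALSE))
  colnames(q) <- labels
  q
}
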