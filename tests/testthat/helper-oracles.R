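# Independent oracles used across the suite. These deliberately avoid the
# package's solver code paths: grid search, normal equations, brute-force
# lattice enumeration and Monte-Carlo simulation.

# Two-stage grid-search minimizer of 0.5*(b - z)^2 + w * MCP(|b|; lambda,
# gamma); resolution ~1e-7 on [-lim, lim].
grid_min_univariate <- function(z, lambda, gamma, w = 1, lim = NULL) {
  if (is.null(lim)) lim <- max(5, abs(z) + 1)
  obj <- function(b) {
    t <- abs(b)
    pen <- ifelse(t <= gamma * lambda,
                  lambda * t - t^2 / (2 * gamma),
                  gamma * lambda^2 / 2)
    0.5 * (b - z)^2 + w * pen
  }
  g1 <- seq(-lim, lim, length.out = 20001)
  b1 <- g1[which.min(obj(g1))]
  step <- g1[2] - g1[1]
  g2 <- seq(b1 - 2 * step, b1 + 2 * step, length.out = 4001)
  g2[which.min(obj(g2))]
}

# Least squares by explicit normal equations.
ols_normal_equations <- function(X, y) {
  solve(crossprod(X), crossprod(X, y))
}

# Brute-force lattice minimum of the composite MCP objective over all
# penalized coefficients (no unpenalized columns). Returns the minimum
# objective value; enumerates res^p lattice points in chunks.
lattice_min_objective <- function(X, y, group, lambda, gamma_inner = 3,
                                  gamma_outer = 3, lim = 2, res = 201) {
  p <- ncol(X)
  n <- nrow(X)
  axis <- seq(-lim, lim, length.out = res)
  G <- crossprod(X) / n
  Xty <- crossprod(X, y) / n
  yty <- sum(y^2) / n
  Kg <- table(group)
  mcp_v <- function(t, l, g) ifelse(t <= g * l, l * t - t^2 / (2 * g),
                                    g * l^2 / 2)
  grids <- rep(list(axis), p)
  total <- res^p
  chunk <- 2e5
  best <- Inf
  idx0 <- 0
  while (idx0 < total) {
    take <- min(chunk, total - idx0)
    ids <- idx0 + seq_len(take)
    B <- matrix(0, take, p)
    rem <- ids - 1
    for (j in seq_len(p)) {
      B[, j] <- axis[rem %% res + 1]
      rem <- rem %/% res
    }
    # quadratic form: 0.5*(yty - 2 b'Xty + b'Gb)
    q <- yty - 2 * (B %*% Xty)
    for (a in seq_len(p)) for (b in seq_len(p)) {
      q <- q + G[a, b] * B[, a] * B[, b]
    }
    pen <- 0
    for (g in unique(group)) {
      cols <- which(group == g)
      s <- rowSums(matrix(mcp_v(abs(B[, cols, drop = FALSE]), lambda,
                                gamma_inner), nrow = take))
      pen <- pen + mcp_v(s / lambda, sum(group == g) * lambda, gamma_outer)
    }
    best <- min(best, min(q / 2 + pen))
    idx0 <- idx0 + take
  }
  best
}

# Monte-Carlo power of the two-sided two-sample t test.
mc_power_t <- function(n, d, alpha, B = 1e4, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * B, 0, 1), n, B)
  y <- matrix(rnorm(n * B, d, 1), n, B)
  mx <- colMeans(x); my <- colMeans(y)
  vx <- colSums((x - rep(mx, each = n))^2)
  vy <- colSums((y - rep(my, each = n))^2)
  sp <- sqrt((vx + vy) / (2 * n - 2))
  tstat <- (my - mx) / (sp * sqrt(2 / n))
  mean(abs(tstat) > qt(1 - alpha / 2, 2 * n - 2))
}

# Small strongly identified two-group fixture for solver tests.
solver_fixture <- function(n = 20, seed = 1, beta = c(1, -0.8, 0, 0),
                           sigma = 0.3) {
  set.seed(seed)
  p <- length(beta)
  X <- matrix(rnorm(n * p), n, p)
  X <- sweep(X, 2, colMeans(X))
  X <- sweep(X, 2, sqrt(colSums(X^2) / n), "/")
  y <- as.numeric(X %*% beta + rnorm(n, 0, sigma))
  list(X = X, y = y, group = rep(seq_len(p / 2), each = 2), beta = beta)
}
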