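# Composite MCP (cMCP) bi-level selection: penalty primitives, coordinate
# descent path, information-criterion model choice, and stationarity checks.

#' Minimax concave penalty (MCP)
#'
#' Evaluates the MCP, \eqn{\lambda\theta - \theta^2/(2\gamma)} for
#' \eqn{\theta \le \gamma\lambda} and the constant plateau
#' \eqn{\gamma\lambda^2/2} beyond. Continuous and non-decreasing in
#' \eqn{\theta}.
#'
#' @param theta Non-negative magnitude(s).
#' @param lambda Non-negative regularization parameter.
#' @param gamma Concavity parameter, must exceed 1.
#' @return Penalty value(s), same length as `theta`.
#' @export
#' @examples
#' mcp(0, 1, 3)          # 0
#' mcp(5, 1, 3)          # plateau: gamma * lambda^2 / 2 = 1.5
mcp <- function(theta, lambda, gamma) {
  check_gamma(gamma)
  if (any(!is.finite(theta)) || any(theta < 0)) {
    stop("`theta` must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(lambda)) || any(lambda < 0)) {
    stop("`lambda` must be finite and non-negative", call. = FALSE)
  }
  ifelse(theta <= gamma * lambda,
         lambda * theta - theta^2 / (2 * gamma),
         gamma * lambda^2 / 2)
}

#' MCP derivative
#'
#' \eqn{\max(0, \lambda - \theta/\gamma)} for \eqn{\theta \ge 0}; zero beyond
#' the plateau.
#' @inheritParams mcp
#' @return Derivative value(s).
#' @export
mcp_deriv <- function(theta, lambda, gamma) {
  check_gamma(gamma)
  pmax(0, lambda - theta / gamma)
}

#' Firm thresholding operator
#'
#' The exact minimizer of \eqn{\frac12 (z-b)^2 + MCP(|b|;\lambda,\gamma)}:
#' soft-thresholding inflated by \eqn{1/(1-1/\gamma)} inside the concave
#' region, the identity beyond \eqn{|z| > \gamma\lambda}. Odd in `z`.
#'
#' @param z Scalar or vector of unpenalized univariate solutions.
#' @inheritParams mcp
#' @return Thresholded value(s).
#' @export
#' @examples
#' firm_threshold(1, 0.5, 3)   # 0.75
#' firm_threshold(10, 0.5, 3)  # 10 (beyond gamma * lambda)
firm_threshold <- function(z, lambda, gamma) {
  check_gamma(gamma)
  ifelse(abs(z) <= gamma * lambda,
         sign(z) * pmax(0, abs(z) - lambda) / (1 - 1 / gamma),
         z)
}

check_gamma <- function(gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma <= 1) {
    stop("`gamma` must be a single finite number > 1", call. = FALSE)
  }
  invisible(gamma)
}

#' Penalty and solver parameters for the cMCP path
#'
#' @param lambda Optional decreasing positive grid of tuning values; when
#'   `NULL` a grid of `nlambda` log-spaced values from the data-determined
#'   `lambda_max` down to `lambda_min_ratio * lambda_max` is used.
#' @param nlambda Number of grid points for the automatic grid.
#' @param lambda_min_ratio Ratio of the smallest to the largest grid value.
#' @param gamma_inner MCP concavity for individual effects (members).
#' @param gamma_outer MCP concavity for protein groups.
#' @param tol Convergence tolerance on the maximum coefficient change per
#'   coordinate-descent sweep (standardized scale).
#' @param max_iter Sweep cap per grid point.
#' @return An object of class `cmcp_penalty_params`.
#' @export
cmcp_penalty_params <- function(lambda = NULL, nlambda = 100,
                                lambda_min_ratio = 0.001,
                                gamma_inner = 3, gamma_outer = 3,
                                tol = 1e-8, max_iter = 1e4) {
  check_gamma(gamma_inner)
  check_gamma(gamma_outer)
  if (!is.null(lambda)) {
    if (any(!is.finite(lambda)) || any(lambda <= 0)) {
      stop("`lambda` grid must be finite and positive", call. = FALSE)
    }
    if (length(lambda) > 1 && any(diff(lambda) >= 0)) {
      stop("`lambda` grid must be strictly decreasing", call. = FALSE)
    }
  }
  if (!is.finite(tol) || tol <= 0) stop("`tol` must be > 0", call. = FALSE)
  structure(list(lambda = lambda, nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio,
                 gamma_inner = gamma_inner, gamma_outer = gamma_outer,
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "cmcp_penalty_params")
}

#' Composite MCP objective
#'
#' \eqn{\frac{1}{2n}\|y - X\beta\|^2 + \sum_g MCP(s_g/\lambda;
#' K_g\lambda, \gamma_{out})} with \eqn{s_g = \sum_{k \in g}
#' MCP(|\beta_{gk}|; \lambda, \gamma_{in})}, where \eqn{K_g} is the number
#' of penalized members of group \eqn{g}. The outer MCP is applied to the
#' inner sum divided by \eqn{\lambda}, which makes the composite penalty
#' \eqn{\lambda}-homogeneous of degree two: rescaling the response and
#' \eqn{\lambda} by \eqn{c} rescales the solution by \eqn{c} exactly, and
#' the zero-solution threshold is \eqn{K_g\lambda} on the gradient scale.
#' Unpenalized columns are excluded from the penalty.
#'
#' @param beta Coefficient vector (same scale as `X`).
#' @param X Design matrix.
#' @param y Response vector.
#' @param group Integer group index per column.
#' @param penalized Logical mask per column.
#' @param lambda Tuning value.
#' @param gamma_inner,gamma_outer MCP concavity parameters.
#' @return Scalar objective value.
#' @export
cmcp_objective <- function(beta, X, y, group, penalized, lambda,
                           gamma_inner = 3, gamma_outer = 3) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(beta) != ncol(X) || length(y) != n ||
      length(group) != ncol(X) || length(penalized) != ncol(X)) {
    stop("dimension mismatch between beta, X, y, group, penalized",
         call. = FALSE)
  }
  rss <- sum((y - X %*% beta)^2)
  pen <- 0
  if (lambda > 0) {
    for (g in unique(group[penalized])) {
      idx <- which(group == g & penalized)
      s <- sum(mcp(abs(beta[idx]), lambda, gamma_inner))
      pen <- pen + mcp(s / lambda, length(idx) * lambda, gamma_outer)
    }
  }
  rss / (2 * n) + pen
}

# Internal: standardize penalized columns to mean 0 and (1/n) x'x = 1.
# Degenerate (constant) penalized columns become all-zero and can never be
# selected. Returns the transform needed to undo it.
standardize_columns <- function(X, penalized) {
  n <- nrow(X)
  center <- rep(0, ncol(X))
  scale <- rep(1, ncol(X))
  Xs <- X
  for (k in which(penalized)) {
    c_k <- mean(X[, k])
    xc <- X[, k] - c_k
    s_k <- sqrt(sum(xc^2) / n)
    if (s_k > 0) {
      Xs[, k] <- xc / s_k
      center[k] <- c_k
      scale[k] <- s_k
    } else {
      Xs[, k] <- 0
      center[k] <- c_k
      scale[k] <- 1
    }
  }
  list(Xs = Xs, center = center, scale = scale)
}

# Internal: invert standardize_columns on a coefficient vector. `absorb`
# names the unpenalized columns that jointly equal the constant vector (the
# per-protein baseline indicators); centering constants are folded into them.
destandardize_coef <- function(beta_std, center, scale, penalized, absorb) {
  beta <- beta_std
  beta[penalized] <- beta_std[penalized] / scale[penalized]
  const <- sum(center[penalized] * beta_std[penalized] / scale[penalized])
  if (const != 0) {
    if (length(absorb) == 0) {
      stop("cannot destandardize: no baseline columns to absorb centering",
           call. = FALSE)
    }
    beta[absorb] <- beta[absorb] - const
  }
  beta
}

#' Fit a composite MCP solution path
#'
#' Cyclic coordinate descent with the firm-threshold update applied to the
#' locally linearized group penalty, warm-started along a decreasing lambda
#' grid. Protein baselines (unpenalized columns) are refit exactly at each
#' step; penalized columns are standardized internally unless the design was
#' built by [build_design()], which standardizes once on construction.
#'
#' @param X A [build_design()] object, or a plain numeric design matrix.
#' @param y Response vector (ignored when `X` is a design object).
#' @param group Integer/factor group index per column (plain-matrix case).
#' @param penalized Logical mask per column (plain-matrix case; default all
#'   `TRUE`).
#' @param params A [cmcp_penalty_params()] object.
#' @param standardize Standardize penalized columns of a plain matrix
#'   internally. When `FALSE` the caller is responsible for supplying
#'   columns with \eqn{(1/n)x'x = 1} (centering is then not required).
#' @param track_objective Record the per-sweep objective (used by the
#'   monotonicity diagnostics; small overhead).
#' @return An object of class `cmcp_path` with per-lambda coefficients on
#'   the original scale (`beta`), standardized-scale coefficients
#'   (`beta_std`), residual sums of squares, objective values, support
#'   sizes, convergence flags and iteration counts.
#' @export
fit_cmcp_path <- function(X, y = NULL, group = NULL, penalized = NULL,
                          params = cmcp_penalty_params(),
                          standardize = TRUE, track_objective = FALSE) {
  stopifnot(inherits(params, "cmcp_penalty_params"))
  if (inherits(X, "cmcp_design")) {
    des <- X
    Xs <- des$Xs
    y <- des$y
    group <- des$group
    penalized <- des$penalized
    center <- des$center
    scale <- des$scale
    absorb <- des$baseline_cols
    col_names <- colnames(des$Xs)
  } else {
    X <- as.matrix(X)
    if (is.null(y)) stop("`y` is required for a plain design matrix",
                         call. = FALSE)
    if (is.null(group)) group <- seq_len(ncol(X))
    group <- as.integer(as.factor(group))
    if (is.null(penalized)) penalized <- rep(TRUE, ncol(X))
    if (standardize) {
      st <- standardize_columns(X, penalized)
      Xs <- st$Xs; center <- st$center; scale <- st$scale
    } else {
      Xs <- X
      center <- rep(0, ncol(X)); scale <- rep(1, ncol(X))
    }
    absorb <- integer(0)
    col_names <- colnames(X)
    des <- NULL
  }
  n <- nrow(Xs); p <- ncol(Xs)
  if (length(y) != n) stop("length(y) != nrow(X)", call. = FALSE)
  grp0 <- as.integer(as.factor(group))
  G <- max(grp0)
  Kg <- vapply(seq_len(G), function(g) sum(grp0 == g & penalized), 0L)

  # residual after fitting the unpenalized block alone -> lambda_max
  lambda <- params$lambda
  unpen <- which(!penalized)
  if (length(unpen) > 0) {
    qr_u <- qr(Xs[, unpen, drop = FALSE])
    if (qr_u$rank < length(unpen)) {
      stop("unpenalized (baseline) block is singular", call. = FALSE)
    }
    r0 <- qr.resid(qr_u, y)
  } else {
    r0 <- y
  }
  if (is.null(lambda)) {
    z0 <- abs(crossprod(Xs[, penalized, drop = FALSE], r0)) / n
    kg_col <- Kg[grp0[penalized]]
    lmax <- max(z0 / pmax(kg_col, 1)) * (1 + 1e-6)  # strict at the boundary
    if (!is.finite(lmax) || lmax <= 0) lmax <- 1e-3
    lambda <- exp(seq(log(lmax), log(lmax * params$lambda_min_ratio),
                      length.out = params$nlambda))
  }

  fit <- cmcp_cd_path(Xs, as.numeric(y), grp0 - 1L, as.logical(penalized),
                      as.numeric(Kg), as.numeric(lambda),
                      params$gamma_inner, params$gamma_outer,
                      params$tol, params$max_iter, track_objective)

  beta_std <- fit$beta
  beta <- apply(beta_std, 2, destandardize_coef, center = center,
                scale = scale, penalized = penalized, absorb = absorb)
  beta <- matrix(beta, nrow = p)
  rownames(beta) <- rownames(beta_std) <- col_names

  structure(list(
    lambda = lambda, beta = beta, beta_std = beta_std,
    rss = fit$rss, objective = fit$objective,
    df = colSums(beta_std != 0), iters = fit$iters,
    converged = fit$converged, obj_trace = fit$obj_trace,
    group = grp0, penalized = penalized, Kg = Kg,
    center = center, scale = scale, Xs = Xs, y = as.numeric(y),
    n = n, params = params, design = des, col_names = col_names
  ), class = "cmcp_path")
}

#' @export
print.cmcp_path <- function(x, ...) {
  cat("cMCP path:", length(x$lambda), "lambda values,",
      ncol(x$Xs), "columns,", max(x$group), "groups\n")
  cat("df range:", min(x$df), "-", max(x$df),
      "| converged:", sum(x$converged), "/", length(x$lambda), "\n")
  invisible(x)
}

#' Choose a path solution by information criterion
#'
#' Evaluates BIC (`n log(RSS/n) + df log(n)`, with `df` the number of
#' nonzero coefficients) or AIC along the path and returns the minimizing
#' grid point; ties break toward the larger lambda (the sparser model).
#' Non-converged grid points are excluded.
#'
#' @param path A [fit_cmcp_path()] result.
#' @param criterion `"bic"` (default) or `"aic"`.
#' @return An object of class `cmcp_selected` with the chosen lambda,
#'   coefficient vectors on both scales, selected groups and members, and
#'   the criterion values.
#' @export
select_model <- function(path, criterion = c("bic", "aic")) {
  stopifnot(inherits(path, "cmcp_path"))
  criterion <- match.arg(criterion)
  ok <- which(as.logical(path$converged))
  if (length(ok) == 0) stop("no converged path solutions", call. = FALSE)
  n <- path$n
  df <- path$df[ok]
  rss <- pmax(path$rss[ok], .Machine$double.eps)
  crit <- n * log(rss / n) + df * (if (criterion == "bic") log(n) else 2)
  best <- ok[which.min(crit)]  # which.min takes the first (largest lambda)
  members <- which(path$beta_std[, best] != 0 & path$penalized)
  groups <- sort(unique(path$group[members]))
  structure(list(
    lambda = path$lambda[best], index = best,
    beta = path$beta[, best], beta_std = path$beta_std[, best],
    selected_members = members, selected_groups = groups,
    criterion = criterion, value = min(crit),
    criterion_path = crit, path = path
  ), class = "cmcp_selected")
}

#' @export
print.cmcp_selected <- function(x, ...) {
  cat("cMCP selected model (", toupper(x$criterion), " = ",
      format(x$value), "): lambda = ", format(x$lambda), "\n", sep = "")
  cat(length(x$selected_groups), "groups,", length(x$selected_members),
      "penalized members selected\n")
  invisible(x)
}

#' Stationarity (KKT) check for a selected cMCP solution
#'
#' Verifies the coordinate-wise stationarity conditions of the composite
#' objective at the returned solution, on the standardized scale: for
#' unpenalized columns the gradient must vanish; for nonzero penalized
#' coefficients the gradient must equal the penalty derivative
#' \eqn{MCP'_{out}(s_g)\,MCP'_{in}(|\beta_k|)\,\mathrm{sign}(\beta_k)}; for
#' zero coefficients it must not exceed the zero-threshold
#' \eqn{MCP'_{out}(s_g)\,\lambda}.
#'
#' @param model A [select_model()] result (or a `cmcp_path` plus `index`).
#' @param index Path index when `model` is a path.
#' @return List with `max_violation` and the per-coordinate violations.
#' @export
kkt_check <- function(model, index = NULL) {
  if (inherits(model, "cmcp_selected")) {
    path <- model$path; index <- model$index
  } else {
    stopifnot(inherits(model, "cmcp_path"), !is.null(index))
    path <- model
  }
  Xs <- path$Xs; y <- path$y; n <- path$n
  b <- path$beta_std[, index]
  lam <- path$lambda[index]
  gi <- path$params$gamma_inner; go <- path$params$gamma_outer
  grad <- as.numeric(crossprod(Xs, y - Xs %*% b)) / n
  s <- vapply(seq_len(max(path$group)), function(g) {
    idx <- which(path$group == g & path$penalized)
    sum(mcp(abs(b[idx]), lam, gi))
  }, 0)
  viol <- numeric(length(b))
  for (k in seq_along(b)) {
    if (!path$penalized[k]) {
      viol[k] <- abs(grad[k])
    } else {
      g <- path$group[k]
      w <- max(0, path$Kg[g] - s[g] / (go * lam^2))
      if (b[k] != 0) {
        viol[k] <- abs(grad[k] - w * mcp_deriv(abs(b[k]), lam, gi) * sign(b[k]))
      } else {
        viol[k] <- max(0, abs(grad[k]) - w * lam)
      }
    }
  }
  # degenerate all-zero columns trivially satisfy stationarity
  viol[colSums(Xs != 0) == 0] <- 0
  list(max_violation = max(viol), violations = viol)
}
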