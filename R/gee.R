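#' Pooled 2x2 odds ratio
#'
#' Cross-product odds ratio `(a/b) / (c/d)` from a collapsed 2x2 table of
#' positive/negative counts in two groups. Serves as the closed-form oracle
#' for the GEE group estimate: with a cluster-level covariate and equal
#' cluster sizes, the exchangeable-GEE point estimate collapses to exactly
#' this quantity.
#'
#' @param a,b Positive and negative counts in the second (exposed) group.
#' @param c,d Positive and negative counts in the first (reference) group.
#' @return A single number, `(a * d) / (b * c)`. `NaN` with a warning when a
#'   denominator count (`b` or `c`) is zero.
#' @examples
#' pooled_odds_ratio(80, 11, 23, 16) # 5.059...
#' @export
pooled_odds_ratio <- function(a, b, c, d) {
  stopifnot(length(a) == 1, length(b) == 1, length(c) == 1, length(d) == 1)
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  if (b * c == 0) {
    warning("odds ratio undefined: zero count in a denominator cell")
    return(NaN)
  }
  (a / b) / (c / d)
}

#' Fit a binary GEE with exchangeable working correlation
#'
#' Solves the generalized estimating equations for a marginal logistic model
#' of a binary outcome on a single covariate, with outcomes correlated within
#' clusters under an exchangeable working correlation. This is the model used
#' to estimate the effect of an additional tracer-spreading period on
#' per-structure presence, with each mouse as a cluster.
#'
#' The mean model is `logit P(y = 1) = beta0 + beta1 * x`. Estimation is by
#' Fisher scoring on the GEE score equations; the exchangeable correlation
#' `rho` is re-estimated each iteration by the moment estimator from Pearson
#' residuals. The binomial dispersion is fixed at 1. Coefficient covariance is
#' the cluster-robust sandwich estimator; the model-based (bread-only)
#' covariance is also returned.
#'
#' @param data A data frame with one row per outcome. Columns (configurable
#'   via the `*_col` arguments): cluster id, binary outcome in `{0, 1}`, and a
#'   binary or numeric covariate constant within cluster.
#' @param y_col,x_col,cluster_col Column names (strings).
#' @param tol Convergence tolerance on the max absolute coefficient change.
#' @param max_iter Maximum Fisher-scoring iterations.
#' @return An object of class `cryoclear_gee` with elements `beta` (named
#'   length-2 vector, log-odds scale), `or`, `ci95` (Wald interval on the OR
#'   scale from the sandwich SE), `p` (two-sided Wald), `rho`, `se_robust`,
#'   `se_model`, `vcov_robust`, `n_iter`, `converged`, `n_obs`, `n_clusters`.
#' @examples
#' tab <- tibble::tibble(
#'   mouse = rep(1:6, each = 4),
#'   group = rep(c(0, 1), each = 12),
#'   present = rbinom(24, 1, 0.5)
#' )
#' @export
fit_gee_binary <- function(data, y_col = "present", x_col = "group",
                           cluster_col = "mouse_id",
                           tol = 1e-8, max_iter = 100L) {
  stopifnot(is.data.frame(data))
  for (cl in c(y_col, x_col, cluster_col)) {
    if (!cl %in% names(data)) stop("column not found: ", cl)
  }
  y <- as.numeric(data[[y_col]])
  x <- as.numeric(data[[x_col]])
  id <- as.character(data[[cluster_col]])
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (anyNA(y) || anyNA(x)) stop("missing values are not supported")

  # covariate must be constant within cluster; both levels represented
  xc <- tapply(x, id, function(v) {
    if (length(unique(v)) != 1L) stop("covariate varies within a cluster")
    v[[1]]
  })
  if (length(unique(xc)) < 2L) stop("both covariate levels must be present")
  if (min(table(xc)) < 2L) stop("need at least 2 clusters per covariate level")

  # complete separation: a covariate group with all-equal outcomes has no
  # finite group log-odds
  for (lev in unique(x)) {
    yy <- y[x == lev]
    if (all(yy == yy[[1]])) {
      stop("complete separation: all outcomes equal (", yy[[1]],
           ") in covariate group x = ", lev)
    }
  }

  clusters <- split(seq_along(y), id)
  n_i <- lengths(clusters)
  X <- cbind(`(Intercept)` = 1, x)
  colnames(X)[2] <- x_col
  p <- 2L

  # independence logistic fit as starting value
  beta <- stats::glm.fit(X, y, family = stats::binomial())$coefficients

  rho <- 0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    v <- mu * (1 - mu)
    e <- (y - mu) / sqrt(v)

    # moment estimate of the exchangeable correlation (dispersion fixed at 1)
    num <- 0; npairs <- 0
    for (idx in clusters) {
      ni <- length(idx)
      if (ni > 1L) {
        s <- sum(e[idx])
        num <- num + (s^2 - sum(e[idx]^2)) / 2
        npairs <- npairs + ni * (ni - 1) / 2
      }
    }
    rho <- if (npairs > p) num / (npairs - p) else 0
    nmax <- max(n_i)
    rho <- min(max(rho, -1 / (nmax - 1) + 1e-6), 1 - 1e-6)

    B <- matrix(0, p, p)
    score <- numeric(p)
    for (idx in clusters) {
      ni <- length(idx)
      Ai <- sqrt(v[idx])
      Xi <- X[idx, , drop = FALSE]
      ri <- y[idx] - mu[idx]
      # R^{-1} for exchangeable: (I - rho/(1+(ni-1)rho) J) / (1-rho)
      g <- rho / (1 + (ni - 1) * rho)
      # W = D' V^{-1} with D = diag(v) X, V = A^{1/2} R A^{1/2}:
      # D' V^{-1} = X' diag(sqrt(v)) R^{-1} diag(1/sqrt(v)) ... worked out as:
      Zi <- Xi * Ai                       # rows scaled by sqrt(v)
      u  <- ri / Ai                       # A^{-1/2} r
      Rinv_u <- (u - g * sum(u)) / (1 - rho)
      score <- score + drop(crossprod(Zi, Rinv_u))
      Rinv_Z <- (Zi - g * matrix(colSums(Zi), ni, p, byrow = TRUE)) / (1 - rho)
      B <- B + crossprod(Zi, Rinv_Z)
    }
    delta <- solve(B, score)
    beta <- beta + delta
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }

  # sandwich covariance at the solution
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  v <- mu * (1 - mu)
  B <- matrix(0, p, p)
  M <- matrix(0, p, p)
  for (idx in clusters) {
    ni <- length(idx)
    Ai <- sqrt(v[idx])
    Xi <- X[idx, , drop = FALSE]
    ri <- y[idx] - mu[idx]
    g <- rho / (1 + (ni - 1) * rho)
    Zi <- Xi * Ai
    u  <- ri / Ai
    Rinv_u <- (u - g * sum(u)) / (1 - rho)
    si <- drop(crossprod(Zi, Rinv_u))
    M <- M + tcrossprod(si)
    Rinv_Z <- (Zi - g * matrix(colSums(Zi), ni, p, byrow = TRUE)) / (1 - rho)
    B <- B + crossprod(Zi, Rinv_Z)
  }
  Binv <- solve(B)
  vc_robust <- Binv %*% M %*% Binv
  se_robust <- sqrt(diag(vc_robust))
  se_model <- sqrt(diag(Binv))
  names(se_robust) <- names(se_model) <- colnames(X)

  if (!converged) {
    warning("GEE did not converge in ", max_iter,
            " iterations; estimates withheld")
  }
  b1 <- unname(beta[2]); se1 <- unname(se_robust[2])
  z <- b1 / se1
  out <- structure(list(
    beta = stats::setNames(as.numeric(beta), colnames(X)),
    or = if (converged) exp(b1) else NA_real_,
    ci95 = if (converged) exp(b1 + c(-1, 1) * 1.96 * se1) else c(NA_real_, NA_real_),
    p = if (converged) 2 * stats::pnorm(-abs(z)) else NA_real_,
    rho = rho,
    se_robust = se_robust,
    se_model = se_model,
    vcov_robust = vc_robust,
    n_iter = iter,
    converged = converged,
    n_obs = length(y),
    n_clusters = length(clusters),
    x_col = x_col
  ), class = "cryoclear_gee")
  out
}

#' @export
print.cryoclear_gee <- function(x, ...) {
  cat("Binary GEE (logit link, exchangeable working correlation)\n")
  cat(sprintf("  clusters: %d   observations: %d   iterations: %d%s\n",
              x$n_clusters, x$n_obs, x$n_iter,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  OR (%s) = %.2f   95%% CI [%.2f, %.2f]   p = %.3f   rho = %.3f\n",
              x$x_col, x$or, x$ci95[1], x$ci95[2], x$p, x$rho))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy cryoclear_gee
#' @export
tidy.cryoclear_gee <- function(x, exponentiate = FALSE, ...) {
  est <- x$beta
  se <- x$se_robust
  tibble::tibble(
    term = names(est),
    estimate = if (exponentiate) exp(unname(est)) else unname(est),
    std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * stats::pnorm(-abs(unname(est / se)))
  )
}

#' @method glance cryoclear_gee
#' @export
glance.cryoclear_gee <- function(x, ...) {
  tibble::tibble(
    or = x$or, ci_low = x$ci95[1], ci_high = x$ci95[2], p.value = x$p,
    rho = x$rho, n_obs = x$n_obs, n_clusters = x$n_clusters,
    n_iter = x$n_iter, converged = x$converged
  )
}
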