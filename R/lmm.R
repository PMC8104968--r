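# REML mixed-model core shared by the expression, mediation, bone and
# morphometric analyses.
#
# Model per response y (n samples):
#   y = X beta + Z u + e,  u ~ MVN(0, sigma_u^2 K),  e ~ MVN(0, sigma_e^2 I)
# so Var(y) = sigma_u^2 (Z K Z' + delta I) with delta = sigma_e^2/sigma_u^2.
# A single eigendecomposition of Z K Z' (shared across all responses) rotates
# the model to independent errors; REML then reduces to a 1-D search over
# delta, done on a log grid and refined by golden-section.

#' Incidence matrix mapping samples to grouping levels
#'
#' @param ids character or factor vector, one entry per sample.
#' @param levels level ordering (defaults to the order of first appearance).
#' @return an n x m 0/1 matrix with one 1 per row.
#' @export
incidence_matrix <- function(ids, levels = unique(as.character(ids))) {
  ids <- as.character(ids)
  missing <- setdiff(ids, levels)
  if (length(missing))
    stop_arg("samples map to unknown individuals: ",
             paste(unique(missing), collapse = ", "))
  Z <- matrix(0, nrow = length(ids), ncol = length(levels),
              dimnames = list(NULL, levels))
  Z[cbind(seq_along(ids), match(ids, levels))] <- 1
  Z
}

#' Eigendecomposition of the sample-level relatedness covariance
#'
#' Computes eigen(Z K Z') once so that many responses measured on the same
#' design can share it.
#'
#' @param K symmetric relatedness matrix over individuals.
#' @param Z incidence matrix mapping samples to the rows of `K`
#'   (default: identity, i.e., samples are the individuals).
#' @return list with `values` (nonnegative, clipped) and `vectors`.
#' @export
lmm_eigen <- function(K, Z = NULL) {
  K <- as.matrix(K)
  if (!isSymmetric(unname(K), tol = 1e-8))
    stop_arg("K must be symmetric")
  V <- if (is.null(Z)) K else Z %*% K %*% t(Z)
  V <- (V + t(V)) / 2
  e <- eigen(V, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1))
    stop_arg("K is not positive semidefinite (eigenvalue ",
             format(min(e$values)), ")")
  e$values <- pmax(e$values, 0)
  e
}

# REML log-likelihood pieces for a shared delta across responses.
# Ys, Xs are the eigen-rotated response matrix (n x G) and design (n x p).
.reml_shared <- function(delta, lambda, Ys, Xs) {
  n <- nrow(Xs); p <- ncol(Xs)
  w <- 1 / (lambda + delta)
  XtWX <- crossprod(Xs, w * Xs)
  R <- chol(XtWX)
  XtWy <- crossprod(Xs, w * Ys)
  q <- colSums(backsolve(R, XtWy, transpose = TRUE)^2)
  rss <- pmax(colSums(w * Ys^2) - q, 1e-300)
  ll <- -0.5 * ((n - p) * log(rss / (n - p)) + sum(log(lambda + delta)) +
                  2 * sum(log(diag(R))))
  list(ll = ll, rss = rss)
}

# Same but with response-specific deltas (used by the golden-section refine).
.reml_pergene <- function(delta, lambda, Ys, Xs, PP, pairs) {
  n <- nrow(Xs); p <- ncol(Xs); G <- ncol(Ys)
  W <- 1 / outer(lambda, delta, "+")             # n x G
  ytWy <- colSums(W * Ys^2)
  XtWy <- crossprod(Xs, W * Ys)                  # p x G
  XtWX_flat <- crossprod(PP, W)                  # p(p+1)/2 x G
  ll <- numeric(G)
  M <- matrix(0, p, p)
  idx <- cbind(pairs$i, pairs$j)
  for (g in seq_len(G)) {
    M[idx] <- XtWX_flat[, g]
    M[idx[, 2:1, drop = FALSE]] <- XtWX_flat[, g]
    R <- chol(M)
    q <- sum(backsolve(R, XtWy[, g], transpose = TRUE)^2)
    rss <- max(ytWy[g] - q, 1e-300)
    ll[g] <- -0.5 * ((n - p) * log(rss / (n - p)) +
                       sum(log(lambda + delta[g])) + 2 * sum(log(diag(R))))
  }
  ll
}

#' Fit the kinship mixed model to many responses at once
#'
#' REML estimation with a single variance ratio per response, profiled on a
#' log10 grid spanning `grid_range` (100 points) and refined by
#' golden-section search between the flanking grid points. Fixed effects are
#' then estimated by GLS at the per-response optimum; per-coefficient
#' p-values use a t reference with n - rank(X) degrees of freedom.
#'
#' @param Y numeric matrix of responses, samples in rows (a vector is
#'   treated as one column).
#' @param X fixed-effect design matrix (full rank).
#' @param eig result of [lmm_eigen()] for the same samples.
#' @param grid_range range of the variance ratio delta = sigma_e^2/sigma_u^2.
#' @param n_grid number of log-spaced grid points.
#' @param refine_tol absolute tolerance on log10(delta) for the refinement.
#' @return list with matrices `beta`, `se`, `t`, `pvalue` (coefficients x
#'   responses) and vectors `sigma_u2`, `sigma_e2`, `delta`, `loglik`, plus
#'   `df`.
#' @export
fit_lmm_matrix <- function(Y, X, eig, grid_range = c(1e-5, 1e5),
                           n_grid = 100, refine_tol = 1e-4) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  n <- nrow(Y); G <- ncol(Y); p <- ncol(X)
  if (nrow(X) != n) stop_arg("X and Y have different sample counts")
  if (qr(X)$rank < p) stop_arg("X is rank deficient")
  U <- eig$vectors
  lambda <- eig$values
  Ys <- crossprod(U, Y)
  Xs <- crossprod(U, X)

  log_grid <- seq(log10(grid_range[1]), log10(grid_range[2]),
                  length.out = n_grid)
  ll_grid <- matrix(NA_real_, n_grid, G)
  for (k in seq_len(n_grid))
    ll_grid[k, ] <- .reml_shared(10^log_grid[k], lambda, Ys, Xs)$ll
  best <- max.col(t(ll_grid), ties.method = "first")

  # golden-section refinement between the grid neighbours of each optimum
  pairs <- expand.grid(i = seq_len(p), j = seq_len(p))
  pairs <- pairs[pairs$i <= pairs$j, ]
  PPs <- Xs[, pairs$i, drop = FALSE] * Xs[, pairs$j, drop = FALSE]
  lo <- log_grid[pmax(best - 1L, 1L)]
  hi <- log_grid[pmin(best + 1L, n_grid)]
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo)
  x2 <- lo + gr * (hi - lo)
  f1 <- .reml_pergene(10^x1, lambda, Ys, Xs, PPs, pairs)
  f2 <- .reml_pergene(10^x2, lambda, Ys, Xs, PPs, pairs)
  while (max(hi - lo) > refine_tol) {
    take1 <- f1 >= f2
    hi <- ifelse(take1, x2, hi)
    lo <- ifelse(take1, lo, x1)
    x1 <- hi - gr * (hi - lo)
    x2 <- lo + gr * (hi - lo)
    f1 <- .reml_pergene(10^x1, lambda, Ys, Xs, PPs, pairs)
    f2 <- .reml_pergene(10^x2, lambda, Ys, Xs, PPs, pairs)
  }
  log_delta <- (lo + hi) / 2
  delta <- 10^log_delta

  beta <- se <- matrix(NA_real_, p, G,
                       dimnames = list(colnames(X), colnames(Y)))
  sigma_u2 <- sigma_e2 <- loglik <- numeric(G)
  idx <- cbind(pairs$i, pairs$j)
  M <- matrix(0, p, p)
  XtWX_flat <- crossprod(PPs, 1 / outer(lambda, delta, "+"))
  W <- 1 / outer(lambda, delta, "+")
  XtWy <- crossprod(Xs, W * Ys)
  ytWy <- colSums(W * Ys^2)
  for (g in seq_len(G)) {
    M[idx] <- XtWX_flat[, g]
    M[idx[, 2:1, drop = FALSE]] <- XtWX_flat[, g]
    R <- chol(M)
    z <- backsolve(R, XtWy[, g], transpose = TRUE)
    b <- backsolve(R, z)
    rss <- max(ytWy[g] - sum(z^2), 1e-300)
    s2u <- rss / (n - p)
    Minv_diag <- diag(chol2inv(R))
    beta[, g] <- b
    se[, g] <- sqrt(s2u * Minv_diag)
    sigma_u2[g] <- s2u
    sigma_e2[g] <- s2u * delta[g]
    loglik[g] <- -0.5 * ((n - p) * log(s2u) +
                           sum(log(lambda + delta[g])) + 2 * sum(log(diag(R))))
  }
  # delta at the upper grid edge means the random effect is effectively absent
  at_edge <- log_delta >= log10(grid_range[2]) - 1e-6
  sigma_e2[at_edge] <- sigma_u2[at_edge] * delta[at_edge]
  sigma_u2[at_edge] <- 0
  df <- n - p
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df = df)
  list(beta = beta, se = se, t = tval, pvalue = pval,
       sigma_u2 = sigma_u2, sigma_e2 = sigma_e2, delta = delta,
       loglik = loglik, df = df, rank = p, n = n)
}

#' Fit the kinship mixed model for a single response
#'
#' Convenience wrapper around [fit_lmm_matrix()] that performs its own
#' eigendecomposition of Z K Z'. Optional residual weights w (Var(e_i) =
#' sigma_e^2 / w_i) are absorbed by rescaling rows of the model, which is
#' exact because the rescaled covariance is re-eigendecomposed here.
#'
#' @param y numeric response vector.
#' @param X design matrix.
#' @param Z incidence matrix mapping samples to `K` rows (default identity).
#' @param K relatedness matrix.
#' @param weights optional positive residual precision weights.
#' @param ... passed to [fit_lmm_matrix()] (grid size, refinement
#'   tolerance).
#' @return one-row fit: list with `beta`, `se`, `t`, `pvalue` vectors and
#'   scalar variance components.
#' @export
fit_gene_lmm <- function(y, X, Z = NULL, K, weights = NULL, ...) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  if (!is.null(weights)) {
    if (any(weights <= 0)) stop_arg("weights must be positive")
    s <- sqrt(weights)
    V <- if (is.null(Z)) K else Z %*% K %*% t(Z)
    V <- s * t(s * t(V))     # D V D with D = diag(s)
    eig <- lmm_eigen(V)
    fit <- fit_lmm_matrix(s * y, s * X, eig, ...)
  } else {
    eig <- lmm_eigen(K, Z)
    fit <- fit_lmm_matrix(y, X, eig, ...)
  }
  list(beta = fit$beta[, 1], se = fit$se[, 1], t = fit$t[, 1],
       pvalue = fit$pvalue[, 1], sigma_u2 = fit$sigma_u2[1],
       sigma_e2 = fit$sigma_e2[1], delta = fit$delta[1],
       loglik = fit$loglik[1], df = fit$df)
}

#' REML fit with several random-effect kernels
#'
#' Direct REML over k variance ratios gamma_j (Var(y) = sigma^2 (I +
#' sum_j gamma_j K_j)), optimized on the log scale by Nelder-Mead. Used for
#' models with two grouping factors (e.g., maternal and litter intercepts).
#'
#' @param y response vector.
#' @param X design matrix.
#' @param K_list list of sample-level covariance kernels (n x n), e.g.
#'   `tcrossprod(incidence_matrix(ids))` for a grouping factor.
#' @return list with `beta`, `se`, `pvalue`, `sigma2` (residual), `gamma`
#'   ratios, per-kernel variances `sigma2_k`, and `df`.
#' @export
reml_multikernel <- function(y, X, K_list) {
  y <- as.numeric(y); X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  if (qr(X)$rank < p) stop_arg("X is rank deficient")
  nk <- length(K_list)
  obj <- function(lg) {
    Vm <- diag(n)
    for (j in seq_len(nk)) Vm <- Vm + exp(lg[j]) * K_list[[j]]
    R <- tryCatch(chol(Vm), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    A <- backsolve(R, cbind(y, X), transpose = TRUE)
    yt <- A[, 1]; Xt <- A[, -1, drop = FALSE]
    qrX <- qr(Xt)
    rss <- sum(qr.resid(qrX, yt)^2)
    Rx <- qr.R(qrX)
    0.5 * ((n - p) * log(rss / (n - p)) + 2 * sum(log(diag(R))) +
             2 * sum(log(abs(diag(Rx)))))
  }
  opt <- stats::optim(rep(0, nk), obj, method = if (nk == 1) "Brent" else "Nelder-Mead",
                      lower = if (nk == 1) -25 else -Inf,
                      upper = if (nk == 1) 25 else Inf,
                      control = list(maxit = 500, reltol = 1e-10))
  gamma <- exp(opt$par)
  Vm <- diag(n)
  for (j in seq_len(nk)) Vm <- Vm + gamma[j] * K_list[[j]]
  R <- chol(Vm)
  A <- backsolve(R, cbind(y, X), transpose = TRUE)
  yt <- A[, 1]; Xt <- A[, -1, drop = FALSE]
  XtX <- crossprod(Xt)
  beta <- solve(XtX, crossprod(Xt, yt))[, 1]
  rss <- sum((yt - Xt %*% beta)^2)
  s2 <- rss / (n - p)
  se <- sqrt(s2 * diag(solve(XtX)))
  names(beta) <- names(se) <- colnames(X)
  tval <- beta / se
  list(beta = beta, se = se, t = tval,
       pvalue = 2 * pt(-abs(tval), df = n - p),
       sigma2 = s2, gamma = gamma, sigma2_k = s2 * gamma, df = n - p)
}
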