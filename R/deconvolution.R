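# Reference-based cell-type deconvolution, PCA summary of composition, and
# bootstrap mediation of the breeding-status effect by composition.

#' Quantile-normalize a matrix to a reference distribution
#'
#' Each column's values are replaced by reference quantiles at matching
#' ranks (average ranks for ties, linear interpolation between reference
#' order statistics when lengths differ).
#'
#' @param mixture genes x samples matrix.
#' @param reference numeric vector (or matrix, pooled) giving the target
#'   distribution.
#' @return matrix with the same dimensions and dimnames as `mixture`.
#' @export
quantile_normalize_to <- function(mixture, reference) {
  mixture <- as.matrix(mixture)
  ref <- sort(as.numeric(reference))
  m <- length(ref)
  if (!m) stop_arg("empty reference distribution")
  n <- nrow(mixture)
  out <- apply(mixture, 2, function(x) {
    r <- rank(x, ties.method = "average")
    pos <- if (n == 1) (m + 1) / 2 else 1 + (r - 1) * (m - 1) / (n - 1)
    approx(seq_len(m), ref, xout = pos, rule = 2)$y
  })
  dimnames(out) <- dimnames(mixture)
  out
}

#' Estimate cell-type proportions by nonnegative least squares
#'
#' Per sample, the mixture profile is regressed on the signature columns
#' over the shared gene set with nonnegativity constraints (Lawson-Hanson
#' NNLS); coefficients are renormalized to sum to one. This is a documented
#' approximation to support-vector-regression deconvolution; `solver` can
#' be replaced by any function(A, b) returning nonnegative coefficients.
#'
#' @param mixture genes x samples expression matrix.
#' @param signature genes x cell-types reference matrix (>= 2 types).
#' @param solver nonnegative solver; defaults to [pracma::lsqnonneg()].
#' @return object of class `mq_props`: list with `proportions` (samples x
#'   types, each row on the simplex), `raw` (unnormalized coefficients) and
#'   `shared_genes`.
#' @export
estimate_proportions <- function(mixture, signature,
                                 solver = function(A, b) pracma::lsqnonneg(A, b)$x) {
  mixture <- as.matrix(mixture)
  signature <- as.matrix(signature)
  if (ncol(signature) < 2) stop_arg("signature needs >= 2 cell types")
  shared <- intersect(rownames(mixture), rownames(signature))
  if (length(shared) < ncol(signature))
    stop_arg("shared genes (", length(shared),
             ") fewer than cell types (", ncol(signature), ")")
  A <- signature[shared, , drop = FALSE]
  raw <- t(apply(mixture[shared, , drop = FALSE], 2, function(b) solver(A, b)))
  colnames(raw) <- colnames(signature)
  props <- raw
  zero <- rowSums(raw) == 0
  if (any(zero)) {
    warning("all-zero coefficient vector for ",
            sum(zero), " sample(s); set to uniform proportions")
    props[zero, ] <- 1 / ncol(raw)
  }
  props[!zero, ] <- raw[!zero, , drop = FALSE] / rowSums(raw)[!zero]
  structure(list(proportions = props, raw = raw, shared_genes = shared),
            class = "mq_props")
}

#' PCA of cell-type proportions
#'
#' Centered (unscaled) principal components; each component's sign is fixed
#' so its largest-magnitude loading is positive.
#'
#' @param props samples x cell-types proportion matrix (or `mq_props`).
#' @return list with `scores`, `loadings`, `var_explained`, `degenerate`
#'   (TRUE when the proportions carry no variance).
#' @export
proportions_pca <- function(props) {
  if (inherits(props, "mq_props")) props <- props$proportions
  props <- as.matrix(props)
  if (nrow(props) < 2) stop_arg("need >= 2 samples")
  pc <- prcomp(props, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  if (tot < 1e-300)
    return(list(scores = pc$x, loadings = pc$rotation,
                var_explained = rep(0, length(pc$sdev)), degenerate = TRUE))
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  list(scores = sweep(pc$x, 2, flip, "*"),
       loadings = sweep(pc$rotation, 2, flip, "*"),
       var_explained = pc$sdev^2 / tot, degenerate = FALSE)
}

#' Mediation of the breeding-status effect by cell composition
#'
#' Total effect: status coefficient from the kinship mixed model without
#' the mediator. Direct effect: the same coefficient with the mediator
#' added. Indirect effect = total - direct. The 95% percentile confidence
#' interval comes from a cluster bootstrap that resamples animals with
#' replacement; replicates in which status is constant are discarded and
#' redrawn.
#'
#' @param y response (one gene's adjusted expression).
#' @param status 0/1 breeding status per sample.
#' @param mediator mediating variable per sample (e.g., composition PC1).
#' @param covariates optional data.frame of additional fixed effects.
#' @param animal animal ID per sample (bootstrap resampling unit).
#' @param K kinship matrix over animals (identity if NULL).
#' @param n_boot bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @param ... passed to the REML fitter (grid size, refinement tolerance).
#' @return object of class `mq_mediation`: total, direct, indirect effects,
#'   percentile CI, significance flag, bootstrap count, redraw count.
#' @export
mediation_indirect <- function(y, status, mediator, covariates = NULL,
                               animal, K = NULL, n_boot = 1000, seed = 1,
                               ...) {
  n_boot <- check_count(n_boot, "n_boot", min = 100L)
  if (length(unique(status)) < 2) stop_arg("status does not vary")
  if (sd(mediator) == 0) stop_arg("mediator does not vary")
  animal <- as.character(animal)
  animals <- unique(animal)
  if (is.null(K)) {
    K <- diag(length(animals))
    dimnames(K) <- list(animals, animals)
  }
  build_X <- function(status, mediator, covariates, with_mediator) {
    X <- cbind(intercept = 1, status = status)
    if (!is.null(covariates))
      X <- cbind(X, stats::model.matrix(~ . - 1,
                                        data = as.data.frame(covariates)))
    if (with_mediator) X <- cbind(X, mediator = mediator)
    X
  }
  effects <- function(idx_animals) {
    keep <- unlist(lapply(idx_animals, function(a) which(animal == a)))
    cl <- rep(seq_along(idx_animals),
              vapply(idx_animals, function(a) sum(animal == a), integer(1)))
    Z <- incidence_matrix(as.character(cl), as.character(seq_along(idx_animals)))
    Kb <- K[idx_animals, idx_animals, drop = FALSE]
    st <- status[keep]
    if (length(unique(st)) < 2) return(NULL)
    cv <- if (is.null(covariates)) NULL else
      as.data.frame(covariates)[keep, , drop = FALSE]
    total <- fit_gene_lmm(y[keep], build_X(st, NULL, cv, FALSE), Z, Kb, ...)
    direct <- fit_gene_lmm(y[keep], build_X(st, mediator[keep], cv, TRUE),
                           Z, Kb, ...)
    c(total = unname(total$beta["status"]),
      direct = unname(direct$beta["status"]))
  }
  point <- effects(animals)
  if (is.null(point)) stop_arg("status constant in the observed data")
  boot <- matrix(NA_real_, n_boot, 2)
  redraws <- 0L
  with_seed(seed, {
    b <- 1L
    while (b <= n_boot) {
      sel <- sample(animals, length(animals), replace = TRUE)
      eff <- effects(sel)
      if (is.null(eff)) { redraws <- redraws + 1L; next }
      boot[b, ] <- eff
      b <- b + 1L
    }
  })
  indirect_boot <- boot[, 1] - boot[, 2]
  ci <- unname(quantile(indirect_boot, c(0.025, 0.975)))
  structure(list(total = unname(point["total"]),
                 direct = unname(point["direct"]),
                 indirect = unname(point["total"] - point["direct"]),
                 ci = ci,
                 significant = ci[1] > 0 || ci[2] < 0,
                 n_boot = n_boot, redraws = redraws, seed = seed),
            class = "mq_mediation")
}
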