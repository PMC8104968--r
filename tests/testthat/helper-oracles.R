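# Independent oracles used across tests: deliberately brute-force and
# separate from the package's implementation paths.

# TMM factors recomputed from the algorithm definition (pairwise trimmed
# weighted mean of M-values against an upper-quartile reference).
tmm_oracle <- function(counts) {
  lib <- colSums(counts)
  uq <- apply(counts, 2, quantile, p = 0.75) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- sapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j]; refc <- counts[, ref]
    nO <- lib[j]; nR <- lib[ref]
    logR <- log2((obs / nO) / (refc / nR))
    absE <- (log2(obs / nO) + log2(refc / nR)) / 2
    v <- (nO - obs) / (nO * obs) + (nR - refc) / (nR * refc)
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
    loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
  })
  f / exp(mean(log(f)))
}

# Euler characteristic by explicit simplex counting for one threshold.
ec_brute_force <- function(mesh, direction, thresholds) {
  hv <- as.numeric(mesh$vertices %*% direction)
  e <- mesh_edges(mesh)
  sapply(thresholds, function(t) {
    vin <- hv <= t
    nV <- sum(vin)
    nE <- sum(vin[e[, 1]] & vin[e[, 2]])
    nF <- sum(vin[mesh$faces[, 1]] & vin[mesh$faces[, 2]] &
                vin[mesh$faces[, 3]])
    nV - nE + nF
  })
}

# Two-sided Fisher exact p by full enumeration over all tables with the
# observed margins.
fisher_enum_p <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(ks, r1, n - r1, c1)
  p_obs <- dhyper(m[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact HWE p by direct enumeration of heterozygote counts conditional on
# the allele counts (independent of the package's implementation).
hwe_enum_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  pr <- sapply(hets, function(h) {
    exp(lfactorial(n) - lfactorial((nA - h) / 2) - lfactorial(h) -
          lfactorial(n - h - (nA - h) / 2) + h * log(2) +
          lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n))
  })
  sum(pr[pr <= pr[hets == n_Aa] * (1 + 1e-9)])
}

# REML log-likelihood computed directly from the covariance matrix (no
# eigendecomposition shortcut); used to check the engine's optimum.
reml_loglik_direct <- function(y, X, V_of_delta, delta) {
  n <- length(y); p <- ncol(X)
  V <- V_of_delta(delta)
  R <- chol(V)
  A <- backsolve(R, cbind(y, X), transpose = TRUE)
  yt <- A[, 1]; Xt <- A[, -1, drop = FALSE]
  qrX <- qr(Xt)
  rss <- sum(qr.resid(qrX, yt)^2)
  -0.5 * ((n - p) * log(rss / (n - p)) + 2 * sum(log(diag(R))) +
            2 * sum(log(abs(diag(qr.R(qrX))))))
}

# Small jittered icospheres serve as "random small meshes".
random_small_mesh <- function(seed, level = 1, jitter = 0.15) {
  base <- icosphere(level)
  set.seed(seed)
  v <- base$vertices + matrix(rnorm(length(base$vertices), 0, jitter),
                              nrow(base$vertices), 3)
  triangle_mesh(v, base$faces)
}

# Shared small expression fixture: sib-structured kinship + design.
make_expression_fixture <- function(n_animals = 12, n_genes = 200,
                                    n_de = 0, effect_size = 1,
                                    sigma_u2 = 0.1, sigma_e2 = 0.2,
                                    n_samples = NULL, seed = 1) {
  animals <- data.frame(animal = paste0("A", seq_len(n_animals)),
                        status = rep(0:1, length.out = n_animals),
                        colony = paste0("F", ceiling(seq_len(n_animals) / 2)))
  design <- sim_expression_design(animals, n_samples = n_samples,
                                  seed = seed)
  # littermate-pair block kinship: sibs 0.5, otherwise unrelated
  K <- diag(n_animals)
  pair <- ceiling(seq_len(n_animals) / 2)
  K[outer(pair, pair, "==")] <- 0.5
  diag(K) <- 1
  dimnames(K) <- list(animals$animal, animals$animal)
  truth <- sim_expression_truth(n_genes, n_de = n_de,
                                effect_size = effect_size,
                                sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
                                seed = seed + 1)
  cm <- simulate_counts(design, truth, K, seed = seed + 2)
  list(animals = animals, design = design, K = K, truth = truth,
       counts = cm$counts, lengths = cm$lengths)
}
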