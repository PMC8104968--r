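# Differential-expression pipeline: TPM filtering, TMM normalization,
# log-CPM transform, per-gene kinship mixed models with nuisance
# covariates, and a permutation-derived empirical FDR.

#' Transcripts per million
#'
#' TPM_gs = 1e6 (c_gs / len_g) / sum_g' (c_g's / len_g'); every column sums
#' to one million.
#'
#' @param counts genes x samples count matrix.
#' @param lengths per-gene effective length in bp.
#' @return TPM matrix.
#' @export
compute_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (any(lengths <= 0)) stop_arg("gene lengths must be positive")
  if (length(lengths) != nrow(counts))
    stop_arg("lengths must match the number of genes")
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) {
    bad <- colnames(counts)[tot == 0] %||% which(tot == 0)
    stop_arg("all-zero sample(s): ", paste(bad, collapse = ", "))
  }
  sweep(rate, 2, tot, "/") * 1e6
}

#' Expressed-gene filter
#'
#' Keeps genes with TPM >= `min_tpm` in at least
#' ceiling(`min_frac` * n_samples) samples (both thresholds inclusive).
#'
#' @param tpm TPM matrix.
#' @param min_tpm expression threshold.
#' @param min_frac minimum fraction of samples, in (0, 1].
#' @return logical vector over genes.
#' @export
filter_genes <- function(tpm, min_tpm = 2, min_frac = 0.25) {
  if (min_frac <= 0 || min_frac > 1) stop_arg("min_frac must be in (0, 1]")
  need <- ceiling(min_frac * ncol(tpm))
  rowSums(tpm >= min_tpm) >= need
}

#' Trimmed mean of M-values normalization factors
#'
#' Pairwise TMM against a reference sample (the one whose upper-quartile
#' count fraction is closest to the mean), with a 30% two-sided trim on
#' log-ratios and 5% on average log-intensity, inverse-asymptotic-variance
#' weighting, and factors rescaled to geometric mean 1.
#'
#' @param counts genes x samples count matrix.
#' @return per-sample normalization factors.
#' @export
tmm_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop_arg("TMM needs at least 2 samples")
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  if (any(!is.finite(f))) {
    warning("samples without genes shared with the reference; factor set to 1")
    f[!is.finite(f)] <- 1
    f <- f / exp(mean(log(f)))
  }
  setNames(f, colnames(counts))
}

#' Log-CPM transform with mean-variance precision weights
#'
#' value = log2((count + 0.5) / (libsize * factor + 1) * 1e6). Precision
#' weights come from a locally weighted regression of sqrt(residual sd) on
#' mean log count (predicted sd^-4). The weights are reported for
#' inspection but are not consumed by the mixed model downstream.
#'
#' @param counts genes x samples count matrix.
#' @param factors TMM normalization factors (positive).
#' @param design optional design matrix for the mean-variance trend fit.
#' @return list with `expr` (log2-CPM matrix) and `weights`.
#' @export
log_cpm_voom <- function(counts, factors = rep(1, ncol(counts)),
                         design = NULL) {
  if (any(factors <= 0)) stop_arg("normalization factors must be positive")
  v <- limma::voom(as.matrix(counts), design = design,
                   lib.size = colSums(counts) * factors)
  list(expr = v$E, weights = v$weights)
}

#' Regress nuisance covariates out of an expression matrix
#'
#' Per gene, ordinary least squares of expression on the covariates (plus
#' intercept); returns residuals with the per-gene mean added back.
#'
#' @param expr genes x samples matrix.
#' @param covariates data.frame or matrix of per-sample covariates.
#' @return adjusted expression matrix.
#' @export
residualize <- function(expr, covariates) {
  expr <- as.matrix(expr)
  X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_arg("collinear covariate columns: ", paste(drop_cols, collapse = ", "))
  }
  res <- t(qr.resid(qrX, t(expr)))
  res + rowMeans(expr)
}

# Nuisance covariates (mapping efficiency, natal colony) entering the
# mixed model as fixed effects. Pre-residualizing them by OLS instead would
# demean groups that align with the kinship blocks and distort the residual
# covariance the mixed model assumes, inflating small p-values under the
# null; folding them into the design keeps the per-gene tests calibrated.
# Constant columns are dropped.
nuisance_covariates <- function(meta) {
  out <- NULL
  if (!is.null(meta$prop_mapped) && length(unique(meta$prop_mapped)) > 1)
    out <- cbind(out, prop_mapped = meta$prop_mapped)
  if (!is.null(meta$colony) && length(unique(meta$colony)) > 1) {
    cm <- stats::model.matrix(~ colony, data = data.frame(
      colony = factor(meta$colony)))[, -1, drop = FALSE]
    out <- cbind(out, cm)
  }
  out
}

# Combine the core design with nuisance covariates, dropping nuisance
# columns that are aliased with the core design (QR with pivoting). Core
# columns are protected; a rank-deficient core is an error.
design_with_nuisance <- function(meta, model_spec = "main") {
  core <- expression_design_matrix(meta, model_spec)
  X <- cbind(core, nuisance_covariates(meta))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- qrX$pivot[(qrX$rank + 1):ncol(X)]
    if (any(drop <= ncol(core)))
      stop_arg("core design is rank deficient")
    X <- X[, -drop, drop = FALSE]
  }
  X
}

# Fixed-effect design of the expression model: intercept, days in culture,
# bone type, and bone-type-specific breeding-status and estradiol effects
# (optionally bone-type-specific solitaire effects).
expression_design_matrix <- function(meta, model_spec = c("main", "solitaire")) {
  model_spec <- match.arg(model_spec)
  is_lv <- as.numeric(meta$bone == "LV")
  X <- cbind(intercept = 1,
             days = meta$days,
             bone_lv = is_lv,
             status_long = meta$status * (1 - is_lv),
             status_lv = meta$status * is_lv,
             estradiol_long = meta$estradiol * (1 - is_lv),
             estradiol_lv = meta$estradiol * is_lv)
  if (model_spec == "solitaire") {
    if (is.null(meta$solitaire))
      stop_arg("model_spec 'solitaire' needs a `solitaire` column")
    X <- cbind(X, solitaire_long = meta$solitaire * (1 - is_lv),
               solitaire_lv = meta$solitaire * is_lv)
  }
  X
}

# Permute breeding status at the animal level: all samples of an animal
# keep concordant labels, preserving the repeated-measures structure.
permute_status_by_animal <- function(meta) {
  animals <- unique(meta$animal)
  status_by_animal <- meta$status[match(animals, meta$animal)]
  perm <- sample(status_by_animal)
  perm[match(meta$animal, animals)]
}

# Permute the estradiol treatment within each animal (the treatment is
# assigned at the sample level, so samples of one animal are exchangeable).
permute_estradiol_within_animal <- function(meta) {
  s <- meta$estradiol
  for (a in unique(meta$animal)) {
    k <- which(meta$animal == a)
    s[k] <- sample(meta$estradiol[k])
  }
  s
}

#' Run the full differential-expression pipeline
#'
#' TPM filter, TMM factors, log-CPM, then a kinship mixed model per gene
#' with bone-type-specific breeding-status and estradiol effects; nuisance
#' covariates (proportion of uniquely mapped reads, natal colony) enter the
#' model as fixed effects. Permutation p-value sets are generated per variable
#' of interest (breeding status permuted across animals, estradiol within
#' animals) and converted to empirical q-values.
#'
#' @param counts genes x samples integer count matrix.
#' @param lengths per-gene effective lengths (bp).
#' @param meta per-sample metadata with columns `sample`, `animal`, `bone`
#'   ("long"/"LV"), `status`, `estradiol`, `days`, `colony`, `prop_mapped`.
#' @param K kinship matrix covering every animal in `meta`.
#' @param model_spec "main" or "solitaire" (adds solitaire fixed effects).
#' @param n_perm permutations per variable of interest.
#' @param seed integer seed for the permutations.
#' @param min_tpm,min_frac expressed-gene filter thresholds.
#' @return object of class `mq_de`: list with `table` (per-gene estimates,
#'   SEs, p- and q-values), `fit`, `filter`, `factors`, `n_perm`, `seed`.
#' @export
run_de <- function(counts, lengths, meta, K,
                   model_spec = c("main", "solitaire"),
                   n_perm = 100, seed = 1, min_tpm = 2, min_frac = 0.25) {
  model_spec <- match.arg(model_spec)
  counts <- as.matrix(counts)
  tpm <- compute_tpm(counts, lengths)
  keep <- filter_genes(tpm, min_tpm = min_tpm, min_frac = min_frac)
  counts <- counts[keep, , drop = FALSE]
  factors <- tmm_factors(counts)
  v <- log_cpm_voom(counts, factors)
  expr <- v$expr

  animals <- unique(meta$animal)
  Z <- incidence_matrix(meta$animal, animals)
  eig <- lmm_eigen(K[animals, animals, drop = FALSE], Z)
  X <- design_with_nuisance(meta, model_spec)
  fit <- fit_lmm_matrix(t(expr), X, eig)

  contrasts <- c("status_long", "status_lv", "estradiol_long", "estradiol_lv")
  p_obs <- t(fit$pvalue[contrasts, , drop = FALSE])

  q <- matrix(NA_real_, nrow(p_obs), length(contrasts),
              dimnames = list(rownames(expr), contrasts))
  if (n_perm > 0) {
    perm_p <- with_seed(seed, {
      lapply(c(status = "status", estradiol = "estradiol"), function(var) {
        sapply(seq_len(n_perm), function(b) {
          m2 <- meta
          if (var == "status") m2$status <- permute_status_by_animal(meta)
          else m2$estradiol <- permute_estradiol_within_animal(meta)
          Xp <- design_with_nuisance(m2, model_spec)
          fp <- fit_lmm_matrix(t(expr), Xp, eig)
          fp$pvalue[if (var == "status") c("status_long", "status_lv")
                    else c("estradiol_long", "estradiol_lv"), , drop = FALSE]
        }, simplify = "array")
      })
    })
    for (ct in contrasts) {
      var <- if (grepl("^status", ct)) "status" else "estradiol"
      pp <- perm_p[[var]][ct, , ]           # genes x perms
      q[, ct] <- empirical_fdr(p_obs[, ct], pp)$q
    }
  }

  tab <- data.frame(gene = rownames(expr),
                    t(fit$beta[contrasts, , drop = FALSE]),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(tab)[-1] <- paste0("beta_", contrasts)
  for (ct in contrasts) {
    tab[[paste0("se_", ct)]] <- fit$se[ct, ]
    tab[[paste0("p_", ct)]] <- fit$pvalue[ct, ]
    tab[[paste0("q_", ct)]] <- q[, ct]
  }
  tab$sigma_u2 <- fit$sigma_u2
  tab$sigma_e2 <- fit$sigma_e2
  structure(list(table = tab, fit = fit, filter = keep, factors = factors,
                 expr = expr, weights = v$weights, design = X,
                 n_perm = n_perm, seed = seed, model_spec = model_spec),
            class = "mq_de")
}

#' Empirical FDR from permutation p-values
#'
#' For each candidate threshold t (the observed p-values), the estimated
#' FDR is the mean number of permutation p-values <= t per permutation,
#' divided by the number of observed p-values <= t. Per-gene q-values take
#' the minimum estimated FDR over all thresholds at or above the gene's p,
#' capped at 1 (step-up monotonization).
#'
#' @param p_obs observed per-gene p-values.
#' @param p_perm matrix of permutation p-values (genes x permutations, or
#'   any matrix pooling the permuted null).
#' @return data.frame of class `mq_fdr` with `p`, `q`, `n_perm`.
#' @export
empirical_fdr <- function(p_obs, p_perm) {
  p_perm <- as.matrix(p_perm)
  if (ncol(p_perm) < 1) stop_arg("need at least one permutation column")
  n_perm <- ncol(p_perm)
  o <- order(p_obs)
  ts <- p_obs[o]
  null_sorted <- sort(as.vector(p_perm))
  # expected null discoveries at each threshold, averaged over permutations
  null_le <- findInterval(ts, null_sorted) / n_perm
  obs_le <- seq_along(ts)
  fdr <- null_le / obs_le
  # q = min FDR over thresholds >= own p
  q_sorted <- rev(cummin(rev(pmin(fdr, 1))))
  q <- numeric(length(p_obs))
  q[o] <- q_sorted
  structure(data.frame(p = p_obs, q = q), n_perm = n_perm,
            class = c("mq_fdr", "data.frame"))
}
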