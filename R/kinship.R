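# SNP filtering and relatedness estimation. The kinship matrix estimated
# here parameterizes the random-effect covariance of the expression mixed
# model.

#' Exact Hardy-Weinberg equilibrium p-value
#'
#' Two-sided exact test conditioning on the observed allele counts: the
#' p-value is the total probability of heterozygote counts whose conditional
#' probability does not exceed that of the observed count.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_arg("genotype counts must be nonnegative integers")
  n <- sum(counts)
  if (n == 0) stop_arg("all-zero genotype table")
  n_rare <- 2 * min(n_AA, n_aa) + n_Aa
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  log_prob <- function(h) {
    n_hom_rare <- (n_rare - h) / 2
    n_hom_com <- n - h - n_hom_rare
    lfactorial(n) - lfactorial(n_hom_rare) - lfactorial(h) -
      lfactorial(n_hom_com) + h * log(2) +
      lfactorial(n_rare) + lfactorial(2 * n - n_rare) - lfactorial(2 * n)
  }
  lp <- log_prob(hets)
  p_obs <- lp[hets == n_Aa]
  min(1, sum(exp(lp[lp <= p_obs + 1e-10])))
}

#' Filter SNP genotypes
#'
#' Applies, in order: biallelic, minor allele frequency, missingness,
#' Hardy-Weinberg equilibrium, and greedy positional thinning (a SNP is kept
#' only if it lies at least `thin_bp` basepairs from the previously kept SNP
#' on the same chromosome, sweeping left to right from the lowest
#' coordinate). Mean-depth and genotype-quality filters are applied only
#' when those fields are present in the input.
#'
#' @param g genotype object (`dosage`, `chrom`, `pos`, `biallelic`, and
#'   optionally `mean_depth`, `min_gq`).
#' @param maf_min minimum minor allele frequency (inclusive).
#' @param max_missing maximum number of missing calls per SNP.
#' @param hwe_p_min SNPs kept when exact HWE p > this value.
#' @param thin_bp minimum distance between retained SNPs.
#' @param min_depth,min_gq thresholds used when depth/quality are present.
#' @param verbose print a per-step retention log.
#' @return filtered genotype object.
#' @export
filter_snps <- function(g, maf_min = 0.1, max_missing = 2, hwe_p_min = 0.05,
                        thin_bp = 10000, min_depth = 5, min_gq = 99,
                        verbose = FALSE) {
  stopifnot(maf_min >= 0, max_missing >= 0, thin_bp >= 0)
  keep <- g$biallelic %||% rep(TRUE, nrow(g$dosage))
  log_step <- function(what, keep) {
    if (verbose) message(sprintf("filter_snps: %d SNPs after %s",
                                 sum(keep), what))
    keep
  }
  keep <- log_step("biallelic", keep)
  p_hat <- rowMeans(g$dosage, na.rm = TRUE) / 2
  maf <- pmin(p_hat, 1 - p_hat)
  keep <- log_step("MAF", keep & !is.na(maf) & maf >= maf_min)
  n_miss <- rowSums(is.na(g$dosage))
  keep <- log_step("missingness", keep & n_miss <= max_missing)
  hwe_p <- vapply(seq_len(nrow(g$dosage)), function(i) {
    if (!keep[i]) return(NA_real_)
    x <- g$dosage[i, ]
    hwe_exact_p(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                sum(x == 2, na.rm = TRUE))
  }, numeric(1))
  keep <- log_step("HWE", keep & !is.na(hwe_p) & hwe_p > hwe_p_min)
  if (!is.null(g$mean_depth))
    keep <- log_step("depth", keep & g$mean_depth >= min_depth)
  if (!is.null(g$min_gq))
    keep <- log_step("GQ", keep & g$min_gq >= min_gq)
  # greedy thinning, ties in position broken by input order
  ord <- order(g$chrom, g$pos)
  last_chrom <- ""
  last_pos <- -Inf
  for (i in ord) {
    if (!keep[i]) next
    if (g$chrom[i] != last_chrom || g$pos[i] - last_pos >= thin_bp) {
      last_chrom <- g$chrom[i]
      last_pos <- g$pos[i]
    } else keep[i] <- FALSE
  }
  keep <- log_step("thinning", keep)
  if (!sum(keep)) warning("no SNPs pass the filters; returning empty matrix")
  out <- list(dosage = g$dosage[keep, , drop = FALSE],
              chrom = g$chrom[keep], pos = g$pos[keep],
              biallelic = rep(TRUE, sum(keep)))
  if (!is.null(g$mean_depth)) out$mean_depth <- g$mean_depth[keep]
  if (!is.null(g$min_gq)) out$min_gq <- g$min_gq[keep]
  out
}

#' Impute missing dosages to the per-SNP mean
#' @param g genotype object.
#' @param verbose report the number of imputed calls.
#' @return genotype object without missing values.
#' @export
impute_mean <- function(g, verbose = FALSE) {
  d <- g$dosage
  n_imp <- sum(is.na(d))
  if (n_imp) {
    mu <- rowMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 1]]
    if (verbose) message(sprintf("impute_mean: imputed %d calls", n_imp))
  }
  g$dosage <- d
  g
}

#' Estimate the genetic relatedness matrix
#'
#' Allele-frequency-weighted relatedness (Yang et al. form): off-diagonal
#' A_jk = mean over SNPs of (x_j - 2p)(x_k - 2p) / (2p(1-p)); diagonal
#' A_jj = 1 + mean of (x_j^2 - (1+2p)x_j + 2p^2) / (2p(1-p)), with p the
#' sample allele frequency. Under Hardy-Weinberg proportions the expected
#' diagonal is 1, full sibs about 0.5 and unrelated pairs about 0.
#'
#' @param g genotype object with no missing dosages (see [impute_mean()]).
#' @return symmetric kinship matrix over individuals.
#' @export
estimate_kinship <- function(g) {
  X <- g$dosage
  if (ncol(X) < 2) stop_arg("need at least 2 individuals")
  if (anyNA(X)) stop_arg("missing dosages; run impute_mean() first")
  p <- rowMeans(X) / 2
  if (any(p <= 0 | p >= 1))
    stop_arg("monomorphic SNPs reached the estimator; filter them out")
  v <- 2 * p * (1 - p)
  N <- nrow(X)
  W <- (X - 2 * p) / sqrt(v)
  K <- crossprod(W) / N
  diag(K) <- 1 + colMeans((X^2 - (1 + 2 * p) * X + 2 * p^2) / v)
  (K + t(K)) / 2
}
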