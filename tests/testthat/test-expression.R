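# Normalization stages and the differential-expression drive.

test_that("TPM normalizes gene length and depth", {
  counts <- cbind(s1 = c(10, 90))
  tpm <- compute_tpm(counts, c(1000, 9000))
  expect_equal(unname(tpm[, 1]), c(5e5, 5e5))
  single <- compute_tpm(cbind(s1 = c(0, 7)), c(100, 200))
  expect_equal(unname(single[2, 1]), 1e6)
  set.seed(71)
  m <- matrix(rpois(500, 20), 50, 10,
              dimnames = list(NULL, paste0("s", 1:10)))
  tp <- compute_tpm(m, runif(50, 200, 2000))
  expect_equal(unname(colSums(tp)), rep(1e6, 10), tolerance = 1e-9)
  bad <- m; bad[, 3] <- 0
  expect_error(compute_tpm(bad, rep(1000, 50)), "s3")
})

test_that("expressed-gene filter applies inclusive thresholds", {
  tpm <- matrix(0, 2, 48)
  tpm[1, 1:12] <- 2        # exactly 25% of samples at exactly TPM 2
  tpm[2, ] <- 1.99
  keep <- filter_genes(tpm, min_tpm = 2, min_frac = 0.25)
  expect_identical(unname(keep), c(TRUE, FALSE))
  # ceiling convention at n = 47: need ceil(11.75) = 12 samples
  tpm47 <- matrix(0, 2, 47)
  tpm47[1, 1:12] <- 5
  tpm47[2, 1:11] <- 5
  expect_identical(unname(filter_genes(tpm47)), c(TRUE, FALSE))
})

test_that("TMM factors match the brute-force reimplementation", {
  set.seed(72)
  counts <- matrix(rnbinom(3000 * 6, mu = 40, size = 1.5), 3000, 6)
  counts[1:150, 2] <- counts[1:150, 2] * 8  # asymmetric contamination
  expect_lt(max(abs(tmm_factors(counts) - tmm_oracle(counts))), 1e-6)
  same <- matrix(rep(c(5, 10, 20, 40), 3), 4, 3)
  expect_equal(unname(tmm_factors(same)), rep(1, 3), tolerance = 1e-12)
  doubled <- cbind(same[, 1], same[, 1] * 2)
  expect_equal(unname(tmm_factors(doubled)), c(1, 1), tolerance = 1e-12)
})

test_that("log-CPM matches its closed form and is depth-stable", {
  counts <- matrix(c(0, 999999, 50, 999950), 2, 2)
  out <- log_cpm_voom(counts, factors = c(1, 1))
  # libsize + 1 = 1e6: log2((0 + 0.5)) = -1
  expect_equal(out$expr[1, 1], log2(0.5), tolerance = 1e-9)
  manual <- log2((counts + 0.5) / (rep(colSums(counts) + 1, each = 2)) * 1e6)
  expect_equal(unname(out$expr), unname(manual), tolerance = 1e-9)
  expect_true(all(is.finite(out$weights)) && all(out$weights > 0))
  set.seed(73)
  big <- matrix(rpois(400, 500) + 100, 40, 10)
  e1 <- log_cpm_voom(big)$expr
  e2 <- log_cpm_voom(big * 2L)$expr
  expect_lt(max(abs(e1 - e2)), 1e-3)
})

test_that("residualization equals the hat-matrix projection", {
  set.seed(74)
  n <- 30
  covar <- data.frame(a = rnorm(n), b = rnorm(n))
  expr <- matrix(rnorm(5 * n), 5, n)
  out <- residualize(expr, covar)
  X <- cbind(1, covar$a, covar$b)
  H <- X %*% solve(crossprod(X), t(X))
  oracle <- expr - expr %*% H + rowMeans(expr)
  expect_equal(out, oracle, tolerance = 1e-8)
  # expression equal to a covariate is flattened to its mean
  expr2 <- rbind(covar$a)
  out2 <- residualize(expr2, covar)
  expect_equal(unname(out2[1, ]), rep(mean(covar$a), n), tolerance = 1e-10)
  expect_error(residualize(expr, data.frame(a = covar$a, a2 = covar$a * 2)),
               "collinear")
})

test_that("injected long-bone effects stay out of the vertebral contrast", {
  fx <- make_expression_fixture(n_animals = 12, n_genes = 300, n_de = 30,
                                effect_size = 1, seed = 75)
  de <- run_de(fx$counts, fx$lengths, fx$design, fx$K, n_perm = 0)
  is_de <- de$table$gene %in% fx$truth$genes[1:30]
  expect_gt(mean(de$table$beta_status_long[is_de]), 0.7)
  expect_lt(abs(mean(de$table$beta_status_lv[is_de])), 0.15)
  # non-null genes shift slightly negative (library composition); the
  # injected contrast stands far above that background
  expect_lt(abs(mean(de$table$beta_status_long[!is_de])), 0.2)
  expect_gt(mean(de$table$beta_status_long[is_de]) -
              mean(de$table$beta_status_long[!is_de]), 0.8)
})

test_that("animal-level permutations keep repeated samples concordant", {
  fx <- make_expression_fixture(n_animals = 8, n_genes = 10, seed = 76)
  set.seed(1)
  for (i in 1:10) {
    perm <- molequeen:::permute_status_by_animal(fx$design)
    split_status <- split(perm, fx$design$animal)
    expect_true(all(vapply(split_status, function(s)
      length(unique(s)) == 1, logical(1))))
    expect_equal(sort(unique(perm)), 0:1)
  }
})

test_that("pipeline output is exchangeable under sample reordering", {
  fx <- make_expression_fixture(n_animals = 8, n_genes = 80, seed = 77)
  de1 <- run_de(fx$counts, fx$lengths, fx$design, fx$K, n_perm = 0)
  perm <- sample(ncol(fx$counts))
  de2 <- run_de(fx$counts[, perm], fx$lengths, fx$design[perm, ], fx$K,
                n_perm = 0)
  expect_equal(de1$table$beta_status_long, de2$table$beta_status_long,
               tolerance = 1e-8)
  expect_equal(de1$table$p_status_lv, de2$table$p_status_lv,
               tolerance = 1e-6)
})

test_that("empirical FDR behaves at its extremes and is perm-count stable", {
  set.seed(78)
  p_obs <- runif(200, 0, 1e-6)
  p_perm <- matrix(runif(200 * 20, 0.2, 1), 200, 20)
  f <- empirical_fdr(p_obs, p_perm)
  expect_true(all(f$q < 0.01))
  # observed from the same distribution as the null
  p_obs2 <- runif(400)
  p_perm2 <- matrix(runif(400 * 30), 400, 30)
  f2 <- empirical_fdr(p_obs2, p_perm2)
  expect_gt(median(f2$q), 0.8)
  # q monotone nondecreasing in p
  expect_true(all(diff(f2$q[order(f2$p)]) >= -1e-12))
  expect_true(all(f2$q >= 0 & f2$q <= 1))
  # doubling the permutation count leaves q stable
  p_perm3 <- cbind(p_perm2, matrix(runif(400 * 30), 400, 30))
  f3 <- empirical_fdr(p_obs2, p_perm3)
  expect_lt(median(abs(f3$q - f2$q)), 0.05)
})
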