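# Synthetic-data generators: Mendelian consistency, determinism, and
# ground-truth behavior of the null configurations.

test_that("offspring genotypes respect Mendelian transmission", {
  sim <- simulate_pedigree_genotypes(1, 2, 500, seed = 51)
  d <- sim$genotypes$dosage
  gs <- d[, "F1S"]; gd <- d[, "F1D"]
  lower <- (gs == 2) + (gd == 2)
  upper <- 2 - (gs == 0) - (gd == 0)
  for (kid in c("F1C1", "F1C2")) {
    expect_true(all(d[, kid] >= lower))
    expect_true(all(d[, kid] <= upper))
  }
})

test_that("founder allele frequencies track the requested MAF range", {
  sim <- simulate_pedigree_genotypes(10, 1, 10000,
                                     maf_range = c(0.5, 0.5), seed = 52)
  founders <- grep("S$|D$", sim$pedigree$individuals, value = TRUE)
  p_hat <- mean(sim$genotypes$dosage[, founders]) / 2
  expect_lt(abs(p_hat - 0.5), 0.01)
  expect_error(simulate_pedigree_genotypes(1, 1, 10, maf_range = c(0, 0.6)),
               "maf_range")
  expect_error(simulate_pedigree_genotypes(0, 1, 10), "integer")
})

test_that("generators are pure functions of parameters and seed", {
  a <- simulate_pedigree_genotypes(3, 2, 200, seed = 53)
  b <- simulate_pedigree_genotypes(3, 2, 200, seed = 53)
  expect_identical(a, b)
  m1 <- simulate_meshes(2, seed = 54)
  m2 <- simulate_meshes(2, seed = 54)
  expect_identical(m1, m2)
  s1 <- simulate_sections_and_morpho(6, seed = 55)
  s2 <- simulate_sections_and_morpho(6, seed = 55)
  expect_identical(s1, s2)
  c1 <- simulate_calibration(20, seed = 56)
  expect_identical(c1, simulate_calibration(20, seed = 56))
})

test_that("null expression generator centers status effects on zero", {
  fx <- make_expression_fixture(n_animals = 12, n_genes = 300,
                                sigma_u2 = 0, seed = 57)
  de <- run_de(fx$counts, fx$lengths, fx$design, fx$K, n_perm = 0)
  expect_lt(abs(mean(de$table$beta_status_long)), 0.05)
  expect_lt(abs(mean(de$table$beta_status_lv)), 0.05)
})

test_that("strong kinship variance induces within-family correlation", {
  fx <- make_expression_fixture(n_animals = 12, n_genes = 400,
                                sigma_u2 = 3, sigma_e2 = 0.05, seed = 58)
  expr <- log2(fx$counts + 1)
  cc <- cor(expr)
  fam <- fx$animals$colony[match(fx$design$animal, fx$animals$animal)]
  same_animal <- outer(fx$design$animal, fx$design$animal, "==")
  same_fam <- outer(fam, fam, "==") & !same_animal
  diff_fam <- !outer(fam, fam, "==")
  ut <- upper.tri(cc)
  expect_gt(mean(cc[same_fam & ut]), mean(cc[diff_fam & ut]))
})

test_that("design animals missing from kinship are reported by name", {
  fx <- make_expression_fixture(n_animals = 4, n_genes = 10, seed = 59)
  K2 <- fx$K[-1, -1]
  expect_error(simulate_counts(fx$design, fx$truth, K2, seed = 1), "A1")
})

test_that("simulated meshes are closed genus-0 surfaces", {
  sm <- simulate_meshes(2, elongation = 1.3, noise_sd = 0.01, seed = 60)
  for (m in sm$meshes) {
    expect_equal(mesh_euler_characteristic(m), 2)
    # every edge is shared by exactly two faces
    f <- m$faces
    e <- rbind(f[, 1:2], f[, 2:3], f[, c(1, 3)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    expect_true(all(table(key) == 2))
  }
  same <- simulate_meshes(3, elongation = 1, noise_sd = 0, seed = 61)
  expect_equal(same$meshes[[1]], same$meshes[[4]])
})

test_that("sections mirror marrow expansion at fixed periosteal area", {
  s <- simulate_sections_and_morpho(24, seed = 62)
  geo <- lapply(s$sections, section_geometry)
  ta <- sapply(geo, `[[`, "ta")
  marrow <- sapply(geo, `[[`, "marrow")
  q <- s$animals$status == 1
  expect_gt(t.test(ta[q], ta[!q])$p.value, 0.01)
  expect_lt(t.test(marrow[q], marrow[!q])$p.value, 0.01)
  # radii with r >= R rejected
  expect_error(molequeen:::annulus_image(0.5, 0.6, 0.02), "smaller")
})

test_that("null section generator leaves cortical area exchangeable", {
  pvals <- sapply(1:20, function(s) {
    sm <- simulate_sections_and_morpho(
      12, params = sim_morpho_params(endosteal_per_pup_mm = 0), seed = 600 + s)
    ca <- sapply(sm$sections, function(x) section_geometry(x)$ca)
    t.test(ca[sm$animals$status == 1], ca[sm$animals$status == 0])$p.value
  })
  # p-values behave like a uniform sample: no excess of small values
  expect_lte(sum(pvals < 0.05), 4)
  expect_gt(mean(pvals), 0.25)
})

test_that("calibration generator hits its noise regime", {
  noiseless <- simulate_calibration(30, noise_sd = 0, seed = 63)
  f0 <- suppressWarnings(
    fit_max_load_calibration(noiseless$ca_mm2, noiseless$max_load_n))
  expect_equal(f0$r_squared, 1, tolerance = 1e-12)
  flat <- simulate_calibration(200, slope = 0, seed = 64)
  ff <- fit_max_load_calibration(flat$ca_mm2, flat$max_load_n)
  expect_lt(ff$r_squared, 0.05)
  r2 <- sapply(1:20, function(s) {
    d <- simulate_calibration(seed = 650 + s)
    fit_max_load_calibration(d$ca_mm2, d$max_load_n)$r_squared
  })
  expect_lt(abs(mean(r2) - 0.88), 0.05)
})
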