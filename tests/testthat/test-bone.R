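# Section geometry, load calibration, failure hazard and thickness deciles.

test_that("annulus geometry matches closed forms", {
  a <- 0.02
  img <- molequeen:::annulus_image(1.0, 0.5, a)
  g <- section_geometry(img, a)
  expect_equal(g$ca, pi * (1 - 0.25), tolerance = 0.02)
  expect_equal(g$marrow, pi * 0.25, tolerance = 0.03)
  expect_equal(g$i_min, pi / 4 * (1 - 0.5^4), tolerance = 0.03)
  expect_equal(g$j, pi / 2 * (1 - 0.5^4), tolerance = 0.03)
  expect_lte(g$i_min, g$i_max)
  expect_equal(g$j, g$i_min + g$i_max, tolerance = 1e-9)
  disk <- molequeen:::annulus_image(0.6, 1e-9, a)
  gd <- section_geometry(disk, a)
  expect_lt(gd$marrow / gd$ta, 0.01)
  expect_error(section_geometry(matrix(0, 5, 5), a), "empty")
})

test_that("section moments are rotation invariant", {
  # build an ellipse-like blob and rotate the raster by 90 degrees
  a <- 0.05
  ax <- seq(-1.5, 1.5, by = a)
  img <- outer(ax, ax, function(y, x) (x / 1.2)^2 + (y / 0.6)^2 <= 1) + 0L
  g1 <- section_geometry(img, a)
  g2 <- section_geometry(t(img)[ncol(img):1, ], a)
  expect_equal(g1$j, g2$j, tolerance = 0.01)
  expect_equal(g1$i_min, g2$i_min, tolerance = 0.02)
  expect_equal(g1$ca, g2$ca, tolerance = 1e-12)
})

test_that("calibration line is recovered exactly without noise", {
  ca <- seq(0.5, 2.5, length.out = 10)
  f <- suppressWarnings(fit_max_load_calibration(ca, 2 + 30 * ca))
  expect_equal(f$slope, 30, tolerance = 1e-10)
  expect_equal(f$intercept, 2, tolerance = 1e-9)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_error(fit_max_load_calibration(rep(1, 5), rnorm(5)), "variance")
  expect_error(fit_max_load_calibration(1:2, 1:2), "3")
})

test_that("relative loads are median-1 for nonbreeders and scale invariant", {
  cal <- list(slope = 20, intercept = 0)
  ca <- c(1, 1.2, 1.4, 0.8, 0.9)
  nb <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  fr <- predict_relative_load(cal, ca, nb)
  expect_equal(median(fr$load[nb]), 1)
  same <- predict_relative_load(cal, rep(1.3, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(same$load == 1))
  # doubling the slope and halving CA cancels when intercept is 0
  fr2 <- predict_relative_load(list(slope = 40, intercept = 0), ca / 2, nb)
  expect_equal(fr$load, fr2$load, tolerance = 1e-12)
  # median rescaling is idempotent
  refit <- predict_relative_load(list(slope = 1, intercept = 0), fr$load, nb)
  expect_equal(refit$load, fr$load, tolerance = 1e-12)
  expect_error(predict_relative_load(list(slope = 1, intercept = -10),
                                     ca, nb), "nonpositive")
})

test_that("Cox hazard recovers exponential rate ratios", {
  set.seed(101)
  hrs <- sapply(1:15, function(i) {
    loads <- c(rexp(200, 1), rexp(200, 2))   # rate ratio 2
    fr <- data.frame(load = loads,
                     group = rep(c("nonbreeder", "queen"), each = 200))
    failure_hazard(fr, "group")$hr
  })
  expect_lt(abs(mean(hrs) - 2) / 2, 0.1)
  # identical distributions: HR near 1
  set.seed(102)
  null_hr <- sapply(1:15, function(i) {
    fr <- data.frame(load = rexp(120), group = rep(c("a", "b"), 60))
    failure_hazard(fr, "group")$hr
  })
  expect_lt(abs(mean(log(null_hr))), 0.15)
})

test_that("stochastically smaller queen loads give HR above one", {
  set.seed(103)
  fr <- data.frame(load = c(rlnorm(40, 0, 0.1), rlnorm(40, -0.4, 0.1)),
                   group = rep(c("nonbreeder", "queen"), each = 40))
  hz <- failure_hazard(fr, "group")
  expect_gt(hz$hr, 1)
  expect_lt(hz$p, 0.05)
  expect_false(is.null(hz$ph_test))
  # per-offspring contrast runs on varying counts
  fr$offspring <- c(rep(0, 40), rpois(40, 4))
  expect_gt(failure_hazard(fr, "offspring")$hr, 1)
})

test_that("synthetic queens face elevated failure hazard across seeds", {
  hr_pos <- sapply(1:20, function(s) {
    sm <- simulate_sections_and_morpho(30, seed = 3000 + s)
    ca <- sapply(sm$sections, function(x) section_geometry(x)$ca)
    cal <- simulate_calibration(81, seed = 3100 + s)
    fit <- fit_max_load_calibration(cal$ca_mm2, cal$max_load_n)
    fr <- predict_relative_load(fit, ca / mean(ca) * 1.5,
                                sm$animals$status == 0)
    failure_hazard(fr, "group")$hr > 1
  })
  expect_gte(mean(hr_pos), 0.95)
})

test_that("decile aggregation trims and re-bins at the documented boundaries", {
  pos <- seq(0, 1, length.out = 101)
  flat <- decile_thickness(pos, rep(0.4, 101))
  expect_equal(flat$decile_means, rep(0.4, 10))
  # linear gradient: decile means are linear in the bin index
  lin <- decile_thickness(pos, 2 * pos)
  fit <- lm(lin$decile_means ~ I(1:10))
  expect_gt(suppressWarnings(summary(fit))$r.squared, 0.999)
  expect_equal(unname(coef(fit)[2]), 2 * 0.08, tolerance = 1e-2)
  # half-open trim: point at exactly 10% kept, at 90% dropped
  expect_warning(
    out <- decile_thickness(c(0, 0.1, 0.5, 0.9, 1, seq(0.2, 0.8, 0.1)),
                            c(99, 1, 1, 99, 99, rep(1, 7))),
    "empty decile")
  expect_true(all(is.na(out$decile_means) | out$decile_means == 1))
  expect_equal(sum(out$counts), 9)  # 0, 0.9, 1 trimmed; 0.1 retained
})

test_that("per-decile mixed models recover an injected offspring effect", {
  set.seed(104)
  hits <- replicate(40, {
    n <- 16
    pair <- rep(paste0("P", 1:(n / 2)), each = 2)
    status <- rep(0:1, n / 2)
    off <- ifelse(status == 1, rpois(n, 4), 0)
    u <- rnorm(n / 2, 0, 0.05)
    dm <- sapply(1:10, function(d)
      0.5 - 0.01 * off + u[match(pair, unique(pair))] + rnorm(n, 0, 0.02))
    fit <- per_decile_model(dm, status, off, pair)
    est <- fit$estimate[fit$term == "offspring"]
    se <- fit$se[fit$term == "offspring"]
    abs(est[1] - (-0.01)) < 3 * se[1]
  })
  expect_gte(mean(hits), 0.9)
})
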