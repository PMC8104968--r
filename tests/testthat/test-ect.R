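# Direction sets, Euler characteristic curves, ECT features and the
# weighted-SVM classifier.

test_that("direction generator emits unit vectors at the expected counts", {
  d0 <- generate_directions(0)
  d2 <- generate_directions(2)
  expect_equal(nrow(d0), 12)
  expect_equal(nrow(d2), 162)
  expect_true(all(abs(sqrt(rowSums(d2^2)) - 1) < 1e-12))
  g <- d2 %*% t(d2)
  diag(g) <- -2
  expect_lt(max(g), 1 - 1e-8)  # no duplicated directions
})

test_that("EC curves equal brute-force simplex counts", {
  set.seed(91)
  dirs <- generate_directions(0)
  for (s in 1:6) {
    mesh <- random_small_mesh(900 + s)
    for (d in sample(nrow(dirs), 3)) {
      ts <- seq(-1.6, 1.6, length.out = 20)
      expect_identical(ec_curve(mesh, dirs[d, ], ts),
                       ec_brute_force(mesh, dirs[d, ], ts))
    }
  }
})

test_that("EC curve endpoints reflect the mesh topology", {
  m <- icosphere(2)
  ts <- seq(-2, 2, length.out = 5)
  expect_equal(ec_curve(m, c(0, 0, 1), ts)[5], 2)  # closed genus-0
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       rbind(c(1, 2, 3)))
  expect_equal(ec_curve(tri, c(0, 0, 1), 0.5), 1)  # 3 - 3 + 1
  expect_error(ec_curve(m, c(0, 0, 1), c(1, 0)), "ascending")
})

test_that("feature vectors have direction-by-height length", {
  sm <- simulate_meshes(1, seed = 92)
  f <- ect_features(sm$meshes, generate_directions(2), n_heights = 100)
  expect_equal(ncol(f), 16200)
  f2 <- ect_features(sm$meshes, generate_directions(1), n_heights = 7)
  expect_equal(ncol(f2), 42 * 7)
})

test_that("SECT ends near zero and features are translation invariant", {
  sm <- simulate_meshes(2, seed = 93)
  dirs <- generate_directions(1)
  fs <- ect_features(sm$meshes, dirs, n_heights = 60, smooth = TRUE)
  # integral of a mean-centered curve over its full range
  ends <- fs[, seq(60, ncol(fs), by = 60)]
  scale_ref <- max(abs(fs))
  expect_lt(max(abs(ends)) / scale_ref, 0.1)
  shifted <- lapply(sm$meshes, function(m)
    triangle_mesh(m$vertices + rep(c(3, -2, 5), each = nrow(m$vertices)),
                  m$faces))
  f1 <- ect_features(sm$meshes, dirs, n_heights = 30)
  f2 <- ect_features(shifted, dirs, n_heights = 30)
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("feature extraction is deterministic", {
  sm <- simulate_meshes(2, seed = 94)
  dirs <- generate_directions(1)
  expect_identical(ect_features(sm$meshes, dirs, n_heights = 25),
                   ect_features(sm$meshes, dirs, n_heights = 25))
})

test_that("weighted SVM separates separable classes and breaks ties", {
  set.seed(95)
  x <- rbind(matrix(rnorm(40, -4), 10, 4), matrix(rnorm(40, 4), 10, 4))
  lab <- factor(rep(c("a", "b"), each = 10))
  r <- loo_weighted_svm(x, lab)
  expect_equal(r$accuracy, 1)
  # identical features: tie goes to the heavier-weighted (minority) class
  xx <- matrix(1, 9, 3)
  ll <- factor(c(rep("maj", 6), rep("min", 3)))
  rt <- loo_weighted_svm(xx, ll)
  expect_true(all(rt$predictions == "min"))
  expect_error(loo_weighted_svm(x[1:10, ], lab[1:10]), "2 classes")
})

test_that("random labels give chance-level accuracy", {
  set.seed(96)
  x <- matrix(rnorm(24 * 5), 24, 5)
  accs <- sapply(1:8, function(i)
    loo_weighted_svm(x, factor(sample(rep(c("a", "b"), 12))),
                     class_weights = c(a = 1, b = 1))$accuracy)
  expect_lt(abs(mean(accs) - 0.5), 0.2)
})

test_that("permutation p has the add-one floor and is never zero", {
  set.seed(97)
  x <- rbind(matrix(rnorm(20, -5), 5, 4), matrix(rnorm(20, 5), 5, 4))
  lab <- factor(rep(c("a", "b"), each = 5))
  r <- permutation_pvalue(x, lab, n_perm = 19, seed = 2)
  expect_equal(r$p, 1 / 20)
  expect_gt(r$p, 0)
})

test_that("synthetic elongated and round meshes are distinguishable", {
  sm <- simulate_meshes(6, elongation = 1.3, noise_sd = 0.02, seed = 98)
  f <- ect_features(sm$meshes, generate_directions(1), n_heights = 30)
  r <- loo_weighted_svm(f, sm$labels)
  expect_gt(r$accuracy, 0.9)
})

test_that("mesh files round trip through OFF and PLY", {
  sm <- simulate_meshes(1, seed = 99)
  m <- sm$meshes[[1]]
  off <- tempfile(fileext = ".off")
  write_off(m, off)
  back <- read_mesh(off)
  expect_equal(back$vertices, m$vertices, tolerance = 1e-12)
  expect_identical(back$faces, m$faces)
  ply <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(m$vertices)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(m$faces)),
               "property list uchar int vertex_indices", "end_header",
               apply(format(m$vertices, digits = 17, trim = TRUE), 1,
                     paste, collapse = " "),
               paste(3, m$faces[, 1] - 1, m$faces[, 2] - 1,
                     m$faces[, 3] - 1)), ply)
  back2 <- read_mesh(ply)
  expect_equal(back2$vertices, m$vertices, tolerance = 1e-12)
  expect_identical(back2$faces, m$faces)
  unlink(c(off, ply))
})
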