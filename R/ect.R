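# Euler characteristic transform (ECT/SECT) featurization of triangle
# meshes and weighted linear-SVM classification with leave-one-out and
# permutation testing.

#' Subdivided-icosahedron sphere mesh
#'
#' Starts from the regular icosahedron and subdivides each triangular face
#' into four, projecting new vertices to the unit sphere. Vertex count is
#' 10 * 4^level + 2.
#'
#' @param level subdivision level (>= 0).
#' @return a `triangle_mesh` with unit-norm vertices.
#' @export
icosphere <- function(level = 0) {
  level <- check_count(level, "level", min = 0L)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (l in seq_len(level)) {
    midpoint_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- list(v)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- midpoint_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (vlist[[1]][a, ] + vlist[[1]][b, ]) / 2
      m <- m / sqrt(sum(m^2))
      vlist[[1]] <<- rbind(vlist[[1]], m)
      idx <- nrow(vlist[[1]])
      midpoint_cache[[key]] <- idx
      idx
    }
    newf <- matrix(0L, nrow(f) * 4, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[(i - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- vlist[[1]]
    f <- newf
  }
  triangle_mesh(v, f)
}

#' Approximately uniform direction set on the sphere
#'
#' Directions are the vertices of a `level`-times subdivided icosahedron,
#' normalized to unit length; the count is 10 * 4^level + 2 (162 at
#' level 2).
#'
#' @param level icosahedral subdivision level.
#' @return matrix of unit row vectors, one direction per row.
#' @export
generate_directions <- function(level = 2) {
  v <- icosphere(level)$vertices
  v / sqrt(rowSums(v^2))
}

#' Euler characteristic curve of a mesh along one direction
#'
#' For each threshold t, the sublevel complex contains the vertices with
#' projection <= t plus every edge and face all of whose vertices are
#' included; the curve reports V - E + F per threshold and reaches the full
#' mesh's Euler characteristic once t passes the largest projection.
#'
#' @param mesh a `triangle_mesh`.
#' @param direction unit 3-vector.
#' @param thresholds ascending threshold values.
#' @return integer vector of Euler characteristics, one per threshold.
#' @export
ec_curve <- function(mesh, direction, thresholds) {
  if (!nrow(mesh$vertices)) stop_arg("empty mesh")
  if (is.unsorted(thresholds)) stop_arg("thresholds must be ascending")
  hv <- as.numeric(mesh$vertices %*% direction)
  e <- mesh_edges(mesh)
  he <- pmax(hv[e[, 1]], hv[e[, 2]])
  hf <- pmax(hv[mesh$faces[, 1]],
             pmax(hv[mesh$faces[, 2]], hv[mesh$faces[, 3]]))
  findInterval(thresholds, sort(hv)) -
    findInterval(thresholds, sort(he)) +
    findInterval(thresholds, sort(hf))
}

#' ECT / SECT features for a set of meshes
#'
#' For every direction, thresholds are `n_heights` evenly spaced values
#' spanning the pooled projection range of all meshes in the set (so
#' features are comparable across meshes); optionally each mesh can use its
#' own range. Raw mode stores the Euler characteristic curve; smooth mode
#' (SECT) stores the cumulative trapezoidal integral of the mean-centered
#' curve. Features are flattened direction-major, giving vectors of length
#' n_directions * n_heights. Meshes are assumed pre-aligned and pre-scaled;
#' no alignment is attempted here.
#'
#' @param meshes list of `triangle_mesh`.
#' @param directions matrix of unit directions ([generate_directions()]).
#' @param n_heights height evaluations per direction.
#' @param smooth logical; TRUE for SECT.
#' @param pooled_range share threshold ranges across the data set (TRUE,
#'   default) or use per-mesh ranges.
#' @return matrix, one flattened feature vector per mesh (rows).
#' @export
ect_features <- function(meshes, directions, n_heights = 100, smooth = FALSE,
                         pooled_range = TRUE) {
  directions <- as.matrix(directions)
  n_dir <- nrow(directions)
  proj <- lapply(meshes, function(m) m$vertices %*% t(directions))
  lo_all <- apply(sapply(proj, function(p) apply(p, 2, min)), 1, min)
  hi_all <- apply(sapply(proj, function(p) apply(p, 2, max)), 1, max)
  edges <- lapply(meshes, mesh_edges)
  feat <- t(vapply(seq_along(meshes), function(i) {
    m <- meshes[[i]]
    e <- edges[[i]]
    pv <- proj[[i]]
    out <- numeric(n_dir * n_heights)
    for (d in seq_len(n_dir)) {
      if (pooled_range) {
        lo <- lo_all[d]; hi <- hi_all[d]
      } else {
        lo <- min(pv[, d]); hi <- max(pv[, d])
      }
      ts <- seq(lo, hi, length.out = n_heights)
      hv <- pv[, d]
      he <- pmax(hv[e[, 1]], hv[e[, 2]])
      hf <- pmax(hv[m$faces[, 1]], pmax(hv[m$faces[, 2]], hv[m$faces[, 3]]))
      chi <- findInterval(ts, sort(hv)) - findInterval(ts, sort(he)) +
        findInterval(ts, sort(hf))
      vals <- if (smooth) pracma::cumtrapz(ts, chi - mean(chi))[, 1] else chi
      out[(d - 1) * n_heights + seq_len(n_heights)] <- vals
    }
    out
  }, numeric(n_dir * n_heights)))
  rownames(feat) <- names(meshes)
  feat
}

#' Center and PCA-align a mesh (convenience only)
#'
#' Translates the centroid to the origin and rotates the principal axes of
#' the vertex cloud onto the coordinate axes. This is a crude stand-in for
#' proper joint surface alignment and is not equivalent to it; use on data
#' whose meshes are not already co-registered is at the caller's risk.
#'
#' @param mesh a `triangle_mesh`.
#' @return aligned `triangle_mesh`.
#' @export
pca_align_mesh <- function(mesh) {
  v <- scale(mesh$vertices, center = TRUE, scale = FALSE)
  rot <- eigen(stats::cov(v), symmetric = TRUE)$vectors
  # fix sign so the rotation is proper and deterministic
  rot <- sweep(rot, 2, sign(colSums(rot^3) + 1e-12), "*")
  if (det(rot) < 0) rot[, 3] <- -rot[, 3]
  triangle_mesh(v %*% rot, mesh$faces)
}

#' Leave-one-out classification with a class-weighted linear SVM
#'
#' For each held-out sample a linear soft-margin SVM (C-classification) is
#' trained on the rest with per-class misclassification costs; the minority
#' class receives the large weight to balance unequal class sizes. Tied
#' decision values predict the heavier-weighted class.
#'
#' @param features samples x features matrix.
#' @param labels two-level factor.
#' @param class_weights named weights; default gives the minority class
#'   weight 1e5 and the majority class 1.
#' @param cost base SVM cost parameter.
#' @return object of class `mq_classifier`: `predictions`, `accuracy`,
#'   `class_weights`.
#' @export
loo_weighted_svm <- function(features, labels, class_weights = NULL,
                             cost = 1) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) stop_arg("labels must have exactly 2 classes")
  if (any(table(labels) < 2)) stop_arg("need >= 2 samples per class")
  if (is.null(class_weights)) {
    tab <- table(labels)
    minority <- names(tab)[which.min(tab)]
    class_weights <- setNames(c(1, 1e5),
                              c(setdiff(names(tab), minority), minority))
  }
  n <- nrow(features)
  heavier <- names(class_weights)[which.max(class_weights)]
  preds <- vapply(seq_len(n), function(i) {
    tr_lab <- labels[-i]
    if (nlevels(droplevels(tr_lab)) < 2)
      stop_arg("single-class training fold at sample ", i)
    fit <- e1071::svm(features[-i, , drop = FALSE], tr_lab,
                      kernel = "linear", type = "C-classification",
                      class.weights = class_weights, cost = cost,
                      scale = FALSE)
    dv <- attr(predict(fit, features[i, , drop = FALSE],
                       decision.values = TRUE), "decision.values")
    if (abs(dv) < 1e-12) return(heavier)
    as.character(predict(fit, features[i, , drop = FALSE]))
  }, character(1))
  structure(list(predictions = factor(preds, levels = levels(labels)),
                 accuracy = mean(preds == as.character(labels)),
                 class_weights = class_weights),
            class = "mq_classifier")
}

#' Permutation p-value for classification accuracy
#'
#' Labels are permuted `n_perm` times and the leave-one-out accuracy
#' recomputed; p = (1 + #\{permuted accuracy >= observed\}) / (1 + n_perm),
#' so p is never zero and its floor is 1/(n_perm + 1).
#'
#' @param features samples x features matrix.
#' @param labels two-level factor.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @param ... passed to [loo_weighted_svm()].
#' @return object of class `mq_classifier_test`: observed report, `p`,
#'   `perm_accuracy`, `n_perm`.
#' @export
permutation_pvalue <- function(features, labels, n_perm = 100, seed = 1, ...) {
  n_perm <- check_count(n_perm, "n_perm", min = 1L)
  obs <- loo_weighted_svm(features, labels, ...)
  perm_acc <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    loo_weighted_svm(features, sample(labels), ...)$accuracy
  }, numeric(1)))
  structure(list(observed = obs,
                 p = (1 + sum(perm_acc >= obs$accuracy)) / (1 + n_perm),
                 perm_accuracy = perm_acc, n_perm = n_perm, seed = seed),
            class = "mq_classifier_test")
}
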