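# Cross-sectional bone geometry, the cortical-area to max-load calibration,
# Cox models of relative failure risk, and cortical-thickness decile models.

#' Cross-sectional geometry of a binary section image
#'
#' Cortical area is the foreground pixel count times pixel area; total
#' (periosteal) area additionally counts enclosed holes, found by flood
#' filling from the image border (any pixel unreachable from the border is
#' enclosed). Second moments of area are accumulated per pixel about the
#' centroidal axes (parallel-axis theorem, including the a^4/12 pixel
#' self-moment); principal moments come from the eigendecomposition of the
#' area-moment tensor and J = I_xx + I_yy is rotation invariant.
#'
#' @param img binary matrix (bone = 1) or list with `img` and `pixel_mm`.
#' @param pixel_mm pixel edge length in mm (ignored when `img` carries it).
#' @return object of class `mq_section_geometry` with areas (mm^2), `i_min`,
#'   `i_max`, `j` (mm^4), `centroid` and `n_components`.
#' @export
section_geometry <- function(img, pixel_mm = NULL) {
  if (is.list(img)) {
    pixel_mm <- pixel_mm %||% img$pixel_mm
    img <- img$img
  }
  if (is.null(pixel_mm) || is.na(pixel_mm))
    stop_arg("pixel_mm is required")
  img <- (as.matrix(img) > 0) + 0L
  if (!sum(img)) stop_arg("empty section image")
  lab <- EBImage::bwlabel(img)
  n_comp <- max(lab)
  if (n_comp > 1) {
    sizes <- tabulate(lab[lab > 0])
    if (sum(sizes) - max(sizes) > 0.01 * sum(sizes))
      warning("section has ", n_comp,
              " connected components; geometry uses all foreground pixels")
  }
  a <- pixel_mm
  ca <- sum(img) * a^2
  filled <- EBImage::fillHull(img)
  ta <- sum(filled > 0) * a^2
  idx <- which(img == 1, arr.ind = TRUE)
  x <- idx[, 2] * a
  y <- idx[, 1] * a
  xc <- mean(x); yc <- mean(y)
  n_px <- nrow(idx)
  ixx <- sum((y - yc)^2) * a^2 + n_px * a^4 / 12
  iyy <- sum((x - xc)^2) * a^2 + n_px * a^4 / 12
  ixy <- sum((x - xc) * (y - yc)) * a^2
  principal <- eigen(matrix(c(ixx, -ixy, -ixy, iyy), 2), symmetric = TRUE)$values
  structure(list(ca = ca, ta = ta, marrow = ta - ca, ca_ta = ca / ta,
                 i_min = min(principal), i_max = max(principal),
                 j = ixx + iyy, centroid = c(x = xc, y = yc),
                 n_components = n_comp, pixel_mm = pixel_mm),
            class = "mq_section_geometry")
}

#' Linear calibration of max load against cortical area
#'
#' @param ca cortical areas (mm^2).
#' @param max_load maximum loads (force units).
#' @return list with `slope`, `intercept`, `r_squared`, `n` and the `lm`
#'   fit.
#' @export
fit_max_load_calibration <- function(ca, max_load) {
  if (length(ca) < 3) stop_arg("need at least 3 specimens")
  if (var(ca) == 0) stop_arg("cortical area has zero variance")
  fit <- lm(max_load ~ ca)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared, n = length(ca), fit = fit)
}

#' Predict relative failure loads from cortical areas
#'
#' Applies the calibration line and rescales so the median predicted load
#' of nonbreeders equals 1.
#'
#' @param calibration result of [fit_max_load_calibration()].
#' @param ca subject cortical areas (mm^2).
#' @param nonbreeder logical mask of nonbreeders (>= 1 TRUE).
#' @param group optional group label per subject.
#' @param offspring optional offspring count per subject.
#' @return `mq_survival_frame` data.frame with `load` (relative force),
#'   `group`, `offspring`.
#' @export
predict_relative_load <- function(calibration, ca, nonbreeder,
                                  group = NULL, offspring = NULL) {
  if (!any(nonbreeder)) stop_arg("need at least one nonbreeder")
  pred <- calibration$intercept + calibration$slope * ca
  if (any(pred <= 0))
    stop_arg("nonpositive predicted load; cortical area outside the ",
             "calibration's validity range")
  rel <- pred / median(pred[nonbreeder])
  out <- data.frame(load = rel,
                    group = if (is.null(group))
                      ifelse(nonbreeder, "nonbreeder", "queen") else group,
                    offspring = offspring %||% NA_real_,
                    stringsAsFactors = FALSE)
  class(out) <- c("mq_survival_frame", "data.frame")
  out
}

#' Cox model of relative bone-failure hazard
#'
#' The predicted relative load is treated as the failure-time axis with no
#' censoring (every bone "fails" at its predicted load), so the Cox partial
#' likelihood (Efron ties) compares entire load distributions: a group with
#' stochastically smaller loads fails earlier and gets a hazard ratio above
#' one. A Schoenfeld-residual proportional-hazards diagnostic and
#' Kaplan-Meier curves per group are attached.
#'
#' @param frame `mq_survival_frame` (or data.frame with `load` plus the
#'   covariate).
#' @param covariate "group" (two-level contrast) or "offspring" (per-pup
#'   hazard ratio).
#' @return object of class `mq_hazard`: `hr`, `ci` (95%), `p` (Wald),
#'   `separation` flag, `ph_test`, `km` (survfit), `medians`, `fit`.
#' @export
failure_hazard <- function(frame, covariate = c("group", "offspring")) {
  covariate <- match.arg(covariate)
  if (covariate == "group") {
    frame$group <- droplevels(as.factor(frame$group))
    if (nlevels(frame$group) != 2) stop_arg("group must have 2 levels")
    if (any(table(frame$group) < 2))
      stop_arg("need >= 2 subjects per group")
    x <- frame$group
  } else {
    if (length(unique(frame$offspring)) < 2)
      stop_arg("offspring counts do not vary")
    x <- frame$offspring
  }
  s <- survival::Surv(frame$load, rep(1, nrow(frame)))
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(s ~ x, ties = "efron"),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(coef(fit)[1])
  se <- sqrt(fit$var[1, 1])
  separation <- warned || se > 50 || abs(beta) > 50
  if (separation)
    warning("monotone partial likelihood (separated load distributions); ",
            "confidence interval unbounded")
  ph <- tryCatch(survival::cox.zph(fit), error = function(e) NULL)
  km <- if (covariate == "group")
    survival::survfit(s ~ frame$group) else survival::survfit(s ~ 1)
  med <- summary(km)$table
  structure(list(hr = exp(beta),
                 ci = exp(beta + c(-1, 1) * 1.96 * se),
                 p = 2 * pnorm(-abs(beta / se)),
                 beta = beta, se = se, separation = separation,
                 ph_test = ph, km = km, medians = med, fit = fit),
            class = "mq_hazard")
}

#' Kaplan-Meier curve points as a table
#' @param hz an `mq_hazard` object.
#' @return data.frame with `group`, `load`, `surv`.
#' @export
km_table <- function(hz) {
  km <- hz$km
  strata <- if (is.null(km$strata)) "all" else
    rep(sub(".*=", "", names(km$strata)), km$strata)
  data.frame(group = strata, load = km$time, surv = km$surv,
             stringsAsFactors = FALSE)
}

#' Aggregate a cortical-thickness point set into axial deciles
#'
#' Points in the first and last tenth of the axial extent are discarded
#' (half-open trim: a point at exactly 10% is retained, one at 90% is not)
#' and the remaining central 80% is re-partitioned into 10 equal axial
#' bins; the mean thickness per bin is reported.
#'
#' @param position axial positions (any units; the extent is taken from the
#'   data).
#' @param thickness thickness at each position (mm).
#' @return list with `decile_means` (length 10), `counts`, `breaks`.
#' @export
decile_thickness <- function(position, thickness) {
  if (length(position) < 10) stop_arg("need >= 10 points spanning the axis")
  lo <- min(position); hi <- max(position)
  if (hi == lo) stop_arg("degenerate axial extent")
  frac <- (position - lo) / (hi - lo)
  keep <- frac >= 0.1 & frac < 0.9
  breaks <- seq(0.1, 0.9, length.out = 11)
  bin <- findInterval(frac[keep], breaks, rightmost.closed = FALSE)
  means <- counts <- rep(NA_real_, 10)
  for (d in 1:10) {
    k <- bin == d
    counts[d] <- sum(k)
    if (counts[d]) means[d] <- mean(thickness[keep][k])
  }
  if (any(counts == 0)) warning("empty decile bin(s): ",
                                paste(which(counts == 0), collapse = ", "))
  list(decile_means = means, counts = counts, breaks = breaks)
}

#' Per-decile mixed models of cortical thickness
#'
#' For each decile, fits thickness ~ breeding status + offspring count with
#' a random intercept per littermate pair (identity kinship over pairs,
#' through the shared REML engine). Animals without a pair form singleton
#' groups.
#'
#' @param decile_means animals x 10 matrix of decile mean thicknesses.
#' @param status 0/1 breeding status per animal.
#' @param offspring offspring count per animal.
#' @param pair littermate pair ID per animal (NA for unpaired).
#' @return data.frame with one row per decile x coefficient: estimate, SE,
#'   t, p.
#' @export
per_decile_model <- function(decile_means, status, offspring, pair) {
  decile_means <- as.matrix(decile_means)
  pair <- as.character(pair)
  unpaired <- is.na(pair) | pair == ""
  if (any(unpaired)) {
    warning(sum(unpaired), " unpaired animal(s) placed in singleton groups")
    pair[unpaired] <- paste0(".singleton", seq_len(sum(unpaired)))
  }
  if (length(unique(pair[!unpaired])) < 2)
    stop_arg("need >= 2 littermate pairs")
  pairs <- unique(pair)
  Z <- incidence_matrix(pair, pairs)
  K <- diag(length(pairs)); dimnames(K) <- list(pairs, pairs)
  X <- cbind(intercept = 1, status = status, offspring = offspring)
  out <- do.call(rbind, lapply(seq_len(ncol(decile_means)), function(d) {
    y <- decile_means[, d]
    ok <- !is.na(y)
    fit <- fit_gene_lmm(y[ok], X[ok, , drop = FALSE],
                        Z[ok, , drop = FALSE], K)
    data.frame(decile = d, term = names(fit$beta),
               estimate = unname(fit$beta), se = unname(fit$se),
               t = unname(fit$t), p = unname(fit$pvalue),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
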