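# Growth, fecundity and growth-plate models on longitudinal and litter
# tables. All mixed-model fits reuse the package's REML core.

#' Growth-by-status interaction model for vertebral length
#'
#' Linear mixed model of LV5 length on time point, breeding status and
#' their interaction, with a random intercept per animal (identity kinship
#' through the shared REML engine). Fit within a stated post-pairing
#' interval.
#'
#' @param records data.frame with `animal`, `status` (0/1), `month`,
#'   `lv5_mm`.
#' @param interval numeric length-2 interval of months to include
#'   (inclusive).
#' @return data.frame of coefficients with estimate, SE, t, p.
#' @export
growth_interaction_model <- function(records, interval = c(0, 4)) {
  r <- records[records$month >= interval[1] & records$month <= interval[2], ]
  if (length(unique(r$month)) < 2)
    stop_arg("need >= 2 time points within the interval")
  if (any(table(unique(r[, c("animal", "status")])$status) < 2))
    stop_arg("need >= 2 animals per status")
  animals <- unique(r$animal)
  Z <- incidence_matrix(r$animal, animals)
  K <- diag(length(animals)); dimnames(K) <- list(animals, animals)
  X <- cbind(intercept = 1, month = r$month, status = r$status,
             month_x_status = r$month * r$status)
  fit <- fit_gene_lmm(r$lv5_mm, X, Z, K)
  data.frame(term = names(fit$beta), estimate = unname(fit$beta),
             se = unname(fit$se), t = unname(fit$t),
             p = unname(fit$pvalue), stringsAsFactors = FALSE)
}

#' Scale skeletal lengths by zygomatic arch width
#' @param lengths lengths (mm).
#' @param zygomatic widths (mm), positive.
#' @return dimensionless ratios.
#' @export
scale_by_zygomatic <- function(lengths, zygomatic) {
  if (any(zygomatic <= 0)) stop_arg("zygomatic widths must be positive")
  lengths / zygomatic
}

#' Litter-size and pup-mass models
#'
#' Model 1: litter size ~ maternal body length + first-litter flag with a
#' random maternal intercept (single-kernel REML). Model 2: pup mass ~
#' maternal body length + litter size + first-litter flag with random
#' maternal and litter intercepts (two-kernel REML by direct optimization
#' over the two variance ratios). Litters without pup masses are skipped in
#' model 2.
#'
#' @param litters data.frame with `litter`, `mother`, `mother_length_cm`,
#'   `first_litter`, `litter_size`.
#' @param pups optional data.frame with `litter`, `mother`,
#'   `mother_length_cm`, `first_litter`, `litter_size`, `pup_mass_g`.
#' @return list with coefficient tables `litter_size` and (when pups are
#'   given) `pup_mass`, plus the raw fits.
#' @export
litter_models <- function(litters, pups = NULL) {
  if (length(unique(litters$mother)) < 2) stop_arg("need >= 2 mothers")
  mothers <- unique(litters$mother)
  Z <- incidence_matrix(litters$mother, mothers)
  K <- diag(length(mothers)); dimnames(K) <- list(mothers, mothers)
  X1 <- cbind(intercept = 1, mother_length = litters$mother_length_cm,
              first_litter = litters$first_litter)
  fit1 <- fit_gene_lmm(litters$litter_size, X1, Z, K)
  tab1 <- data.frame(term = names(fit1$beta), estimate = unname(fit1$beta),
                     se = unname(fit1$se), p = unname(fit1$pvalue),
                     stringsAsFactors = FALSE)
  out <- list(litter_size = tab1, fit_litter_size = fit1)
  if (!is.null(pups)) {
    pups <- pups[!is.na(pups$pup_mass_g), ]
    X2 <- cbind(intercept = 1, mother_length = pups$mother_length_cm,
                litter_size = pups$litter_size,
                first_litter = pups$first_litter)
    Km <- tcrossprod(incidence_matrix(pups$mother))
    Kl <- tcrossprod(incidence_matrix(pups$litter))
    fit2 <- reml_multikernel(pups$pup_mass_g, X2, list(mother = Km,
                                                       litter = Kl))
    out$pup_mass <- data.frame(term = names(fit2$beta),
                               estimate = unname(fit2$beta),
                               se = unname(fit2$se),
                               p = unname(fit2$pvalue),
                               stringsAsFactors = FALSE)
    out$fit_pup_mass <- fit2
  }
  out
}

#' Growth-plate fusion / chondrocyte-column models
#'
#' Ordinary least squares of the growth-plate response (fusion fraction or
#' chondrocyte columns per mm) on offspring count and age.
#'
#' @param response growth-plate measurement per animal.
#' @param offspring offspring counts.
#' @param age ages (months).
#' @return data.frame of coefficients with estimate, SE, p.
#' @export
growth_plate_models <- function(response, offspring, age) {
  if (length(response) < 4) stop_arg("need n >= 4")
  X <- cbind(offspring = offspring, age = age)
  if (qr(cbind(1, X))$rank < 3) stop_arg("collinear covariates")
  fit <- lm(response ~ offspring + age)
  s <- summary(fit)$coefficients
  data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
             p = s[, 4], row.names = NULL, stringsAsFactors = FALSE)
}
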