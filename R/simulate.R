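# Synthetic-data generators. Every input the pipeline consumes can be
# produced here with known ground truth, so all downstream stages are
# testable without animal data. Generators are pure functions of
# (parameters, seed).

with_seed <- function(seed, code) {
  seed <- check_count(seed, "seed", min = 0L)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Offspring counts: Poisson(lambda) capped at `cap`, emulating the spread of
# live offspring per queen observed in captive colonies.
draw_offspring <- function(n, lambda = 3, cap = 12) {
  pmin(rpois(n, lambda), cap)
}

#' Simulate a sib-family pedigree with SNP genotypes
#'
#' Each family consists of two unrelated founder parents and
#' `sibs_per_family` full-sib offspring. Founder genotypes are drawn
#' binomial(2, p) per SNP with allele frequency p uniform over `maf_range`;
#' offspring inherit one allele from each parent (Mendelian transmission).
#'
#' @param n_families number of independent families.
#' @param sibs_per_family full sibs per family.
#' @param n_snps number of biallelic SNPs.
#' @param maf_range allele-frequency interval in (0, 0.5].
#' @param missing_rate fraction of genotype calls set to missing.
#' @param n_chrom number of chromosomes SNPs are scattered over.
#' @param seed integer seed.
#' @return list with `pedigree` (individuals, parent map, family), a
#'   genotype object (`dosage` SNPs x individuals, `chrom`, `pos`,
#'   `biallelic`) and `truth` (allele frequencies).
#' @export
simulate_pedigree_genotypes <- function(n_families, sibs_per_family,
                                        n_snps, maf_range = c(0.1, 0.5),
                                        missing_rate = 0, n_chrom = 10,
                                        seed = 1) {
  n_families <- check_count(n_families, "n_families")
  sibs_per_family <- check_count(sibs_per_family, "sibs_per_family")
  n_snps <- check_count(n_snps, "n_snps")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop_arg("maf_range must lie within (0, 0.5]")
  with_seed(seed, {
    p <- runif(n_snps, maf_range[1], maf_range[2])
    fam <- rep(seq_len(n_families), each = 2 + sibs_per_family)
    role <- rep(c("S", "D", paste0("C", seq_len(sibs_per_family))),
                n_families)
    ids <- paste0("F", fam, role)
    m <- length(ids)
    dosage <- matrix(NA_real_, n_snps, m, dimnames = list(
      paste0("snp", seq_len(n_snps)), ids))
    parent_of <- setNames(vector("list", m), ids)
    for (f in seq_len(n_families)) {
      sire <- paste0("F", f, "S"); dam <- paste0("F", f, "D")
      gs <- rbinom(n_snps, 2, p); gd <- rbinom(n_snps, 2, p)
      dosage[, sire] <- gs
      dosage[, dam] <- gd
      parent_of[[sire]] <- c(NA_character_, NA_character_)
      parent_of[[dam]] <- c(NA_character_, NA_character_)
      transmit <- function(g) ifelse(g == 0, 0, ifelse(g == 2, 1,
                                                       rbinom(n_snps, 1, 0.5)))
      for (s in seq_len(sibs_per_family)) {
        kid <- paste0("F", f, "C", s)
        dosage[, kid] <- transmit(gs) + transmit(gd)
        parent_of[[kid]] <- c(sire, dam)
      }
    }
    if (missing_rate > 0)
      dosage[runif(length(dosage)) < missing_rate] <- NA_real_
    chrom <- sort(sample.int(n_chrom, n_snps, replace = TRUE))
    pos <- integer(n_snps)
    for (ch in unique(chrom)) {
      k <- chrom == ch
      pos[k] <- sort(sample.int(2e8, sum(k)))
    }
    o <- order(chrom, pos)
    list(pedigree = list(individuals = ids,
                         parents = parent_of,
                         family = setNames(paste0("F", fam), ids)),
         genotypes = list(dosage = dosage[o, , drop = FALSE],
                          chrom = as.character(chrom[o]), pos = pos[o],
                          biallelic = rep(TRUE, n_snps)),
         truth = list(allele_freq = p[o], maf_range = maf_range,
                      missing_rate = missing_rate, seed = seed))
  })
}

#' Expected additive relatedness from a pedigree
#'
#' Tabular-method additive relationship matrix: founders are unrelated
#' (off-diagonal 0, diagonal 1) and full sibs have expected relatedness 0.5.
#'
#' @param pedigree pedigree list as produced by
#'   [simulate_pedigree_genotypes()].
#' @return symmetric relatedness matrix over all pedigree individuals.
#' @export
pedigree_kinship <- function(pedigree) {
  ids <- pedigree$individuals
  m <- length(ids)
  A <- matrix(0, m, m, dimnames = list(ids, ids))
  # individuals are listed parents-first within family, so a single pass works
  for (i in seq_len(m)) {
    par <- pedigree$parents[[ids[i]]]
    par <- par[!is.na(par)]
    pi_ <- match(par, ids)
    A[i, i] <- if (length(pi_) == 2) 1 + 0.5 * A[pi_[1], pi_[2]] else 1
    js <- seq_len(i - 1L)
    if (length(js) && length(pi_))
      A[i, js] <- A[js, i] <- 0.5 * colSums(A[pi_, js, drop = FALSE])
  }
  A
}

#' Build a bone-culture expression design table
#'
#' One row per RNA-seq sample: animal x bone type (long bone or lumbar
#' vertebra) x estradiol treatment, with days in culture, natal colony and
#' proportion of uniquely mapped reads as nuisance covariates.
#'
#' @param animals data.frame with columns `animal`, `status` (0/1 queen) and
#'   optionally `colony`.
#' @param n_samples optionally subsample to this many rows (keeps at least
#'   one sample per animal).
#' @param seed integer seed.
#' @return design data.frame.
#' @export
sim_expression_design <- function(animals, n_samples = NULL, seed = 1) {
  with_seed(seed, {
    d <- expand.grid(animal = animals$animal, bone = c("long", "LV"),
                     estradiol = c(0L, 1L), stringsAsFactors = FALSE)
    d$status <- animals$status[match(d$animal, animals$animal)]
    d$colony <- if (!is.null(animals$colony))
      animals$colony[match(d$animal, animals$animal)] else "colonyA"
    d$days <- round(runif(nrow(d), 2, 9))
    d$prop_mapped <- runif(nrow(d), 0.6, 0.9)
    if (!is.null(n_samples) && n_samples < nrow(d))
      d <- d[sort(sample.int(nrow(d), n_samples)), ]
    d$sample <- paste0("s", seq_len(nrow(d)))
    rownames(d) <- NULL
    d[, c("sample", "animal", "bone", "status", "estradiol", "days",
          "colony", "prop_mapped")]
  })
}

#' Ground-truth parameters for the expression generator
#'
#' Per-gene log2-scale effect sizes for the fixed effects of the expression
#' model, variance components, negative-binomial dispersions (log-normal,
#' mu = -1.5, sigma = 0.5 on the log scale) and gene lengths.
#'
#' @param n_genes total genes.
#' @param n_de genes given a nonzero queen effect in long bone.
#' @param effect_size log2 fold change injected into the `n_de` genes.
#' @param sigma_u2,sigma_e2 animal-level (kinship) and residual variance on
#'   the log2 scale.
#' @param seed integer seed.
#' @return truth list consumed by [simulate_counts()].
#' @export
sim_expression_truth <- function(n_genes, n_de = 0, effect_size = 1,
                                 sigma_u2 = 0.1, sigma_e2 = 0.2, seed = 1) {
  n_genes <- check_count(n_genes, "n_genes")
  with_seed(seed, {
    de <- rep(0, n_genes)
    if (n_de > 0) de[seq_len(n_de)] <- effect_size
    list(genes = paste0("g", seq_len(n_genes)),
         baseline_log2 = runif(n_genes, 3, 9),
         beta_days = rnorm(n_genes, 0, 0.02),
         beta_bone = rnorm(n_genes, 0, 0.5),
         beta_status_long = de,
         beta_status_lv = rep(0, n_genes),
         beta_estradiol_long = rep(0, n_genes),
         beta_estradiol_lv = rep(0, n_genes),
         dispersion = exp(rnorm(n_genes, -1.5, 0.5)),
         gene_length = round(runif(n_genes, 500, 5000)),
         sigma_u2 = sigma_u2, sigma_e2 = sigma_e2, seed = seed)
  })
}

#' Simulate RNA-seq counts under the kinship mixed model
#'
#' Per gene, the log2 mean follows the expression model's fixed effects with
#' the truth's coefficients, plus an animal-level random effect drawn
#' MVN(0, sigma_u^2 K) and i.i.d. residual noise; counts are drawn
#' negative-binomial with per-gene dispersion, and library sizes vary
#' log-normally across samples.
#'
#' @param design design table from [sim_expression_design()].
#' @param truth truth list from [sim_expression_truth()].
#' @param kinship relatedness matrix whose rows cover every design animal.
#' @param lib_size_meanlog,lib_size_sdlog log-normal library-size factors.
#' @param seed integer seed.
#' @return list with `counts` (genes x samples), `lengths`, `design`,
#'   `truth`.
#' @export
simulate_counts <- function(design, truth, kinship,
                            lib_size_meanlog = 0, lib_size_sdlog = 0.3,
                            seed = 1) {
  missing <- setdiff(unique(design$animal), rownames(kinship))
  if (length(missing))
    stop_arg("design animals missing from kinship: ",
             paste(missing, collapse = ", "))
  G <- length(truth$genes)
  n <- nrow(design)
  with_seed(seed, {
    animals <- unique(design$animal)
    K <- kinship[animals, animals, drop = FALSE]
    L <- t(chol(K + diag(1e-8, nrow(K))))
    U <- L %*% matrix(rnorm(nrow(K) * G), nrow(K), G) * sqrt(truth$sigma_u2)
    Z <- incidence_matrix(design$animal, animals)
    is_lv <- as.numeric(design$bone == "LV")
    eta <- outer(truth$baseline_log2, rep(1, n)) +
      outer(truth$beta_days, design$days) +
      outer(truth$beta_bone, is_lv) +
      outer(truth$beta_status_long, design$status * (1 - is_lv)) +
      outer(truth$beta_status_lv, design$status * is_lv) +
      outer(truth$beta_estradiol_long, design$estradiol * (1 - is_lv)) +
      outer(truth$beta_estradiol_lv, design$estradiol * is_lv) +
      t(Z %*% U) +
      matrix(rnorm(G * n, 0, sqrt(truth$sigma_e2)), G, n)
    sf <- rlnorm(n, lib_size_meanlog, lib_size_sdlog)
    mu <- 2^eta * rep(sf, each = G)
    counts <- matrix(rnbinom(G * n, mu = mu,
                             size = rep(1 / truth$dispersion, n)), G, n,
                     dimnames = list(truth$genes, design$sample))
    list(counts = counts, lengths = setNames(truth$gene_length, truth$genes),
         design = design, truth = truth)
  })
}

#' Simulate elongated-vs-round labelled meshes
#'
#' Class "queen" meshes are level-3 icospheres stretched by `elongation`
#' along the z axis; class "nonbreeder" meshes are unstretched. Independent
#' Gaussian jitter of sd `noise_sd` is added to every vertex coordinate.
#' Jitter large enough to invert faces is not checked for.
#'
#' @param n_per_class meshes per class.
#' @param elongation stretch factor >= 1 along one axis.
#' @param noise_sd vertex jitter standard deviation (mesh length units).
#' @param level icosphere subdivision level of the base shape.
#' @param seed integer seed.
#' @return list with `meshes` (list of `triangle_mesh`) and `labels`
#'   (factor, "queen"/"nonbreeder").
#' @export
simulate_meshes <- function(n_per_class, elongation = 1.3, noise_sd = 0.02,
                            level = 3, seed = 1) {
  n_per_class <- check_count(n_per_class, "n_per_class")
  if (elongation < 1) stop_arg("elongation must be >= 1")
  base <- icosphere(level)
  with_seed(seed, {
    make <- function(stretch) {
      v <- base$vertices
      v[, 3] <- v[, 3] * stretch
      v <- v + matrix(rnorm(length(v), 0, noise_sd), nrow(v), 3)
      triangle_mesh(v, base$faces)
    }
    meshes <- c(replicate(n_per_class, make(elongation), simplify = FALSE),
                replicate(n_per_class, make(1), simplify = FALSE))
    labels <- factor(rep(c("queen", "nonbreeder"), each = n_per_class),
                     levels = c("nonbreeder", "queen"))
    list(meshes = meshes, labels = labels)
  })
}

#' Default ground-truth parameters for sections and morphometrics
#'
#' Radii are in mm; the per-pup endosteal expansion mirrors marrow-cavity
#' enlargement at fixed periosteal area in parous queens.
#'
#' @param periosteal_radius_mm mean outer (periosteal) radius.
#' @param endosteal_radius_mm mean inner (endosteal) radius of nulliparous
#'   animals.
#' @param endosteal_per_pup_mm endosteal radius increase per offspring in
#'   queens.
#' @param radius_sd_mm between-animal radius variation.
#' @param pixel_mm raster pixel size.
#' @param offspring_lambda Poisson mean of queen offspring counts (capped
#'   at 12).
#' @param lv5_baseline_mm,lv5_growth_mm_per_month,lv5_interaction_mm_per_month
#'   longitudinal LV5 parameters; the queen-by-time interaction acts in the
#'   first inter-x-ray interval only.
#' @param lv5_noise_sd_mm,lv5_animal_sd_mm residual and animal-level LV5 sd.
#' @param litter_intercept,litter_slope_per_cm,litter_first_effect,litter_sd,litter_mother_sd
#'   litter-size model parameters (slope per cm of maternal body length).
#' @param pup_mass_intercept,pup_mass_slope_per_cm,pup_mass_litter_effect,pup_mass_first_effect,pup_mass_sd,pup_mass_litter_sd
#'   pup-mass model parameters.
#' @param fusion_slope_per_pup,columns_slope_per_pup,gp_age_effect,gp_noise_sd
#'   growth-plate model parameters.
#' @return named list of ground-truth parameters.
#' @export
sim_morpho_params <- function(periosteal_radius_mm = 1.0,
                              endosteal_radius_mm = 0.55,
                              endosteal_per_pup_mm = 0.02,
                              radius_sd_mm = 0.03,
                              pixel_mm = 0.02,
                              offspring_lambda = 3,
                              lv5_baseline_mm = 4.0,
                              lv5_growth_mm_per_month = 0.02,
                              lv5_interaction_mm_per_month = 0.08,
                              lv5_noise_sd_mm = 0.06,
                              lv5_animal_sd_mm = 0.15,
                              litter_intercept = 0.1,
                              litter_slope_per_cm = 0.35,
                              litter_first_effect = -0.5,
                              litter_sd = 1.3,
                              litter_mother_sd = 0.5,
                              pup_mass_intercept = 5,
                              pup_mass_slope_per_cm = 0.29,
                              pup_mass_litter_effect = -0.15,
                              pup_mass_first_effect = -0.2,
                              pup_mass_sd = 0.6,
                              pup_mass_litter_sd = 0.3,
                              fusion_slope_per_pup = 0.05,
                              columns_slope_per_pup = -0.132,
                              gp_age_effect = 0.005,
                              gp_noise_sd = 0.08) {
  as.list(environment())
}

# Rasterize an annulus (outer radius R, inner radius r, mm) on a pixel grid.
annulus_image <- function(R_mm, r_mm, pixel_mm, pad = 1.15) {
  if (r_mm >= R_mm) stop_arg("endosteal radius must be smaller than periosteal")
  half <- ceiling(R_mm * pad / pixel_mm)
  ax <- (seq(-half, half) ) * pixel_mm
  d2 <- outer(ax^2, ax^2, "+")
  img <- (d2 <= R_mm^2 & d2 > r_mm^2) + 0L
  img
}

#' Simulate femoral cross-sections and morphometric tables
#'
#' Generates, with known ground truth: annular midshaft section images in
#' which queens' endosteal radius grows with offspring count at fixed
#' periosteal radius; a paired longitudinal LV5 table whose queen-by-time
#' interaction acts in the first interval only; a litter table with litter
#' size increasing in maternal body length; and a growth-plate table.
#'
#' @param n_animals number of animals (split half queens, half nonbreeders,
#'   paired as littermates).
#' @param params parameter list from [sim_morpho_params()].
#' @param n_litters rows of the litter table.
#' @param n_growth_plate rows of the growth-plate table.
#' @param time_points months post-pairing at which LV5 is measured.
#' @param seed integer seed.
#' @return list with `animals`, `sections` (list of section images),
#'   `lv5_long` (longitudinal table), `litters`, `pups`, `growth_plate`,
#'   `params`.
#' @export
simulate_sections_and_morpho <- function(n_animals = 18,
                                         params = sim_morpho_params(),
                                         n_litters = 100,
                                         n_growth_plate = 12,
                                         time_points = c(0, 4, 8, 12),
                                         seed = 1) {
  n_animals <- check_count(n_animals, "n_animals", min = 2L)
  p <- params
  with_seed(seed, {
    n_q <- floor(n_animals / 2)
    animals <- data.frame(
      animal = paste0("A", seq_len(n_animals)),
      status = rep(c(1L, 0L), length.out = n_animals),
      pair = paste0("P", ceiling(seq_len(n_animals) / 2)),
      stringsAsFactors = FALSE)
    animals$offspring <- ifelse(animals$status == 1L,
                                draw_offspring(n_animals, p$offspring_lambda),
                                0L)
    R <- rnorm(n_animals, p$periosteal_radius_mm, p$radius_sd_mm)
    r <- p$endosteal_radius_mm +
      animals$status * animals$offspring * p$endosteal_per_pup_mm +
      rnorm(n_animals, 0, p$radius_sd_mm / 2)
    r <- pmin(r, R - 5 * p$pixel_mm)
    sections <- lapply(seq_len(n_animals), function(i)
      list(img = annulus_image(R[i], r[i], p$pixel_mm),
           pixel_mm = p$pixel_mm))
    names(sections) <- animals$animal

    u_animal <- rnorm(n_animals, 0, p$lv5_animal_sd_mm)
    lv5 <- do.call(rbind, lapply(seq_len(n_animals), function(i) {
      t <- time_points
      first_growth <- pmin(t, time_points[2])  # months inside first interval
      mu <- p$lv5_baseline_mm + p$lv5_growth_mm_per_month * t +
        animals$status[i] * p$lv5_interaction_mm_per_month * first_growth +
        u_animal[i]
      data.frame(animal = animals$animal[i], status = animals$status[i],
                 month = t, lv5_mm = mu + rnorm(length(t), 0, p$lv5_noise_sd_mm),
                 stringsAsFactors = FALSE)
    }))

    n_mothers <- max(2L, round(n_litters / 4))
    mother <- paste0("M", sample.int(n_mothers, n_litters, replace = TRUE))
    mother_len <- setNames(rnorm(n_mothers, 14, 1),
                           paste0("M", seq_len(n_mothers)))
    u_mother <- setNames(rnorm(n_mothers, 0, p$litter_mother_sd),
                         names(mother_len))
    first <- as.integer(!duplicated(mother))
    size_raw <- p$litter_intercept + p$litter_slope_per_cm * mother_len[mother] +
      p$litter_first_effect * first + u_mother[mother] +
      rnorm(n_litters, 0, p$litter_sd)
    litters <- data.frame(litter = paste0("L", seq_len(n_litters)),
                          mother = mother,
                          mother_length_cm = unname(mother_len[mother]),
                          first_litter = first,
                          litter_size = pmax(1L, round(size_raw)),
                          stringsAsFactors = FALSE)
    u_litter <- rnorm(n_litters, 0, p$pup_mass_litter_sd)
    pups <- do.call(rbind, lapply(seq_len(n_litters), function(i) {
      k <- litters$litter_size[i]
      data.frame(litter = litters$litter[i], mother = litters$mother[i],
                 mother_length_cm = litters$mother_length_cm[i],
                 first_litter = litters$first_litter[i],
                 litter_size = k,
                 pup_mass_g = p$pup_mass_intercept +
                   p$pup_mass_slope_per_cm * litters$mother_length_cm[i] +
                   p$pup_mass_litter_effect * k +
                   p$pup_mass_first_effect * litters$first_litter[i] +
                   u_litter[i] + rnorm(k, 0, p$pup_mass_sd),
                 stringsAsFactors = FALSE)
    }))

    gp_off <- draw_offspring(n_growth_plate, p$offspring_lambda)
    gp_age <- runif(n_growth_plate, 24, 40)
    growth_plate <- data.frame(
      animal = paste0("GP", seq_len(n_growth_plate)),
      offspring = gp_off, age_months = gp_age,
      fusion = pmin(1, pmax(0, 0.2 + p$fusion_slope_per_pup * gp_off +
                              p$gp_age_effect * gp_age +
                              rnorm(n_growth_plate, 0, p$gp_noise_sd))),
      columns_per_mm = pmax(0, 4 + p$columns_slope_per_pup * gp_off -
                              0.01 * gp_age +
                              rnorm(n_growth_plate, 0, 0.25)),
      stringsAsFactors = FALSE)

    list(animals = animals, sections = sections, lv5_long = lv5,
         litters = litters, pups = pups, growth_plate = growth_plate,
         params = p,
         truth = list(periosteal_radius_mm = R, endosteal_radius_mm = r,
                      seed = seed))
  })
}

#' Simulate a max-load calibration table
#'
#' Emulates a rodent femur data set in which maximum load (force at
#' mechanical failure in four-point bending) is linear in midshaft cortical
#' area. With defaults (n = 81, noise sd 6.5 N over a 2 mm^2 CA range at
#' slope 30 N/mm^2) the expected R^2 of the fitted line is about 0.88.
#'
#' @param n number of specimens (>= 3).
#' @param slope N per mm^2 of cortical area.
#' @param intercept N.
#' @param noise_sd residual sd in N.
#' @param ca_range cortical-area range sampled uniformly (mm^2).
#' @param seed integer seed.
#' @return data.frame with `ca_mm2`, `max_load_n`; truth in attributes.
#' @export
simulate_calibration <- function(n = 81, slope = 30, intercept = 2,
                                 noise_sd = 6.5, ca_range = c(0.5, 2.5),
                                 seed = 1) {
  n <- check_count(n, "n", min = 3L)
  with_seed(seed, {
    ca <- runif(n, ca_range[1], ca_range[2])
    load <- intercept + slope * ca + rnorm(n, 0, noise_sd)
    out <- data.frame(ca_mm2 = ca, max_load_n = load)
    attr(out, "truth") <- list(slope = slope, intercept = intercept,
                               noise_sd = noise_sd, seed = seed)
    out
  })
}

#' Simulate a cell-type signature matrix and mixtures with known proportions
#'
#' @param n_genes marker genes.
#' @param n_types reference cell types.
#' @param n_samples mixture samples.
#' @param noise_sd relative Gaussian noise added to mixtures.
#' @param seed integer seed.
#' @return list with `signature` (genes x types), `mixture` (genes x
#'   samples) and `proportions` (samples x types, the ground truth).
#' @export
simulate_signature_mixture <- function(n_genes = 500, n_types = 5,
                                       n_samples = 20, noise_sd = 0.05,
                                       seed = 1) {
  with_seed(seed, {
    sig <- matrix(rlnorm(n_genes * n_types, 2, 1), n_genes, n_types,
                  dimnames = list(paste0("g", seq_len(n_genes)),
                                  paste0("type", seq_len(n_types))))
    props <- matrix(rgamma(n_samples * n_types, 1), n_samples, n_types)
    props <- props / rowSums(props)
    rownames(props) <- paste0("s", seq_len(n_samples))
    colnames(props) <- colnames(sig)
    mix <- sig %*% t(props)
    mix <- mix * matrix(pmax(0.01, 1 + rnorm(length(mix), 0, noise_sd)),
                        nrow(mix))
    list(signature = sig, mixture = mix, proportions = props)
  })
}

#' Serialize generator ground truth as JSON
#' @param truth any truth list produced by the simulators.
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
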