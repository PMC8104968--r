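# End-to-end orchestration from a single structured configuration, with a
# run manifest for reproducibility.

.pipeline_schema <- list(
  top = c("seed", "out_dir", "stages", "simulate", "kinship", "de", "ect",
          "bone"),
  simulate = c("n_families", "sibs_per_family", "n_snps", "maf_range",
               "n_genes", "n_de", "effect_size", "sigma_u2", "sigma_e2",
               "n_per_class", "elongation", "mesh_noise_sd", "mesh_level",
               "n_animals", "n_litters", "calibration_n"),
  kinship = c("maf_min", "max_missing", "hwe_p_min", "thin_bp"),
  de = c("n_perm", "min_tpm", "min_frac", "model_spec"),
  ect = c("level", "n_heights", "smooth", "n_perm"),
  bone = c())

#' Default pipeline configuration
#'
#' Problem sizes are chosen so a full default run finishes in minutes on
#' one CPU while every stage still exercises its statistics.
#'
#' @param seed global seed; per-stage seeds are spawned from it.
#' @param out_dir output directory.
#' @return configuration list for [run_pipeline()].
#' @export
default_config <- function(seed = 1, out_dir = tempfile("molequeen_run")) {
  list(seed = seed, out_dir = out_dir,
       stages = c("simulate", "kinship", "de", "ect", "bone"),
       simulate = list(n_families = 6, sibs_per_family = 2, n_snps = 4000,
                       n_genes = 500, n_de = 25, effect_size = 1,
                       sigma_u2 = 0.1, sigma_e2 = 0.2,
                       n_per_class = 8, elongation = 1.3,
                       mesh_noise_sd = 0.02, mesh_level = 3,
                       n_animals = 18, n_litters = 100, calibration_n = 81),
       kinship = list(maf_min = 0.1, max_missing = 2, hwe_p_min = 0.05,
                      thin_bp = 10000),
       de = list(n_perm = 20, min_tpm = 2, min_frac = 0.25,
                 model_spec = "main"),
       ect = list(level = 2, n_heights = 100, smooth = FALSE, n_perm = 50),
       bone = list())
}

validate_config <- function(config) {
  check_keys <- function(block, allowed, label) {
    unknown <- setdiff(names(block), allowed)
    if (length(unknown))
      stop_arg("unknown configuration key(s) in ", label, ": ",
               paste(unknown, collapse = ", "))
  }
  check_keys(config, .pipeline_schema$top, "top level")
  for (st in c("simulate", "kinship", "de", "ect"))
    if (!is.null(config[[st]]))
      check_keys(config[[st]], .pipeline_schema[[st]], st)
  if (is.null(config$seed)) stop_arg("config needs a global `seed`")
  if (is.null(config$out_dir)) stop_arg("config needs `out_dir`")
  bad <- setdiff(config$stages, c("simulate", "kinship", "de", "ect", "bone"))
  if (length(bad)) stop_arg("unknown stage(s): ", paste(bad, collapse = ", "))
  invisible(config)
}

require_file <- function(path, stage, needed_by) {
  if (!file.exists(path))
    stop_arg("stage '", needed_by, "' needs output of stage '", stage,
             "' (missing: ", basename(path), ")")
  path
}

#' Run the synthetic analysis pipeline end to end
#'
#' Executes the requested stages in dependency order (simulate, kinship,
#' differential expression, shape classification, bone failure hazard),
#' writing each stage's outputs as plain-text files and a JSON manifest
#' with seeds, parameters, checksums and package version. Per-stage seeds
#' are spawned deterministically from the global seed.
#'
#' @param config configuration list (see [default_config()]) or path to a
#'   YAML file with the same structure.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(default_config(seed = config$seed %||% 1),
                              config)
  validate_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  manifest <- list(package = "molequeen",
                   version = as.character(utils::packageVersion("molequeen")),
                   r_version = R.version.string,
                   seed = config$seed, stages = list(), outputs = list())
  seed_of <- function(i) child_seed(config$seed, i)

  paths <- list(vcf = file.path(out, "genotypes.vcf"),
                counts = file.path(out, "counts.tsv"),
                meta = file.path(out, "meta.tsv"),
                lengths = file.path(out, "gene_lengths.tsv"),
                kin_true = file.path(out, "kinship_pedigree.tsv"),
                kinship = file.path(out, "kinship.tsv"),
                de = file.path(out, "de_results.tsv"),
                labels = file.path(out, "mesh_labels.tsv"),
                ect = file.path(out, "ect_features.tsv"),
                ect_report = file.path(out, "ect_report.json"),
                geometry = file.path(out, "section_geometry.tsv"),
                calibration = file.path(out, "calibration.tsv"),
                hazard = file.path(out, "failure_hazard.tsv"),
                km = file.path(out, "km_curves.tsv"),
                truth = file.path(out, "truth.json"))

  if ("simulate" %in% stages) {
    sm <- config$simulate
    sseed <- seed_of(1)
    ped <- simulate_pedigree_genotypes(sm$n_families, sm$sibs_per_family,
                                       sm$n_snps, seed = sseed)
    write_vcf(ped$genotypes, paths$vcf)
    Ktrue <- pedigree_kinship(ped$pedigree)
    write_kinship_tsv(Ktrue, paths$kin_true)
    sibs <- grep("C", ped$pedigree$individuals, value = TRUE)
    animals <- data.frame(animal = sibs,
                          status = rep(c(1L, 0L), length.out = length(sibs)),
                          colony = ped$pedigree$family[sibs],
                          stringsAsFactors = FALSE)
    design <- sim_expression_design(animals, seed = child_seed(sseed, 1))
    truth <- sim_expression_truth(sm$n_genes, n_de = sm$n_de,
                                  effect_size = sm$effect_size,
                                  sigma_u2 = sm$sigma_u2,
                                  sigma_e2 = sm$sigma_e2,
                                  seed = child_seed(sseed, 2))
    cm <- simulate_counts(design, truth, Ktrue, seed = child_seed(sseed, 3))
    write_matrix_tsv(cm$counts, paths$counts, id_col = "gene")
    write_tsv(design, paths$meta)
    write_tsv(data.frame(gene = names(cm$lengths), length = cm$lengths),
              paths$lengths)
    meshes <- simulate_meshes(sm$n_per_class, sm$elongation,
                              sm$mesh_noise_sd, level = sm$mesh_level,
                              seed = child_seed(sseed, 4))
    mesh_dir <- file.path(out, "meshes")
    dir.create(mesh_dir, showWarnings = FALSE)
    mesh_files <- vapply(seq_along(meshes$meshes), function(i) {
      f <- file.path(mesh_dir, sprintf("mesh%03d.off", i))
      write_off(meshes$meshes[[i]], f)
      f
    }, character(1))
    write_tsv(data.frame(file = basename(mesh_files),
                         label = as.character(meshes$labels)), paths$labels)
    morpho <- simulate_sections_and_morpho(sm$n_animals,
                                           n_litters = sm$n_litters,
                                           seed = child_seed(sseed, 5))
    sec_dir <- file.path(out, "sections")
    dir.create(sec_dir, showWarnings = FALSE)
    for (a in names(morpho$sections))
      write_pgm(morpho$sections[[a]]$img,
                file.path(sec_dir, paste0(a, ".pgm")),
                pixel_mm = morpho$sections[[a]]$pixel_mm)
    write_tsv(morpho$animals, file.path(out, "animals.tsv"))
    calib <- simulate_calibration(sm$calibration_n,
                                  seed = child_seed(sseed, 6))
    write_tsv(calib, paths$calibration)
    write_truth_json(list(expression = truth["seed"],
                          n_de = sm$n_de, effect_size = sm$effect_size,
                          seed = sseed), paths$truth)
    manifest$stages$simulate <- list(seed = sseed, params = sm)
  }

  if ("kinship" %in% stages) {
    kc <- config$kinship
    require_file(paths$vcf, "simulate", "kinship")
    g <- read_vcf_dosage(paths$vcf)
    g <- filter_snps(g, maf_min = kc$maf_min, max_missing = kc$max_missing,
                     hwe_p_min = kc$hwe_p_min, thin_bp = kc$thin_bp)
    K <- estimate_kinship(impute_mean(g))
    write_kinship_tsv(K, paths$kinship)
    manifest$stages$kinship <- list(params = kc, n_snps = nrow(g$dosage))
  }

  if ("de" %in% stages) {
    dc <- config$de
    require_file(paths$counts, "simulate", "de")
    require_file(paths$kinship, "kinship", "de")
    counts <- read_matrix_tsv(paths$counts)
    meta <- read_tsv(paths$meta)
    lens <- read_tsv(paths$lengths)
    K <- read_kinship_tsv(paths$kinship)
    dseed <- seed_of(3)
    de <- run_de(counts, setNames(lens$length, lens$gene), meta, K,
                 model_spec = dc$model_spec, n_perm = dc$n_perm,
                 seed = dseed, min_tpm = dc$min_tpm, min_frac = dc$min_frac)
    write_tsv(de$table, paths$de)
    manifest$stages$de <- list(seed = dseed, params = dc,
                               n_genes_tested = nrow(de$table))
  }

  if ("ect" %in% stages) {
    ec <- config$ect
    require_file(paths$labels, "simulate", "ect")
    lab <- read_tsv(paths$labels)
    meshes <- lapply(file.path(out, "meshes", lab$file), read_mesh)
    names(meshes) <- lab$file
    dirs <- generate_directions(ec$level)
    feats <- ect_features(meshes, dirs, n_heights = ec$n_heights,
                          smooth = ec$smooth)
    write_matrix_tsv(feats, paths$ect, id_col = "mesh")
    eseed <- seed_of(4)
    test <- permutation_pvalue(feats, factor(lab$label),
                               n_perm = ec$n_perm, seed = eseed)
    jsonlite::write_json(list(accuracy = test$observed$accuracy,
                              p = test$p, n_perm = test$n_perm,
                              seed = eseed, n_directions = nrow(dirs),
                              feature_length = ncol(feats)),
                         paths$ect_report, auto_unbox = TRUE, digits = NA)
    manifest$stages$ect <- list(seed = eseed, params = ec,
                                accuracy = test$observed$accuracy,
                                p = test$p)
  }

  if ("bone" %in% stages) {
    require_file(file.path(out, "animals.tsv"), "simulate", "bone")
    require_file(paths$calibration, "simulate", "bone")
    animals <- read_tsv(file.path(out, "animals.tsv"))
    geo <- do.call(rbind, lapply(animals$animal, function(a) {
      s <- read_pgm(file.path(out, "sections", paste0(a, ".pgm")))
      g <- section_geometry(s$img, s$pixel_mm)
      data.frame(animal = a, ca = g$ca, ta = g$ta, marrow = g$marrow,
                 ca_ta = g$ca_ta, i_min = g$i_min, j = g$j)
    }))
    write_tsv(geo, paths$geometry)
    calib_tab <- read_tsv(paths$calibration)
    calib <- fit_max_load_calibration(calib_tab$ca_mm2, calib_tab$max_load_n)
    # mole-rat CA scaled onto the calibration's CA range before prediction
    ca <- geo$ca / mean(geo$ca) * mean(calib_tab$ca_mm2)
    frame <- predict_relative_load(calib, ca, animals$status == 0,
                                   group = ifelse(animals$status == 1,
                                                  "queen", "nonbreeder"),
                                   offspring = animals$offspring)
    hz_group <- failure_hazard(frame, "group")
    hz_pup <- failure_hazard(frame, "offspring")
    write_tsv(data.frame(contrast = c("queen_vs_nonbreeder", "per_offspring"),
                         hr = c(hz_group$hr, hz_pup$hr),
                         ci_lo = c(hz_group$ci[1], hz_pup$ci[1]),
                         ci_hi = c(hz_group$ci[2], hz_pup$ci[2]),
                         p = c(hz_group$p, hz_pup$p)), paths$hazard)
    write_tsv(km_table(hz_group), paths$km)
    manifest$stages$bone <- list(calibration_r2 = calib$r_squared,
                                 hr_group = hz_group$hr, hr_pup = hz_pup$hr)
  }

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out, "manifest.json"))
  manifest$outputs <- lapply(setNames(files, sub(paste0(out, "/?"), "",
                                                 files)),
                             function(f) list(md5 = unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
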