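#' Pipeline run configuration
#'
#' Bundles every tunable of a full asymmetry analysis run: cohort simulation
#' parameters (or an input directory of already-written volumes), analysis
#' list, thresholds, and the master seed. All stage seeds are derived from
#' the master seed and recorded in the run manifest, so a rerun with the
#' same config reproduces every numeric output bit-exactly.
#'
#' @param out_dir output directory for reports.
#' @param seed master integer seed.
#' @param cohort named list of overrides for [cohort_config()].
#' @param effects list of `effect_spec` injected into the simulation.
#' @param input_dir optional directory with `phenotype.csv` and
#'   `<SUB_ID>.nii.gz` volumes; when given, simulation is skipped.
#' @param analyses subset of `c("general", "SI", "VA", "RRB")`.
#' @param instrument `"adir"` or `"ados"` score columns for subgrouping.
#' @param voxel_p,cluster_p GRF thresholds (defaults 0.005 and 0.05).
#' @param fwhm_mm AI smoothing kernel FWHM in mm (default 8).
#' @param gm_threshold GM probability cutoff for the hemisphere mask
#'   (default 0.2).
#' @param age_tolerance control-matching age tolerance in years (default 2).
#' @param connectivity cluster connectivity (default 18).
#' @return A validated `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, cohort = list(), effects = list(),
                       input_dir = NULL,
                       analyses = c("general", "SI", "VA", "RRB"),
                       instrument = c("adir", "ados"), voxel_p = 0.005,
                       cluster_p = 0.05, fwhm_mm = 8, gm_threshold = 0.2,
                       age_tolerance = 2, connectivity = 18L) {
  instrument <- match.arg(instrument)
  analyses <- match.arg(analyses, several.ok = TRUE)
  if (voxel_p <= 0 || voxel_p >= 1 || cluster_p <= 0 || cluster_p >= 1) {
    stop("thresholds must lie in (0, 1)")
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), cohort = cohort,
                 effects = effects, input_dir = input_dir,
                 analyses = analyses, instrument = instrument,
                 voxel_p = voxel_p, cluster_p = cluster_p,
                 fwhm_mm = fwhm_mm, gm_threshold = gm_threshold,
                 age_tolerance = age_tolerance,
                 connectivity = as.integer(connectivity)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML file holds the [run_config()] arguments; `cohort:` is passed on
#' to [cohort_config()], and `effects:` is a list of [effect_spec()]
#' argument sets.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$effects)) {
    y$effects <- lapply(y$effects, function(e) do.call(effect_spec, e))
  }
  do.call(run_config, y)
}

instrument_columns <- function(instrument) {
  switch(instrument,
         adir = c("ADI_R_SOCIAL_TOTAL_A", "ADI_R_VERBAL_TOTAL_BV",
                  "ADI_RRB_TOTAL_C"),
         ados = c("ADOS_SOCIAL", "ADOS_COMM", "ADOS_RRB"),
         stop("unknown instrument: ", instrument))
}

#' Load a cohort directory written by [write_cohort()]
#'
#' @param dir directory with `phenotype.csv` and `<SUB_ID>.nii.gz`.
#' @return list with `phenotypes` and `volumes` (named list of `gm_volume`).
#' @export
load_cohort <- function(dir) {
  pheno <- utils::read.csv(file.path(dir, "phenotype.csv"),
                           stringsAsFactors = FALSE)
  vols <- lapply(pheno$SUB_ID, function(id) {
    f <- file.path(dir, paste0(id, ".nii.gz"))
    if (!file.exists(f)) f <- file.path(dir, paste0(id, ".nii"))
    if (!file.exists(f)) stop("missing volume for subject ", id)
    read_nifti(f)
  })
  names(vols) <- pheno$SUB_ID
  list(phenotypes = pheno, volumes = vols)
}

stage_log <- function(run_dir, stage, ...) {
  msg <- sprintf("[%s] %s", stage, sprintf(...))
  message(msg)
  cat(msg, "\n", file = file.path(run_dir, "run.log"), append = TRUE)
}

#' Run the full asymmetry analysis pipeline
#'
#' simulate (or load) -> subgroup + matched controls -> symmetric template,
#' right-hemisphere mask and per-subject AI maps -> per-analysis voxel-wise
#' GLM -> GRF cluster inference -> cluster-restricted brain-behavior and age
#' regressions. Writes, under `config$out_dir`: `phenotype.csv`,
#' `assignments.csv`, `clusters_<analysis>.tsv`, cluster mask volumes,
#' `brain_behavior.tsv`, `run.log`, and `manifest.json` (config hash, seeds,
#' stage counts, package version).
#'
#' @param config a `run_config`.
#' @return Invisibly, a list with the phenotypes, assignments, per-analysis
#'   cluster tables (`clusters`), brain-behavior table, and manifest.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(config$out_dir, "run.log"))

  # -- stage 1: cohort ------------------------------------------------------
  if (is.null(config$input_dir)) {
    cc <- do.call(cohort_config, c(config$cohort, list(seed = config$seed)))
    sim <- simulate_cohort(cc, effects = config$effects)
    pheno <- sim$phenotypes
    volumes <- sim$volumes
    manifest_truth <- sim$manifest
  } else {
    loaded <- load_cohort(config$input_dir)
    pheno <- loaded$phenotypes
    volumes <- loaded$volumes
    manifest_truth <- NULL
  }
  stage_log(config$out_dir, "cohort", "%d subjects (%d cases, %d controls)",
            nrow(pheno), sum(pheno$DX_GROUP == 1L), sum(pheno$DX_GROUP == 2L))
  utils::write.csv(pheno[setdiff(names(pheno), "true_subgroup")],
                   file.path(config$out_dir, "phenotype.csv"),
                   row.names = FALSE)

  # -- stage 2: subgrouping + matching --------------------------------------
  assign <- subgroup_phenotypes(pheno,
                                columns = instrument_columns(config$instrument))
  utils::write.csv(assign, file.path(config$out_dir, "assignments.csv"),
                   row.names = FALSE)
  case_sets <- list()
  for (an in config$analyses) {
    case_sets[[an]] <- if (an == "general") {
      pheno$SUB_ID[pheno$DX_GROUP == 1L]
    } else {
      assign$subject_id[assign$label == an]
    }
  }
  td_pool <- pheno[pheno$DX_GROUP == 2L, , drop = FALSE]
  matches <- match_controls(pheno[pheno$DX_GROUP == 1L, , drop = FALSE],
                            td_pool, case_sets,
                            age_tolerance = config$age_tolerance,
                            seed = config$seed + 201L)
  stage_log(config$out_dir, "subgroup",
            "labels: %s; matched controls per analysis: %s",
            paste(names(table(assign$label)), table(assign$label),
                  sep = "=", collapse = " "),
            paste(names(matches), vapply(matches, nrow, integer(1)),
                  sep = "=", collapse = " "))

  # -- stage 3: template, mask, AI maps -------------------------------------
  template <- build_symmetric_template(volumes)
  mask <- make_right_mask(template, config$gm_threshold)
  ai_maps <- lapply(volumes, subject_ai_map, mask = mask,
                    fwhm_mm = config$fwhm_mm)
  stage_log(config$out_dir, "asym", "%d mask voxels, %d AI maps",
            sum(mask$data), length(ai_maps))

  # -- stage 4: GLM + GRF per analysis --------------------------------------
  clusters <- list()
  for (an in config$analyses) {
    m <- matches[[an]]
    ids <- c(m$case_id, m$control_id)
    labels <- rep(c("CASE", "TD"), c(nrow(m), nrow(m)))
    recs <- pheno[match(ids, pheno$SUB_ID), , drop = FALSE]
    design <- build_design(recs, labels, case_level = "CASE")
    tm <- fit_glm_voxelwise(ai_maps[ids], design)
    cl <- significant_clusters(tm, voxel_p = config$voxel_p,
                               cluster_p = config$cluster_p,
                               connectivity = config$connectivity)
    clusters[[an]] <- cl
    utils::write.table(as.data.frame(cl),
                       file.path(config$out_dir,
                                 paste0("clusters_", an, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    for (nm in names(attr(cl, "masks"))) {
      write_nifti(gm_volume(array(as.numeric(attr(cl, "masks")[[nm]]),
                                  dim(mask$data)), mask$voxel_size),
                  file.path(config$out_dir,
                            sprintf("mask_%s_%s.nii.gz", an, nm)))
    }
    stage_log(config$out_dir, "glm", "%s: n = %d, df = %d, %d clusters",
              an, nrow(recs), tm$df, nrow(cl))
  }

  # -- stage 5: brain-behavior ----------------------------------------------
  bb <- list()
  if ("general" %in% names(clusters) && nrow(clusters$general) > 0) {
    asd <- pheno[pheno$DX_GROUP == 1L, , drop = FALSE]
    if (any(!is.na(asd$ADOS_SOCIAL)) &&
        stats::sd(asd$ADOS_SOCIAL, na.rm = TRUE) > 0) {
      bb$ados <- run_brain_behavior(clusters$general, ai_maps, asd,
                                    "ADOS_SOCIAL")
    }
    bb$age_asd <- run_brain_behavior(clusters$general, ai_maps, asd,
                                     "AGE_AT_SCAN")
    bb$age_td <- run_brain_behavior(clusters$general, ai_maps, td_pool,
                                    "AGE_AT_SCAN")
  }
  bb_tab <- if (length(bb)) {
    cbind(group = rep(names(bb), vapply(bb, nrow, integer(1))),
          do.call(rbind, bb))
  } else {
    data.frame(group = character(0), cluster = character(0),
               predictor = character(0), n = integer(0), r = numeric(0),
               p = numeric(0))
  }
  utils::write.table(bb_tab, file.path(config$out_dir, "brain_behavior.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  stage_log(config$out_dir, "report", "%d brain-behavior rows", nrow(bb_tab))

  # -- manifest -------------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("asymvbm")),
    config_hash = digest::digest(unclass(config)[setdiff(names(config),
                                                         "out_dir")]),
    seed = config$seed,
    stage_seeds = list(phenotypes = config$seed + 101L,
                       matching = config$seed + 201L),
    n_subjects = nrow(pheno), n_mask_voxels = sum(mask$data),
    n_clusters = lapply(clusters, nrow))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(phenotypes = pheno, assignments = assign,
                 matches = matches, template = template, mask = mask,
                 ai_maps = ai_maps, clusters = clusters,
                 brain_behavior = bb_tab, manifest = manifest,
                 ground_truth = manifest_truth))
}

#' One group comparison, in memory
#'
#' Composes the imaging stages for a single case-control contrast without
#' touching disk: symmetric template, right-hemisphere mask, per-subject AI
#' maps, voxel-wise GLM, and GRF cluster inference.
#'
#' @param volumes named list of subject `gm_volume` objects.
#' @param records phenotype data.frame aligned with `volumes`.
#' @param labels group label per subject (two levels).
#' @param gm_threshold,fwhm_mm,voxel_p,cluster_p,connectivity see
#'   [run_config()].
#' @param case_level passed to [build_design()].
#' @return list with `template`, `mask`, `ai_maps`, `tmap`, `clusters`.
#' @export
analyze_group_difference <- function(volumes, records, labels,
                                     gm_threshold = 0.2, fwhm_mm = 8,
                                     voxel_p = 0.005, cluster_p = 0.05,
                                     connectivity = 18L, case_level = NULL) {
  template <- build_symmetric_template(volumes)
  mask <- make_right_mask(template, gm_threshold)
  ai <- lapply(volumes, subject_ai_map, mask = mask, fwhm_mm = fwhm_mm)
  design <- build_design(records, labels, case_level = case_level)
  tm <- fit_glm_voxelwise(ai, design)
  cl <- significant_clusters(tm, voxel_p = voxel_p, cluster_p = cluster_p,
                             connectivity = connectivity)
  list(template = template, mask = mask, ai_maps = ai, tmap = tm,
       clusters = cl)
}
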