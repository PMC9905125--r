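#' Synthetic multi-site cohort configuration
#'
#' Describes the simulated world: a case-control cohort spread unevenly over
#' several acquisition sites, ages 7-18 with a male-skewed gender mix, cases
#' partitioned into three symptom-dominance subpopulations (social
#' interaction SI, verbal communication VA, restricted repetitive behaviors
#' RRB) in proportions of roughly 146:43:41, and per-subject GM probability
#' volumes on a symmetric 3 mm lattice. Defaults mirror the cohort structure
#' the pipeline is designed for: 230 cases, 274 controls, 8 sites.
#'
#' @param n_asd,n_td numbers of cases and controls.
#' @param n_sites number of acquisition sites (unequal sizes).
#' @param age_range age span in years.
#' @param male_fraction probability of male gender.
#' @param subgroup_proportions length-3 vector (SI, VA, RRB) summing to 1.
#' @param grid_shape voxels per axis; x extent must be even so the midline
#'   falls between voxel columns and flipping is exact.
#' @param voxel_size mm per axis (scalar or length 3).
#' @param seed integer master seed; every stage derives its stream from it.
#' @param site_weights optional unnormalized site-size weights.
#' @param ados_fraction fraction of cases carrying ADOS scores.
#' @param adir_max instrument maxima used to normalize the three ADI-R
#'   subscales (social 0-30, verbal 0-26, RRB 0-12 by default).
#' @param noise_sd per-voxel sd of the smooth subject noise field.
#' @param noise_fwhm FWHM (mm) of the noise field's spatial correlation.
#' @param site_bias_sd per-voxel sd of the smooth per-site bias field.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_asd = 230, n_td = 274, n_sites = 8,
                          age_range = c(7, 18), male_fraction = 0.85,
                          subgroup_proportions = c(146, 43, 41) / 230,
                          grid_shape = c(48, 56, 48), voxel_size = 3,
                          seed = 1L, site_weights = NULL,
                          ados_fraction = 129 / 230,
                          adir_max = c(social = 30, verbal = 26, rrb = 12),
                          noise_sd = 0.02, noise_fwhm = 6,
                          site_bias_sd = 0.005) {
  p <- as.numeric(subgroup_proportions)
  if (length(p) != 3L || any(p < 0) || any(p > 1) ||
      abs(sum(p) - 1) > 1e-9) {
    stop("`subgroup_proportions` must be 3 values in [0,1] summing to 1")
  }
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 4L)) {
    stop("`grid_shape` must be 3 integers >= 4")
  }
  if (grid_shape[1] %% 2L != 0L) {
    stop("x extent must be even so the midline lies between voxel columns")
  }
  if (length(age_range) != 2L || age_range[1] <= 0 ||
      age_range[2] <= age_range[1]) {
    stop("invalid `age_range`")
  }
  if (is.null(site_weights)) {
    # unequal site sizes patterned on a typical aggregated consortium
    canonical <- c(56, 52, 65, 14, 7, 14, 9, 13)
    site_weights <- if (n_sites == 8L) canonical
                    else 0.6^(seq_len(n_sites) - 1)
  }
  if (length(site_weights) != n_sites || any(site_weights <= 0)) {
    stop("`site_weights` must be ", n_sites, " positive numbers")
  }
  voxel_size <- rep(as.numeric(voxel_size), length.out = 3L)
  structure(list(
    n_asd = as.integer(n_asd), n_td = as.integer(n_td),
    n_sites = as.integer(n_sites), age_range = as.numeric(age_range),
    male_fraction = male_fraction, subgroup_proportions = p,
    grid_shape = grid_shape, voxel_size = voxel_size,
    seed = as.integer(seed),
    site_weights = site_weights / sum(site_weights),
    ados_fraction = ados_fraction, adir_max = adir_max,
    noise_sd = noise_sd, noise_fwhm = noise_fwhm,
    site_bias_sd = site_bias_sd
  ), class = "cohort_config")
}

#' Localized asymmetry effect specification
#'
#' One spherical region in which a subpopulation's GM is scaled on one
#' hemisphere, creating a known asymmetry. `delta` is the fractional GM
#' change: scaling the right-side region by (1 + delta) while the left
#' homologue is untouched produces an expected asymmetry index of
#' 2*delta / (2 + delta) (positive = rightward). `side = "left"` applies the
#' scaling to the mirrored region instead, yielding the negated AI. Optional
#' per-year drift (`age_slope`, AI units/year about the cohort age center),
#' between-subject variation (`subject_sd`, AI units), and a coupling that
#' generates a symptom score with a target partial correlation to the
#' region's latent AI.
#'
#' @param region_center world mm coordinates (x > 0; mirrored internally for
#'   left-sided effects).
#' @param region_radius sphere radius in mm (> voxel size).
#' @param delta fractional GM amplitude change, |delta| < 1.
#' @param side `"right"` or `"left"`.
#' @param target which subpopulation carries the effect:
#'   `"general_ASD"`, `"SI"`, `"VA"`, or `"RRB"`.
#' @param age_slope AI units per year (default 0).
#' @param subject_sd between-subject latent AI sd (default 0.05).
#' @param behavior_coupling `NULL`, or `list(score = "ADOS_SOCIAL", r = -0.19)`
#'   giving the symptom column to couple and the target partial correlation.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(region_center, region_radius, delta,
                        side = c("right", "left"),
                        target = c("general_ASD", "SI", "VA", "RRB"),
                        age_slope = 0, subject_sd = 0.05,
                        behavior_coupling = NULL) {
  side <- match.arg(side)
  target <- match.arg(target)
  if (abs(delta) >= 1) stop("|delta| must be < 1")
  if (length(region_center) != 3L) stop("`region_center` must be length 3")
  structure(list(region_center = as.numeric(region_center),
                 region_radius = as.numeric(region_radius), delta = delta,
                 side = side, target = target, age_slope = age_slope,
                 subject_sd = subject_sd,
                 behavior_coupling = behavior_coupling),
            class = "effect_spec")
}

# expected AI from a fractional GM change delta on one side
delta_to_ai <- function(delta) 2 * delta / (2 + delta)

# multiplier that realizes latent AI `a` against an untouched homologue
ai_to_multiplier <- function(a) (2 + a) / (2 - a)

#' Default blob layout for the synthetic template
#'
#' Gaussian blob centers expressed as fractions of the half-grid so the
#' layout scales with `grid_shape`; placed in the right hemisphere and
#' mirrored by [generate_template()]. Amplitudes are chosen so the summed
#' (overlapping) field peaks near 0.83, well below 1: a saturated template
#' would censor the additive noise at the clip boundary and distort the
#' per-voxel error distribution the GLM assumes.
#'
#' @param config a `cohort_config`.
#' @return data.frame with columns cx, cy, cz (mm), amp, sigma (mm).
#' @export
default_blob_spec <- function(config) {
  half <- config$grid_shape * config$voxel_size / 2
  f <- rbind(
    c(0.30,  0.15,  0.12, 0.60, 0.22),
    c(0.34, -0.44,  0.08, 0.56, 0.20),
    c(0.21, -0.22,  0.17, 0.54, 0.15),
    c(0.46,  0.30, -0.17, 0.49, 0.14),
    c(0.38, -0.65,  0.46, 0.53, 0.16))
  data.frame(cx = f[, 1] * half[1], cy = f[, 2] * half[2],
             cz = f[, 3] * half[3], amp = f[, 4], sigma = f[, 5] * half[1])
}

#' Default injected effect: a rightward asymmetry in the deep "thalamus" blob
#'
#' @param config a `cohort_config`.
#' @param delta fractional GM change (default 0.15).
#' @param ... further arguments to [effect_spec()].
#' @return An `effect_spec` centered on the third default blob.
#' @export
default_effect <- function(config, delta = 0.15, ...) {
  b <- default_blob_spec(config)[3, ]
  effect_spec(region_center = c(b$cx, b$cy, b$cz),
              region_radius = 4 * config$voxel_size[1], delta = delta, ...)
}

#' Generate the multi-site phenotype table
#'
#' Cases receive integer ADI-R subscale scores rejection-sampled so that the
#' intended dominance label is the strict maximum after normalization by the
#' instrument maxima (no ties by construction); a configurable subset of
#' cases carries ADOS_SOCIAL; controls carry no ADI-R scores. Sites are
#' assigned with unequal probabilities; ages are drawn from a truncated
#' normal (mean 12.3, sd 2.6) over `age_range`.
#'
#' @param config a `cohort_config`.
#' @return data.frame with columns SUB_ID, SITE_ID, DX_GROUP (1 = case,
#'   2 = control), AGE_AT_SCAN, SEX (1 = male, 2 = female),
#'   ADI_R_SOCIAL_TOTAL_A, ADI_R_VERBAL_TOTAL_BV, ADI_RRB_TOTAL_C,
#'   ADOS_SOCIAL, and the ground-truth column true_subgroup (NA for
#'   controls; dropped when the table is written as phenotype.csv).
#' @export
generate_phenotypes <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed + 101L, {
    n <- config$n_asd + config$n_td
    dx <- rep(c(1L, 2L), c(config$n_asd, config$n_td))
    site <- sample(sprintf("SITE%02d", seq_len(config$n_sites)), n,
                   replace = TRUE, prob = config$site_weights)
    age <- truncnorm(n, 12.3, 2.6, config$age_range[1], config$age_range[2])
    sex <- ifelse(stats::runif(n) < config$male_fraction, 1L, 2L)

    labels <- c("SI", "VA", "RRB")
    true_sub <- rep(NA_character_, n)
    adir <- matrix(NA_integer_, n, 3)
    if (config$n_asd > 0) {
      intended <- sample(labels, config$n_asd, replace = TRUE,
                         prob = config$subgroup_proportions)
      true_sub[seq_len(config$n_asd)] <- intended
      mx <- as.numeric(config$adir_max)
      lo <- c(8L, 6L, 1L)   # plausible symptomatic floors per subscale
      for (i in seq_len(config$n_asd)) {
        want <- match(intended[i], labels)
        ok <- FALSE
        for (try in seq_len(10000L)) {
          x <- c(sample(lo[1]:mx[1], 1L), sample(lo[2]:mx[2], 1L),
                 sample(lo[3]:mx[3], 1L))
          z <- x / mx
          if (which.max(z) == want && sum(z == max(z)) == 1L) {
            ok <- TRUE
            break
          }
        }
        if (!ok) stop("could not sample tie-free ADI-R scores for label ",
                      intended[i])
        adir[i, ] <- x
      }
    }

    ados <- rep(NA_integer_, n)
    if (config$n_asd > 0 && config$ados_fraction > 0) {
      n_ados <- round(config$ados_fraction * config$n_asd)
      who <- sample(seq_len(config$n_asd), n_ados)
      ados[who] <- sample(4:14, n_ados, replace = TRUE)
    }

    data.frame(
      SUB_ID = sprintf("S%04d", seq_len(n)), SITE_ID = site, DX_GROUP = dx,
      AGE_AT_SCAN = round(age, 2), SEX = sex,
      ADI_R_SOCIAL_TOTAL_A = adir[, 1], ADI_R_VERBAL_TOTAL_BV = adir[, 2],
      ADI_RRB_TOTAL_C = adir[, 3], ADOS_SOCIAL = ados,
      true_subgroup = true_sub, stringsAsFactors = FALSE)
  })
}

truncnorm <- function(n, mean, sd, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Generate the symmetric synthetic GM template
#'
#' Sum of 3-D Gaussian blobs, each added together with its exact mirror
#' across the mid-sagittal plane, clipped to `[0, 1]`. Because the voxel x
#' coordinates are symmetric about 0, the result equals its own left-right
#' flip bit-exactly.
#'
#' @param config a `cohort_config`.
#' @param blob_spec data.frame(cx, cy, cz, amp, sigma) with centers given for
#'   one hemisphere (or the midline); defaults to [default_blob_spec()].
#' @return A symmetric `gm_volume`.
#' @export
generate_template <- function(config, blob_spec = default_blob_spec(config)) {
  half <- config$grid_shape * config$voxel_size / 2
  vol <- gm_volume(array(0, config$grid_shape), config$voxel_size)
  if (is.null(blob_spec) || nrow(blob_spec) == 0L) return(vol)
  xs <- axis_world(vol, 1); ys <- axis_world(vol, 2); zs <- axis_world(vol, 3)
  acc <- vol$data
  for (i in seq_len(nrow(blob_spec))) {
    b <- blob_spec[i, ]
    if (abs(b$cx) > half[1] || abs(b$cy) > half[2] || abs(b$cz) > half[3]) {
      stop("blob center outside the grid: (", b$cx, ", ", b$cy, ", ", b$cz, ")")
    }
    gy <- exp(-(ys - b$cy)^2 / (2 * b$sigma^2))
    gz <- exp(-(zs - b$cz)^2 / (2 * b$sigma^2))
    # sum each blob with its mirror BEFORE accumulating: the pair is bitwise
    # flip-symmetric (fp addition is commutative), so the template stays
    # bit-exactly symmetric for any number of blobs
    pair <- array(0, config$grid_shape)
    for (cx in unique(c(b$cx, -b$cx))) {
      gx <- exp(-(xs - cx)^2 / (2 * b$sigma^2))
      pair <- pair + b$amp * (gx %o% gy %o% gz)
    }
    acc <- acc + pair
  }
  vol$data <- pmin(acc, 1)
  vol
}

# logical sphere on one side of the midline
effect_region_mask <- function(vol, effect) {
  ctr <- effect$region_center
  if (effect$side == "left") ctr[1] <- -abs(ctr[1])
  xs <- axis_world(vol, 1); ys <- axis_world(vol, 2); zs <- axis_world(vol, 3)
  d2 <- outer(outer((xs - ctr[1])^2, (ys - ctr[2])^2, "+"), (zs - ctr[3])^2,
              "+")
  inside <- d2 <= effect$region_radius^2
  if (effect$side == "left") inside[xs > 0, , ] <- FALSE
  else inside[xs < 0, , ] <- FALSE
  inside
}

effect_applies <- function(effect, record) {
  if (record$DX_GROUP != 1L) return(FALSE)
  effect$target == "general_ASD" ||
    (!is.na(record$true_subgroup) && record$true_subgroup == effect$target)
}

# latent (noise-free) AI a subject expresses in an effect region
latent_effect_ai <- function(effect, record, age_center, subject_dev) {
  base <- delta_to_ai(effect$delta) +
    effect$age_slope * (record$AGE_AT_SCAN - age_center)
  base + subject_dev
}

#' Render one subject's GM volume
#'
#' Starts from the symmetric template, applies each effect carried by the
#' subject (scaling the specified-side spherical region by the multiplier
#' that realizes the subject's latent AI), adds an optional smooth site-bias
#' field and a smooth subject noise field, and clips to `[0, 1]`. With all
#' deltas 0 and no noise the output equals the template exactly.
#'
#' @param template symmetric `gm_volume`.
#' @param record one-row phenotype data.frame.
#' @param effects list of `effect_spec`.
#' @param seed integer seed for the subject's noise and latent deviation.
#' @param noise_sd,noise_fwhm smooth noise amplitude (sd after smoothing)
#'   and spatial correlation FWHM in mm.
#' @param site_field optional precomputed 3-D bias array for this subject's
#'   site (see [simulate_cohort()]).
#' @param age_center age about which `age_slope` pivots (default 12.5).
#' @return A `gm_volume` with an extra `latent` field: the named vector of
#'   latent AI values, one per effect (0 for effects the subject does not
#'   carry).
#' @export
generate_subject_volume <- function(template, record, effects, seed,
                                    noise_sd = 0.02, noise_fwhm = 6,
                                    site_field = NULL, age_center = 12.5) {
  out <- template
  dat <- template$data
  latent <- numeric(length(effects))
  names(latent) <- vapply(seq_along(effects), function(i)
    paste0("effect", i), character(1))
  with_seed(seed, {
    for (i in seq_along(effects)) {
      ef <- effects[[i]]
      dev <- if (ef$subject_sd > 0) stats::rnorm(1, 0, ef$subject_sd) else 0
      if (!effect_applies(ef, record)) next
      a <- latent_effect_ai(ef, record, age_center, dev)
      latent[i] <- a
      if (a != 0) {
        m <- ai_to_multiplier(a)
        reg <- effect_region_mask(template, ef)
        dat[reg] <- dat[reg] * m
      }
    }
    if (!is.null(site_field)) dat <- dat + site_field
    if (noise_sd > 0) {
      raw_sd <- noise_sd / sqrt(smooth_var_factor(noise_fwhm,
                                                  template$voxel_size))
      noise <- array(stats::rnorm(length(dat), 0, raw_sd), dim(dat))
      dat <- dat + gaussian_smooth(noise, noise_fwhm, template$voxel_size)
    }
  })
  out$data <- pmin(pmax(dat, 0), 1)
  out$latent <- latent
  out
}

#' Simulate a full synthetic cohort
#'
#' Drives [generate_phenotypes()], [generate_template()] and
#' [generate_subject_volume()] under seeds derived from the config's master
#' seed, applies any requested symptom-score couplings, and assembles the
#' ground-truth manifest. Regenerating with the same config is bit-exact.
#'
#' @param config a `cohort_config`.
#' @param effects list of `effect_spec` (may be empty for a null cohort).
#' @param blob_spec template blob layout (default [default_blob_spec()]).
#' @param render if `FALSE`, skip volume rendering (phenotypes + latent
#'   ground truth only; used for score-coupling studies).
#' @return list with `phenotypes`, `template`, `volumes` (named list of
#'   `gm_volume`, or `NULL`), and `manifest` (effects, per-subject latent AI
#'   matrix, seed).
#' @export
simulate_cohort <- function(config, effects = list(),
                            blob_spec = default_blob_spec(config),
                            render = TRUE) {
  pheno <- generate_phenotypes(config)
  template <- generate_template(config, blob_spec)
  n <- nrow(pheno)
  age_center <- mean(config$age_range)

  latent <- matrix(0, n, length(effects),
                   dimnames = list(pheno$SUB_ID,
                                   if (length(effects))
                                     paste0("effect", seq_along(effects))))
  site_fields <- NULL
  if (render && config$site_bias_sd > 0) {
    site_fields <- lapply(seq_len(config$n_sites), function(s) {
      with_seed(config$seed + 5000L + s, {
        raw_sd <- config$site_bias_sd /
          sqrt(smooth_var_factor(20, config$voxel_size))
        noise <- array(stats::rnorm(prod(config$grid_shape), 0, raw_sd),
                       config$grid_shape)
        gaussian_smooth(noise, 20, config$voxel_size)
      })
    })
    names(site_fields) <- sprintf("SITE%02d", seq_len(config$n_sites))
  }

  volumes <- if (render) vector("list", n)
  for (i in seq_len(n)) {
    rec <- pheno[i, ]
    if (render) {
      v <- generate_subject_volume(
        template, rec, effects, seed = config$seed + 10000L + i,
        noise_sd = config$noise_sd, noise_fwhm = config$noise_fwhm,
        site_field = site_fields[[rec$SITE_ID]], age_center = age_center)
      if (length(effects)) latent[i, ] <- v$latent
      v$latent <- NULL
      volumes[[i]] <- v
    } else if (length(effects)) {
      # same seed stream as rendering so latent truth is identical either way
      with_seed(config$seed + 10000L + i, {
        for (j in seq_along(effects)) {
          ef <- effects[[j]]
          dev <- if (ef$subject_sd > 0) stats::rnorm(1, 0, ef$subject_sd)
                 else 0
          if (effect_applies(ef, rec)) {
            latent[i, j] <- latent_effect_ai(ef, rec, age_center, dev)
          }
        }
      })
    }
  }
  if (render) names(volumes) <- pheno$SUB_ID

  pheno <- apply_score_couplings(pheno, effects, latent, config)

  list(phenotypes = pheno, template = template, volumes = volumes,
       manifest = list(seed = config$seed,
                       effects = lapply(effects, unclass),
                       latent_ai = latent,
                       true_subgroup = stats::setNames(pheno$true_subgroup,
                                                       pheno$SUB_ID)))
}

# generate coupled symptom scores: score = round(11 + 4 (b z + e)), clipped to
# [0, 22], with z the standardized latent AI and b = r / sqrt(1 - r^2), which
# gives correlation r with the latent AI in expectation (discretization
# attenuates it by < 1%)
apply_score_couplings <- function(pheno, effects, latent, config) {
  for (j in seq_along(effects)) {
    bc <- effects[[j]]$behavior_coupling
    if (is.null(bc)) next
    stopifnot(is.character(bc$score), is.numeric(bc$r), abs(bc$r) < 1)
    idx <- which(pheno$DX_GROUP == 1L & !is.na(pheno[[bc$score]]))
    if (length(idx) < 4L) next
    x <- latent[idx, j]
    if (stats::sd(x) == 0) {
      warning("zero-variance latent AI for coupled effect ", j,
              "; coupling skipped")
      next
    }
    z <- (x - mean(x)) / stats::sd(x)
    b <- bc$r / sqrt(1 - bc$r^2)
    with_seed(config$seed + 7000L + j, {
      e <- stats::rnorm(length(idx))
      sc <- round(11 + 4 * (b * z + e))
      pheno[[bc$score]][idx] <- pmin(pmax(sc, 0L), 22L)
    })
  }
  pheno
}

#' Write a simulated cohort to disk
#'
#' Writes per-subject `<SUB_ID>.nii.gz` volumes, `phenotype.csv` (without the
#' ground-truth column), and `ground_truth.json`.
#'
#' @param sim result of [simulate_cohort()] (with `render = TRUE`).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  if (is.null(sim$volumes)) stop("cohort was simulated with render = FALSE")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pheno <- sim$phenotypes
  utils::write.csv(pheno[setdiff(names(pheno), "true_subgroup")],
                   file.path(dir, "phenotype.csv"), row.names = FALSE)
  for (id in names(sim$volumes)) {
    write_nifti(sim$volumes[[id]], file.path(dir, paste0(id, ".nii.gz")))
  }
  jsonlite::write_json(
    list(seed = sim$manifest$seed, effects = sim$manifest$effects,
         true_subgroup = as.list(sim$manifest$true_subgroup),
         latent_ai = as.data.frame(sim$manifest$latent_ai)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}
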