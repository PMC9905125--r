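test_that("cohort_config rejects invalid worlds", {
  expect_error(cohort_config(subgroup_proportions = c(0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(cohort_config(grid_shape = c(15, 18, 16)), "even")
  expect_error(cohort_config(age_range = c(18, 7)), "age_range")
})

test_that("phenotype generation is deterministic and honors proportions", {
  cc <- small_config(seed = 42)
  expect_identical(generate_phenotypes(cc), generate_phenotypes(cc))

  # degenerate proportions: every case must be SI-dominant
  cc1 <- small_config(seed = 3, subgroup_proportions = c(1, 0, 0))
  ph1 <- generate_phenotypes(cc1)
  expect_true(all(ph1$true_subgroup[ph1$DX_GROUP == 1L] == "SI"))
  # controls never carry interview scores
  expect_true(all(is.na(ph1$ADI_R_SOCIAL_TOTAL_A[ph1$DX_GROUP == 2L])))

  # empirical fractions near (0.635, 0.187, 0.178) at n = 200:
  # binomial se at p ~ 0.64 and n = 200 is ~ 0.034, so +/- 5 points ~ 1.5 se
  cc2 <- cohort_config(n_asd = 200, n_td = 10, grid_shape = c(16, 18, 16),
                       seed = 8)
  ph2 <- generate_phenotypes(cc2)
  frac <- table(factor(ph2$true_subgroup, c("SI", "VA", "RRB"))) / 200
  expect_true(all(abs(frac - c(0.635, 0.187, 0.178)) < 0.05))

  # ages and sites look like the stated world
  expect_true(all(ph2$AGE_AT_SCAN >= 7 & ph2$AGE_AT_SCAN <= 18))
  expect_gt(length(unique(ph2$SITE_ID)), 1)
})

test_that("the synthetic template is bit-exactly symmetric", {
  cc <- small_config()
  tpl <- generate_template(cc)
  expect_identical(flip_lr(tpl)$data, tpl$data)
  expect_true(all(tpl$data >= 0 & tpl$data <= 1))

  empty <- generate_template(cc, blob_spec = NULL)
  expect_true(all(empty$data == 0))

  # a single blob reaches its nominal amplitude at its center voxel
  # (center far enough lateral that the mirrored blob contributes < 1e-12)
  ctr <- c(22.5, 4.5, 1.5)  # on-grid voxel center for 16x18x16 at 3 mm
  one <- generate_template(cc, data.frame(cx = ctr[1], cy = ctr[2],
                                          cz = ctr[3], amp = 0.8, sigma = 6))
  i <- asymvbm:::world_to_index(one, ctr)
  expect_equal(one$data[i[1], i[2], i[3]], 0.8, tolerance = 1e-12)

  expect_error(generate_template(cc, data.frame(cx = 500, cy = 0, cz = 0,
                                                amp = 1, sigma = 5)),
               "outside the grid")
})

test_that("subject volumes degrade gracefully to the template", {
  cc <- small_config(seed = 5, noise_sd = 0, site_bias_sd = 0)
  tpl <- generate_template(cc)
  rec <- generate_phenotypes(cc)[1, ]

  v0 <- generate_subject_volume(tpl, rec, effects = list(), seed = 1,
                                noise_sd = 0)
  expect_identical(v0$data, tpl$data)

  # zero-delta, zero-deviation effect is also the identity
  ef0 <- default_effect(cc, delta = 0, subject_sd = 0)
  v00 <- generate_subject_volume(tpl, rec, list(ef0), seed = 1, noise_sd = 0)
  expect_identical(v00$data, tpl$data)
})

test_that("a rightward delta raises right-region GM and hits the analytic AI", {
  cc <- small_config(seed = 5)
  tpl <- generate_template(cc)
  ph <- generate_phenotypes(cc)
  rec <- ph[ph$DX_GROUP == 1L, ][1, ]
  ef <- default_effect(cc, delta = 0.2, subject_sd = 0)
  reg <- asymvbm:::effect_region_mask(tpl, ef)

  v <- generate_subject_volume(tpl, rec, list(ef), seed = 2, noise_sd = 0)
  left_reg <- flip_lr(gm_volume(reg * 1, cc$voxel_size))$data > 0
  expect_gt(mean(v$data[reg]), mean(v$data[left_reg]))

  # sample mean regional AI vs the analytic value 2*delta/(2+delta)
  analytic <- 2 * 0.2 / (2 + 0.2)
  mask <- make_right_mask(tpl, 0.2)
  ai_reg <- replicate(40, NA_real_)
  for (k in 1:40) {
    vk <- generate_subject_volume(tpl, rec, list(ef), seed = 100 + k,
                                  noise_sd = cc$noise_sd,
                                  noise_fwhm = cc$noise_fwhm)
    ai <- compute_ai(vk, flip_lr(vk), mask)
    ai_reg[k] <- mean(ai$data[reg & mask$data])
  }
  expect_lt(abs(mean(ai_reg) - analytic), 0.2 * analytic)
})

test_that("null cohorts carry no systematic asymmetry", {
  cc <- small_config(seed = 17, n_asd = 0, n_td = 100)
  sim <- simulate_cohort(cc)
  tpl <- sim$template
  mask <- make_right_mask(tpl, 0.2)
  # a 5-mm ball around an on-template location inside the mask
  b <- default_blob_spec(cc)[3, ]
  ctr <- c(b$cx, b$cy, b$cz)
  reg <- asymvbm:::effect_region_mask(
    tpl, effect_spec(ctr, region_radius = 5, delta = 0)) & mask$data
  expect_gt(sum(reg), 0)
  ball_means <- vapply(sim$volumes, function(v) {
    mean(compute_ai(v, flip_lr(v), mask)$data[reg])
  }, numeric(1))
  se <- stats::sd(ball_means) / sqrt(length(ball_means))
  expect_lt(abs(mean(ball_means)), 3 * se)
})

test_that("ground-truth manifest regeneration is bit-exact", {
  cc <- small_config(seed = 23)
  ef <- default_effect(cc, behavior_coupling = list(score = "ADOS_SOCIAL",
                                                    r = -0.3))
  s1 <- simulate_cohort(cc, effects = list(ef))
  s2 <- simulate_cohort(cc, effects = list(ef))
  expect_identical(s1$manifest, s2$manifest)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$volumes[[5]]$data, s2$volumes[[5]]$data)

  # latent truth computed without rendering matches the rendered stream
  s3 <- simulate_cohort(cc, effects = list(ef), render = FALSE)
  expect_identical(s3$manifest$latent_ai, s1$manifest$latent_ai)
})

test_that("write_cohort round-trips through disk", {
  cc <- small_config(seed = 31, n_asd = 3, n_td = 3)
  sim <- simulate_cohort(cc)
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(sim, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  loaded <- load_cohort(dir)
  expect_equal(loaded$phenotypes$SUB_ID, sim$phenotypes$SUB_ID)
  expect_false("true_subgroup" %in% names(loaded$phenotypes))
  expect_lt(max(abs(loaded$volumes[["S0002"]]$data -
                      sim$volumes[["S0002"]]$data)), 1e-7)
  unlink(dir, recursive = TRUE)
})
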