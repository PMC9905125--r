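test_that("subscale normalization is X / X_MAX with strict domain checks", {
  mx <- c(30, 26, 12)
  expect_equal(unlist(normalize_subscales(30, 26, 12, mx)),
               c(s = 1, v = 1, r = 1))
  expect_equal(unlist(normalize_subscales(0, 0, 0, mx)),
               c(s = 0, v = 0, r = 0))
  # hand arithmetic: 20/30, 18/26, 6/12
  got <- normalize_subscales(20, 18, 6, mx)
  expect_equal(unlist(got), c(s = 0.6667, v = 0.6923, r = 0.5),
               tolerance = 1e-4)
  expect_error(normalize_subscales(NA, 18, 6, mx), "present")
  expect_error(normalize_subscales(31, 18, 6, mx), "X_MAX")
  expect_error(normalize_subscales(20, 18, 6, c(30, -1, 12)), "positive")
})

test_that("subgroup assignment follows the strict-maximum rule with ties excluded", {
  cases <- data.frame(
    s = c(0.9, 0.5, 0.1, 0.3, 0.2, 1 / 3),
    v = c(0.3, 0.5, 0.2, 0.3, 0.9, 1 / 3),
    r = c(0.3, 0.2, 0.9, 0.9, 0.2, 1 / 3))
  expect_equal(assign_subgroup(cases),
               c("SI", "EXCLUDED", "RRB", "RRB", "VA", "EXCLUDED"))
  # sub-maximal ties do not exclude (row 4: s = v below the max)
  # evaluation-order invariance: permuting rows permutes labels only
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(assign_subgroup(cases[perm, ]), assign_subgroup(cases)[perm])
})

test_that("generator-intended labels are recovered perfectly", {
  cc <- small_config(seed = 12, n_asd = 60, n_td = 5)
  ph <- generate_phenotypes(cc)
  got <- subgroup_phenotypes(ph)
  expect_equal(nrow(got), 60)
  expect_false(any(got$label == "EXCLUDED"))
  truth <- ph$true_subgroup[match(got$subject_id, ph$SUB_ID)]
  expect_identical(got$label, truth)
})

test_that("subgrouping is instrument-agnostic (column mapping only)", {
  ph <- data.frame(SUB_ID = c("a", "b"), DX_GROUP = c(1L, 1L),
                   ADOS_SOCIAL = c(12L, 2L), ADOS_COMM = c(2L, 3L),
                   ADOS_RRB = c(1L, 7L))
  got <- subgroup_phenotypes(ph, columns = c("ADOS_SOCIAL", "ADOS_COMM",
                                             "ADOS_RRB"),
                             max_scores = c(14, 8, 8))
  expect_equal(got$label, c("SI", "RRB"))
})

test_that("chi-square (no continuity correction) reproduces known tables", {
  # proportional rows give exactly zero
  z <- chi_square_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(z$statistic, 0)
  expect_equal(z$p, 1)
  prop <- chi_square_2x2(matrix(c(30, 60, 10, 20), 2))
  expect_equal(prop$statistic, 0)

  # cross-check against the independent base-R implementation
  m <- matrix(c(124, 213, 22, 36), 2)
  expect_equal(chi_square_2x2(m)$statistic,
               unname(stats::chisq.test(m, correct = FALSE)$statistic),
               tolerance = 1e-12)

  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "margin")
  expect_error(chi_square_2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("two-sample t matches the closed form and is antisymmetric", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  got <- two_sample_t(a, b)
  # hand computation: pooled sp2 = 1, se = sqrt(2/3), t = -sqrt(3/2), df = 4
  expect_equal(got$t, -sqrt(1.5), tolerance = 1e-12)
  expect_equal(got$df, 4)
  expect_equal(got$p, 2 * pt(-sqrt(1.5), 4), tolerance = 1e-12)

  swapped <- two_sample_t(b, a)
  expect_equal(swapped$t, -got$t)
  expect_equal(swapped$p, got$p)

  same <- two_sample_t(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # Welch option against the base-R oracle
  x <- with_seed(4, rnorm(12)); y <- with_seed(5, rnorm(7, sd = 3))
  w <- two_sample_t(x, y, pooled = FALSE)
  ref <- stats::t.test(x, y)
  expect_equal(w$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)
})

test_that("Dunn pairwise statistics match a rank-arithmetic oracle", {
  # three clearly separated groups of 3: pooled ranks are 1:9, mean ranks
  # (2, 5, 8), sigma2 = 9*10/12 = 7.5, so z12 = -3 / sqrt(7.5 * 2/3)
  g <- list(A = c(1, 2, 3), B = c(11, 12, 13), C = c(21, 22, 23))
  got <- subscale_pairwise_nonparametric(g)
  zref <- c(-3, -6, -3) / sqrt(7.5 * (2 / 3))
  expect_equal(got$statistic, zref, tolerance = 1e-12)
  expect_equal(got$p_bonferroni, pmin(1, 3 * got$p_raw))
  expect_equal(got$p_raw, 2 * pnorm(-abs(zref)), tolerance = 1e-12)

  # identical groups: all statistics 0, all p = 1
  same <- subscale_pairwise_nonparametric(list(rep(2, 4), rep(2, 5),
                                               rep(2, 3)))
  expect_true(all(same$statistic == 0))
  expect_true(all(same$p_bonferroni == 1))

  expect_error(subscale_pairwise_nonparametric(list(1:3, numeric(0), 1:3)),
               "non-empty")
})

test_that("matched-control selection respects site/gender/age and reuses across analyses", {
  cases <- data.frame(SUB_ID = "case1", SITE_ID = "siteA", DX_GROUP = 1L,
                      AGE_AT_SCAN = 10.0, SEX = 1L)
  pool <- data.frame(SUB_ID = c("ctlA", "ctlB"),
                     SITE_ID = c("siteA", "siteB"), DX_GROUP = 2L,
                     AGE_AT_SCAN = c(10.5, 10.0), SEX = 1L)
  m <- match_controls(cases, pool, list(an1 = "case1"), seed = 1)
  expect_equal(m$an1$control_id, "ctlA")   # site match beats exact age

  # same seed, same inputs -> identical selection
  bigger <- rbind(pool, data.frame(SUB_ID = "ctlC", SITE_ID = "siteA",
                                   DX_GROUP = 2L, AGE_AT_SCAN = 9.5,
                                   SEX = 1L))
  m1 <- match_controls(cases, bigger, list(an1 = "case1"), seed = 7)
  m2 <- match_controls(cases, bigger, list(an1 = "case1"), seed = 7)
  expect_identical(m1, m2)

  # one eligible control, two analyses -> reused in both
  m3 <- match_controls(cases, pool, list(an1 = "case1", an2 = "case1"),
                       seed = 1)
  expect_equal(m3$an1$control_id, m3$an2$control_id)

  # out-of-tolerance ages are reported, not silently matched
  far <- data.frame(SUB_ID = "ctlD", SITE_ID = "siteA", DX_GROUP = 2L,
                    AGE_AT_SCAN = 16, SEX = 1L)
  m4 <- match_controls(cases, far, list(an1 = "case1"), age_tolerance = 2,
                       seed = 1)
  expect_equal(nrow(m4$an1), 0)
  expect_equal(attr(m4$an1, "unmatched"), "case1")

  expect_error(match_controls(cases, cases, list(a = "case1")),
               "only control")
})
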