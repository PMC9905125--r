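smooth_unit_noise <- function(seed, dims, fwhm, voxel = 3, n = 12) {
  with_seed(seed, {
    imgs <- lapply(seq_len(n), function(i) {
      gaussian_smooth(array(rnorm(prod(dims)), dims), fwhm, voxel)
    })
    t(vapply(imgs, as.numeric, numeric(prod(dims))))
  })
}

test_that("smoothness estimation recovers known FWHM and flags rough fields", {
  dims <- c(20, 22, 20)
  mask <- array(TRUE, dims)

  # applied 8 mm kernel on 3 mm voxels: median estimate within 15%
  est <- vapply(1:20, function(s) {
    estimate_fwhm(smooth_unit_noise(s, dims, 8), mask, 3)$fwhm[1]
  }, numeric(1))
  expect_lt(abs(stats::median(est) - 8), 0.15 * 8)

  # doubling voxel size with the same lattice doubles the FWHM in mm
  R <- smooth_unit_noise(50, dims, 8)
  e3 <- estimate_fwhm(R, mask, 3)
  e6 <- estimate_fwhm(R, mask, 6)
  expect_equal(e6$fwhm, 2 * e3$fwhm, tolerance = 1e-12)
  expect_equal(e6$fwhm_vox, e3$fwhm_vox, tolerance = 1e-12)
  # resel count: mask volume in FWHM^3 units
  expect_equal(e3$resel_count,
               prod(dims) * prod(3 / e3$fwhm), tolerance = 1e-12)

  # independent (unsmoothed) noise: estimate at or below 1.5 voxels, flagged
  e0 <- estimate_fwhm(smooth_unit_noise(51, dims, 0), mask, 3)
  expect_lt(max(e0$fwhm_vox), 1.5)
  expect_true(attr(e0, "below_voxel"))

  expect_error(estimate_fwhm(R[1:2, ], mask, 3), ">= 3")
  expect_error(estimate_fwhm(matrix(1, 5, prod(dims)), mask, 3), "constant")
})

test_that("cluster labeling honors the three connectivity conventions", {
  d <- c(6, 6, 6)
  two_face <- array(FALSE, d); two_face[2, 2, 2] <- two_face[3, 2, 2] <- TRUE
  corner <- array(FALSE, d); corner[2, 2, 2] <- corner[3, 3, 3] <- TRUE
  edge <- array(FALSE, d); edge[2, 2, 2] <- edge[3, 3, 2] <- TRUE
  n_comp <- function(m, conn) max(asymvbm:::connected_components(m, conn))
  for (conn in c(6, 18, 26)) expect_equal(n_comp(two_face, conn), 1)
  expect_equal(n_comp(corner, 6), 2)
  expect_equal(n_comp(corner, 18), 2)
  expect_equal(n_comp(corner, 26), 1)
  expect_equal(n_comp(edge, 6), 2)
  expect_equal(n_comp(edge, 18), 1)
  expect_error(asymvbm:::connected_components(corner, 7), "connectivity")
})

test_that("component labels agree with an independent graph-component oracle", {
  igraph_components <- function(mask, conn) {   # oracle via igraph
    idx <- which(mask)
    if (length(idx) == 0) return(0L)
    co <- arrayInd(idx, dim(mask))
    off <- asymvbm:::connectivity_offsets(conn)
    key <- function(m) paste(m[, 1], m[, 2], m[, 3])
    lookup <- stats::setNames(seq_along(idx), key(co))
    edges <- integer(0)
    for (k in seq_len(nrow(off))) {
      nb <- sweep(co, 2, off[k, ], "+")
      hit <- lookup[key(nb)]
      ok <- !is.na(hit)
      edges <- c(edges, rbind(which(ok), hit[ok]))
    }
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    if (length(edges)) g <- igraph::add_edges(g, edges)
    igraph::components(g)$no
  }
  with_seed(21, {
    for (rep in 1:5) {
      m <- array(runif(1000) < 0.2, c(10, 10, 10))
      for (conn in c(6, 18, 26)) {
        expect_equal(max(asymvbm:::connected_components(m, conn)),
                     igraph_components(m, conn))
      }
    }
  })
})

test_that("RFT cluster p has the right monotonicities and limits", {
  sm <- structure(list(fwhm = c(9, 9, 9), fwhm_vox = c(3, 3, 3),
                       resel_count = 2000 / 27, search_volume = 2000,
                       voxel_size = c(3, 3, 3)), class = "smoothness")
  u <- qnorm(1 - 0.005)
  p <- cluster_p_rft(c(1, 5, 20, 100, 500), u, sm)
  expect_true(all(diff(p) < 0))                       # larger extent, smaller p
  Em <- asymvbm:::expected_clusters(u, sm$resel_count)
  expect_equal(cluster_p_rft(0, u, sm), 1 - exp(-Em), tolerance = 1e-12)
  expect_lt(cluster_p_rft(1e6, u, sm), 1e-12)

  # larger search region (more resels) -> larger corrected p, all else fixed
  sm2 <- sm; sm2$resel_count <- sm$resel_count * 4
  sm2$search_volume <- sm$search_volume * 4
  expect_gt(cluster_p_rft(30, u, sm2), cluster_p_rft(30, u, sm))

  # no-smoothness limit: FWHM = voxel size makes resels = voxel count
  sm3 <- sm; sm3$fwhm <- c(3, 3, 3); sm3$fwhm_vox <- c(1, 1, 1)
  expect_equal(sm3$search_volume * prod(sm3$voxel_size / sm3$fwhm),
               sm3$search_volume)

  expect_error(cluster_p_rft(10, 0.5, sm), "exceed 1")
})

test_that("significant_clusters reports one row per suprathreshold blob", {
  cc <- small_config(seed = 33, n_asd = 20, n_td = 20,
                     subgroup_proportions = c(1, 0, 0))
  ef <- default_effect(cc, delta = 0.25)
  sim <- simulate_cohort(cc, effects = list(ef))
  cl <- cohort_clusters(sim)
  expect_gte(nrow(cl), 1)
  expect_true(all(cl$p_corrected < 0.05))
  expect_true(all(cl$extent >= 1))
  masks <- attr(cl, "masks")
  expect_equal(vapply(masks, sum, integer(1)), setNames(cl$extent, cl$cluster))
  # clusters are disjoint
  if (length(masks) > 1) {
    expect_equal(max(Reduce(`+`, lapply(masks, function(m) m * 1L))), 1)
  }
  # the dominant cluster is rightward with its peak inside the injected region
  top <- cl[1, ]
  expect_equal(top$direction, "rightward")
  expect_gt(top$peak_t, 0)
  ctr <- ef$region_center
  expect_lte(sqrt((top$peak_x - ctr[1])^2 + (top$peak_y - ctr[2])^2 +
                    (top$peak_z - ctr[3])^2), ef$region_radius)
})

test_that("dice_overlap counts shared voxels as a hand oracle does", {
  d <- c(4, 4, 4)
  A <- array(FALSE, d); B <- array(FALSE, d)
  A[1:2, 1, 1] <- TRUE                 # |A| = 2
  B[2:4, 1, 1] <- TRUE                 # |B| = 3, overlap = 1
  expect_equal(dice_overlap(A, B), 2 * 1 / (2 + 3))
  expect_equal(dice_overlap(A, A), 1)
  expect_equal(dice_overlap(A, array(FALSE, d)), 0)
  expect_equal(dice_overlap(array(FALSE, d), array(FALSE, d)), 0)
  expect_error(dice_overlap(A, array(FALSE, c(3, 3, 3))), "geometry")
})
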