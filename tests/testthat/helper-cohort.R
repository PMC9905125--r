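# shared fixtures: all synthetic, built in code at test time

# a small cohort configuration that keeps imaging tests fast
small_config <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(n_asd = 16, n_td = 16, n_sites = 2,
                   grid_shape = c(16, 18, 16), seed = seed)
  do.call(cohort_config, utils::modifyList(defaults, args))
}

# the reduced lattice used for calibration/power studies
calib_config <- function(seed, n_asd = 20, n_td = 20, ...) {
  cohort_config(n_asd = n_asd, n_td = n_td, n_sites = 2,
                grid_shape = c(24, 28, 24), seed = seed, ...)
}

random_volume <- function(seed, dims = c(8, 10, 8), voxel = 3) {
  with_seed(seed, gm_volume(array(stats::runif(prod(dims)), dims), voxel))
}

# case/control labels for a simulated cohort
dx_labels <- function(pheno) ifelse(pheno$DX_GROUP == 1L, "ASD", "TD")

# run one simulated cohort through GLM + GRF, returning the cluster table
cohort_clusters <- function(sim, ...) {
  res <- analyze_group_difference(sim$volumes, sim$phenotypes,
                                  dx_labels(sim$phenotypes), ...)
  res$clusters
}
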