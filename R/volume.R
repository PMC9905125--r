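#' Gray-matter probability volume
#'
#' A minimal 3-D lattice container for spatially normalized gray-matter (GM)
#' probability maps. The grid is centered on the origin of a right-handed RAS
#' world frame (+x = subject's right), with the mid-sagittal plane x = 0 lying
#' exactly between two voxel columns whenever the x extent is even, so that
#' left-right flipping is an exact index reversal with no interpolation.
#'
#' The world coordinate of voxel `i` (1-based) along an axis with `n` voxels of
#' size `v` mm is `(i - (n + 1) / 2) * v`.
#'
#' @param data 3-D numeric array of GM probabilities (values in `[0, 1]` for
#'   tissue maps; asymmetry-index maps reuse the same geometry with values in
#'   `[-2, 2]`).
#' @param voxel_size voxel edge length in mm; length 1 (isotropic) or 3.
#' @return An object of class `gm_volume`: a list with elements `data` and
#'   `voxel_size`.
#' @export
gm_volume <- function(data, voxel_size = 3) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-D array")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stop("`voxel_size` must be 1 or 3 positive numbers (mm)")
  }
  structure(list(data = data, voxel_size = voxel_size), class = "gm_volume")
}

#' @export
print.gm_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<gm_volume> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @rdname gm_volume
#' @param x object to test.
#' @export
is_gm_volume <- function(x) inherits(x, "gm_volume")

# world coordinates of voxel centers along one axis (1 = x, 2 = y, 3 = z)
axis_world <- function(vol, axis) {
  n <- dim(vol$data)[axis]
  (seq_len(n) - (n + 1) / 2) * vol$voxel_size[axis]
}

#' Test that two volumes share grid and voxel geometry
#'
#' @param a,b `gm_volume` (or mask) objects.
#' @return `TRUE`/`FALSE`.
#' @export
same_geometry <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$voxel_size, b$voxel_size, tolerance = 1e-12))
}

stop_if_geometry_mismatch <- function(a, b) {
  if (!same_geometry(a, b)) stop("volume geometry mismatch (grid or voxel size)")
  invisible(TRUE)
}

# world -> nearest voxel index (1-based), per axis
world_to_index <- function(vol, world) {
  d <- dim(vol$data)
  idx <- round(world / vol$voxel_size + (d + 1) / 2)
  as.integer(idx)
}

#' Evaluate seeded code without disturbing the caller's RNG state
#'
#' All stochastic operations in the package funnel their randomness through
#' this helper so that a run is fully reproducible from its recorded seeds.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  code
}
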