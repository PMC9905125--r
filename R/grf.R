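#' Estimate residual field smoothness (FWHM and resel count)
#'
#' Per-axis roughness is estimated from spatial first differences of the
#' standardized GLM residuals over in-mask neighbor pairs:
#' lambda_j = E[(dZ)^2] / Var(Z), the variance of the unit-variance field's
#' one-voxel difference along axis j. For a Gaussian autocorrelation this
#' gives FWHM_j = sqrt(4 ln 2 / lambda_j) voxels, converted to mm by the
#' voxel size. The resel count is the mask volume in FWHM^3 units:
#' sum over mask voxels of prod_j(voxel_size_j / FWHM_j).
#'
#' @param residuals n x V matrix of (standardized) residual images over the
#'   mask, n >= 3.
#' @param mask logical 3-D array with V `TRUE` voxels.
#' @param voxel_size mm per axis (scalar or length 3).
#' @return A `smoothness` list: `fwhm` (mm, length 3), `fwhm_vox`,
#'   `resel_count`, `search_volume` (voxels), `voxel_size`. FWHM below one
#'   voxel is flagged via attribute `below_voxel`.
#' @export
estimate_fwhm <- function(residuals, mask, voxel_size) {
  if (nrow(residuals) < 3L) stop("need >= 3 residual images")
  V <- sum(mask)
  if (V == 0L) stop("empty mask")
  if (ncol(residuals) != V) stop("residual columns must match mask voxels")
  voxel_size <- rep(as.numeric(voxel_size), length.out = 3L)

  d <- dim(mask)
  id <- array(0L, d)
  id[mask] <- seq_len(V)
  lambda <- numeric(3)
  for (ax in 1:3) {
    n_ax <- d[ax]
    if (n_ax < 2L) { lambda[ax] <- NA_real_; next }
    lo <- switch(ax, id[-n_ax, , , drop = FALSE], id[, -n_ax, , drop = FALSE],
                 id[, , -n_ax, drop = FALSE])
    hi <- switch(ax, id[-1, , , drop = FALSE], id[, -1, , drop = FALSE],
                 id[, , -1, drop = FALSE])
    keep <- lo > 0L & hi > 0L
    a <- lo[keep]; b <- hi[keep]
    if (length(a) == 0L) { lambda[ax] <- NA_real_; next }
    D <- residuals[, a, drop = FALSE] - residuals[, b, drop = FALSE]
    num <- sum(D^2)
    den <- sum(residuals[, a, drop = FALSE]^2 +
                 residuals[, b, drop = FALSE]^2) / 2
    if (den <= 0) stop("constant residual field; smoothness undefined")
    lambda[ax] <- num / den
  }
  if (anyNA(lambda)) {
    stop("could not estimate roughness on every axis (degenerate mask?)")
  }
  if (any(lambda <= 0)) {
    stop("constant residual field; smoothness undefined")
  }
  fwhm_vox <- sqrt(4 * log(2) / lambda)
  fwhm_mm <- fwhm_vox * voxel_size
  resel <- V * prod(voxel_size / fwhm_mm)
  out <- structure(list(fwhm = fwhm_mm, fwhm_vox = fwhm_vox,
                        resel_count = resel, search_volume = V,
                        voxel_size = voxel_size),
                   class = "smoothness")
  # the white-noise floor of this estimator is sqrt(2 ln 2) ~ 1.18 voxels, so
  # estimates under 1.5 voxels signal unresolved (unsmooth) residual fields
  attr(out, "below_voxel") <- any(fwhm_vox < 1.5)
  out
}

connectivity_offsets <- function(connectivity = 18L) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  ord <- rowSums(abs(g))
  switch(as.character(connectivity),
         "6"  = g[ord == 1L, , drop = FALSE],
         "18" = g[ord <= 2L, , drop = FALSE],
         "26" = g,
         stop("`connectivity` must be 6, 18, or 26"))
}

# label connected components of a logical 3-D array (BFS over in-mask voxels)
connected_components <- function(mask, connectivity = 18L) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (length(idx) == 0L) return(lab)
  off <- connectivity_offsets(connectivity)
  coords <- arrayInd(idx, d)
  id <- array(0L, d)
  id[idx] <- seq_along(idx)
  comp <- integer(length(idx))
  cur <- 0L
  for (s in seq_along(idx)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      batch <- coords[queue, , drop = FALSE]
      queue <- integer(0)
      for (k in seq_len(nrow(off))) {
        nb <- sweep(batch, 2L, off[k, ], "+")
        ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] &
              nb[, 2] >= 1L & nb[, 2] <= d[2] &
              nb[, 3] >= 1L & nb[, 3] <= d[3]
        if (!any(ok)) next
        ids <- id[nb[ok, , drop = FALSE]]
        ids <- ids[ids > 0L]
        ids <- ids[comp[ids] == 0L]
        if (length(ids)) {
          comp[ids] <- cur
          queue <- c(queue, ids)
        }
      }
      queue <- unique(queue)
    }
  }
  lab[idx] <- comp
  lab
}

#' Label suprathreshold clusters of a t map
#'
#' Connected components of the positive exceedance set (t >= threshold) and,
#' separately, of the negative set (t <= -threshold). Default 18-connectivity
#' (faces + edges), the common neuroimaging convention; 6 and 26 available.
#'
#' @param tmap a `tmap` (or plain 3-D array of t values).
#' @param threshold_t positive cluster-forming threshold on |t|.
#' @param connectivity 6, 18, or 26.
#' @return list with elements `positive` and `negative`, each a list of
#'   integer label array `labels` and `sizes` table (possibly empty).
#' @export
label_clusters <- function(tmap, threshold_t, connectivity = 18L) {
  if (threshold_t <= 0) stop("`threshold_t` must be > 0")
  tarr <- if (inherits(tmap, "tmap")) tmap$t else tmap
  one_sign <- function(m) {
    lab <- connected_components(m, connectivity)
    sz <- if (max(lab) > 0L) tabulate(lab[lab > 0L]) else integer(0)
    list(labels = lab, sizes = sz)
  }
  list(positive = one_sign(tarr >= threshold_t),
       negative = one_sign(tarr <= -threshold_t))
}

# expected number of clusters above Gaussian threshold u in a 3-D field with
# the given resel count (Euler-characteristic density of a Gaussian field)
expected_clusters <- function(u, resel_count) {
  resel_count * (4 * log(2))^(3 / 2) * (2 * pi)^(-2) * (u^2 - 1) *
    exp(-u^2 / 2)
}

#' Cluster-level corrected p value from Gaussian random field theory
#'
#' The t map is Gaussianized voxel-wise (probability transform), so the
#' cluster-forming threshold enters as the equivalent normal deviate u.
#' With E[m] the expected cluster count at u and E[N] the expected
#' suprathreshold volume (search_volume * Phi(-u), in voxels), the cluster
#' extent k (voxels) has tail probability P(extent >= k) = exp(-beta k^(2/3))
#' with beta = (Gamma(5/2) E[m] / E[N])^(2/3), and the family-wise corrected
#' p is 1 - exp(-E[m] * P(extent >= k)).
#'
#' @param extent cluster size in voxels (>= 1; vectorized).
#' @param u cluster-forming threshold as an equivalent normal deviate (> 1).
#' @param smoothness a `smoothness` object from [estimate_fwhm()].
#' @return corrected p value(s) in `[0, 1]`.
#' @export
cluster_p_rft <- function(extent, u, smoothness) {
  if (u <= 1) stop("`u` must exceed 1 (EC density changes sign at u = 1)")
  Em <- expected_clusters(u, smoothness$resel_count)
  EN <- smoothness$search_volume * stats::pnorm(-u)
  beta <- (gamma(5 / 2) * Em / EN)^(2 / 3)
  p_ext <- exp(-beta * pmax(extent, 0)^(2 / 3))
  p <- 1 - exp(-Em * p_ext)
  if (any(!is.finite(p))) {
    stop(sprintf("non-finite corrected p (u = %.3f, Em = %.3g, EN = %.3g)",
                 u, Em, EN))
  }
  pmin(pmax(p, 0), 1)
}

#' Cluster table of significant between-group differences
#'
#' Thresholds the t map at the t value whose one-tailed tail probability is
#' `voxel_p` (both signs handled as two one-tailed families), labels
#' clusters, computes GRF-corrected cluster p values, and keeps clusters
#' with corrected p below `cluster_p`. Direction follows the contrast sign:
#' positive t = case group more rightward.
#'
#' @param tmap a `tmap` from [fit_glm_voxelwise()].
#' @param smoothness a `smoothness` from [estimate_fwhm()]; estimated from
#'   the tmap's residuals when `NULL`.
#' @param voxel_p voxel-level cluster-forming p (default 0.005).
#' @param cluster_p cluster-level corrected threshold (default 0.05).
#' @param connectivity 6, 18, or 26 (default 18).
#' @return data.frame with columns cluster, extent, peak_x, peak_y, peak_z
#'   (world mm), peak_t, direction, p_corrected; cluster masks are attached
#'   as attribute `"masks"` (list of logical arrays), the smoothness as
#'   `"smoothness"`.
#' @export
significant_clusters <- function(tmap, smoothness = NULL, voxel_p = 0.005,
                                 cluster_p = 0.05, connectivity = 18L) {
  stopifnot(inherits(tmap, "tmap"))
  if (voxel_p <= 0 || voxel_p >= 1 || cluster_p <= 0 || cluster_p >= 1) {
    stop("thresholds must lie in (0, 1)")
  }
  if (is.null(smoothness)) {
    smoothness <- estimate_fwhm(tmap$residuals, tmap$mask, tmap$voxel_size)
  }
  t_thr <- stats::qt(1 - voxel_p, df = tmap$df)
  u <- stats::qnorm(1 - voxel_p)
  lab <- label_clusters(tmap, t_thr, connectivity)

  rows <- list(); masks <- list()
  for (sgn in c("positive", "negative")) {
    L <- lab[[sgn]]
    ncl <- length(L$sizes)
    if (ncl == 0L) next
    pcorr <- cluster_p_rft(L$sizes, u, smoothness)
    for (cl in seq_len(ncl)) {
      if (pcorr[cl] >= cluster_p) next
      vox <- which(L$labels == cl)
      tv <- tmap$t[vox]
      pk <- vox[which.max(abs(tv))]
      pk3 <- arrayInd(pk, dim(tmap$t))
      world <- (pk3 - (dim(tmap$t) + 1) / 2) * rep(tmap$voxel_size,
                                                   length.out = 3L)
      rows[[length(rows) + 1L]] <- data.frame(
        extent = L$sizes[cl], peak_x = world[1], peak_y = world[2],
        peak_z = world[3], peak_t = tmap$t[pk],
        direction = if (sgn == "positive") "rightward" else "leftward",
        p_corrected = pcorr[cl], stringsAsFactors = FALSE)
      masks[[length(masks) + 1L]] <- L$labels == cl
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(cluster = character(0), extent = integer(0),
                      peak_x = numeric(0), peak_y = numeric(0),
                      peak_z = numeric(0), peak_t = numeric(0),
                      direction = character(0), p_corrected = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "masks") <- list()
    attr(out, "smoothness") <- smoothness
    return(out)
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$extent)
  out <- out[ord, , drop = FALSE]
  masks <- masks[ord]
  out <- cbind(cluster = sprintf("C%d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  names(masks) <- out$cluster
  attr(out, "masks") <- masks
  attr(out, "smoothness") <- smoothness
  out
}

#' Dice overlap of two binary maps
#'
#' 2 |A intersect B| / (|A| + |B|); defined as 0 when both maps are empty.
#'
#' @param mapA,mapB logical arrays of identical dimension.
#' @return dimensionless overlap in `[0, 1]`.
#' @export
dice_overlap <- function(mapA, mapB) {
  if (!identical(dim(mapA), dim(mapB))) stop("geometry mismatch")
  sa <- sum(mapA); sb <- sum(mapB)
  if (sa + sb == 0L) return(0)
  2 * sum(mapA & mapB) / (sa + sb)
}
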