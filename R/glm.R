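# Moore-Penrose pseudo-inverse via SVD; returns the pinv and effective rank
pinv_svd <- function(X, tol = NULL) {
  s <- svd(X)
  if (is.null(tol)) tol <- max(dim(X)) * max(s$d) * .Machine$double.eps
  keep <- s$d > tol
  r <- sum(keep)
  dinv <- ifelse(keep, 1 / s$d, 0)
  list(pinv = s$v %*% (dinv * t(s$u)), rank = r,
       xtx_pinv = s$v %*% (dinv^2 * t(s$v)))
}

#' Build the group-comparison design matrix
#'
#' Columns: intercept, case indicator (1 = case), centered age, gender
#' indicator (1 = female), and one indicator per site (full one-hot, so the
#' site block sums to the all-ones vector). The full one-hot coding is kept
#' deliberately even though it overlaps the intercept: the model is fitted by
#' pseudo-inverse, the effective rank is reported, and the case-control
#' contrast is estimable regardless. Age is centered for conditioning only;
#' the contrast is invariant to it.
#'
#' @param records phenotype data.frame with SITE_ID, AGE_AT_SCAN, SEX.
#' @param group_labels character/factor of length nrow(records) with two
#'   levels.
#' @param case_level which label is the case group (default: the level that
#'   is not "TD", else the first level).
#' @return A `design_matrix`: list with `X`, `labels` (column names),
#'   `contrast`, `effective_rank`, `case_level`, `group` (0/1 vector).
#' @export
build_design <- function(records, group_labels, case_level = NULL) {
  group_labels <- as.character(group_labels)
  lv <- unique(group_labels)
  if (length(lv) != 2L) stop("`group_labels` must have exactly 2 levels")
  if (is.null(case_level)) {
    case_level <- if ("TD" %in% lv) setdiff(lv, "TD") else lv[1]
  }
  if (!case_level %in% lv) stop("unknown `case_level`: ", case_level)
  n <- nrow(records)
  if (n != length(group_labels)) stop("length mismatch")
  grp <- as.numeric(group_labels == case_level)
  if (min(table(group_labels)) < 2L) stop("need >= 2 subjects per group")

  sites <- sort(unique(records$SITE_ID))
  site_cols <- sapply(sites, function(s) as.numeric(records$SITE_ID == s))
  site_cols <- matrix(site_cols, nrow = n,
                      dimnames = list(NULL, paste0("site_", sites)))
  sex01 <- as.numeric(records$SEX == 2L)   # 1 = female
  X <- cbind(intercept = 1, group = grp,
             age_c = records$AGE_AT_SCAN - mean(records$AGE_AT_SCAN),
             female = sex01, site_cols)
  contrast <- as.numeric(colnames(X) == "group")
  pv <- pinv_svd(X)
  structure(list(X = X, labels = colnames(X), contrast = contrast,
                 effective_rank = pv$rank, case_level = case_level,
                 group = grp),
            class = "design_matrix")
}

#' Fit the mass-univariate general linear model over the mask
#'
#' Ordinary least squares per in-mask voxel via the design's pseudo-inverse;
#' t = c'b / sqrt(sigma2 * c'(X'X)^- c) with sigma2 = RSS / df and
#' df = n - rank(X). Voxels with (numerically) zero residual variance get
#' t = 0 and are counted in attribute `n_zero_var`. Standardized residuals
#' and the raw case-minus-control mean AI (for direction reporting) are
#' retained.
#'
#' @param ai_maps list of `ai_map` objects sharing one mask, one per design
#'   row.
#' @param design a `design_matrix` from [build_design()].
#' @return A `tmap`: list with `t` (3-D array, 0 off-mask), `df`, `mask`,
#'   `voxel_size`, `residuals` (n x V standardized matrix), `group_diff`
#'   (3-D array of case-minus-control mean AI), `contrast_estimate`.
#' @export
fit_glm_voxelwise <- function(ai_maps, design) {
  stopifnot(inherits(design, "design_matrix"))
  X <- design$X
  n <- nrow(X)
  if (length(ai_maps) != n) stop("one AI map per design row required")
  mask <- ai_maps[[1]]$mask
  vs <- ai_maps[[1]]$voxel_size
  for (m in ai_maps) {
    if (!identical(dim(m$data), dim(ai_maps[[1]]$data)))
      stop("AI map geometry mismatch")
  }
  V <- sum(mask)
  Y <- vapply(ai_maps, function(m) m$data[mask], numeric(V))  # V x n
  Y <- matrix(Y, nrow = V)                 # guard the single-voxel drop
  pv <- pinv_svd(X)
  df <- n - pv$rank
  if (df <= 0L) stop("non-positive residual degrees of freedom")

  B <- Y %*% t(pv$pinv)                   # V x p coefficient estimates
  fitted <- B %*% t(X)                    # V x n
  R <- Y - fitted
  rss <- rowSums(R^2)
  cxx <- drop(t(design$contrast) %*% pv$xtx_pinv %*% design$contrast)
  cb <- drop(B %*% design$contrast)
  sigma2 <- rss / df
  se <- sqrt(sigma2 * cxx)
  zero_var <- se < .Machine$double.eps^0.5 * max(abs(Y), 1e-12)
  tvals <- ifelse(zero_var, 0, cb / se)

  sd_vox <- sqrt(pmax(sigma2, .Machine$double.eps))
  Rstd <- t(R / sd_vox)                   # n x V

  tarr <- array(0, dim(mask)); tarr[mask] <- tvals
  grp <- design$group
  gd <- array(0, dim(mask))
  gd[mask] <- rowMeans(Y[, grp == 1, drop = FALSE]) -
    rowMeans(Y[, grp == 0, drop = FALSE])

  structure(list(t = tarr, df = df, mask = mask, voxel_size = vs,
                 residuals = Rstd, group_diff = gd,
                 contrast_estimate = cb, n_zero_var = sum(zero_var)),
            class = "tmap")
}

#' @export
print.tmap <- function(x, ...) {
  cat(sprintf("<tmap> %d in-mask voxels, df = %d, t range [%.3f, %.3f]\n",
              sum(x$mask), x$df, min(x$t[x$mask]), max(x$t[x$mask])))
  invisible(x)
}
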