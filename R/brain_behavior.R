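#' Mean asymmetry index within a cluster mask, per subject
#'
#' @param ai_maps list of `ai_map` objects on one grid.
#' @param cluster_mask logical 3-D array (nonempty).
#' @return numeric vector, one mean per map (named by the list names).
#' @export
extract_cluster_means <- function(ai_maps, cluster_mask) {
  if (sum(cluster_mask) == 0L) stop("empty cluster mask")
  vapply(ai_maps, function(m) {
    if (!identical(dim(m$data), dim(cluster_mask))) stop("geometry mismatch")
    mean(m$data[cluster_mask])
  }, numeric(1))
}

#' Partial correlation of a score with a predictor given covariates
#'
#' Regresses y on the predictor, an intercept, and the covariates; the
#' predictor's t statistic is converted to the partial correlation
#' r = sign(t) * sqrt(t^2 / (t^2 + df)) with its two-sided p. With no
#' covariates this equals the Pearson correlation. A covariate numerically
#' identical (up to affine scaling) to the predictor is rejected rather than
#' silently fitted; rank-deficient covariate blocks are handled by
#' pseudo-inverse with a warning.
#'
#' @param y numeric response vector.
#' @param x numeric predictor vector.
#' @param covariates optional numeric matrix / data.frame of covariates.
#' @return list with `r`, `p`, `t`, `df`, `n`.
#' @export
partial_correlation <- function(y, x, covariates = NULL) {
  n <- length(y)
  if (length(x) != n) stop("length mismatch between y and x")
  if (stats::sd(x) == 0) stop("zero-variance predictor")
  C <- NULL
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    if (nrow(C) != n) stop("covariate rows must match length(y)")
    for (j in seq_len(ncol(C))) {
      if (stats::sd(C[, j]) > 0 &&
          abs(stats::cor(C[, j], x)) > 1 - 1e-10) {
        stop("covariate ", j, " duplicates the predictor")
      }
    }
  }
  X <- cbind(intercept = 1, C, x = x)
  p_needed <- ncol(X)
  if (n <= p_needed) stop("n too small for the covariate set")
  pv <- pinv_svd(X)
  if (pv$rank < p_needed) {
    warning("rank-deficient covariate block; pseudo-inverse fit ",
            "(effective rank ", pv$rank, " of ", p_needed, ")")
  }
  beta <- drop(pv$pinv %*% y)
  res <- y - drop(X %*% beta)
  df <- n - pv$rank
  sigma2 <- sum(res^2) / df
  cvec <- as.numeric(colnames(X) == "x")
  se <- sqrt(sigma2 * drop(t(cvec) %*% pv$xtx_pinv %*% cvec))
  tval <- beta[length(beta)] / se
  r <- sign(tval) * sqrt(tval^2 / (tval^2 + df))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), t = tval, df = df, n = n)
}

#' Cluster-restricted brain-behavior / age regressions
#'
#' For every cluster in a significant-cluster table, extracts each subject's
#' mean AI within the cluster mask and reports the partial correlation of
#' the predictor with those means. Covariates follow the analysis protocol:
#' age, gender, and site for symptom-severity predictors; gender and site
#' only when the predictor is age itself.
#'
#' @param clusters result of [significant_clusters()] (its `"masks"`
#'   attribute supplies the cluster masks).
#' @param ai_maps named list of `ai_map`, one per subject in `pheno`.
#' @param pheno phenotype data.frame for the analyzed subjects (rows align
#'   with `ai_maps` by SUB_ID).
#' @param predictor phenotype column to use (e.g. `"ADOS_SOCIAL"` or
#'   `"AGE_AT_SCAN"`).
#' @return data.frame with columns cluster, predictor, n, r, p (one row per
#'   cluster; empty when the cluster table is empty). The per-cluster
#'   subject AI means are attached as attribute `"scatter"` for plotting.
#' @export
run_brain_behavior <- function(clusters, ai_maps, pheno, predictor) {
  stopifnot(predictor %in% names(pheno))
  masks <- attr(clusters, "masks")
  keep <- !is.na(pheno[[predictor]])
  if (!any(keep)) stop("predictor is missing for every subject")
  ph <- pheno[keep, , drop = FALSE]
  maps <- ai_maps[ph$SUB_ID]
  if (any(vapply(maps, is.null, logical(1)))) {
    stop("missing AI map for some subjects")
  }
  y <- ph[[predictor]]
  if (stats::sd(y) == 0) stop("predictor is constant")

  sites <- sort(unique(ph$SITE_ID))
  site_cols <- sapply(sites, function(s) as.numeric(ph$SITE_ID == s))
  site_cols <- matrix(site_cols, nrow = nrow(ph))[, -1, drop = FALSE]
  covs <- cbind(female = as.numeric(ph$SEX == 2L), site_cols)
  if (predictor != "AGE_AT_SCAN") {
    covs <- cbind(age = ph$AGE_AT_SCAN, covs)
  }

  rows <- list(); scatter <- list()
  for (k in seq_along(masks)) {
    ai_mean <- extract_cluster_means(maps, masks[[k]])
    pc <- partial_correlation(y, ai_mean, covs)
    rows[[k]] <- data.frame(cluster = names(masks)[k], predictor = predictor,
                            n = pc$n, r = pc$r, p = pc$p,
                            stringsAsFactors = FALSE)
    scatter[[k]] <- data.frame(SUB_ID = ph$SUB_ID, ai = ai_mean,
                               score = y, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = character(0), predictor = character(0),
               n = integer(0), r = numeric(0), p = numeric(0))
  names(scatter) <- names(masks)
  attr(out, "scatter") <- scatter
  out
}
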