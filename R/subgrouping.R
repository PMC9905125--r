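#' Normalize symptom subscale scores to [0, 1]
#'
#' Each raw subscale score X is divided by its maximal value X_MAX, giving
#' three comparable values (s, v, r) for the social, verbal, and restricted
#' repetitive behavior domains. The default maxima are the instrument maxima
#' (social 30, verbal 26, RRB 12), which makes subgroup assignment
#' sample-independent; pass sample maxima to reproduce a sample-relative
#' normalization instead.
#'
#' @param social,verbal,rrb raw subscale scores (vectors recycle together).
#' @param max_scores length-3 positive maxima, in (social, verbal, rrb) order.
#' @return data.frame with columns s, v, r, each in `[0, 1]`.
#' @export
normalize_subscales <- function(social, verbal, rrb,
                                max_scores = c(30, 26, 12)) {
  if (length(max_scores) != 3L || any(!is.finite(max_scores)) ||
      any(max_scores <= 0)) {
    stop("`max_scores` must be 3 positive numbers")
  }
  if (anyNA(social) || anyNA(verbal) || anyNA(rrb)) {
    stop("all three subscale scores must be present")
  }
  if (any(social < 0) || any(verbal < 0) || any(rrb < 0) ||
      any(social > max_scores[1]) || any(verbal > max_scores[2]) ||
      any(rrb > max_scores[3])) {
    stop("scores must satisfy 0 <= X <= X_MAX")
  }
  data.frame(s = social / max_scores[1], v = verbal / max_scores[2],
             r = rrb / max_scores[3])
}

#' Assign symptom-dominance subgroups by the strict-maximum rule
#'
#' A subject whose normalized social score s is strictly greater than both v
#' and r joins SI; strictly largest v joins VA; strictly largest r joins RRB.
#' Any tie involving the maximum (s = v, s = r, or v = r at the top) leads to
#' exclusion. The rule is deterministic and invariant to evaluation order.
#'
#' @param scores data.frame with columns s, v, r (from
#'   [normalize_subscales()]), or three numbers.
#' @return character vector of labels in
#'   `c("SI", "VA", "RRB", "EXCLUDED")`.
#' @export
assign_subgroup <- function(scores) {
  if (!is.data.frame(scores)) scores <- as.data.frame(as.list(scores))
  stopifnot(all(c("s", "v", "r") %in% names(scores)) ||
            ncol(scores) == 3L)
  if (!all(c("s", "v", "r") %in% names(scores))) names(scores) <- c("s", "v", "r")
  m <- unname(as.matrix(scores[, c("s", "v", "r")]))
  apply(m, 1L, function(z) {
    mx <- max(z)
    if (sum(z == mx) > 1L) "EXCLUDED"
    else c("SI", "VA", "RRB")[which.max(z)]
  })
}

#' Subgroup a phenotype table
#'
#' Applies [normalize_subscales()] and [assign_subgroup()] to every case row
#' of a phenotype table. Instrument-agnostic: the three score columns are
#' arguments, so ADOS-based subgrouping is a column-mapping change only.
#'
#' @param pheno phenotype data.frame (see [generate_phenotypes()] for the
#'   column conventions).
#' @param columns names of the (social, verbal, rrb) score columns.
#' @param max_scores per-subscale maxima (default ADI-R instrument maxima).
#' @return data.frame with subject_id, label, s, v, r for every case row
#'   with all three scores present.
#' @export
subgroup_phenotypes <- function(pheno,
                                columns = c("ADI_R_SOCIAL_TOTAL_A",
                                            "ADI_R_VERBAL_TOTAL_BV",
                                            "ADI_RRB_TOTAL_C"),
                                max_scores = c(30, 26, 12)) {
  stopifnot(all(columns %in% names(pheno)))
  asd <- pheno[pheno$DX_GROUP == 1L &
                 stats::complete.cases(pheno[columns]), , drop = FALSE]
  ns <- normalize_subscales(asd[[columns[1]]], asd[[columns[2]]],
                            asd[[columns[3]]], max_scores)
  data.frame(subject_id = asd$SUB_ID, label = assign_subgroup(ns), ns,
             stringsAsFactors = FALSE)
}

#' Greedy matched-control selection
#'
#' For each analysis independently, walks the cases in order and selects for
#' each a uniformly random, not-yet-used control from the pool with the same
#' site, the same gender, and an age difference within `age_tolerance`
#' years. Controls are drawn without replacement within an analysis but may
#' be reused across analyses (so a control can serve several subgroup
#' comparisons). Cases with no eligible control are reported and the
#' analysis proceeds with the matched subset.
#'
#' @param cases phenotype data.frame of case records.
#' @param pool phenotype data.frame of control records (DX_GROUP 2 only).
#' @param analyses named list of case SUB_ID vectors, one per analysis.
#' @param age_tolerance maximal |age difference| in years (default 2).
#' @param seed integer seed.
#' @return named list (one element per analysis) of data.frames with columns
#'   case_id, control_id; unmatched cases carry attribute `"unmatched"`.
#' @export
match_controls <- function(cases, pool, analyses, age_tolerance = 2,
                           seed = 1L) {
  if (any(pool$DX_GROUP != 2L)) stop("`pool` must contain only control records")
  with_seed(seed, {
    out <- lapply(analyses, function(ids) {
      sel <- character(0); matched_case <- character(0)
      unmatched <- character(0)
      used <- rep(FALSE, nrow(pool))
      for (id in ids) {
        cs <- cases[cases$SUB_ID == id, ]
        if (nrow(cs) != 1L) stop("unknown or duplicated case id: ", id)
        elig <- which(!used & pool$SITE_ID == cs$SITE_ID &
                        pool$SEX == cs$SEX &
                        abs(pool$AGE_AT_SCAN - cs$AGE_AT_SCAN) <=
                          age_tolerance)
        if (length(elig) == 0L) {
          unmatched <- c(unmatched, id)
          next
        }
        pick <- if (length(elig) == 1L) elig else sample(elig, 1L)
        used[pick] <- TRUE
        sel <- c(sel, pool$SUB_ID[pick])
        matched_case <- c(matched_case, id)
      }
      res <- data.frame(case_id = matched_case, control_id = sel,
                        stringsAsFactors = FALSE)
      attr(res, "unmatched") <- unmatched
      res
    })
    names(out) <- names(analyses)
    out
  })
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Plain Pearson statistic without Yates continuity correction, df = 1,
#' upper-tail p from the chi-square(1) distribution. (The no-correction
#' choice is what reproduces standard gender-by-group tables computed in
#' mainstream statistics packages.)
#'
#' @param counts 2x2 matrix of non-negative counts.
#' @return list with `statistic`, `p`, and `df = 1`.
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop("`counts` must be 2x2")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero row or column margin")
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  stat <- sum((counts - expected)^2 / expected)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L)
}

#' Independent two-sample t test
#'
#' Student's t with pooled variance by default; set `pooled = FALSE` for the
#' Welch statistic. Two-sided p. Sign convention: positive t means group A
#' has the larger mean.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param pooled pooled-variance Student t (default) or Welch.
#' @return list with `t`, `p`, `df`.
#' @export
two_sample_t <- function(a, b, pooled = TRUE) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 observations")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1, df = na + nb - 2L))
    stop("zero variance in both groups with unequal means")
  }
  if (pooled) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (mean(a) - mean(b)) / se
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Pairwise nonparametric subscale comparison
#'
#' Kruskal-Wallis omnibus on the pooled ranks of three groups, followed by
#' Dunn's pairwise z comparisons (tie-corrected), reported as standardized
#' test statistics with Bonferroni-adjusted p values (raw p x 3, capped at
#' 1). Positive z means the first group of the pair has the larger mean
#' rank.
#'
#' @param groups list of three non-empty numeric vectors (named or not).
#' @return data.frame with columns pair, statistic, p_raw, p_bonferroni;
#'   the Kruskal-Wallis omnibus is attached as attribute `"omnibus"`.
#' @export
subscale_pairwise_nonparametric <- function(groups) {
  if (length(groups) != 3L || any(lengths(groups) == 0L)) {
    stop("`groups` must be a list of three non-empty vectors")
  }
  if (is.null(names(groups))) names(groups) <- c("G1", "G2", "G3")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  n <- length(x)
  rk <- rank(x)
  mean_rank <- tapply(rk, g, mean)[names(groups)]
  sizes <- lengths(groups)

  ties <- table(x)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n * (n + 1) / 12 - tie_term / (12 * (n - 1))

  pairs <- utils::combn(names(groups), 2L)
  res <- apply(pairs, 2L, function(pr) {
    i <- pr[1]; j <- pr[2]
    z <- (mean_rank[[i]] - mean_rank[[j]]) /
      sqrt(sigma2 * (1 / sizes[[i]] + 1 / sizes[[j]]))
    if (!is.finite(z)) z <- 0   # all observations identical
    p <- 2 * stats::pnorm(-abs(z))
    c(z = z, p = p)
  })
  out <- data.frame(pair = paste(pairs[1, ], "vs", pairs[2, ]),
                    statistic = res["z", ], p_raw = res["p", ],
                    p_bonferroni = pmin(1, 3 * res["p", ]),
                    stringsAsFactors = FALSE)
  attr(out, "omnibus") <- stats::kruskal.test(x, factor(g))
  out
}
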