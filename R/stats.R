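#' Wilcoxon rank-sum group comparison
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test. The null distribution
#' is exact (full enumeration) when both groups have fewer than 50
#' observations and the pooled sample has no ties, and a normal
#' approximation with tie and continuity corrections otherwise — the
#' default behavior of [stats::wilcox.test()], which this wraps.
#'
#' @param values_a,values_b Numeric vectors, each nonempty.
#' @return List with `statistic` (the rank sum W of group A), `u` (the
#'   Mann-Whitney U), `p_value`, `exact` (logical), `group_means`,
#'   `group_sds`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value  # exact 0.1
#' @export
wilcoxon_rank_sum <- function(values_a, values_b) {
  if (length(values_a) == 0L || length(values_b) == 0L)
    stop("both groups must be nonempty", call. = FALSE)
  m <- length(values_a)
  ties <- anyDuplicated(c(values_a, values_b)) > 0L
  exact <- m < 50 && length(values_b) < 50 && !ties
  if (length(unique(c(values_a, values_b))) == 1L) {
    # fully tied pooled sample: no evidence either way (the normal
    # approximation is 0/0 here)
    return(list(statistic = sum(rank(c(values_a, values_b))[seq_len(m)]),
                u = m * length(values_b) / 2, p_value = 1, exact = FALSE,
                group_means = c(a = mean(values_a), b = mean(values_b)),
                group_sds = c(a = stats::sd(values_a), b = stats::sd(values_b))))
  }
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            alternative = "two.sided"))
  u <- unname(wt$statistic)
  list(statistic = u + m * (m + 1) / 2,
       u = u,
       p_value = wt$p.value,
       exact = exact,
       group_means = c(a = mean(values_a), b = mean(values_b)),
       group_sds = c(a = stats::sd(values_a), b = stats::sd(values_b)))
}

#' Simple linear regression of contrast on age
#'
#' Ordinary least squares of `values ~ ages`, reporting the slope,
#' intercept, coefficient of determination `R^2 = 1 - SSE/SST`, and the
#' two-sided t-test p-value for the slope (n - 2 df). A response with zero
#' variance is degenerate: `R^2 = 0`, `p = 1`.
#'
#' @param values Response (percent contrast), length >= 3.
#' @param ages Predictor (years); must not all be equal.
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`,
#'   `degenerate`.
#' @export
linreg_age <- function(values, ages) {
  if (length(values) != length(ages)) stop("length mismatch", call. = FALSE)
  if (length(values) < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::var(ages) == 0) stop("ages must not all be equal", call. = FALSE)
  if (stats::var(values) == 0) {
    return(list(slope = 0, intercept = values[1], r_squared = 0,
                p_value = 1, degenerate = TRUE))
  }
  fit <- stats::lm(values ~ ages)
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]),
       degenerate = FALSE)
}

#' Volume-contrast correlations
#'
#' Per group and tissue, OLS of whole-brain mean contrast on the normalized
#' tissue volume fraction, with R^2. Rows with missing fractions are
#' dropped (their count is reported).
#'
#' @param cohort A cohort table from [run_pipeline()] /
#'   [build_cohort_table()]: one row per subject x region with columns
#'   `subject_id`, `group`, `region`, `mean_percent`, `gm_fraction`,
#'   `wm_fraction`.
#' @return data.frame with one row per group x tissue: `group`, `tissue`,
#'   `slope`, `intercept`, `r_squared`, `p_value`, `n`, `n_dropped`.
#' @export
volume_contrast_correlation <- function(cohort) {
  wb <- cohort[cohort$region == "WholeBrain", ]
  rows <- list()
  for (g in unique(wb$group)) {
    for (tissue in c("gm_fraction", "wm_fraction")) {
      sub <- wb[wb$group == g, c("mean_percent", tissue)]
      keep <- stats::complete.cases(sub)
      n_drop <- sum(!keep)
      sub <- sub[keep, ]
      fit <- if (nrow(sub) >= 3 && stats::var(sub[[tissue]]) > 0) {
        linreg_age(sub$mean_percent, sub[[tissue]])
      } else {
        # identical geometry (or too few subjects): correlation undefined
        list(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
             p_value = NA_real_)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, tissue = sub("_fraction", "", tissue),
        slope = fit$slope, intercept = fit$intercept,
        r_squared = fit$r_squared, p_value = fit$p_value,
        n = nrow(sub), n_dropped = n_drop, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Cohort results bundle
#'
#' Builds the study's summary outputs from a per-subject regional table:
#' a group-comparison table (one row per region x group with mean, SD and
#' the two-sided Wilcoxon rank-sum p for the group contrast), per-group
#' age regressions for GM, WM and the seven cortical regions, and the
#' volume-contrast correlations. No multiple-testing correction is applied;
#' p-values are per-region.
#'
#' @param cohort Cohort table: one row per subject x region with columns
#'   `subject_id`, `group`, `age`, `region`, `mean_percent` (and
#'   `gm_fraction`/`wm_fraction` for the volume correlations).
#' @param drop_threshold Regions observed in fewer than this fraction of
#'   subjects are excluded with a warning.
#' @return List of class `cohort_results` with `table1` (data.frame:
#'   region, group, mean, sd, n, p_value, low_confidence),
#'   `age_regressions` (region, group, slope, intercept, r_squared,
#'   p_value, n) and `volume_correlations`.
#' @export
build_results_table <- function(cohort, drop_threshold = 0.5) {
  needed <- c("subject_id", "group", "age", "region", "mean_percent")
  if (!all(needed %in% names(cohort)))
    stop("cohort table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  n_subj <- length(unique(cohort$subject_id))
  groups <- c("non-smoker", "smoker")

  t1 <- list(); reg <- list()
  for (r in region_names()) {
    sub <- cohort[cohort$region == r & is.finite(cohort$mean_percent), ]
    if (nrow(sub) < drop_threshold * n_subj) {
      warning("region ", r, " observed for fewer than half the subjects; excluded")
      next
    }
    va <- sub$mean_percent[sub$group == groups[1]]
    vb <- sub$mean_percent[sub$group == groups[2]]
    wt <- wilcoxon_rank_sum(va, vb)
    low <- if ("low_confidence" %in% names(sub)) any(sub$low_confidence) else FALSE
    t1[[r]] <- data.frame(
      region = r, group = groups,
      mean = c(mean(va), mean(vb)), sd = c(stats::sd(va), stats::sd(vb)),
      n = c(length(va), length(vb)),
      p_value = wt$p_value, low_confidence = low, stringsAsFactors = FALSE)
    if (r != "WholeBrain") {
      for (g in groups) {
        gs <- sub[sub$group == g, ]
        fit <- linreg_age(gs$mean_percent, gs$age)
        reg[[paste(r, g)]] <- data.frame(
          region = r, group = g, slope = fit$slope, intercept = fit$intercept,
          r_squared = fit$r_squared, p_value = fit$p_value, n = nrow(gs),
          stringsAsFactors = FALSE)
      }
    }
  }
  vols <- if (all(c("gm_fraction", "wm_fraction") %in% names(cohort)))
    volume_contrast_correlation(cohort) else NULL
  structure(list(table1 = do.call(rbind, c(t1, list(make.row.names = FALSE))),
                 age_regressions = do.call(rbind, c(reg, list(make.row.names = FALSE))),
                 volume_correlations = vols),
            class = "cohort_results")
}

#' @export
print.cohort_results <- function(x, ...) {
  cat("Cohort results: group comparisons\n")
  print(x$table1, digits = 3)
  cat("\nAge regressions\n")
  print(x$age_regressions, digits = 3)
  if (!is.null(x$volume_correlations)) {
    cat("\nVolume-contrast correlations\n")
    print(x$volume_correlations, digits = 3)
  }
  invisible(x)
}

#' Exact null distribution of the two-sided Wilcoxon rank-sum p-value
#'
#' For group sizes `m` and `n` without ties, the exact two-sided p-value is
#' a discrete statistic; this returns its support and null probabilities
#' (from the exact Mann-Whitney U distribution). Used to assess the
#' calibration of the group-comparison p-values: the probability-integral
#' transform of observed p-values against this distribution (randomized
#' across each atom) is exactly uniform under the null, which a direct
#' comparison of discrete p-values to the uniform is not.
#'
#' @param m,n Group sizes.
#' @return data.frame with columns `p` (ascending support) and `prob`.
#' @export
wilcoxon_exact_p_null <- function(m, n) {
  u <- 0:(m * n)
  # the two-sided p of u equals that of its mirror m*n - u (symmetric null);
  # evaluate on the lower tail only so mirrored atoms aggregate exactly
  p2 <- pmin(1, 2 * stats::pwilcox(pmin(u, m * n - u), m, n))
  prob <- stats::dwilcox(u, m, n)
  ord <- order(p2)
  p_sorted <- p2[ord]
  grp <- cumsum(c(TRUE, diff(p_sorted) > 0))
  data.frame(p = p_sorted[!duplicated(grp)],
             prob = as.numeric(tapply(prob[ord], grp, sum)))
}

#' Randomized PIT of exact Wilcoxon p-values against their null
#'
#' Maps each observed exact two-sided p-value to
#' `F(p-) + V * Pr(p)` with `V ~ U(0,1)`, using the exact discrete null of
#' [wilcoxon_exact_p_null()]; the result is exactly U(0,1) under the null
#' hypothesis, making uniformity tests applicable despite the discreteness.
#'
#' @param p Observed exact two-sided p-values.
#' @param m,n Group sizes used for every element of `p`.
#' @return Numeric vector of PIT values in (0, 1).
#' @export
wilcoxon_p_pit <- function(p, m, n) {
  null <- wilcoxon_exact_p_null(m, n)
  cdf <- cumsum(null$prob)
  idx <- vapply(p, function(x) which.min(abs(null$p - x)), integer(1))
  if (any(abs(null$p[idx] - p) > 1e-8))
    stop("p-values do not lie on the exact null support; were there ties?",
         call. = FALSE)
  lower <- c(0, cdf)[idx]
  lower + stats::runif(length(p)) * null$prob[idx]
}
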