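# Relative-validity and test-retest reliability battery: Bland-Altman,
# paired t, de-attenuation, kappa, cross-classification, Cronbach's alpha,
# skewness, boxplot outlier screen, limits-of-agreement sample size.

#' Bland-Altman agreement analysis
#'
#' Differences are \code{a - b}; the limits of agreement are
#' \code{bias +/- z * sd(diff)} with the n-1 SD denominator and z = 1.96.
#' Proportional bias is the least-squares slope of the differences on the
#' pair means, with its two-sided p-value.
#'
#' @param a,b paired measurements (mg/day), equal length n >= 3, no missing
#'   values.
#' @param z quantile for the limits (default 1.96).
#' @return object of class \code{bland_altman}: \code{bias}, \code{sd_diff},
#'   \code{loa_lower}, \code{loa_upper}, \code{pct_within_loa},
#'   \code{prop_bias_slope}, \code{prop_bias_p} (slope and p are NA, with
#'   \code{zero_variance = TRUE}, when the differences are constant),
#'   \code{n}.
#' @export
bland_altman <- function(a, b, z = 1.96) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 3) stop("need at least 3 pairs")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("missing pairs not allowed")
  d <- a - b
  m <- (a + b) / 2
  bias <- mean(d)
  sd_d <- stats::sd(d)
  lo <- bias - z * sd_d
  hi <- bias + z * sd_d
  zero_var <- sd_d == 0
  if (zero_var || stats::var(m) == 0) {
    slope <- NA_real_
    slope_p <- NA_real_
  } else {
    fit <- stats::lm(d ~ m)
    cf <- summary(fit)$coefficients
    slope <- cf["m", "Estimate"]
    slope_p <- cf["m", "Pr(>|t|)"]
  }
  structure(list(n = length(d), bias = bias, sd_diff = sd_d,
                 loa_lower = lo, loa_upper = hi,
                 pct_within_loa = 100 * mean(d >= lo & d <= hi),
                 prop_bias_slope = slope, prop_bias_p = slope_p,
                 zero_variance = zero_var),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.1f +/- %.1f mg/day\n",
              x$n, x$bias, x$sd_diff))
  cat(sprintf("  limits of agreement: [%.1f, %.1f]; %.0f%% of points within\n",
              x$loa_lower, x$loa_upper, x$pct_within_loa))
  if (!is.na(x$prop_bias_slope))
    cat(sprintf("  proportional bias slope %.3f (p = %.3f)\n",
                x$prop_bias_slope, x$prop_bias_p))
  invisible(x)
}

#' Paired t test with original-scale effect summaries
#'
#' The t statistic and p-value are computed on the (optionally transformed)
#' pairs; skewed intake data are square-root transformed by default before
#' testing. The mean difference, percent mean difference and Cohen's d
#' (mean difference / SD of differences) are always reported on the original
#' mg/day scale.
#'
#' @param a,b paired measurements, equal length n >= 2.
#' @param transform \code{"sqrt"} (default for intakes), \code{"none"} or
#'   \code{"log"} (natural log; requires strictly positive data).
#' @return object of class \code{paired_test}: \code{t_stat}, \code{df},
#'   \code{p_value}, \code{mean_diff}, \code{pct_mean_diff}, \code{cohen_d},
#'   \code{transform}, \code{zero_variance}.
#' @export
paired_t <- function(a, b, transform = c("sqrt", "none", "log")) {
  transform <- match.arg(transform)
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 2) stop("need at least 2 pairs")
  ta <- switch(transform,
               none = a,
               sqrt = { if (any(a < 0) || any(b < 0))
                 stop("sqrt transform needs non-negative data"); sqrt(a) },
               log = { if (any(a <= 0) || any(b <= 0))
                 stop("log transform needs positive data"); log(a) })
  tb <- switch(transform, none = b, sqrt = sqrt(b), log = log(b))
  d_orig <- a - b
  mean_diff <- mean(d_orig)
  sd_orig <- stats::sd(d_orig)
  zero_var <- stats::sd(ta - tb) == 0
  if (zero_var) {
    t_stat <- NA_real_
    p <- NA_real_
  } else {
    tt <- stats::t.test(ta, tb, paired = TRUE)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(list(t_stat = t_stat, df = length(a) - 1L, p_value = p,
                 mean_diff = mean_diff,
                 pct_mean_diff = if (mean(b) != 0)
                   pct_mean_difference(mean(a), mean(b)) else NA_real_,
                 cohen_d = if (sd_orig > 0) mean_diff / sd_orig
                           else if (mean_diff == 0) 0 else NA_real_,
                 transform = transform, zero_variance = zero_var),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("Paired t (%s scale): t(%d) = %s, p = %s\n", x$transform, x$df,
              format(round(x$t_stat, 3)), format.pval(x$p_value, digits = 3)))
  cat(sprintf("  mean difference %.1f mg/day (%.1f%%), Cohen's d = %.3f\n",
              x$mean_diff, x$pct_mean_diff, x$cohen_d))
  invisible(x)
}

#' Percent mean difference between two methods
#'
#' \code{(mean_a - mean_b) / mean_b * 100}, the relative bias of method a
#' against reference method b.
#'
#' @param mean_a,mean_b method means (mg/day); \code{mean_b} must be nonzero.
#' @return percent.
#' @export
pct_mean_difference <- function(mean_a, mean_b) {
  if (any(mean_b == 0)) stop("reference mean must be nonzero")
  (mean_a - mean_b) / mean_b * 100
}

#' Cohen's d for paired differences
#'
#' @param mean_diff mean of the paired differences.
#' @param sd_diff standard deviation of the paired differences (> 0).
#' @return dimensionless effect size \code{mean_diff / sd_diff}.
#' @export
cohens_d <- function(mean_diff, sd_diff) {
  if (any(sd_diff <= 0)) stop("sd_diff must be > 0")
  mean_diff / sd_diff
}

#' De-attenuate an observed correlation for replicate error
#'
#' Corrects a correlation against a replicate-based reference (mean of
#' \code{n_replicates} repeats) for the random day-to-day error in that
#' reference: \code{r_c = r_o * sqrt(1 + lambda / n_replicates)}, where
#' lambda is the within/between-person variance ratio of the replicates.
#' The result is clipped to [-1, 1]; attribute \code{"clipped"} records
#' whether clipping occurred.
#'
#' @param r_observed observed correlation in [-1, 1].
#' @param lambda_ratio within/between variance ratio >= 0 (see
#'   \code{\link{variance_components}}).
#' @param n_replicates number of replicates averaged in the reference (>= 1).
#' @return corrected correlation (numeric, with attribute \code{clipped}).
#' @examples
#' deattenuate(0.202, 0.49, 3) # 0.2179
#' @export
deattenuate <- function(r_observed, lambda_ratio, n_replicates) {
  if (!is.finite(r_observed) || abs(r_observed) > 1)
    stop("r_observed must lie in [-1, 1]")
  if (!is.finite(lambda_ratio) || lambda_ratio < 0)
    stop("lambda_ratio must be >= 0")
  if (!is.finite(n_replicates) || n_replicates < 1)
    stop("n_replicates must be >= 1")
  r <- r_observed * sqrt(1 + lambda_ratio / n_replicates)
  clipped <- abs(r) > 1
  r <- max(-1, min(1, r))
  attr(r, "clipped") <- clipped
  r
}

# Landis-Koch qualitative band for a kappa value
kappa_band <- function(kappa) {
  if (is.na(kappa)) return(NA_character_)
  if (kappa == 1) "perfect"
  else if (kappa > 0.80) "almost perfect"
  else if (kappa > 0.60) "substantial"
  else if (kappa > 0.40) "moderate"
  else if (kappa > 0.20) "fair"
  else "poor"
}

#' Cohen's kappa for a classification agreement table
#'
#' Chance-corrected agreement \code{(p_o - p_e) / (1 - p_e)} with observed
#' agreement \code{p_o} (diagonal share) and expected agreement \code{p_e}
#' from the marginal products. Significance against kappa = 0 uses the
#' standard large-sample z test. The qualitative label follows the
#' Landis-Koch bands (<= 0.20 poor, 0.21-0.40 fair, 0.41-0.60 moderate,
#' 0.61-0.80 substantial, 0.81-0.99 almost perfect, 1 perfect).
#'
#' @param x square contingency table of counts (matrix), or a factor/vector
#'   of classifications to cross with \code{y}.
#' @param y optional second classification vector when \code{x} is not a
#'   table.
#' @return object of class \code{kappa_result}: \code{kappa}, \code{z},
#'   \code{p_value}, \code{p_observed}, \code{p_expected},
#'   \code{band_label}, \code{n}, \code{table}. \code{kappa} is NA (flagged
#'   \code{undefined = TRUE}) when expected agreement is 1.
#' @examples
#' cohens_kappa(matrix(c(20, 19, 17, 44), nrow = 2))
#' @export
cohens_kappa <- function(x, y = NULL) {
  if (!is.null(y)) {
    lev <- union(unique(as.character(x)), unique(as.character(y)))
    tab <- table(factor(as.character(x), levels = lev),
                 factor(as.character(y), levels = lev))
    tab <- unclass(as.matrix(tab))
  } else {
    tab <- as.matrix(x)
  }
  if (nrow(tab) != ncol(tab)) stop("agreement table must be square")
  if (any(tab < 0)) stop("counts must be >= 0")
  n <- sum(tab)
  if (n <= 0) stop("table total must be > 0")
  p <- tab / n
  po <- sum(diag(p))
  prow <- rowSums(p)
  pcol <- colSums(p)
  pe <- sum(prow * pcol)
  if (pe >= 1) {
    return(structure(list(kappa = NA_real_, z = NA_real_, p_value = NA_real_,
                          p_observed = po, p_expected = pe,
                          band_label = NA_character_, n = n, table = tab,
                          undefined = TRUE),
                     class = "kappa_result"))
  }
  kap <- (po - pe) / (1 - pe)
  # large-sample SE of kappa under H0: kappa = 0 (Fleiss)
  se0 <- sqrt(pe + pe^2 - sum(prow * pcol * (prow + pcol))) /
    ((1 - pe) * sqrt(n))
  z <- if (se0 > 0) kap / se0 else NA_real_
  structure(list(kappa = kap, z = z,
                 p_value = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)),
                 p_observed = po, p_expected = pe,
                 band_label = kappa_band(kap), n = n, table = tab,
                 undefined = FALSE),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (%s), p = %s\n", x$kappa, x$band_label,
              format.pval(x$p_value, digits = 3)))
  cat(sprintf("  observed agreement %.1f%%, expected %.1f%% (n = %d)\n",
              100 * x$p_observed, 100 * x$p_expected, x$n))
  invisible(x)
}

#' Quartile cross-classification of two methods
#'
#' Tabulates joint quartile membership and reports the share classified into
#' the same quartile, the same or an adjacent quartile, and grossly
#' misclassified (opposite extreme quartiles).
#'
#' @param qa,qb integer quartile labels in 1..4, equal length.
#' @return object of class \code{cross_classification}: \code{joint_table}
#'   (4x4 counts, rows = \code{qa}), \code{pct_same},
#'   \code{pct_same_or_adjacent}, \code{pct_gross}, \code{n}.
#' @export
cross_classify <- function(qa, qb) {
  if (length(qa) != length(qb)) stop("label vectors must have equal length")
  if (!all(qa %in% 1:4) || !all(qb %in% 1:4))
    stop("quartile labels must be in 1..4")
  tab <- unclass(as.matrix(table(factor(qa, levels = 1:4),
                                 factor(qb, levels = 1:4))))
  dimnames(tab) <- list(paste0("a_q", 1:4), paste0("b_q", 1:4))
  dd <- abs(qa - qb)
  n <- length(qa)
  structure(list(joint_table = tab,
                 pct_same = 100 * mean(dd == 0),
                 pct_same_or_adjacent = 100 * mean(dd <= 1),
                 pct_gross = 100 * mean(dd == 3),
                 n = n),
            class = "cross_classification")
}

#' @export
print.cross_classification <- function(x, ...) {
  cat(sprintf("Cross-classification (n = %d): %.0f%% same, %.0f%% same or adjacent, %.0f%% gross\n",
              x$n, x$pct_same, x$pct_same_or_adjacent, x$pct_gross))
  print(x$joint_table)
  invisible(x)
}

#' Cronbach's alpha
#'
#' Internal consistency of an item battery:
#' \code{alpha = k/(k-1) * (1 - sum(item variances) / var(total))}, with
#' n-1 variance denominators.
#'
#' @param item_matrix numeric matrix, participants x items (>= 2 of each);
#'   for a scored screener, the per-item mg/day contributions.
#' @return alpha in (-Inf, 1].
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 participants and >= 2 items")
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) stop("zero total-score variance; alpha undefined")
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

#' Sample skewness with standard error
#'
#' Adjusted Fisher-Pearson skewness
#' \code{G1 = sqrt(n(n-1))/(n-2) * m3/m2^(3/2)} (moment estimators with n
#' denominators) and its large-sample standard error
#' \code{sqrt(6n(n-1) / ((n-2)(n+1)(n+3)))}.
#'
#' @param x numeric vector, length >= 3.
#' @return list with \code{skewness} (NA, with \code{zero_variance = TRUE},
#'   for constant data), \code{se}, \code{n}.
#' @export
skewness_with_se <- function(x) {
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  se <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0)
    return(list(skewness = NA_real_, se = se, n = n, zero_variance = TRUE))
  m3 <- mean((x - mean(x))^3)
  g1 <- m3 / m2^1.5
  list(skewness = sqrt(n * (n - 1)) / (n - 2) * g1, se = se, n = n,
       zero_variance = FALSE)
}

#' Boxplot outlier screen
#'
#' Flags values more than 1.5 interquartile ranges outside the quartiles
#' (outliers) and more than 3 IQRs outside (extreme values), the standard
#' boxplot fences used to screen intake data before analysis.
#'
#' @param x numeric vector, length >= 4.
#' @return list with integer index vectors \code{outliers} and
#'   \code{extremes} and the \code{fences} used.
#' @export
boxplot_outliers <- function(x) {
  if (length(x) < 4) stop("need at least 4 observations")
  q <- stats::quantile(x, probs = c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  out_lo <- q[1] - 1.5 * iqr; out_hi <- q[2] + 1.5 * iqr
  ext_lo <- q[1] - 3 * iqr;   ext_hi <- q[2] + 3 * iqr
  list(outliers = which(x < out_lo | x > out_hi),
       extremes = which(x < ext_lo | x > ext_hi),
       fences = c(outlier_lower = out_lo, outlier_upper = out_hi,
                  extreme_lower = ext_lo, extreme_upper = ext_hi))
}

#' Sample size for estimating a Bland-Altman limit of agreement
#'
#' Smallest n >= 3 for which the coefficient of variation of the estimated
#' lower limit of agreement is at or below a target, using
#' \code{SE(limit) = sd_diff * sqrt(1/n + z^2 / (2(n-1)))} and
#' \code{CV = SE / |expected_diff - z * sd_diff|}. The CV is strictly
#' decreasing in n, so the search returns the minimal n.
#'
#' @param expected_diff anticipated mean difference between methods (mg/day).
#' @param sd_diff anticipated SD of the differences (> 0).
#' @param cv_target target coefficient of variation, in (0, 1).
#' @param z limit quantile (default 1.96).
#' @return integer sample size.
#' @examples
#' ba_sample_size(75, 457, 0.10)
#' @export
ba_sample_size <- function(expected_diff, sd_diff, cv_target = 0.10, z = 1.96) {
  if (sd_diff <= 0) stop("sd_diff must be > 0")
  if (cv_target <= 0 || cv_target >= 1) stop("cv_target must be in (0, 1)")
  limit <- abs(expected_diff - z * sd_diff)
  if (limit == 0) stop("lower limit of agreement is 0; CV undefined")
  cv_at <- function(n) sd_diff * sqrt(1 / n + z^2 / (2 * (n - 1))) / limit
  n <- 3
  while (cv_at(n) > cv_target) {
    n <- n + 1
    if (n > 1e6) stop("no attainable sample size below 1e6")
  }
  as.integer(n)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' large-sample t approximation (appropriate with ties).
#'
#' @param x,y numeric vectors, equal length n >= 3.
#' @return list with \code{rho}, \code{p_value}, \code{n}; \code{rho} is NA
#'   (flagged) when either vector is constant.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x),
                undefined = TRUE))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       undefined = FALSE)
}
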