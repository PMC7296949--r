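# Bundled validity/reliability report for a screener cohort: the screener's
# second administration against the recall reference (relative validity) and
# the first against the second administration (test-retest reliability).

# align a named numeric intake vector out of score_responses output / df
intake_vector <- function(x, what) {
  if (is.data.frame(x)) {
    need <- c("participant_id", "sodium_mg_day")
    if (!all(need %in% names(x)))
      stop(what, " must have columns participant_id and sodium_mg_day")
    stats::setNames(x$sodium_mg_day, as.character(x$participant_id))
  } else if (is.numeric(x) && !is.null(names(x))) {
    x
  } else stop(what, " must be a scored data.frame or a named numeric vector")
}

# Pearson correlation on log scale; pairs with a nonpositive member are
# dropped (screener scores of 0 carry no log-scale information).
pearson_log <- function(a, b) {
  ok <- a > 0 & b > 0
  if (sum(ok) < 3) stop("fewer than 3 positive pairs for log-scale correlation")
  ct <- stats::cor.test(log(a[ok]), log(b[ok]), method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n_used = sum(ok))
}

#' Full validity and reliability report
#'
#' Runs the complete statistical battery for a validation cohort. The
#' validity block compares the retest (second) screener administration with
#' the mean of the repeated recalls: Bland-Altman agreement, a paired t test
#' on the square-root scale, Pearson correlation on the log scale with
#' de-attenuation for recall replicate error, Cohen's kappa for the binary
#' UL classification, and quartile cross-classification. The reliability
#' block compares the two screener administrations (Bland-Altman, paired t,
#' log-scale Pearson, kappa) and adds Cronbach's alpha on the per-item
#' contributions when supplied.
#'
#' @param test_intakes,retest_intakes first and second screener
#'   administrations: output of \code{\link{score_responses}} (or a named
#'   mg/day vector).
#' @param recalls recall cohort (long data.frame or matrix, see
#'   \code{\link{recall_means}}).
#' @param item_contributions optional participants x items mg/day matrix
#'   (e.g. \code{\link{item_contributions}} of the scored first
#'   administration) for Cronbach's alpha.
#' @param ul_threshold classification threshold, mg/day.
#' @return object of class \code{validation_report}.
#' @export
validation_report <- function(test_intakes, retest_intakes, recalls,
                              item_contributions = NULL,
                              ul_threshold = 2300) {
  t1 <- intake_vector(test_intakes, "test_intakes")
  t2 <- intake_vector(retest_intakes, "retest_intakes")
  rm_df <- recall_means(recalls)
  ref <- stats::setNames(rm_df$mean_mg_day, rm_df$participant_id)
  common <- Reduce(intersect, list(names(t1), names(t2), names(ref)))
  if (length(common) < 3) stop("fewer than 3 participants common to all inputs")
  t1 <- t1[common]; t2 <- t2[common]; ref <- ref[common]

  vc <- variance_components(recalls)
  k <- vc$k
  lam <- vc$ratio_lambda

  plog_v <- pearson_log(t2, ref)
  r_c <- if (is.na(lam)) NA_real_ else deattenuate(plog_v$r, lam, k)
  validity <- list(
    mean_retest = mean(t2), sd_retest = stats::sd(t2),
    mean_reference = mean(ref), sd_reference = stats::sd(ref),
    mean_difference_mg = mean(t2) - mean(ref),
    pct_mean_difference = pct_mean_difference(mean(t2), mean(ref)),
    bland_altman = bland_altman(t2, ref),
    paired_t = paired_t(t2, ref, transform = "sqrt"),
    pearson_log = plog_v,
    deattenuation = list(lambda_ratio = lam, n_replicates = k,
                         r_deattenuated = as.numeric(r_c),
                         clipped = isTRUE(attr(r_c, "clipped"))),
    kappa_ul = cohens_kappa(classify_ul(t2, ul_threshold),
                            classify_ul(ref, ul_threshold)),
    cross_classification = cross_classify(assign_quartiles(t2),
                                          assign_quartiles(ref))
  )

  plog_r <- pearson_log(t1, t2)
  reliability <- list(
    mean_test = mean(t1), sd_test = stats::sd(t1),
    mean_retest = mean(t2), sd_retest = stats::sd(t2),
    mean_difference_mg = mean(t1) - mean(t2),
    pct_mean_difference = pct_mean_difference(mean(t1), mean(t2)),
    bland_altman = bland_altman(t1, t2),
    paired_t = paired_t(t1, t2, transform = "sqrt"),
    pearson_log = plog_r,
    kappa_ul = cohens_kappa(classify_ul(t1, ul_threshold),
                            classify_ul(t2, ul_threshold)),
    cronbach_alpha = if (is.null(item_contributions)) NA_real_ else
      cronbach_alpha(item_contributions[rownames(item_contributions) %in% common, ,
                                        drop = FALSE])
  )

  structure(list(n = length(common), ul_threshold_mg = ul_threshold,
                 n_recalls = k,
                 variance_components = list(s2_within = vc$s2_within,
                                            s2_between = vc$s2_between,
                                            ratio_lambda = lam),
                 validity = validity, reliability = reliability),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Screener validation report (n = ", x$n, ", UL threshold ",
      x$ul_threshold_mg, " mg/day)\n", sep = "")
  v <- x$validity
  cat(sprintf("Validity (retest screener vs mean of %d recalls):\n", x$n_recalls))
  cat(sprintf("  means %.0f vs %.0f mg/day; bias %.1f (LoA %.0f to %.0f)\n",
              v$mean_retest, v$mean_reference, v$bland_altman$bias,
              v$bland_altman$loa_lower, v$bland_altman$loa_upper))
  cat(sprintf("  log-scale r = %.3f (de-attenuated %.3f); kappa = %.3f (%s)\n",
              v$pearson_log$r, v$deattenuation$r_deattenuated,
              v$kappa_ul$kappa, v$kappa_ul$band_label))
  cat(sprintf("  quartiles: %.0f%% same or adjacent, %.0f%% gross\n",
              v$cross_classification$pct_same_or_adjacent,
              v$cross_classification$pct_gross))
  r <- x$reliability
  cat("Reliability (test vs retest administration):\n")
  cat(sprintf("  means %.0f vs %.0f mg/day; bias %.1f; r = %.3f; kappa = %.3f (%s)\n",
              r$mean_test, r$mean_retest, r$bland_altman$bias,
              r$pearson_log$r, r$kappa_ul$kappa, r$kappa_ul$band_label))
  if (!is.na(r$cronbach_alpha))
    cat(sprintf("  Cronbach's alpha = %.3f\n", r$cronbach_alpha))
  invisible(x)
}

# strip classes recursively so jsonlite serializes plainly
strip_classes <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, strip_classes)
  } else if (is.matrix(x)) {
    unname(x)
  } else {
    x
  }
}

#' Serialize / restore a validation report
#'
#' Reports round-trip through structured JSON; matrices (agreement and
#' cross-classification tables) are stored as nested arrays.
#'
#' @param report a \code{validation_report}.
#' @param path output (input) JSON path.
#' @return \code{write_validation_report}: \code{path}, invisibly;
#'   \code{read_validation_report}: the restored report.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  jsonlite::write_json(strip_classes(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", null = "null")
  invisible(path)
}

#' @rdname write_validation_report
#' @export
read_validation_report <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  structure(x, class = "validation_report")
}
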