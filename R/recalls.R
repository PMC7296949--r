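# Reference method: repeated 24-h recalls. Per-participant means,
# within/between-person variance components from the balanced one-way
# random-effects layout, and a shrinkage adjustment toward usual intake.

# Accepts a long data.frame (participant_id, recall_index, sodium_mg_day) or
# a participants x recalls matrix; returns the matrix form.
as_recall_matrix <- function(recalls) {
  if (is.matrix(recalls)) {
    m <- recalls
  } else {
    need <- c("participant_id", "sodium_mg_day")
    if (!all(need %in% names(recalls)))
      stop("recalls must have columns participant_id, recall_index, sodium_mg_day")
    pids <- unique(recalls$participant_id)
    ks <- table(recalls$participant_id)
    if (length(unique(as.integer(ks))) != 1)
      stop("unbalanced recall design: all participants need the same number of recalls")
    k <- as.integer(ks[1])
    ord <- if ("recall_index" %in% names(recalls))
      order(match(recalls$participant_id, pids), recalls$recall_index)
    else order(match(recalls$participant_id, pids))
    x <- recalls[ord, ]
    m <- matrix(x$sodium_mg_day, nrow = length(pids), ncol = k, byrow = TRUE,
                dimnames = list(pids, NULL))
  }
  if (any(!is.finite(m)) || any(m < 0))
    stop("recall intakes must be finite and >= 0")
  m
}

#' Mean of a participant's repeated recalls
#'
#' The unweighted arithmetic mean of the daily sodium intakes, the reference
#' quantity ("m24HR" for a three-recall design) used in validation.
#'
#' @param series numeric vector of daily sodium intakes (mg/day), length >= 1.
#' @return mg/day.
#' @export
mean_recall <- function(series) {
  if (length(series) == 0) stop("empty recall series")
  if (any(!is.finite(series)) || any(series < 0))
    stop("recall intakes must be finite and >= 0")
  mean(series)
}

#' Per-participant recall means for a cohort
#'
#' @param recalls long data.frame (\code{participant_id},
#'   \code{recall_index}, \code{sodium_mg_day}) or participants x recalls
#'   matrix.
#' @return data.frame with columns \code{participant_id},
#'   \code{mean_mg_day}.
#' @export
recall_means <- function(recalls) {
  m <- as_recall_matrix(recalls)
  data.frame(participant_id = rownames(m), mean_mg_day = rowMeans(m),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Within/between-person variance components of repeated recalls
#'
#' One-way random-effects decomposition for the balanced design: the
#' within-person component is the within mean square (day-to-day variation);
#' the between-person component is the moment estimator
#' \code{(MSB - MSW) / k}, truncated at zero. Their ratio (lambda) drives
#' de-attenuation of observed correlations.
#'
#' @inheritParams recall_means
#' @return object of class \code{variance_components}: list with
#'   \code{s2_within}, \code{s2_between}, \code{ratio_lambda} (NA when the
#'   between component is zero), \code{msb}, \code{msw}, \code{k}, \code{n}.
#' @export
variance_components <- function(recalls) {
  m <- as_recall_matrix(recalls)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2) stop("need at least 2 participants")
  if (k < 2) stop("need at least 2 recalls per participant")
  pm <- rowMeans(m)
  grand <- mean(m)
  msw <- sum((m - pm)^2) / (n * (k - 1))
  msb <- k * sum((pm - grand)^2) / (n - 1)
  s2b <- max(0, (msb - msw) / k)
  structure(list(s2_within = msw,
                 s2_between = s2b,
                 ratio_lambda = if (s2b > 0) msw / s2b else NA_real_,
                 msb = msb, msw = msw, k = k, n = n),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Recall variance components (n = ", x$n, ", k = ", x$k, ")\n", sep = "")
  cat(sprintf("  within-person  s2w: %.1f\n", x$s2_within))
  cat(sprintf("  between-person s2b: %.1f\n", x$s2_between))
  cat(sprintf("  ratio s2w/s2b:      %s\n",
              if (is.na(x$ratio_lambda)) "undefined" else
                sprintf("%.3f", x$ratio_lambda)))
  invisible(x)
}

#' Shrinkage adjustment of recall means toward usual intake
#'
#' Shrinks each participant's recall mean toward the cohort mean by the
#' reliability factor \code{sqrt(s2b / (s2b + s2w/k))}, removing the excess
#' spread that day-to-day variation adds to observed means. The cohort mean
#' is preserved; the adjusted spread equals the spread of raw means times the
#' shrinkage factor. This is the classic best-linear approximation to usual
#' intake for a balanced design (distribution-estimation software implements
#' a transformed-scale refinement of the same idea).
#'
#' @inheritParams recall_means
#' @param vc variance components for the same cohort; computed from
#'   \code{recalls} when omitted.
#' @return data.frame with \code{participant_id}, \code{mean_mg_day},
#'   \code{adjusted_mg_day}.
#' @export
usual_intake_adjust <- function(recalls, vc = NULL) {
  m <- as_recall_matrix(recalls)
  if (is.null(vc)) vc <- variance_components(m)
  stopifnot(inherits(vc, "variance_components"))
  denom <- vc$s2_between + vc$s2_within / vc$k
  if (denom <= 0) stop("degenerate variance components: nothing to adjust")
  shrink <- sqrt(vc$s2_between / denom)
  pm <- rowMeans(m)
  grand <- mean(pm)
  data.frame(participant_id = rownames(m),
             mean_mg_day = pm,
             adjusted_mg_day = grand + (pm - grand) * shrink,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read/write recall tables
#'
#' Long format: \code{participant_id}, \code{recall_index},
#' \code{sodium_mg_day}.
#'
#' @param path CSV path.
#' @return data.frame of recalls.
#' @export
read_recalls <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_recalls
#' @param recalls recalls data.frame.
#' @export
write_recalls <- function(recalls, path) {
  utils::write.csv(recalls, path, row.names = FALSE)
  invisible(path)
}
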