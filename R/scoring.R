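# Scoring: screener responses -> estimated sodium intake (mg/day), UL
# classification, and empirical quartile assignment.

#' Score screener responses into daily sodium intake
#'
#' Each answered item contributes \code{daily_factor(option) x value}, where
#' the value is the item's reduced-sodium composite when the reduced box is
#' ticked (and a reduced value exists) and the regular composite otherwise.
#' The estimate is the sum over items; discretionary-salt answers contribute
#' nothing unless an explicit per-option mg/day add-on is configured.
#'
#' @param responses data.frame of item responses (see
#'   \code{\link{validate_responses}}); scoring refuses invalid response sets
#'   and lists the violations.
#' @param instrument a \code{salt_instrument}.
#' @param discretionary_responses optional data.frame with columns
#'   \code{participant_id}, \code{item_id}, \code{response}.
#' @param discretionary_mg optional named list mapping discretionary
#'   \code{item_id} to a named numeric vector of mg/day add-ons per ordinal
#'   option; only used when \code{discretionary_responses} is supplied.
#' @return data.frame of class \code{intake_estimates} with columns
#'   \code{participant_id}, \code{sodium_mg_day}; the per-item mg/day
#'   contribution matrix (participants x items) is attached as attribute
#'   \code{"contributions"}.
#' @examples
#' instr <- default_instrument()
#' resp <- data.frame(participant_id = "P1",
#'                    item_id = instr$food_items$item_id,
#'                    frequency_label = "never", reduced_flag = FALSE)
#' resp$frequency_label[1] <- "1/day"
#' score_responses(resp, instr)
#' @export
score_responses <- function(responses, instrument,
                            discretionary_responses = NULL,
                            discretionary_mg = NULL) {
  bad <- validate_responses(responses, instrument)
  if (length(bad) > 0)
    stop("invalid responses:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  items <- instrument$food_items
  fmap <- frequency_factor_map(instrument)
  reg <- stats::setNames(items$sodium_mg_per_serving, items$item_id)
  red <- stats::setNames(items$reduced_sodium_mg_per_serving, items$item_id)

  use_red <- as.logical(responses$reduced_flag) & !is.na(red[responses$item_id])
  value <- ifelse(use_red, red[responses$item_id], reg[responses$item_id])
  contrib <- as.numeric(fmap[responses$frequency_label]) * value

  pids <- unique(responses$participant_id)
  pidx <- match(responses$participant_id, pids)
  iidx <- match(responses$item_id, items$item_id)
  m <- matrix(0, nrow = length(pids), ncol = nrow(items),
              dimnames = list(pids, items$item_id))
  m[cbind(pidx, iidx)] <- contrib
  total <- rowSums(m)

  if (!is.null(discretionary_responses) && !is.null(discretionary_mg)) {
    dr <- discretionary_responses
    for (i in seq_len(nrow(dr))) {
      addons <- discretionary_mg[[dr$item_id[i]]]
      if (!is.null(addons) && dr$response[i] %in% names(addons)) {
        pid <- as.character(dr$participant_id[i])
        if (pid %in% pids) total[pid] <- total[pid] + addons[[dr$response[i]]]
      }
    }
  }
  out <- data.frame(participant_id = pids, sodium_mg_day = unname(total),
                    stringsAsFactors = FALSE)
  attr(out, "contributions") <- m
  class(out) <- c("intake_estimates", "data.frame")
  out
}

#' Per-item contribution matrix of scored intakes
#'
#' @param x an \code{intake_estimates} object from
#'   \code{\link{score_responses}}.
#' @return numeric matrix, participants x items, in mg/day.
#' @export
item_contributions <- function(x) {
  m <- attr(x, "contributions")
  if (is.null(m)) stop("no contribution matrix attached")
  m
}

#' Classify sodium intake against the tolerable upper intake level
#'
#' Intakes at or above the threshold (default 2300 mg/day, the adult UL)
#' fall in the upper class; the boundary value itself is classified
#' \code{at_or_above_UL}. A secondary threshold of interest, 1500 mg/day, can
#' be passed the same way.
#'
#' @param intake numeric vector of mg/day, all >= 0.
#' @param threshold classification threshold in mg/day.
#' @return factor with levels \code{below_UL}, \code{at_or_above_UL}.
#' @export
classify_ul <- function(intake, threshold = 2300) {
  if (any(!is.finite(intake)) || any(intake < 0))
    stop("intakes must be finite and >= 0")
  factor(ifelse(intake >= threshold, "at_or_above_UL", "below_UL"),
         levels = c("below_UL", "at_or_above_UL"))
}

#' Assign empirical intake quartiles
#'
#' Cut points are the 25th/50th/75th percentiles (linear interpolation);
#' values equal to a cut point go to the lower quartile, so the assignment is
#' deterministic and invariant under monotone relabelling of the intakes.
#'
#' @param x numeric vector of cohort intakes, length >= 4.
#' @return integer vector in 1..4, same length as \code{x}.
#' @export
assign_quartiles <- function(x) {
  if (length(x) < 4) stop("need at least 4 observations for quartiles")
  q <- stats::quantile(x, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  1L + (x > q[1]) + (x > q[2]) + (x > q[3])
}
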