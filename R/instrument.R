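# Screener instrument: frequency ladder, food items, discretionary-salt items,
# and participant response validation.

#' Construct a screener instrument
#'
#' An instrument bundles the food-based screener items (each carrying a
#' composite sodium value in mg per weighted serving), the ordinal
#' discretionary-salt questions, and the frequency ladder respondents choose
#' from. Frequencies are interpreted over a four-week recall window, so a
#' monthly option has \code{period_days = 28}.
#'
#' @param food_items data.frame with columns \code{item_id},
#'   \code{category_name}, \code{sodium_mg_per_serving},
#'   \code{reduced_sodium_mg_per_serving} (NA when the item has no
#'   reduced-sodium variant), \code{serving_size_g}, and optionally a
#'   list-column \code{example_foods}.
#' @param discretionary_items list; each element a list with \code{item_id},
#'   \code{question_text} and \code{ordinal_options} (ordered character
#'   vector, length >= 2). These items are scored as ordinal covariates and
#'   contribute no sodium unless an explicit per-option add-on is supplied at
#'   scoring time.
#' @param frequency_options data.frame with columns \code{label},
#'   \code{occurrences} (count per period, 0 for "never") and
#'   \code{period_days} (1 daily, 7 weekly, 28 monthly). Defaults to
#'   \code{\link{default_frequency_options}}.
#' @param version character version tag.
#' @param min_sodium_per_serving items below this sodium content
#'   (mg/serving) are invalid; mirrors the 50 mg exclusion rule used when
#'   the instrument is derived from consumption data.
#' @return An object of class \code{salt_instrument}.
#' @seealso \code{\link{load_instrument}}, \code{\link{build_instrument}}
#' @export
salt_instrument <- function(food_items, discretionary_items = list(),
                            frequency_options = default_frequency_options(),
                            version = "custom",
                            min_sodium_per_serving = 50) {
  if (is.null(food_items$example_foods)) {
    food_items$example_foods <- lapply(seq_len(nrow(food_items)),
                                       function(i) character(0))
  }
  if (is.null(food_items$reduced_sodium_mg_per_serving)) {
    food_items$reduced_sodium_mg_per_serving <- NA_real_
  }
  x <- structure(list(version = version,
                      frequency_options = as.data.frame(frequency_options),
                      food_items = as.data.frame(food_items),
                      discretionary_items = discretionary_items),
                 class = "salt_instrument")
  attr(x, "min_sodium_per_serving") <- min_sodium_per_serving
  bad <- instrument_violations(x)
  if (length(bad) > 0) {
    stop("invalid instrument definition:\n  - ",
         paste(bad, collapse = "\n  - "), call. = FALSE)
  }
  x
}

#' Default frequency ladder
#'
#' Eight options spanning never to four or more times per day, each mapped to
#' the midpoint count over its period (e.g. "1-3/month" is 2 occurrences per
#' 28 days). The ladder is configurable: any instrument may carry its own.
#'
#' @return data.frame with columns \code{label}, \code{occurrences},
#'   \code{period_days}.
#' @export
default_frequency_options <- function() {
  data.frame(
    label = c("never", "1-3/month", "1/week", "2-4/week", "5-6/week",
              "1/day", "2-3/day", "4+/day"),
    occurrences = c(0, 2, 1, 3, 5.5, 1, 2.5, 4),
    period_days = c(28, 28, 7, 7, 7, 1, 1, 1),
    stringsAsFactors = FALSE
  )
}

#' Default discretionary-salt questions
#'
#' Three behavioural items on salt added in cooking, salt added at the table,
#' and how often reduced/low-sodium products are chosen.
#'
#' @return list of discretionary item definitions.
#' @export
default_discretionary_items <- function() {
  list(
    list(item_id = "d1_salt_cooking",
         question_text = "How often is salt added to your food during cooking or preparation?",
         ordinal_options = c(">=1 times/day", "<1 times/day", "<=1 times/week")),
    list(item_id = "d2_salt_table",
         question_text = "How often do you add salt to your food at the table?",
         ordinal_options = c(">=1 times/day", "<1 times/day", "<=1 times/week")),
    list(item_id = "d3_reduced_products",
         question_text = "How often do you choose reduced or low sodium versions of foods?",
         ordinal_options = c("daily", "weekly", "monthly", "never or less than monthly"))
  )
}

# All invariant checks; returns character vector of violations (empty if ok).
instrument_violations <- function(x) {
  v <- character(0)
  fo <- x$frequency_options
  need_fo <- c("label", "occurrences", "period_days")
  if (!all(need_fo %in% names(fo))) {
    return(paste("frequency_options must have columns",
                 paste(need_fo, collapse = ", ")))
  }
  if (anyDuplicated(fo$label)) v <- c(v, "duplicate frequency option labels")
  if (any(fo$occurrences < 0 | !is.finite(fo$occurrences)))
    v <- c(v, "frequency option 'occurrences' must be finite and >= 0")
  if (any(fo$period_days <= 0 | !is.finite(fo$period_days)))
    v <- c(v, "frequency option 'period_days' must be finite and > 0")

  fi <- x$food_items
  need_fi <- c("item_id", "category_name", "sodium_mg_per_serving",
               "reduced_sodium_mg_per_serving", "serving_size_g")
  if (!all(need_fi %in% names(fi))) {
    return(paste("food_items must have columns",
                 paste(need_fi, collapse = ", ")))
  }
  disc_ids <- vapply(x$discretionary_items, function(d) d$item_id, "")
  ids <- c(fi$item_id, disc_ids)
  if (anyDuplicated(ids))
    v <- c(v, paste("duplicate item ids:",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  thr <- attr(x, "min_sodium_per_serving")
  if (is.null(thr)) thr <- 50
  bad_na <- !is.finite(fi$sodium_mg_per_serving) | fi$sodium_mg_per_serving < thr
  if (any(bad_na))
    v <- c(v, paste0("items below ", thr, " mg sodium/serving: ",
                     paste(fi$item_id[bad_na], collapse = ", ")))
  if (any(fi$serving_size_g <= 0 | !is.finite(fi$serving_size_g)))
    v <- c(v, "serving_size_g must be > 0")
  red <- fi$reduced_sodium_mg_per_serving
  bad_red <- !is.na(red) & (red < 0 | red > fi$sodium_mg_per_serving)
  if (any(bad_red))
    v <- c(v, paste0("reduced value exceeds regular value (or is negative) for: ",
                     paste(fi$item_id[bad_red], collapse = ", ")))
  for (d in x$discretionary_items) {
    if (length(d$ordinal_options) < 2)
      v <- c(v, paste0("discretionary item '", d$item_id,
                       "' needs >= 2 ordered options"))
  }
  v
}

#' Frequency of consumption per day
#'
#' Converts a frequency option (occurrences over a reporting period) to a
#' daily rate, the factor used to turn a per-serving sodium value into a
#' mg/day contribution.
#'
#' @param option a frequency option: a list or one-or-more-row data.frame with
#'   elements \code{occurrences} and \code{period_days}.
#' @return numeric vector of occurrences per day.
#' @examples
#' daily_factor(list(occurrences = 2, period_days = 7)) # 2/week
#' @export
daily_factor <- function(option) {
  occ <- option$occurrences
  per <- option$period_days
  if (is.null(occ) || is.null(per))
    stop("option must have 'occurrences' and 'period_days'")
  if (any(!is.finite(per) | per <= 0)) stop("period_days must be > 0")
  if (any(!is.finite(occ) | occ < 0)) stop("occurrences must be >= 0")
  occ / per
}

# label -> occurrences/day lookup for an instrument's ladder
frequency_factor_map <- function(instrument) {
  fo <- instrument$frequency_options
  stats::setNames(daily_factor(fo), fo$label)
}

#' Load a screener instrument from a YAML config
#'
#' The config mirrors the instrument structure: \code{version},
#' \code{frequency_options}, \code{food_items} (with optional
#' \code{reduced_sodium_mg_per_serving} per item), and
#' \code{discretionary_items}. All instrument invariants are checked and a
#' structured error naming the offending fields is raised on violation.
#'
#' @param path path to a YAML instrument definition.
#' @return \code{salt_instrument} object.
#' @export
load_instrument <- function(path) {
  if (!file.exists(path)) stop("instrument file not found: ", path)
  raw <- yaml::read_yaml(path)
  for (field in c("frequency_options", "food_items")) {
    if (is.null(raw[[field]])) stop("instrument config missing '", field, "'")
  }
  fo <- do.call(rbind, lapply(raw$frequency_options, function(o) {
    data.frame(label = o$label, occurrences = as.numeric(o$occurrences),
               period_days = as.numeric(o$period_days),
               stringsAsFactors = FALSE)
  }))
  fi <- do.call(rbind, lapply(raw$food_items, function(it) {
    data.frame(item_id = it$item_id,
               category_name = it$category_name,
               sodium_mg_per_serving = as.numeric(it$sodium_mg_per_serving),
               reduced_sodium_mg_per_serving =
                 if (is.null(it$reduced_sodium_mg_per_serving)) NA_real_
                 else as.numeric(it$reduced_sodium_mg_per_serving),
               serving_size_g = as.numeric(it$serving_size_g),
               stringsAsFactors = FALSE)
  }))
  fi$example_foods <- lapply(raw$food_items, function(it) {
    if (is.null(it$example_foods)) character(0)
    else as.character(unlist(it$example_foods))
  })
  disc <- lapply(raw$discretionary_items, function(d) {
    list(item_id = d$item_id, question_text = d$question_text,
         ordinal_options = as.character(unlist(d$ordinal_options)))
  })
  salt_instrument(food_items = fi, discretionary_items = disc,
                  frequency_options = fo,
                  version = if (is.null(raw$version)) "unversioned" else raw$version)
}

#' Save a screener instrument to YAML
#'
#' Writes a config that \code{\link{load_instrument}} reads back to an
#' identical instrument.
#'
#' @param instrument a \code{salt_instrument}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
save_instrument <- function(instrument, path) {
  stopifnot(inherits(instrument, "salt_instrument"))
  fi <- instrument$food_items
  items <- lapply(seq_len(nrow(fi)), function(i) {
    it <- list(item_id = fi$item_id[i],
               category_name = fi$category_name[i],
               example_foods = as.list(fi$example_foods[[i]]),
               sodium_mg_per_serving = fi$sodium_mg_per_serving[i],
               serving_size_g = fi$serving_size_g[i])
    if (!is.na(fi$reduced_sodium_mg_per_serving[i]))
      it$reduced_sodium_mg_per_serving <- fi$reduced_sodium_mg_per_serving[i]
    it
  })
  fo <- instrument$frequency_options
  opts <- lapply(seq_len(nrow(fo)), function(i) {
    list(label = fo$label[i], occurrences = fo$occurrences[i],
         period_days = fo$period_days[i])
  })
  disc <- lapply(instrument$discretionary_items, function(d) {
    list(item_id = d$item_id, question_text = d$question_text,
         ordinal_options = as.list(d$ordinal_options))
  })
  out <- list(version = instrument$version, frequency_options = opts,
              food_items = items, discretionary_items = disc)
  writeLines(yaml::as.yaml(out, precision = 15), path)
  invisible(path)
}

#' The bundled default sodium screener
#'
#' Forty food-category items plus three discretionary-salt questions, with
#' composite sodium values (mg per weighted serving), reduced-sodium values
#' where lower-sodium market variants are common (breads, canned soups and
#' vegetables, snacks, gravies, condiments, ...), and the default frequency
#' ladder. The wording and values are a plausible reconstruction intended as
#' a working default; a transcription of a specific questionnaire can be
#' dropped in via \code{\link{load_instrument}}.
#'
#' @return \code{salt_instrument} with 40 food items and 3 discretionary
#'   items.
#' @export
default_instrument <- function() {
  path <- system.file("extdata", "salt_instrument.yaml",
                      package = "saltscreener")
  if (path == "") stop("bundled instrument not found")
  load_instrument(path)
}

#' Validate participant screener responses against an instrument
#'
#' Checks that every food item is answered exactly once per participant with
#' a known frequency label (a "never" answer is explicit, not implied by
#' omission), and that the reduced-sodium box is only ticked for items that
#' define a reduced value. Violations are returned, not raised.
#'
#' @param responses data.frame with columns \code{participant_id},
#'   \code{item_id}, \code{frequency_label}, \code{reduced_flag} (logical);
#'   one row per participant x item.
#' @param instrument a \code{salt_instrument}.
#' @return character vector of violation messages; empty when valid.
#' @export
validate_responses <- function(responses, instrument) {
  stopifnot(inherits(instrument, "salt_instrument"))
  need <- c("participant_id", "item_id", "frequency_label", "reduced_flag")
  if (!all(need %in% names(responses))) {
    return(paste("responses must have columns:", paste(need, collapse = ", ")))
  }
  v <- character(0)
  items <- instrument$food_items
  known_items <- items$item_id
  known_labels <- instrument$frequency_options$label

  bad_item <- !(responses$item_id %in% known_items)
  if (any(bad_item))
    v <- c(v, paste0("unknown item_id: ",
                     paste(unique(responses$item_id[bad_item]), collapse = ", ")))
  bad_lab <- !(responses$frequency_label %in% known_labels)
  if (any(bad_lab))
    v <- c(v, paste0("unknown frequency_label: ",
                     paste(unique(responses$frequency_label[bad_lab]), collapse = ", ")))

  has_reduced <- stats::setNames(!is.na(items$reduced_sodium_mg_per_serving),
                                 items$item_id)
  flag <- as.logical(responses$reduced_flag)
  bad_flag <- !bad_item & !is.na(flag) & flag & !has_reduced[responses$item_id]
  if (any(bad_flag))
    v <- c(v, paste0("reduced_flag set for items without a reduced value: ",
                     paste(unique(responses$item_id[bad_flag]), collapse = ", ")))
  if (any(is.na(flag)))
    v <- c(v, "reduced_flag must be TRUE/FALSE with no missing values")

  for (pid in unique(responses$participant_id)) {
    sub <- responses[responses$participant_id == pid, ]
    missing <- setdiff(known_items, sub$item_id)
    if (length(missing) > 0)
      v <- c(v, paste0("participant ", pid, ": unanswered items: ",
                       paste(missing, collapse = ", ")))
    dup <- sub$item_id[duplicated(sub$item_id)]
    if (length(dup) > 0)
      v <- c(v, paste0("participant ", pid, ": duplicated items: ",
                       paste(unique(dup), collapse = ", ")))
  }
  v
}

#' @export
print.salt_instrument <- function(x, ...) {
  nred <- sum(!is.na(x$food_items$reduced_sodium_mg_per_serving))
  cat("Sodium screener instrument (version ", x$version, ")\n", sep = "")
  cat("  food items:          ", nrow(x$food_items),
      " (", nred, " with reduced-sodium values)\n", sep = "")
  cat("  discretionary items: ", length(x$discretionary_items), "\n", sep = "")
  cat("  frequency options:   ",
      paste(x$frequency_options$label, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read/write screener responses
#'
#' Responses are a delimited table with one row per participant x item and
#' columns \code{participant_id}, \code{item_id}, \code{frequency_label},
#' \code{reduced_flag}.
#'
#' @param path CSV path.
#' @return data.frame of responses.
#' @export
read_responses <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$reduced_flag <- as.logical(x$reduced_flag)
  x
}

#' @rdname read_responses
#' @param responses responses data.frame.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE)
  invisible(path)
}
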