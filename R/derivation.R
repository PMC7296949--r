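# Instrument derivation from a food-consumption/composition table:
# consumption-weighted serving sizes, composite sodium values, and
# reduced-sodium composites per screener category.

#' Construct a consumption table
#'
#' One row per food: its category, sodium density (mg/g), reference serving
#' size (g), per-capita consumption (g/day) by sex stratum, and optionally
#' the sodium density of a reduced-sodium market variant. Per-capita grams
#' are the weighting basis for all composite values; sex strata are combined
#' by a stratum-weighted mean (default equal weights, configurable to e.g.
#' population shares).
#'
#' @param foods data.frame with columns \code{food_id}, \code{category_name},
#'   \code{sodium_mg_per_g}, \code{serving_g}, one \code{per_capita_g_<stratum>}
#'   column per stratum, and optionally \code{reduced_sodium_mg_per_g} (NA
#'   when no reduced variant exists).
#' @param stratum_weights named non-negative weights over sex strata;
#'   normalised to sum to 1.
#' @return object of class \code{consumption_table}.
#' @export
consumption_table <- function(foods, stratum_weights = c(male = 0.5, female = 0.5)) {
  foods <- as.data.frame(foods)
  need <- c("food_id", "category_name", "sodium_mg_per_g", "serving_g")
  if (!all(need %in% names(foods)))
    stop("foods must have columns: ", paste(need, collapse = ", "))
  strata <- names(stratum_weights)
  if (is.null(strata) || any(strata == ""))
    stop("stratum_weights must be a named vector")
  pc_cols <- paste0("per_capita_g_", strata)
  if (!all(pc_cols %in% names(foods)))
    stop("foods must have per-capita columns: ", paste(pc_cols, collapse = ", "))
  if (any(stratum_weights < 0)) stop("stratum weights must be >= 0")
  if (sum(stratum_weights) <= 0) stop("stratum weights must not all be zero")
  stratum_weights <- stratum_weights / sum(stratum_weights)
  if (is.null(foods$reduced_sodium_mg_per_g))
    foods$reduced_sodium_mg_per_g <- rep(NA_real_, nrow(foods))
  if (anyDuplicated(foods$food_id)) stop("duplicate food_id values")
  if (any(foods$sodium_mg_per_g < 0)) stop("sodium_mg_per_g must be >= 0")
  if (any(foods$serving_g <= 0)) stop("serving_g must be > 0")
  red <- foods$reduced_sodium_mg_per_g
  if (any(!is.na(red) & (red < 0 | red > foods$sodium_mg_per_g)))
    stop("reduced_sodium_mg_per_g must lie in [0, sodium_mg_per_g]")
  for (col in pc_cols) {
    if (any(foods[[col]] < 0)) stop(col, " must be >= 0")
  }
  structure(list(foods = foods, sex_strata = strata,
                 stratum_weights = stratum_weights),
            class = "consumption_table")
}

#' Read a consumption table from CSV
#'
#' Expected columns: \code{food_id}, \code{category},
#' \code{sodium_mg_per_g}, \code{per_capita_g_male},
#' \code{per_capita_g_female}, \code{serving_g}, and optionally
#' \code{reduced_sodium_mg_per_g}.
#'
#' @param path CSV path.
#' @param stratum_weights passed to \code{\link{consumption_table}}.
#' @return \code{consumption_table}.
#' @export
read_consumption_table <- function(path, stratum_weights = c(male = 0.5, female = 0.5)) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("category" %in% names(x) && !"category_name" %in% names(x))
    names(x)[names(x) == "category"] <- "category_name"
  consumption_table(x, stratum_weights = stratum_weights)
}

#' @export
print.consumption_table <- function(x, ...) {
  cat("Consumption table: ", nrow(x$foods), " foods in ",
      length(unique(x$foods$category_name)), " categories\n", sep = "")
  cat("  strata: ", paste(sprintf("%s (%.2f)", x$sex_strata, x$stratum_weights),
                          collapse = ", "), "\n", sep = "")
  invisible(x)
}

# stratum-weighted per-capita grams per food
per_capita_weighted <- function(table) {
  pc <- sapply(table$sex_strata, function(s)
    table$foods[[paste0("per_capita_g_", s)]])
  pc <- matrix(pc, nrow = nrow(table$foods))
  as.numeric(pc %*% table$stratum_weights)
}

#' Exclude foods contributing little sodium per serving
#'
#' Drops every food whose sodium content at its own reference serving
#' (density x serving) is below \code{threshold} mg; the boundary value is
#' retained. Categories left without any food are dropped with a warning.
#'
#' @param table a \code{consumption_table}.
#' @param threshold mg sodium per serving; default 50.
#' @return filtered \code{consumption_table}.
#' @export
filter_low_contributors <- function(table, threshold = 50) {
  stopifnot(inherits(table, "consumption_table"))
  if (threshold < 0) stop("threshold must be >= 0")
  if (nrow(table$foods) == 0) stop("consumption table is empty")
  mg_per_serving <- table$foods$sodium_mg_per_g * table$foods$serving_g
  keep <- mg_per_serving >= threshold
  before <- unique(table$foods$category_name)
  out <- table
  out$foods <- table$foods[keep, , drop = FALSE]
  rownames(out$foods) <- NULL
  gone <- setdiff(before, unique(out$foods$category_name))
  if (length(gone) > 0)
    warning("categories dropped (no food at or above ", threshold,
            " mg/serving): ", paste(gone, collapse = ", "))
  out
}

# convex weights over a category's foods, proportional to stratum-weighted
# per-capita grams
category_weights <- function(table, category) {
  idx <- which(table$foods$category_name == category)
  if (length(idx) == 0) stop("category not present: ", category)
  pc <- per_capita_weighted(table)[idx]
  tot <- sum(pc)
  if (tot <= 0)
    stop("category '", category, "' has zero per-capita consumption; ",
         "no weighting basis")
  list(idx = idx, w = pc / tot)
}

#' Consumption-weighted serving size for a category
#'
#' The convex combination of member foods' reference serving sizes, weighted
#' by stratum-combined per-capita grams: foods eaten more contribute more to
#' the serving a respondent is asked to picture.
#'
#' @param table a \code{consumption_table} (already filtered).
#' @param category category name.
#' @return serving size in grams.
#' @export
weighted_serving_size <- function(table, category) {
  cw <- category_weights(table, category)
  sum(cw$w * table$foods$serving_g[cw$idx])
}

#' Composite sodium value for a category
#'
#' Consumption-weighted mean sodium density of the member foods multiplied by
#' the weighted serving size, giving mg sodium per (weighted) serving for the
#' screener item covering the category.
#'
#' @inheritParams weighted_serving_size
#' @return mg sodium per serving.
#' @export
composite_sodium_value <- function(table, category) {
  cw <- category_weights(table, category)
  dens <- sum(cw$w * table$foods$sodium_mg_per_g[cw$idx])
  dens * weighted_serving_size(table, category)
}

#' Composite reduced-sodium value for a category
#'
#' Same weighting as \code{\link{composite_sodium_value}} but substituting
#' each member food's reduced-sodium density where a reduced variant exists
#' (regular density otherwise). \code{NA} when no member food has a reduced
#' variant.
#'
#' @inheritParams weighted_serving_size
#' @return mg sodium per serving, or \code{NA}.
#' @export
composite_reduced_value <- function(table, category) {
  cw <- category_weights(table, category)
  reg <- table$foods$sodium_mg_per_g[cw$idx]
  red <- table$foods$reduced_sodium_mg_per_g[cw$idx]
  if (all(is.na(red))) return(NA_real_)
  dens <- sum(cw$w * ifelse(is.na(red), reg, red))
  dens * weighted_serving_size(table, category)
}

#' Build a screener instrument from a consumption table
#'
#' Applies the low-contributor filter, then creates one screener item per
#' surviving category with its weighted serving size, composite sodium value
#' and (where applicable) composite reduced-sodium value. Item ids are
#' generated as \code{qNN_<category-slug>}; member food ids become the
#' example-food list.
#'
#' @param table a \code{consumption_table}.
#' @param frequency_options frequency ladder for the instrument.
#' @param discretionary_items discretionary-salt questions.
#' @param threshold mg/serving exclusion threshold (default 50).
#' @param version instrument version tag.
#' @return \code{salt_instrument}.
#' @export
build_instrument <- function(table,
                             frequency_options = default_frequency_options(),
                             discretionary_items = default_discretionary_items(),
                             threshold = 50,
                             version = "derived-1.0") {
  ft <- filter_low_contributors(table, threshold)
  if (nrow(ft$foods) == 0) stop("no foods survive the ", threshold,
                                " mg/serving filter")
  cats <- unique(ft$foods$category_name)
  rows <- lapply(seq_along(cats), function(i) {
    cat_i <- cats[i]
    slug <- gsub("[^a-z0-9]+", "_", tolower(cat_i))
    data.frame(item_id = sprintf("q%02d_%s", i, slug),
               category_name = cat_i,
               sodium_mg_per_serving = composite_sodium_value(ft, cat_i),
               reduced_sodium_mg_per_serving = composite_reduced_value(ft, cat_i),
               serving_size_g = weighted_serving_size(ft, cat_i),
               stringsAsFactors = FALSE)
  })
  items <- do.call(rbind, rows)
  items$example_foods <- lapply(cats, function(cat_i)
    ft$foods$food_id[ft$foods$category_name == cat_i])
  salt_instrument(food_items = items,
                  discretionary_items = discretionary_items,
                  frequency_options = frequency_options,
                  version = version,
                  min_sodium_per_serving = threshold)
}
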