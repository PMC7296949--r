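# Seeded synthetic validation cohorts: lognormal usual intakes, repeated
# recalls with a target within/between variance ratio, two correlated
# screener administrations expressed on the instrument's frequency ladder,
# and a synthetic food-consumption table for derivation.

# evaluate code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions the generator emulates: usual sodium
#' intake 2742 +/- 980 mg/day, three recalls per participant with a
#' within/between-person variance ratio of 0.49 on the intake scale, and
#' reduced-sodium purchasing prevalences of 32\% monthly / 13\% weekly /
#' 4\% daily (nested: weekly users are also monthly users). The screener
#' error magnitude and the correlation between the two administrations have
#' no directly reported counterparts and are package defaults (see the
#' methods vignette).
#'
#' @param n_participants cohort size.
#' @param n_recalls recalls per participant (balanced design).
#' @param usual_intake_mean,usual_intake_sd moments of the lognormal usual
#'   intake distribution, mg/day.
#' @param lambda_within_between target within/between-person variance ratio
#'   of the simulated recalls (intake scale).
#' @param instrument_error_sd_log log-scale SD of the screener's
#'   multiplicative error around true usual intake.
#' @param instrument_bias_factor multiplicative bias of the screener
#'   (1 = unbiased).
#' @param reduced_use_prevalence named vector \code{c(monthly=, weekly=,
#'   daily=)} of cumulative prevalences of reduced-sodium product use.
#' @param retest_consistency correlation of the two administrations' error
#'   terms, in [0, 1]; 1 makes the administrations identical.
#' @param seed integer; fully determines the generated cohort.
#' @return object of class \code{generator_config}.
#' @export
generator_config <- function(n_participants = 100,
                             n_recalls = 3,
                             usual_intake_mean = 2742,
                             usual_intake_sd = 980,
                             lambda_within_between = 0.49,
                             instrument_error_sd_log = 0.60,
                             instrument_bias_factor = 1,
                             reduced_use_prevalence = c(monthly = 0.32,
                                                        weekly = 0.13,
                                                        daily = 0.04),
                             retest_consistency = 0.70,
                             seed = 1) {
  stopifnot(n_participants >= 2, n_recalls >= 1,
            usual_intake_mean > 0, usual_intake_sd >= 0,
            lambda_within_between >= 0,
            instrument_error_sd_log >= 0, instrument_bias_factor > 0,
            retest_consistency >= 0, retest_consistency <= 1)
  prev <- reduced_use_prevalence
  if (!all(c("monthly", "weekly", "daily") %in% names(prev)))
    stop("reduced_use_prevalence needs monthly, weekly and daily entries")
  if (any(prev < 0 | prev > 1)) stop("prevalences must be in [0, 1]")
  if (prev["daily"] > prev["weekly"] || prev["weekly"] > prev["monthly"])
    stop("prevalences must be nested: daily <= weekly <= monthly")
  structure(list(n_participants = as.integer(n_participants),
                 n_recalls = as.integer(n_recalls),
                 usual_intake_mean = usual_intake_mean,
                 usual_intake_sd = usual_intake_sd,
                 lambda_within_between = lambda_within_between,
                 instrument_error_sd_log = instrument_error_sd_log,
                 instrument_bias_factor = instrument_bias_factor,
                 reduced_use_prevalence = prev,
                 retest_consistency = retest_consistency,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Express per-participant target intakes as responses on the instrument's
# frequency ladder. Ideal per-item daily frequencies follow the allocation
# shares; each is rounded to the nearest ladder option with the running
# mg/day residual carried into the next item, then a local single-move
# refinement minimises the total-score residual so that the configured
# instrument error (not grid rounding) controls the scored intake.
match_frequencies <- function(target, share, values, factors) {
  J <- length(values)
  ideal <- target * share / values
  choice <- integer(J)
  carry <- 0
  for (j in order(values, decreasing = TRUE)) {
    a <- ideal[j] + carry / values[j]
    i <- which.min(abs(factors - a))
    choice[j] <- i
    carry <- values[j] * (a - factors[i])
  }
  # single-move refinement on the total residual
  resid <- sum(values * factors[choice]) - target
  delta <- outer(values, factors)           # J x O contribution grid
  for (iter in 1:50) {
    cur <- values * factors[choice]
    cand <- abs(resid + delta - cur)        # residual after moving item j to o
    best <- arrayInd(which.min(cand), dim(cand))
    if (cand[best] >= abs(resid) - 1e-9) break
    j <- best[1]; o <- best[2]
    resid <- resid + delta[j, o] - cur[j]
    choice[j] <- o
  }
  choice
}

#' Generate a synthetic validation cohort
#'
#' Draws usual intakes from a moment-matched lognormal, simulates repeated
#' recalls with multiplicative day-to-day noise calibrated (against the
#' sample moments of the drawn intakes) so the within/between variance ratio
#' of the recalls matches the configured lambda, and constructs two screener
#' administrations whose scored intakes track
#' \code{bias_factor x truth x exp(error)} with log-scale error SD
#' \code{instrument_error_sd_log} and between-administration error
#' correlation \code{retest_consistency}. Responses are expressed on the
#' instrument's frequency ladder; reduced-sodium box ticks follow each
#' participant's reduced-use level and are shared across administrations.
#' The same seed always regenerates the identical cohort.
#'
#' @param config a \code{\link{generator_config}}.
#' @param instrument screener instrument to express responses on; default
#'   \code{\link{default_instrument}}.
#' @return object of class \code{synthetic_cohort}: list with \code{truth}
#'   (participant_id, usual_intake_mg, target_t1_mg, target_t2_mg,
#'   reduced_user_level), \code{recalls} (long data.frame),
#'   \code{responses_t1}, \code{responses_t2}, \code{discretionary}
#'   (long data.frame of ordinal answers), \code{consumption_table},
#'   \code{config}.
#' @export
generate_cohort <- function(config, instrument = default_instrument()) {
  stopifnot(inherits(config, "generator_config"),
            inherits(instrument, "salt_instrument"))
  with_seed(config$seed, {
    n <- config$n_participants
    k <- config$n_recalls
    pid <- sprintf("P%04d", seq_len(n))

    mu <- config$usual_intake_mean
    sdv <- config$usual_intake_sd
    sdlog <- sqrt(log(1 + (sdv / mu)^2))
    meanlog <- log(mu) - sdlog^2 / 2
    truth <- stats::rlnorm(n, meanlog, sdlog)

    # day-to-day noise calibrated to the target intake-scale variance ratio
    s2b_hat <- stats::var(truth)
    sigw2 <- log(1 + config$lambda_within_between * s2b_hat / mean(truth^2))
    eps <- matrix(stats::rnorm(n * k, -sigw2 / 2, sqrt(sigw2)), n, k)
    recall_mat <- truth * exp(eps)
    recalls <- data.frame(
      participant_id = rep(pid, each = k),
      recall_index = rep(seq_len(k), times = n),
      sodium_mg_day = as.numeric(t(recall_mat)),
      stringsAsFactors = FALSE)

    # correlated screener error for the two administrations
    s <- config$instrument_error_sd_log
    rho <- config$retest_consistency
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    e1 <- s * z1
    e2 <- s * (rho * z1 + sqrt(1 - rho^2) * z2)
    bf <- config$instrument_bias_factor
    tgt1 <- bf * truth * exp(e1 - s^2 / 2)
    tgt2 <- bf * truth * exp(e2 - s^2 / 2)

    items <- instrument$food_items
    J <- nrow(items)
    v_reg <- items$sodium_mg_per_serving
    v_red <- items$reduced_sodium_mg_per_serving
    fo <- instrument$frequency_options
    factors <- daily_factor(fo)

    # reduced-use level (nested prevalences) and per-item box ticks,
    # shared across administrations
    prev <- config$reduced_use_prevalence
    u <- stats::runif(n)
    level <- ifelse(u < prev["daily"], "daily",
             ifelse(u < prev["weekly"], "weekly",
             ifelse(u < prev["monthly"], "monthly", "never")))
    p_flag <- c(never = 0, monthly = 0.10, weekly = 0.25, daily = 0.50)
    capable <- !is.na(v_red)
    flags <- matrix(stats::runif(n * J), n, J) < p_flag[level]
    flags <- flags & matrix(capable, n, J, byrow = TRUE)

    # participant-level allocation shares, proportional to item composite
    # values with gamma jitter; shared across administrations
    jitter <- matrix(stats::rgamma(n * J, shape = 4, rate = 4), n, J)
    w <- jitter * matrix(v_reg, n, J, byrow = TRUE)
    w <- w / rowSums(w)

    build_responses <- function(targets) {
      lab <- matrix("", n, J)
      for (i in seq_len(n)) {
        v_eff <- ifelse(flags[i, ], v_red, v_reg)
        ch <- match_frequencies(targets[i], w[i, ], v_eff, factors)
        lab[i, ] <- fo$label[ch]
      }
      data.frame(participant_id = rep(pid, each = J),
                 item_id = rep(items$item_id, times = n),
                 frequency_label = as.character(t(lab)),
                 reduced_flag = as.logical(t(flags)),
                 stringsAsFactors = FALSE)
    }
    responses_t1 <- build_responses(tgt1)
    responses_t2 <- build_responses(tgt2)

    discretionary <- generate_discretionary(pid, level, instrument)
    ctab <- generate_consumption_table()

    structure(list(
      truth = data.frame(participant_id = pid, usual_intake_mg = truth,
                         target_t1_mg = tgt1, target_t2_mg = tgt2,
                         reduced_user_level = level,
                         stringsAsFactors = FALSE),
      recalls = recalls,
      responses_t1 = responses_t1,
      responses_t2 = responses_t2,
      discretionary = discretionary,
      consumption_table = ctab,
      config = config), class = "synthetic_cohort")
  })
}

# ordinal discretionary answers; the reduced-products item follows the
# participant's generated reduced-use level, salt-use items follow fixed
# population-style distributions
generate_discretionary <- function(pid, level, instrument) {
  n <- length(pid)
  rows <- list()
  for (d in instrument$discretionary_items) {
    opts <- d$ordinal_options
    if (d$item_id == "d3_reduced_products" && length(opts) == 4) {
      resp <- c(daily = opts[1], weekly = opts[2], monthly = opts[3],
                never = opts[4])[level]
    } else if (length(opts) == 3) {
      probs <- if (d$item_id == "d2_salt_table") c(0.06, 0.15, 0.79)
               else c(0.24, 0.22, 0.54)
      resp <- sample(opts, n, replace = TRUE, prob = probs)
    } else {
      resp <- sample(opts, n, replace = TRUE)
    }
    rows[[d$item_id]] <- data.frame(participant_id = pid, item_id = d$item_id,
                                    response = unname(resp),
                                    stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort: ", nrow(x$truth), " participants, ",
      x$config$n_recalls, " recalls each (seed ", x$config$seed, ")\n",
      sep = "")
  cat(sprintf("  usual intake %.0f +/- %.0f mg/day\n",
              mean(x$truth$usual_intake_mg), stats::sd(x$truth$usual_intake_mg)))
  invisible(x)
}

#' Generate a synthetic food-consumption table
#'
#' Plausible sodium densities, serving sizes and per-capita consumption for
#' derivation testing. Each category receives exactly
#' \code{round(fraction_below_threshold * foods_per_category)} foods whose
#' per-serving sodium falls below the exclusion threshold, and exactly
#' \code{round(fraction_reduced * foods_per_category)} foods with a
#' reduced-sodium variant.
#'
#' @param n_categories,foods_per_category table dimensions (>= 1).
#' @param fraction_below_threshold fraction of foods per category engineered
#'   to fail the per-serving sodium filter.
#' @param fraction_reduced fraction of foods per category given a
#'   reduced-sodium density.
#' @param threshold mg/serving exclusion threshold the fractions refer to.
#' @param seed optional integer; when supplied the table is generated under
#'   that seed without disturbing the caller's RNG state.
#' @return \code{consumption_table}.
#' @export
generate_consumption_table <- function(n_categories = 10,
                                       foods_per_category = 5,
                                       fraction_below_threshold = 0.2,
                                       fraction_reduced = 0.4,
                                       threshold = 50,
                                       seed = NULL) {
  stopifnot(n_categories >= 1, foods_per_category >= 1,
            fraction_below_threshold >= 0, fraction_below_threshold <= 1,
            fraction_reduced >= 0, fraction_reduced <= 1)
  gen <- function() {
    n_below <- round(fraction_below_threshold * foods_per_category)
    n_red <- round(fraction_reduced * foods_per_category)
    rows <- list()
    fid <- 0
    for (ci in seq_len(n_categories)) {
      for (fi in seq_len(foods_per_category)) {
        fid <- fid + 1
        serving <- stats::runif(1, 15, 250)
        below <- fi <= n_below
        per_serving <- if (below) stats::runif(1, 5, threshold - 5)
                       else stats::runif(1, threshold + 10, 600)
        dens <- per_serving / serving
        red <- if (fi > n_below && fi <= n_below + n_red)
          dens * stats::runif(1, 0.3, 0.7) else NA_real_
        rows[[fid]] <- data.frame(
          food_id = sprintf("f%03d", fid),
          category_name = sprintf("category_%02d", ci),
          sodium_mg_per_g = dens,
          per_capita_g_male = stats::rgamma(1, shape = 2, scale = 7),
          per_capita_g_female = stats::rgamma(1, shape = 2, scale = 5),
          serving_g = serving,
          reduced_sodium_mg_per_g = red,
          stringsAsFactors = FALSE)
      }
    }
    consumption_table(do.call(rbind, rows))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Write a synthetic cohort to delimited files
#'
#' Writes \code{truth.csv}, \code{recalls.csv}, \code{responses_t1.csv},
#' \code{responses_t2.csv}, \code{discretionary.csv} and
#' \code{consumption.csv} into a directory.
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  utils::write.csv(cohort$recalls, file.path(dir, "recalls.csv"), row.names = FALSE)
  utils::write.csv(cohort$responses_t1, file.path(dir, "responses_t1.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$responses_t2, file.path(dir, "responses_t2.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$discretionary, file.path(dir, "discretionary.csv"),
                   row.names = FALSE)
  foods <- cohort$consumption_table$foods
  names(foods)[names(foods) == "category_name"] <- "category"
  utils::write.csv(foods, file.path(dir, "consumption.csv"), row.names = FALSE)
  invisible(dir)
}
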