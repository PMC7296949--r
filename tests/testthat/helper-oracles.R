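# Independent brute-force oracles and small fixture builders used across the
# suite. Every oracle is written from the defining formula, not by calling
# the implementation under test.

oracle_mean_sd <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  list(mean = m, sd = sqrt(sum((x - m)^2) / (n - 1)))
}

oracle_bland_altman <- function(a, b, z = 1.96) {
  d <- a - b
  ms <- oracle_mean_sd(d)
  list(bias = ms$mean, sd_diff = ms$sd,
       loa_lower = ms$mean - z * ms$sd, loa_upper = ms$mean + z * ms$sd,
       pct_within = 100 * sum(d >= ms$mean - z * ms$sd &
                              d <= ms$mean + z * ms$sd) / length(d))
}

oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  ms <- oracle_mean_sd(d)
  list(t = ms$mean / (ms$sd / sqrt(n)), df = n - 1)
}

oracle_kappa <- function(tab) {
  n <- sum(tab)
  p <- tab / n
  po <- sum(diag(p))
  pe <- sum(rowSums(p) * colSums(p))
  list(po = po, pe = pe, kappa = (po - pe) / (1 - pe))
}

oracle_variance_components <- function(m) {
  n <- nrow(m); k <- ncol(m)
  pm <- rowMeans(m); grand <- mean(m)
  ssw <- sum((m - matrix(pm, n, k))^2)
  ssb <- k * sum((pm - grand)^2)
  msw <- ssw / (n * (k - 1))
  msb <- ssb / (n - 1)
  list(msw = msw, msb = msb, s2w = msw, s2b = max(0, (msb - msw) / k))
}

oracle_alpha <- function(m) {
  k <- ncol(m)
  item_vars <- numeric(k)
  for (j in 1:k) item_vars[j] <- oracle_mean_sd(m[, j])$sd^2
  tot <- oracle_mean_sd(rowSums(m))$sd^2
  k / (k - 1) * (1 - sum(item_vars) / tot)
}

oracle_skewness <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  sqrt(n * (n - 1)) / (n - 2) * m3 / m2^1.5
}

# average ranks with explicit tie handling, then Pearson on the ranks
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  mx <- oracle_mean_sd(rx); my <- oracle_mean_sd(ry)
  sum((rx - mx$mean) * (ry - my$mean)) / ((length(x) - 1) * mx$sd * my$sd)
}

oracle_quartiles <- function(x) {
  # empirical percentile cut points (linear interpolation), boundaries low
  cuts <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  out <- integer(length(x))
  for (i in seq_along(x)) {
    out[i] <- 1L
    for (c in cuts) if (x[i] > c) out[i] <- out[i] + 1L
  }
  out
}

# three-category, hand-checkable consumption table fixture
fixture_table <- function() {
  foods <- data.frame(
    food_id = c("bread_a", "bread_b", "soup_a", "chip_a", "chip_b"),
    category_name = c("breads", "breads", "soups", "snacks", "snacks"),
    sodium_mg_per_g = c(5, 4, 3.5, 6, 6),
    per_capita_g_male = c(10, 30, 20, 8, 8),
    per_capita_g_female = c(10, 30, 20, 8, 8),
    serving_g = c(30, 50, 250, 50, 50),
    reduced_sodium_mg_per_g = c(NA, 2, NA, 3, NA),
    stringsAsFactors = FALSE)
  consumption_table(foods)
}

# a tiny custom instrument with a simple ladder, for hand-scored cases
fixture_instrument <- function() {
  items <- data.frame(
    item_id = c("it1", "it2", "it3"),
    category_name = c("c1", "c2", "c3"),
    sodium_mg_per_serving = c(200, 350, 500),
    reduced_sodium_mg_per_serving = c(NA, 140, 250),
    serving_size_g = c(100, 50, 250),
    stringsAsFactors = FALSE)
  opts <- data.frame(label = c("never", "2/week", "1/day"),
                     occurrences = c(0, 2, 1),
                     period_days = c(28, 7, 1),
                     stringsAsFactors = FALSE)
  salt_instrument(items, frequency_options = opts, version = "fixture")
}

# complete response set for fixture_instrument()
fixture_responses <- function(pid = "P1",
                              labels = c("never", "never", "never"),
                              reduced = c(FALSE, FALSE, FALSE)) {
  data.frame(participant_id = pid, item_id = c("it1", "it2", "it3"),
             frequency_label = labels, reduced_flag = reduced,
             stringsAsFactors = FALSE)
}
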