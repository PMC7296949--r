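test_that("low-contributor filter applies the per-serving threshold with >= retained", {
  foods <- data.frame(
    food_id = c("f1", "f2", "f3"),
    category_name = c("a", "a", "b"),
    sodium_mg_per_g = c(0.3, 0.5, 2),
    per_capita_g_male = c(10, 10, 10),
    per_capita_g_female = c(10, 10, 10),
    serving_g = c(100, 100, 100))
  tab <- consumption_table(foods)
  ft <- filter_low_contributors(tab, 50)
  expect_identical(ft$foods$food_id, c("f2", "f3")) # 30 mg out, 50 mg boundary in
  # all foods at or above threshold: identity
  expect_identical(filter_low_contributors(ft, 50)$foods, ft$foods)
  # category emptied by the filter is dropped with a warning
  foods$sodium_mg_per_g[3] <- 0.1
  expect_warning(ft2 <- filter_low_contributors(consumption_table(foods), 50),
                 "categories dropped.*b")
  expect_false("b" %in% ft2$foods$category_name)
  expect_error(filter_low_contributors(consumption_table(foods[0, ])),
               "empty|category")
})

test_that("weighted serving size is the per-capita-weighted mean of servings", {
  foods <- data.frame(
    food_id = c("f1", "f2"), category_name = "a",
    sodium_mg_per_g = c(2, 2),
    per_capita_g_male = c(10, 30), per_capita_g_female = c(10, 30),
    serving_g = c(30, 50))
  tab <- consumption_table(foods)
  expect_equal(weighted_serving_size(tab, "a"), 0.25 * 30 + 0.75 * 50)
  # single-food category: its own serving
  expect_equal(weighted_serving_size(fixture_table(), "soups"), 250)
  # zero consumption basis errors
  foods$per_capita_g_male <- 0; foods$per_capita_g_female <- 0
  expect_error(weighted_serving_size(consumption_table(foods), "a"),
               "zero per-capita")
})

test_that("composite sodium and reduced values follow the convex weighting", {
  # single food: density x serving
  expect_equal(composite_sodium_value(fixture_table(), "soups"), 3.5 * 250)
  # equal weights, densities 1 and 3 mg/g, 100 g servings -> 200 mg
  foods <- data.frame(
    food_id = c("f1", "f2"), category_name = "a",
    sodium_mg_per_g = c(1, 3),
    per_capita_g_male = c(5, 5), per_capita_g_female = c(5, 5),
    serving_g = c(100, 100))
  expect_equal(composite_sodium_value(consumption_table(foods), "a"), 200)
  # no reduced variant anywhere -> NA
  expect_true(is.na(composite_reduced_value(consumption_table(foods), "a")))
  # reduced density equal to regular -> identical composite
  foods$reduced_sodium_mg_per_g <- foods$sodium_mg_per_g
  tab <- consumption_table(foods)
  expect_equal(composite_reduced_value(tab, "a"),
               composite_sodium_value(tab, "a"))
  # halving one of two equal-weight equal-density foods drops composite 25%
  foods$sodium_mg_per_g <- c(2, 2)
  foods$reduced_sodium_mg_per_g <- c(NA, 1)
  tab <- consumption_table(foods)
  expect_equal(composite_reduced_value(tab, "a"),
               0.75 * composite_sodium_value(tab, "a"))
})

test_that("build_instrument composes the derivation on a hand-checkable table", {
  tab <- fixture_table()
  instr <- build_instrument(tab, version = "t")
  expect_identical(nrow(instr$food_items), 3L)
  expect_setequal(instr$food_items$category_name, c("breads", "soups", "snacks"))
  br <- instr$food_items[instr$food_items$category_name == "breads", ]
  # breads: weights 0.25/0.75; serving 0.25*30+0.75*50 = 45;
  # density 0.25*5+0.75*4 = 4.25 -> 191.25 mg
  expect_equal(br$serving_size_g, 45)
  expect_equal(br$sodium_mg_per_serving, 4.25 * 45)
  expect_equal(br$reduced_sodium_mg_per_serving, (0.25 * 5 + 0.75 * 2) * 45)
  expect_true(is.na(
    instr$food_items$reduced_sodium_mg_per_serving[
      instr$food_items$category_name == "soups"]))
  expect_true(all(instr$food_items$sodium_mg_per_serving >= 50))
  # example foods carry the member food ids
  expect_setequal(br$example_foods[[1]], c("bread_a", "bread_b"))
})

test_that("composites are convex, order-invariant and scale-invariant", {
  set.seed(101)
  for (rep in 1:10) {
    tab <- generate_consumption_table(n_categories = 4, foods_per_category = 4,
                                      fraction_below_threshold = 0,
                                      fraction_reduced = 0.5)
    for (cat_i in unique(tab$foods$category_name)) {
      idx <- tab$foods$category_name == cat_i
      sv <- weighted_serving_size(tab, cat_i)
      expect_gte(sv, min(tab$foods$serving_g[idx]))
      expect_lte(sv, max(tab$foods$serving_g[idx]))
      cv <- composite_sodium_value(tab, cat_i)
      per_serv <- tab$foods$sodium_mg_per_g[idx] * sv
      expect_gte(cv, min(per_serv) - 1e-9)
      expect_lte(cv, max(per_serv) + 1e-9)
    }
    # permuting record order changes nothing
    perm <- tab
    perm$foods <- perm$foods[sample(nrow(perm$foods)), ]
    # doubling per-capita grams changes nothing (weights are shares)
    dbl <- tab
    dbl$foods$per_capita_g_male <- 2 * dbl$foods$per_capita_g_male
    dbl$foods$per_capita_g_female <- 2 * dbl$foods$per_capita_g_female
    for (cat_i in unique(tab$foods$category_name)) {
      expect_equal(composite_sodium_value(perm, cat_i),
                   composite_sodium_value(tab, cat_i))
      expect_equal(weighted_serving_size(perm, cat_i),
                   weighted_serving_size(tab, cat_i))
      expect_equal(composite_sodium_value(dbl, cat_i),
                   composite_sodium_value(tab, cat_i))
    }
  }
})

test_that("one stratum, one food per category embeds the table identically", {
  foods <- data.frame(
    food_id = c("f1", "f2"), category_name = c("a", "b"),
    sodium_mg_per_g = c(2, 3),
    per_capita_g_all = c(5, 9),
    serving_g = c(100, 60))
  tab <- consumption_table(foods, stratum_weights = c(all = 1))
  instr <- build_instrument(tab, version = "t")
  expect_equal(instr$food_items$serving_size_g, foods$serving_g)
  expect_equal(instr$food_items$sodium_mg_per_serving,
               foods$sodium_mg_per_g * foods$serving_g)
})

test_that("consumption tables round-trip through CSV", {
  tab <- generate_consumption_table(n_categories = 2, foods_per_category = 3,
                                    seed = 5)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  foods <- tab$foods
  names(foods)[names(foods) == "category_name"] <- "category"
  write.csv(foods, path, row.names = FALSE)
  back <- read_consumption_table(path)
  expect_equal(back$foods, tab$foods)
})
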