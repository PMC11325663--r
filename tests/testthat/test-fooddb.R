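foods3 <- data.frame(food_code = c("A", "B", "C"),
                     description = c("a", "b", "c"),
                     food_group = "GRP_X", stringsAsFactors = FALSE)

no_entries <- data.frame(parent_code = character(),
                         component_code = character(),
                         grams_per_100g = numeric())

test_that("an empty recipe table yields a base-only database", {
  db <- recipe_db(foods3, no_entries)
  expect_s3_class(db, "recipe_db")
  expect_equal(nrow(db$entries), 0)
  expect_equal(length(db$base_ingredients), 0)
  for (fc in foods3$food_code) {
    res <- resolve_recipe(db, fc)
    expect_equal(res$ingredient_code, fc)
    expect_equal(res$grams_per_100g, 100)
  }
})

test_that("a single under-window entry loads with a warning", {
  e <- data.frame(parent_code = "A", component_code = "milk",
                  grams_per_100g = 40)
  expect_warning(db <- recipe_db(foods3, e), "outside \\[50, 130\\]")
  expect_equal(nrow(db$entries), 1)
  expect_equal(sum(db$entries$grams_per_100g), 40)
  expect_equal(db$base_ingredients, "milk")
  # the window is configurable; a tighter one flags the same row
  expect_warning(recipe_db(foods3, e, sum_window = c(90, 110)),
                 "outside \\[90, 110\\]")
  expect_silent(db2 <- recipe_db(foods3, e, sum_window = c(30, 130)))
  expect_error(recipe_db(foods3,
                         data.frame(parent_code = "A",
                                    component_code = "milk",
                                    grams_per_100g = 0)),
               "<= 0")
})

test_that("structural defects are distinct named failures", {
  cyc <- data.frame(parent_code = c("A", "B"), component_code = c("B", "A"),
                    grams_per_100g = c(100, 100))
  expect_error(recipe_db(foods3, cyc), "cycle.*A.*B")

  dup <- data.frame(parent_code = c("A", "A"),
                    component_code = c("milk", "milk"),
                    grams_per_100g = c(50, 50))
  expect_error(recipe_db(foods3, dup), "duplicate \\(parent_code")

  expect_error(recipe_db(foods3[, 1:2], no_entries), "missing column")
  expect_error(
    recipe_db(foods3, data.frame(parent_code = "Z",
                                 component_code = "milk",
                                 grams_per_100g = 100)),
    "absent from the food list: Z")
  expect_error(
    recipe_db(foods3, data.frame(parent_code = "A",
                                 component_code = "milk",
                                 grams_per_100g = -5)),
    "non-negative")
  expect_error(
    suppressWarnings(recipe_db(rbind(foods3, foods3[1, ]), no_entries)),
    "duplicate food_code")
})

test_that("CSV loading round-trips the documented schemas", {
  td <- withr::local_tempdir()
  fl <- file.path(td, "foods.csv")
  rc <- file.path(td, "recipes.csv")
  write.csv(foods3, fl, row.names = FALSE)
  write.csv(data.frame(parent_code = "A", component_code = c("milk", "oats"),
                       grams_per_100g = c(60, 40)),
            rc, row.names = FALSE)
  db <- load_recipe_db(fl, rc)
  expect_equal(sort(db$base_ingredients), c("milk", "oats"))
  expect_error(load_recipe_db(fl, file.path(td, "nope.csv")), "not found")
})

test_that("substitutions map present codes to themselves and missing codes to substitutes", {
  db <- recipe_db(foods3, no_entries)
  subs <- substitution_map("X1", "A", "nearest neighbour")
  got <- apply_substitutions(db, subs, c("A", "X1", "B"), quiet = TRUE)
  expect_equal(unname(got), c("A", "A", "B"))
  expect_equal(names(got), c("A", "X1", "B"))

  expect_error(apply_substitutions(db, subs, c("A", "ZZZ"), quiet = TRUE),
               "unresolvable food code\\(s\\).*ZZZ")
  # substitute must exist; chains are rejected at construction
  expect_error(apply_substitutions(db, substitution_map("X1", "QQ"), "X1"),
               "absent from the database: QQ")
  expect_error(substitution_map(c("X1", "X2"), c("X2", "A")),
               "chains")
})

test_that("resolution scales sub-recipes proportionally and sums repeats", {
  foods <- data.frame(food_code = c("P", "S"), description = "",
                      food_group = "GRP_X")
  entries <- rbind(
    data.frame(parent_code = "P", component_code = c("S", "flour"),
               grams_per_100g = c(50, 50)),
    data.frame(parent_code = "S", component_code = c("milk", "flour"),
               grams_per_100g = c(60, 40)))
  db <- recipe_db(foods, entries)
  res <- resolve_recipe(db, "P")
  # 50 g of S contributes 50x60/100 = 30 milk and 50x40/100 = 20 flour,
  # plus the direct 50 flour
  expect_equal(res$ingredient_code, c("flour", "milk"))
  expect_equal(res$grams_per_100g, c(70, 30))

  leaf <- resolve_recipe(db, "milk")
  expect_equal(leaf$ingredient_code, "milk")
  expect_equal(leaf$grams_per_100g, 100)

  expect_error(resolve_recipe(db, "nope"), "unknown food code")
})

test_that("resolver matches the brute-force path-product flattener on random databases", {
  for (seed in 1:12) {
    x <- random_test_db(n_foods = sample(5:30, 1), max_depth = 4,
                        seed = seed)
    for (fc in x$db$foods$food_code) {
      got <- resolved_as_vector(resolve_recipe(x$db, fc))
      want <- flatten_by_paths(x$db$entries, fc)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("nested resolution conserves mass", {
  for (seed in 13:18) {
    x <- random_test_db(n_foods = 15, max_depth = 4, seed = seed)
    for (fc in x$db$foods$food_code) {
      direct <- sum(x$db$entries$grams_per_100g[
        x$db$entries$parent_code == fc])
      resolved <- sum(resolve_recipe(x$db, fc)$grams_per_100g)
      expect_equal(resolved, direct, tolerance = 1e-9)
    }
  }
})

test_that("resolving an already-flat database returns it unchanged", {
  foods <- data.frame(food_code = c("A", "B"), description = "",
                      food_group = "GRP_X")
  entries <- data.frame(parent_code = c("A", "A", "B"),
                        component_code = c("milk", "flour", "oats"),
                        grams_per_100g = c(60, 40, 100))
  db <- recipe_db(foods, entries)
  for (fc in c("A", "B")) {
    res <- resolve_recipe(db, fc)
    direct <- entries[entries$parent_code == fc, ]
    direct <- direct[order(direct$component_code), ]
    expect_equal(res$ingredient_code, direct$component_code)
    expect_equal(res$grams_per_100g, direct$grams_per_100g)
  }
})
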