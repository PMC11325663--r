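fx <- dairy_fixtures()
fx_profiles <- dairy_profiles(fx$db, fx$map)

one_person <- data.frame(person_id = "p1", weight = 1)

test_that("disaggregated items contribute proportionally to their profile", {
  # 200 g of Yorkshire pudding (60 g semiskimmed milk / 100 g) -> 120 g milk
  rec <- data.frame(person_id = "p1", day = 1,
                    food_code = "yorkshire_pudding", grams_consumed = 200)
  pv <- person_daily_intake(rec, one_person, "disaggregated",
                            profiles = fx_profiles)
  expect_equal(pv$g_per_day[pv$category == "milk"], 120)
  expect_equal(sum(pv$g_per_day), 120)
})

test_that("naive mode counts full weight in dairy groups and nothing elsewhere", {
  rec <- data.frame(person_id = "p1", day = 1,
                    food_code = c("yorkshire_pudding", "kulfi"),
                    grams_consumed = c(200, 50))
  pv <- person_daily_intake(rec, one_person, "food_group",
                            foods = fx$db$foods, group_map = fx$group_map)
  # Yorkshire pudding sits in a cereal-dish (non-dairy) group -> nothing;
  # kulfi sits in the ice-cream group mapped to cream -> all 50 g as cream
  expect_equal(pv$g_per_day[pv$category == "cream"], 50)
  expect_equal(sum(pv$g_per_day), 50)
})

test_that("day totals are averaged over completed days", {
  rec <- data.frame(person_id = "p1", day = c(1, 2),
                    food_code = "whole_milk", grams_consumed = c(100, 300))
  pv <- person_daily_intake(rec, one_person, "disaggregated",
                            profiles = fx_profiles)
  expect_equal(pv$g_per_day[pv$category == "milk"], 200)

  # an explicit n_days_completed dominates the observed day count
  p2 <- data.frame(person_id = "p1", weight = 1, n_days_completed = 2)
  rec1 <- data.frame(person_id = "p1", day = 1, food_code = "whole_milk",
                     grams_consumed = 100)
  pv2 <- person_daily_intake(rec1, p2, "disaggregated",
                             profiles = fx_profiles)
  expect_equal(pv2$g_per_day[pv2$category == "milk"], 50)
})

test_that("input contract violations are named errors", {
  rec <- data.frame(person_id = "p1", day = 1, food_code = "nope",
                    grams_consumed = 10)
  expect_error(person_daily_intake(rec, one_person, "disaggregated",
                                   profiles = fx_profiles),
               "no dairy profile: nope")
  rec2 <- data.frame(person_id = "ghost", day = 1,
                     food_code = "whole_milk", grams_consumed = 10)
  expect_error(person_daily_intake(rec2, one_person, "disaggregated",
                                   profiles = fx_profiles),
               "no survey weight: ghost")
  expect_error(person_daily_intake(
    data.frame(person_id = "p1", day = 3, food_code = "whole_milk",
               grams_consumed = 10),
    one_person, "disaggregated", profiles = fx_profiles), "day")
  expect_error(population_mean(data.frame(), one_person[0, ]),
               "empty population")
  expect_error(
    population_mean(data.frame(person_id = "a", category = "milk",
                               g_per_day = 1),
                    data.frame(person_id = "a", weight = 0)),
    "positive")
})

test_that("weighted means reduce to hand-computable values", {
  pv <- data.frame(person_id = rep(c("a", "b"), each = 5),
                   category = rep(c("milk", "cheese", "yogurt", "cream",
                                    "butter"), 2),
                   g_per_day = c(100, 0, 0, 0, 0, 300, 0, 0, 0, 0))
  eq <- population_mean(pv, data.frame(person_id = c("a", "b"),
                                       weight = c(1, 1)))
  expect_equal(eq$estimates$mean_g_per_day[eq$estimates$subtype == "milk"],
               200)
  wt <- population_mean(pv, data.frame(person_id = c("a", "b"),
                                       weight = c(3, 1)))
  expect_equal(wt$estimates$mean_g_per_day[wt$estimates$subtype == "milk"],
               150)
  # total row equals the sum of category rows
  tot <- wt$estimates$mean_g_per_day[wt$estimates$subtype == "total"]
  cats <- wt$estimates$mean_g_per_day[wt$estimates$subtype != "total"]
  expect_equal(tot, sum(cats), tolerance = 1e-9)
  # equal weights: SD reduces to the ordinary sample SD
  expect_equal(eq$estimates$sd_g_per_day[eq$estimates$subtype == "milk"],
               sd(c(100, 300)))
})

test_that("bias percentages reproduce the published worked arithmetic", {
  expect_equal(round_half_away(percent_bias(238.6, 218.4,
                                            "denominator_with")), 8)
  # Bolognese-sauce meat example: 145 g counted fully vs 81 g disaggregated
  expect_equal(round_half_away(percent_bias(81, 145,
                                            "denominator_without")), -44)
  expect_equal(percent_bias(5, 5), 0)
  expect_equal(percent_bias(0, 0), 0)
  expect_error(percent_bias(1, 0, "denominator_without"),
               "zero denominator")
})

test_that("bias reports compare the two modes subtype by subtype", {
  mk <- function(means, mode) {
    pv <- data.frame(person_id = "p1",
                     category = c("milk", "cheese", "yogurt", "cream",
                                  "butter"),
                     g_per_day = means)
    population_mean(pv, one_person, mode)
  }
  a <- mk(c(100, 50, 10, 5, 5), "disaggregated")
  b <- mk(c(107, 25, 11.5, 8.95, 2.5), "food_group")
  br <- bias_report(a, b, "denominator_with")
  expect_s3_class(br, "bias_report")
  expect_equal(attr(br, "convention"), "denominator_with")
  expect_equal(br$percent_bias_int[br$subtype == "cheese"], 50)
  expect_equal(br$direction[br$subtype == "milk"], "overestimated")
  expect_equal(br$direction[br$subtype == "cheese"], "underestimated")
  same <- bias_report(a, a)
  expect_true(all(same$percent_bias == 0))
  expect_true(all(same$direction == "unbiased"))
})

test_that("contribution shares are ratios of weighted group dairy mass", {
  rec <- data.frame(person_id = "p1", day = 1,
                    food_code = c("whole_milk", "croissant"),
                    grams_consumed = c(74, 104))
  # milk group: 74 g dairy; pastry group: 104 x 25/100 = 26 g dairy
  ct <- contribution_shares(rec, fx_profiles, one_person, fx$db$foods,
                            group_map = fx$group_map)
  expect_equal(ct$by_group$percent[ct$by_group$food_group == "GRP_MILK"],
               74)
  expect_equal(ct$by_group$percent[ct$by_group$food_group == "GRP_PASTRIES"],
               26)
  expect_equal(sum(ct$by_group$percent), 100)
  expect_equal(ct$rollup$percent[ct$rollup$source == "noncomposite"], 74)
  expect_equal(ct$rollup$percent[ct$rollup$source == "composite"], 26)

  solo <- contribution_shares(
    data.frame(person_id = "p1", day = 1, food_code = "whole_milk",
               grams_consumed = 10),
    fx_profiles, one_person, fx$db$foods)
  expect_equal(solo$by_group$percent, 100)

  expect_warning(
    empty <- contribution_shares(
      data.frame(person_id = "p1", day = 1, food_code = "wheat_flour",
                 grams_consumed = 10),
      fx_profiles, one_person,
      rbind(fx$db$foods,
            data.frame(food_code = "wheat_flour", description = "",
                       food_group = "GRP_FLOUR"))),
    "no dairy consumed")
  expect_equal(nrow(empty$by_group), 0)
})

test_that("estimates are scale-equivariant in grams and invariant to weight rescaling", {
  cfg <- generator_config(seed = 314, n_foods = 60, n_persons = 40)
  sim <- generate_recipe_db(cfg)
  sv <- generate_survey(cfg, sim)
  profs <- dairy_profiles(sim$db, sim$map)

  base_pv <- person_daily_intake(sv$recalls, sv$persons, "disaggregated",
                                 profiles = profs)
  base <- population_mean(base_pv, sv$persons)

  scaled_rec <- sv$recalls
  scaled_rec$grams_consumed <- scaled_rec$grams_consumed * 2.5
  scaled <- population_mean(
    person_daily_intake(scaled_rec, sv$persons, "disaggregated",
                        profiles = profs), sv$persons)
  expect_equal(scaled$estimates$mean_g_per_day,
               2.5 * base$estimates$mean_g_per_day, tolerance = 1e-12)

  reweighted <- sv$persons
  reweighted$weight <- reweighted$weight * 17
  rw <- population_mean(base_pv, reweighted)
  expect_equal(rw$estimates$mean_g_per_day, base$estimates$mean_g_per_day,
               tolerance = 1e-12)
  expect_equal(rw$estimates$sd_g_per_day, base$estimates$sd_g_per_day,
               tolerance = 1e-12)
})

test_that("modes agree when dairy foods are pure single-category and composites are dairy-free", {
  foods <- data.frame(food_code = c("milk_pint", "bread"),
                      description = "",
                      food_group = c("GRP_MILK", "GRP_CEREALS"))
  entries <- rbind(
    data.frame(parent_code = "milk_pint", component_code = "raw_milk",
               grams_per_100g = 100),
    data.frame(parent_code = "bread", component_code = c("flour", "water"),
               grams_per_100g = c(60, 40)))
  db <- recipe_db(foods, entries)
  map <- classification_map(data.frame(
    ingredient_code = c("raw_milk", "flour", "water"),
    category = c("milk", "non_dairy", "non_dairy"),
    fat_level = c("full_fat", "", ""), cheese_variety = ""))
  gm <- data.frame(food_group = c("GRP_MILK", "GRP_CEREALS"),
                   dairy_category = c("milk", "non_dairy"))
  profs <- dairy_profiles(db, map)
  set.seed(99)
  rec <- data.frame(person_id = rep(sprintf("p%02d", 1:20), each = 4),
                    day = rep(c(1, 1, 2, 2), 20),
                    food_code = sample(foods$food_code, 80, replace = TRUE),
                    grams_consumed = runif(80, 10, 400))
  per <- data.frame(person_id = sprintf("p%02d", 1:20),
                    weight = runif(20, 0.5, 2))
  a <- population_mean(person_daily_intake(rec, per, "disaggregated",
                                           profiles = profs), per,
                       "disaggregated")
  b <- population_mean(person_daily_intake(rec, per, "food_group",
                                           foods = foods, group_map = gm),
                       per, "food_group")
  br <- bias_report(a, b)
  expect_true(all(abs(br$percent_bias) < 1e-9))
})

test_that("estimates recover generator truth on a synthetic survey", {
  cfg <- generator_config(seed = 2718, n_foods = 150, n_persons = 2000)
  sim <- generate_recipe_db(cfg)
  sv <- generate_survey(cfg, sim)
  profs <- dairy_profiles(sim$db, sim$map)
  pv <- person_daily_intake(sv$recalls, sv$persons, "disaggregated",
                            profiles = profs)
  est <- population_mean(pv, sv$persons)
  x <- tapply(pv$g_per_day, pv$person_id, sum)[sv$persons$person_id]
  se <- dairydisagg:::weighted_mean_se(as.numeric(x), sv$persons$weight)
  got <- est$estimates$mean_g_per_day[est$estimates$subtype == "total"]
  truth <- sv$truth$expected_disaggregated[["total"]]
  expect_lt(abs(got - truth), 3 * se)
})
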