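# Synthetic recipe databases and weighted recall surveys with recorded
# ground truth, so every pipeline stage is testable without the restricted
# survey and recipe data the real analysis runs on. Ground-truth dairy
# profiles are computed with a brute-force path-product flattener that
# shares no code with the production resolver, so generator and pipeline
# cannot share a bug.

#' Configuration for the synthetic generators
#'
#' Defaults emulate the structure of the real study inputs: roughly 3%
#' pure-dairy foods, 29% dairy-containing composites and 68% dairy-free
#' foods; composite dairy content log-uniform over 0.01--98.44 g/100 g
#' (the observed four-orders-of-magnitude range); nested recipes; up to
#' two recall days per person; positive calibration-style survey weights
#' with mean 1. Distributional shapes the study does not pin down
#' (portion sizes, items per day, weights) are package conventions,
#' documented in the methods vignette.
#'
#' @param n_foods number of foods in the generated database.
#' @param fractions named numeric (pure_dairy, composite_dairy, non_dairy)
#'   summing to 1.
#' @param dairy_content_range composite dairy content range, g/100 g,
#'   sampled log-uniformly.
#' @param max_depth maximum recipe nesting depth (1 = no sub-recipes).
#' @param p_subrecipe probability a composite or dairy-free food embeds an
#'   earlier food as a sub-recipe (depth allowing).
#' @param p_composite_in_dairy_group probability a composite food is filed
#'   under a dairy food group (the "ice cream in the cream group" effect).
#' @param n_persons number of survey respondents.
#' @param p_two_days probability a respondent completes a second recall day.
#' @param items_per_day_mean Poisson mean of recalled items per day
#'   (truncated below at 1).
#' @param portion_meanlog,portion_sdlog log-normal portion size parameters
#'   (grams).
#' @param weight_shift,weight_shape,weight_rate survey weight =
#'   shift + Gamma(shape, rate); defaults give positive weights with
#'   mean 1.
#' @param seed integer random seed; mandatory, recorded in the outputs.
#' @return list of class \code{generator_config}.
#' @export
generator_config <- function(n_foods = 300L,
                             fractions = c(pure_dairy = 0.03,
                                           composite_dairy = 0.29,
                                           non_dairy = 0.68),
                             dairy_content_range = c(0.01, 98.44),
                             max_depth = 3L,
                             p_subrecipe = 0.3,
                             p_composite_in_dairy_group = 0.1,
                             n_persons = 500L,
                             p_two_days = 0.8,
                             items_per_day_mean = 12,
                             portion_meanlog = log(80),
                             portion_sdlog = 0.6,
                             weight_shift = 0.2,
                             weight_shape = 2,
                             weight_rate = 2.5,
                             seed) {
  if (missing(seed) || is.null(seed))
    stop("a seed is mandatory for reproducibility", call. = FALSE)
  fr <- fractions[c("pure_dairy", "composite_dairy", "non_dairy")]
  if (anyNA(fr) || abs(sum(fr) - 1) > 1e-9)
    stop("fractions must name pure_dairy/composite_dairy/non_dairy and sum ",
         "to 1", call. = FALSE)
  if (max_depth < 1L)
    stop("max_depth must be >= 1", call. = FALSE)
  if (max_depth == 1L && p_subrecipe > 0)
    stop("infeasible config: sub-recipes require max_depth >= 2",
         call. = FALSE)
  stopifnot(n_foods >= 1L, all(dairy_content_range > 0),
            dairy_content_range[1] < dairy_content_range[2],
            dairy_content_range[2] < 100,
            p_two_days >= 0, p_two_days <= 1,
            items_per_day_mean > 0, portion_sdlog >= 0,
            weight_shift >= 0, weight_shape > 0, weight_rate > 0)
  structure(
    list(n_foods = as.integer(n_foods), fractions = fr,
         dairy_content_range = dairy_content_range,
         max_depth = as.integer(max_depth), p_subrecipe = p_subrecipe,
         p_composite_in_dairy_group = p_composite_in_dairy_group,
         n_persons = as.integer(n_persons), p_two_days = p_two_days,
         items_per_day_mean = items_per_day_mean,
         portion_meanlog = portion_meanlog, portion_sdlog = portion_sdlog,
         weight_shift = weight_shift, weight_shape = weight_shape,
         weight_rate = weight_rate, seed = as.integer(seed)),
    class = "generator_config"
  )
}

# dairy ingredient roster spanning the subtype space
synthetic_dairy_ingredients <- function() {
  data.frame(
    ingredient_code = c("ING_MILK_SKIMMED", "ING_MILK_SEMISKIMMED",
                        "ING_MILK_FULLFAT", "ING_CHEESE_CHEDDAR",
                        "ING_CHEESE_COTTAGE", "ING_CHEESE_OTHER",
                        "ING_YOGURT_SKIMMED", "ING_YOGURT_FULLFAT",
                        "ING_CREAM_SEMI", "ING_CREAM_FULLFAT",
                        "ING_BUTTER"),
    category = c("milk", "milk", "milk", "cheese", "cheese", "cheese",
                 "yogurt", "yogurt", "cream", "cream", "butter"),
    fat_level = c("skimmed", "semiskimmed", "full_fat", "full_fat",
                  "not_applicable", "full_fat", "skimmed", "full_fat",
                  "semiskimmed", "full_fat", "not_applicable"),
    cheese_variety = c(rep("not_applicable", 3), "cheddar", "cottage",
                       "other", rep("not_applicable", 5)),
    stringsAsFactors = FALSE
  )
}

NON_DAIRY_GROUPS <- c("GRP_CEREALS", "GRP_MEAT_DISHES", "GRP_VEG",
                      "GRP_SWEETS", "GRP_SANDWICHES")
DAIRY_GROUP_OF <- c(milk = "GRP_MILK", cheese = "GRP_CHEESE",
                    yogurt = "GRP_YOGURT", cream = "GRP_CREAM",
                    butter = "GRP_BUTTER")

#' Generate a synthetic recipe database with known truth
#'
#' Draws each food's class from the configured fractions, builds acyclic
#' recipes (sub-recipes only reference earlier foods, bounding depth by
#' construction), assigns food groups, and records ground-truth dairy
#' profiles computed by the independent path-product flattener
#' [flatten_by_paths()].
#'
#' Pure-dairy foods are composed only of dairy ingredients; composite foods
#' carry a log-uniform direct dairy mass plus non-dairy remainder (possibly
#' through a nested sub-recipe); dairy-free foods contain no dairy anywhere.
#' All recipes sum to 100 g per 100 g.
#'
#' @param config a [generator_config()].
#' @return list with \code{db} ([recipe_db()]), \code{map}
#'   ([classification_map()]), \code{group_map}, \code{truth} (list:
#'   \code{profiles} long data.frame, \code{food_class},
#'   \code{total_dairy}, per-food named vectors), and \code{config}.
#' @export
generate_recipe_db <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(config$seed)

  dairy <- synthetic_dairy_ingredients()
  nd_codes <- sprintf("ING_ND_%02d", 1:20)
  map <- classification_map(rbind(
    dairy,
    data.frame(ingredient_code = nd_codes, category = NON_DAIRY,
               fat_level = "not_applicable",
               cheese_variety = "not_applicable",
               stringsAsFactors = FALSE)))

  n <- config$n_foods
  classes <- sample(names(config$fractions), n, replace = TRUE,
                    prob = config$fractions)
  codes <- sprintf("F%04d", seq_len(n))
  lo <- log(config$dairy_content_range[1])
  hi <- log(config$dairy_content_range[2])

  entries <- vector("list", n)
  groups <- character(n)
  depth <- integer(n)          # recipe depth; base ingredients are depth 0
  names(depth) <- codes

  # earlier foods eligible as sub-recipes of the current one
  embeddable <- function(i, want_classes) {
    if (i == 1L || stats::runif(1) > config$p_subrecipe) return(NA_character_)
    prev <- which(classes[seq_len(i - 1L)] %in% want_classes &
                    depth[seq_len(i - 1L)] < config$max_depth - 1L)
    if (length(prev) == 0L) return(NA_character_)
    codes[[sample(prev, 1L)]]
  }

  for (i in seq_len(n)) {
    code <- codes[[i]]
    cl <- classes[[i]]
    if (cl == "pure_dairy") {
      k <- sample(1:2, 1L)
      ing <- sample(dairy$ingredient_code, k)
      amt <- as.numeric(stats::rmultinom(1L, 100L, rep(1, k)))
      keep <- amt > 0
      entries[[i]] <- data.frame(parent_code = code,
                                 component_code = ing[keep],
                                 grams_per_100g = amt[keep],
                                 stringsAsFactors = FALSE)
      depth[[i]] <- 1L
      dom <- dairy$category[match(ing[keep][which.max(amt[keep])],
                                  dairy$ingredient_code)]
      groups[[i]] <- DAIRY_GROUP_OF[[dom]]
    } else if (cl == "composite_dairy") {
      d <- exp(stats::runif(1, lo, hi))
      ing <- sample(dairy$ingredient_code, 1L)
      rem <- 100 - d
      sub <- embeddable(i, c("non_dairy"))
      rows <- data.frame(parent_code = code, component_code = ing,
                         grams_per_100g = d, stringsAsFactors = FALSE)
      comp_depth <- 1L
      if (!is.na(sub) && rem > 1) {
        sub_g <- rem * stats::runif(1, 0.3, 0.7)
        rows <- rbind(rows, data.frame(parent_code = code,
                                       component_code = sub,
                                       grams_per_100g = sub_g,
                                       stringsAsFactors = FALSE))
        rem <- rem - sub_g
        comp_depth <- depth[[sub]] + 1L
      }
      nd <- sample(nd_codes, 2L)
      split_f <- stats::runif(1, 0.2, 0.8)
      rows <- rbind(rows,
                    data.frame(parent_code = code,
                               component_code = nd,
                               grams_per_100g = c(rem * split_f,
                                                  rem * (1 - split_f)),
                               stringsAsFactors = FALSE))
      entries[[i]] <- rows
      depth[[i]] <- max(1L, comp_depth)
      dom <- dairy$category[match(ing, dairy$ingredient_code)]
      groups[[i]] <-
        if (stats::runif(1) < config$p_composite_in_dairy_group)
          DAIRY_GROUP_OF[[dom]]
        else sample(NON_DAIRY_GROUPS, 1L)
    } else {
      k <- sample(2:4, 1L)
      ing <- sample(nd_codes, k)
      amt <- as.numeric(stats::rmultinom(1L, 100L, rep(1, k)))
      rows <- data.frame(parent_code = code, component_code = ing,
                         grams_per_100g = amt, stringsAsFactors = FALSE)
      rows <- rows[rows$grams_per_100g > 0, , drop = FALSE]
      comp_depth <- 1L
      sub <- embeddable(i, c("non_dairy"))
      if (!is.na(sub)) {
        take <- which.max(rows$grams_per_100g)
        rows$component_code[take] <- sub
        comp_depth <- depth[[sub]] + 1L
      }
      entries[[i]] <- rows
      depth[[i]] <- comp_depth
      groups[[i]] <- sample(NON_DAIRY_GROUPS, 1L)
    }
  }

  foods <- data.frame(food_code = codes,
                      description = paste("synthetic food", codes),
                      food_group = groups, stringsAsFactors = FALSE)
  entries <- do.call(rbind, entries)
  # collapse any repeated (parent, component) pairs from repeated sampling
  entries <- stats::aggregate(grams_per_100g ~ parent_code + component_code,
                              data = entries, FUN = sum)
  db <- recipe_db(foods, entries)

  group_map <- data.frame(
    food_group = c(unname(DAIRY_GROUP_OF), NON_DAIRY_GROUPS),
    dairy_category = c(names(DAIRY_GROUP_OF),
                       rep(NON_DAIRY, length(NON_DAIRY_GROUPS))),
    stringsAsFactors = FALSE)

  truth <- truth_profiles(db, map)
  list(db = db, map = map, group_map = group_map, truth = truth,
       config = config)
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Brute-force path-product recipe flattener
#'
#' Independent oracle for recipe resolution: enumerates every root-to-leaf
#' path in the recipe graph, multiplying the per-100 g fractions along the
#' path, and sums leaf contributions. Exponential in depth, linear-minded
#' and obviously correct; used to compute generator ground truth and as the
#' reference the recursive resolver is tested against.
#'
#' @param entries recipe entry data.frame (\code{parent_code,
#'   component_code, grams_per_100g}).
#' @param food_code code to flatten.
#' @return named numeric vector: grams of each base ingredient per 100 g,
#'   sorted by code.
#' @export
flatten_by_paths <- function(entries, food_code) {
  rec <- function(code, mult) {
    rows <- which(entries$parent_code == code)
    if (length(rows) == 0L)
      return(stats::setNames(mult * 100, code))
    out <- numeric(0)
    for (r in rows) {
      out <- c(out, rec(entries$component_code[[r]],
                        mult * entries$grams_per_100g[[r]] / 100))
    }
    out
  }
  v <- rec(as.character(food_code), 1)
  s <- tapply(v, names(v), sum)
  out <- stats::setNames(as.numeric(s), names(s))
  out[order(names(out))]
}

# Ground-truth profiles via the brute-force flattener (NOT resolve_recipe).
truth_profiles <- function(db, map) {
  rows <- lapply(db$foods$food_code, function(fc) {
    flat <- flatten_by_paths(db$entries, fc)
    cls <- lookup_classes(map, names(flat))
    isd <- cls$category != NON_DAIRY
    total <- sum(flat[isd])
    fclass <- if (total <= 0) "non_dairy"
      else if (all(isd)) "pure_dairy" else "composite_dairy"
    prof <- if (any(isd)) {
      data.frame(food_code = fc, category = cls$category[isd],
                 fat_level = cls$fat_level[isd],
                 cheese_variety = cls$cheese_variety[isd],
                 grams_per_100g = as.numeric(flat[isd]),
                 stringsAsFactors = FALSE)
    } else NULL
    list(profile = prof, total = total, fclass = fclass)
  })
  profiles <- do.call(rbind, lapply(rows, `[[`, "profile"))
  if (!is.null(profiles)) {
    profiles <- stats::aggregate(
      grams_per_100g ~ food_code + category + fat_level + cheese_variety,
      data = profiles, FUN = sum)
  } else {
    profiles <- data.frame(food_code = character(), category = character(),
                           fat_level = character(),
                           cheese_variety = character(),
                           grams_per_100g = numeric(),
                           stringsAsFactors = FALSE)
  }
  list(profiles = profiles,
       total_dairy = stats::setNames(vapply(rows, `[[`, numeric(1), "total"),
                                     db$foods$food_code),
       food_class = stats::setNames(vapply(rows, `[[`, character(1),
                                           "fclass"),
                                    db$foods$food_code))
}

#' Generate a synthetic weighted recall survey
#'
#' Draws respondents (positive survey weights, 1 or 2 completed recall
#' days), then per person-day a Poisson number of items (at least 1), foods
#' uniform over the database, and log-normal portions. Records the analytic
#' expected per-capita intake implied by the sampling scheme under both
#' estimation modes, and the expected food-group contribution shares, so
#' estimator output can be checked against truth.
#'
#' @param config a [generator_config()].
#' @param sim output of [generate_recipe_db()] (its db, group_map and truth
#'   are used).
#' @return list with \code{recalls}, \code{persons} data.frames and
#'   \code{truth}: \code{expected_disaggregated} and
#'   \code{expected_food_group} (named g/day by category plus total) and
#'   \code{expected_shares} (by food group, plus composite/noncomposite
#'   rollup).
#' @export
generate_survey <- function(config, sim) {
  stopifnot(inherits(config, "generator_config"))
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed((config$seed + 499979L) %% .Machine$integer.max)

  db <- sim$db
  n <- config$n_persons
  if (n < 1L) stop("n_persons must be >= 1", call. = FALSE)
  persons <- data.frame(
    person_id = sprintf("P%05d", seq_len(n)),
    weight = config$weight_shift +
      stats::rgamma(n, shape = config$weight_shape,
                    rate = config$weight_rate),
    n_days_completed = 1L + stats::rbinom(n, 1L, config$p_two_days),
    stringsAsFactors = FALSE)

  recs <- vector("list", n)
  for (i in seq_len(n)) {
    days <- seq_len(persons$n_days_completed[[i]])
    per_day <- pmax(1L, stats::rpois(length(days),
                                     config$items_per_day_mean))
    total_items <- sum(per_day)
    recs[[i]] <- data.frame(
      person_id = persons$person_id[[i]],
      day = rep(days, per_day),
      food_code = sample(db$foods$food_code, total_items, replace = TRUE),
      grams_consumed = stats::rlnorm(total_items, config$portion_meanlog,
                                     config$portion_sdlog),
      stringsAsFactors = FALSE)
  }
  recalls <- do.call(rbind, recs)

  # analytic expectations under the sampling scheme:
  #   E[items/day] for max(1, Pois(lambda)) = lambda + P(X = 0)
  #   E[portion]   = exp(meanlog + sdlog^2/2)
  lam <- config$items_per_day_mean
  e_items <- lam + stats::dpois(0L, lam)
  e_portion <- exp(config$portion_meanlog + config$portion_sdlog^2 / 2)
  nf <- nrow(db$foods)

  prof <- sim$truth$profiles
  cat_g <- tapply(prof$grams_per_100g, prof$category, sum)
  exp_dis <- stats::setNames(numeric(length(DAIRY_CATEGORIES)),
                             DAIRY_CATEGORIES)
  exp_dis[names(cat_g)] <- e_items * e_portion * as.numeric(cat_g) /
    (100 * nf)
  exp_dis[["total"]] <- sum(exp_dis)

  gm <- sim$group_map
  grp_cat <- stats::setNames(gm$dairy_category, gm$food_group)
  food_cat <- grp_cat[db$foods$food_group]
  exp_fg <- stats::setNames(numeric(length(DAIRY_CATEGORIES) + 1L),
                            c(DAIRY_CATEGORIES, "total"))
  for (ct in DAIRY_CATEGORIES)
    exp_fg[[ct]] <- e_items * e_portion * sum(food_cat == ct) / nf
  exp_fg[["total"]] <- sum(exp_fg[DAIRY_CATEGORIES])

  per_food_dairy <- sim$truth$total_dairy[db$foods$food_code]
  per_group <- tapply(per_food_dairy, db$foods$food_group, sum)
  per_group <- per_group[per_group > 0]
  shares <- 100 * as.numeric(per_group) / sum(per_group)
  exp_shares <- data.frame(food_group = names(per_group), percent = shares,
                           stringsAsFactors = FALSE)
  src <- ifelse(grp_cat[exp_shares$food_group] == NON_DAIRY,
                "composite", "noncomposite")
  rollup <- tapply(exp_shares$percent, src, sum)

  truth <- c(sim$truth,
             list(expected_disaggregated = exp_dis,
                  expected_food_group = exp_fg,
                  expected_shares = exp_shares,
                  expected_rollup = stats::setNames(as.numeric(rollup),
                                                    names(rollup))))
  list(recalls = recalls, persons = persons, truth = truth)
}

#' Worked-example fixture bundle
#'
#' A small hand-built database of the canonical worked examples used
#' throughout the documentation and tests: a plain croissant (25 g butter
#' per 100 g), homemade Yorkshire pudding (60 g semiskimmed milk per
#' 100 g), spreadable butter (63 g butter), salted butter (98.44 g butter +
#' 1.56 g salt -- a composite, since salt is not dairy), a Kulfi-style ice
#' cream (40 g cream), whole milk (pure dairy), and a nested
#' lasagna/cheese-sauce pair exercising sub-recipe resolution.
#'
#' @return list with \code{db}, \code{map}, \code{group_map}.
#' @examples
#' fx <- dairy_fixtures()
#' dairy_profile(fx$db, fx$map, "croissant")$total_dairy_g_per_100g
#' @export
dairy_fixtures <- function() {
  foods <- data.frame(
    food_code = c("croissant", "yorkshire_pudding", "spreadable_butter",
                  "salted_butter", "kulfi", "whole_milk", "cheese_sauce",
                  "lasagna"),
    description = c("plain croissant", "homemade Yorkshire pudding",
                    "spreadable butter blend", "butter, salted",
                    "Kulfi, Indian ice cream", "whole milk",
                    "cheddar cheese sauce", "lasagna with cheese sauce"),
    food_group = c("GRP_PASTRIES", "GRP_CEREAL_DISHES", "GRP_BUTTER",
                   "GRP_BUTTER", "GRP_ICE_CREAM", "GRP_MILK",
                   "GRP_SAUCES", "GRP_PASTA"),
    stringsAsFactors = FALSE)
  entries <- rbind(
    data.frame(parent_code = "croissant",
               component_code = c("butter", "wheat_flour"),
               grams_per_100g = c(25, 75)),
    data.frame(parent_code = "yorkshire_pudding",
               component_code = c("semiskimmed_milk", "wheat_flour", "egg"),
               grams_per_100g = c(60, 25, 15)),
    data.frame(parent_code = "spreadable_butter",
               component_code = c("butter", "vegetable_oil"),
               grams_per_100g = c(63, 37)),
    data.frame(parent_code = "salted_butter",
               component_code = c("butter", "salt"),
               grams_per_100g = c(98.44, 1.56)),
    data.frame(parent_code = "kulfi",
               component_code = c("double_cream", "sugar", "nuts"),
               grams_per_100g = c(40, 35, 25)),
    data.frame(parent_code = "whole_milk",
               component_code = "raw_whole_milk",
               grams_per_100g = 100),
    data.frame(parent_code = "cheese_sauce",
               component_code = c("cheddar_cheese", "semiskimmed_milk",
                                  "wheat_flour"),
               grams_per_100g = c(30, 50, 20)),
    data.frame(parent_code = "lasagna",
               component_code = c("cheese_sauce", "pasta", "minced_beef"),
               grams_per_100g = c(40, 30, 30)))
  db <- recipe_db(foods, entries)

  map <- classification_map(data.frame(
    ingredient_code = c("butter", "semiskimmed_milk", "raw_whole_milk",
                        "double_cream", "cheddar_cheese", "wheat_flour",
                        "egg", "vegetable_oil", "salt", "sugar", "nuts",
                        "pasta", "minced_beef"),
    category = c("butter", "milk", "milk", "cream", "cheese",
                 rep(NON_DAIRY, 8)),
    fat_level = c("not_applicable", "semiskimmed", "full_fat", "full_fat",
                  "full_fat", rep("not_applicable", 8)),
    cheese_variety = c(rep("not_applicable", 4), "cheddar",
                       rep("not_applicable", 8)),
    stringsAsFactors = FALSE))

  group_map <- data.frame(
    food_group = c("GRP_MILK", "GRP_BUTTER", "GRP_ICE_CREAM",
                   "GRP_PASTRIES", "GRP_CEREAL_DISHES", "GRP_SAUCES",
                   "GRP_PASTA"),
    dairy_category = c("milk", "butter", "cream", NON_DAIRY, NON_DAIRY,
                       NON_DAIRY, NON_DAIRY),
    stringsAsFactors = FALSE)

  list(db = db, map = map, group_map = group_map)
}

#' Write a synthetic dataset to the pipeline's CSV schemas
#'
#' @param sim output of [generate_recipe_db()].
#' @param survey output of [generate_survey()] (optional).
#' @param dir output directory, created if absent.
#' @param header metadata lines for the file headers.
#' @return Invisibly, the vector of files written.
#' @export
write_synthetic_csvs <- function(sim, survey = NULL, dir,
                                 header = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(foods = "foods.csv", recipes = "recipes.csv",
             classification = "classification.csv",
             group_map = "group_map.csv", truth = "truth_profiles.csv")
  write_csv_with_header(sim$db$foods, file.path(dir, files[["foods"]]),
                        header)
  write_csv_with_header(sim$db$entries, file.path(dir, files[["recipes"]]),
                        header)
  cm <- sim$map
  class(cm) <- "data.frame"
  write_csv_with_header(cm, file.path(dir, files[["classification"]]),
                        header)
  write_csv_with_header(sim$group_map, file.path(dir, files[["group_map"]]),
                        header)
  write_csv_with_header(sim$truth$profiles,
                        file.path(dir, files[["truth"]]), header)
  if (!is.null(survey)) {
    files <- c(files, recalls = "recalls.csv", persons = "persons.csv")
    write_csv_with_header(survey$recalls, file.path(dir, "recalls.csv"),
                          header)
    write_csv_with_header(survey$persons, file.path(dir, "persons.csv"),
                          header)
  }
  invisible(file.path(dir, files))
}
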