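# Random acyclic recipe databases for property tests. Sub-recipes only
# reference earlier foods, so the graph is acyclic and depth-bounded by
# construction; every recipe sums to exactly 100 g/100 g so that nested
# resolution conserves mass.

test_dairy_pool <- function() {
  data.frame(
    ingredient_code = c("D_MILK_SK", "D_MILK_SS", "D_MILK_FF", "D_CHED",
                        "D_COTT", "D_YOG", "D_CREAM", "D_BUTTER"),
    category = c("milk", "milk", "milk", "cheese", "cheese", "yogurt",
                 "cream", "butter"),
    fat_level = c("skimmed", "semiskimmed", "full_fat", "full_fat",
                  "not_applicable", "full_fat", "full_fat",
                  "not_applicable"),
    cheese_variety = c(rep("not_applicable", 3), "cheddar", "cottage",
                       rep("not_applicable", 3)),
    stringsAsFactors = FALSE)
}

test_classification <- function() {
  d <- test_dairy_pool()
  nd <- sprintf("N_%02d", 1:10)
  classification_map(rbind(
    d,
    data.frame(ingredient_code = nd, category = "non_dairy",
               fat_level = "not_applicable",
               cheese_variety = "not_applicable",
               stringsAsFactors = FALSE)))
}

# n_foods foods, nesting depth <= max_depth; returns list(db, map)
random_test_db <- function(n_foods = 20, max_depth = 4, seed = 1) {
  set.seed(seed)
  map <- test_classification()
  ings <- map$ingredient_code
  codes <- sprintf("RF%03d", seq_len(n_foods))
  depth <- integer(n_foods)
  entries <- vector("list", n_foods)
  for (i in seq_len(n_foods)) {
    k <- sample(1:4, 1)
    pool <- ings
    # candidate earlier foods shallow enough to embed
    prev <- if (i > 1) which(depth[seq_len(i - 1)] < max_depth - 1) else
      integer(0)
    comp <- character(k)
    for (j in seq_len(k)) {
      if (length(prev) > 0 && runif(1) < 0.4) {
        comp[j] <- codes[sample(prev, 1)]
      } else {
        comp[j] <- sample(pool, 1)
      }
    }
    comp <- unique(comp)
    amt <- as.numeric(rmultinom(1, 100, rep(1, length(comp))))
    keep <- amt > 0
    entries[[i]] <- data.frame(parent_code = codes[i],
                               component_code = comp[keep],
                               grams_per_100g = amt[keep],
                               stringsAsFactors = FALSE)
    sub_depth <- depth[match(comp[keep], codes)]
    sub_depth[is.na(sub_depth)] <- 0L
    depth[i] <- 1L + max(sub_depth)
  }
  foods <- data.frame(food_code = codes, description = codes,
                      food_group = "GRP_X", stringsAsFactors = FALSE)
  db <- recipe_db(foods, do.call(rbind, entries))
  list(db = db, map = map)
}

# resolved table -> named vector, for comparison against flatten_by_paths
resolved_as_vector <- function(res) {
  stats::setNames(res$grams_per_100g, res$ingredient_code)
}
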