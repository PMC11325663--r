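# Per-food dairy profiles: grams of each dairy subtype per 100 g of product,
# obtained by flattening the recipe and summing the resolved masses of
# dairy-classified ingredients within each (category, fat level, variety)
# triple. Foods are classed structurally: "pure dairy" means every resolved
# ingredient is dairy-classified, regardless of mass -- which is why 98.44 g
# dairy "butter, salted" still counts as a composite (the salt is not dairy).

#' Dairy profile of one food
#'
#' Resolves \code{food_code} to base ingredients, classifies each, and sums
#' grams per 100 g within each dairy subtype. The food is classed as
#' \code{pure_dairy} (every resolved ingredient dairy), \code{non_dairy}
#' (zero dairy mass) or \code{composite_dairy} (anything between).
#'
#' @param db a [recipe_db()].
#' @param map a [classification_map()] covering every base ingredient the
#'   food resolves to.
#' @param food_code single food code.
#' @return Object of class \code{dairy_profile}: list with \code{food_code},
#'   \code{total_dairy_g_per_100g}, \code{by_subtype} (data.frame
#'   \code{category, fat_level, cheese_variety, grams_per_100g}, dairy rows
#'   only, sorted), \code{food_class} and \code{resolved_mass_g_per_100g}.
#' @examples
#' fx <- dairy_fixtures()
#' dairy_profile(fx$db, fx$map, "croissant")
#' @export
dairy_profile <- function(db, map, food_code) {
  res <- resolve_recipe(db, food_code)
  cls <- lookup_classes(map, res$ingredient_code)
  dairy <- cls$category != NON_DAIRY
  resolved_mass <- sum(res$grams_per_100g)

  if (any(dairy)) {
    key <- interaction(cls$category[dairy], cls$fat_level[dairy],
                       cls$cheese_variety[dairy], drop = TRUE, lex.order = TRUE)
    g <- tapply(res$grams_per_100g[dairy], key, sum)
    parts <- do.call(rbind, strsplit(names(g), ".", fixed = TRUE))
    by_subtype <- data.frame(category = parts[, 1], fat_level = parts[, 2],
                             cheese_variety = parts[, 3],
                             grams_per_100g = as.numeric(g),
                             row.names = NULL, stringsAsFactors = FALSE)
    ord <- order(by_subtype$category, by_subtype$fat_level,
                 by_subtype$cheese_variety)
    by_subtype <- by_subtype[ord, , drop = FALSE]
    rownames(by_subtype) <- NULL
  } else {
    by_subtype <- data.frame(category = character(), fat_level = character(),
                             cheese_variety = character(),
                             grams_per_100g = numeric(),
                             stringsAsFactors = FALSE)
  }
  total <- sum(by_subtype$grams_per_100g)

  structure(
    list(food_code = as.character(food_code),
         total_dairy_g_per_100g = total,
         by_subtype = by_subtype,
         food_class = .food_class(dairy, total),
         resolved_mass_g_per_100g = resolved_mass),
    class = "dairy_profile"
  )
}

.food_class <- function(dairy_flags, total_dairy) {
  if (total_dairy <= 0) "non_dairy"
  else if (all(dairy_flags)) "pure_dairy"
  else "composite_dairy"
}

#' @export
print.dairy_profile <- function(x, ...) {
  cat("<dairy_profile> ", x$food_code, " [", x$food_class, "]: ",
      format(x$total_dairy_g_per_100g), " g dairy / 100 g\n", sep = "")
  if (nrow(x$by_subtype) > 0L) print(x$by_subtype)
  invisible(x)
}

#' Classify a resolved food
#'
#' Structural classification of a flattened ingredient list:
#' \code{pure_dairy} iff every resolved ingredient is dairy-classified,
#' \code{non_dairy} iff the total dairy mass is zero, else
#' \code{composite_dairy}.
#'
#' @param resolved data.frame as returned by [resolve_recipe()].
#' @param map a [classification_map()].
#' @return One of \code{"pure_dairy"}, \code{"composite_dairy"},
#'   \code{"non_dairy"}.
#' @export
classify_food <- function(resolved, map) {
  cls <- lookup_classes(map, resolved$ingredient_code)
  dairy <- cls$category != NON_DAIRY
  .food_class(dairy, sum(resolved$grams_per_100g[dairy]))
}

#' Dairy profiles for every food in a database
#'
#' @param db a [recipe_db()].
#' @param map a [classification_map()].
#' @return Named list of [dairy_profile()] objects, one per food in
#'   \code{db$foods}, in food-list order.
#' @export
dairy_profiles <- function(db, map) {
  codes <- db$foods$food_code
  out <- lapply(codes, function(fc) dairy_profile(db, map, fc))
  names(out) <- codes
  out
}

#' Long profile table
#'
#' One row per (food, dairy subtype) with grams per 100 g, plus the per-food
#' class and total. This is the join-ready form the intake estimator
#' consumes; [write_profiles_csv()] writes the wide reporting form.
#'
#' @param profiles list of [dairy_profile()] objects.
#' @return data.frame \code{food_code, food_class, total_dairy_g_per_100g,
#'   category, fat_level, cheese_variety, grams_per_100g} (dairy rows only;
#'   non-dairy foods appear with zero rows here but are retained in
#'   [summarize_database()]).
#' @export
profile_table <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    if (nrow(p$by_subtype) == 0L) return(NULL)
    cbind(data.frame(food_code = p$food_code, food_class = p$food_class,
                     total_dairy_g_per_100g = p$total_dairy_g_per_100g,
                     stringsAsFactors = FALSE),
          p$by_subtype)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(food_code = character(), food_class = character(),
                      total_dairy_g_per_100g = numeric(),
                      category = character(), fat_level = character(),
                      cheese_variety = character(),
                      grams_per_100g = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarise a profiled database
#'
#' Counts foods by class and reports the percentage containing any dairy.
#' Percentages are carried at full precision; \code{percent_any_dairy_int}
#' applies reporting-time rounding (nearest integer, half away from zero).
#'
#' @param profiles non-empty list of [dairy_profile()] objects, one per food.
#' @return list of class \code{db_summary}: \code{n_foods},
#'   \code{n_pure_dairy}, \code{n_composite_dairy}, \code{n_non_dairy},
#'   \code{percent_any_dairy}, \code{percent_any_dairy_int}.
#' @export
summarize_database <- function(profiles) {
  if (length(profiles) == 0L)
    stop("empty profile set", call. = FALSE)
  cls <- vapply(profiles, function(p) p$food_class, character(1))
  n <- length(cls)
  np <- sum(cls == "pure_dairy")
  nc <- sum(cls == "composite_dairy")
  nn <- sum(cls == "non_dairy")
  pct <- 100 * (np + nc) / n
  structure(
    list(n_foods = n, n_pure_dairy = np, n_composite_dairy = nc,
         n_non_dairy = nn, percent_any_dairy = pct,
         percent_any_dairy_int = round_half_away(pct)),
    class = "db_summary"
  )
}

#' @export
print.db_summary <- function(x, ...) {
  cat("<db_summary> ", x$n_foods, " foods: ", x$n_pure_dairy,
      " pure dairy, ", x$n_composite_dairy, " composite dairy, ",
      x$n_non_dairy, " non-dairy (", x$percent_any_dairy_int,
      "% contain dairy)\n", sep = "")
  invisible(x)
}

#' Reporting-time rounding: nearest integer, halves away from zero
#'
#' All percentages in this package are carried at full precision and only
#' rounded when reported; base \code{round()} rounds halves to even, which
#' is not the convention used for published percentages.
#'
#' @param x numeric vector.
#' @return \code{x} rounded to the nearest integer, halves away from zero.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Write the wide profiles CSV
#'
#' One row per food: \code{food_code, food_class, total_dairy_g_per_100g},
#' then one \code{category.fat_level.cheese_variety} column per subtype
#' present anywhere in the database.
#'
#' @param profiles list of [dairy_profile()] objects.
#' @param path output path.
#' @param header optional character vector of \code{#}-prefixed metadata
#'   lines to prepend.
#' @return The wide data.frame, invisibly.
#' @export
write_profiles_csv <- function(profiles, path, header = NULL) {
  long <- profile_table(profiles)
  keys <- unique(long[c("category", "fat_level", "cheese_variety")])
  keys <- keys[order(keys$category, keys$fat_level, keys$cheese_variety), ,
               drop = FALSE]
  wide <- data.frame(
    food_code = vapply(profiles, function(p) p$food_code, character(1)),
    food_class = vapply(profiles, function(p) p$food_class, character(1)),
    total_dairy_g_per_100g =
      vapply(profiles, function(p) p$total_dairy_g_per_100g, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(keys))) {
    col <- paste(keys$category[i], keys$fat_level[i], keys$cheese_variety[i],
                 sep = ".")
    sel <- long$category == keys$category[i] &
      long$fat_level == keys$fat_level[i] &
      long$cheese_variety == keys$cheese_variety[i]
    v <- stats::setNames(long$grams_per_100g[sel], long$food_code[sel])
    wide[[col]] <- unname(v[wide$food_code])
    wide[[col]][is.na(wide[[col]])] <- 0
  }
  write_csv_with_header(wide, path, header)
  invisible(wide)
}

write_csv_with_header <- function(df, path, header = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE)
}
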