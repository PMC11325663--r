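# Survey-weighted per-capita intake estimation, in two modes:
#
#   disaggregated -- each recalled item contributes
#                    grams_consumed x (subtype g per 100 g) / 100,
#                    using the dairy profiles from the recipe resolver;
#   food_group    -- the naive "without disaggregation" mode: an item whose
#                    food group is mapped to a dairy category contributes its
#                    FULL reported weight to that category, every other item
#                    contributes nothing. This is what treating "dairy food
#                    groups" as 100% dairy means, and it reproduces the
#                    characteristic signs of non-disaggregation bias: fruit
#                    yogurts and ice creams count fully (overestimation of
#                    yogurt and cream), while cheese and butter hidden in
#                    composites are missed entirely (underestimation).
#
# Per person, day totals are averaged over the person's completed days, so
# the unit is g/day per capita; nonconsumers contribute zeros. Estimates are
# then weighted across persons with the survey weights.

#' Per-person daily dairy intake by category
#'
#' @param recalls data.frame \code{person_id, day, food_code,
#'   grams_consumed}; day is a positive integer (at most
#'   \code{max_days}), grams non-negative.
#' @param persons data.frame \code{person_id, weight} and optionally
#'   \code{n_days_completed}; if absent, completed days are taken as the
#'   number of distinct recall days observed per person (minimum 1).
#' @param mode \code{"disaggregated"} or \code{"food_group"}.
#' @param profiles list of [dairy_profile()] objects covering every recalled
#'   food (disaggregated mode).
#' @param foods food list data.frame with \code{food_code, food_group}
#'   (food_group mode).
#' @param group_map data.frame \code{food_group, dairy_category} where
#'   \code{dairy_category} is a dairy category or \code{non_dairy}; must
#'   cover every food group encountered (food_group mode).
#' @param max_days maximum permitted recall day index (default 2).
#' @return data.frame \code{person_id, category, g_per_day}, complete over
#'   persons x dairy categories (zeros filled in).
#' @export
person_daily_intake <- function(recalls, persons,
                                mode = c("disaggregated", "food_group"),
                                profiles = NULL, foods = NULL,
                                group_map = NULL, max_days = 2L) {
  mode <- match.arg(mode)
  recalls <- validate_recalls(recalls, max_days)
  persons <- validate_persons(persons)

  nop <- setdiff(unique(recalls$person_id), persons$person_id)
  if (length(nop) > 0L)
    stop("recall(s) for person(s) with no survey weight: ",
         paste(nop, collapse = ", "), call. = FALSE)

  if (mode == "disaggregated") {
    if (is.null(profiles))
      stop("disaggregated mode requires `profiles`", call. = FALSE)
    long <- profile_table(profiles)
    known <- vapply(profiles, function(p) p$food_code, character(1))
    unknown <- setdiff(unique(recalls$food_code), known)
    if (length(unknown) > 0L)
      stop("recall(s) reference food(s) with no dairy profile: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    m <- merge(recalls, long[c("food_code", "category", "grams_per_100g")],
               by = "food_code")
    m$g <- m$grams_consumed * m$grams_per_100g / 100
  } else {
    if (is.null(foods) || is.null(group_map))
      stop("food_group mode requires `foods` and `group_map`", call. = FALSE)
    gi <- match(recalls$food_code, foods$food_code)
    if (anyNA(gi))
      stop("recall(s) reference food(s) absent from the food list: ",
           paste(unique(recalls$food_code[is.na(gi)]), collapse = ", "),
           call. = FALSE)
    grp <- foods$food_group[gi]
    ci <- match(grp, group_map$food_group)
    if (anyNA(ci))
      stop("food group(s) missing from the group-dairy map: ",
           paste(unique(grp[is.na(ci)]), collapse = ", "), call. = FALSE)
    cat_ <- group_map$dairy_category[ci]
    keep <- cat_ != NON_DAIRY
    m <- data.frame(person_id = recalls$person_id[keep],
                    category = cat_[keep],
                    g = recalls$grams_consumed[keep],
                    stringsAsFactors = FALSE)
  }

  # sum each person's contributions across items and days, then divide by
  # the number of completed days: equivalent to averaging per-day totals,
  # with dairy-free days counting as zero
  grid <- expand.grid(person_id = persons$person_id,
                      category = DAIRY_CATEGORIES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(m) > 0L && any(m$g > 0)) {
    agg <- stats::aggregate(g ~ person_id + category, data = m, FUN = sum)
    grid <- merge(grid, agg, by = c("person_id", "category"), all.x = TRUE)
    grid$g[is.na(grid$g)] <- 0
  } else {
    grid$g <- 0
  }
  nd <- person_n_days(recalls, persons)
  grid$g_per_day <- grid$g / nd[grid$person_id]
  grid <- grid[order(grid$person_id, grid$category),
               c("person_id", "category", "g_per_day")]
  rownames(grid) <- NULL
  grid
}

validate_recalls <- function(recalls, max_days = 2L) {
  recalls <- as.data.frame(recalls, stringsAsFactors = FALSE)
  need <- c("person_id", "day", "food_code", "grams_consumed")
  miss <- setdiff(need, names(recalls))
  if (length(miss) > 0L)
    stop("recalls are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  recalls$person_id <- as.character(recalls$person_id)
  recalls$food_code <- as.character(recalls$food_code)
  recalls$day <- as.integer(recalls$day)
  recalls$grams_consumed <- as.numeric(recalls$grams_consumed)
  if (any(recalls$grams_consumed < 0, na.rm = TRUE))
    stop("grams_consumed must be non-negative", call. = FALSE)
  bad <- recalls$day < 1L | recalls$day > max_days
  if (any(bad, na.rm = TRUE))
    stop("recall day(s) outside 1..", max_days, call. = FALSE)
  recalls
}

validate_persons <- function(persons) {
  persons <- as.data.frame(persons, stringsAsFactors = FALSE)
  miss <- setdiff(c("person_id", "weight"), names(persons))
  if (length(miss) > 0L)
    stop("persons are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  persons$person_id <- as.character(persons$person_id)
  persons$weight <- as.numeric(persons$weight)
  if (anyDuplicated(persons$person_id))
    stop("duplicate person_id in persons table", call. = FALSE)
  if (any(!is.finite(persons$weight) | persons$weight <= 0))
    stop("survey weights must be positive", call. = FALSE)
  persons
}

person_n_days <- function(recalls, persons) {
  if ("n_days_completed" %in% names(persons)) {
    nd <- as.integer(persons$n_days_completed)
    if (any(nd < 1L)) stop("n_days_completed must be >= 1", call. = FALSE)
  } else {
    obs <- tapply(recalls$day, recalls$person_id,
                  function(d) length(unique(d)))
    nd <- as.integer(obs[persons$person_id])
    nd[is.na(nd) | nd < 1L] <- 1L
  }
  stats::setNames(nd, persons$person_id)
}

# -- population estimates ------------------------------------------------

# Weighted mean Sum(w x)/Sum(w); weighted SD from the reliability-style
# weighted variance Sum(w (x-m)^2)/Sum(w) * n/(n-1), which is invariant to
# rescaling all weights (a requirement for calibration weights) and reduces
# to the ordinary sample SD under equal weights.
weighted_mean_sd <- function(x, w) {
  sw <- sum(w)
  m <- sum(w * x) / sw
  n <- length(x)
  v <- if (n > 1L) sum(w * (x - m)^2) / sw * n / (n - 1L) else 0
  c(mean = m, sd = sqrt(v))
}

# Standard error of the weighted mean (Hajek form), used by the synthetic
# recovery checks.
weighted_mean_se <- function(x, w) {
  sw <- sum(w)
  m <- sum(w * x) / sw
  sqrt(sum((w / sw)^2 * (x - m)^2))
}

#' Survey-weighted per-capita intake estimate
#'
#' Weighted mean and SD of per-person daily intake, per dairy category and
#' in total, including nonconsumers (per capita). The total is each person's
#' sum across categories, so the total mean equals the sum of category means
#' by construction.
#'
#' @param person_values output of [person_daily_intake()].
#' @param persons persons table with positive \code{weight}s.
#' @param mode label recorded on the estimate.
#' @return Object of class \code{intake_estimate}: list with \code{mode},
#'   \code{n_persons} and \code{estimates} (data.frame \code{subtype,
#'   mean_g_per_day, sd_g_per_day}; subtypes are the five dairy categories
#'   plus \code{total}).
#' @export
population_mean <- function(person_values, persons,
                            mode = c("disaggregated", "food_group")) {
  mode <- match.arg(mode)
  persons <- validate_persons(persons)
  if (nrow(persons) == 0L)
    stop("empty population", call. = FALSE)
  w <- stats::setNames(persons$weight, persons$person_id)

  rows <- lapply(c(DAIRY_CATEGORIES, "total"), function(ct) {
    if (ct == "total") {
      x <- tapply(person_values$g_per_day, person_values$person_id, sum)
    } else {
      sel <- person_values$category == ct
      x <- stats::setNames(person_values$g_per_day[sel],
                           person_values$person_id[sel])
    }
    x <- x[persons$person_id]
    x[is.na(x)] <- 0
    ms <- weighted_mean_sd(as.numeric(x), as.numeric(w))
    data.frame(subtype = ct, mean_g_per_day = ms[["mean"]],
               sd_g_per_day = ms[["sd"]], stringsAsFactors = FALSE)
  })
  structure(
    list(mode = mode, n_persons = nrow(persons),
         estimates = do.call(rbind, rows)),
    class = "intake_estimate"
  )
}

#' @export
print.intake_estimate <- function(x, ...) {
  cat("<intake_estimate> mode =", x$mode, "| n =", x$n_persons, "persons\n")
  print(x$estimates, row.names = FALSE)
  invisible(x)
}

# -- bias ----------------------------------------------------------------

#' Percent bias of the naive mode relative to disaggregation
#'
#' For each subtype, percent bias = 100 x (mean_with - mean_without) /
#' denominator, where "with" is the disaggregated estimate and "without"
#' the naive food-group estimate. Positive values mean the naive mode
#' underestimates. The denominator convention is an explicit parameter:
#' \code{denominator_with} divides by the disaggregated mean,
#' \code{denominator_without} by the naive mean.
#'
#' @param est_with disaggregated [population_mean()] estimate.
#' @param est_without food-group-mode estimate over the same subtypes.
#' @param convention \code{"denominator_with"} or
#'   \code{"denominator_without"}.
#' @return Object of class \code{bias_report}: data.frame \code{subtype,
#'   mean_with, mean_without, percent_bias, percent_bias_int, direction}
#'   with the convention stored as attribute \code{"convention"}.
#'   \code{percent_bias_int} is rounded half away from zero at reporting.
#' @export
bias_report <- function(est_with, est_without,
                        convention = c("denominator_with",
                                       "denominator_without")) {
  convention <- match.arg(convention)
  a <- est_with$estimates
  b <- est_without$estimates
  if (!identical(a$subtype, b$subtype))
    stop("estimates do not cover the same subtypes", call. = FALSE)
  num <- a$mean_g_per_day - b$mean_g_per_day
  den <- if (convention == "denominator_with") a$mean_g_per_day else
    b$mean_g_per_day
  pct <- numeric(length(num))
  for (i in seq_along(num)) {
    if (den[i] == 0) {
      if (num[i] == 0) pct[i] <- 0
      else stop("undefined bias for subtype '", a$subtype[i],
                "': zero denominator with nonzero difference",
                call. = FALSE)
    } else pct[i] <- 100 * num[i] / den[i]
  }
  out <- data.frame(subtype = a$subtype,
                    mean_with = a$mean_g_per_day,
                    mean_without = b$mean_g_per_day,
                    percent_bias = pct,
                    percent_bias_int = round_half_away(pct),
                    direction = ifelse(pct > 0, "underestimated",
                                       ifelse(pct < 0, "overestimated",
                                              "unbiased")),
                    stringsAsFactors = FALSE)
  attr(out, "convention") <- convention
  class(out) <- c("bias_report", "data.frame")
  out
}

#' Percent-bias arithmetic on two scalar estimates
#'
#' The same convention-tagged percent computation as [bias_report()], for a
#' single pair of values: 100 x (with - without) / denominator.
#'
#' @param with_value,without_value scalar estimates of the same quantity
#'   with and without disaggregation.
#' @inheritParams bias_report
#' @return Percent bias (unrounded); positive means "without" underestimates.
#' @export
percent_bias <- function(with_value, without_value,
                         convention = c("denominator_with",
                                        "denominator_without")) {
  convention <- match.arg(convention)
  den <- if (convention == "denominator_with") with_value else without_value
  if (den == 0) {
    if (with_value == without_value) return(0)
    stop("undefined bias: zero denominator with nonzero difference",
         call. = FALSE)
  }
  100 * (with_value - without_value) / den
}

# -- contribution shares -------------------------------------------------

#' Food-group contributions to total disaggregated dairy intake
#'
#' Attributes each person's disaggregated dairy mass to the food group of
#' the food it came from, weights across persons, and expresses each group
#' as a percent of the weighted grand total. When a \code{group_map} is
#' supplied, groups mapped to a dairy category are additionally rolled up
#' as \code{noncomposite} (the classic "dairy foods") against
#' \code{composite} (dairy arriving inside other food groups).
#'
#' @inheritParams person_daily_intake
#' @param foods food list with \code{food_code, food_group}.
#' @param group_map optional group-dairy map for the composite/noncomposite
#'   rollup.
#' @return Object of class \code{contribution_table}: list with
#'   \code{by_group} (data.frame \code{food_group, percent}) and
#'   \code{rollup} (data.frame \code{source, percent} or NULL). Percents
#'   sum to 100.
#' @export
contribution_shares <- function(recalls, profiles, persons, foods,
                                group_map = NULL, max_days = 2L) {
  recalls <- validate_recalls(recalls, max_days)
  persons <- validate_persons(persons)
  long <- profile_table(profiles)
  totals <- tapply(long$grams_per_100g, long$food_code, sum)

  gi <- match(recalls$food_code, foods$food_code)
  if (anyNA(gi))
    stop("recall(s) reference food(s) absent from the food list: ",
         paste(unique(recalls$food_code[is.na(gi)]), collapse = ", "),
         call. = FALSE)
  dairy_g <- as.numeric(totals[recalls$food_code])
  dairy_g[is.na(dairy_g)] <- 0
  m <- data.frame(person_id = recalls$person_id,
                  food_group = foods$food_group[gi],
                  g = recalls$grams_consumed * dairy_g / 100,
                  stringsAsFactors = FALSE)
  nd <- person_n_days(recalls, persons)
  w <- stats::setNames(persons$weight, persons$person_id)
  m$wg <- m$g / nd[m$person_id] * w[m$person_id]

  tot <- sum(m$wg)
  if (tot <= 0) {
    warning("no dairy consumed; contribution table is empty", call. = FALSE)
    return(structure(list(by_group = data.frame(food_group = character(),
                                                percent = numeric()),
                          rollup = NULL),
                     class = "contribution_table"))
  }
  per_group <- tapply(m$wg, m$food_group, sum)
  by_group <- data.frame(food_group = names(per_group),
                         percent = 100 * as.numeric(per_group) / tot,
                         stringsAsFactors = FALSE)
  by_group <- by_group[order(-by_group$percent), ]
  rownames(by_group) <- NULL

  rollup <- NULL
  if (!is.null(group_map)) {
    ci <- match(by_group$food_group, group_map$food_group)
    if (anyNA(ci))
      stop("food group(s) missing from the group-dairy map: ",
           paste(by_group$food_group[is.na(ci)], collapse = ", "),
           call. = FALSE)
    src <- ifelse(group_map$dairy_category[ci] == NON_DAIRY,
                  "composite", "noncomposite")
    per_src <- tapply(by_group$percent, src, sum)
    rollup <- data.frame(source = names(per_src),
                         percent = as.numeric(per_src),
                         stringsAsFactors = FALSE)
  }
  structure(list(by_group = by_group, rollup = rollup),
            class = "contribution_table")
}

#' @export
print.contribution_table <- function(x, ...) {
  cat("<contribution_table>\n")
  print(x$by_group, row.names = FALSE)
  if (!is.null(x$rollup)) {
    cat("rollup:\n")
    print(x$rollup, row.names = FALSE)
  }
  invisible(x)
}
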