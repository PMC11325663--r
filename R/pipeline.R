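# End-to-end orchestration behind the command-line wrapper
# (inst/cli/dairydisagg.R): each run_* function is a thin composition of the
# module functions, reading the documented CSV schemas and writing tidy CSV
# outputs whose header lines record the package version, seed and a hash of
# the effective configuration, so identical configurations give
# byte-identical files.

pkg_version <- function() {
  as.character(utils::packageVersion("dairydisagg"))
}

# Polynomial rolling hash over the deparsed config (mod 2^31 - 1); enough
# to fingerprint a run in the output headers.
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

run_header <- function(config, seed = NULL) {
  c(paste0("dairydisagg ", pkg_version()),
    paste0("seed: ", if (is.null(seed)) "none" else seed),
    paste0("config: ", config_hash(config)))
}

#' Run the disaggregation stage
#'
#' Loads the food list, recipes and classification map, applies optional
#' substitutions, profiles every food and writes \code{profiles.csv} (wide,
#' one row per food) and \code{summary.csv} (class counts) to
#' \code{out_dir}.
#'
#' @param food_list,recipes,classification paths to the input CSVs.
#' @param substitutions optional path to a substitutions CSV.
#' @param out_dir output directory, created if absent.
#' @param sum_window recipe-mass validity window.
#' @return Invisibly, list with \code{profiles} and \code{summary}.
#' @export
run_disaggregate <- function(food_list, recipes, classification,
                             substitutions = NULL, out_dir = ".",
                             sum_window = c(50, 130)) {
  db <- load_recipe_db(food_list, recipes, sum_window = sum_window)
  if (nrow(db$foods) == 0L)
    stop("empty food list", call. = FALSE)
  map <- load_classification_map(classification)
  if (!is.null(substitutions)) {
    subs <- load_substitution_map(substitutions)
    apply_substitutions(db, subs, db$foods$food_code, quiet = TRUE)
  }
  profiles <- dairy_profiles(db, map)
  summ <- summarize_database(profiles)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg <- list(food_list = food_list, recipes = recipes,
              classification = classification, sum_window = sum_window)
  hdr <- run_header(cfg)
  write_profiles_csv(profiles, file.path(out_dir, "profiles.csv"), hdr)
  sdf <- data.frame(n_foods = summ$n_foods, n_pure_dairy = summ$n_pure_dairy,
                    n_composite_dairy = summ$n_composite_dairy,
                    n_non_dairy = summ$n_non_dairy,
                    percent_any_dairy = summ$percent_any_dairy,
                    percent_any_dairy_int = summ$percent_any_dairy_int)
  write_csv_with_header(sdf, file.path(out_dir, "summary.csv"), hdr)
  invisible(list(profiles = profiles, summary = summ))
}

#' Run the intake-estimation stage
#'
#' Estimates survey-weighted per-capita intake under both modes, the bias
#' report and the contribution shares; writes \code{estimates.csv} (one row
#' per mode x subtype), \code{bias.csv} and \code{contributions.csv}.
#'
#' @param food_list,recipes,classification,group_map,recalls,persons paths
#'   to the input CSVs.
#' @param out_dir output directory.
#' @param convention bias denominator convention (see [bias_report()]).
#' @return Invisibly, list with \code{with}, \code{without}, \code{bias},
#'   \code{contributions}.
#' @export
run_intake <- function(food_list, recipes, classification, group_map,
                       recalls, persons, out_dir = ".",
                       convention = "denominator_with") {
  db <- load_recipe_db(food_list, recipes)
  map <- load_classification_map(classification)
  gm <- read_csv_strict(group_map, c("food_group", "dairy_category"))
  rec <- read_csv_strict(recalls,
                         c("person_id", "day", "food_code",
                           "grams_consumed"))
  per <- read_csv_strict(persons, c("person_id", "weight"))
  per$weight <- as.numeric(per$weight)
  if ("n_days_completed" %in% names(per))
    per$n_days_completed <- as.integer(per$n_days_completed)

  profiles <- dairy_profiles(db, map)
  pv_with <- person_daily_intake(rec, per, "disaggregated",
                                 profiles = profiles)
  pv_without <- person_daily_intake(rec, per, "food_group",
                                    foods = db$foods, group_map = gm)
  est_with <- population_mean(pv_with, per, "disaggregated")
  est_without <- population_mean(pv_without, per, "food_group")
  bias <- bias_report(est_with, est_without, convention)
  contrib <- contribution_shares(rec, profiles, per, db$foods,
                                 group_map = gm)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg <- list(food_list = food_list, recipes = recipes,
              classification = classification, group_map = group_map,
              recalls = recalls, persons = persons,
              convention = convention)
  hdr <- run_header(cfg)
  est <- rbind(cbind(mode = "disaggregated", est_with$estimates),
               cbind(mode = "food_group", est_without$estimates))
  write_csv_with_header(est, file.path(out_dir, "estimates.csv"), hdr)
  bdf <- as.data.frame(bias)
  write_csv_with_header(bdf, file.path(out_dir, "bias.csv"),
                        c(hdr, paste0("convention: ", convention)))
  cdf <- contrib$by_group
  if (!is.null(contrib$rollup)) {
    cdf <- rbind(cdf,
                 data.frame(food_group = paste0("rollup_",
                                                contrib$rollup$source),
                            percent = contrib$rollup$percent))
  }
  write_csv_with_header(cdf, file.path(out_dir, "contributions.csv"), hdr)
  invisible(list(with = est_with, without = est_without, bias = bias,
                 contributions = contrib))
}

#' Run the emissions stage
#'
#' Converts a pair of intake estimate files (modes \code{disaggregated} and
#' \code{food_group}, as written by [run_intake()]) into milk-equivalent
#' litres and annual per-capita kg CO2e, and writes \code{emissions.csv}
#' with the bias percent.
#'
#' @param estimates path to an \code{estimates.csv} from [run_intake()].
#' @param factors optional path to a milk-equivalence factors CSV
#'   (defaults to the built-in factor table).
#' @param footprint_kg_per_l milk carbon footprint, kg CO2e/L.
#' @param milk_density_kg_per_l milk density, kg/L.
#' @param convention bias denominator convention.
#' @param out_dir output directory.
#' @return Invisibly, list with \code{with}, \code{without},
#'   \code{bias_percent}.
#' @export
run_emissions <- function(estimates, factors = NULL,
                          footprint_kg_per_l = 1.2,
                          milk_density_kg_per_l = 1.03,
                          convention = "denominator_without",
                          out_dir = ".") {
  est <- read_csv_strict(estimates, c("mode", "subtype", "mean_g_per_day"))
  est$mean_g_per_day <- as.numeric(est$mean_g_per_day)
  fac <- if (is.null(factors)) {
    milk_equivalence_factors(milk_density_kg_per_l = milk_density_kg_per_l)
  } else {
    load_milk_equivalence_factors(factors,
                                  milk_density_kg_per_l =
                                    milk_density_kg_per_l)
  }
  one <- function(mode) {
    e <- est[est$mode == mode & est$subtype %in% DAIRY_CATEGORIES, ]
    if (nrow(e) == 0L)
      stop("no '", mode, "' rows in ", estimates, call. = FALSE)
    litres <- to_milk_equivalents(
      stats::setNames(e$mean_g_per_day, e$subtype), fac)
    annual_per_capita_emissions(litres, footprint_kg_per_l, mode = mode)
  }
  ew <- one("disaggregated")
  eo <- one("food_group")
  bias <- emissions_bias(ew, eo, convention)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg <- list(estimates = estimates, factors = factors,
              footprint_kg_per_l = footprint_kg_per_l,
              milk_density_kg_per_l = milk_density_kg_per_l,
              convention = convention)
  hdr <- c(run_header(cfg), paste0("convention: ", convention))
  out <- data.frame(
    mode = c(ew$mode, eo$mode),
    litres_per_capita_per_year = c(ew$litres_per_capita_per_year,
                                   eo$litres_per_capita_per_year),
    kg_co2e_per_capita_per_year = c(ew$kg_co2e_per_capita_per_year,
                                    eo$kg_co2e_per_capita_per_year),
    percent_bias = c(bias, bias),
    percent_bias_int = round_half_away(c(bias, bias)))
  write_csv_with_header(out, file.path(out_dir, "emissions.csv"), hdr)
  invisible(list(with = ew, without = eo, bias_percent = bias))
}

#' Run the simulation stage
#'
#' Generates a synthetic recipe database and recall survey and writes all
#' pipeline input CSVs plus the ground-truth profile table to
#' \code{out_dir}.
#'
#' @param seed integer seed.
#' @param out_dir output directory.
#' @param ... overrides passed to [generator_config()].
#' @return Invisibly, list with \code{sim} and \code{survey}.
#' @export
run_simulate <- function(seed, out_dir = ".", ...) {
  config <- generator_config(seed = seed, ...)
  sim <- generate_recipe_db(config)
  survey <- generate_survey(config, sim)
  hdr <- run_header(config, seed = seed)
  write_synthetic_csvs(sim, survey, out_dir, hdr)
  invisible(list(sim = sim, survey = survey))
}
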