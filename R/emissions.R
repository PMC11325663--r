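# Production-side accounting: per-capita dairy intake -> litres of raw milk
# required to produce it (milk equivalents) -> annual greenhouse-gas
# emissions through a single milk carbon-footprint coefficient
# (UK raw milk: 1.2 kg CO2e per litre).

#' Milk-equivalence factor table
#'
#' Litres of raw milk required per kg of product, by dairy category, with
#' optional variety-level overrides (e.g., cheddar at 9.5 L/kg). Milk
#' itself converts through its density: 1/density litres per kg.
#'
#' The default category factors are package conventions except cheddar's
#' 9.5 L/kg, which is the published milk-utilisation figure; all are
#' configurable.
#'
#' @param category_factors named numeric vector, litres of raw milk per kg
#'   of product for each dairy category (milk's entry is derived from
#'   \code{milk_density_kg_per_l} and ignored if supplied).
#' @param variety_overrides named numeric vector of cheese-variety
#'   overrides, names like \code{"cheese.cheddar"}.
#' @param milk_density_kg_per_l density of milk, kg per litre (default
#'   1.03).
#' @return Object of class \code{milk_equivalence_factors}.
#' @export
milk_equivalence_factors <- function(category_factors = c(cheese = 9.5,
                                                          yogurt = 1.0,
                                                          cream = 8.0,
                                                          butter = 20.0),
                                     variety_overrides = c(cheese.cheddar = 9.5),
                                     milk_density_kg_per_l = 1.03) {
  stopifnot(milk_density_kg_per_l > 0)
  f <- as.list(category_factors)
  f$milk <- 1 / milk_density_kg_per_l
  bad <- names(f)[!names(f) %in% DAIRY_CATEGORIES]
  if (length(bad) > 0L)
    stop("unknown dairy categor(ies) in factor table: ",
         paste(bad, collapse = ", "), call. = FALSE)
  vals <- unlist(f)
  if (any(!is.finite(vals) | vals <= 0))
    stop("milk-equivalence factors must be positive", call. = FALSE)
  if (length(variety_overrides) > 0L &&
      any(!is.finite(variety_overrides) | variety_overrides <= 0))
    stop("variety overrides must be positive", call. = FALSE)
  structure(list(category = vals,
                 variety = variety_overrides,
                 milk_density_kg_per_l = milk_density_kg_per_l),
            class = "milk_equivalence_factors")
}

#' Load milk-equivalence factors from CSV
#'
#' @param path CSV with columns \code{category, variety, litres_per_kg};
#'   empty \code{variety} rows set the category-level factor, non-empty
#'   rows set a \code{category.variety} override.
#' @param milk_density_kg_per_l density used for the milk category.
#' @return A [milk_equivalence_factors()] object.
#' @export
load_milk_equivalence_factors <- function(path, milk_density_kg_per_l = 1.03) {
  x <- read_csv_strict(path, c("category", "litres_per_kg"))
  if (!"variety" %in% names(x)) x$variety <- ""
  x$litres_per_kg <- as.numeric(x$litres_per_kg)
  is_var <- !is.na(x$variety) & x$variety != ""
  cf <- stats::setNames(x$litres_per_kg[!is_var], x$category[!is_var])
  vo <- stats::setNames(x$litres_per_kg[is_var],
                        paste(x$category[is_var], x$variety[is_var],
                              sep = "."))
  milk_equivalence_factors(category_factors = cf, variety_overrides = vo,
                           milk_density_kg_per_l = milk_density_kg_per_l)
}

#' Convert a per-capita intake estimate to milk-equivalent litres per day
#'
#' litres/day = sum over dairy categories of (g/day / 1000) x factor(L/kg).
#' Variety-level overrides are applied when \code{intake_by_variety}
#' supplies variety-resolved masses; otherwise the category factor is used
#' for the whole category.
#'
#' @param intake an [population_mean()] estimate (its category rows are
#'   used) or a named numeric vector of g/day by dairy category.
#' @param factors a [milk_equivalence_factors()] table.
#' @return Litres of raw milk per capita per day (scalar).
#' @export
to_milk_equivalents <- function(intake, factors = milk_equivalence_factors()) {
  stopifnot(inherits(factors, "milk_equivalence_factors"))
  if (inherits(intake, "intake_estimate")) {
    e <- intake$estimates
    e <- e[e$subtype %in% DAIRY_CATEGORIES, ]
    g <- stats::setNames(e$mean_g_per_day, e$subtype)
  } else {
    g <- intake
  }
  g <- g[g > 0]
  if (length(g) == 0L) return(0)
  missing <- setdiff(names(g), names(factors$category))
  # variety-keyed entries ("cheese.cheddar") fall back to overrides
  missing <- missing[!missing %in% names(factors$variety)]
  if (length(missing) > 0L)
    stop("no milk-equivalence factor for consumed categor(ies): ",
         paste(missing, collapse = ", "), call. = FALSE)
  f <- ifelse(names(g) %in% names(factors$variety),
              factors$variety[names(g)],
              factors$category[names(g)])
  sum(g / 1000 * f)
}

#' Annual per-capita dairy emissions
#'
#' kg CO2e per person per year = litres/day x 365 x footprint (kg CO2e per
#' litre of raw milk). A fixed 365-day year is used.
#'
#' @param litres_per_day milk-equivalent litres per capita per day.
#' @param footprint_kg_per_l carbon footprint of raw milk, kg CO2e/L
#'   (default 1.2, UK figure).
#' @param mode label recorded on the estimate.
#' @return Object of class \code{emissions_estimate}: list with
#'   \code{mode}, \code{litres_per_capita_per_year},
#'   \code{kg_co2e_per_capita_per_year}, \code{footprint_kg_per_l}.
#' @export
annual_per_capita_emissions <- function(litres_per_day,
                                        footprint_kg_per_l = 1.2,
                                        mode = "disaggregated") {
  if (!is.finite(litres_per_day) || litres_per_day < 0)
    stop("litres_per_day must be non-negative", call. = FALSE)
  if (!is.finite(footprint_kg_per_l) || footprint_kg_per_l <= 0)
    stop("footprint must be positive", call. = FALSE)
  litres_yr <- litres_per_day * 365
  structure(list(mode = mode,
                 litres_per_capita_per_year = litres_yr,
                 kg_co2e_per_capita_per_year = litres_yr * footprint_kg_per_l,
                 footprint_kg_per_l = footprint_kg_per_l),
            class = "emissions_estimate")
}

#' @export
print.emissions_estimate <- function(x, ...) {
  cat("<emissions_estimate> mode =", x$mode, "|",
      format(x$litres_per_capita_per_year), "L milk-eq/capita/yr ->",
      format(x$kg_co2e_per_capita_per_year), "kg CO2e/capita/yr\n")
  invisible(x)
}

#' Percent emissions bias from non-disaggregation
#'
#' Same arithmetic as [percent_bias()], applied to two
#' [annual_per_capita_emissions()] estimates.
#'
#' @param est_with,est_without \code{emissions_estimate} objects for the
#'   disaggregated and naive modes.
#' @inheritParams bias_report
#' @return Percent bias (unrounded); positive means the naive mode
#'   underestimates emissions.
#' @export
emissions_bias <- function(est_with, est_without,
                           convention = c("denominator_with",
                                          "denominator_without")) {
  percent_bias(est_with$kg_co2e_per_capita_per_year,
               est_without$kg_co2e_per_capita_per_year,
               convention = match.arg(convention))
}
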