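# -- recipe database -----------------------------------------------------

#' Construct a recipe database
#'
#' A recipe database couples a food list with a hierarchical recipe table.
#' Each recipe row states the grams of one component present in 100 g of a
#' parent product; components may themselves be food codes carrying their own
#' recipes (sub-recipes), so the parent/component relation forms a directed
#' acyclic graph. Codes that only ever appear as components are the base
#' ingredients.
#'
#' Per-100 g component masses are taken as recorded: they are \emph{not}
#' renormalised to sum to 100 and no cooking-yield adjustment is applied
#' (amounts are pre-cooking, as in standard recipe databases). A per-parent
#' mass sum outside \code{sum_window} triggers a warning; a sum of zero or
#' less for a parent that has entries is an error.
#'
#' @param foods data.frame with columns \code{food_code}, \code{description},
#'   \code{food_group}. \code{food_code} must be unique.
#' @param entries data.frame with columns \code{parent_code},
#'   \code{component_code}, \code{grams_per_100g}. May have zero rows.
#' @param sum_window numeric length 2, validity window for the per-parent
#'   grams sum. Default \code{c(50, 130)}.
#' @return An object of class \code{recipe_db}: a list with elements
#'   \code{foods}, \code{entries}, \code{base_ingredients} (codes appearing
#'   only as components) and \code{sum_window}.
#' @seealso [load_recipe_db()] to read the CSV schemas, [resolve_recipe()]
#'   to flatten a food to base ingredients.
#' @export
recipe_db <- function(foods, entries, sum_window = c(50, 130)) {
  foods <- as.data.frame(foods, stringsAsFactors = FALSE)
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  need_f <- c("food_code", "description", "food_group")
  need_e <- c("parent_code", "component_code", "grams_per_100g")
  miss <- setdiff(need_f, names(foods))
  if (length(miss) > 0L)
    stop("food list is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(need_e, names(entries))
  if (length(miss) > 0L)
    stop("recipe table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  foods <- foods[need_f]
  entries <- entries[need_e]
  foods$food_code <- as.character(foods$food_code)
  foods$food_group <- as.character(foods$food_group)
  entries$parent_code <- as.character(entries$parent_code)
  entries$component_code <- as.character(entries$component_code)
  entries$grams_per_100g <- as.numeric(entries$grams_per_100g)

  dup <- duplicated(foods$food_code)
  if (any(dup))
    stop("duplicate food_code in food list: ",
         paste(unique(foods$food_code[dup]), collapse = ", "), call. = FALSE)
  key <- paste(entries$parent_code, entries$component_code, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    rows <- which(dup)
    stop("duplicate (parent_code, component_code) pair(s) at recipe row(s) ",
         paste(rows, collapse = ", "), ": ",
         paste(unique(sub("\r", " -> ", key[dup])), collapse = "; "),
         call. = FALSE)
  }
  bad <- which(!is.finite(entries$grams_per_100g) | entries$grams_per_100g < 0)
  if (length(bad) > 0L)
    stop("grams_per_100g must be a non-negative number; offending recipe row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  orphan <- setdiff(unique(entries$parent_code), foods$food_code)
  if (length(orphan) > 0L)
    stop("parent_code(s) absent from the food list: ",
         paste(orphan, collapse = ", "), call. = FALSE)

  check_acyclic(entries)

  if (nrow(entries) > 0L) {
    sums <- tapply(entries$grams_per_100g, entries$parent_code, sum)
    zero <- names(sums)[sums <= 0]
    if (length(zero) > 0L)
      stop("recipe mass sums to <= 0 g/100 g for parent(s): ",
           paste(zero, collapse = ", "), call. = FALSE)
    out <- names(sums)[sums < sum_window[1] | sums > sum_window[2]]
    if (length(out) > 0L)
      warning("per-100 g recipe mass outside [", sum_window[1], ", ",
              sum_window[2], "] for parent(s): ",
              paste(sprintf("%s (%.4g g)", out, sums[out]), collapse = ", "),
              call. = FALSE)
  }

  base <- setdiff(unique(entries$component_code), unique(entries$parent_code))
  structure(
    list(foods = foods, entries = entries,
         base_ingredients = sort(base), sum_window = sum_window),
    class = "recipe_db"
  )
}

# Kahn's algorithm on the parent -> component edges; reports the codes stuck
# on a cycle so corrupt recipe files are diagnosable.
check_acyclic <- function(entries) {
  if (nrow(entries) == 0L) return(invisible(TRUE))
  nodes <- unique(c(entries$parent_code, entries$component_code))
  indeg <- table(factor(entries$component_code, levels = nodes))
  indeg <- as.integer(indeg)
  names(indeg) <- nodes
  out_edges <- split(entries$component_code, entries$parent_code)
  queue <- nodes[indeg == 0L]
  seen <- 0L
  while (length(queue) > 0L) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (w in out_edges[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (seen < length(nodes)) {
    cyc <- nodes[indeg > 0L]
    stop("recipe graph contains a cycle involving: ",
         paste(sort(cyc), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.recipe_db <- function(x, ...) {
  cat("<recipe_db> ", nrow(x$foods), " foods, ", nrow(x$entries),
      " recipe entries, ", length(x$base_ingredients),
      " base ingredients\n", sep = "")
  invisible(x)
}

#' Load a recipe database from CSV files
#'
#' Reads the food list and recipe CSVs (UTF-8, header row, "." decimal) and
#' validates them into a [recipe_db()]. The food list has columns
#' \code{food_code, description, food_group}; the recipe file has columns
#' \code{parent_code, component_code, grams_per_100g}. An empty recipe file
#' yields a database in which every food resolves to itself.
#'
#' @param food_list_path path to the food list CSV.
#' @param recipe_path path to the recipes CSV.
#' @inheritParams recipe_db
#' @return A validated \code{recipe_db}.
#' @export
load_recipe_db <- function(food_list_path, recipe_path,
                           sum_window = c(50, 130)) {
  foods <- read_csv_strict(food_list_path,
                           c("food_code", "description", "food_group"))
  entries <- read_csv_strict(recipe_path,
                             c("parent_code", "component_code",
                               "grams_per_100g"))
  recipe_db(foods, entries, sum_window = sum_window)
}

read_csv_strict <- function(path, required_cols) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character", comment.char = "#",
                       fileEncoding = "UTF-8")
  miss <- setdiff(required_cols, names(x))
  if (length(miss) > 0L)
    stop(basename(path), " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  x
}

# -- substitutions -------------------------------------------------------

#' Build a nearest-neighbour substitution map
#'
#' Foods reported in a survey occasionally have no match in the recipe
#' database; the standard remedy is to assign each a nearest-neighbour
#' substitute food that does. A substitution map records those assignments
#' together with a free-text rationale. Chains are rejected: a substitute
#' may never itself be a missing code.
#'
#' @param missing_code character vector of unmatched food codes.
#' @param substitute_code character vector, same length, of replacement codes.
#' @param rationale character vector of free-text justifications (recycled).
#' @return data.frame of class \code{substitution_map}.
#' @export
substitution_map <- function(missing_code = character(),
                             substitute_code = character(),
                             rationale = "") {
  x <- data.frame(missing_code = as.character(missing_code),
                  substitute_code = as.character(substitute_code),
                  rationale = rep_len(as.character(rationale),
                                      length(missing_code)),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(x$missing_code))
    stop("duplicate missing_code in substitution map", call. = FALSE)
  chained <- intersect(x$substitute_code, x$missing_code)
  if (length(chained) > 0L)
    stop("substitution chains are not allowed; substitute(s) also listed as ",
         "missing: ", paste(chained, collapse = ", "), call. = FALSE)
  class(x) <- c("substitution_map", "data.frame")
  x
}

#' Load a substitution map from CSV
#'
#' @param path CSV with columns \code{missing_code, substitute_code,
#'   rationale}.
#' @return A \code{substitution_map}.
#' @export
load_substitution_map <- function(path) {
  x <- read_csv_strict(path, c("missing_code", "substitute_code", "rationale"))
  substitution_map(x$missing_code, x$substitute_code, x$rationale)
}

#' Resolve reported food codes through a substitution map
#'
#' Codes present in the database map to themselves; codes listed in the
#' substitution map map to their substitute (which must exist in the
#' database); anything else is an error naming the unresolvable codes.
#'
#' @param db a [recipe_db()].
#' @param subs a [substitution_map()].
#' @param query_codes character vector of reported food codes.
#' @param quiet suppress the per-substitution log messages.
#' @return named character vector: \code{query_code -> effective_code}.
#' @export
apply_substitutions <- function(db, subs, query_codes, quiet = FALSE) {
  stopifnot(inherits(db, "recipe_db"))
  query_codes <- as.character(query_codes)
  known <- c(db$foods$food_code, db$base_ingredients)
  bad_sub <- setdiff(subs$substitute_code, known)
  if (length(bad_sub) > 0L)
    stop("substitute code(s) absent from the database: ",
         paste(bad_sub, collapse = ", "), call. = FALSE)
  out <- query_codes
  names(out) <- query_codes
  idx <- match(query_codes, subs$missing_code)
  subbed <- !is.na(idx) & !(query_codes %in% known)
  out[subbed] <- subs$substitute_code[idx[subbed]]
  unresolved <- !(query_codes %in% known) & !subbed
  if (any(unresolved))
    stop("unresolvable food code(s), neither in the database nor in the ",
         "substitution map: ",
         paste(unique(query_codes[unresolved]), collapse = ", "),
         call. = FALSE)
  if (!quiet && any(subbed))
    message("substituted ", sum(subbed), " code(s): ",
            paste(sprintf("%s -> %s", query_codes[subbed], out[subbed]),
                  collapse = ", "))
  out
}

# -- recursive resolution ------------------------------------------------

#' Flatten a food to base ingredients per 100 g
#'
#' Recursively expands a food's recipe until only base ingredients remain.
#' A sub-recipe contributing g grams per 100 g of the parent contributes
#' g/100 times its own per-100 g composition; masses of a base ingredient
#' reached along several paths are summed. A code with no recipe entries
#' resolves to itself at 100 g. Output rows are sorted by ingredient code so
#' downstream results are reproducible byte for byte.
#'
#' @param db a [recipe_db()].
#' @param food_code a single code present in the database.
#' @return data.frame with columns \code{ingredient_code},
#'   \code{grams_per_100g}, sorted by code.
#' @export
resolve_recipe <- function(db, food_code) {
  stopifnot(inherits(db, "recipe_db"), length(food_code) == 1L)
  food_code <- as.character(food_code)
  known <- c(db$foods$food_code, db$base_ingredients)
  if (!food_code %in% known)
    stop("unknown food code: ", food_code, call. = FALSE)
  ent <- split(seq_len(nrow(db$entries)), db$entries$parent_code)
  memo <- new.env(parent = emptyenv())

  expand <- function(code, stack) {
    if (code %in% stack)
      stop("recipe graph contains a cycle involving: ",
           paste(sort(unique(c(stack, code))), collapse = ", "),
           call. = FALSE)
    hit <- get0(code, envir = memo)
    if (!is.null(hit)) return(hit)
    rows <- ent[[code]]
    if (is.null(rows)) {
      res <- c(100)
      names(res) <- code
    } else {
      comp <- db$entries$component_code[rows]
      g <- db$entries$grams_per_100g[rows]
      parts <- vector("list", length(rows))
      for (i in seq_along(rows)) {
        sub <- expand(comp[[i]], c(stack, code))
        parts[[i]] <- sub * (g[[i]] / 100)
      }
      all <- unlist(parts)
      res <- tapply(all, names(all), sum)
      res <- stats::setNames(as.numeric(res), names(res))
    }
    assign(code, res, envir = memo)
    res
  }

  v <- expand(food_code, character())
  v <- v[order(names(v))]
  data.frame(ingredient_code = names(v), grams_per_100g = as.numeric(v),
             row.names = NULL, stringsAsFactors = FALSE)
}
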