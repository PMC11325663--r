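# Dairy classification scheme: every base ingredient is either dairy --
# carrying a (category, fat_level, cheese_variety) label -- or explicitly
# non-dairy. There is no silent default: an ingredient in neither roster is
# an error, because a complete dual-coded classification is assumed and a
# gap signals data drift, not "non-dairy".

DAIRY_CATEGORIES <- c("milk", "cheese", "yogurt", "cream", "butter")
FAT_LEVELS <- c("skimmed", "semiskimmed", "full_fat", "not_applicable")
CHEESE_VARIETIES <- c("cheddar", "cottage", "other", "not_applicable")
NON_DAIRY <- "non_dairy"

#' Construct a dairy class label
#'
#' A dairy class is a triple (category, fat level, cheese variety).
#' Categories are milk, cheese, yogurt, cream and butter. Fat level
#' (skimmed / semiskimmed / full fat) applies to milk, cheese, yogurt and
#' cream only -- and cream cannot be skimmed. Cheese variety (cheddar /
#' cottage / other) applies to cheese only. Butter carries neither
#' refinement.
#'
#' @param category one of \code{milk, cheese, yogurt, cream, butter}.
#' @param fat_level one of \code{skimmed, semiskimmed, full_fat,
#'   not_applicable}.
#' @param cheese_variety one of \code{cheddar, cottage, other,
#'   not_applicable}.
#' @return list of class \code{dairy_class} with the three fields.
#' @export
dairy_class <- function(category,
                        fat_level = "not_applicable",
                        cheese_variety = "not_applicable") {
  category <- match.arg(category, DAIRY_CATEGORIES)
  fat_level <- match.arg(fat_level, FAT_LEVELS)
  cheese_variety <- match.arg(cheese_variety, CHEESE_VARIETIES)
  if (category == "butter" && (fat_level != "not_applicable" ||
                               cheese_variety != "not_applicable"))
    stop("butter takes neither a fat level nor a variety", call. = FALSE)
  if (category == "cream" && fat_level == "skimmed")
    stop("cream fat level must be semiskimmed or full_fat", call. = FALSE)
  if (category != "cheese" && cheese_variety != "not_applicable")
    stop("cheese_variety applies to cheese only (got category '", category,
         "')", call. = FALSE)
  structure(list(category = category, fat_level = fat_level,
                 cheese_variety = cheese_variety),
            class = "dairy_class")
}

#' @export
format.dairy_class <- function(x, ...) {
  paste(x$category, x$fat_level, x$cheese_variety, sep = "/")
}

#' @export
print.dairy_class <- function(x, ...) {
  cat("<dairy_class>", format(x), "\n")
  invisible(x)
}

#' Construct an ingredient classification map
#'
#' Couples a dairy roster (ingredient code -> dairy class) with an explicit
#' non-dairy roster. The two rosters must be disjoint; together they are
#' expected to cover every base ingredient the active database resolves to.
#'
#' @param x data.frame with columns \code{ingredient_code}, \code{category}
#'   (a dairy category or \code{non_dairy}), \code{fat_level},
#'   \code{cheese_variety}; empty strings read as \code{not_applicable}.
#' @return data.frame of class \code{classification_map} with normalised
#'   columns; non-dairy rows have \code{category == "non_dairy"}.
#' @export
classification_map <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("ingredient_code", "category")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L)
    stop("classification table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"fat_level" %in% names(x)) x$fat_level <- ""
  if (!"cheese_variety" %in% names(x)) x$cheese_variety <- ""
  x <- x[c("ingredient_code", "category", "fat_level", "cheese_variety")]
  for (col in names(x)) x[[col]] <- as.character(x[[col]])
  x$fat_level[is.na(x$fat_level) | x$fat_level == ""] <- "not_applicable"
  x$cheese_variety[is.na(x$cheese_variety) |
                     x$cheese_variety == ""] <- "not_applicable"

  dup <- duplicated(x$ingredient_code)
  if (any(dup))
    stop("duplicate ingredient_code in classification map: ",
         paste(unique(x$ingredient_code[dup]), collapse = ", "),
         call. = FALSE)
  ok_cat <- x$category %in% c(DAIRY_CATEGORIES, NON_DAIRY)
  if (any(!ok_cat))
    stop("unknown category token at row(s) ",
         paste(which(!ok_cat), collapse = ", "), ": ",
         paste(unique(x$category[!ok_cat]), collapse = ", "), call. = FALSE)
  # validate each dairy row through the dairy_class invariants
  for (i in which(x$category != NON_DAIRY)) {
    cl <- tryCatch(
      dairy_class(x$category[i], x$fat_level[i], x$cheese_variety[i]),
      error = function(e) {
        stop("classification row ", i, " (", x$ingredient_code[i], "): ",
             conditionMessage(e), call. = FALSE)
      })
  }
  bad_nd <- which(x$category == NON_DAIRY &
                    (x$fat_level != "not_applicable" |
                       x$cheese_variety != "not_applicable"))
  if (length(bad_nd) > 0L)
    stop("non-dairy row(s) must not carry fat level or variety: row(s) ",
         paste(bad_nd, collapse = ", "), call. = FALSE)
  class(x) <- c("classification_map", "data.frame")
  x
}

#' Load an ingredient classification map from CSV
#'
#' @param path CSV with columns \code{ingredient_code, category, fat_level,
#'   cheese_variety}; empty cells mean \code{not_applicable};
#'   \code{category} is a dairy category or \code{non_dairy}.
#' @return A [classification_map()].
#' @export
load_classification_map <- function(path) {
  x <- read_csv_strict(path, c("ingredient_code", "category"))
  classification_map(x)
}

#' Classify a single ingredient
#'
#' Total over the codes the map covers: returns a [dairy_class()] for dairy
#' ingredients, the string \code{"non_dairy"} for rostered non-dairy
#' ingredients, and errors (naming the code) for anything else.
#'
#' @param map a [classification_map()].
#' @param ingredient_code single ingredient code.
#' @return A \code{dairy_class}, or \code{"non_dairy"}.
#' @export
classify_ingredient <- function(map, ingredient_code) {
  stopifnot(inherits(map, "classification_map"), length(ingredient_code) == 1L)
  i <- match(as.character(ingredient_code), map$ingredient_code)
  if (is.na(i))
    stop("unclassified ingredient: ", ingredient_code, call. = FALSE)
  if (map$category[i] == NON_DAIRY) return(NON_DAIRY)
  dairy_class(map$category[i], map$fat_level[i], map$cheese_variety[i])
}

# Vectorised lookup used internally by the disaggregation step: returns the
# map rows matching `codes`, erroring on any gap.
lookup_classes <- function(map, codes) {
  idx <- match(codes, map$ingredient_code)
  if (anyNA(idx))
    stop("unclassified ingredient(s): ",
         paste(unique(codes[is.na(idx)]), collapse = ", "), call. = FALSE)
  map[idx, , drop = FALSE]
}
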