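#' Names of the tracked nutrients
#'
#' The instrument records, for every item, total calories (kcal) plus seven
#' macronutrient amounts in grams: fat, saturated fat, carbohydrates, sugar,
#' salt, protein and fibre. Salt and fibre may be flagged unavailable (`NA`)
#' when a data source does not report them.
#'
#' @return Character vector of the eight nutrient names, in canonical order.
#' @export
nutrient_names <- function() {
  c(
    "calories", "fat", "saturated_fat", "carbohydrates",
    "sugar", "salt", "protein", "fibre"
  )
}

#' Construct a nutrient profile
#'
#' A nutrient profile is a named numeric vector over [nutrient_names()],
#' interpreted either per 100 g of a food or as an aggregate total (per basket
#' or per day). `NA` marks a nutrient as unavailable.
#'
#' @param calories,fat,saturated_fat,carbohydrates,sugar,salt,protein,fibre
#'   non-negative scalars; `NA` = unavailable (salt and fibre typically).
#' @return A `nutrient_profile` object.
#' @export
#' @examples
#' nutrient_profile(calories = 245.5, fat = 18, saturated_fat = 11,
#'                  carbohydrates = 5, sugar = 5, protein = 14)
nutrient_profile <- function(calories = NA_real_, fat = NA_real_,
                             saturated_fat = NA_real_,
                             carbohydrates = NA_real_, sugar = NA_real_,
                             salt = NA_real_, protein = NA_real_,
                             fibre = NA_real_) {
  x <- c(
    calories = as.numeric(calories), fat = as.numeric(fat),
    saturated_fat = as.numeric(saturated_fat),
    carbohydrates = as.numeric(carbohydrates), sugar = as.numeric(sugar),
    salt = as.numeric(salt), protein = as.numeric(protein),
    fibre = as.numeric(fibre)
  )
  validate_nutrient_profile(x)
  structure(x, class = "nutrient_profile")
}

#' @rdname nutrient_profile
#' @param x numeric vector (named over a subset of [nutrient_names()]) or list.
#' @export
as_nutrient_profile <- function(x) {
  out <- stats::setNames(rep(NA_real_, 8L), nutrient_names())
  x <- unlist(x)
  keep <- intersect(names(x), nutrient_names())
  out[keep] <- as.numeric(x[keep])
  validate_nutrient_profile(out)
  structure(out, class = "nutrient_profile")
}

validate_nutrient_profile <- function(x, what = "nutrient profile") {
  neg <- names(x)[!is.na(x) & x < 0]
  if (length(neg) > 0) {
    stop(sprintf("%s has negative values: %s", what, paste(neg, collapse = ", ")),
         call. = FALSE)
  }
  tol <- 1e-8
  if (!is.na(x[["fat"]]) && !is.na(x[["saturated_fat"]]) &&
      x[["saturated_fat"]] > x[["fat"]] + tol) {
    stop(sprintf("%s: saturated_fat (%g) exceeds fat (%g)", what,
                 x[["saturated_fat"]], x[["fat"]]), call. = FALSE)
  }
  if (!is.na(x[["carbohydrates"]]) && !is.na(x[["sugar"]]) &&
      x[["sugar"]] > x[["carbohydrates"]] + tol) {
    stop(sprintf("%s: sugar (%g) exceeds carbohydrates (%g)", what,
                 x[["sugar"]], x[["carbohydrates"]]), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.nutrient_profile <- function(x, ...) {
  cat("<nutrient_profile>\n")
  v <- unclass(x)
  shown <- ifelse(is.na(v), "unavailable", format(round(v, 3)))
  units <- c("kcal", rep("g", 7))
  for (i in seq_along(v)) {
    cat(sprintf("  %-14s %s %s\n", names(v)[i], shown[i],
                ifelse(is.na(v[i]), "", units[i])))
  }
  invisible(x)
}

# Sum profiles row-wise; NA in any addend marks the nutrient unavailable,
# except that an empty sum is an all-zero profile.
np_sum <- function(profiles) {
  if (length(profiles) == 0L) {
    return(structure(stats::setNames(rep(0, 8L), nutrient_names()),
                     class = "nutrient_profile"))
  }
  m <- do.call(rbind, lapply(profiles, function(p) unclass(p)[nutrient_names()]))
  structure(colSums(m), class = "nutrient_profile")
}

np_scale <- function(profile, k) {
  structure(unclass(profile) * k, class = "nutrient_profile")
}
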