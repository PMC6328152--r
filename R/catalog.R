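#' The six food and drink categories
#'
#' Items in the choice instrument are organized under six headings, mirroring
#' the tabs of an online supermarket: fruit and vegetables, meat and fish,
#' bread and grains, confectionery and snacks, ready meals, and drinks.
#'
#' @return Character vector of the six category tokens.
#' @export
food_categories <- function() {
  c("fruit_veg", "meat_fish", "bread_grains", "confectionery",
    "ready_meals", "drinks")
}

#' Pretty labels for the six categories
#' @return Named character vector mapping tokens to display labels.
#' @export
category_labels <- function() {
  c(fruit_veg = "Fruit and Veg", meat_fish = "Meat and Fish",
    bread_grains = "Bread and Grains", confectionery = "Confectionery",
    ready_meals = "Ready Meals", drinks = "Drinks")
}

catalog_columns <- function() {
  c("item_id", "name", "category", "price_pence", "pack_size_g",
    "kcal_100g", "fat_100g", "satfat_100g", "carb_100g", "sugar_100g",
    "salt_100g", "protein_100g", "fibre_100g")
}

nutrient_column_map <- function() {
  c(calories = "kcal_100g", fat = "fat_100g", saturated_fat = "satfat_100g",
    carbohydrates = "carb_100g", sugar = "sugar_100g", salt = "salt_100g",
    protein = "protein_100g", fibre = "fibre_100g")
}

new_catalog <- function(items, version = "unversioned") {
  structure(items, class = c("food_catalog", "data.frame"), version = version)
}

#' Validate a catalog table
#'
#' Checks the schema and the type invariants: required columns present, unique
#' item ids, categories among the six valid tokens, strictly positive integer
#' prices and pack sizes, non-negative nutrient values with saturated fat not
#' exceeding fat and sugar not exceeding carbohydrates.
#'
#' @param catalog a `food_catalog` or plain data.frame in catalog layout.
#' @return The validated catalog, invisibly.
#' @export
validate_catalog <- function(catalog) {
  missing_cols <- setdiff(catalog_columns(), names(catalog))
  if (length(missing_cols) > 0) {
    stop("catalog is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(catalog) == 0L) return(invisible(catalog))
  dup <- unique(catalog$item_id[duplicated(catalog$item_id)])
  if (length(dup) > 0) {
    stop("duplicate item_id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  bad_cat <- unique(catalog$category[!catalog$category %in% food_categories()])
  if (length(bad_cat) > 0) {
    stop("invalid category value(s): ", paste(bad_cat, collapse = ", "),
         "; expected one of ", paste(food_categories(), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(catalog$price_pence)) || any(catalog$price_pence <= 0) ||
      any(catalog$price_pence != round(catalog$price_pence))) {
    stop("price_pence must be positive integers (pence)", call. = FALSE)
  }
  if (any(is.na(catalog$pack_size_g)) || any(catalog$pack_size_g <= 0)) {
    stop("pack_size_g must be positive", call. = FALSE)
  }
  for (i in seq_len(nrow(catalog))) {
    validate_nutrient_profile(
      item_per100g(catalog[i, , drop = FALSE]),
      what = sprintf("item '%s'", catalog$item_id[i])
    )
  }
  invisible(catalog)
}

item_per100g <- function(row) {
  cols <- nutrient_column_map()
  stats::setNames(as.numeric(row[1, cols]), names(cols))
}

#' Load a grocery catalog from CSV or JSON
#'
#' The CSV layout has one row per item with columns
#' `item_id,name,category,price_pence,pack_size_g,kcal_100g,fat_100g,
#' satfat_100g,carb_100g,sugar_100g,salt_100g,protein_100g,fibre_100g`;
#' empty nutrient cells mean the nutrient is unavailable for that item.
#' The JSON format mirrors the same schema (`version` plus an `items` array).
#'
#' @param path file path.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @return A validated `food_catalog` (a data.frame subclass with a `version`
#'   attribute).
#' @export
#' @examples
#' cat_path <- system.file("extdata", "catalog_synthetic.csv", package = "basketlab")
#' catalog <- load_catalog(cat_path)
#' nrow(catalog)
load_catalog <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop("catalog file not found: ", path, call. = FALSE)
  if (format == "csv") {
    items <- utils::read.csv(path, stringsAsFactors = FALSE,
                             colClasses = c(item_id = "character"))
    version <- "unversioned"
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    items <- as.data.frame(obj$items, stringsAsFactors = FALSE)
    if (nrow(items) == 0L) {
      items <- as.data.frame(
        stats::setNames(rep(list(character(0)), length(catalog_columns())),
                        catalog_columns())
      )
    }
    version <- obj$version %||% "unversioned"
  }
  for (col in setdiff(catalog_columns(), names(items))) {
    # a fully-empty CSV nutrient column reads as logical NA; coerce silently
    if (col %in% nutrient_column_map()) items[[col]] <- NA_real_
  }
  num_cols <- c("price_pence", "pack_size_g", unname(nutrient_column_map()))
  for (col in intersect(num_cols, names(items))) {
    items[[col]] <- as.numeric(items[[col]])
  }
  items <- items[, intersect(catalog_columns(), names(items)), drop = FALSE]
  validate_catalog(items)
  new_catalog(items, version = version)
}

#' Write a catalog to CSV or JSON
#'
#' Round-trips with [load_catalog()]: reloading a written catalog reproduces it
#' field for field, including unavailable (`NA`) salt/fibre flags.
#'
#' @param catalog a validated `food_catalog`.
#' @inheritParams load_catalog
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  validate_catalog(catalog)
  if (format == "csv") {
    utils::write.csv(as.data.frame(catalog)[, catalog_columns(), drop = FALSE],
                     path, row.names = FALSE, na = "")
  } else {
    obj <- list(version = attr(catalog, "version") %||% "unversioned",
                items = as.data.frame(catalog)[, catalog_columns(), drop = FALSE])
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  }
  invisible(path)
}

#' The packaged reference catalog
#'
#' Loads the catalog fixture shipped with the package: the instrument's item
#' list (117 items across the six categories) with synthetic per-item prices
#' and per-100g nutrient values, calibrated so that the unweighted per-category
#' nutrient means reproduce the published category-level averages (e.g. fruit
#' and veg 47.4 kcal/100g, confectionery 471.9 kcal/100g). Salt and fibre are
#' carried in the schema but unavailable in the fixture.
#'
#' @return A `food_catalog`.
#' @export
default_catalog <- function() {
  load_catalog(system.file("extdata", "catalog_synthetic.csv",
                           package = "basketlab"))
}

#' Per-category unweighted nutrient means
#'
#' Averages the per-100g nutrient values over the items of each category
#' present in the catalog (unweighted by pack size or price). Categories with
#' no items are absent from the result.
#'
#' @param catalog a `food_catalog`.
#' @return A data.frame with one row per category present and one column per
#'   nutrient (per 100 g).
#' @export
#' @examples
#' means <- category_nutrient_means(default_catalog())
#' means[means$category == "fruit_veg", "calories"]
category_nutrient_means <- function(catalog) {
  validate_catalog(catalog)
  cats <- intersect(food_categories(), unique(catalog$category))
  cols <- nutrient_column_map()
  rows <- lapply(cats, function(cc) {
    sub <- catalog[catalog$category == cc, , drop = FALSE]
    vals <- vapply(cols, function(col) mean(sub[[col]]), numeric(1))
    cbind(data.frame(category = cc, n_items = nrow(sub),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(stats::setNames(vals, names(cols)))))
  })
  if (length(rows) == 0L) {
    return(data.frame(category = character(0), n_items = integer(0)))
  }
  do.call(rbind, rows)
}

#' Total nutrients in one pack of an item
#'
#' @param catalog a `food_catalog`.
#' @param item_id item token.
#' @return A `nutrient_profile`: per-100g values times `pack_size_g / 100`.
#' @export
item_pack_nutrients <- function(catalog, item_id) {
  row <- catalog[catalog$item_id == item_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown item_id: ", item_id, call. = FALSE)
  structure(item_per100g(row) * row$pack_size_g / 100,
            class = "nutrient_profile")
}

#' @export
print.food_catalog <- function(x, ...) {
  cat(sprintf("<food_catalog> %d items, version '%s'\n", nrow(x),
              attr(x, "version") %||% "unversioned"))
  if (nrow(x) > 0) {
    print(table(factor(x$category, levels = food_categories())))
  }
  invisible(x)
}
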