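#' Frequency scales of the dietary screener
#'
#' The screener offers two answer scales: the standard 8-option scale running
#' from "Rarely or Never" up to "5+ a day", and a 6-option scale used for the
#' seven meat and fish categories, running from "Rarely or Never" to "At least
#' everyday". Each option carries a numeric weight in occasions per day used by
#' the frequency-to-nutrient conversion. Only three weights are anchored by the
#' conversion protocol itself ("Rarely or Never" = 0, "Once per week" =
#' 1/7 = 0.14286, "1-2 times a day" = 1.5); the remaining options follow a
#' midpoint-occasions-per-day convention and are read from the packaged
#' configuration, never hard-coded, so they can be revised without touching
#' code.
#'
#' @param path optional path to a YAML scales file; defaults to the packaged
#'   configuration.
#' @return Named list of scales; each scale is a list with `scale_id`,
#'   `options` (ordered labels) and `weights` (occasions/day).
#' @export
#' @examples
#' sc <- ffq_scales()
#' sc$standard8$options
ffq_scales <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ffq_scales.yaml",
                                package = "basketlab")
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(id) {
    opts <- vapply(raw[[id]], function(o) o$label, character(1))
    wts <- vapply(raw[[id]], function(o) eval(parse(text = as.character(o$weight))),
                  numeric(1))
    validate_scale(id, opts, wts)
    list(scale_id = id, options = opts, weights = stats::setNames(wts, opts))
  })
  stats::setNames(out, names(raw))
}

validate_scale <- function(scale_id, options, weights) {
  if (length(options) != length(weights)) {
    stop("scale ", scale_id, ": options and weights differ in length",
         call. = FALSE)
  }
  if (weights[1] != 0) {
    stop("scale ", scale_id, ": first option must carry weight 0", call. = FALSE)
  }
  if (any(diff(weights) < 0)) {
    stop("scale ", scale_id, ": weights must be non-decreasing", call. = FALSE)
  }
  invisible(TRUE)
}

#' Daily frequency weight of a screener answer
#'
#' @param option answer label, e.g. `"Once per week"`.
#' @param scale a scale object from [ffq_scales()], or a scale id
#'   (`"standard8"` or `"meat6"`).
#' @return The option's weight in occasions per day.
#' @export
#' @examples
#' frequency_weight("Once per week", "standard8") # 1/7
#' frequency_weight("1-2 times a day", "standard8") # 1.5
frequency_weight <- function(option, scale = "standard8") {
  if (is.character(scale)) scale <- ffq_scales()[[scale]]
  if (is.null(scale)) stop("unknown scale", call. = FALSE)
  if (!option %in% scale$options) {
    stop(sprintf("'%s' is not an option on scale %s", option, scale$scale_id),
         call. = FALSE)
  }
  unname(scale$weights[[option]])
}

#' Construct a screener instrument
#'
#' An instrument is a set of food and drink categories, each answered on one
#' of the two frequency scales and carrying average per-100g nutrient values
#' used by the conversion. The deployed screener has exactly 23 categories, of
#' which the 7 meat and fish categories use the 6-option scale; smaller
#' instruments are permitted for single-category calculations and testing.
#'
#' @param categories data.frame with columns `label`, `scale_id` and the
#'   per-100g nutrient columns `kcal_100g, fat_100g, satfat_100g, carb_100g,
#'   sugar_100g, salt_100g, protein_100g, fibre_100g` (missing nutrient
#'   columns are treated as unavailable).
#' @param scales scale set from [ffq_scales()].
#' @return An `ffq_instrument` object.
#' @export
ffq_instrument <- function(categories, scales = ffq_scales()) {
  stopifnot(is.data.frame(categories),
            all(c("label", "scale_id") %in% names(categories)))
  if (anyDuplicated(categories$label)) {
    stop("instrument category labels must be unique", call. = FALSE)
  }
  bad <- setdiff(unique(categories$scale_id), names(scales))
  if (length(bad) > 0) {
    stop("unknown scale_id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  for (col in unname(nutrient_column_map())) {
    if (!col %in% names(categories)) categories[[col]] <- NA_real_
  }
  for (i in seq_len(nrow(categories))) {
    validate_nutrient_profile(
      stats::setNames(as.numeric(categories[i, nutrient_column_map()]),
                      names(nutrient_column_map())),
      what = sprintf("category '%s'", categories$label[i])
    )
  }
  structure(list(categories = categories, scales = scales),
            class = "ffq_instrument")
}

#' Load a screener instrument from YAML
#'
#' @param path YAML file listing the categories (label, scale, per-100g
#'   nutrient values).
#' @param scales scale set from [ffq_scales()].
#' @return An `ffq_instrument`.
#' @export
load_ffq_instrument <- function(path, scales = ffq_scales()) {
  raw <- yaml::read_yaml(path)
  rows <- lapply(raw$categories, function(cc) {
    nut <- cc$per_100g %||% list()
    data.frame(
      label = cc$label, scale_id = cc$scale,
      kcal_100g = as.numeric(nut$calories %||% NA),
      fat_100g = as.numeric(nut$fat %||% NA),
      satfat_100g = as.numeric(nut$saturated_fat %||% NA),
      carb_100g = as.numeric(nut$carbohydrates %||% NA),
      sugar_100g = as.numeric(nut$sugar %||% NA),
      salt_100g = as.numeric(nut$salt %||% NA),
      protein_100g = as.numeric(nut$protein %||% NA),
      fibre_100g = as.numeric(nut$fibre %||% NA),
      stringsAsFactors = FALSE
    )
  })
  ffq_instrument(do.call(rbind, rows), scales = scales)
}

#' The packaged 23-category screener instrument
#'
#' Loads the screener fixture shipped with the package: 23 food and drink
#' categories, 16 on the standard 8-option scale and the 7 meat and fish
#' categories on the 6-option scale. The per-100g nutrient means are synthetic
#' (the deployed instrument's nutrient table was not published); the
#' cheese/yoghurt category carries 245.5 kcal/100g, the value used in the
#' conversion protocol's worked example.
#'
#' @return An `ffq_instrument`.
#' @export
default_ffq_instrument <- function() {
  load_ffq_instrument(system.file("extdata", "ffq_instrument_synthetic.yaml",
                                  package = "basketlab"))
}

#' Convert screener answers to estimated daily nutrient intake
#'
#' For each category, the answer's frequency weight (occasions/day) is
#' multiplied by the category's average per-100g nutrient values — i.e. each
#' consumption occasion is valued at a 100 g reference portion, as the
#' conversion protocol's worked example implies (cheese/yoghurt at
#' "1-2 times a day" with 245.5 kcal/100g gives 1.5 x 245.5 = 368.25
#' kcal/day) — and the products are summed over categories.
#'
#' @param response data.frame with columns `category_label` and
#'   `option_label`, exactly one row per instrument category.
#' @param instrument an [ffq_instrument()].
#' @param portion_multiplier optional named numeric vector of per-category
#'   reference-portion multipliers (default 1 for every category), provided
#'   for sensitivity analysis.
#' @return A `nutrient_profile` of estimated daily intake.
#' @export
#' @examples
#' inst <- default_ffq_instrument()
#' resp <- data.frame(category_label = inst$categories$label,
#'                    option_label = "Rarely or Never")
#' ffq_daily_nutrients(resp, inst) # all-zero profile
ffq_daily_nutrients <- function(response, instrument,
                                portion_multiplier = NULL) {
  stopifnot(inherits(instrument, "ffq_instrument"),
            all(c("category_label", "option_label") %in% names(response)))
  cats <- instrument$categories
  missing_ans <- setdiff(cats$label, response$category_label)
  if (length(missing_ans) > 0) {
    stop("response is missing answer(s) for: ",
         paste(missing_ans, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(response$category_label, cats$label)
  if (length(extra) > 0) {
    stop("response answers unknown categor(ies): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(response$category_label)) {
    stop("response has duplicate answers", call. = FALSE)
  }
  ans <- response$option_label[match(cats$label, response$category_label)]
  w <- vapply(seq_len(nrow(cats)), function(i) {
    frequency_weight(ans[i], instrument$scales[[cats$scale_id[i]]])
  }, numeric(1))
  if (!is.null(portion_multiplier)) {
    mult <- rep(1, nrow(cats))
    idx <- match(names(portion_multiplier), cats$label)
    mult[idx[!is.na(idx)]] <- portion_multiplier[!is.na(idx)]
    w <- w * mult
  }
  cols <- nutrient_column_map()
  vals <- vapply(cols, function(col) {
    # a never-consumed category contributes a known zero even where the
    # instrument's nutrient value is unavailable
    contrib <- ifelse(w == 0, 0, w * cats[[col]])
    sum(contrib)
  }, numeric(1))
  structure(stats::setNames(vals, names(cols)), class = "nutrient_profile")
}

#' Read screener responses from CSV
#'
#' Layout: `participant_id,category_label,option_label`.
#'
#' @param path CSV path.
#' @return Named list of per-participant response data.frames.
#' @export
read_ffq_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character"))
  need <- c("participant_id", "category_label", "option_label")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("response file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  lapply(split(df[c("category_label", "option_label")], df$participant_id),
         `rownames<-`, NULL)
}

#' @export
print.ffq_instrument <- function(x, ...) {
  tab <- table(x$categories$scale_id)
  cat(sprintf("<ffq_instrument> %d categories (%s)\n", nrow(x$categories),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}
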