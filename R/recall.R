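#' Aggregate 24-hour recall entries to daily nutrient intake
#'
#' Each entry records one food consumed in the recalled day, with its portion
#' in grams and per-100g nutrient values (as exported from a web recall
#' system). The daily total is the sum over entries of
#' `portion_g / 100` times the per-100g values; it is additive over entry
#' lists. All entries must belong to one participant-day.
#'
#' @param entries data.frame with columns `participant_id`, `food`,
#'   `portion_g` and per-100g nutrient columns (`kcal_100g`, `fat_100g`,
#'   `satfat_100g`, `carb_100g`, `sugar_100g`, `salt_100g`, `protein_100g`,
#'   `fibre_100g`; missing columns are treated as unavailable). Zero rows
#'   give an all-zero profile.
#' @return A `nutrient_profile` of daily totals.
#' @export
#' @examples
#' e <- data.frame(participant_id = "P1", food = "porridge",
#'                 portion_g = 250, kcal_100g = 200)
#' recall_daily_nutrients(e)[["calories"]] # 500
recall_daily_nutrients <- function(entries) {
  cols <- nutrient_column_map()
  if (is.null(entries) || nrow(entries) == 0L) {
    out <- stats::setNames(rep(0, 8L), names(cols))
    return(structure(out, class = "nutrient_profile"))
  }
  stopifnot(all(c("participant_id", "portion_g") %in% names(entries)))
  if (length(unique(entries$participant_id)) > 1L) {
    stop("entries mix participants: ",
         paste(unique(entries$participant_id), collapse = ", "),
         "; aggregate one participant-day at a time", call. = FALSE)
  }
  if (any(is.na(entries$portion_g)) || any(entries$portion_g <= 0)) {
    stop("portion_g must be positive for every entry", call. = FALSE)
  }
  for (col in unname(cols)) {
    if (!col %in% names(entries)) entries[[col]] <- NA_real_
  }
  vals <- vapply(cols, function(col) {
    sum(entries$portion_g / 100 * entries[[col]])
  }, numeric(1))
  structure(stats::setNames(vals, names(cols)), class = "nutrient_profile")
}

#' Read recall entries from CSV
#'
#' Layout: `participant_id,food,portion_g,kcal_100g,...` (one row per food
#' consumed in the recalled day).
#'
#' @param path CSV path.
#' @return Named list of per-participant entry data.frames, ready for
#'   [recall_daily_nutrients()].
#' @export
read_recall_entries <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character"))
  need <- c("participant_id", "food", "portion_g")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("recall file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  lapply(split(df, df$participant_id), `rownames<-`, NULL)
}
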