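#' Create an empty shopping basket
#'
#' A basket holds a participant's item quantities together with the budget
#' state. The default budget is 3000 pence (the 30 GBP weekly allowance) with a
#' 100 pence spend-down margin: participants are asked to spend to within one
#' pound of the budget, but underspending is allowed and only triggers an
#' advisory warning at checkout.
#'
#' @param participant_id participant token.
#' @param budget budget in pence (> 0).
#' @param margin advisory underspend margin in pence (>= 0).
#' @return A `food_basket` object with status `"open"`.
#' @export
#' @examples
#' b <- new_basket("P001")
#' b <- set_quantity(b, "FV01", 2, default_catalog())
new_basket <- function(participant_id, budget = 3000L, margin = 100L) {
  stopifnot(length(participant_id) == 1L, budget > 0, margin >= 0)
  structure(
    list(
      participant_id = as.character(participant_id),
      lines = data.frame(item_id = character(0), quantity = integer(0),
                         stringsAsFactors = FALSE),
      budget = as.integer(budget),
      margin = as.integer(margin),
      status = "open"
    ),
    class = "food_basket"
  )
}

#' Set the quantity of an item in a basket
#'
#' There are no restrictions on which items or how many packs may be chosen;
#' the budget is enforced only at checkout. Setting a quantity of zero removes
#' the line. A checked-out basket can no longer be mutated.
#'
#' @param basket an open `food_basket`.
#' @param item_id item token; must resolve in `catalog`.
#' @param quantity non-negative integer number of packs.
#' @param catalog the session's `food_catalog`.
#' @return The updated basket.
#' @export
set_quantity <- function(basket, item_id, quantity, catalog) {
  stopifnot(inherits(basket, "food_basket"))
  if (basket$status != "open") {
    stop("basket for participant ", basket$participant_id,
         " is checked out and cannot be modified", call. = FALSE)
  }
  if (length(quantity) != 1L || is.na(quantity) || quantity < 0 ||
      quantity != round(quantity)) {
    stop("quantity must be a single non-negative integer", call. = FALSE)
  }
  if (!item_id %in% catalog$item_id) {
    stop("unknown item_id: ", item_id, call. = FALSE)
  }
  lines <- basket$lines[basket$lines$item_id != item_id, , drop = FALSE]
  if (quantity > 0) {
    lines <- rbind(lines, data.frame(item_id = as.character(item_id),
                                     quantity = as.integer(quantity),
                                     stringsAsFactors = FALSE))
  }
  rownames(lines) <- NULL
  basket$lines <- lines
  basket
}

resolve_lines <- function(basket, catalog) {
  if (nrow(basket$lines) == 0L) {
    return(cbind(basket$lines, catalog[0, , drop = FALSE]))
  }
  idx <- match(basket$lines$item_id, catalog$item_id)
  if (anyNA(idx)) {
    stop("basket line(s) reference unknown item_id(s): ",
         paste(basket$lines$item_id[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  cbind(basket$lines, catalog[idx, setdiff(names(catalog), "item_id"),
                              drop = FALSE])
}

#' Total cost of a basket, in pence
#'
#' @inheritParams set_quantity
#' @return Integer pence: the sum over lines of quantity times pack price.
#' @export
total_cost <- function(basket, catalog) {
  resolved <- resolve_lines(basket, catalog)
  as.integer(sum(resolved$quantity * resolved$price_pence))
}

#' Aggregate nutrient content of a basket
#'
#' Sums, per nutrient, quantity times per-100g value times `pack_size_g / 100`
#' over all lines. A nutrient unavailable for any selected item is flagged
#' unavailable (`NA`) in the total; the others are still computed.
#'
#' @inheritParams set_quantity
#' @return A `nutrient_profile` of basket totals (kcal and grams).
#' @export
nutrient_totals <- function(basket, catalog) {
  resolved <- resolve_lines(basket, catalog)
  if (nrow(resolved) == 0L) {
    return(structure(stats::setNames(rep(0, 8L), nutrient_names()),
                     class = "nutrient_profile"))
  }
  cols <- nutrient_column_map()
  vals <- vapply(cols, function(col) {
    sum(resolved$quantity * resolved[[col]] * resolved$pack_size_g / 100)
  }, numeric(1))
  structure(stats::setNames(vals, names(cols)), class = "nutrient_profile")
}

#' Check a basket out against its budget
#'
#' The budget is a hard ceiling at checkout: a basket costing more than the
#' budget is rejected (with the overspend named in the reason) and stays open,
#' mirroring the pop-up that invites participants to delete items. On
#' acceptance the basket is frozen (`status = "checked_out"`) and the change
#' `budget - cost` is reported; change above the margin raises an advisory
#' underspend warning only, since spending less was allowed.
#'
#' @inheritParams set_quantity
#' @return A list of class `checkout_result` with fields `accepted`,
#'   `total_cost`, `change`, `underspend_warning`, `reason`, and the (possibly
#'   frozen) `basket`.
#' @export
checkout <- function(basket, catalog) {
  stopifnot(inherits(basket, "food_basket"))
  cost <- total_cost(basket, catalog)
  if (basket$status == "checked_out") {
    # idempotent: re-checkout reports the frozen state unchanged
    change <- basket$budget - cost
    return(structure(
      list(accepted = TRUE, total_cost = cost, change = change,
           underspend_warning = change > basket$margin,
           reason = "already checked out", basket = basket),
      class = "checkout_result"
    ))
  }
  if (cost > basket$budget) {
    return(structure(
      list(accepted = FALSE, total_cost = cost, change = NA_integer_,
           underspend_warning = FALSE,
           reason = sprintf("budget exceeded by %dp (cost %dp > budget %dp); remove items and retry",
                            cost - basket$budget, cost, basket$budget),
           basket = basket),
      class = "checkout_result"
    ))
  }
  basket$status <- "checked_out"
  change <- basket$budget - cost
  structure(
    list(accepted = TRUE, total_cost = cost, change = as.integer(change),
         underspend_warning = change > basket$margin,
         reason = if (change > basket$margin) {
           sprintf("accepted; change %dp exceeds the %dp margin (advisory)",
                   change, basket$margin)
         } else "accepted",
         basket = basket),
    class = "checkout_result"
  )
}

#' @export
print.checkout_result <- function(x, ...) {
  cat(sprintf("<checkout_result> %s: cost %sp, change %sp%s\n",
              if (x$accepted) "accepted" else "rejected",
              x$total_cost, x$change,
              if (isTRUE(x$underspend_warning)) " [underspend warning]" else ""))
  cat("  ", x$reason, "\n", sep = "")
  invisible(x)
}

category_vector <- function(basket, catalog, what = c("spend", "count")) {
  what <- match.arg(what)
  resolved <- resolve_lines(basket, catalog)
  out <- stats::setNames(rep(0, 6L), food_categories())
  if (nrow(resolved) == 0L) return(out)
  per_line <- if (what == "spend") {
    resolved$quantity * resolved$price_pence
  } else {
    resolved$quantity
  }
  agg <- tapply(per_line, factor(resolved$category, levels = food_categories()),
                sum, default = 0)
  out[names(agg)] <- as.numeric(agg)
  out
}

#' Expenditure per category, in pence
#'
#' @inheritParams set_quantity
#' @return Named numeric six-vector over [food_categories()]; sums exactly to
#'   [total_cost()].
#' @export
spend_by_category <- function(basket, catalog) {
  category_vector(basket, catalog, "spend")
}

#' Number of items selected per category
#'
#' @inheritParams set_quantity
#' @return Named numeric six-vector of pack counts; sums to the total quantity.
#' @export
items_by_category <- function(basket, catalog) {
  category_vector(basket, catalog, "count")
}

#' Read participant baskets from a CSV file
#'
#' Layout: `participant_id,item_id,quantity`, one row per basket line.
#'
#' @param path CSV path.
#' @param catalog the `food_catalog` lines must resolve against.
#' @param budget,margin budget state, in pence, applied to every basket.
#' @return Named list of `food_basket` objects, one per participant.
#' @export
read_baskets <- function(path, catalog, budget = 3000L, margin = 100L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character",
                                       item_id = "character"))
  need <- c("participant_id", "item_id", "quantity")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("basket file missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  baskets_from_lines(df, catalog, budget = budget, margin = margin)
}

# build baskets from a long lines table (participant_id,item_id,quantity)
baskets_from_lines <- function(lines, catalog, budget = 3000L, margin = 100L) {
  split_lines <- split(lines, lines$participant_id)
  out <- lapply(names(split_lines), function(pid) {
    b <- new_basket(pid, budget = budget, margin = margin)
    sub <- split_lines[[pid]]
    agg <- tapply(sub$quantity, sub$item_id, sum)
    for (iid in names(agg)) b <- set_quantity(b, iid, agg[[iid]], catalog)
    b
  })
  stats::setNames(out, names(split_lines))
}

#' @export
print.food_basket <- function(x, ...) {
  cat(sprintf("<food_basket> participant %s, %d line(s), status %s, budget %dp\n",
              x$participant_id, nrow(x$lines), x$status, x$budget))
  invisible(x)
}
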