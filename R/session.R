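#' Create an experimental session
#'
#' Sessions hold between 1 and 18 participants; at the end of each session one
#' participant is drawn at random and receives their chosen basket (the
#' random-lottery incentive).
#'
#' @param session_id session token.
#' @param participant_ids character vector of unique participant tokens
#'   (length 1 to 18).
#' @param seed integer root seed for the session's random draws.
#' @return A `lab_session` object.
#' @export
#' @examples
#' s <- lab_session("S01", paste0("P", 1:10), seed = 7L)
#' draw_winner(s)
lab_session <- function(session_id, participant_ids, seed = 1L) {
  participant_ids <- as.character(participant_ids)
  if (length(participant_ids) < 1L || length(participant_ids) > 18L) {
    stop("a session holds between 1 and 18 participants, got ",
         length(participant_ids), call. = FALSE)
  }
  if (anyDuplicated(participant_ids)) {
    stop("participant_ids must be unique within a session", call. = FALSE)
  }
  structure(
    list(session_id = as.character(session_id),
         participant_ids = participant_ids, seed = as.integer(seed)),
    class = "lab_session"
  )
}

#' Randomize initial category exposure
#'
#' Upon login each participant is shown one of the six food and drink
#' categories first; the category varies randomly across participants to avoid
#' systematic priming. Draws are i.i.d. uniform over the six categories, each
#' from a per-participant stream derived from the root seed, so adding
#' participants never perturbs existing assignments.
#'
#' @param participant_ids non-empty character vector of participant tokens.
#' @param seed integer root seed.
#' @return A data.frame `participant_id, front_category` (one row each).
#' @export
assign_initial_category <- function(participant_ids, seed) {
  if (length(participant_ids) == 0L) {
    stop("participant_ids must be non-empty", call. = FALSE)
  }
  participant_ids <- as.character(participant_ids)
  if (anyDuplicated(participant_ids)) {
    stop("participant_ids must be unique", call. = FALSE)
  }
  cats <- vapply(participant_ids, function(pid) {
    with_rng(derived_seed(seed, paste0("exposure:", pid)),
             sample(food_categories(), 1L))
  }, character(1))
  data.frame(participant_id = participant_ids, front_category = unname(cats),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Draw the session's lottery winner
#'
#' Uniform draw over the session's participants, from a stream derived from
#' the session seed and id; repeated draws on the same session reproduce the
#' same winner.
#'
#' @param session a `lab_session`.
#' @return The winning participant id (length-1 character).
#' @export
draw_winner <- function(session) {
  stopifnot(inherits(session, "lab_session"))
  if (length(session$participant_ids) == 0L) {
    stop("cannot draw a winner from an empty session", call. = FALSE)
  }
  with_rng(
    derived_seed(session$seed, paste0("winner:", session$session_id)),
    session$participant_ids[sample.int(length(session$participant_ids), 1L)]
  )
}

#' Relationship between session size and basket calories
#'
#' Participants in smaller sessions face better lottery odds of receiving
#' their basket; a material association between session size and chosen
#' calories would signal that the incentive's dilution affects choices. This
#' fits a simple linear regression of basket calories on session size with
#' heteroskedasticity-consistent standard errors.
#'
#' @param records data.frame with columns `session_size` and
#'   `basket_calories`, one row per participant.
#' @param hc_type sandwich estimator flavor (default `"HC1"`).
#' @return List with `slope`, `robust_se`, `p_value`, `n` and the `lm` fit.
#' @export
group_size_robustness <- function(records, hc_type = "HC1") {
  stopifnot(all(c("session_size", "basket_calories") %in% names(records)))
  if (length(unique(records$session_size)) < 2L) {
    stop("session size is constant; slope is not identified (collinear design)",
         call. = FALSE)
  }
  fit <- stats::lm(basket_calories ~ session_size, data = records)
  vc <- sandwich::vcovHC(fit, type = hc_type)
  ct <- lmtest::coeftest(fit, vcov. = vc)
  list(
    slope = unname(ct["session_size", "Estimate"]),
    robust_se = unname(ct["session_size", "Std. Error"]),
    p_value = unname(ct["session_size", "Pr(>|t|)"]),
    n = stats::nobs(fit),
    fit = fit
  )
}

#' @export
print.lab_session <- function(x, ...) {
  cat(sprintf("<lab_session> %s: %d participant(s), seed %d\n",
              x$session_id, length(x$participant_ids), x$seed))
  invisible(x)
}
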