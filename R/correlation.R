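#' Cross-instrument correlation matrix for one nutrient
#'
#' Computes pairwise Pearson correlations of a nutrient's measurements across
#' the three dietary assessment tools (basket instrument, 24-hour recall,
#' screener), over the participants present in both tools of each pair, with
#' two-sided p-values and a 5% significance flag. Note the tools are not on a
#' common scale (the basket is a weekly-shop total, the other two are per-day
#' estimates); Pearson correlation is invariant to such affine rescaling.
#'
#' @param measures data.frame in long layout: columns `participant_id`,
#'   `tool` (values among `"basket"`, `"recall"`, `"ffq"`) and one column per
#'   nutrient (e.g. `calories`), one row per participant-tool.
#' @param nutrient nutrient column to correlate (default `"calories"`).
#' @param tools tools to include, in display order.
#' @return A `dietary_correlation` object: list with matrices `r`, `p_value`,
#'   `n`, logical `significant` (5% level), and the nutrient name.
#' @export
#' @examples
#' m <- data.frame(
#'   participant_id = rep(sprintf("P%02d", 1:6), 3),
#'   tool = rep(c("basket", "recall", "ffq"), each = 6),
#'   calories = c(1:6, c(2, 1, 4, 3, 6, 5) * 100, 6:1 * 10)
#' )
#' correlation_matrix(m, "calories")
correlation_matrix <- function(measures, nutrient = "calories",
                               tools = c("basket", "recall", "ffq")) {
  stopifnot(all(c("participant_id", "tool") %in% names(measures)))
  if (!nutrient %in% names(measures)) {
    stop("measures has no column '", nutrient, "'", call. = FALSE)
  }
  k <- length(tools)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(tools, tools))
  diag(r) <- 1
  diag(p) <- 0
  for (tool in tools) {
    sub <- measures[measures$tool == tool, , drop = FALSE]
    diag(n)[match(tool, tools)] <- sum(!is.na(sub[[nutrient]]))
  }
  complete_pairs <- 0L
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      a <- measures[measures$tool == tools[i], c("participant_id", nutrient)]
      b <- measures[measures$tool == tools[j], c("participant_id", nutrient)]
      merged <- merge(a, b, by = "participant_id",
                      suffixes = c(".a", ".b"))
      merged <- merged[stats::complete.cases(merged), , drop = FALSE]
      x <- merged[[paste0(nutrient, ".a")]]
      y <- merged[[paste0(nutrient, ".b")]]
      if (nrow(merged) >= 3L) complete_pairs <- complete_pairs + 1L
      if (nrow(merged) < 3L) {
        stop(sprintf("fewer than 3 complete participants for pair %s/%s",
                     tools[i], tools[j]), call. = FALSE)
      }
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        stop(sprintf("correlation undefined for pair %s/%s: constant values",
                     tools[i], tools[j]), call. = FALSE)
      }
      ct <- stats::cor.test(x, y, method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
      n[i, j] <- n[j, i] <- nrow(merged)
    }
  }
  structure(
    list(nutrient = nutrient, r = r, p_value = p, n = n,
         significant = p < 0.05),
    class = "dietary_correlation"
  )
}

#' @export
print.dietary_correlation <- function(x, digits = 2, ...) {
  cat(sprintf("<dietary_correlation> nutrient: %s\n", x$nutrient))
  shown <- matrix(
    paste0(format(round(x$r, digits)),
           ifelse(x$significant & row(x$r) != col(x$r), "**", "")),
    nrow = nrow(x$r), dimnames = dimnames(x$r)
  )
  shown[upper.tri(shown)] <- ""
  print(shown, quote = FALSE)
  cat("** significant at the 5% level (two-sided)\n")
  invisible(x)
}
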