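#' RAND/UCLA disagreement index
#'
#' Panel ratings on the 1--9 scale are summarized by the interpercentile
#' range IPR = P70 - P30 and compared to the interpercentile range adjusted
#' for symmetry, IPRAS = 2.35 + 1.5 * AI, where AI = |5 - IPRCP| is the
#' asymmetry index and IPRCP = (P30 + P70) / 2 the central point of the
#' interpercentile range (constants from the RAND/UCLA appropriateness
#' manual). The disagreement index DI = IPR / IPRAS flags panel
#' disagreement when it exceeds 1.
#'
#' @param ratings Integer vector of ratings in 1..9; at least 3 required.
#' @param quantile_type Percentile convention passed to
#'   [stats::quantile()]; default 7 (linear interpolation between order
#'   statistics). DI values near the 1.0 boundary are sensitive to this
#'   choice, so it is exposed.
#' @return A list of class `rqit_disagreement` with `ipr`, `ipras`, `di`
#'   and `median`.
#' @examples
#' disagreement_index(c(1, 1, 2, 8, 9, 9))$di  # polarized panel: DI > 1
#' @export
disagreement_index <- function(ratings, quantile_type = 7) {
  ratings <- as.numeric(ratings)
  if (length(ratings) < 3L)
    stop_rqit("need at least 3 ratings for a disagreement index",
              class = "rqit_insufficient_data")
  if (any(is.na(ratings)) || any(ratings < 1 | ratings > 9))
    stop_rqit("ratings must be on the 1-9 scale",
              class = "rqit_validation_error")
  q <- stats::quantile(ratings, c(0.3, 0.7), type = quantile_type, names = FALSE)
  ipr <- q[2L] - q[1L]
  iprcp <- (q[1L] + q[2L]) / 2
  ipras <- 2.35 + 1.5 * abs(5 - iprcp)
  structure(list(ipr = ipr, ipras = ipras, di = ipr / ipras,
                 median = stats::median(ratings)),
            class = "rqit_disagreement")
}

#' @export
print.rqit_disagreement <- function(x, ...) {
  cat(sprintf("median %.1f, IPR %.2f, IPRAS %.2f, DI %.3f%s\n",
              x$median, x$ipr, x$ipras, x$di,
              if (x$di > 1) " (disagreement)" else ""))
  invisible(x)
}

#' Select Delphi items for re-rating
#'
#' An item goes back to the panel if opinion is uncertain (median rating 4
#' through 6) or if there is significant disagreement (disagreement index
#' greater than 1).
#'
#' @param items A data.frame with columns `item_id` and `ratings` (a list
#'   column of rating vectors), or a named list of rating vectors.
#' @param quantile_type See [disagreement_index()].
#' @return A data.frame with `item_id`, `median`, `di`, `selected` and
#'   `reason` (`"median"`, `"disagreement"`, `"both"` or `""`).
#' @export
select_for_rerating <- function(items, quantile_type = 7) {
  items <- as_delphi_items(items)
  stats_ <- lapply(items$ratings, disagreement_index,
                   quantile_type = quantile_type)
  med <- vapply(stats_, `[[`, numeric(1), "median")
  di <- vapply(stats_, `[[`, numeric(1), "di")
  med_rule <- med >= 4 & med <= 6
  dis_rule <- di > 1
  reason <- ifelse(med_rule & dis_rule, "both",
                   ifelse(med_rule, "median",
                          ifelse(dis_rule, "disagreement", "")))
  data.frame(item_id = items$item_id, median = med, di = di,
             selected = med_rule | dis_rule, reason = reason)
}

as_delphi_items <- function(items) {
  if (is.data.frame(items)) {
    if (!all(c("item_id", "ratings") %in% names(items)))
      stop_rqit("items need `item_id` and `ratings` columns",
                class = "rqit_validation_error")
    return(items)
  }
  if (is.list(items))
    return(data.frame(item_id = names(items) %||% seq_along(items),
                      ratings = I(unname(items))))
  stop_rqit("items must be a data.frame or named list of rating vectors",
            class = "rqit_validation_error")
}

#' Theme contributions to the sum of median ratings
#'
#' Items surviving the consensus floor (median rating at or above
#' `rating_floor`) are grouped by theme; each theme's contribution is the
#' sum of its item medians as a percentage of the grand total.
#'
#' @param items A data.frame with columns `item_id`, `theme` and `ratings`
#'   (list column of rating vectors), or with a precomputed `median`
#'   column.
#' @param rating_floor Minimum item median to retain (default 7).
#' @return A data.frame with `theme`, `n_items`, `sum_medians`, `percent`
#'   (percentages sum to 100 up to rounding).
#' @examples
#' items <- data.frame(theme = rep(c("impact", "deliver"), c(2, 1)),
#'                     item_id = 1:3)
#' items$ratings <- list(c(8, 8, 9), c(7, 7, 8), c(7, 7, 7))
#' theme_contributions(items)
#' @export
theme_contributions <- function(items, rating_floor = 7) {
  if (!"theme" %in% names(items))
    stop_rqit("items need a `theme` column", class = "rqit_validation_error")
  med <- if ("median" %in% names(items)) items$median else
    vapply(items$ratings, function(r) stats::median(as.numeric(r)), numeric(1))
  keep <- med >= rating_floor
  if (!any(keep)) {
    warning("no items at or above the rating floor")
    return(data.frame(theme = character(), n_items = integer(),
                      sum_medians = numeric(), percent = numeric()))
  }
  med <- med[keep]
  theme <- as.character(items$theme)[keep]
  sums <- tapply(med, theme, sum)
  out <- data.frame(theme = names(sums), n_items = as.integer(table(theme)[names(sums)]),
                    sum_medians = as.numeric(sums))
  out$percent <- 100 * out$sum_medians / sum(out$sum_medians)
  out[order(-out$sum_medians), , drop = FALSE]
}
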