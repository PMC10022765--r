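#' Unweighted instrument score on the 0--18 scale
#'
#' Before utilities are calibrated, an instrument can be scored by a simple
#' sum with every dimension's levels mapped linearly onto 0--3 (lowest
#' level 0, highest 3; a 3-level dimension maps to 0, 1.5, 3). With six
#' dimensions the possible range is 0 to 18.
#'
#' @param profile Character vector of element codes, one per dimension.
#' @param instrument The instrument defining level counts; defaults to the
#'   packaged six-dimension original ([rqit_original()]).
#' @return Numeric score.
#' @examples
#' unweighted_rqit_score(c("A4", "B3", "C4", "D4", "E4", "F4"))  # 18
#' @export
unweighted_rqit_score <- function(profile, instrument = rqit_original()) {
  instrument <- as_instrument(instrument)
  profile <- check_profile(profile, instrument)
  counts <- instrument_level_counts(instrument)
  idx <- as.integer(substring(profile, 2L))
  sum(3 * (idx - 1) / (counts - 1))
}

#' Cramer's V association for a contingency table
#'
#' V = sqrt(chi-square / (n * min(rows - 1, cols - 1))) with the Pearson
#' chi-square (no continuity correction), interpreted like a correlation
#' coefficient. The p-value comes from the chi-square distribution, or
#' from Fisher's exact test when any expected count is below 5.
#'
#' @param table An r x c matrix of non-negative counts (or something
#'   coercible via [as.matrix()]).
#' @return A list of class `rqit_association`: `statistic = "Cramer's V"`,
#'   `value`, `p_value`, `df`, `test` (`"chi-squared"` or `"fisher"`).
#' @examples
#' cramers_v(matrix(c(10, 0, 0, 10), 2))  # perfect association: V = 1
#' @export
cramers_v <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0) || sum(m) <= 0)
    stop_rqit("counts must be non-negative with positive total",
              class = "rqit_validation_error")
  live_r <- rowSums(m) > 0; live_c <- colSums(m) > 0
  if (sum(live_r) < 2L || sum(live_c) < 2L) {
    warning("degenerate table (single non-empty row or column); V = 0")
    return(structure(list(statistic = "Cramer's V", value = 0,
                          p_value = NA_real_, df = 0L, test = "none"),
                     class = "rqit_association"))
  }
  m <- m[live_r, live_c, drop = FALSE]
  chi <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  v <- sqrt(chi$statistic[[1L]] /
              (sum(m) * min(nrow(m) - 1L, ncol(m) - 1L)))
  small <- any(chi$expected < 5)
  p <- if (small) stats::fisher.test(m, simulate.p.value = nrow(m) * ncol(m) > 8,
                                     B = 1e4)$p.value else chi$p.value
  structure(list(statistic = "Cramer's V", value = unname(v),
                 p_value = unname(p), df = unname(chi$parameter),
                 chi_square = chi$statistic[[1L]],
                 test = if (small) "fisher" else "chi-squared"),
            class = "rqit_association")
}

#' @export
print.rqit_association <- function(x, ...) {
  cat(sprintf("%s = %.3f (p = %.3g, %s test)\n", x$statistic, x$value,
              x$p_value, x$test))
  invisible(x)
}

#' Tertile logistic regression of an outcome group on scores
#'
#' Scores are cut into tertiles at the empirical 1/3 and 2/3 quantiles
#' (right-closed intervals; ties that would empty a tertile shift the
#' boundary to the nearest distinct value, with a note). A logistic
#' regression of the binary group on tertile indicators (lowest tertile as
#' reference) gives odds ratios with Wald confidence intervals, the model
#' likelihood-ratio chi-square, and Nagelkerke's R-squared.
#'
#' @param scores Numeric vector.
#' @param groups Binary vector (0/1, logical, or 2-level factor); 1/TRUE =
#'   the outcome of interest (e.g. high-impact journal group).
#' @param conf_level Confidence level for the odds-ratio intervals.
#' @return A list of class `rqit_tertile_fit`: data.frame `odds_ratios`
#'   (tertiles 2 and 3), `model_chi_square`, `df`, `p_value`,
#'   `nagelkerke_r2`, `tertile` assignment and the underlying `glm` fit.
#' @export
tertile_logistic <- function(scores, groups, conf_level = 0.95) {
  scores <- as.numeric(scores)
  g <- as_binary(groups)
  if (length(scores) != length(g))
    stop_rqit("scores and groups lengths differ", class = "rqit_validation_error")
  if (length(unique(scores)) < 3L)
    stop_rqit("need at least 3 distinct score values",
              class = "rqit_validation_error")
  tert <- cut_tertiles(scores)
  fit <- stats::glm(g ~ tert, family = stats::binomial())
  co <- stats::coef(fit)[-1L]
  se <- sqrt(diag(stats::vcov(fit)))[-1L]
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  or <- data.frame(tertile = 2:3, or = exp(co),
                   conf_low = exp(co - zq * se), conf_high = exp(co + zq * se),
                   p_value = 2 * stats::pnorm(-abs(co / se)),
                   row.names = NULL)
  dev0 <- fit$null.deviance; dev1 <- stats::deviance(fit); n <- length(g)
  chi2 <- dev0 - dev1
  r2 <- (1 - exp((dev1 - dev0) / n)) / (1 - exp(-dev0 / n))
  structure(list(odds_ratios = or, model_chi_square = chi2, df = 2L,
                 p_value = stats::pchisq(chi2, 2L, lower.tail = FALSE),
                 nagelkerke_r2 = r2, tertile = tert, fit = fit),
            class = "rqit_tertile_fit")
}

#' @export
print.rqit_tertile_fit <- function(x, ...) {
  cat("Tertile logistic regression (tertile 1 = reference)\n")
  for (i in seq_len(nrow(x$odds_ratios)))
    cat(sprintf("  tertile %d: OR %.2f (%.2f to %.2f), p = %.3g\n",
                x$odds_ratios$tertile[i], x$odds_ratios$or[i],
                x$odds_ratios$conf_low[i], x$odds_ratios$conf_high[i],
                x$odds_ratios$p_value[i]))
  cat(sprintf("  model chi-square %.2f (%d df, p = %.3g), Nagelkerke R2 %.2f\n",
              x$model_chi_square, x$df, x$p_value, x$nagelkerke_r2))
  invisible(x)
}

as_binary <- function(groups) {
  if (is.factor(groups) || is.character(groups)) {
    f <- factor(groups)
    if (nlevels(f) != 2L)
      stop_rqit("groups must be binary", class = "rqit_validation_error")
    return(as.integer(f) - 1L)
  }
  g <- as.numeric(groups)
  if (!all(g %in% c(0, 1)))
    stop_rqit("groups must be binary", class = "rqit_validation_error")
  as.integer(g)
}

cut_tertiles <- function(scores) {
  qs <- stats::quantile(scores, c(1, 2) / 3, names = FALSE)
  tert <- 1L + (scores > qs[1L]) + (scores > qs[2L])
  if (length(unique(tert)) < 3L) {
    message("tied scores emptied a tertile; boundaries shifted to nearest distinct values")
    u <- sort(unique(scores))
    qs <- u[pmax(1L, pmin(length(u) - 1L,
                          findInterval(qs, u)))]
    qs[2L] <- max(qs[2L], min(u[u > qs[1L]]))
    tert <- 1L + (scores > qs[1L]) + (scores > qs[2L])
  }
  factor(tert, levels = 1:3)
}

#' Regression of log citation counts on scores
#'
#' Citation counts are natural-log transformed (with `offset` added to
#' accommodate zero counts) and regressed on the score; the standardized
#' slope (both variables scaled to unit variance) is reported with its
#' p-value.
#'
#' @param scores Numeric vector.
#' @param citations Non-negative integer counts, same length.
#' @param offset Added inside the log, default 1.
#' @return A list of class `rqit_citation_fit`: `std_coefficient`, `se`,
#'   `p_value`, `n` and the underlying `lm` fit.
#' @export
citation_regression <- function(scores, citations, offset = 1) {
  scores <- as.numeric(scores)
  if (length(scores) != length(citations))
    stop_rqit("scores and citations lengths differ",
              class = "rqit_validation_error")
  if (any(citations < 0))
    stop_rqit("citations must be non-negative", class = "rqit_validation_error")
  if (stats::sd(scores) == 0)
    stop_rqit("scores are constant; slope undefined",
              class = "rqit_validation_error")
  y <- log(as.numeric(citations) + offset)
  fit <- stats::lm(scale(y) ~ scale(scores))
  sm <- summary(fit)$coefficients
  structure(list(std_coefficient = unname(sm[2L, 1L]), se = unname(sm[2L, 2L]),
                 p_value = unname(sm[2L, 4L]), n = length(scores), fit = fit),
            class = "rqit_citation_fit")
}

#' @export
print.rqit_citation_fit <- function(x, ...) {
  cat(sprintf("standardized coefficient %.3f (SE %.3f, p = %.3g, n = %d)\n",
              x$std_coefficient, x$se, x$p_value, x$n))
  invisible(x)
}
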