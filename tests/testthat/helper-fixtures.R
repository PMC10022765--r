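# shared fixtures and independent oracles

tiny_instrument <- function() {
  rqit_instrument(list(
    list(code = "A", label = "first", levels = c("a1", "a2", "a3")),
    list(code = "B", label = "second", levels = c("b1", "b2", "b3"))
  ), name = "tiny")
}

# a small calibrated table on the tiny instrument (independent errors)
tiny_table <- function() {
  u <- c(A1 = 0, A2 = 100, A3 = 600, B1 = 0, B2 = 250, B3 = 400)
  s <- c(A1 = 3, A2 = 4, A3 = 5, B1 = 2, B2 = 3, B3 = 4)
  utility_table(tiny_instrument(), u, s)
}

# brute-force pairwise-agreement oracle for Gwet's AC2: observed agreement
# by enumerating all ordered rater pairs per subject, chance agreement from
# average category propensities
ac2_oracle <- function(m, w) {
  k <- ncol(w)
  keep <- rowSums(!is.na(m)) >= 2L
  m <- m[keep, , drop = FALSE]
  pa_i <- apply(m, 1L, function(row) {
    row <- row[!is.na(row)]
    tot <- 0
    for (g in seq_along(row)) for (h in seq_along(row))
      if (g != h) tot <- tot + w[row[g], row[h]]
    tot / (length(row) * (length(row) - 1L))
  })
  pik <- t(apply(m, 1L, function(row) {
    row <- row[!is.na(row)]
    tabulate(row, k) / length(row)
  }))
  pk <- colMeans(pik)
  pe <- sum(w) / (k * (k - 1)) * sum(pk * (1 - pk))
  (mean(pa_i) - pe) / (1 - pe)
}

# ICC oracle: mean squares from stats::aov on the long layout
icc_oracle <- function(m, unit = "single") {
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(nrow(m)), ncol(m))),
                   rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  sm <- summary(stats::aov(y ~ subj + rater, data = df))[[1L]]
  msr <- sm["subj", "Mean Sq"]; msc <- sm["rater", "Mean Sq"]
  mse <- sm["Residuals", "Mean Sq"]
  n <- nrow(m); k <- ncol(m)
  if (unit == "single")
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  else
    (msr - mse) / (msr + (msc - mse) / n)
}

# direct chi-square summation oracle
chisq_oracle <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# per-term evaluation of the Thurstone negative log-likelihood
nll_oracle <- function(u, s, comparisons) {
  tot <- 0
  for (i in seq_len(nrow(comparisons))) {
    uw <- sum(u[strsplit(comparisons$winner_option[i], "+", fixed = TRUE)[[1]]])
    ul <- sum(u[strsplit(comparisons$loser_option[i], "+", fixed = TRUE)[[1]]])
    si <- if (length(s) == 1L) s else s[[as.character(comparisons$respondent_id[i])]]
    tot <- tot - log(pnorm((uw - ul) / (si * sqrt(2))))
  }
  tot
}

# hand-built comparisons data.frame (bypassing a design)
make_comparisons <- function(winner_option, loser_option,
                             respondent_id = "R1", task_id = "T1") {
  structure(data.frame(respondent_id = respondent_id, task_id = task_id,
                       winner = 1L, loser = 2L,
                       winner_option = winner_option,
                       loser_option = loser_option),
            class = c("rqit_comparisons", "data.frame"))
}

# exhaustive enumeration oracle for the anti-chain rule: all 3-subsets of
# the full option grid of a dimension pair that can be ordered strictly
# increasing in one dimension and strictly decreasing in the other
antichain_count_oracle <- function(la, lb) {
  grid <- expand.grid(a = seq_len(la), b = seq_len(lb))
  idx <- utils::combn(nrow(grid), 3L)
  ok <- 0L
  for (j in seq_len(ncol(idx))) {
    g <- grid[idx[, j], ]
    g <- g[order(g$a), ]
    if (!anyDuplicated(g$a) && all(diff(g$b) < 0)) ok <- ok + 1L
  }
  ok
}
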