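test_that("best-worst answers expand to the implied paired comparisons", {
  d <- generate_tasks(tiny_instrument())
  r <- data.frame(respondent_id = "R1", task_id = d$task_id[1],
                  best_option = 1L, worst_option = 3L)
  cmp <- expand_comparisons(r, d)
  expect_identical(nrow(cmp), 3L)
  expect_setequal(paste(cmp$winner, cmp$loser), c("1 2", "1 3", "2 3"))

  # empty input
  empty <- expand_comparisons(r[0, ], d)
  expect_identical(nrow(empty), 0L)

  # single-ended answers give two comparisons each
  r_best <- data.frame(respondent_id = "R1", task_id = d$task_id[1],
                       best_option = 2L, worst_option = NA_integer_)
  cb <- expand_comparisons(r_best, d)
  expect_setequal(paste(cb$winner, cb$loser), c("2 1", "2 3"))
  r_worst <- data.frame(respondent_id = "R1", task_id = d$task_id[1],
                        best_option = NA_integer_, worst_option = 2L)
  cw <- expand_comparisons(r_worst, d)
  expect_setequal(paste(cw$winner, cw$loser), c("1 2", "3 2"))

  expect_error(expand_comparisons(
    data.frame(respondent_id = "R1", task_id = "nope",
               best_option = 1L, worst_option = 2L), d), "unknown task_id")
  expect_warning(expand_comparisons(
    data.frame(respondent_id = "R1", task_id = d$task_id[1],
               best_option = 2L, worst_option = 2L), d), "best = worst")
})

test_that("expansion count is 3 per complete and 2 per partial answer", {
  tab <- anzmusc_rqit()
  d <- generate_tasks(tab)
  for (seed in 1:3) {
    r <- simulate_bws_responses(d, tab$utilities / 250, n_respondents = 7,
                                single_rate = 0.1, seed = seed)
    n_both <- sum(!is.na(r$best_option) & !is.na(r$worst_option))
    n_single <- nrow(r) - n_both
    expect_identical(nrow(expand_comparisons(r, d)),
                     3L * n_both + 2L * n_single)
  }
})

test_that("negative log-likelihood matches per-term evaluation", {
  tab <- anzmusc_rqit()
  d <- generate_tasks(tab)
  r <- simulate_bws_responses(d, tab$utilities / 250, 3, seed = 4)
  cmp <- expand_comparisons(r, d)
  u <- setNames(rnorm(18, 0, 0.5), instrument_elements(tab))
  expect_equal(bws_neg_loglik(u, 1.3, cmp), nll_oracle(u, 1.3, cmp))
  # respondent-specific dispersions
  s_r <- setNames(c(0.8, 1, 1.7), unique(cmp$respondent_id))
  expect_equal(bws_neg_loglik(u, s_r, cmp), nll_oracle(u, s_r, cmp))
  # a tied comparison contributes -log(1/2)
  tie <- make_comparisons("A1+B2", "A2+B1")
  u0 <- setNames(rep(1, 18), instrument_elements(tab))
  expect_equal(bws_neg_loglik(u0, 1, tie), -log(0.5))
  expect_error(bws_neg_loglik(u0, -1, tie), "positive")
})

test_that("likelihood is invariant to within-dimension location shifts", {
  tab <- anzmusc_rqit()
  d <- generate_tasks(tab)
  r <- simulate_bws_responses(d, tab$utilities / 250, 5, seed = 9)
  cmp <- expand_comparisons(r, d)
  u <- setNames(rnorm(18, 0, 0.5), instrument_elements(tab))
  base <- bws_neg_loglik(u, 1, cmp)
  for (dim_code in c("A", "B", "E")) {
    u2 <- u
    idx <- substr(names(u2), 1, 1) == dim_code
    u2[idx] <- u2[idx] + 3.7
    expect_equal(bws_neg_loglik(u2, 1, cmp), base, tolerance = 1e-9)
  }
})

test_that("evenly split comparisons give a zero utility difference", {
  ins <- rqit_instrument(list(list(code = "A", levels = c("l", "h")),
                              list(code = "B", levels = c("l", "h"))))
  cmp <- rbind(make_comparisons(rep("A2+B1", 10), rep("A1+B2", 10)),
               make_comparisons(rep("A1+B2", 10), rep("A2+B1", 10)))
  class(cmp) <- c("rqit_comparisons", "data.frame")
  fit <- fit_bws(cmp, ins, model = "2b", seed = 1)
  diff <- (fit$utilities[["A2"]] + fit$utilities[["B1"]]) -
    (fit$utilities[["A1"]] + fit$utilities[["B2"]])
  expect_equal(diff, 0, tolerance = 1e-6)
})

test_that("model 2b recovers simulated utilities and honours its constraint", {
  tab <- anzmusc_rqit()
  d <- generate_tasks(tab)
  truth <- tab$utilities / 250
  r <- simulate_bws_responses(d, truth, n_respondents = 60, dispersion = 1,
                              seed = 21)
  cmp <- expand_comparisons(r, d)
  fit <- fit_bws(cmp, tab, model = "2b", seed = 1)
  expect_lt(fit$convergence$gradient_norm, 1e-6)
  # sum-to-zero within each dimension
  for (grp in split(fit$utilities, substr(names(fit$utilities), 1, 1)))
    expect_equal(sum(grp), 0, tolerance = 1e-8)
  # compare truth on the same (per-dimension centered) scale as the fit
  truth_c <- truth
  for (g in c("A", "B", "C", "D", "E")) {
    i <- substr(names(truth_c), 1, 1) == g
    truth_c[i] <- truth_c[i] - mean(truth_c[i])
  }
  expect_gt(cor(truth_c, fit$utilities), 0.95)
  # covariance symmetric positive semi-definite
  expect_equal(fit$vcov, t(fit$vcov), tolerance = 1e-8)
  expect_gte(min(eigen(fit$vcov, symmetric = TRUE)$values), -1e-8)
})

test_that("fitted preference probabilities are transitive", {
  tab <- anzmusc_rqit()
  d <- generate_tasks(tab)
  r <- simulate_bws_responses(d, tab$utilities / 250, 20, seed = 13)
  fit <- fit_bws(expand_comparisons(r, d), tab, seed = 1)
  opts <- c("A1+B3", "A2+B2", "A3+B1")
  p12 <- predict_preference(fit, opts[1], opts[2])
  p23 <- predict_preference(fit, opts[2], opts[3])
  p13 <- predict_preference(fit, opts[1], opts[3])
  if (p12 > 0.5 && p23 > 0.5) expect_gt(p13, 0.5)
  if (p12 < 0.5 && p23 < 0.5) expect_lt(p13, 0.5)
})

test_that("separation engages the ridge penalty with a warning", {
  ins <- rqit_instrument(list(list(code = "A", levels = c("l", "h")),
                              list(code = "B", levels = c("l", "h"))))
  cmp <- make_comparisons(rep("A2+B1", 15), rep("A1+B2", 15))
  class(cmp) <- c("rqit_comparisons", "data.frame")
  expect_warning(fit <- fit_bws(cmp, ins, seed = 1), "separation")
  expect_true(fit$convergence$ridge)
  expect_true(all(is.finite(fit$utilities)))
})

test_that("rescaling anchors the scale at 0 and 1000", {
  # forced two-step transform: per-dimension {-1, 0, 1} -> {0, 250, 500}
  ins <- rqit_instrument(list(list(code = "A", levels = c("l", "m", "h")),
                              list(code = "B", levels = c("l", "m", "h"))))
  fit <- structure(list(
    utilities = setNames(rep(c(-1, 0, 1), 2), instrument_elements(ins)),
    se = setNames(rep(0.1, 6), instrument_elements(ins)),
    correlations = diag(6), dispersions = 1, model = "2b",
    instrument = ins), class = "rqit_fit")
  dimnames(fit$correlations) <- list(names(fit$utilities), names(fit$utilities))
  tab <- rescale_fit(fit)
  expect_equal(unname(tab$utilities), rep(c(0, 250, 500), 2))
  expect_equal(unname(tab$se), rep(25, 6))  # scaled by k = 250
  expect_identical(score_profile(c("A3", "B3"), tab)$value, 1000)
  expect_identical(score_profile(c("A1", "B1"), tab)$value, 0)

  # a real fit rescales to exactly 1000 at the maximal profile
  big <- anzmusc_rqit()
  d <- generate_tasks(big)
  r <- simulate_bws_responses(d, big$utilities / 250, 25, seed = 3)
  f <- fit_bws(expand_comparisons(r, d), big, seed = 2)
  rt <- rescale_fit(f)
  top <- vapply(rt$instrument$dimensions,
                function(dd) dd$levels$code[nrow(dd$levels)], character(1))
  expect_equal(score_profile(top, rt)$value, 1000)
  bottom <- vapply(rt$instrument$dimensions,
                   function(dd) dd$levels$code[1], character(1))
  expect_equal(score_profile(bottom, rt)$value, 0)
})

test_that("model 1 and model 2a agree closely on common-dispersion data", {
  tab <- anzmusc_rqit()
  d <- generate_tasks(tab)
  truth <- tab$utilities / 250
  r <- simulate_bws_responses(d, truth, n_respondents = 40, dispersion = 1,
                              seed = 31)
  cmp <- expand_comparisons(r, d)
  f2a <- fit_bws(cmp, tab, model = "2a", seed = 1)
  f1 <- fit_bws(cmp, tab, model = "1", seed = 1)
  # compare on the sum-to-zero scale to remove the identification offset
  center <- function(u) {
    for (grp in unique(substr(names(u), 1, 1))) {
      i <- substr(names(u), 1, 1) == grp
      u[i] <- u[i] - mean(u[i])
    }
    u
  }
  diffs <- abs(center(f1$utilities) - center(f2a$utilities))
  rng <- diff(range(f2a$utilities))
  expect_lt(median(diffs), 0.05 * rng)
  # scale normalization: respondent SEMs have geometric mean 1
  expect_equal(mean(log(f1$dispersions)), 0, tolerance = 1e-8)
})
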