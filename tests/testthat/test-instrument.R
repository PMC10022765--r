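test_that("packaged ANZMUSC-RQIT has the published structure", {
  tab <- anzmusc_rqit()
  expect_s3_class(tab, "rqit_utility_table")
  expect_equal(unname(instrument_level_counts(tab)), c(4, 3, 4, 3, 4))
  expect_length(instrument_elements(tab), 18)
  expect_identical(dim(tab$correlations), c(18L, 18L))
})

test_that("instrument construction validates structure", {
  ins <- rqit_instrument(list(list(code = "A", label = "only",
                                   levels = c("lo", "hi"))))
  expect_length(instrument_elements(ins), 2)
  expect_error(
    rqit_instrument(list(list(code = "A", levels = "one"))),
    "at least 2")
  expect_error(
    rqit_instrument(list(list(code = "A", levels = c("x", "y")),
                         list(code = "A", levels = c("x", "y")))),
    "duplicate")
})

test_that("load_instrument round-trips a JSON definition", {
  path <- system.file("extdata", "rqit_original.json", package = "rqit")
  ins <- load_instrument(path)
  expect_equal(unname(instrument_level_counts(ins)), c(4, 3, 4, 4, 4, 4))
  expect_length(instrument_elements(ins), 23)
})

test_that("worked scoring examples reproduce the published values", {
  tab <- anzmusc_rqit()
  expect_identical(score_profile(c("A4", "B1", "C3", "D3", "E1"), tab)$value, 582)
  expect_identical(score_profile(c("A1", "B1", "C1", "D1", "E1"), tab)$value, 0)
  expect_identical(score_profile(c("A4", "B3", "C4", "D3", "E4"), tab)$value, 1000)
  # order of elements is irrelevant
  expect_identical(score_profile(c("E1", "D3", "C3", "B1", "A4"), tab)$value, 582)
  expect_error(score_profile(c("A4", "B1", "C3", "D3", "Z9"), tab),
               "unknown element")
  expect_error(score_profile(c("A4", "A1", "C3", "D3", "E1"), tab),
               "one element per dimension")
})

test_that("SE propagation handles uncorrelated and degenerate cases", {
  ins <- rqit_instrument(list(
    list(code = "A", levels = c("l", "m", "h")),
    list(code = "B", levels = c("l", "h")),
    list(code = "C", levels = c("l", "h")),
    list(code = "D", levels = c("l", "h")),
    list(code = "E", levels = c("l", "h"))))
  u <- setNames(c(0, 1, 2, 0, 2, 0, 2, 0, 2, 0, 2),
                instrument_elements(ins))
  u <- u / sum(u[c("A3", "B2", "C2", "D2", "E2")]) * 1000
  s <- setNames(c(3, 1, 3, 4, 1, 0, 0, 0, 0, 0, 0), names(u))
  tab <- utility_table(ins, u, s)
  # independent errors: sqrt(3^2 + 4^2) = 5
  expect_equal(propagate_profile_se(c("A1", "B1", "C1", "D1", "E1"), tab), 5)
  # single-dimension instrument: SE is the element's own sigma
  ins1 <- rqit_instrument(list(list(code = "A", levels = c("l", "h"))))
  tab1 <- utility_table(ins1, c(A1 = 0, A2 = 1000), c(A1 = 7, A2 = 7))
  expect_equal(propagate_profile_se("A1", tab1), 7)
})

test_that("worked-example SE matches the rounded-table recomputation", {
  tab <- anzmusc_rqit()
  p <- c("A4", "B1", "C3", "D3", "E1")
  se <- propagate_profile_se(p, tab)
  expect_equal(se, 12.44058, tolerance = 1e-5)
  # invariant to element ordering
  expect_equal(propagate_profile_se(rev(p), tab), se)
})

test_that("SE propagation matches a Monte-Carlo multivariate-normal oracle", {
  skip_if_not_installed("MASS")
  tab <- anzmusc_rqit()
  profiles <- all_profiles(tab)
  set.seed(42)
  n_mc <- 1e5
  for (i in sample(nrow(profiles), 20)) {
    p <- profiles[i, ]
    sig <- tab$se[p]
    cov <- tab$correlations[p, p] * outer(sig, sig)
    draws <- MASS::mvrnorm(n_mc, mu = tab$utilities[p], Sigma = cov)
    mc_sd <- sd(rowSums(draws))
    mc_se <- mc_sd / sqrt(2 * (n_mc - 1))
    expect_lt(abs(propagate_profile_se(p, tab) - mc_sd), 3 * mc_se)
  }
})

test_that("scores are additive across single-dimension changes", {
  tab <- anzmusc_rqit()
  base <- c("A2", "B2", "C2", "D2", "E2")
  for (swap in list(c("A2", "A4"), c("C2", "C1"), c("E2", "E3"))) {
    alt <- replace(base, base == swap[1], swap[2])
    expect_equal(
      score_profile(alt, tab)$value - score_profile(base, tab)$value,
      unname(tab$utilities[swap[2]] - tab$utilities[swap[1]]))
  }
})

test_that("every profile scores within bounds; bounds attained once each", {
  tab <- anzmusc_rqit()
  profiles <- all_profiles(tab)
  expect_identical(nrow(profiles), 576L)
  vals <- apply(profiles, 1, function(p) sum(tab$utilities[p]))
  expect_true(all(vals >= 0 & vals <= 1000))
  expect_identical(sum(vals == 0), 1L)
  expect_identical(sum(vals == 1000), 1L)
})

test_that("utility table constructor enforces the scale anchors", {
  ins <- tiny_instrument()
  u <- c(A1 = 0, A2 = 1, A3 = 600, B1 = 0, B2 = 1, B3 = 400)
  s <- rep(1, 6); names(s) <- names(u)
  expect_silent(utility_table(ins, u, s))
  u_bad <- u; u_bad["A1"] <- 5
  expect_error(utility_table(ins, u_bad, s), "utility 0")
  u_bad2 <- u; u_bad2["A3"] <- 601
  expect_error(utility_table(ins, u_bad2, s), "sum to the upper")
})
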