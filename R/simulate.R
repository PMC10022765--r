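#' Simulate Thurstonian best-worst responses
#'
#' Generative counterpart of the fitting model: for every respondent-task,
#' each option's perceived utility is its true utility (sum of its two
#' element utilities) plus normal noise with the respondent's SEM; the
#' option with the highest perceived utility is marked best and the lowest
#' worst. Optionally a subset of answers is single-ended (best-only or
#' worst-only, chosen at random), mimicking partial survey answers.
#'
#' @param design An `rqit_design`; every respondent answers every task (to
#'   emulate blocked administration, call once per block with the block's
#'   subset of the design).
#' @param utilities Named numeric vector of true element utilities (latent
#'   scale) covering the design's elements.
#' @param n_respondents Number of respondents; each answers every task of
#'   their design/block.
#' @param dispersion Common SEM (scalar), or `"lognormal"` to draw
#'   per-respondent SEMs log-normally (meanlog `0`, sdlog
#'   `dispersion_sdlog`), the heterogeneity the full model estimates.
#' @param dispersion_sdlog Log-scale SD of respondent SEMs, default 0.4.
#' @param single_rate Probability that an answer is single-ended.
#' @param n_single Exact number of single-ended answers (overrides
#'   `single_rate`).
#' @param seed Integer seed; outputs are fully reproducible from it.
#' @return A data.frame of responses (`respondent_id`, `task_id`,
#'   `best_option`, `worst_option`) with the drawn respondent SEMs in
#'   attribute `"dispersions"`.
#' @examples
#' tab <- anzmusc_rqit()
#' des <- generate_tasks(tab)
#' r <- simulate_bws_responses(des, tab$utilities, n_respondents = 5, seed = 1)
#' head(r)
#' @export
simulate_bws_responses <- function(design, utilities, n_respondents,
                                   dispersion = 1, dispersion_sdlog = 0.4,
                                   single_rate = 0, n_single = NULL,
                                   seed = NULL) {
  if (inherits(design, "rqit_blocks"))
    stop_rqit("pass an rqit_design (a block's subset of tasks), not the block list",
              class = "rqit_validation_error")
  with_seed(seed, {
    # per-respondent SEMs
    s_r <- if (identical(dispersion, "lognormal"))
      stats::rlnorm(n_respondents, 0, dispersion_sdlog)
    else rep(as.numeric(dispersion), n_respondents)
    rows <- vector("list", n_respondents)
    opts <- design_options(design)
    # option utilities per task (n_tasks x 3)
    optu <- apply(opts, c(1, 2), function(o)
      sum(utilities[split_option(o)[[1L]]]))
    n_tasks <- nrow(opts)
    for (r in seq_len(n_respondents)) {
      eps <- matrix(stats::rnorm(n_tasks * 3L, 0, s_r[r]), n_tasks, 3L)
      perc <- optu + eps
      best <- max.col(perc)
      worst <- max.col(-perc)
      rows[[r]] <- data.frame(respondent_id = sprintf("R%03d", r),
                              task_id = design$task_id,
                              best_option = best, worst_option = worst)
    }
    out <- do.call(rbind, rows)
    # single-ended answers: blank one end at random
    ns <- n_single %||% stats::rbinom(1L, nrow(out), single_rate)
    if (ns > 0L) {
      pick <- sample(nrow(out), ns)
      drop_best <- stats::runif(ns) < 0.5
      out$best_option[pick[drop_best]] <- NA_integer_
      out$worst_option[pick[!drop_best]] <- NA_integer_
    }
    rownames(out) <- NULL
    attr(out, "dispersions") <- stats::setNames(s_r, sprintf("R%03d",
                                                             seq_len(n_respondents)))
    out
  })
}

#' Simulate a ratings matrix with controlled agreement
#'
#' Latent-variable generator: subject effects `b_i ~ N(0, subject_sd^2)`
#' plus rater noise `e_ij ~ N(0, noise_sd^2)` are discretized into K
#' ordinal categories at equal-probability cutpoints of the latent marginal
#' distribution. The latent intraclass correlation
#' `subject_sd^2 / (subject_sd^2 + noise_sd^2)` is recorded in attribute
#' `"true_icc"`; larger subject-to-noise variance ratios yield higher
#' observed agreement.
#'
#' @param n_subjects,n_raters Matrix dimensions.
#' @param k Number of ordinal categories.
#' @param subject_sd,noise_sd Latent SDs (both > 0).
#' @param missing_rate Probability an individual rating is missing.
#' @param seed Integer seed.
#' @return A subjects x raters matrix (see [as_ratings()]) with attributes
#'   `"true_icc"` and `"k"`.
#' @export
simulate_ratings <- function(n_subjects, n_raters, k = 4,
                             subject_sd = 1, noise_sd = 1,
                             missing_rate = 0, seed = NULL) {
  if (subject_sd <= 0 || noise_sd <= 0)
    stop_rqit("latent SDs must be positive", class = "rqit_validation_error")
  if (k < 2L) stop_rqit("need k >= 2 categories", class = "rqit_validation_error")
  with_seed(seed, {
    b <- stats::rnorm(n_subjects, 0, subject_sd)
    lat <- outer(b, rep(0, n_raters), `+`) +
      matrix(stats::rnorm(n_subjects * n_raters, 0, noise_sd),
             n_subjects, n_raters)
    cuts <- stats::qnorm(seq_len(k - 1L) / k, 0,
                         sqrt(subject_sd^2 + noise_sd^2))
    m <- matrix(findInterval(lat, cuts) + 1, n_subjects, n_raters,
                dimnames = list(sprintf("S%02d", seq_len(n_subjects)),
                                sprintf("R%02d", seq_len(n_raters))))
    if (missing_rate > 0)
      m[stats::runif(length(m)) < missing_rate] <- NA
    storage.mode(m) <- "double"
    attr(m, "true_icc") <- subject_sd^2 / (subject_sd^2 + noise_sd^2)
    attr(m, "k") <- as.integer(k)
    m
  })
}

#' Simulate article records with controlled score-outcome associations
#'
#' Draws article profiles level-by-level (uniformly over each dimension),
#' scores them with a utility table, then generates (a) a binary journal
#' impact-factor group by a logistic link on the score's tertile
#' indicators, so `tertile3_log_odds` is exactly the log odds ratio of the
#' third versus first tertile, and (b) citation counts log-normally with a
#' chosen standardized score effect. In stratified mode, exactly
#' `n/2` articles per journal group are kept (emulating a balanced
#' journal-based sampling frame).
#'
#' @param n Number of articles (>= 30).
#' @param table Utility table for scoring, default [anzmusc_rqit()].
#' @param tertile3_log_odds True log odds ratio (tertile 3 vs 1) of being
#'   in the high-impact group; the tertile-2 effect is half of it.
#' @param citation_effect True standardized coefficient of the score in
#'   the log-citation regression (|value| < 1).
#' @param citation_meanlog,citation_sdlog Location/scale of log citations.
#' @param stratified If `TRUE`, balance group sizes exactly at `n/2` each.
#' @param seed Integer seed.
#' @return A data.frame with `article_id`, one column per dimension code,
#'   `score`, `journal_group` (`"low"`/`"high"`), `citations`; true
#'   parameters are stored in attribute `"truth"`.
#' @export
simulate_articles <- function(n, table = anzmusc_rqit(),
                              tertile3_log_odds = 0, citation_effect = 0,
                              citation_meanlog = 2.5, citation_sdlog = 1,
                              stratified = FALSE, seed = NULL) {
  if (n < 30L) stop_rqit("need n >= 30 articles", class = "rqit_validation_error")
  stopifnot(inherits(table, "rqit_utility_table"))
  ins <- table$instrument
  with_seed(seed, {
    n_draw <- if (stratified) 6L * n else n
    prof <- vapply(ins$dimensions, function(d)
      sample(d$levels$code, n_draw, replace = TRUE), character(n_draw))
    colnames(prof) <- vapply(ins$dimensions, `[[`, character(1), "code")
    score <- rowSums(matrix(table$utilities[prof], nrow = n_draw))
    tert <- cut_tertiles(score)
    eta <- -0.5 * tertile3_log_odds +
      ifelse(tert == 2, 0.5 * tertile3_log_odds, 0) +
      ifelse(tert == 3, tertile3_log_odds, 0)
    high <- stats::runif(n_draw) < stats::plogis(eta)
    if (stratified) {
      keep <- c(utils::head(which(high), n / 2),
                utils::head(which(!high), n / 2))
      if (length(keep) < n)
        stop_rqit("stratified draw failed to fill both groups",
                  class = "rqit_sizing_error")
      keep <- sort(keep)
      prof <- prof[keep, , drop = FALSE]; score <- score[keep]
      high <- high[keep]; n_draw <- n
    }
    z <- (score - mean(score)) / stats::sd(score)
    noise_sd <- if (abs(citation_effect) >= 1)
      stop_rqit("citation_effect must be in (-1, 1)",
                class = "rqit_validation_error")
    else sqrt(1 - citation_effect^2)
    loglat <- citation_meanlog +
      citation_sdlog * (citation_effect * z + stats::rnorm(n_draw, 0, noise_sd))
    out <- data.frame(article_id = sprintf("P%04d", seq_len(n_draw)),
                      prof, score = score,
                      journal_group = ifelse(high, "high", "low"),
                      citations = as.integer(round(exp(loglat))))
    attr(out, "truth") <- list(tertile3_log_odds = tertile3_log_odds,
                               citation_effect = citation_effect)
    out
  })
}
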