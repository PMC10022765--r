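#' Ratings matrices
#'
#' Agreement statistics operate on a subjects x raters matrix of ordinal
#' category indices (1-based); `NA` marks a missing rating. `as_ratings()`
#' accepts such a matrix, or a long data.frame with columns `subject_id`,
#' `rater_id`, `category`.
#'
#' @param x Matrix or long data.frame.
#' @param k Number of categories; defaults to the maximum observed.
#' @return A numeric matrix with attribute `k`.
#' @export
as_ratings <- function(x, k = NULL) {
  if (is.data.frame(x) && all(c("subject_id", "rater_id", "category") %in% names(x))) {
    subj <- factor(x$subject_id, levels = unique(x$subject_id))
    rat <- factor(x$rater_id, levels = unique(x$rater_id))
    m <- matrix(NA_real_, nlevels(subj), nlevels(rat),
                dimnames = list(levels(subj), levels(rat)))
    m[cbind(as.integer(subj), as.integer(rat))] <- x$category
    x <- m
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  vals <- x[!is.na(x)]
  if (length(vals) == 0L)
    stop_rqit("ratings matrix is empty", class = "rqit_validation_error")
  if (any(vals < 1) || any(vals != round(vals)))
    stop_rqit("ratings must be positive integer category indices",
              class = "rqit_validation_error")
  attr(x, "k") <- as.integer(k %||% max(vals))
  x
}

agreement_estimate <- function(statistic, estimate, lower = NA_real_,
                               upper = NA_real_, n_subjects, n_raters,
                               details = list()) {
  structure(list(statistic = statistic, estimate = estimate,
                 conf_low = lower, conf_high = upper,
                 n_subjects = n_subjects, n_raters = n_raters,
                 details = details),
            class = "rqit_agreement")
}

#' @export
print.rqit_agreement <- function(x, ...) {
  ci <- if (is.na(x$conf_low)) "" else
    sprintf(" (95%% CI %.2f to %.2f)", x$conf_low, x$conf_high)
  cat(sprintf("%s = %.3f%s  [%d subjects, %d raters]\n",
              x$statistic, x$estimate, ci, x$n_subjects, x$n_raters))
  invisible(x)
}

# two-way ANOVA mean squares for a complete subjects x raters matrix
two_way_ms <- function(m) {
  n <- nrow(m); k <- ncol(m)
  mu <- mean(m)
  rm_ <- rowMeans(m); cm <- colMeans(m)
  ssr <- k * sum((rm_ - mu)^2)
  ssc <- n * sum((cm - mu)^2)
  sse <- sum((m - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + mu)^2)
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Two-way random-effects intraclass correlation (absolute agreement)
#'
#' ICC from the two-way random-effects model with absolute agreement:
#' subjects and raters are both random samples, and rater main effects
#' count as disagreement. `unit = "single"` gives ICC(2,1), the reliability
#' of one rater; `unit = "average"` gives ICC(2,k), the reliability of the
#' mean over the k observed raters. Confidence intervals use the F-based
#' method; the average-measures interval applies the Spearman-Brown step-up
#' to the single-measures bounds. Raters with any missing rating are
#' dropped (listwise deletion).
#'
#' @param ratings See [as_ratings()].
#' @param unit `"single"` or `"average"`.
#' @param conf_level Confidence level, default 0.95.
#' @return An `rqit_agreement` with the mean squares in `$details`.
#' @export
icc_two_way <- function(ratings, unit = c("single", "average"),
                        conf_level = 0.95) {
  unit <- match.arg(unit)
  m <- as_ratings(ratings)
  m <- m[, colSums(is.na(m)) == 0L, drop = FALSE]
  if (ncol(m) < 2L || nrow(m) < 2L)
    stop_rqit("need >= 2 subjects and >= 2 complete-data raters",
              class = "rqit_validation_error")
  ms <- two_way_ms(m)
  n <- ms$n; k <- ms$k
  denom1 <- ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n
  if (ms$msr <= ms$mse) {
    warning("between-subject variance not above error; ICC reported as 0")
    est1 <- 0
  } else est1 <- (ms$msr - ms$mse) / denom1

  # F-based interval for ICC(A,1) (McGraw & Wong)
  alpha <- 1 - conf_level
  icc_a <- max(est1, 0)
  a <- k * icc_a / (n * (1 - icc_a))
  b <- 1 + k * icc_a * (n - 1) / (n * (1 - icc_a))
  v <- (a * ms$msc + b * ms$mse)^2 /
    ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lo1 <- n * (ms$msr - fl * ms$mse) /
    (fl * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
  hi1 <- n * (fu * ms$msr - ms$mse) /
    (k * ms$msc + (k * n - k - n) * ms$mse + n * fu * ms$msr)

  sb <- function(r) k * r / (1 + (k - 1) * r)
  if (unit == "single") {
    agreement_estimate("ICC(2,1)", est1, lo1, hi1, n, k, details = ms)
  } else {
    est_k <- if (est1 == 0) 0 else
      (ms$msr - ms$mse) / (ms$msr + (ms$msc - ms$mse) / n)
    agreement_estimate("ICC(2,k)", est_k, sb(lo1), sb(hi1), n, k, details = ms)
  }
}

# quadratic ordinal agreement weights w[i,j] = 1 - (i-j)^2/(k-1)^2;
# identity weights reduce AC2 to AC1
agreement_weights <- function(k, weights = c("quadratic", "nominal")) {
  weights <- match.arg(weights)
  if (weights == "nominal") return(diag(k))
  outer(seq_len(k), seq_len(k), function(i, j) 1 - (i - j)^2 / (k - 1)^2)
}

#' Gwet's AC2 chance-corrected agreement
#'
#' Weighted multi-rater agreement coefficient with Gwet's chance-agreement
#' term, which stays stable when category prevalences are skewed (the
#' "kappa paradox" situations). With nominal (identity) weights the
#' statistic is Gwet's AC1. Default weights are quadratic ordinal weights
#' `1 - (i-j)^2/(K-1)^2`. Missing ratings are allowed; subjects rated by
#' fewer than two raters are excluded (with a message of the count). The
#' variance is the subject-level jackknife.
#'
#' @inheritParams icc_two_way
#' @param weights `"quadratic"` (default) or `"nominal"`.
#' @return An `rqit_agreement`.
#' @export
gwet_ac2 <- function(ratings, weights = c("quadratic", "nominal"),
                     conf_level = 0.95) {
  weights <- match.arg(weights)
  m <- as_ratings(ratings)
  k <- attr(m, "k")
  w <- agreement_weights(k, weights)
  rated <- rowSums(!is.na(m))
  if (any(rated < 2L)) {
    message(sum(rated < 2L), " subject(s) rated by < 2 raters excluded")
    m <- m[rated >= 2L, , drop = FALSE]
  }
  if (nrow(m) == 0L)
    stop_rqit("no subject has >= 2 ratings", class = "rqit_validation_error")

  ac2_of <- function(mm) {
    # r_ik: raters per subject per category
    rik <- t(apply(mm, 1L, function(row) tabulate(row[!is.na(row)], nbins = k)))
    ri <- rowSums(rik)
    rik_star <- rik %*% w
    pa_i <- rowSums(rik * (rik_star - 1)) / (ri * (ri - 1))
    pik <- rik / ri
    pk <- colMeans(pik)
    tw <- sum(w)
    pe <- tw * sum(pk * (1 - pk)) / (k * (k - 1))
    (mean(pa_i) - pe) / (1 - pe)
  }
  est <- ac2_of(m)
  n <- nrow(m)
  lo <- hi <- NA_real_
  if (n > 2L) {
    jack <- vapply(seq_len(n), function(i) ac2_of(m[-i, , drop = FALSE]),
                   numeric(1))
    se <- sqrt((n - 1) / n * sum((jack - mean(jack))^2))
    zq <- stats::qnorm(1 - (1 - conf_level) / 2)
    lo <- est - zq * se; hi <- min(est + zq * se, 1)
  }
  name <- if (weights == "nominal") "Gwet's AC1" else "Gwet's AC2"
  agreement_estimate(name, est, lo, hi, n, ncol(m),
                     details = list(weights = weights, k = k))
}

#' Modal percent agreement
#'
#' For each subject, the percentage of its raters that chose the modal
#' (most frequent) category; ties use the tied maximum count. Returns the
#' mean over subjects (0--100).
#'
#' @inheritParams icc_two_way
#' @return Numeric percentage.
#' @export
modal_agreement <- function(ratings) {
  m <- as_ratings(ratings)
  per_subject <- apply(m, 1L, function(row) {
    row <- row[!is.na(row)]
    if (length(row) == 0L) return(NA_real_)
    100 * max(tabulate(row)) / length(row)
  })
  mean(per_subject, na.rm = TRUE)
}

#' Committee-resampled intraclass correlation
#'
#' Instruments meant to be scored by committee consensus are better judged
#' by the reliability of committee averages than of individuals. Raters
#' with complete data are randomly partitioned (seeded) into committees of
#' the given sizes; each committee's mean rating per subject forms a
#' subjects x committees matrix on which ICC(2,1) is computed. No
#' confidence interval is reported for the resampled statistic.
#'
#' @inheritParams icc_two_way
#' @param committee_sizes Integer vector; must sum to the number of
#'   complete-data raters (e.g. `c(5, 5, 5, 5, 6)` for 26 raters).
#' @param seed Integer seed for the partition.
#' @return An `rqit_agreement` (CI omitted), with the committee assignment
#'   in `$details`.
#' @export
committee_icc <- function(ratings, committee_sizes, seed = NULL) {
  m <- as_ratings(ratings)
  m <- m[, colSums(is.na(m)) == 0L, drop = FALSE]
  if (sum(committee_sizes) != ncol(m))
    stop_rqit("committee sizes sum to ", sum(committee_sizes),
              " but there are ", ncol(m), " complete-data raters",
              class = "rqit_sizing_error")
  assignment <- with_seed(seed, {
    idx <- sample(ncol(m))
    rep(seq_along(committee_sizes), committee_sizes)[order(idx)]
  })
  comm <- vapply(seq_along(committee_sizes), function(g)
    rowMeans(m[, assignment == g, drop = FALSE]), numeric(nrow(m)))
  ms <- two_way_ms(comm)
  denom <- ms$msr + (ms$k - 1) * ms$mse + ms$k * (ms$msc - ms$mse) / ms$n
  est <- if (ms$msr <= ms$mse) 0 else (ms$msr - ms$mse) / denom
  agreement_estimate("committee ICC(2,1)", est,
                     n_subjects = nrow(m), n_raters = ncol(m),
                     details = list(committees = assignment,
                                    sizes = committee_sizes))
}
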