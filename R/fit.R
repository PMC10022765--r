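#' Negative log-likelihood of the Thurstone paired-comparison model
#'
#' Each option's perceived utility is its true utility (the sum of its two
#' element utilities) plus normal perception error with standard deviation
#' \eqn{s} (the respondent's standard error of measurement, SEM). With
#' independent errors on the two options the probability that the winner is
#' preferred is \eqn{\Phi((U_w - U_l) / (s\sqrt{2}))}, and the negative
#' log-likelihood is minus the sum of the log probabilities over all
#' comparisons. A common dispersion (scalar `dispersions`) corresponds to
#' the simpler model; a per-respondent named vector to the full model.
#'
#' @param utilities Named numeric vector of element utilities (latent scale)
#'   covering every element appearing in `comparisons`.
#' @param dispersions Positive scalar SEM, or a named vector indexed by
#'   respondent id.
#' @param comparisons An `rqit_comparisons` data.frame from
#'   [expand_comparisons()].
#' @param error_correlation Correlation of the two options' perception
#'   errors; 0 (independent errors) by default. The difference variance is
#'   \eqn{2 s^2 (1 - r)}.
#' @return The negative log-likelihood (scalar, finite for finite inputs).
#' @export
bws_neg_loglik <- function(utilities, dispersions, comparisons,
                           error_correlation = 0) {
  if (any(dispersions <= 0))
    stop_rqit("dispersions must be positive", class = "rqit_domain_error")
  X <- comparison_incidence(comparisons, names(utilities))
  s <- dispersion_per_row(dispersions, comparisons)
  z <- drop(X %*% utilities) / (s * sqrt(2 * (1 - error_correlation)))
  -sum(stats::pnorm(z, log.p = TRUE))
}

dispersion_per_row <- function(dispersions, comparisons) {
  if (length(dispersions) == 1L && is.null(names(dispersions)))
    return(rep(as.numeric(dispersions), nrow(comparisons)))
  s <- dispersions[as.character(comparisons$respondent_id)]
  if (anyNA(s))
    stop_rqit("dispersions missing for some respondents",
              class = "rqit_domain_error")
  as.numeric(s)
}

# block-diagonal contrast matrix mapping free parameters to full element
# utilities; "sum" = sum-to-zero (model 2b), "corner" = first level 0
# (model 2a)
utility_contrast <- function(instrument, type = c("sum", "corner")) {
  type <- match.arg(type)
  blocks <- lapply(instrument$dimensions, function(d) {
    l <- nrow(d$levels)
    if (type == "sum") rbind(diag(l - 1L), -1) else rbind(0, diag(l - 1L))
  })
  p <- sum(vapply(blocks, ncol, integer(1)))
  C <- matrix(0, length(instrument_elements(instrument)), p)
  r <- 0L; c0 <- 0L
  for (b in blocks) {
    C[r + seq_len(nrow(b)), c0 + seq_len(ncol(b))] <- b
    r <- r + nrow(b); c0 <- c0 + ncol(b)
  }
  rownames(C) <- instrument_elements(instrument)
  C
}

#' Fit Thurstone's paired-comparison model to best-worst data
#'
#' Maximum-likelihood estimation of element utilities from implied paired
#' comparisons. Three model variants are available:
#' \describe{
#'   \item{`"2b"`}{common respondent dispersion, utilities identified by a
#'     within-dimension sum-to-zero constraint (the parameterization that
#'     makes standard errors directly available from the observed
#'     information);}
#'   \item{`"2a"`}{common dispersion, corner parameterization (lowest level
#'     of each dimension fixed at 0) --- equivalent fit, different
#'     identification;}
#'   \item{`"1"`}{respondent-specific dispersions \eqn{s_r}, with the
#'     geometric mean of the \eqn{s_r} fixed at 1 to pin the scale.}
#' }
#' The common dispersion is fixed at 1 (only utility/SEM ratios are
#' identified; the probit scale is the unit). Optimization is quasi-Newton
#' with an analytic gradient, multi-started from `seed`, followed by Newton
#' polishing; convergence requires gradient norm below `1e-6`. If any
#' element wins or loses every comparison it appears in (separation), a
#' ridge penalty `1e-4 * sum(u^2)` keeps the estimate finite and the fit is
#' flagged.
#'
#' @param comparisons An `rqit_comparisons` data.frame.
#' @param instrument The instrument the elements belong to.
#' @param model `"2b"` (default), `"2a"` or `"1"`.
#' @param seed Integer seed for multi-start initialization (the fit is
#'   deterministic given the seed).
#' @param n_starts Number of optimizer starts (first start is at zero).
#' @param error_correlation See [bws_neg_loglik()].
#' @return An object of class `rqit_fit`: utilities (named, all elements),
#'   dispersions, `se` and `vcov`/`correlations` of the utility estimates
#'   (common-dispersion models), log-likelihood, model tag and a
#'   convergence record.
#' @seealso [rescale_fit()] to produce a 0--1000 [utility_table()].
#' @export
fit_bws <- function(comparisons, instrument, model = c("2b", "2a", "1"),
                    seed = NULL, n_starts = 3, error_correlation = 0) {
  model <- match.arg(model)
  instrument <- as_instrument(instrument)
  el <- instrument_elements(instrument)
  X <- comparison_incidence(comparisons, el)
  a0 <- 1 / sqrt(2 * (1 - error_correlation))

  # separation: element present but never on the winning (or losing) side
  wins <- colSums(X > 0); losses <- colSums(X < 0)
  present <- (wins + losses) > 0
  if (!all(present))
    warning("element(s) absent from all comparisons: ",
            paste(el[!present], collapse = ", "), "; ridge penalty engaged")
  separated <- present & (wins == 0 | losses == 0)
  ridge <- if (any(separated) || !all(present)) 1e-4 else 0
  if (any(separated))
    warning("separation detected for element(s) ",
            paste(el[separated], collapse = ", "),
            "; estimates are ridge-penalized")

  C <- utility_contrast(instrument, if (model == "2a") "corner" else "sum")
  pu <- ncol(C)
  XC <- X %*% C
  resp <- NULL; R <- 0L
  if (model == "1") {
    resp <- factor(comparisons$respondent_id)
    R <- nlevels(resp)
    if (R < 2L) stop_rqit("Model 1 needs at least 2 respondents",
                          class = "rqit_validation_error")
    ri <- as.integer(resp)
  }
  np <- pu + if (model == "1") R - 1L else 0L

  # log-dispersion per respondent from free parameters (sum-to-zero)
  expand_delta <- function(th) {
    d <- th[pu + seq_len(R - 1L)]
    c(d, -sum(d))
  }

  # weak shrinkage on the log-SEMs keeps Model 1 bounded when a respondent
  # answers almost perfectly consistently (their SEM would otherwise drift
  # to zero)
  ridge_delta <- if (model == "1") 1e-4 else 0

  raw_nll <- function(th) {
    z <- drop(XC %*% th[seq_len(pu)]) * a0
    if (model == "1") z <- z / exp(expand_delta(th))[ri]
    -sum(stats::pnorm(z, log.p = TRUE))
  }
  nll <- function(th) {
    u <- drop(C %*% th[seq_len(pu)])
    pen <- ridge * sum(u^2)
    if (model == "1") pen <- pen + ridge_delta * sum(expand_delta(th)^2)
    raw_nll(th) + pen
  }
  grad <- function(th) {
    z <- drop(XC %*% th[seq_len(pu)]) * a0
    srow <- if (model == "1") exp(expand_delta(th))[ri] else 1
    z <- z / srow
    g <- exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
    gu <- -drop(crossprod(XC, g * a0 / srow)) +
      ridge * 2 * drop(crossprod(C, drop(C %*% th[seq_len(pu)])))
    if (model != "1") return(gu)
    delta <- expand_delta(th)
    gd_full <- vapply(seq_len(R), function(r) sum((g * z)[ri == r]), numeric(1)) +
      2 * ridge_delta * delta
    c(gu, gd_full[seq_len(R - 1L)] - gd_full[R])
  }

  starts <- with_seed(seed, {
    lapply(seq_len(n_starts), function(i)
      if (i == 1L) rep(0, np) else stats::rnorm(np, 0, 0.5))
  })
  best <- NULL
  iters <- 0L
  for (st in starts) {
    opt <- stats::optim(st, nll, grad, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    iters <- iters + opt$counts[["function"]]
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  # damped Newton polish to drive the gradient norm down
  th <- best$par
  f_cur <- nll(th)
  for (it in 1:50) {
    g <- grad(th)
    gn <- sqrt(sum(g^2))
    if (gn < 1e-8) break
    H <- stats::optimHess(th, nll, grad)
    step <- tryCatch(solve(H, g), error = function(e) g / max(gn, 1))
    alpha <- 1
    accepted <- FALSE
    while (alpha >= 1e-6) {
      cand <- th - alpha * step
      f_cand <- nll(cand)
      if (f_cand < f_cur || sqrt(sum(grad(cand)^2)) < gn) {
        th <- cand; f_cur <- f_cand; accepted <- TRUE; break
      }
      alpha <- alpha / 2
    }
    iters <- iters + 1L
    if (!accepted) break
  }
  gnorm <- sqrt(sum(grad(th)^2))
  if (gnorm > 1e-6)
    stop_rqit("optimizer did not converge (gradient norm ",
              format(gnorm, digits = 3), ")", class = "rqit_convergence_error")

  u <- drop(C %*% th[seq_len(pu)])
  names(u) <- el
  H <- stats::optimHess(th, nll, grad)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, np, np))
  Vu <- C %*% V[seq_len(pu), seq_len(pu), drop = FALSE] %*% t(C)
  dimnames(Vu) <- list(el, el)
  se <- sqrt(pmax(diag(Vu), 0))
  corr <- Vu / outer(se, se)
  diag(corr) <- 1
  corr[se == 0, ] <- corr[, se == 0] <- 0
  diag(corr) <- 1

  disp <- if (model == "1") {
    d <- exp(expand_delta(th)); names(d) <- levels(resp); d
  } else 1

  structure(list(
    utilities = u, dispersions = disp, se = se, vcov = Vu,
    correlations = corr, logLik = -raw_nll(th),
    model = model, instrument = instrument,
    n_comparisons = nrow(comparisons),
    convergence = list(iterations = as.integer(iters), gradient_norm = gnorm,
                       separation = el[separated], ridge = ridge > 0),
    seed = seed), class = "rqit_fit")
}

#' @export
print.rqit_fit <- function(x, ...) {
  cat(sprintf("<rqit_fit> Thurstone model %s: %d comparisons, logLik %.2f\n",
              x$model, x$n_comparisons, x$logLik))
  cat("  utilities (latent scale):\n")
  print(round(x$utilities, 3))
  if (length(x$dispersions) > 1L)
    cat(sprintf("  respondent SEMs: %d values, range %.2f-%.2f\n",
                length(x$dispersions), min(x$dispersions), max(x$dispersions)))
  cat(sprintf("  converged: gradient norm %.2e after %d evaluations\n",
              x$convergence$gradient_norm, x$convergence$iterations))
  invisible(x)
}

#' Rescale a fitted model to a 0--1000 utility table
#'
#' Per dimension the lowest level's utility is translated to zero; all
#' utilities are then multiplied by a common factor so the highest profile
#' (every dimension at its top level) scores exactly the upper bound.
#' Standard errors are multiplied by the same factor (translation leaves
#' them unchanged); correlations are unchanged.
#'
#' @param fit An `rqit_fit`.
#' @param instrument Instrument (defaults to the fit's).
#' @param bounds Target scale, default `c(0, 1000)`.
#' @return An [utility_table()].
#' @export
rescale_fit <- function(fit, instrument = fit$instrument, bounds = c(0, 1000)) {
  stopifnot(inherits(fit, "rqit_fit"))
  instrument <- as_instrument(instrument)
  u <- fit$utilities
  for (d in instrument$dimensions) {
    lv <- d$levels$code
    u[lv] <- u[lv] - u[[lv[1L]]]
  }
  total <- sum(vapply(instrument$dimensions,
                      function(d) u[[d$levels$code[nrow(d$levels)]]],
                      numeric(1)))
  if (total <= 0)
    stop_rqit("degenerate fit: maximal profile utility is not positive",
              class = "rqit_degenerate_error")
  k <- (bounds[2L] - bounds[1L]) / total
  utility_table(instrument, utilities = u * k, se = fit$se * k,
                correlations = fit$correlations, bounds = bounds)
}

#' Predicted preference probability between two options
#'
#' @param fit An `rqit_fit`.
#' @param option_a,option_b Option strings like `"A3+B1"` from the same
#'   dimension pair.
#' @param dispersion SEM to use (default 1, the common-model unit).
#' @return `P(option_a` is preferred over `option_b)`.
#' @export
predict_preference <- function(fit, option_a, option_b, dispersion = 1) {
  ua <- sum(fit$utilities[split_option(option_a)[[1L]]])
  ub <- sum(fit$utilities[split_option(option_b)[[1L]]])
  stats::pnorm((ua - ub) / (dispersion * sqrt(2)))
}
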