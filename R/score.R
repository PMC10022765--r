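#' Score a profile
#'
#' The score of a profile is the sum of its element utilities; its standard
#' error propagates the joint uncertainty of the utility estimates through
#' the quadratic form over all ordered element pairs (see
#' [propagate_profile_se()]).
#'
#' @param profile Character vector of element codes, one per dimension of
#'   the instrument (any order), e.g. `c("A4","B1","C3","D3","E1")`.
#' @param table An [utility_table()] such as [anzmusc_rqit()].
#' @return An object of class `rqit_score`: a list with `value`,
#'   `standard_error` and the (dimension-ordered) `profile`.
#' @examples
#' score_profile(c("A4", "B1", "C3", "D3", "E1"), anzmusc_rqit())
#' @export
score_profile <- function(profile, table) {
  stopifnot(inherits(table, "rqit_utility_table"))
  profile <- check_profile(profile, table)
  structure(list(value = sum(table$utilities[profile]),
                 standard_error = propagate_profile_se(profile, table),
                 profile = profile),
            class = "rqit_score")
}

#' @export
print.rqit_score <- function(x, ...) {
  cat(sprintf("Profile (%s): score %g (SE %.2f)\n",
              paste(x$profile, collapse = ", "), x$value, x$standard_error))
  invisible(x)
}

#' Standard error of a profile score
#'
#' Treats the profile's element-utility estimates as jointly normal with
#' standard errors \eqn{\sigma_e} and correlations \eqn{\rho_{e,e'}} and
#' returns \eqn{\sqrt{\sum_e \sum_{e'} \rho_{e,e'} \sigma_e \sigma_{e'}}}
#' over all ordered pairs of the profile's elements. The result is
#' invariant to element ordering. No respondent-level uncertainty is
#' included: this is the sampling error of the calibrated utilities only.
#'
#' @inheritParams score_profile
#' @return Standard error in score units.
#' @export
propagate_profile_se <- function(profile, table) {
  stopifnot(inherits(table, "rqit_utility_table"))
  profile <- check_profile(profile, table)
  sig <- table$se[profile]
  rho <- table$correlations[profile, profile, drop = FALSE]
  v <- drop(crossprod(sig, rho %*% sig))
  if (v < -1e-8)
    stop_rqit("negative propagated variance (", format(v),
              "): correlation/SE inputs are inconsistent",
              class = "rqit_numeric_error")
  sqrt(max(v, 0))
}

#' Enumerate every profile of an instrument
#'
#' @inheritParams instrument_elements
#' @return A character matrix, one row per profile, one column per dimension.
#' @export
all_profiles <- function(instrument) {
  instrument <- as_instrument(instrument)
  grids <- lapply(instrument$dimensions, function(d) d$levels$code)
  names(grids) <- vapply(instrument$dimensions, `[[`, character(1), "code")
  as.matrix(rev(expand.grid(rev(grids), stringsAsFactors = FALSE)))
}
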