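#' Construct a utility table
#'
#' A utility table attaches calibrated element utilities, their standard
#' errors, and the correlation matrix of the utility estimates to an
#' instrument. On the published scale the lowest level of every dimension
#' has utility 0 and the top-level elements sum to the upper scale bound,
#' so any profile score lies within the scale bounds.
#'
#' @param instrument An [rqit_instrument()].
#' @param utilities Named numeric vector of element utilities (score units);
#'   names are element codes covering the full instrument.
#' @param se Named numeric vector of standard errors (score units).
#' @param correlations Numeric matrix of correlations between the utility
#'   estimates, with element codes as dimnames. Defaults to the identity.
#' @param bounds Numeric length-2 scale bounds, default `c(0, 1000)`.
#' @return An object of class `rqit_utility_table`.
#' @seealso [anzmusc_rqit()], [score_profile()], [rescale_fit()]
#' @export
utility_table <- function(instrument, utilities, se, correlations = NULL,
                          bounds = c(0, 1000)) {
  instrument <- as_instrument(instrument)
  el <- instrument_elements(instrument)
  for (nm in c("utilities", "se")) {
    v <- get(nm)
    if (is.null(names(v)) || !all(el %in% names(v)))
      stop_rqit("`", nm, "` must be named with every element code",
                class = "rqit_validation_error")
  }
  utilities <- utilities[el]
  se <- se[el]
  if (any(se < 0)) stop_rqit("standard errors must be non-negative",
                             class = "rqit_validation_error")
  if (is.null(correlations)) {
    correlations <- diag(length(el))
    dimnames(correlations) <- list(el, el)
  }
  if (!all(el %in% rownames(correlations)) || !all(el %in% colnames(correlations)))
    stop_rqit("correlation matrix must have element codes as dimnames",
              class = "rqit_validation_error")
  correlations <- correlations[el, el]
  check_correlations(correlations)
  # scale anchors: each dimension's lowest level at 0, top levels sum to
  # the upper bound
  for (d in instrument$dimensions) {
    lo <- d$levels$code[1L]
    if (abs(utilities[[lo]]) > 1e-6)
      stop_rqit("lowest level ", lo, " must have utility 0 (got ",
                format(utilities[[lo]]), ")", class = "rqit_validation_error")
  }
  top <- vapply(instrument$dimensions,
                function(d) utilities[[d$levels$code[nrow(d$levels)]]], numeric(1))
  if (abs(sum(top) - bounds[2L]) > 1e-6)
    stop_rqit("top-level utilities must sum to the upper scale bound ",
              bounds[2L], " (got ", format(sum(top)), ")",
              class = "rqit_validation_error")
  structure(list(instrument = instrument, utilities = utilities, se = se,
                 correlations = correlations, bounds = as.numeric(bounds)),
            class = "rqit_utility_table")
}

check_correlations <- function(rho) {
  if (any(abs(rho) > 1 + 1e-9))
    stop_rqit("correlations must lie in [-1, 1]", class = "rqit_validation_error")
  if (any(abs(diag(rho) - 1) > 1e-9))
    stop_rqit("correlation matrix must have unit diagonal",
              class = "rqit_validation_error")
  asym <- abs(rho - t(rho))
  if (any(asym > 1e-9)) {
    idx <- which(asym == max(asym), arr.ind = TRUE)[1L, ]
    stop_rqit("correlation matrix is asymmetric at (",
              rownames(rho)[idx[1L]], ", ", colnames(rho)[idx[2L]], ")",
              class = "rqit_validation_error")
  }
  invisible(rho)
}

#' @export
print.rqit_utility_table <- function(x, ...) {
  cat(sprintf("<rqit_utility_table> %s: scale %g-%g\n",
              x$instrument$name, x$bounds[1L], x$bounds[2L]))
  for (d in x$instrument$dimensions) {
    cat(sprintf("  %s. %s\n", d$code, d$label))
    for (code in d$levels$code)
      cat(sprintf("    %-3s %5.0f (SE %.1f)\n", code, round(x$utilities[[code]]),
                  x$se[[code]]))
  }
  invisible(x)
}

#' Read and write utility tables as structured text
#'
#' The JSON layout is
#' `{name, version, bounds, dimensions: [{code, label, levels: [{code,
#' descriptor, utility, se}]}], correlations: {elements, matrix}}`.
#' Values round-trip at full stored precision.
#'
#' @param path File path (or, for reading, a JSON string).
#' @param table An `rqit_utility_table`.
#' @return `load_utility_table()` returns an `rqit_utility_table`;
#'   `write_utility_table()` returns `path` invisibly.
#' @export
load_utility_table <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  dims <- lapply(x$dimensions, function(d)
    list(code = d$code, label = d$label,
         levels = vapply(d$levels, function(l) l$descriptor %||% "", character(1))))
  ins <- rqit_instrument(dims, name = x$name %||% "instrument",
                         version = x$version %||% "1")
  lv <- unlist(lapply(x$dimensions, function(d) d$levels), recursive = FALSE)
  u <- vapply(lv, function(l) as.numeric(l$utility), numeric(1))
  s <- vapply(lv, function(l) as.numeric(l$se), numeric(1))
  names(u) <- names(s) <- vapply(lv, `[[`, character(1), "code")
  el <- unlist(x$correlations$elements)
  rho <- do.call(rbind, lapply(x$correlations$matrix, unlist))
  dimnames(rho) <- list(el, el)
  utility_table(ins, u, s, rho,
                bounds = as.numeric(unlist(x$bounds %||% c(0, 1000))))
}

#' @rdname load_utility_table
#' @export
write_utility_table <- function(table, path) {
  stopifnot(inherits(table, "rqit_utility_table"))
  el <- instrument_elements(table)
  out <- list(
    name = table$instrument$name,
    version = table$instrument$version,
    bounds = table$bounds,
    dimensions = lapply(table$instrument$dimensions, function(d) list(
      code = d$code, label = d$label,
      levels = lapply(seq_len(nrow(d$levels)), function(i) list(
        code = d$levels$code[i], descriptor = d$levels$descriptor[i],
        utility = unname(table$utilities[[d$levels$code[i]]]),
        se = unname(table$se[[d$levels$code[i]]]))))),
    correlations = list(elements = el,
                        matrix = lapply(seq_along(el),
                                        function(i) unname(table$correlations[i, ])))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
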