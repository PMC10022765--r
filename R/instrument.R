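#' Construct a scoring instrument
#'
#' An instrument is an ordered set of dimensions, each with ordered levels.
#' Level codes are formed as dimension code plus 1-based level index
#' (`"A1"`, `"A2"`, ...), with index 1 the lowest-ranked level. A
#' dimension/level combination such as `"A3"` is called an *element*; a
#' *profile* picks exactly one element per dimension.
#'
#' @param dimensions A list of dimension definitions. Each is a list with
#'   `code` (single letter), `label` (text) and `levels`, a character vector
#'   of level descriptors in ordinal order (lowest first), or a list of
#'   `list(descriptor = ...)` entries.
#' @param name,version Instrument metadata.
#' @return An object of class `rqit_instrument`.
#' @examples
#' ins <- rqit_instrument(list(
#'   list(code = "A", label = "Burden", levels = c("low", "high")),
#'   list(code = "B", label = "Effect", levels = c("small", "medium", "large"))
#' ))
#' instrument_elements(ins)
#' @seealso [load_instrument()], [anzmusc_rqit()]
#' @export
rqit_instrument <- function(dimensions, name = "instrument", version = "1") {
  if (!is.list(dimensions) || length(dimensions) < 1L)
    stop_rqit("`dimensions` must be a non-empty list", class = "rqit_validation_error")
  dims <- lapply(dimensions, function(d) {
    code <- d$code
    if (is.null(code) || !nzchar(code))
      stop_rqit("dimension is missing a `code` field", class = "rqit_validation_error")
    lv <- d$levels
    if (is.list(lv)) lv <- vapply(lv, function(x) x$descriptor %||% x[[1L]], character(1))
    if (length(lv) < 2L)
      stop_rqit("dimension ", code, " must have at least 2 ordered levels",
                class = "rqit_validation_error")
    list(code = as.character(code),
         label = as.character(d$label %||% code),
         levels = data.frame(code = paste0(code, seq_along(lv)),
                             descriptor = as.character(lv)))
  })
  codes <- vapply(dims, `[[`, character(1), "code")
  if (anyDuplicated(codes))
    stop_rqit("duplicate dimension code: ", codes[duplicated(codes)][1L],
              class = "rqit_validation_error")
  el <- unlist(lapply(dims, function(d) d$levels$code))
  if (anyDuplicated(el))
    stop_rqit("duplicate level code: ", el[duplicated(el)][1L],
              class = "rqit_validation_error")
  structure(list(name = name, version = as.character(version), dimensions = dims),
            class = "rqit_instrument")
}

#' Load an instrument definition from structured text
#'
#' Reads a JSON instrument definition with fields
#' `{name, version, dimensions: [{code, label, levels: [{code, descriptor}]}]}`.
#' Utility annotations, if present, are ignored here; use
#' [load_utility_table()] for a full utility table.
#'
#' @param path Path to a JSON file, or a JSON string.
#' @return An `rqit_instrument`.
#' @export
load_instrument <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  dims <- lapply(x$dimensions, function(d)
    list(code = d$code, label = d$label,
         levels = vapply(d$levels, function(l) l$descriptor %||% "", character(1))))
  rqit_instrument(dims, name = x$name %||% "instrument", version = x$version %||% "1")
}

#' @export
print.rqit_instrument <- function(x, ...) {
  cat(sprintf("<rqit_instrument> %s (version %s): %d dimensions, %d elements\n",
              x$name, x$version, length(x$dimensions), length(instrument_elements(x))))
  for (d in x$dimensions)
    cat(sprintf("  %s. %s [%d levels]\n", d$code, d$label, nrow(d$levels)))
  invisible(x)
}

#' Element codes of an instrument
#'
#' @param instrument An `rqit_instrument` or `rqit_utility_table`.
#' @return Character vector of element codes in instrument order.
#' @export
instrument_elements <- function(instrument) {
  instrument <- as_instrument(instrument)
  unlist(lapply(instrument$dimensions, function(d) d$levels$code), use.names = FALSE)
}

#' Number of levels per dimension
#'
#' @inheritParams instrument_elements
#' @return Named integer vector (names are dimension codes).
#' @export
instrument_level_counts <- function(instrument) {
  instrument <- as_instrument(instrument)
  n <- vapply(instrument$dimensions, function(d) nrow(d$levels), integer(1))
  names(n) <- vapply(instrument$dimensions, `[[`, character(1), "code")
  n
}

as_instrument <- function(x) {
  if (inherits(x, "rqit_utility_table")) return(x$instrument)
  if (!inherits(x, "rqit_instrument"))
    stop_rqit("expected an rqit_instrument", class = "rqit_validation_error")
  x
}

# Validate a profile (character vector of element codes, one per dimension,
# any order) against an instrument; returns codes ordered by dimension.
check_profile <- function(profile, instrument) {
  instrument <- as_instrument(instrument)
  profile <- as.character(profile)
  dims <- vapply(instrument$dimensions, `[[`, character(1), "code")
  el <- instrument_elements(instrument)
  bad <- setdiff(profile, el)
  if (length(bad))
    stop_rqit("unknown element code(s): ", paste(bad, collapse = ", "),
              class = "rqit_lookup_error")
  pd <- substr(profile, 1L, 1L)
  if (length(profile) != length(dims) || !setequal(pd, dims) || anyDuplicated(pd))
    stop_rqit("profile must contain exactly one element per dimension (",
              paste(dims, collapse = ", "), ")", class = "rqit_validation_error")
  profile[match(dims, pd)]
}

#' The ANZMUSC-RQIT dimension structure and published utility table
#'
#' Returns the packaged ANZMUSC Research Question Importance Tool: five
#' dimensions --- stakeholder importance (A, 4 levels), patient burden
#' (B, 3), social burden (C, 4), intervention effect (D, 3) and health
#' equity (E, 4) --- with the published element utilities on the 0--1000
#' scale, their standard errors, and the 18x18 correlation matrix of the
#' utility estimates.
#'
#' @return An `rqit_utility_table`.
#' @examples
#' tab <- anzmusc_rqit()
#' score_profile(c("A4", "B1", "C3", "D3", "E1"), tab)
#' @export
anzmusc_rqit <- function() {
  load_utility_table(system.file("extdata", "anzmusc_rqit.json",
                                 package = "rqit", mustWork = TRUE))
}

#' The original six-dimension RQIT structure
#'
#' The precursor instrument with six dimensions (stakeholder importance,
#' patient burden, social burden, intervention effect, implementability,
#' and equity; levels 4/3/4/4/4/4). It carries no calibrated utilities and
#' is scored with the unweighted 0--18 sum; see [unweighted_rqit_score()].
#'
#' @return An `rqit_instrument`.
#' @export
rqit_original <- function() {
  load_instrument(system.file("extdata", "rqit_original.json",
                              package = "rqit", mustWork = TRUE))
}
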