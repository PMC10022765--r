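#' Read best-worst responses from delimited text
#'
#' Comma-separated, UTF-8, mandatory header
#' `respondent_id,task_id,best_option,worst_option`; option positions are
#' 1-based, an empty cell means that end was not answered (a single-ended
#' response). Rows with `best_option == worst_option` are rejected with a
#' diagnostic naming their line numbers.
#'
#' @param path File path.
#' @return A data.frame of validated responses suitable for
#'   [expand_comparisons()].
#' @export
read_responses <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(respondent_id = "character",
                                        task_id = "character"))
  need <- c("respondent_id", "task_id", "best_option", "worst_option")
  if (!identical(sort(names(out)), sort(need)))
    stop_rqit("responses file must have exactly the columns ",
              paste(need, collapse = ", "), class = "rqit_schema_error")
  for (cc in c("best_option", "worst_option")) {
    out[[cc]] <- suppressWarnings(as.integer(out[[cc]]))
    bad <- !is.na(out[[cc]]) & !(out[[cc]] %in% 1:3)
    if (any(bad))
      stop_rqit(cc, " outside 1..3 at line(s) ",
                paste(utils::head(which(bad) + 1L, 5), collapse = ", "),
                class = "rqit_schema_error")
  }
  empty <- is.na(out$best_option) & is.na(out$worst_option)
  if (any(empty))
    stop_rqit("neither best nor worst answered at line(s) ",
              paste(utils::head(which(empty) + 1L, 5), collapse = ", "),
              class = "rqit_schema_error")
  clash <- !is.na(out$best_option) & !is.na(out$worst_option) &
    out$best_option == out$worst_option
  if (any(clash)) {
    warning("best = worst at line(s) ",
            paste(utils::head(which(clash) + 1L, 5), collapse = ", "),
            "; row(s) rejected")
    out <- out[!clash, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' @rdname read_responses
#' @param responses Response data.frame.
#' @param path File path.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read ratings from delimited text
#'
#' Accepts long format (`subject_id,rater_id,category`) or a wide grid
#' (first column subject id, remaining columns one per rater).
#'
#' @param path File path.
#' @return A ratings matrix (see [as_ratings()]).
#' @export
read_ratings <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("subject_id", "rater_id", "category") %in% names(out)))
    return(as_ratings(out))
  m <- as.matrix(out[, -1L, drop = FALSE])
  rownames(m) <- out[[1L]]
  as_ratings(m)
}

#' Write a machine-readable provenance record
#'
#' Records inputs, options, seed and package version for a run so it can
#' be reproduced exactly.
#'
#' @param path Output JSON path.
#' @param command Name of the operation.
#' @param inputs Named list of input paths.
#' @param options Named list of options (include the seed).
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, command, inputs = list(), options = list()) {
  jsonlite::write_json(
    list(command = command, inputs = inputs, options = options,
         package = "rqit",
         version = as.character(utils::packageVersion("rqit")),
         timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
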