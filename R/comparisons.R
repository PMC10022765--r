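#' Expand best-worst answers into implied paired comparisons
#'
#' A best-worst answer to a three-option task implies a full ranking of the
#' options: best beats the middle option, best beats worst, and the middle
#' option beats worst --- three paired comparisons. An answer giving only
#' the best option implies it beats each of the other two; only the worst,
#' that each of the other two beats it --- two comparisons either way. So a
#' set of responses with `n_both` complete and `n_single` single-ended
#' answers expands to exactly `3 * n_both + 2 * n_single` comparisons.
#'
#' @param responses A data.frame of best-worst responses with columns
#'   `respondent_id`, `task_id`, `best_option`, `worst_option` (option
#'   positions 1--3; `NA` = not answered). See [read_responses()].
#' @param design An `rqit_design` giving each task's options.
#' @return A data.frame of class `rqit_comparisons` with columns
#'   `respondent_id`, `task_id`, `winner`, `loser` (option positions) and
#'   `winner_option`, `loser_option` (element-pair strings).
#' @examples
#' d <- data.frame(task_id = "T1", dim_pair = "AB",
#'                 opt1 = "A1+B3", opt2 = "A2+B2", opt3 = "A3+B1")
#' r <- data.frame(respondent_id = 1, task_id = "T1",
#'                 best_option = 1, worst_option = 3)
#' expand_comparisons(r, d)
#' @export
expand_comparisons <- function(responses, design) {
  if (nrow(responses) == 0L) {
    out <- data.frame(respondent_id = character(), task_id = character(),
                      winner = integer(), loser = integer(),
                      winner_option = character(), loser_option = character())
    class(out) <- c("rqit_comparisons", "data.frame")
    return(out)
  }
  unknown <- setdiff(responses$task_id, design$task_id)
  if (length(unknown))
    stop_rqit("response references unknown task_id: ",
              paste(utils::head(unknown, 3), collapse = ", "),
              class = "rqit_reference_error")
  b <- responses$best_option
  w <- responses$worst_option
  if (any(is.na(b) & is.na(w)))
    stop_rqit("response with neither best nor worst answered",
              class = "rqit_validation_error")
  clash <- !is.na(b) & !is.na(w) & b == w
  if (any(clash)) {
    warning(sum(clash), " response(s) with best = worst rejected (rows ",
            paste(utils::head(which(clash), 5), collapse = ", "), ")")
    responses <- responses[!clash, , drop = FALSE]
    b <- responses$best_option; w <- responses$worst_option
  }
  opts <- design_options(design)
  rownames(opts) <- design$task_id

  pairs <- function(win, lose) data.frame(
    respondent_id = responses$respondent_id[idx],
    task_id = responses$task_id[idx], winner = win, loser = lose)

  res <- list()
  # complete answers: best > middle > worst
  idx <- which(!is.na(b) & !is.na(w))
  if (length(idx)) {
    mid <- 6L - b[idx] - w[idx]
    res <- c(res, list(pairs(b[idx], mid), pairs(b[idx], w[idx]),
                       pairs(mid, w[idx])))
  }
  # best only: best beats both others
  idx <- which(!is.na(b) & is.na(w))
  if (length(idx)) {
    others <- lapply(b[idx], function(x) setdiff(1:3, x))
    o1 <- vapply(others, `[`, integer(1), 1L)
    o2 <- vapply(others, `[`, integer(1), 2L)
    res <- c(res, list(pairs(b[idx], o1), pairs(b[idx], o2)))
  }
  # worst only: both others beat worst
  idx <- which(is.na(b) & !is.na(w))
  if (length(idx)) {
    others <- lapply(w[idx], function(x) setdiff(1:3, x))
    o1 <- vapply(others, `[`, integer(1), 1L)
    o2 <- vapply(others, `[`, integer(1), 2L)
    res <- c(res, list(pairs(o1, w[idx]), pairs(o2, w[idx])))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  ti <- match(out$task_id, design$task_id)
  out$winner_option <- opts[cbind(ti, out$winner)]
  out$loser_option <- opts[cbind(ti, out$loser)]
  class(out) <- c("rqit_comparisons", "data.frame")
  out
}

# Signed element-incidence matrix of comparisons: one row per comparison,
# one column per element; +1 for each winner element, -1 for each loser
# element, entries cancel where the options share an element.
comparison_incidence <- function(comparisons, elements) {
  n <- nrow(comparisons)
  X <- matrix(0, n, length(elements), dimnames = list(NULL, elements))
  win <- split_option(comparisons$winner_option)
  los <- split_option(comparisons$loser_option)
  for (k in 1:2) {
    wk <- vapply(win, `[`, character(1), k)
    lk <- vapply(los, `[`, character(1), k)
    jw <- match(wk, elements); jl <- match(lk, elements)
    if (anyNA(jw) || anyNA(jl))
      stop_rqit("comparison references element not in the instrument",
                class = "rqit_reference_error")
    iw <- cbind(seq_len(n), jw); il <- cbind(seq_len(n), jl)
    X[iw] <- X[iw] + 1
    X[il] <- X[il] - 1
  }
  X
}
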