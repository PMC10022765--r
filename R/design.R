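#' Generate best-worst choice tasks over dimension pairs
#'
#' Each choice task shows three options drawn from the same two dimensions;
#' an option pairs one level of each dimension (e.g. `"A3+B1"`). Under the
#' default `"antichain"` rule the three options are strictly increasing in
#' one dimension and strictly decreasing in the other --- e.g. (A1,B3),
#' (A2,B2), (A3,B1) --- so that under any additive model with
#' within-dimension monotone utilities no option dominates by construction.
#' All rule-conforming triples over all unordered dimension pairs are
#' enumerated. A dimension with fewer than 3 levels cannot supply three
#' distinct levels for its side of the anti-chain; the rule then relaxes to
#' non-strict ordering on that side (one repeated level), with a message.
#'
#' @param instrument An [rqit_instrument()] (or utility table).
#' @param rule Design rule; only `"antichain"` is built in, but the rule
#'   set is open: pass a function `(dimension_a_levels, dimension_b_levels)
#'   -> list of 3x2 level-index matrices` for a custom catalogue.
#' @return A data.frame of class `rqit_design` with columns `task_id`,
#'   `dim_pair`, `opt1`, `opt2`, `opt3` (element codes joined by `"+"`).
#' @examples
#' d <- generate_tasks(anzmusc_rqit())
#' nrow(d)
#' @export
generate_tasks <- function(instrument, rule = "antichain") {
  instrument <- as_instrument(instrument)
  dims <- instrument$dimensions
  if (length(dims) < 2L)
    stop_rqit("need at least 2 dimensions to form choice tasks",
              class = "rqit_validation_error")
  triple_fun <- if (is.function(rule)) rule else switch(
    rule,
    antichain = antichain_triples,
    stop_rqit("unknown design rule: ", rule, class = "rqit_validation_error"))
  rows <- list()
  for (i in seq_len(length(dims) - 1L)) for (j in seq((i + 1L), length(dims))) {
    da <- dims[[i]]; db <- dims[[j]]
    triples <- triple_fun(nrow(da$levels), nrow(db$levels))
    for (tr in triples) {
      opts <- paste0(da$levels$code[tr[, 1L]], "+", db$levels$code[tr[, 2L]])
      rows[[length(rows) + 1L]] <- data.frame(
        dim_pair = paste0(da$code, db$code),
        opt1 = opts[1L], opt2 = opts[2L], opt3 = opts[3L])
    }
  }
  out <- do.call(rbind, rows)
  out <- cbind(task_id = sprintf("T%03d", seq_len(nrow(out))), out)
  class(out) <- c("rqit_design", "data.frame")
  out
}

# All 3-option anti-chain triples for a pair of dimensions with la and lb
# levels: levels strictly increasing on side a, strictly decreasing on side
# b. A side with 2 levels falls back to non-strict monotone sequences that
# use both levels (one repeat), keeping options pairwise distinct.
antichain_triples <- function(la, lb) {
  up <- monotone_triples(la)
  down <- lapply(monotone_triples(lb), rev)
  out <- list()
  for (a in up) for (b in down) {
    m <- cbind(a, b)
    if (anyDuplicated(paste(m[, 1L], m[, 2L]))) next
    out[[length(out) + 1L]] <- unname(m)
  }
  out
}

monotone_triples <- function(l) {
  if (l >= 3L) {
    co <- utils::combn(l, 3L)
    lapply(seq_len(ncol(co)), function(i) co[, i])
  } else {
    message("dimension with ", l,
            " levels: anti-chain relaxed to allow one repeated level")
    if (l == 2L) list(c(1L, 1L, 2L), c(1L, 2L, 2L)) else
      stop_rqit("dimension must have at least 2 levels",
                class = "rqit_validation_error")
  }
}

design_options <- function(design) {
  as.matrix(design[, c("opt1", "opt2", "opt3")])
}

# element codes of one option string "A3+B1"
split_option <- function(opt) strsplit(opt, "+", fixed = TRUE)

#' Allocate choice tasks to respondent blocks
#'
#' Selects `n_common` tasks that every block answers, then (in partition
#' mode, the default) partitions a random subset of the remaining tasks so
#' that each non-common task appears in exactly one block. Option display
#' order is independently shuffled per block and task, a standard guard
#' against position effects.
#'
#' @param design An `rqit_design` from [generate_tasks()].
#' @param n_blocks Number of respondent groups.
#' @param tasks_per_block Tasks answered by each respondent.
#' @param n_common Tasks shared by all blocks.
#' @param seed Integer seed; the allocation is reproducible from it.
#' @param partition If `TRUE`, non-common tasks are disjoint across blocks
#'   (requires `n_common + n_blocks * (tasks_per_block - n_common)` tasks or
#'   fewer); if `FALSE` each block samples independently.
#' @return A list of class `rqit_blocks`: one data.frame per block with
#'   columns `task_id` and `option_order` (a permutation like `"2,1,3"`).
#' @examples
#' d <- generate_tasks(anzmusc_rqit())
#' b <- allocate_blocks(d, n_blocks = 3, tasks_per_block = 25, n_common = 2,
#'                      seed = 1)
#' lengths(lapply(b, `[[`, "task_id"))
#' @export
allocate_blocks <- function(design, n_blocks, tasks_per_block, n_common = 0,
                            seed = NULL, partition = TRUE) {
  ids <- design$task_id
  n <- length(ids)
  per_block_extra <- tasks_per_block - n_common
  if (per_block_extra < 0L)
    stop_rqit("n_common exceeds tasks_per_block", class = "rqit_sizing_error")
  need <- n_common + if (partition) n_blocks * per_block_extra else per_block_extra
  if (need > n)
    stop_rqit("infeasible allocation: need at least ", need,
              " tasks but design has ", n, class = "rqit_sizing_error")
  with_seed(seed, {
    common <- sample(ids, n_common)
    rest <- setdiff(ids, common)
    blocks <- vector("list", n_blocks)
    if (partition) {
      picked <- sample(rest, n_blocks * per_block_extra)
      split_idx <- rep(seq_len(n_blocks), each = per_block_extra)
      for (b in seq_len(n_blocks))
        blocks[[b]] <- c(common, picked[split_idx == b])
    } else {
      for (b in seq_len(n_blocks))
        blocks[[b]] <- c(common, sample(rest, per_block_extra))
    }
    out <- lapply(seq_len(n_blocks), function(b) {
      tid <- sample(blocks[[b]])  # task presentation order
      data.frame(task_id = tid,
                 option_order = vapply(tid, function(.)
                   paste(sample(3L), collapse = ","), character(1)))
    })
  })
  names(out) <- sprintf("block%d", seq_len(n_blocks))
  structure(out, common_tasks = sort(common), class = c("rqit_blocks", "list"))
}

#' Read and write choice-task designs as delimited text
#'
#' Comma-separated with header `task_id,dim_pair,opt1,opt2,opt3`; options
#' are element codes joined by `"+"`.
#'
#' @param design An `rqit_design`.
#' @param path File path.
#' @return `read_design()` returns an `rqit_design`; `write_design()`
#'   returns `path` invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("task_id", "dim_pair", "opt1", "opt2", "opt3")
  if (!all(need %in% names(out)))
    stop_rqit("design file must have columns ", paste(need, collapse = ", "),
              class = "rqit_schema_error")
  class(out) <- c("rqit_design", "data.frame")
  out
}
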