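test_that("anti-chain rule reproduces the canonical example task", {
  ins <- rqit_instrument(list(
    list(code = "A", levels = paste0("a", 1:4)),
    list(code = "B", levels = paste0("b", 1:3))))
  d <- generate_tasks(ins)
  key <- apply(as.matrix(d[, c("opt1", "opt2", "opt3")]), 1,
               function(o) paste(sort(o), collapse = "|"))
  expect_true("A1+B3|A2+B2|A3+B1" %in% key)
  expect_true(all(d$dim_pair == "AB"))
})

test_that("two 3-level dimensions force reversed-order pairings", {
  d <- generate_tasks(tiny_instrument())
  expect_identical(nrow(d), 1L)
  for (i in seq_len(nrow(d))) {
    opts <- strsplit(unlist(d[i, c("opt1", "opt2", "opt3")]), "+", fixed = TRUE)
    a <- as.integer(substring(vapply(opts, `[`, "", 1), 2))
    b <- as.integer(substring(vapply(opts, `[`, "", 2), 2))
    expect_true(all(diff(a[order(a)]) > 0))
    expect_true(all(diff(b[order(a)]) < 0))
  }
})

test_that("task counts match exhaustive enumeration over all dimension pairs", {
  tab <- anzmusc_rqit()
  d <- generate_tasks(tab)
  counts <- instrument_level_counts(tab)
  dims <- names(counts)
  expected <- 0L
  for (i in 1:(length(dims) - 1)) for (j in (i + 1):length(dims))
    expected <- expected + antichain_count_oracle(counts[[i]], counts[[j]])
  expect_identical(nrow(d), expected)
  # every element covered at least once
  opts <- unlist(strsplit(unlist(d[, c("opt1", "opt2", "opt3")]), "+",
                          fixed = TRUE))
  expect_setequal(unique(opts), instrument_elements(tab))
})

test_that("a 2-level dimension falls back to one repeated level", {
  ins <- rqit_instrument(list(
    list(code = "A", levels = paste0("a", 1:3)),
    list(code = "B", levels = c("lo", "hi"))))
  expect_message(d <- generate_tasks(ins), "relaxed")
  for (i in seq_len(nrow(d))) {
    opts <- unlist(d[i, c("opt1", "opt2", "opt3")])
    expect_identical(anyDuplicated(opts), 0L)  # options pairwise distinct
  }
})

test_that("no option dominates within a task under monotone utilities", {
  tab <- anzmusc_rqit()
  d <- generate_tasks(tab)
  opts <- as.matrix(d[, c("opt1", "opt2", "opt3")])
  set.seed(11)
  for (rep in 1:5) {
    # random strictly increasing within-dimension utilities
    el <- instrument_elements(tab)
    u <- numeric(0)
    for (grp in split(el, substr(el, 1, 1)))
      u <- c(u, setNames(sort(runif(length(grp))), grp))
    for (i in seq_len(nrow(d))) {
      parts <- strsplit(opts[i, ], "+", fixed = TRUE)
      a <- vapply(parts, function(p) u[[p[1]]], numeric(1))
      b <- vapply(parts, function(p) u[[p[2]]], numeric(1))
      # anti-chain: the two dimensions rank the options in exactly
      # opposite orders, so neither coordinate-wise dominance nor a
      # uniformly best option by construction
      expect_identical(order(a), rev(order(b)))
    }
  }
})

test_that("block allocation partitions non-common tasks and is seeded", {
  tab <- anzmusc_rqit()
  d <- generate_tasks(tab)
  b <- allocate_blocks(d, n_blocks = 3, tasks_per_block = 25, n_common = 2,
                       seed = 7)
  expect_length(b, 3)
  common <- attr(b, "common_tasks")
  expect_length(common, 2)
  for (blk in b) {
    expect_identical(nrow(blk), 25L)
    expect_true(all(common %in% blk$task_id))
  }
  # non-common tasks disjoint across blocks
  noncommon <- lapply(b, function(blk) setdiff(blk$task_id, common))
  all_nc <- unlist(noncommon)
  expect_identical(anyDuplicated(all_nc), 0L)
  expect_identical(length(all_nc), 69L)
  # determinism and seed sensitivity
  b2 <- allocate_blocks(d, 3, 25, 2, seed = 7)
  expect_identical(b, b2)
  b3 <- allocate_blocks(d, 3, 25, 2, seed = 8)
  expect_false(identical(lapply(b, `[[`, "task_id"),
                         lapply(b3, `[[`, "task_id")))
  expect_identical(vapply(b3, nrow, integer(1)), vapply(b, nrow, integer(1)))
})

test_that("exact partition and infeasible allocations behave as specified", {
  d <- generate_tasks(rqit_instrument(list(
    list(code = "A", levels = paste0("a", 1:3)),
    list(code = "B", levels = paste0("b", 1:3)),
    list(code = "C", levels = paste0("c", 1:3)))))
  expect_identical(nrow(d), 3L)
  b <- allocate_blocks(d, n_blocks = 3, tasks_per_block = 1, n_common = 0,
                       seed = 1)
  ids <- sort(unlist(lapply(b, `[[`, "task_id"), use.names = FALSE))
  expect_identical(ids, sort(d$task_id))  # each task in exactly one block
  expect_error(allocate_blocks(d, 3, 2, 0, seed = 1), "infeasible")
  expect_error(allocate_blocks(d, 2, 1, 2, seed = 1), "n_common exceeds")
})

test_that("designs round-trip through delimited text", {
  d <- generate_tasks(tiny_instrument())
  path <- withr::local_tempfile(fileext = ".csv")
  write_design(d, path)
  d2 <- read_design(path)
  expect_equal(as.data.frame(d), as.data.frame(d2))
  expect_error(read_design(write_design(data.frame(x = 1), path)),
               "must have columns")
})
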