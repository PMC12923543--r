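test_that("maximal runs of 1s become sorted disjoint intervals", {
  expect_identical(nrow(labels_to_intervals(integer(9))), 0L)
  iv <- labels_to_intervals(c(0L, 0L, 0L, 1L, 1L, 1L, 1L, 0L, 0L))
  expect_equal(unname(iv), matrix(c(3L, 7L), 1))
  iv2 <- labels_to_intervals(c(1L, 1L, 0L, 1L))
  expect_equal(unname(iv2), matrix(c(0L, 3L, 2L, 4L), 2))
  expect_identical(nrow(labels_to_intervals(integer())), 0L)
  expect_identical(unname(labels_to_intervals(rep(1L, 5))[1, ]), c(0L, 5L))
})

test_that("the four filtering rules fire in order", {
  r <- make_reads(paste(rep("ACGT", 25), collapse = ""))  # 100 nt

  # rule 3: one long-enough adapter splits the read in two
  res <- chop_read(r$read_id, r$sequence, r$quality,
                   cbind(start = 40L, end = 60L))
  expect_identical(res$action, "split")
  expect_identical(nchar(res$segments$sequence), c(40L, 40L))
  expect_identical(res$segments$read_id, c("r1:1", "r1:2"))
  expect_identical(res$segments$sequence[1], substr(r$sequence, 1, 40))
  expect_identical(res$segments$sequence[2], substr(r$sequence, 61, 100))

  # rule 1: a 12 nt candidate is not a valid adapter
  res <- chop_read(r$read_id, r$sequence, r$quality,
                   cbind(start = 40L, end = 52L))
  expect_identical(res$action, "unchanged")
  expect_identical(res$segments$sequence, r$sequence)
  expect_identical(nrow(res$removed), 0L)

  # rule 2: five surviving candidates -> whole read retained, nothing removed
  five <- cbind(start = c(0L, 20L, 40L, 60L, 80L),
                end = c(15L, 35L, 55L, 75L, 95L))
  res <- chop_read(r$read_id, r$sequence, r$quality, five)
  expect_identical(res$action, "retained_multiadapter")
  expect_identical(res$segments$sequence, r$sequence)
  expect_identical(nrow(res$removed), 0L)
  # ...but four candidates are excised
  res4 <- chop_read(r$read_id, r$sequence, r$quality, five[1:4, ])
  expect_identical(nrow(res4$removed), 4L)

  # rule 4: both flanks under 20 nt vanish, the removed span is recorded
  short <- make_reads(strrep("A", 50))
  res <- chop_read(short$read_id, short$sequence, short$quality,
                   cbind(start = 15L, end = 35L))
  expect_identical(nrow(res$segments), 0L)
  expect_equal(unname(res$removed), matrix(c(15L, 35L), 1))
  expect_identical(nrow(res$discarded), 2L)
})

test_that("rule interaction: the multi-adapter count applies after the length filter", {
  r <- make_reads(strrep("ACGT", 50))  # 200 nt
  # 6 candidates, 2 of them under 13 nt -> 4 survive -> read is split
  cand <- cbind(start = c(0L, 30L, 60L, 90L, 120L, 150L),
                end = c(20L, 40L, 80L, 100L, 140L, 170L))
  res <- chop_read(r$read_id, r$sequence, r$quality, cand)
  expect_identical(res$action, "split")
  expect_identical(nrow(res$removed), 4L)
})

test_that("thresholds are configurable", {
  r <- make_reads(strrep("ACGT", 25))
  res <- chop_read(r$read_id, r$sequence, r$quality,
                   cbind(start = 40L, end = 52L), min_adapter_len = 5L)
  expect_identical(res$action, "split")
  res <- chop_read(r$read_id, r$sequence, r$quality,
                   cbind(start = 40L, end = 60L), min_segment_len = 50L)
  expect_identical(nrow(res$segments), 0L)
  res <- chop_read(r$read_id, r$sequence, r$quality,
                   cbind(start = c(20L, 60L), end = c(40L, 80L)),
                   max_adapters = 1L)
  expect_identical(res$action, "retained_multiadapter")
})

test_that("overlapping candidates are refused", {
  r <- make_reads(strrep("A", 100))
  expect_error(chop_read(r$read_id, r$sequence, r$quality,
                         cbind(start = c(10L, 25L), end = c(30L, 45L))),
               "overlapping")
})

test_that("base conservation holds on random reads and candidate sets", {
  set.seed(13)
  for (rep in seq_len(1000)) {
    n <- sample(10:400, 1L)
    seq <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    qual <- int_to_qual(sample(0:60, n, TRUE))
    cand <- random_candidates(n)
    res <- chop_read("x", seq, qual, cand)
    total <- sum(nchar(res$segments$sequence)) +
      sum(res$removed[, 2] - res$removed[, 1]) +
      sum(res$discarded[, 2] - res$discarded[, 1])
    expect_identical(total, n)
    # no emitted segment may overlap a removed adapter span
    if (nrow(res$removed) > 0L && nrow(res$segments) > 0L &&
        res$action == "split") {
      cut <- unlist(apply(res$removed, 1L,
                          function(x) (x[1] + 1L):x[2], simplify = FALSE))
      kept <- unlist(lapply(res$segments$sequence, nchar))
      expect_identical(sum(kept) + length(cut) +
                         sum(res$discarded[, 2] - res$discarded[, 1]), n)
    }
  }
})

test_that("truth labels recover exactly two segments from internal reads", {
  ds <- generate_dataset(200, pos_neg_ratio = c(1, 0),
                         internal_end3_ratio = c(1, 0), seed = 14)
  reads <- rbind(ds$train, ds$val, ds$test)
  reads$pred_labels <- lapply(seq_len(nrow(reads)), function(i)
    labels_from_intervals(nchar(reads$sequence[i]),
                          reads$adapter_start[i], reads$adapter_end[i]))
  results <- chop_reads(reads, smooth_window = 21L)
  expect_true(all(vapply(results, function(r) r$action, "") == "split"))
  expect_true(all(vapply(results, function(r) nrow(r$segments), 0L) == 2L))
  for (i in seq_len(nrow(reads))) {
    expected <- paste0(substr(reads$sequence[i], 1L, reads$adapter_start[i]),
                       substr(reads$sequence[i], reads$adapter_end[i] + 1L,
                              nchar(reads$sequence[i])))
    expect_identical(paste(results[[i]]$segments$sequence, collapse = ""),
                     expected)
  }
})

test_that("chop summaries report lengths, positions and segment counts", {
  r <- make_reads(strrep("ACGTA", 62))  # 310 nt
  res <- chop_read(r$read_id, r$sequence, r$quality,
                   cbind(start = 120L, end = 190L))
  summ <- summarize_chops(list(res))
  expect_identical(summ$adapter_length, 70L)
  expect_equal(summ$relative_position, 120 / 310)
  expect_identical(summ$n_segments, 2L)

  end3 <- chop_read("e", strrep("A", 100), strrep("I", 100),
                    cbind(start = 70L, end = 100L))
  s2 <- summarize_chops(list(end3))
  expect_identical(s2$n_segments, 1L)  # 3'-end trim leaves one segment
  expect_identical(s2$action, "trimmed_end")

  expect_identical(nrow(summarize_chops(list())), 0L)
})

test_that("multi-adapter reads split into k+1 segments until the count rule fires", {
  set.seed(15)
  bodies <- toy_bodies(len = 60L)
  for (k in 2:4) {
    r <- build_multiadapter_read(bodies, adapter_model(), n_adapters = k)
    expect_identical(nchar(r$sequence), nchar(r$quality))
    expect_identical(sum(r$labels[[1]]),
                     sum(r$truth_intervals[[1]][, 2] - r$truth_intervals[[1]][, 1]))
    r$pred_labels <- r$labels
    res <- chop_reads(r)[[1]]
    expect_identical(res$action, "split")
    expect_identical(nrow(res$segments), k + 1L)
  }
  r5 <- build_multiadapter_read(bodies, adapter_model(), n_adapters = 5L)
  r5$pred_labels <- r5$labels
  res5 <- chop_reads(r5)[[1]]
  expect_identical(res5$action, "retained_multiadapter")
  expect_identical(res5$segments$sequence, r5$sequence)
})
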