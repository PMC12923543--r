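#' Extract maximal adapter intervals from a refined label track
#'
#' @param labels Integer 0/1 vector.
#' @return An integer matrix with columns `start`, `end`: the maximal runs
#'   of 1s as sorted, disjoint, 0-based half-open intervals (no length
#'   filtering).
#' @export
labels_to_intervals <- function(labels) {
  stopifnot(all(labels %in% c(0L, 1L)))
  n <- length(labels)
  empty <- matrix(integer(), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  if (n == 0L) return(empty)
  d <- diff(c(0L, labels, 0L))
  starts <- which(d == 1L) - 1L
  ends <- which(d == -1L) - 1L
  if (!length(starts)) return(empty)
  cbind(start = starts, end = ends)
}

#' Excise predicted adapters from one read under the filtering rules
#'
#' Applies, in order: (1) candidate adapters shorter than `min_adapter_len`
#' (default 13 nt) are dropped; (2) if more than `max_adapters` (default 4)
#' candidates survive, the whole read is retained untouched; (3) otherwise
#' the surviving adapter spans are removed and the read is divided into the
#' between-cut segments, which keep their original qualities; (4) segments
#' shorter than `min_segment_len` (default 20 nt) are discarded. Segment ids
#' are `<read_id>:<ordinal>`.
#'
#' @param read_id,sequence,quality One read (quality as a Phred+33 string).
#' @param candidates Integer matrix (columns `start`, `end`) of candidate
#'   adapter intervals, 0-based half-open, sorted and disjoint (e.g. from
#'   [labels_to_intervals()]).
#' @param min_adapter_len,max_adapters,min_segment_len Filtering thresholds.
#' @return A list of class `nc_chop`: `source_id`, `segments` (tibble
#'   `read_id`/`sequence`/`quality`), `removed` (interval matrix of excised
#'   adapters), `discarded` (interval matrix of dropped short segments), and
#'   `action`, one of `"unchanged"`, `"trimmed_end"`, `"split"`,
#'   `"retained_multiadapter"`.
#' @export
chop_read <- function(read_id, sequence, quality, candidates,
                      min_adapter_len = 13L, max_adapters = 4L,
                      min_segment_len = 20L) {
  n <- nchar(sequence)
  stopifnot(nchar(quality) == n)
  cand <- candidates
  if (is.null(dim(cand))) cand <- matrix(cand, ncol = 2L)
  if (nrow(cand) > 1L) {
    if (any(cand[-1L, 1L] < cand[-nrow(cand), 2L])) {
      stop("overlapping or unsorted candidate intervals for read '",
           read_id, "'", call. = FALSE)
    }
  }
  if (nrow(cand) > 0L) {
    stopifnot(all(cand[, 1L] >= 0L), all(cand[, 2L] <= n),
              all(cand[, 1L] < cand[, 2L]))
  }
  empty_iv <- matrix(integer(), ncol = 2L,
                     dimnames = list(NULL, c("start", "end")))
  seg_tbl <- function(starts, ends, ids) {
    if (length(starts) == 0L) {
      return(tibble::tibble(read_id = character(), sequence = character(),
                            quality = character()))
    }
    tibble::tibble(read_id = ids,
                   sequence = substring(sequence, starts + 1L, ends),
                   quality = substring(quality, starts + 1L, ends))
  }

  # rule 1: minimum adapter length
  keep <- (cand[, 2L] - cand[, 1L]) >= min_adapter_len
  surv <- cand[keep, , drop = FALSE]
  if (nrow(surv) == 0L) {
    return(structure(list(source_id = read_id,
                          segments = seg_tbl(0L, n, read_id),
                          removed = empty_iv, discarded = empty_iv,
                          action = "unchanged"), class = "nc_chop"))
  }
  # rule 2: too many adapters -> retain whole read
  if (nrow(surv) > max_adapters) {
    return(structure(list(source_id = read_id,
                          segments = seg_tbl(0L, n, read_id),
                          removed = empty_iv, discarded = empty_iv,
                          action = "retained_multiadapter"), class = "nc_chop"))
  }
  # rule 3: excise adapters, keep between-cut segments
  seg_start <- c(0L, unname(surv[, 2L]))
  seg_end <- c(unname(surv[, 1L]), n)
  nonempty <- seg_end > seg_start
  seg_start <- seg_start[nonempty]; seg_end <- seg_end[nonempty]
  # rule 4: drop short segments
  long_enough <- (seg_end - seg_start) >= min_segment_len
  disc <- cbind(start = seg_start[!long_enough], end = seg_end[!long_enough])
  seg_start <- seg_start[long_enough]; seg_end <- seg_end[long_enough]
  segs <- seg_tbl(seg_start, seg_end,
                  if (length(seg_start)) paste0(read_id, ":", seq_along(seg_start))
                  else character())
  action <- if (length(seg_start) >= 2L) "split" else "trimmed_end"
  colnames(surv) <- c("start", "end")
  structure(list(source_id = read_id, segments = segs, removed = surv,
                 discarded = disc, action = action), class = "nc_chop")
}

#' Refine and chop a collection of reads
#'
#' Pipeline convenience: refine each raw label track with the
#' sliding-window majority vote, extract maximal adapter runs, and apply the
#' chopping rules to every read.
#'
#' @param reads A read tibble with a list column of per-base 0/1 labels
#'   (named by `label_col`, default `"pred_labels"`).
#' @param smooth_window Sliding-window size for [refine_labels()]; use 1 to
#'   disable smoothing.
#' @param label_col Name of the list column holding raw labels.
#' @param ... Thresholds passed to [chop_read()].
#' @return A list of `nc_chop` results, one per read.
#' @export
chop_reads <- function(reads, smooth_window = 21L, label_col = "pred_labels",
                       ...) {
  stopifnot(is.data.frame(reads), label_col %in% names(reads))
  lapply(seq_len(nrow(reads)), function(i) {
    refined <- refine_labels(reads[[label_col]][[i]], smooth_window)
    chop_read(reads$read_id[i], reads$sequence[i], reads$quality[i],
              labels_to_intervals(refined), ...)
  })
}

#' Collect chopped segments into one read table
#'
#' @param results A list of `nc_chop` results.
#' @return A tibble of all emitted segments (`read_id`, `sequence`,
#'   `quality`), ready for [write_fastq()].
#' @export
chop_segments <- function(results) {
  tbls <- lapply(results, `[[`, "segments")
  out <- do.call(rbind, tbls)
  if (is.null(out)) out <- tibble::tibble(read_id = character(),
                                          sequence = character(),
                                          quality = character())
  out
}

#' Per-read chopping summary
#'
#' For each read: how many adapters were removed, their lengths and
#' relative positions (adapter start divided by read length), how many
#' segments were emitted, and the action taken. This is the per-read basis
#' for the standard summary views: adapter-length histogram, relative
#' adapter position, and segments per read (1 segment = 3'-end trim, 2+ =
#' internal adapters removed).
#'
#' @param results A list of `nc_chop` results.
#' @return A tibble with one row per removed adapter (reads without removed
#'   adapters contribute one row with NA adapter fields), columns `read_id`,
#'   `read_length`, `n_adapters`, `adapter_start`, `adapter_end`,
#'   `adapter_length`, `relative_position`, `n_segments`, `action`.
#' @export
summarize_chops <- function(results) {
  rows <- lapply(results, function(r) {
    rem_start <- unname(r$removed[, 1L]); rem_end <- unname(r$removed[, 2L])
    read_len <- sum(nchar(r$segments$sequence)) +
      sum(rem_end - rem_start) +
      sum(r$discarded[, 2L] - r$discarded[, 1L])
    if (identical(r$action, "unchanged") ||
        identical(r$action, "retained_multiadapter")) {
      read_len <- nchar(r$segments$sequence[1L])
    }
    n_ad <- nrow(r$removed)
    if (n_ad == 0L) {
      tibble::tibble(read_id = r$source_id, read_length = read_len,
                     n_adapters = 0L, adapter_start = NA_integer_,
                     adapter_end = NA_integer_, adapter_length = NA_integer_,
                     relative_position = NA_real_,
                     n_segments = nrow(r$segments), action = r$action)
    } else {
      tibble::tibble(read_id = r$source_id, read_length = read_len,
                     n_adapters = n_ad,
                     adapter_start = rem_start,
                     adapter_end = rem_end,
                     adapter_length = rem_end - rem_start,
                     relative_position = rem_start / read_len,
                     n_segments = nrow(r$segments), action = r$action)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- tibble::tibble(read_id = character(), read_length = integer(),
                          n_adapters = integer(), adapter_start = integer(),
                          adapter_end = integer(), adapter_length = integer(),
                          relative_position = double(),
                          n_segments = integer(), action = character())
  }
  out
}
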