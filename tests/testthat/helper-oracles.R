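# Independent brute-force oracles used to check the vectorised implementations.

# literal sliding-window majority vote, evaluated position by position with
# window truncation at the read ends
brute_refine <- function(labels, W) {
  n <- length(labels)
  k <- (W - 1L) %/% 2L
  out <- integer(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - k)
    hi <- min(n, i + k)
    out[i] <- as.integer(sum(labels[lo:hi]) > (hi - lo + 1L) / 2)
  }
  out
}

# reference-consuming CIGAR span by walking the operations one by one
brute_cigar_span <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  span <- 0L
  for (op in ops) {
    n <- as.integer(sub("[MIDNSHP=X]$", "", op))
    type <- sub("^[0-9]+", "", op)
    if (type %in% c("M", "D", "N", "=", "X")) span <- span + n
  }
  span
}

# quick literal confusion-matrix count over pooled positions
brute_confusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    for (j in seq_along(pred[[i]])) {
      p <- pred[[i]][j]; y <- truth[[i]][j]
      if (p == 1L && y == 1L) tp <- tp + 1L
      else if (p == 1L && y == 0L) fp <- fp + 1L
      else if (p == 0L && y == 1L) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# a small read tibble with the given sequences and flat quality 'qchar'
make_reads <- function(seqs, qchar = "I", ids = NULL) {
  if (is.null(ids)) ids <- paste0("r", seq_along(seqs))
  tibble::tibble(read_id = ids, sequence = seqs,
                 quality = strrep(qchar, nchar(seqs)))
}

# random sorted disjoint candidate intervals within a read of length n
random_candidates <- function(n, max_k = 4L) {
  k <- sample(0:max_k, 1L)
  if (k == 0L || n < 2L) {
    return(matrix(integer(), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  cuts <- sort(sample(0:n, min(2L * k, n + 1L)))
  cuts <- cuts[seq_len(2L * (length(cuts) %/% 2L))]
  iv <- matrix(cuts, ncol = 2L, byrow = TRUE,
               dimnames = list(NULL, c("start", "end")))
  iv[iv[, 1L] < iv[, 2L], , drop = FALSE]
}

# one SAM line with optional SA tag
sam_line <- function(qname, flag, rname, pos, cigar, sa = NULL) {
  f <- c(qname, flag, rname, pos, "60", cigar, "*", "0", "0", "A", "!")
  if (!is.null(sa)) f <- c(f, paste0("SA:Z:", sa))
  paste(f, collapse = "\t")
}

# fast generator settings for training smoke tests: short reads, clean signal
toy_bodies <- function(len = 80L, qmean = 13) {
  body_model(length_distribution = list(name = "fixed", value = len),
             polya_distribution = list(name = "fixed", value = 10L),
             quality_mean = qmean, quality_sd = 2)
}
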