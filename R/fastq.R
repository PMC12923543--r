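#' Read a 4-line FASTQ file
#'
#' Parses a plain (or gzip-compressed) FASTQ file in the strict 4-line
#' dialect emitted by modern basecallers: header, sequence, `+`, quality.
#' Wrapped (multi-line) records are rejected. Qualities are interpreted as
#' Phred+33. `U` bases are mapped to `T` at ingest so a single DNA alphabet
#' flows through the rest of the pipeline.
#'
#' @param path Path to a FASTQ file (".gz" is decompressed transparently).
#' @return A [tibble::tibble] with character columns `read_id`, `sequence`
#'   and `quality` (the raw Phred+33 quality string), one row per record, in
#'   file order. Use [qual_to_int()] to decode qualities.
#' @seealso [write_fastq()], [qual_to_int()]
#' @export
read_fastq <- function(path) {
  stopifnot(is.character(path), length(path) == 1L, file.exists(path))
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ file '", path, "' does not contain a multiple of 4 lines; ",
         "only the 4-line dialect is supported", call. = FALSE)
  }
  n <- length(lines) %/% 4L
  if (n == 0L) {
    return(tibble::tibble(read_id = character(), sequence = character(),
                          quality = character()))
  }
  idx <- seq_len(n)
  head_l <- lines[4L * idx - 3L]
  seq_l  <- lines[4L * idx - 2L]
  plus_l <- lines[4L * idx - 1L]
  qual_l <- lines[4L * idx]

  bad_head <- which(!startsWith(head_l, "@"))
  if (length(bad_head)) {
    stop("record ", bad_head[1L], ": header line does not start with '@' ",
         "(multi-line FASTQ is not supported)", call. = FALSE)
  }
  bad_plus <- which(!startsWith(plus_l, "+"))
  if (length(bad_plus)) {
    stop("record ", bad_plus[1L], ": separator line does not start with '+'",
         call. = FALSE)
  }
  bad_len <- which(nchar(seq_l) != nchar(qual_l))
  if (length(bad_len)) {
    id <- sub("^@", "", sub("\\s.*$", "", head_l[bad_len[1L]]))
    stop("record '", id, "': sequence length ", nchar(seq_l[bad_len[1L]]),
         " != quality length ", nchar(qual_l[bad_len[1L]]), call. = FALSE)
  }

  ids <- sub("\\s.*$", "", substring(head_l, 2L))
  if (any(!nzchar(ids))) {
    stop("record ", which(!nzchar(ids))[1L], ": empty read id", call. = FALSE)
  }
  seqs <- chartr("uU", "tT", seq_l)
  seqs <- toupper(seqs)
  tibble::tibble(read_id = ids, sequence = seqs, quality = qual_l)
}

#' Write reads as a 4-line FASTQ file
#'
#' The inverse of [read_fastq()]: writing what was read from a well-formed
#' 4-line FASTQ reproduces the input byte-for-byte (provided the input used
#' bare `+` separators, uppercase `T` and no header comments).
#'
#' @param reads A data frame with columns `read_id`, `sequence`, `quality`
#'   (Phred+33 quality strings, same width as `sequence`).
#' @param path Output path.
#' @return Invisibly, the number of records written.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "sequence", "quality") %in% names(reads)))
  if (nrow(reads) == 0L) {
    file.create(path)
    return(invisible(0L))
  }
  if (any(nchar(reads$sequence) != nchar(reads$quality))) {
    bad <- which(nchar(reads$sequence) != nchar(reads$quality))[1L]
    stop("read '", reads$read_id[bad], "': sequence and quality lengths differ",
         call. = FALSE)
  }
  lines <- as.vector(rbind(paste0("@", reads$read_id),
                           reads$sequence, "+", reads$quality))
  writeLines(lines, path)
  invisible(nrow(reads))
}

#' Convert between Phred+33 quality strings and integer Q-scores
#'
#' @param qual A character vector of Phred+33 quality strings.
#' @return For `qual_to_int`, a list of integer vectors (one per string);
#'   scalar input returns a list of length one.
#' @examples
#' qual_to_int("!I")  # list(c(0L, 40L))
#' @export
qual_to_int <- function(qual) {
  lapply(qual, function(q) {
    if (!nzchar(q)) return(integer())
    utf8ToInt(q) - 33L
  })
}

#' @rdname qual_to_int
#' @param q An integer vector of Q-scores, each in `[0, 93]`.
#' @return For `int_to_qual`, a single Phred+33 string.
#' @export
int_to_qual <- function(q) {
  if (length(q) == 0L) return("")
  if (any(q < 0L | q > 93L)) {
    stop("quality values must lie in [0, 93] to be Phred+33 encodable",
         call. = FALSE)
  }
  intToUtf8(as.integer(q) + 33L)
}
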