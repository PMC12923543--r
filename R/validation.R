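#' Extract chimeric alignments from SAM records
#'
#' A chimeric alignment is a primary alignment carrying an `SA` tag,
#' together with the supplementary alignments the tag lists. Each record is
#' converted into an ordered list of genomic intervals: the primary interval
#' (from `POS` and the reference-consuming CIGAR length) followed by one
#' interval per `SA` entry (`rname,pos,strand,CIGAR,mapQ,NM;`). Secondary
#' (0x100) and supplementary (0x800) records are ignored; unmapped records
#' and unparsable CIGAR/SA entries are skipped with a warning.
#'
#' @param sam Either a path to a SAM file or a character vector of SAM
#'   lines (header lines are ignored).
#' @return A named list, one element per chimeric read, each a tibble with
#'   columns `chrom`, `start`, `end` (0-based half-open) and `strand`.
#' @export
extract_chimeras <- function(sam) {
  lines <- if (length(sam) == 1L && file.exists(sam)) readLines(sam) else sam
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) { warning("malformed SAM record skipped"); next }
    flag <- suppressWarnings(as.integer(f[2L]))
    if (is.na(flag) || bitwAnd(flag, 0x4L) != 0L) next      # unmapped
    if (bitwAnd(flag, bitwOr(0x100L, 0x800L)) != 0L) next   # not primary
    sa <- grep("^SA:Z:", f[-(1:11)], value = TRUE)
    if (!length(sa)) next                                   # not chimeric
    span <- .cigar_ref_span(f[6L])
    if (is.na(span)) {
      warning("read '", f[1L], "': unparsable CIGAR, record skipped")
      next
    }
    pos0 <- as.integer(f[4L]) - 1L
    strand <- if (bitwAnd(flag, 0x10L) != 0L) "-" else "+"
    ivs <- list(tibble::tibble(chrom = f[3L], start = pos0,
                               end = pos0 + span, strand = strand))
    ok <- TRUE
    entries <- strsplit(sub("^SA:Z:", "", sa[1L]), ";", fixed = TRUE)[[1]]
    for (ent in entries[nzchar(entries)]) {
      p <- strsplit(ent, ",", fixed = TRUE)[[1]]
      sp <- if (length(p) >= 4L) .cigar_ref_span(p[4L]) else NA_integer_
      if (length(p) < 4L || is.na(sp) || is.na(suppressWarnings(as.integer(p[2L])))) {
        warning("read '", f[1L], "': unparsable SA entry, record skipped")
        ok <- FALSE
        break
      }
      s0 <- as.integer(p[2L]) - 1L
      ivs[[length(ivs) + 1L]] <- tibble::tibble(chrom = p[1L], start = s0,
                                                end = s0 + sp, strand = p[3L])
    }
    if (!ok) next
    out[[f[1L]]] <- do.call(rbind, ivs)
  }
  out
}

# reference-consuming length of a CIGAR string (M/D/N/=/X), NA if unparsable
.cigar_ref_span <- function(cigar) {
  if (is.na(cigar) || cigar == "*" ||
      !grepl("^([0-9]+[MIDNSHP=X])+$", cigar)) {
    return(NA_integer_)
  }
  as.integer(GenomicAlignments::cigarWidthAlongReferenceSpace(cigar))
}

#' Concordance of two chimeric alignments
#'
#' Two chimeric alignments are concordant when their interval lists can be
#' matched one-to-one such that matched intervals lie on the same chromosome
#' and strand with both endpoint offsets strictly below `tol` base pairs
#' (default 1000). Lists of different lengths are never concordant: a
#' two-part chimera cannot support a three-part one.
#'
#' @param a,b Interval tibbles as returned by [extract_chimeras()] (columns
#'   `chrom`, `start`, `end`, `strand`).
#' @param tol Maximum endpoint distance in bp (exclusive).
#' @return Logical scalar.
#' @export
is_concordant <- function(a, b, tol = 1000L) {
  na <- nrow(a)
  if (na != nrow(b)) return(FALSE)
  if (na == 0L) return(TRUE)
  ok <- outer(seq_len(na), seq_len(na), Vectorize(function(i, j) {
    a$chrom[i] == b$chrom[j] && a$strand[i] == b$strand[j] &&
      abs(a$start[i] - b$start[j]) < tol && abs(a$end[i] - b$end[j]) < tol
  }))
  .has_perfect_matching(ok)
}

# backtracking search for a perfect matching in a small boolean bipartite
# adjacency matrix (rows to columns)
.has_perfect_matching <- function(ok) {
  n <- nrow(ok)
  recurse <- function(i, used) {
    if (i > n) return(TRUE)
    for (j in which(ok[i, ] & !used)) {
      used[j] <- TRUE
      if (recurse(i + 1L, used)) return(TRUE)
      used[j] <- FALSE
    }
    FALSE
  }
  recurse(1L, logical(n))
}

#' Cross-platform support rate for chimeric alignments
#'
#' Counts each query chimera as supported when it is concordant (under
#' [is_concordant()]) with at least one reference chimera, and reports the
#' supported fraction — e.g. the proportion of dRNA-seq chimeric alignments
#' corroborated by a cDNA platform.
#'
#' @param query,reference Lists of chimera interval tibbles
#'   (see [extract_chimeras()]).
#' @param tol Concordance tolerance in bp.
#' @return A list of class `nc_support`: `n_query`, `n_supported`,
#'   `support_rate` (0 when the query set is empty), and a logical vector
#'   `supported` parallel to `query`.
#' @export
support_rate <- function(query, reference, tol = 1000L) {
  supported <- vapply(query, function(q) {
    any(vapply(reference, is_concordant, logical(1), a = q, tol = tol))
  }, logical(1))
  n_query <- length(query)
  n_supported <- sum(supported)
  structure(list(n_query = n_query, n_supported = n_supported,
                 support_rate = if (n_query > 0) n_supported / n_query else 0,
                 supported = supported),
            class = "nc_support")
}

#' @export
print.nc_support <- function(x, ...) {
  cat(sprintf("chimera support: %d / %d supported (rate %.4f)\n",
              x$n_supported, x$n_query, x$support_rate))
  invisible(x)
}

#' BLAT-style alignment identity
#'
#' The ratio of aligned (matched) bases to the total query length. Used to
#' show that excised adapter spans align poorly to the reference genome.
#'
#' @param match_length Number of query bases aligned to the reference.
#' @param sequence_length Total query length (> 0).
#' @return `match_length / sequence_length`, vectorized.
#' @export
blat_identity <- function(match_length, sequence_length) {
  if (any(sequence_length <= 0)) {
    stop("sequence_length must be positive", call. = FALSE)
  }
  stopifnot(all(match_length >= 0), all(match_length <= sequence_length))
  match_length / sequence_length
}
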