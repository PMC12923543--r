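#' @importFrom stats rnorm runif rlnorm rgeom
NULL

.BASES <- c("A", "C", "G", "T")
.BASE_RAW <- as.integer(charToRaw("ACGT"))

#' Default adapter template
#'
#' A fixed, arbitrary 70-mer standing in for the ~70 bp DNA sequencing
#' adapter of the ONT direct RNA kit. The detector learns whatever template
#' the generator is configured with; the proprietary adapter sequence is not
#' public, so the shipped default is synthetic. Supply your own template via
#' [adapter_model()] to emulate a specific kit.
#'
#' @return A 70-character DNA string.
#' @export
default_adapter_sequence <- function() {
  "GAGTCTTGCAACGTAGACCGTTAGCTAAGGCATCACGGTTCAGTAAGGCTCAGATCGTACGATTCCAGTG"
}

#' Describe the adapter corruption model
#'
#' Adapters in dRNA-seq reads are DNA base-called under an RNA model, so they
#' come out heavily corrupted and with low base qualities. The generator
#' emulates this by copying a fixed template and applying per-base
#' substitutions (always to a different base) and indels, then drawing low
#' Phred qualities.
#'
#' @param reference_sequence Adapter template (DNA string, length >= 13).
#' @param substitution_rate Per-base probability of substitution in `[0, 1]`.
#' @param indel_rate Per-base probability of an indel event in `[0, 1]`
#'   (split evenly between a deletion of the base and an insertion after it).
#' @param quality_mean,quality_sd Normal parameters (Phred units) for adapter
#'   base qualities; draws are rounded and clipped to `[0, 93]`.
#' @return An object of class `nc_adapter_model`.
#' @export
adapter_model <- function(reference_sequence = default_adapter_sequence(),
                          substitution_rate = 0.1,
                          indel_rate = 0.05,
                          quality_mean = 10,
                          quality_sd = 3) {
  reference_sequence <- toupper(reference_sequence)
  stopifnot(is.character(reference_sequence), length(reference_sequence) == 1L,
            nchar(reference_sequence) >= 13L,
            grepl("^[ACGT]+$", reference_sequence),
            substitution_rate >= 0, substitution_rate <= 1,
            indel_rate >= 0, indel_rate <= 1,
            quality_mean >= 0, quality_mean <= 93, quality_sd >= 0)
  structure(list(reference_sequence = reference_sequence,
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 quality_mean = quality_mean,
                 quality_sd = quality_sd),
            class = "nc_adapter_model")
}

#' Describe the transcript-body model
#'
#' Non-adapter read segments are emulated as random-composition sequences
#' with transcript-like lengths, ending in a polyA tail. Lengths below
#' `length_min` are clamped up so that every body survives the chopper's
#' minimum-segment filter by construction.
#'
#' @param length_distribution Named distribution for body lengths: either
#'   `list(name = "lognormal", meanlog =, sdlog =)` or
#'   `list(name = "fixed", value =)`.
#' @param base_probs Sampling probabilities for A, C, G, T (normalised
#'   internally).
#' @param quality_mean,quality_sd Normal parameters (Phred units) for body
#'   (and polyA) base qualities.
#' @param polya_distribution Named distribution for polyA tail lengths:
#'   `list(name = "geometric", mean =)` or `list(name = "fixed", value =)`.
#' @param length_min,length_max Clamp bounds for sampled body lengths.
#' @return An object of class `nc_body_model`.
#' @export
body_model <- function(length_distribution = list(name = "lognormal",
                                                  meanlog = log(700),
                                                  sdlog = 0.6),
                       base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       quality_mean = 12,
                       quality_sd = 4,
                       polya_distribution = list(name = "geometric", mean = 30),
                       length_min = 20L,
                       length_max = 20000L) {
  stopifnot(is.list(length_distribution), !is.null(length_distribution$name),
            is.list(polya_distribution), !is.null(polya_distribution$name),
            length(base_probs) == 4L, all(base_probs >= 0), sum(base_probs) > 0,
            quality_mean >= 0, quality_mean <= 93, quality_sd >= 0,
            length_min >= 20L, length_max >= length_min)
  structure(list(length_distribution = length_distribution,
                 base_probs = base_probs / sum(base_probs),
                 quality_mean = quality_mean,
                 quality_sd = quality_sd,
                 polya_distribution = polya_distribution,
                 length_min = as.integer(length_min),
                 length_max = as.integer(length_max)),
            class = "nc_body_model")
}

.sample_lengths <- function(dist, n, min_len = 1L, max_len = .Machine$integer.max) {
  x <- switch(dist$name,
    lognormal = floor(rlnorm(n, meanlog = dist$meanlog, sdlog = dist$sdlog)),
    geometric = rgeom(n, prob = 1 / (dist$mean + 1)),
    fixed = rep.int(dist$value, n),
    stop("unknown length distribution '", dist$name, "'", call. = FALSE))
  as.integer(pmin(pmax(x, min_len), max_len))
}

# Sample integer Phred scores and return them as one packed Phred+33 string.
.sample_qual_string <- function(n, mean, sd) {
  if (n == 0L) return("")
  q <- as.integer(round(rnorm(n, mean, sd)))
  q[q < 0L] <- 0L
  q[q > 93L] <- 93L
  rawToChar(as.raw(q + 33L))
}

# n corrupted copies of an adapter template. Returns one packed string plus
# per-copy lengths; copy i is substring(seq, cumsum-style offsets).
.corrupt_copies <- function(template, n, sub_rate, indel_rate) {
  codes <- match(strsplit(template, "", fixed = TRUE)[[1]], .BASES)
  L <- length(codes)
  base <- rep.int(codes, n)
  nL <- length(base)
  sub <- runif(nL) < sub_rate
  if (any(sub)) {
    base[sub] <- ((base[sub] - 1L + sample.int(3L, sum(sub), replace = TRUE)) %% 4L) + 1L
  }
  del <- runif(nL) < indel_rate / 2
  ins <- runif(nL) < indel_rate / 2
  ins_base <- sample.int(4L, nL, replace = TRUE)
  all_codes <- as.vector(rbind(base, ins_base))
  keep <- as.vector(rbind(!del, ins))
  out <- all_codes[keep]
  n_del <- colSums(matrix(del, nrow = L))
  n_ins <- colSums(matrix(ins, nrow = L))
  lens <- as.integer(L - n_del + n_ins)
  list(packed = rawToChar(as.raw(.BASE_RAW[out])), lengths = lens)
}

.unpack <- function(packed, lengths) {
  ends <- cumsum(as.numeric(lengths))
  starts <- ends - lengths + 1
  substring(packed, starts, ends)
}

#' Sample corrupted adapter copies
#'
#' Draws `n` independent corrupted copies of the adapter template together
#' with low-quality Phred scores, as they would appear inside a base-called
#' dRNA-seq read.
#'
#' @param model An [adapter_model()].
#' @param n Number of copies.
#' @return A tibble with columns `sequence` and `quality` (Phred+33 string).
#' @export
sample_adapter <- function(model, n = 1L) {
  stopifnot(inherits(model, "nc_adapter_model"), n >= 1L)
  cc <- .corrupt_copies(model$reference_sequence, n,
                        model$substitution_rate, model$indel_rate)
  qual_packed <- .sample_qual_string(sum(cc$lengths),
                                     model$quality_mean, model$quality_sd)
  tibble::tibble(sequence = .unpack(cc$packed, cc$lengths),
                 quality = .unpack(qual_packed, cc$lengths))
}

# Vectorised generation of n reads of one category.
# Returns tibble(sequence, quality, adapter_start, adapter_end) where the
# adapter interval is 0-based half-open (NA for negatives).
.generate_category <- function(n, category, bodies, adapters) {
  stopifnot(category %in% c("negative", "end3", "internal"))
  two_bodies <- category == "internal"
  has_adapter <- category != "negative"

  len1 <- .sample_lengths(bodies$length_distribution, n,
                          bodies$length_min, bodies$length_max)
  lenA <- .sample_lengths(bodies$polya_distribution, n, 0L, 5000L)
  body_total <- sum(as.numeric(len1))
  len2 <- if (two_bodies) {
    l2 <- .sample_lengths(bodies$length_distribution, n,
                          bodies$length_min, bodies$length_max)
    body_total <- body_total + sum(as.numeric(l2))
    l2
  } else integer(n)

  n_body_bases <- body_total + sum(as.numeric(lenA))
  body_codes <- sample.int(4L, n_body_bases, replace = TRUE,
                           prob = bodies$base_probs)
  # carve body1 / body2 strings out of one packed pool; polyA is literal A
  pool <- rawToChar(as.raw(.BASE_RAW[body_codes]))
  off <- cumsum(as.numeric(len1))
  body1 <- substring(pool, off - len1 + 1, off)
  used <- sum(as.numeric(len1))
  body2 <- if (two_bodies) {
    off2 <- used + cumsum(as.numeric(len2))
    substring(pool, off2 - len2 + 1, off2)
  } else character(n)
  polya <- strrep("A", lenA)

  q_body <- .sample_qual_string(n_body_bases, bodies$quality_mean, bodies$quality_sd)
  qoff <- cumsum(as.numeric(len1 + lenA))
  qual1 <- substring(q_body, qoff - (len1 + lenA) + 1, qoff)  # body1 + polyA quals
  qused <- sum(as.numeric(len1 + lenA))
  qual2 <- if (two_bodies) {
    qoff2 <- qused + cumsum(as.numeric(len2))
    substring(q_body, qoff2 - len2 + 1, qoff2)
  } else character(n)

  if (has_adapter) {
    ad <- sample_adapter(adapters, n)
    lenAd <- nchar(ad$sequence)
    sequence <- if (two_bodies) {
      paste0(body1, polya, ad$sequence, body2)
    } else {
      paste0(body1, polya, ad$sequence)
    }
    quality <- if (two_bodies) paste0(qual1, ad$quality, qual2)
               else paste0(qual1, ad$quality)
    adapter_start <- len1 + lenA
    adapter_end <- adapter_start + lenAd
  } else {
    sequence <- paste0(body1, polya)
    quality <- qual1
    adapter_start <- rep(NA_integer_, n)
    adapter_end <- rep(NA_integer_, n)
  }
  tibble::tibble(sequence = sequence, quality = quality,
                 category = category,
                 adapter_start = as.integer(adapter_start),
                 adapter_end = as.integer(adapter_end))
}

#' Build a single labeled read
#'
#' Constructs one synthetic read of the requested category:
#' `negative` = body + polyA (no adapter), `end3` = body + polyA + adapter,
#' `internal` = body1 + polyA + adapter + body2. PolyA bases are biological
#' (label 0); only the inserted adapter span is labeled 1.
#'
#' @param bodies A [body_model()].
#' @param adapters An [adapter_model()].
#' @param category One of `"negative"`, `"end3"`, `"internal"`.
#' @param read_id Read identifier.
#' @return A one-row tibble with columns `read_id`, `sequence`, `quality`,
#'   `category`, `adapter_start`, `adapter_end` (0-based half-open; NA for
#'   negatives) and a list column `labels` holding the per-base 0/1 vector.
#' @export
build_labeled_read <- function(bodies = body_model(),
                               adapters = adapter_model(),
                               category = c("internal", "end3", "negative"),
                               read_id = "read_1") {
  category <- match.arg(category)
  out <- .generate_category(1L, category, bodies, adapters)
  out <- tibble::add_column(out, read_id = read_id, .before = 1L)
  out$labels <- list(labels_from_intervals(nchar(out$sequence),
                                           out$adapter_start, out$adapter_end))
  out
}

#' Per-base 0/1 labels from adapter intervals
#'
#' @param len Read length.
#' @param starts,ends Parallel vectors of 0-based half-open adapter intervals
#'   (NAs ignored).
#' @return An integer vector of length `len` with 1 inside adapter spans.
#' @export
labels_from_intervals <- function(len, starts, ends) {
  lab <- integer(len)
  keep <- !is.na(starts) & !is.na(ends)
  for (i in which(keep)) {
    if (ends[i] > starts[i]) lab[(starts[i] + 1L):ends[i]] <- 1L
  }
  lab
}

# Largest-remainder apportionment of n into parts proportional to w.
.apportion <- function(n, w) {
  stopifnot(all(w >= 0), sum(w) > 0)
  exact <- n * w / sum(w)
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a stratified labeled dataset
#'
#' Generates `n_total` synthetic reads with adapter-bearing and adapter-free
#' reads in `pos_neg_ratio`, internal and 3'-end adapters in
#' `internal_end3_ratio` among positives, and splits them into train /
#' validation / test partitions by stratified sampling in `split_ratios`.
#' All ratio-to-count conversions use largest-remainder rounding, so e.g.
#' 600,000 reads at 8:1:1 give exactly 480,000 / 60,000 / 60,000.
#'
#' @param n_total Total number of reads. If not divisible by
#'   `sum(split_ratios)` it is truncated down to the nearest multiple (with a
#'   message).
#' @param pos_neg_ratio Length-2 ratio of adapter-bearing to adapter-free
#'   reads (default 9:1).
#' @param internal_end3_ratio Length-2 ratio of internal to 3'-end adapters
#'   among positives (default 1:1).
#' @param split_ratios Length-3 train/validation/test ratio (default 8:1:1).
#' @param seed Integer seed; the run is fully reproducible from it.
#' @param bodies,adapters Generator component models.
#' @param chunk_size Reads generated per internal chunk (memory knob only).
#' @return A list with tibbles `train`, `val`, `test`, each with columns
#'   `read_id`, `sequence`, `quality`, `category`, `adapter_start`,
#'   `adapter_end`.
#' @export
generate_dataset <- function(n_total,
                             pos_neg_ratio = c(9, 1),
                             internal_end3_ratio = c(1, 1),
                             split_ratios = c(8, 1, 1),
                             seed = 1L,
                             bodies = body_model(),
                             adapters = adapter_model(),
                             chunk_size = 50000L) {
  stopifnot(length(pos_neg_ratio) == 2L, length(internal_end3_ratio) == 2L,
            length(split_ratios) == 3L, n_total >= 1)
  if (sum(pos_neg_ratio) <= 0 || sum(split_ratios) <= 0 ||
      sum(internal_end3_ratio) <= 0 || any(pos_neg_ratio < 0) ||
      any(internal_end3_ratio < 0) || any(split_ratios < 0)) {
    stop("ratios must be non-negative with a positive sum", call. = FALSE)
  }
  if (n_total %% sum(split_ratios) != 0) {
    n_new <- (n_total %/% sum(split_ratios)) * sum(split_ratios)
    message("n_total truncated from ", n_total, " to ", n_new,
            " (nearest multiple of sum(split_ratios))")
    n_total <- n_new
  }
  if (n_total < 1) stop("n_total too small for the requested ratios", call. = FALSE)
  set.seed(seed)

  pn <- .apportion(n_total, pos_neg_ratio)
  ie <- .apportion(pn[1L], internal_end3_ratio)
  n_cat <- c(internal = ie[1L], end3 = ie[2L], negative = pn[2L])

  parts <- list()
  for (cat in names(n_cat)) {
    n <- n_cat[[cat]]
    if (n == 0L) next
    done <- 0L
    while (done < n) {
      k <- min(chunk_size, n - done)
      parts[[length(parts) + 1L]] <- .generate_category(k, cat, bodies, adapters)
      done <- done + k
    }
  }
  all <- do.call(rbind, parts)
  all <- tibble::add_column(
    all, read_id = sprintf("sim_%07d", seq_len(nrow(all))), .before = 1L)

  # stratified split: apportion each category across partitions, assign by
  # a seeded permutation within category
  part_label <- character(nrow(all))
  for (cat in names(n_cat)) {
    idx <- which(all$category == cat)
    if (!length(idx)) next
    sizes <- .apportion(length(idx), split_ratios)
    idx <- sample(idx)
    part_label[idx] <- rep(c("train", "val", "test"), times = sizes)
  }
  out <- lapply(c(train = "train", val = "val", test = "test"), function(p) {
    sub <- all[part_label == p, , drop = FALSE]
    sub[sample.int(nrow(sub)), , drop = FALSE]
  })
  out
}

#' Write a labeled dataset partition to FASTQ plus a truth BED sidecar
#'
#' @param reads A labeled tibble as produced by [generate_dataset()].
#' @param fastq Path for the FASTQ output.
#' @param bed Path for the BED sidecar of truth adapter intervals (0-based
#'   half-open; the name column carries the read category). Adapter-free
#'   reads have no BED row.
#' @return Invisibly, the number of reads written.
#' @export
write_labeled_dataset <- function(reads, fastq, bed) {
  write_fastq(reads, fastq)
  pos <- reads[!is.na(reads$adapter_start), , drop = FALSE]
  lines <- if (nrow(pos)) {
    paste(pos$read_id, pos$adapter_start, pos$adapter_end, pos$category,
          sep = "\t")
  } else character()
  writeLines(lines, bed)
  invisible(nrow(reads))
}

#' Read a truth/prediction BED sidecar
#'
#' @param path BED path (columns: read_id, start, end, optional name).
#' @return A tibble with columns `read_id`, `start`, `end`, `name`.
#' @export
read_intervals_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tibble::tibble(read_id = character(), start = integer(),
                          end = integer(), name = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) stop("BED line with fewer than 3 fields", call. = FALSE)
  tibble::tibble(
    read_id = vapply(parts, `[[`, "", 1L),
    start = as.integer(vapply(parts, `[[`, "", 2L)),
    end = as.integer(vapply(parts, `[[`, "", 3L)),
    name = ifelse(nf >= 4L, vapply(parts, function(p) if (length(p) >= 4L) p[[4L]] else NA_character_, ""), NA_character_))
}

#' Build a read containing several adapters
#'
#' Chains `n_adapters` corrupted adapter copies, each preceded by a body and
#' polyA tail and followed by a final body:
#' `body + polyA + adapter + ... + body`. The default generator inserts at
#' most one adapter per read; this constructor exists to exercise the
#' chopper's multi-adapter rules.
#'
#' @param bodies A [body_model()].
#' @param adapters An [adapter_model()].
#' @param n_adapters Number of adapter insertions (>= 1).
#' @param read_id Read identifier.
#' @return A one-row tibble with `read_id`, `sequence`, `quality`, a
#'   `labels` list column, and a `truth_intervals` list column (matrix with
#'   `start`/`end` columns, 0-based half-open).
#' @export
build_multiadapter_read <- function(bodies = body_model(),
                                    adapters = adapter_model(),
                                    n_adapters = 2L,
                                    read_id = "read_1") {
  stopifnot(n_adapters >= 1L)
  n_bodies <- n_adapters + 1L
  blen <- .sample_lengths(bodies$length_distribution, n_bodies,
                          bodies$length_min, bodies$length_max)
  alen <- .sample_lengths(bodies$polya_distribution, n_adapters, 0L, 5000L)
  body_codes <- sample.int(4L, sum(blen), replace = TRUE,
                           prob = bodies$base_probs)
  pool <- rawToChar(as.raw(.BASE_RAW[body_codes]))
  off <- cumsum(as.numeric(blen))
  body <- substring(pool, off - blen + 1, off)
  bq_packed <- .sample_qual_string(sum(blen) + sum(alen),
                                   bodies$quality_mean, bodies$quality_sd)
  qoff <- cumsum(as.numeric(c(blen[-n_bodies] + alen, blen[n_bodies])))
  bqual <- substring(bq_packed, qoff - c(blen[-n_bodies] + alen,
                                         blen[n_bodies]) + 1, qoff)
  ad <- sample_adapter(adapters, n_adapters)

  seq_parts <- character(0); qual_parts <- character(0)
  starts <- integer(n_adapters); ends <- integer(n_adapters)
  pos <- 0L
  for (i in seq_len(n_adapters)) {
    seq_parts <- c(seq_parts, body[i], strrep("A", alen[i]), ad$sequence[i])
    qual_parts <- c(qual_parts, bqual[i], ad$quality[i])
    starts[i] <- pos + blen[i] + alen[i]
    ends[i] <- starts[i] + nchar(ad$sequence[i])
    pos <- ends[i]
  }
  seq_parts <- c(seq_parts, body[n_bodies])
  qual_parts <- c(qual_parts, bqual[n_bodies])
  sequence <- paste(seq_parts, collapse = "")
  quality <- paste(qual_parts, collapse = "")
  iv <- cbind(start = starts, end = ends)
  lab <- integer(nchar(sequence))
  for (i in seq_len(n_adapters)) lab[(starts[i] + 1L):ends[i]] <- 1L
  tibble::tibble(read_id = read_id, sequence = sequence, quality = quality,
                 labels = list(lab), truth_intervals = list(iv))
}
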