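.VOCAB <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)
.PAD_ID <- 6L

#' Tokenize a nucleotide sequence at single-base resolution
#'
#' Each nucleotide is one token: A, C, G, T and N form the vocabulary
#' (U is mapped to T, consistent with FASTQ ingest). Padding is applied only
#' at batch assembly, never here.
#'
#' @param sequence A single nucleotide string.
#' @return An integer vector of token ids (empty for the empty string).
#' @export
tokenize <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) return(integer())
  s <- chartr("uU", "tT", sequence)
  ids <- .VOCAB[strsplit(toupper(s), "", fixed = TRUE)[[1]]]
  if (anyNA(ids)) {
    bad <- which(is.na(ids))[1L]
    stop("invalid base at position ", bad, call. = FALSE)
  }
  unname(ids)
}

#' Tokenize a collection of reads, excluding over-long sequences
#'
#' Reads longer than `max_input_length` are excluded with a warning naming
#' how many were dropped, mirroring the classifier's input-length contract.
#'
#' @param reads A read tibble (columns `read_id`, `sequence`, `quality`).
#' @param max_input_length Maximum accepted read length (default 32770).
#' @return The input tibble restricted to accepted reads, with list columns
#'   `tokens` (integer ids) and `qnorm` (z-scored qualities) added.
#' @export
tokenize_reads <- function(reads, max_input_length = 32770L) {
  len <- nchar(reads$sequence)
  keep <- len <= max_input_length
  if (any(!keep)) {
    warning(sum(!keep), " read(s) longer than ", max_input_length,
            " nt excluded from analysis", call. = FALSE)
    reads <- reads[keep, , drop = FALSE]
  }
  reads$tokens <- lapply(reads$sequence, tokenize)
  reads$qnorm <- lapply(qual_to_int(reads$quality), normalize_qualities)
  reads
}

#' Z-score standardize per-base quality scores
#'
#' Standardization is per read (population standard deviation), so inference
#' needs no dataset-level statistics and is robust to flow-cell-wide quality
#' shifts. A constant input maps to all zeros.
#'
#' @param qualities Integer (or numeric) vector of Phred scores.
#' @return A numeric vector with mean 0 and population SD 1 (or all zeros).
#' @export
normalize_qualities <- function(qualities) {
  n <- length(qualities)
  if (n == 0L) return(numeric())
  m <- mean(qualities)
  s <- sqrt(mean((qualities - m)^2))
  if (s == 0) return(numeric(n))
  (qualities - m) / s
}

#' Classifier architecture configuration
#'
#' The backbone is a stack of gated, dilated 1-D convolutions with residual
#' connections: attention-free, with a receptive field that grows
#' exponentially with depth, producing a per-position feature vector of
#' dimension `embed_dim`. Base qualities enter through a quality block (two
#' ReLU MLPs with residual connections) whose output is added to the token
#' embeddings; disabling it (`quality_block = FALSE`) yields the
#' sequence-only ablated variant.
#'
#' @param embed_dim Feature dimension per position (default 256).
#' @param quality_hidden_dim Hidden width of the quality block (default 256).
#' @param backbone_layers Number of gated conv layers; layer `l` uses
#'   dilation `dilation_base^(l-1)`.
#' @param kernel_width Odd convolution kernel width.
#' @param dilation_base Dilation growth factor per layer; defaults to
#'   `kernel_width`, which tiles the receptive field without holes.
#' @param max_input_length Longest accepted read (default 32770 nt).
#' @param quality_block Whether the quality pathway is active.
#' @param seed Seed for weight initialization.
#' @return An object of class `nc_model_config`.
#' @export
model_config <- function(embed_dim = 256L,
                         quality_hidden_dim = 256L,
                         backbone_layers = 4L,
                         kernel_width = 5L,
                         dilation_base = NULL,
                         max_input_length = 32770L,
                         quality_block = TRUE,
                         seed = 1L) {
  if (is.null(dilation_base)) dilation_base <- kernel_width
  stopifnot(embed_dim > 0, quality_hidden_dim > 0, backbone_layers > 0,
            kernel_width > 0, kernel_width %% 2L == 1L, max_input_length > 0,
            dilation_base >= 1)
  structure(list(embed_dim = as.integer(embed_dim),
                 quality_hidden_dim = as.integer(quality_hidden_dim),
                 backbone_layers = as.integer(backbone_layers),
                 kernel_width = as.integer(kernel_width),
                 dilation_base = as.integer(dilation_base),
                 max_input_length = as.integer(max_input_length),
                 quality_block = isTRUE(quality_block),
                 seed = as.integer(seed)),
            class = "nc_model_config")
}

#' Desk-scale classifier configuration
#'
#' A reduced configuration (32-dimensional features, 3 layers) that trains in
#' minutes on one CPU core while keeping the full architecture: embeddings,
#' quality block, gated dilated convolutions, softmax head.
#'
#' @param ... Overrides passed on to [model_config()].
#' @return An `nc_model_config`.
#' @export
small_model_config <- function(...) {
  args <- list(embed_dim = 32L, quality_hidden_dim = 32L,
               backbone_layers = 3L, kernel_width = 3L)
  args[names(list(...))] <- list(...)
  do.call(model_config, args)
}

.rmat <- function(nr, nc, sd) matrix(rnorm(nr * nc, sd = sd), nr, nc)

#' Initialize an untrained classifier
#'
#' @param config An [model_config()].
#' @return An object of class `nc_model` (configuration plus weights).
#' @export
init_model <- function(config = model_config()) {
  stopifnot(inherits(config, "nc_model_config"))
  set.seed(config$seed)
  D <- config$embed_dim; H <- config$quality_hidden_dim
  K <- config$kernel_width; L <- config$backbone_layers
  p <- list()
  p$EMB <- .rmat(.PAD_ID, D, 0.5)
  if (config$quality_block) {
    p$q_w1 <- rnorm(H, sd = 0.5); p$q_b1 <- numeric(H)
    p$q_W2 <- .rmat(H, H, sqrt(2 / H)); p$q_b2 <- numeric(H)
    p$q_W3 <- .rmat(H, D, sqrt(1 / H)); p$q_b3 <- numeric(D)
  }
  for (l in seq_len(L)) {
    # fused filter+gate conv weights: (K*D) x 2D, filter in columns 1..D
    p[[sprintf("Wfg_%d", l)]] <- .rmat(K * D, 2L * D, sqrt(1 / (K * D)))
    p[[sprintf("bf_%d", l)]] <- numeric(D)
    p[[sprintf("bg_%d", l)]] <- rep(1, D)  # gates start mostly open
  }
  p$Wh1 <- .rmat(D, D, sqrt(2 / D)); p$bh1 <- numeric(D)
  p$Wh2 <- .rmat(D, 2L, sqrt(1 / D)); p$bh2 <- numeric(2L)
  structure(list(config = config, params = p), class = "nc_model")
}

#' Number of trainable parameters
#'
#' @param model An `nc_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "nc_model"))
  sum(vapply(model$params, length, integer(1)))
}

# ---- batched forward pass ------------------------------------------------
# Layout: a batch of B reads padded to Lmax is flattened position-major:
# row (t-1)*B + b holds position t of read b. Shifting rows by s*B moves all
# reads s positions at once and never crosses read boundaries.

# Assemble a position-major batch from token/qnorm list columns. Lmax is
# rounded up to a multiple of `pad_multiple` so batch matrices recur in a
# small set of shapes and the allocator can recycle them across steps.
.make_batch <- function(tokens, qnorm, labels = NULL, pad_multiple = 128L) {
  B <- length(tokens)
  lens <- lengths(tokens)
  Lmax <- max(lens, 1L)
  Lmax <- as.integer(ceiling(Lmax / pad_multiple) * pad_multiple)
  tok <- matrix(.PAD_ID, B, Lmax)
  qv <- matrix(0, B, Lmax)
  lab <- matrix(0, B, Lmax)
  for (b in seq_len(B)) {
    n <- lens[b]
    if (n > 0L) {
      tok[b, seq_len(n)] <- tokens[[b]]
      qv[b, seq_len(n)] <- qnorm[[b]]
      if (!is.null(labels)) lab[b, seq_len(n)] <- labels[[b]]
    }
  }
  mask <- as.numeric(as.vector(tok) != .PAD_ID)
  # weight: 1/(N_b * B) per real token of read b (read mean then batch mean)
  wt <- mask / (rep.int(pmax(lens, 1L), Lmax) * B)
  list(tokens = as.vector(tok), qv = as.vector(qv),
       labels = if (is.null(labels)) NULL else as.vector(lab),
       mask = mask, padidx = which(mask == 0), wt = wt,
       B = B, Lmax = Lmax, lens = lens)
}

# batches of row indices: consecutive runs of `ord` capped both by reads per
# batch and by padded matrix rows (B * Lmax), so one long read cannot blow
# up the padding of a whole batch
.pack_runs <- function(ord, lens, batch_size, row_budget) {
  out <- list()
  cur <- integer(0); maxlen <- 0L
  for (i in ord) {
    newmax <- max(maxlen, lens[i])
    if (length(cur) &&
        (length(cur) >= batch_size ||
         (length(cur) + 1L) * newmax > row_budget)) {
      out[[length(out) + 1L]] <- cur
      cur <- integer(0); newmax <- lens[i]
    }
    cur <- c(cur, i); maxlen <- newmax
  }
  if (length(cur)) out[[length(out) + 1L]] <- cur
  out
}

#' Per-base adapter probabilities and labels for a set of reads
#'
#' Runs the classifier forward over reads in length-sorted mini-batches and
#' returns, per read, the per-base adapter probability and its thresholded
#' 0/1 label (adapter iff `p_adapter > 0.5`, i.e. the argmax of the two-class
#' softmax).
#'
#' @param model A trained (or freshly initialized) `nc_model`.
#' @param reads A read tibble; rows longer than the model's
#'   `max_input_length` are excluded with a warning.
#' @param batch_size Reads per forward batch.
#' @param return_probabilities Keep the numeric probability track.
#' @return The accepted reads with list columns `pred_labels` (integer 0/1)
#'   and, optionally, `prob_adapter` added.
#' @export
predict_reads <- function(model, reads, batch_size = 64L,
                          return_probabilities = FALSE) {
  stopifnot(inherits(model, "nc_model"))
  if (nrow(reads) == 0L) {
    reads$pred_labels <- list()
    if (return_probabilities) reads$prob_adapter <- list()
    return(reads)
  }
  if (!("tokens" %in% names(reads))) reads <- tokenize_reads(reads, model$config$max_input_length)
  n <- nrow(reads)
  lens <- nchar(reads$sequence)
  ord <- order(lens)
  preds <- vector("list", n)
  probs <- if (return_probabilities) vector("list", n) else NULL
  for (idx in .pack_runs(ord, lens, batch_size, row_budget = 200000L)) {
    batch <- .make_batch(reads$tokens[idx], reads$qnorm[idx])
    pa <- .nc_forward_cpp(model$params, unclass(model$config),
                          batch$tokens, batch$qv, batch$B)
    pa <- matrix(pa, batch$B, batch$Lmax)
    for (j in seq_along(idx)) {
      len <- batch$lens[j]
      pj <- if (len > 0L) pa[j, seq_len(len)] else numeric()
      preds[[idx[j]]] <- as.integer(pj > 0.5)
      if (return_probabilities) probs[[idx[j]]] <- pj
    }
  }
  reads$pred_labels <- preds
  if (return_probabilities) reads$prob_adapter <- probs
  reads
}

#' Save / load a classifier checkpoint
#'
#' The checkpoint is self-describing: it stores the architecture
#' configuration together with the weights.
#'
#' @param model An `nc_model`.
#' @param path Checkpoint path.
#' @return `load_model` returns the restored `nc_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "nc_model"))
  saveRDS(list(config = unclass(model$config), params = model$params,
               package = "nanochopper", format = 1L), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  stopifnot(identical(x$package, "nanochopper"))
  cfg <- do.call(model_config, x$config[setdiff(names(x$config), NULL)])
  structure(list(config = cfg, params = x$params), class = "nc_model")
}
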