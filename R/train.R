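#' Training hyperparameter configuration
#'
#' Defaults follow the classifier's training contract: Adam with
#' `beta1 = 0.9`, `beta2 = 0.999`, initial learning rate `2e-5`, batch size
#' 64 reads, validation every 20,000 steps, up to 60 epochs with early
#' stopping, checkpoint selection by highest validation F1, and a
#' reduce-on-plateau schedule driven by validation loss. The default
#' learning rate suits fine-tuning a converged model; training the compact
#' backbone from random weights needs a larger rate (the desk-scale runs in
#' this package use `1e-2`).
#'
#' @param batch_size Reads per mini-batch.
#' @param beta1,beta2 Adam moment decay rates.
#' @param initial_lr Initial learning rate.
#' @param plateau_patience Validations without loss improvement before the
#'   learning rate is multiplied by `plateau_factor`.
#' @param plateau_factor Learning-rate decay factor.
#' @param val_interval_steps Validate every this many optimizer steps
#'   (validation also runs at every epoch end).
#' @param max_epochs Maximum passes over the training set.
#' @param max_steps Optional hard cap on optimizer steps.
#' @param early_stop_patience Validations without F1 improvement before
#'   training stops.
#' @param early_stopping_metric Metric used for checkpoint selection and
#'   early stopping (only `"F1"` is supported).
#' @param row_budget Cap on padded batch rows (reads x padded length); long
#'   reads get smaller batches, bounding per-step memory.
#' @param crop_length When set, each epoch trains on one random crop of at
#'   most this many bases per read instead of the full read (random offsets,
#'   so successive epochs cover different windows). Crops of adapter-bearing
#'   reads overlap the adapter with probability `crop_positive_prob`.
#'   Validation, checkpoint selection and all downstream evaluation always
#'   use full reads. `NULL` trains on whole reads.
#' @param crop_positive_prob Probability that the crop of an adapter-bearing
#'   read is drawn from windows overlapping the adapter.
#' @return An object of class `nc_train_config`.
#' @export
train_config <- function(batch_size = 64L,
                         beta1 = 0.9,
                         beta2 = 0.999,
                         initial_lr = 2e-5,
                         plateau_patience = 5L,
                         plateau_factor = 0.5,
                         val_interval_steps = 20000L,
                         max_epochs = 60L,
                         max_steps = Inf,
                         early_stop_patience = 10L,
                         early_stopping_metric = "F1",
                         row_budget = 120000L,
                         crop_length = NULL,
                         crop_positive_prob = 0.5) {
  stopifnot(batch_size >= 1, initial_lr > 0,
            beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            plateau_patience >= 1, plateau_factor > 0, plateau_factor < 1,
            val_interval_steps >= 1, max_epochs >= 1,
            identical(early_stopping_metric, "F1"))
  structure(list(batch_size = as.integer(batch_size), beta1 = beta1,
                 beta2 = beta2, initial_lr = initial_lr,
                 plateau_patience = as.integer(plateau_patience),
                 plateau_factor = plateau_factor,
                 val_interval_steps = as.integer(val_interval_steps),
                 max_epochs = as.integer(max_epochs), max_steps = max_steps,
                 early_stop_patience = as.integer(early_stop_patience),
                 early_stopping_metric = early_stopping_metric,
                 row_budget = as.integer(row_budget),
                 crop_length = if (is.null(crop_length)) NULL
                               else as.integer(crop_length),
                 crop_positive_prob = crop_positive_prob),
            class = "nc_train_config")
}

#' Binary cross-entropy loss over reads
#'
#' The loss for one read is the mean over its bases of
#' `-[y log(p) + (1-y) log(1-p)]` with `p` the predicted adapter
#' probability; the batch loss is the unweighted mean of the per-read
#' losses (reads contribute equally regardless of length). Probabilities are
#' clipped to `[1e-7, 1 - 1e-7]`.
#'
#' @param probabilities List of per-base adapter-probability vectors, one
#'   per read.
#' @param labels List of matching 0/1 truth vectors.
#' @return The scalar batch loss.
#' @export
bce_loss <- function(probabilities, labels) {
  stopifnot(length(probabilities) == length(labels))
  eps <- 1e-7
  per_read <- mapply(function(p, y) {
    stopifnot(length(p) == length(y))
    p <- pmin(pmax(p, eps), 1 - eps)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }, probabilities, labels)
  mean(per_read)
}

#' Pooled per-base classification metrics
#'
#' Confusion counts are pooled over every base position of every read
#' (class 1 = adapter), and precision, recall, F1 and accuracy follow from
#' them. Any metric with a zero denominator is defined as 0.
#'
#' @param pred_labels List of predicted 0/1 vectors.
#' @param truth_labels List of matching truth 0/1 vectors.
#' @return An object of class `nc_eval`: a list with `tp`, `fp`, `fn`, `tn`,
#'   `precision`, `recall`, `f1`, `accuracy`.
#' @export
evaluate_predictions <- function(pred_labels, truth_labels) {
  stopifnot(length(pred_labels) == length(truth_labels))
  if (!all(lengths(pred_labels) == lengths(truth_labels))) {
    bad <- which(lengths(pred_labels) != lengths(truth_labels))[1L]
    stop("read ", bad, ": prediction and truth lengths differ", call. = FALSE)
  }
  p <- unlist(pred_labels, use.names = FALSE)
  y <- unlist(truth_labels, use.names = FALSE)
  tp <- sum(p == 1L & y == 1L); fp <- sum(p == 1L & y == 0L)
  fn <- sum(p == 0L & y == 1L); tn <- sum(p == 0L & y == 0L)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  accuracy <- safe_div(tp + tn, tp + fp + fn + tn)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, precision = precision,
                 recall = recall, f1 = f1, accuracy = accuracy),
            class = "nc_eval")
}

#' @export
print.nc_eval <- function(x, ...) {
  cat(sprintf(
    "per-base evaluation: TP=%d FP=%d FN=%d TN=%d\n  precision=%.4f recall=%.4f F1=%.4f accuracy=%.4f\n",
    x$tp, x$fp, x$fn, x$tn, x$precision, x$recall, x$f1, x$accuracy))
  invisible(x)
}

.adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

#' Per-base truth labels for a labeled read table
#'
#' Returns the list of per-base 0/1 truth vectors for a tibble that carries
#' either a `labels` list column or `adapter_start`/`adapter_end` interval
#' columns (as produced by [generate_dataset()]).
#'
#' @param reads A labeled read tibble.
#' @return A list of integer 0/1 vectors, one per read.
#' @export
truth_labels <- function(reads) {
  if ("labels" %in% names(reads)) return(reads[["labels"]])
  stopifnot("adapter_start" %in% names(reads))
  mapply(function(len, s, e) labels_from_intervals(len, s, e),
         nchar(reads$sequence), reads$adapter_start, reads$adapter_end,
         SIMPLIFY = FALSE)
}

# length-sorted batches of row indices; shuffling sorts within pools of
# consecutive batches so batches stay length-homogeneous but vary by epoch
.index_batches <- function(lens, batch_size, shuffle = FALSE,
                           pool_factor = 20L, row_budget = 200000L) {
  n <- length(lens)
  if (!shuffle) {
    return(.pack_runs(order(lens), lens, batch_size, row_budget))
  }
  ord <- sample.int(n)
  pool <- batch_size * pool_factor
  out <- list()
  for (s in seq(1L, n, by = pool)) {
    chunk <- ord[s:min(s + pool - 1L, n)]
    chunk <- chunk[order(lens[chunk])]
    out <- c(out, .pack_runs(chunk, lens, batch_size, row_budget))
  }
  out[sample.int(length(out))]
}

.validate <- function(model, val, val_batches) {
  losses <- numeric(length(val_batches))
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(val_batches)) {
    idx <- val_batches[[i]]
    batch <- .make_batch(val$tokens[idx], val$qnorm[idx], val$labels[idx])
    pa <- .nc_forward_cpp(model$params, unclass(model$config),
                          batch$tokens, batch$qv, batch$B)
    eps <- 1e-7
    pc <- pmin(pmax(pa, eps), 1 - eps)
    losses[i] <- -sum(batch$wt * (batch$labels * log(pc) +
                                    (1 - batch$labels) * log(1 - pc)))
    pl <- as.integer(pa > 0.5) * (batch$mask == 1)
    yv <- batch$labels; mk <- batch$mask == 1
    tp <- tp + sum(pl == 1L & yv == 1L & mk)
    fp <- fp + sum(pl == 1L & yv == 0L & mk)
    fn <- fn + sum(pl == 0L & yv == 1L & mk)
    tn <- tn + sum(pl == 0L & yv == 0L & mk)
  }
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  list(loss = mean(losses), f1 = f1)
}

.crop_read <- function(tokens, qnorm, labels, crop, p_pos) {
  n <- length(tokens)
  if (n <= crop) return(list(tokens = tokens, qnorm = qnorm, labels = labels))
  pos <- which(labels == 1L)
  lo <- 0L; hi <- n - crop
  if (length(pos) && runif(1) < p_pos) {
    # any start for which the window [start+1, start+crop] hits the run
    lo <- max(0L, pos[1L] - crop); hi <- min(hi, pos[length(pos)] - 1L)
    if (hi < lo) { lo <- 0L; hi <- n - crop }
  }
  s <- lo + sample.int(hi - lo + 1L, 1L) - 1L
  idx <- (s + 1L):(s + crop)
  list(tokens = tokens[idx], qnorm = qnorm[idx], labels = labels[idx])
}

#' Train the per-base adapter classifier
#'
#' Mini-batch Adam training of the gated-convolution classifier with
#' read-mean binary cross-entropy loss, periodic validation, a
#' reduce-on-plateau learning-rate schedule keyed to validation loss,
#' early stopping keyed to validation F1, and checkpoint selection of the
#' weights with the highest validation F1. Fully reproducible from `seed`
#' in single-threaded BLAS mode.
#'
#' @param train,val Labeled read tibbles (from [generate_dataset()], or any
#'   tibble with `sequence`, `quality` and either a `labels` list column or
#'   `adapter_start`/`adapter_end` columns).
#' @param config An [model_config()].
#' @param tconfig A [train_config()].
#' @param seed Seed for batch shuffling (weights are seeded by `config$seed`).
#' @param verbose Print one line per validation.
#' @return A trained `nc_model` carrying `history` (a tibble with one row
#'   per validation: step, epoch, train_loss, val_loss, val_f1, lr) and
#'   `best_val_f1`.
#' @export
train_model <- function(train, val, config = model_config(),
                        tconfig = train_config(), seed = 1L, verbose = TRUE) {
  stopifnot(inherits(config, "nc_model_config"),
            inherits(tconfig, "nc_train_config"))
  if (nrow(train) == 0L || nrow(val) == 0L) {
    stop("training and validation sets must be non-empty", call. = FALSE)
  }
  if (!("tokens" %in% names(train))) train <- tokenize_reads(train, config$max_input_length)
  if (!("tokens" %in% names(val))) val <- tokenize_reads(val, config$max_input_length)
  train$labels <- truth_labels(train)
  val$labels <- truth_labels(val)

  model <- init_model(config)
  set.seed(seed)
  opt <- .adam_init(model$params)
  lr <- tconfig$initial_lr
  val_batches <- .index_batches(nchar(val$sequence), tconfig$batch_size,
                                row_budget = tconfig$row_budget)
  lens <- nchar(train$sequence)

  deep_copy <- function(p) lapply(p, function(x) x * 1)
  best <- list(f1 = -Inf, params = deep_copy(model$params))
  best_loss <- Inf
  since_loss_improve <- 0L; since_f1_improve <- 0L
  step <- 0L; run_loss <- 0; run_n <- 0L
  hist <- list()
  stop_now <- FALSE
  last_val_step <- -1L

  record_val <- function(epoch) {
    if (step == last_val_step) return(invisible())
    last_val_step <<- step
    vm <- .validate(model, val, val_batches)
    hist[[length(hist) + 1L]] <<- tibble::tibble(
      step = step, epoch = epoch,
      train_loss = if (run_n > 0) run_loss / run_n else NA_real_,
      val_loss = vm$loss, val_f1 = vm$f1, lr = lr)
    run_loss <<- 0; run_n <<- 0L
    if (vm$f1 > best$f1) {
      best <<- list(f1 = vm$f1, params = deep_copy(model$params))
      since_f1_improve <<- 0L
    } else since_f1_improve <<- since_f1_improve + 1L
    if (vm$loss < best_loss - 1e-6) {
      best_loss <<- vm$loss
      since_loss_improve <<- 0L
    } else {
      since_loss_improve <<- since_loss_improve + 1L
      if (since_loss_improve >= tconfig$plateau_patience) {
        lr <<- lr * tconfig$plateau_factor
        since_loss_improve <<- 0L
      }
    }
    if (verbose) {
      message(sprintf("step %d (epoch %d): val_loss=%.5f val_f1=%.4f lr=%.2g",
                      step, epoch, vm$loss, vm$f1, lr))
    }
    if (since_f1_improve >= tconfig$early_stop_patience) stop_now <<- TRUE
  }

  for (epoch in seq_len(tconfig$max_epochs)) {
    if (!is.null(tconfig$crop_length)) {
      crops <- lapply(seq_len(nrow(train)), function(i)
        .crop_read(train$tokens[[i]], train$qnorm[[i]], train$labels[[i]],
                   tconfig$crop_length, tconfig$crop_positive_prob))
      ep_tokens <- lapply(crops, `[[`, "tokens")
      ep_qnorm <- lapply(crops, `[[`, "qnorm")
      ep_labels <- lapply(crops, `[[`, "labels")
      ep_lens <- lengths(ep_tokens)
    } else {
      ep_tokens <- train$tokens; ep_qnorm <- train$qnorm
      ep_labels <- train$labels; ep_lens <- lens
    }
    batches <- .index_batches(ep_lens, tconfig$batch_size, shuffle = TRUE,
                              row_budget = tconfig$row_budget)
    for (idx in batches) {
      batch <- .make_batch(ep_tokens[idx], ep_qnorm[idx], ep_labels[idx])
      step <- step + 1L
      loss <- .nc_train_step_cpp(model$params, unclass(model$config),
                                 opt$m, opt$v, step, lr,
                                 tconfig$beta1, tconfig$beta2,
                                 batch$tokens, batch$qv, batch$labels,
                                 batch$wt, batch$B)
      run_loss <- run_loss + loss; run_n <- run_n + 1L
      if (step %% tconfig$val_interval_steps == 0L) record_val(epoch)
      if (step >= tconfig$max_steps) { stop_now <- TRUE }
      if (stop_now) break
    }
    if (!stop_now || step >= tconfig$max_steps) record_val(epoch)
    if (stop_now) break
  }

  model$params <- best$params
  model$history <- do.call(rbind, hist)
  model$best_val_f1 <- best$f1
  model
}

#' Write a per-validation metrics log
#'
#' @param model A trained `nc_model`.
#' @param path TSV output path (columns: step, epoch, train_loss, val_loss,
#'   val_f1, lr).
#' @export
write_history <- function(model, path) {
  stopifnot(inherits(model, "nc_model"), !is.null(model$history))
  utils::write.table(model$history, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
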