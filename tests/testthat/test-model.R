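test_that("tokenization is an injective per-base map over the vocabulary", {
  ids <- tokenize("ACGTN")
  expect_length(ids, 5L)
  expect_length(unique(ids), 5L)
  expect_identical(tokenize(""), integer())
  expect_identical(tokenize("ACGU"), tokenize("ACGT"))
  expect_error(tokenize("ACXG"), "position 3")
})

test_that("over-long reads are excluded with a warning", {
  reads <- make_reads(c(strrep("A", 10), strrep("C", 32771)))
  expect_warning(kept <- tokenize_reads(reads), "32770")
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$read_id, "r1")
  # at the boundary nothing is dropped
  ok <- make_reads(strrep("A", 100))
  expect_silent(tokenize_reads(ok, max_input_length = 100L))
})

test_that("per-read quality standardization has mean 0 and population SD 1", {
  expect_identical(normalize_qualities(c(10, 10, 10)), c(0, 0, 0))
  expect_equal(normalize_qualities(c(0, 20)), c(-1, 1))
  set.seed(20)
  q <- sample(0:60, 200, TRUE)
  z <- normalize_qualities(q)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sqrt(mean(z^2)) - 1), 1e-9)
  expect_identical(normalize_qualities(integer()), numeric())
})

test_that("forward pass emits valid probability tracks, invariant to batching", {
  set.seed(21)
  reads <- make_reads(c(strrep("ACGT", 30), strrep("GATTACA", 20),
                        strrep("TTAGC", 33)))
  reads$quality <- vapply(nchar(reads$sequence),
                          function(n) int_to_qual(sample(5:30, n, TRUE)), "")
  m <- init_model(small_model_config(seed = 3))
  joint <- predict_reads(m, reads, return_probabilities = TRUE)
  for (i in 1:3) {
    p <- joint$prob_adapter[[i]]
    expect_length(p, nchar(reads$sequence[i]))
    expect_true(all(p >= 0 & p <= 1))
    # the two-class softmax pair always sums to 1
    expect_true(all(abs(p + (1 - p) - 1) < 1e-6))
    expect_identical(joint$pred_labels[[i]], as.integer(p > 0.5))
    solo <- predict_reads(m, reads[i, ], return_probabilities = TRUE)
    expect_lt(max(abs(solo$prob_adapter[[1]] - p)), 1e-5)
  }
})

test_that("loss matches its closed forms and is an unweighted read mean", {
  y1 <- c(1, 0, 1, 1)
  expect_equal(bce_loss(list(c(0.5, 0.5, 0.5, 0.5)), list(y1)), log(2),
               tolerance = 1e-12)
  expect_lt(bce_loss(list(y1), list(y1)), 1e-6)
  # reads of different lengths contribute equally to the batch loss
  p1 <- rep(0.9, 4); t1 <- rep(1, 4)
  p2 <- rep(0.6, 50); t2 <- rep(1, 50)
  l1 <- bce_loss(list(p1), list(t1))
  l2 <- bce_loss(list(p2), list(t2))
  expect_equal(bce_loss(list(p1, p2), list(t1, t2)), (l1 + l2) / 2,
               tolerance = 1e-12)
  expect_error(bce_loss(list(c(0.5, 0.5)), list(c(1, 0, 1))))
})

test_that("evaluation metrics follow the confusion-count definitions", {
  perfect <- evaluate_predictions(list(rep(1L, 5)), list(rep(1L, 5)))
  expect_identical(c(perfect$precision, perfect$recall, perfect$f1), c(1, 1, 1))

  mixed <- evaluate_predictions(list(c(1L, 1L, 0L, 0L)),
                                list(c(1L, 0L, 1L, 0L)))
  expect_identical(c(mixed$tp, mixed$fp, mixed$fn, mixed$tn),
                   c(1L, 1L, 1L, 1L))
  expect_identical(c(mixed$precision, mixed$recall, mixed$f1),
                   c(0.5, 0.5, 0.5))

  none <- evaluate_predictions(list(integer(3)), list(rep(1L, 3)))
  expect_identical(c(none$precision, none$recall, none$f1), c(0, 0, 0))
  expect_error(evaluate_predictions(list(integer(3)), list(integer(4))),
               "lengths differ")
})

test_that("pooled metrics agree with a positionwise brute-force count", {
  set.seed(22)
  for (rep in seq_len(20)) {
    n_reads <- sample(1:5, 1L)
    pred <- lapply(seq_len(n_reads), function(i) rbinom(sample(1:30, 1), 1, 0.4))
    truth <- lapply(pred, function(p) rbinom(length(p), 1, 0.5))
    got <- evaluate_predictions(pred, truth)
    want <- brute_confusion(pred, truth)
    expect_identical(c(got$tp, got$fp, got$fn, got$tn), unname(want))
  }
})

test_that("the default architecture stays under 10 million parameters", {
  m <- init_model(model_config())
  expect_lt(n_parameters(m), 1e7)
  expect_gt(n_parameters(m), 1e6)
  small <- init_model(small_model_config())
  expect_lt(n_parameters(small), 1e5)
  # ablation removes exactly the quality-block weights
  abl <- init_model(small_model_config(quality_block = FALSE))
  expect_lt(n_parameters(abl), n_parameters(small))
})

test_that("training reduces loss and recovers clean adapters", {
  set.seed(23)
  ds <- generate_dataset(400, seed = 24, bodies = toy_bodies(),
                         adapters = adapter_model(substitution_rate = 0,
                                                  indel_rate = 0,
                                                  quality_mean = 8,
                                                  quality_sd = 2))
  cfg <- small_model_config(embed_dim = 16L, quality_hidden_dim = 16L,
                            backbone_layers = 2L, seed = 5)
  tcfg <- train_config(initial_lr = 1e-2, max_epochs = 4, batch_size = 32L,
                       val_interval_steps = 1000L)
  m <- train_model(ds$train, ds$val, cfg, tcfg, seed = 6, verbose = FALSE)
  h <- m$history
  expect_true(all(c("step", "train_loss", "val_loss", "val_f1") %in% names(h)))
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1L])
  expect_gt(m$best_val_f1, 0.9)

  test <- predict_reads(m, ds$test)
  rep <- evaluate_predictions(test$pred_labels, truth_labels(ds$test))
  expect_gt(rep$f1, 0.9)
})

test_that("training is reproducible from its seeds", {
  ds <- generate_dataset(120, seed = 25, bodies = toy_bodies(),
                         adapters = adapter_model(substitution_rate = 0,
                                                  indel_rate = 0))
  cfg <- small_model_config(embed_dim = 8L, quality_hidden_dim = 8L,
                            backbone_layers = 2L, seed = 7)
  tcfg <- train_config(initial_lr = 5e-3, max_epochs = 2, batch_size = 16L,
                       val_interval_steps = 1000L)
  a <- train_model(ds$train, ds$val, cfg, tcfg, seed = 8, verbose = FALSE)
  b <- train_model(ds$train, ds$val, cfg, tcfg, seed = 8, verbose = FALSE)
  expect_identical(a$best_val_f1, b$best_val_f1)
  expect_identical(a$params, b$params)
  expect_error(train_model(ds$train[0, ], ds$val, cfg, tcfg), "non-empty")
})

test_that("checkpoints round-trip through save_model/load_model", {
  m <- init_model(small_model_config(embed_dim = 8L, seed = 9))
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(m2$params, m$params)
  expect_identical(m2$config$embed_dim, 8L)
  reads <- make_reads(strrep("ACGT", 25))
  p1 <- predict_reads(m, reads, return_probabilities = TRUE)$prob_adapter[[1]]
  p2 <- predict_reads(m2, reads, return_probabilities = TRUE)$prob_adapter[[1]]
  expect_identical(p1, p2)
})

test_that("the quality block helps when sequence is ambiguous but quality is not", {
  # adapters share the body base composition (saturating substitution makes
  # the template uniform-random) and are separable by quality alone
  set.seed(26)
  ds <- generate_dataset(
    500, seed = 27, bodies = toy_bodies(len = 60L, qmean = 15),
    adapters = adapter_model(substitution_rate = 0.75, indel_rate = 0,
                             quality_mean = 6, quality_sd = 2))
  tcfg <- train_config(initial_lr = 1e-2, max_epochs = 4, batch_size = 32L,
                       val_interval_steps = 1000L)
  cfg_q <- small_model_config(embed_dim = 16L, quality_hidden_dim = 16L,
                              backbone_layers = 2L, seed = 10)
  cfg_n <- small_model_config(embed_dim = 16L, quality_hidden_dim = 16L,
                              backbone_layers = 2L, seed = 10,
                              quality_block = FALSE)
  m_q <- train_model(ds$train, ds$val, cfg_q, tcfg, seed = 11, verbose = FALSE)
  m_n <- train_model(ds$train, ds$val, cfg_n, tcfg, seed = 11, verbose = FALSE)
  f1 <- function(m) {
    pr <- predict_reads(m, ds$test)
    evaluate_predictions(pr$pred_labels, truth_labels(ds$test))$f1
  }
  expect_gt(f1(m_q), f1(m_n))
})

test_that("analytic gradients match central finite differences", {
  set.seed(40)
  ds <- generate_dataset(12, seed = 41, bodies = toy_bodies())
  sub <- tokenize_reads(ds$train)
  sub$labels <- truth_labels(sub)
  m <- init_model(small_model_config(embed_dim = 8L, quality_hidden_dim = 8L,
                                     backbone_layers = 3L, seed = 12))
  tb <- nanochopper:::.make_batch(sub$tokens[1:3], sub$qnorm[1:3],
                                  sub$labels[1:3])
  cfg <- unclass(m$config)
  loss_at <- function(params) {
    pa <- nanochopper:::.nc_forward_cpp(params, cfg, tb$tokens, tb$qv, tb$B)
    eps <- 1e-7
    pc <- pmin(pmax(pa, eps), 1 - eps)
    -sum(tb$wt * (tb$labels * log(pc) + (1 - tb$labels) * log(1 - pc)))
  }
  # a step with lr = 0 and beta1 = 0 leaves the first moment equal to the
  # gradient and the parameters untouched
  pcopy <- lapply(m$params, function(x) x * 1)
  mst <- lapply(m$params, function(x) x * 0)
  vst <- lapply(m$params, function(x) x * 0)
  nanochopper:::.nc_train_step_cpp(pcopy, cfg, mst, vst, 1L, 0, 0, 0.999,
                                   tb$tokens, tb$qv, tb$labels, tb$wt, tb$B)
  expect_identical(pcopy, lapply(m$params, function(x) x * 1))
  h <- 1e-6
  for (nm in names(m$params)) {
    i <- sample(length(m$params[[nm]]), 1L)
    pp <- lapply(m$params, function(x) x * 1)
    pp[[nm]][i] <- pp[[nm]][i] + h
    up <- loss_at(pp)
    pp[[nm]][i] <- pp[[nm]][i] - 2 * h
    dn <- loss_at(pp)
    numeric_grad <- (up - dn) / (2 * h)
    analytic <- mst[[nm]][i]
    expect_lt(abs(analytic - numeric_grad),
              1e-6 * max(1, abs(numeric_grad)))
  }
})
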