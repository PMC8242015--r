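test_that("model configuration is validated", {
  expect_error(rm_model_config(input_length = 50), "odd")
  expect_error(rm_model_config(dropout = 1), "dropout")
  cfg <- rm_model_config()
  expect_equal(cfg$heads, 12L)
  expect_equal(cfg$batch_size, 128L)
  expect_equal(cfg$patience, 5L)
  expect_equal(cfg$max_epochs, 100L)
})

test_that("build_rm_model rejects inconsistent embedding configuration", {
  cfg_w <- rm_model_config(embedding = "word2vec")
  expect_error(build_rm_model(cfg_w), "requires an embedding table")
  cfg_o <- rm_model_config(embedding = "onehot_cnn")
  expect_error(build_rm_model(cfg_o, fixture_embedding()),
               "takes no embedding table")
  m <- build_rm_model(cfg_o)
  expect_s3_class(m, "rm_model")
  expect_false(m$trained)
})

test_that("forward pass yields valid probabilities and normalized attention", {
  model <- build_rm_model(rm_model_config(input_length = 21, lstm_hidden = 8,
                                          attention_dim = 6, fc_hidden = 8,
                                          seed = 5),
                          embedding = fixture_embedding())
  seqs <- random_rna(8, 21, seed = 17)
  probs <- predict(model, seqs)
  expect_equal(dim(probs), c(8L, 12L))
  expect_true(all(probs > 0 & probs < 1))
  X <- rmnet:::model_input(model, seqs)
  fwd <- rmnet:::model_forward(model, X, training = FALSE)
  sums <- apply(fwd$fw$alpha, c(2, 3), sum)
  expect_equal(as.vector(sums), rep(1, 8 * 12), tolerance = 1e-6)
  expect_true(all(fwd$fw$alpha >= 0))
  # eval-mode forwards are deterministic
  probs2 <- predict(model, seqs)
  expect_identical(probs, probs2)
})

test_that("constant attention scores give uniform position weights", {
  model <- build_rm_model(rm_model_config(input_length = 21, lstm_hidden = 8,
                                          attention_dim = 6, fc_hidden = 8,
                                          bidirectional = FALSE, seed = 5),
                          embedding = fixture_embedding())
  seqs <- random_rna(3, 21, seed = 19)
  X <- rmnet:::model_input(model, seqs)
  # recompute context from a forward pass with a probe: perturbing h is not
  # possible from R, so check via the one-hot identity on a single position:
  # with uniform attention over T positions the context is the mean of the
  # hidden features, which the probability head must reproduce exactly when
  # the score vector V is zeroed (constant scores -> uniform softmax).
  model$params$V[] <- 0
  fwd <- rmnet:::model_forward(model, X, training = FALSE)
  a <- fwd$fw$alpha
  T_ <- dim(a)[1]
  expect_equal(as.vector(a), rep(1 / T_, length(a)), tolerance = 1e-12)
})

test_that("training reduces the loss on a separable task and is seed-reproducible", {
  split <- fixture_split()
  cfg <- rm_model_config(input_length = 51, lstm_hidden = 12,
                         attention_dim = 8, fc_hidden = 12, loss = "bce",
                         lr = 4e-3, batch_size = 128, max_epochs = 4,
                         schedule = "cosine_annealing", seed = 21)
  m1 <- train_rm_model(build_rm_model(cfg, fixture_embedding()), split)
  h <- m1$history
  expect_lte(nrow(h), 4L)
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_true(all(c("epoch", "lr", "train_loss", "val_loss") %in% names(h)))
  expect_true(all(paste0("auc_", rm_labels()$label) %in% names(h)))
  m2 <- train_rm_model(build_rm_model(cfg, fixture_embedding()), split)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("learning-rate schedules decay from the configured rate", {
  cfg_e <- rm_model_config(lr = 1e-2, lr_decay = 0.9, max_epochs = 10)
  expect_equal(rmnet:::epoch_lr(cfg_e, 1), 1e-2)
  expect_equal(rmnet:::epoch_lr(cfg_e, 3), 1e-2 * 0.81)
  cfg_c <- rm_model_config(lr = 1e-2, schedule = "cosine_annealing",
                           max_epochs = 11)
  expect_equal(rmnet:::epoch_lr(cfg_c, 1), 1e-2)
  expect_lt(rmnet:::epoch_lr(cfg_c, 11), 2e-4)
  expect_true(all(diff(sapply(1:11, function(e) rmnet:::epoch_lr(cfg_c, e))) < 0))
})

test_that("per-position prediction masks inapplicable labels and is deterministic", {
  model <- fixture_model()
  seq <- random_rna(1, 120, seed = 23)
  tab <- predict_sequence(model, seq)
  expect_equal(nrow(tab), 120L)
  expect_equal(tab$position, 1:120)
  c_rows <- tab$base == "C"
  expect_true(all(is.na(tab$prob_m6A[c_rows])))   # C cannot form m6A
  expect_true(all(!is.na(tab$prob_m5C[c_rows])))
  a_rows <- tab$base == "A"
  expect_true(all(!is.na(tab$prob_m6A[a_rows])))
  expect_identical(tab, predict_sequence(model, seq))
})

test_that("checkpoints round-trip and refuse a tampered embedding table", {
  model <- fixture_model()
  tf <- withr::local_tempfile(fileext = ".rds")
  save_rm_model(model, tf)
  back <- load_rm_model(tf)
  seqs <- fixture_split()$test$sequence[1:8]
  expect_equal(predict(back, seqs), predict(model, seqs))
  obj <- readRDS(tf)
  obj$embedding$vectors[1, 1] <- obj$embedding$vectors[1, 1] + 1
  tf2 <- withr::local_tempfile(fileext = ".rds")
  saveRDS(obj, tf2)
  expect_error(load_rm_model(tf2), "fingerprint")
})

test_that("the one-hot convolutional pathway trains end to end", {
  split <- fixture_split()
  cfg <- rm_model_config(input_length = 51, embedding = "onehot_cnn",
                         lstm_hidden = 12, attention_dim = 8, fc_hidden = 12,
                         conv_filters = 16, conv_width = 8, conv_pool = 4,
                         loss = "bce", lr = 4e-3, batch_size = 128,
                         max_epochs = 3, seed = 29)
  m <- train_rm_model(build_rm_model(cfg), split)
  h <- m$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  probs <- predict(m, split$test$sequence[1:6])
  expect_true(all(probs > 0 & probs < 1))
})

test_that("training aborts with a diagnostic when the loss turns non-finite", {
  split <- fixture_split()
  cfg <- rm_model_config(input_length = 51, lstm_hidden = 8,
                         attention_dim = 6, fc_hidden = 8, loss = "bce",
                         max_epochs = 3, seed = 3)
  model <- build_rm_model(cfg, fixture_embedding())
  model$params$Wx[1] <- NaN
  expect_error(train_rm_model(model, split), "diverged")
})
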