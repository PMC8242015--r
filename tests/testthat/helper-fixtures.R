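# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, build(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# small two-label corpus (m6A on A, m5C on C) with planted 5-mer motifs
fixture_corpus <- function() {
  memo("corpus", function() {
    cfg <- synth_config(labels = c("m6A", "m5C"), n_positives = 260,
                        n_transcripts = 80, transcript_length = 1600,
                        seed = 101)
    synth_generate(cfg)
  })
}

fixture_windows <- function(L = 51) {
  memo(paste0("windows", L), function() {
    corpus <- fixture_corpus()
    s <- rbind(corpus$sites[, 1:4], corpus$negatives[, 1:4])
    class(s) <- c("rm_sites", "data.frame")
    extract_windows(s, corpus$sequences, L = L)
  })
}

fixture_split <- function() {
  memo("split", function() {
    split_dataset(fixture_windows(), val_per_class = 60, test_per_class = 30,
                  seed = 7)
  })
}

fixture_embedding <- function() {
  memo("embedding", function() {
    train_word2vec(fixture_corpus()$sequences, dim = 24, epochs = 2,
                   seed = 13)
  })
}

# a small trained model shared by prediction/interpretation tests
fixture_model <- function() {
  memo("model", function() {
    cfg <- rm_model_config(input_length = 51, lstm_hidden = 24,
                           attention_dim = 12, fc_hidden = 24,
                           loss = "bce", lr = 4e-3, batch_size = 64,
                           schedule = "cosine_annealing", max_epochs = 18,
                           seed = 31)
    model <- build_rm_model(cfg, fixture_embedding())
    train_rm_model(model, fixture_split())
  })
}

random_rna <- function(n, len, seed = NULL) {
  with_seed <- rmnet:::with_seed
  with_seed(seed, vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, character(1)))
}
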