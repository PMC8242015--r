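# The multi-label network: embedding front-end -> LSTM -> one additive
# (Bahdanau) attention head per modification -> 12 parallel FC branches.
# Forward and backward passes run in compiled code (src/nnet.cpp); this file
# owns configuration, parameter initialization, batching, the Adam training
# loop with early stopping, and checkpoint I/O.

#' Model configuration
#'
#' @param input_length Odd window length L fed to the model (default 51, the
#'   length with the best average binary AUC in our evaluations).
#' @param embedding `"word2vec"` (k-mer embedding table, default) or
#'   `"onehot_cnn"` (one-hot input through a Conv1D + max-pool front-end).
#' @param k k-mer size for the word2vec pathway (default 3).
#' @param lstm_hidden LSTM hidden size per direction (the learned
#'   per-position features the attention summarizes have this dimension, or
#'   twice it when bidirectional).
#' @param bidirectional Run the LSTM in both directions and concatenate the
#'   states (default TRUE). The additive attention was designed over a
#'   bidirectional encoder, and the two directions give every position a
#'   distance-from-both-ends signature that lets the attention localize the
#'   candidate site quickly.
#' @param attention_dim Dimension of the additive attention score space; the
#'   12 score vectors live here and drive the association analysis.
#' @param fc_hidden Width of the hidden FC layer in each label branch.
#' @param dropout Dropout rate after the attention context and between FC
#'   layers (default 0.2).
#' @param conv_filters,conv_width,conv_pool Conv1D front-end shape for the
#'   one-hot pathway.
#' @param loss Training objective; see [rm_loss()].
#' @param gamma,ohem_q,en_beta Loss hyper-parameters: focal exponent, OHEM
#'   retained fraction, effective-number beta.
#' @param lr Adam learning rate (default 2e-3).
#' @param schedule Learning-rate decay: `"exponential"` (default) or
#'   `"cosine_annealing"`.
#' @param lr_decay Per-epoch factor for the exponential schedule.
#' @param batch_size Mini-batch size (default 128).
#' @param max_epochs Maximum training epochs (default 100).
#' @param patience Early stopping after this many successive epochs of rising
#'   validation loss (default 5).
#' @param seed Integer seed controlling initialization, shuffling and dropout.
#' @return A validated `rm_model_config` list.
#' @export
rm_model_config <- function(input_length = 51L,
                            embedding = c("word2vec", "onehot_cnn"),
                            k = 3L, lstm_hidden = 32L, bidirectional = TRUE,
                            attention_dim = 16L,
                            fc_hidden = 32L, dropout = 0.2,
                            conv_filters = 32L, conv_width = 8L, conv_pool = 4L,
                            loss = c("bce", "bce+ohem", "bce+uw",
                                     "bce+ohem+uw", "focal", "effective_number"),
                            gamma = 2, ohem_q = 0.7, en_beta = 0.999,
                            lr = 2e-3,
                            schedule = c("exponential", "cosine_annealing"),
                            lr_decay = 0.95, batch_size = 128L,
                            max_epochs = 100L, patience = 5L, seed = NULL) {
  embedding <- match.arg(embedding)
  loss <- match.arg(loss)
  schedule <- match.arg(schedule)
  input_length <- as.integer(input_length)
  if (input_length %% 2L == 0L) {
    stop("input_length must be odd, got ", input_length)
  }
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(
    input_length = input_length, embedding = embedding, k = as.integer(k),
    lstm_hidden = as.integer(lstm_hidden),
    bidirectional = isTRUE(bidirectional),
    attention_dim = as.integer(attention_dim), fc_hidden = as.integer(fc_hidden),
    dropout = dropout, conv_filters = as.integer(conv_filters),
    conv_width = as.integer(conv_width), conv_pool = as.integer(conv_pool),
    loss = loss, gamma = gamma, ohem_q = ohem_q, en_beta = en_beta,
    lr = lr, schedule = schedule, lr_decay = lr_decay,
    batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
    patience = as.integer(patience), heads = 12L, seed = seed),
    class = "rm_model_config")
}

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -s, s), nr, nc)
}

#' Build an untrained model
#'
#' @param config `rm_model_config`.
#' @param embedding `rm_embedding` table (required for the word2vec pathway;
#'   must be absent for the one-hot pathway).
#' @return An `rm_model` object.
#' @export
build_rm_model <- function(config, embedding = NULL) {
  stopifnot(inherits(config, "rm_model_config"))
  if (config$embedding == "word2vec" && is.null(embedding)) {
    stop("word2vec mode requires an embedding table (see train_word2vec)")
  }
  if (config$embedding == "onehot_cnn" && !is.null(embedding)) {
    stop("onehot_cnn mode takes no embedding table")
  }
  H <- config$lstm_hidden
  nH <- if (isTRUE(config$bidirectional)) 2L * H else H
  A <- config$attention_dim
  Fh <- config$fc_hidden
  K <- config$heads
  D <- if (config$embedding == "word2vec") embedding$dim else config$conv_filters

  params <- with_seed(config$seed, {
    p <- list(
      Wx = glorot(4L * H, D), Wh = glorot(4L * H, H),
      b = c(rep(0, H), rep(1, H), rep(0, 2L * H)),  # forget-gate bias 1
      Wc = glorot(A, nH), Wy = glorot(A, nH),
      Ba = matrix(0, A, K), V = glorot(A, K),
      W1 = array(0, dim = c(Fh, nH, K)), b1 = matrix(0, Fh, K),
      W2 = glorot(Fh, K), b2 = rep(0, K))
    for (j in seq_len(K)) p$W1[, , j] <- glorot(Fh, nH)
    if (isTRUE(config$bidirectional)) {
      p$Wx_r <- glorot(4L * H, D)
      p$Wh_r <- glorot(4L * H, H)
      p$b_r <- c(rep(0, H), rep(1, H), rep(0, 2L * H))
    }
    if (config$embedding == "onehot_cnn") {
      p$Wk <- glorot(config$conv_filters, 4L * config$conv_width)
      p$bk <- rep(0, config$conv_filters)
    }
    p
  })

  structure(list(config = config, params = params, embedding = embedding,
                 log_sigma = rep(0, 12L), class_weights = rep(1, 12L),
                 trained = FALSE, history = NULL, background = NULL),
            class = "rm_model")
}

#' @export
print.rm_model <- function(x, ...) {
  cfg <- x$config
  cat("rm_model (", cfg$embedding, "), L=", cfg$input_length,
      ", LSTM hidden ", cfg$lstm_hidden, ", attention dim ",
      cfg$attention_dim, ", 12 heads, loss ", cfg$loss,
      if (x$trained) ", trained" else ", untrained", "\n", sep = "")
  invisible(x)
}

# sequences -> model input array (D, B, T)
model_input <- function(model, seqs) {
  if (model$config$embedding == "word2vec") {
    embed_ids(token_ids(seqs, model$embedding), model$embedding)
  } else {
    onehot_array(seqs)
  }
}

# single forward pass over one batch; returns probs (B x 12) and caches
model_forward <- function(model, X, training = FALSE) {
  cfg <- model$config
  conv_cache <- NULL
  if (cfg$embedding == "onehot_cnn") {
    conv_cache <- conv_forward_cpp(model$params$Wk, model$params$bk, X,
                                   cfg$conv_pool)
    Xin <- conv_cache$out
  } else {
    Xin <- X
  }
  fw <- nn_forward_cpp(model$params, Xin, training, cfg$dropout)
  list(probs = t(fw$probs), fw = fw, Xin = Xin, conv_cache = conv_cache, X = X)
}

# backward pass; dlogits is B x 12. Returns named gradient list (and dX
# when requested; the conv pathway always needs it to reach its own weights).
model_backward <- function(model, cache, dlogits, want_dx = TRUE) {
  if (model$config$embedding == "onehot_cnn") want_dx <- TRUE
  gr <- nn_backward_cpp(model$params, cache$fw$cache, cache$Xin, t(dlogits),
                        want_dx)
  grads <- list(Wx = gr$dWx, Wh = gr$dWh, b = as.numeric(gr$db),
                Wc = gr$dWc, Wy = gr$dWy, Ba = gr$dBa, V = gr$dV,
                W1 = gr$dW1, b1 = gr$db1, W2 = gr$dW2, b2 = as.numeric(gr$db2))
  if (!is.null(gr$dWx_r)) {
    grads$Wx_r <- gr$dWx_r
    grads$Wh_r <- gr$dWh_r
    grads$b_r <- as.numeric(gr$db_r)
  }
  if (model$config$embedding == "onehot_cnn") {
    cg <- conv_backward_cpp(model$params$Wk, cache$conv_cache, cache$X, gr$dX)
    grads$Wk <- cg$dWk
    grads$bk <- as.numeric(cg$dbk)
    grads$dX <- cg$dX
  } else {
    grads$dX <- gr$dX
  }
  grads
}

# batched probability predictions for a character vector of sequences
predict_probs <- function(model, seqs, chunk = 512L) {
  out <- matrix(NA_real_, nrow = length(seqs), ncol = 12L,
                dimnames = list(NULL, rm_label_names()))
  for (lo in seq.int(1L, length(seqs), by = chunk)) {
    hi <- min(lo + chunk - 1L, length(seqs))
    X <- model_input(model, seqs[lo:hi])
    out[lo:hi, ] <- model_forward(model, X, training = FALSE)$probs
  }
  out
}

#' Predict modification probabilities for sequence windows
#'
#' @param object Trained `rm_model`.
#' @param newdata `rm_windows` data.frame or character vector of sequences of
#'   the model's input length.
#' @param ... Unused.
#' @return B x 12 matrix of probabilities in \[0, 1\] (no sum-to-one
#'   constraint: the tasks are independent binary decisions).
#' @export
predict.rm_model <- function(object, newdata, ...) {
  seqs <- if (is.character(newdata)) newdata else newdata$sequence
  stopifnot(all(nchar(seqs) == object$config$input_length))
  predict_probs(object, seqs)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

epoch_lr <- function(cfg, epoch) {
  if (cfg$schedule == "exponential") {
    cfg$lr * cfg$lr_decay^(epoch - 1L)
  } else {
    lr_min <- cfg$lr * 0.01
    lr_min + 0.5 * (cfg$lr - lr_min) *
      (1 + cos(pi * (epoch - 1L) / max(cfg$max_epochs - 1L, 1L)))
  }
}

# masked loss of a window set under the configured mode, without OHEM
# selection (generalization loss for early stopping)
validation_loss <- function(model, probs, labels, mask) {
  cfg <- model$config
  mode <- sub("\\+ohem", "", cfg$loss)
  rm_loss(probs, labels, mask, mode = mode, gamma = cfg$gamma, q = 1,
          log_sigma = model$log_sigma, class_weights = model$class_weights)$loss
}

# per-label binary AUC on a window set: positives of the label vs negative
# windows on the label's original base
val_auc_by_label <- function(probs, labels, bases) {
  vapply(seq_len(12L), function(j) {
    base_j <- rm_labels()$base[j]
    pos <- labels[, j] == 1L
    neg <- rowSums(labels) == 0L & bases == base_j
    if (!any(pos) || !any(neg)) return(NA_real_)
    auc_b(probs[pos, j], probs[neg, j])
  }, numeric(1))
}

#' Train the multi-label model
#'
#' Mini-batch Adam with the configured imbalance-aware loss, label masking by
#' center base, learning-rate decay, and early stopping when the validation
#' loss rises for `patience` successive epochs. The parameters of the best
#' validation epoch are retained. Deterministic under a fixed config seed.
#'
#' @param model `rm_model` from [build_rm_model()].
#' @param split `rm_split` from [split_dataset()], or a list with `train` and
#'   `validation` `rm_windows` elements.
#' @param average_from Optional epoch number: when set, the returned weights
#'   are the running (Polyak) average of the per-epoch weights from that
#'   epoch on, which damps the end-of-training oscillation of SGD-family
#'   optimizers; early-stopping bookkeeping still runs, but the averaged
#'   weights are kept instead of the single best-validation epoch.
#' @param verbose Print per-epoch progress.
#' @return The trained model with a `history` data.frame (per-epoch losses and
#'   per-label validation AUC).
#' @export
train_rm_model <- function(model, split, average_from = NULL,
                           verbose = FALSE) {
  cfg <- model$config
  train <- split$train
  val <- split$validation
  if (is.null(train) || nrow(train) == 0) stop("empty training set")
  if (is.null(val) || nrow(val) == 0) stop("empty validation set")
  stopifnot(all(nchar(train$sequence) == cfg$input_length))

  y_tr <- rm_window_labels(train)
  m_tr <- rm_supervision_mask(y_tr, train$base)
  y_va <- rm_window_labels(val)
  m_va <- rm_supervision_mask(y_va, val$base)

  if (cfg$loss == "effective_number") {
    # class size per task: positives of the label (its negatives share the
    # base pool, so the positive count is what drives the skew)
    n_j <- pmax(colSums(y_tr), 1L)
    model$class_weights <- effective_num_weights(n_j, cfg$en_beta)
  }

  # pre-encode inputs once
  if (cfg$embedding == "word2vec") {
    ids_tr <- token_ids(train$sequence, model$embedding)
    ids_va <- token_ids(val$sequence, model$embedding)
    get_X <- function(ids, rows) embed_ids(ids[rows, , drop = FALSE],
                                           model$embedding)
  } else {
    ids_tr <- seq_len(nrow(train))
    ids_va <- seq_len(nrow(val))
    get_X <- NULL
  }

  B_all <- nrow(train)
  use_uw <- cfg$loss %in% c("bce+uw", "bce+ohem+uw")
  history <- NULL
  best <- list(loss = Inf, params = NULL, log_sigma = NULL, epoch = 0L)
  avg <- NULL
  n_avg <- 0L

  with_seed(cfg$seed, {
    opt <- adam_init(model$params)
    opt_s <- if (use_uw) list(m = rep(0, 12), v = rep(0, 12), t = 0L) else NULL
    streak <- 0L
    prev_val <- Inf

    for (epoch in seq_len(cfg$max_epochs)) {
      lr <- epoch_lr(cfg, epoch)
      ord <- sample.int(B_all)
      tr_loss <- 0
      nb <- 0L
      for (lo in seq.int(1L, B_all, by = cfg$batch_size)) {
        rows <- ord[lo:min(lo + cfg$batch_size - 1L, B_all)]
        X <- if (cfg$embedding == "word2vec") get_X(ids_tr, rows) else
          onehot_array(train$sequence[rows])
        fwd <- model_forward(model, X, training = TRUE)
        ls <- rm_loss(fwd$probs, y_tr[rows, , drop = FALSE],
                      m_tr[rows, , drop = FALSE], mode = cfg$loss,
                      gamma = cfg$gamma, q = cfg$ohem_q,
                      log_sigma = model$log_sigma,
                      class_weights = model$class_weights)
        if (!is.finite(ls$loss)) {
          stop("training diverged (non-finite loss) at epoch ", epoch,
               "; try a smaller learning rate")
        }
        grads <- model_backward(model, fwd, ls$dlogits, want_dx = FALSE)
        st <- adam_step(model$params, grads, opt, lr)
        model$params <- st$params
        opt <- st$state
        if (use_uw && !is.null(ls$dlog_sigma)) {
          opt_s$t <- opt_s$t + 1L
          opt_s$m <- 0.9 * opt_s$m + 0.1 * ls$dlog_sigma
          opt_s$v <- 0.999 * opt_s$v + 0.001 * ls$dlog_sigma^2
          model$log_sigma <- model$log_sigma -
            lr * (opt_s$m / (1 - 0.9^opt_s$t)) /
              (sqrt(opt_s$v / (1 - 0.999^opt_s$t)) + 1e-8)
        }
        tr_loss <- tr_loss + ls$loss
        nb <- nb + 1L
      }
      tr_loss <- tr_loss / nb

      if (!is.null(average_from) && epoch >= average_from) {
        n_avg <- n_avg + 1L
        avg <- if (is.null(avg)) model$params else
          mapply(function(a, p) a + (p - a) / n_avg, avg, model$params,
                 SIMPLIFY = FALSE)
      }

      va_probs <- predict_probs(model, val$sequence)
      va_loss <- validation_loss(model, va_probs, y_va, m_va)
      aucs <- val_auc_by_label(va_probs, y_va, val$base)
      row <- data.frame(epoch = epoch, lr = lr, train_loss = tr_loss,
                        val_loss = va_loss)
      row[paste0("auc_", rm_label_names())] <- as.list(aucs)
      history <- rbind(history, row)
      if (verbose) {
        message(sprintf("epoch %3d  lr %.2e  train %.4f  val %.4f  mean AUC_b %.3f",
                        epoch, lr, tr_loss, va_loss, mean(aucs, na.rm = TRUE)))
      }

      if (va_loss < best$loss) {
        best <- list(loss = va_loss, params = model$params,
                     log_sigma = model$log_sigma, epoch = epoch)
      }
      streak <- if (va_loss > prev_val) streak + 1L else 0L
      prev_val <- va_loss
      if (streak >= cfg$patience) break
    }
  })

  if (!is.null(avg)) {
    model$params <- avg
  } else if (!is.null(best$params)) {
    model$params <- best$params
    model$log_sigma <- best$log_sigma
  }
  model$trained <- TRUE
  model$history <- history
  model$best_epoch <- best$epoch
  model
}

#' Per-position modification prediction along a long sequence
#'
#' Every position of the input is scored by evaluating the model on the
#' centered window of the configured input length (out-of-sequence flanks are
#' N-filled). Labels whose original base does not match the position's base
#' are reported as NA: a C cannot form m6A, so its m6A slot is not applicable.
#'
#' @param model Trained `rm_model`.
#' @param sequence A nucleotide string (T read as U).
#' @param background Optional background score table from
#'   [build_background()]; when provided, rank-based p-value upper bounds are
#'   added.
#' @return A data.frame with `position` (1-based for display), `base`, twelve
#'   `prob_*` columns and (if background given) twelve `pval_*` columns.
#' @export
predict_sequence <- function(model, sequence, background = NULL) {
  sequence <- as_rna(sequence)
  check_rna_alphabet(sequence)
  n <- nchar(sequence)
  if (n < 1L) stop("empty sequence")
  L <- model$config$input_length
  flank <- (L - 1L) %/% 2L
  padded <- paste0(strrep("N", flank), sequence, strrep("N", flank))
  starts <- seq_len(n)
  wins <- substring(padded, starts, starts + L - 1L)
  bases <- substring(sequence, starts, starts)
  probs <- predict_probs(model, wins)
  mask <- rm_base_mask(bases)
  probs[!mask] <- NA_real_
  out <- data.frame(position = starts, base = bases, stringsAsFactors = FALSE)
  pcols <- as.data.frame(probs)
  names(pcols) <- paste0("prob_", rm_label_names())
  out <- cbind(out, pcols)
  if (!is.null(background)) {
    pv <- matrix(NA_real_, n, 12L)
    for (j in seq_len(12L)) {
      lab <- rm_label_names()[j]
      rows <- which(mask[, j] & !is.na(probs[, j]))
      if (length(rows) > 0 && !is.null(background$scores[[lab]])) {
        pv[rows, j] <- empirical_pvalue_bound(probs[rows, j], background, lab)
      }
    }
    pvc <- as.data.frame(pv)
    names(pvc) <- paste0("pval_", rm_label_names())
    out <- cbind(out, pvc)
  }
  out
}

#' Save a model checkpoint
#'
#' A single-file archive holding the weights, the configuration, the
#' embedding table and a fingerprint tying predictions to that table.
#'
#' @param model `rm_model`.
#' @param path Output path (conventionally `.rds`).
#' @export
save_rm_model <- function(model, path) {
  obj <- list(config = unclass(model$config), params = model$params,
              embedding = if (!is.null(model$embedding)) unclass(model$embedding),
              log_sigma = model$log_sigma, class_weights = model$class_weights,
              trained = model$trained, history = model$history,
              background = model$background,
              embedding_hash = embedding_hash(model$embedding),
              format = 1L)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint written by [save_rm_model()]
#' @param path Checkpoint path.
#' @return `rm_model` object.
#' @export
load_rm_model <- function(path) {
  obj <- readRDS(path)
  emb <- if (!is.null(obj$embedding)) structure(obj$embedding,
                                                class = "rm_embedding")
  if (embedding_hash(emb) != obj$embedding_hash) {
    stop("checkpoint refuses to load: embedding table does not match its ",
         "recorded fingerprint")
  }
  structure(list(config = structure(obj$config, class = "rm_model_config"),
                 params = obj$params, embedding = emb,
                 log_sigma = obj$log_sigma, class_weights = obj$class_weights,
                 trained = obj$trained, history = obj$history,
                 background = obj$background),
            class = "rm_model")
}
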