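# Sequence representations: one-hot matrices and k-mer word2vec embeddings.

#' One-hot encode a nucleotide sequence
#'
#' A maps to (1,0,0,0), C to (0,1,0,0), G to (0,0,1,0), U to (0,0,0,1) and N
#' to the all-zero row.
#'
#' @param sequence A string over {A,C,G,U,N} (T is read as U).
#' @return An L x 4 matrix with columns A, C, G, U.
#' @examples
#' one_hot_encode("ACGUN")
#' @export
one_hot_encode <- function(sequence) {
  sequence <- as_rna(sequence)
  check_rna_alphabet(sequence)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  m <- matrix(0, nrow = length(ch), ncol = 4,
              dimnames = list(NULL, c("A", "C", "G", "U")))
  idx <- match(ch, c("A", "C", "G", "U"))
  hit <- !is.na(idx)
  m[cbind(which(hit), idx[hit])] <- 1
  m
}

#' Tokenize a sequence into overlapping k-mers
#'
#' A k-nt window slides along the sequence with the given stride, producing
#' `floor((L - k) / stride) + 1` tokens; a 1001-nt window with k = 3 and
#' stride 1 yields 999 tokens.
#'
#' @param sequence Nucleotide string.
#' @param k k-mer size (default 3).
#' @param stride Step between successive k-mers (default 1).
#' @return Character vector of k-mer tokens.
#' @examples
#' tokenize_kmers("ACGU", k = 3)
#' @export
tokenize_kmers <- function(sequence, k = 3L, stride = 1L) {
  sequence <- as_rna(sequence)
  L <- nchar(sequence)
  if (L < k) stop("sequence of length ", L, " is shorter than k = ", k)
  starts <- seq.int(1L, L - k + 1L, by = stride)
  substring(sequence, starts, starts + k - 1L)
}

# inverse of tokenize_kmers for stride 1
detokenize_kmers <- function(tokens, k = 3L) {
  if (length(tokens) == 1L) return(tokens)
  paste0(tokens[1], paste(substring(tokens[-1], k, k), collapse = ""))
}

#' Train k-mer word2vec embeddings on a sequence corpus
#'
#' Each sequence is treated as a sentence of overlapping k-mers and a
#' word2vec model (skip-gram with negative sampling by default, CBOW
#' selectable) is trained on the corpus. Training is single-threaded and all
#' randomness flows through R's RNG, so a fixed seed reproduces the table
#' exactly.
#'
#' @param corpus Character vector of sequences (sentences), or a list of
#'   pre-tokenized character vectors.
#' @param k k-mer size used for tokenization (default 3).
#' @param dim Embedding dimension (default 300).
#' @param window Context radius in tokens (default 5).
#' @param negative Number of negative samples per positive pair (default 5).
#' @param epochs Passes over the corpus (default 5).
#' @param lr Initial learning rate, linearly decayed (default 0.025).
#' @param method `"skipgram"` (default) or `"cbow"`.
#' @param seed Optional integer seed.
#' @return An `rm_embedding` object: vocabulary of observed k-mers and a
#'   |vocabulary| x dim numeric matrix.
#' @export
train_word2vec <- function(corpus, k = 3L, dim = 300L, window = 5L,
                           negative = 5L, epochs = 5L, lr = 0.025,
                           method = c("skipgram", "cbow"), seed = NULL) {
  method <- match.arg(method)
  if (length(corpus) == 0) stop("empty corpus")
  toks <- if (is.list(corpus)) corpus else lapply(corpus, tokenize_kmers, k = k)
  vocab <- sort(unique(unlist(toks)), method = "radix")
  if (length(vocab) == 0) stop("empty corpus after tokenization")
  counts <- table(factor(unlist(toks), levels = vocab))
  sentences <- lapply(toks, function(t) match(t, vocab) - 1L)
  vecs <- with_seed(seed,
    w2v_train_cpp(sentences, length(vocab), as.numeric(counts), as.integer(dim),
                  as.integer(window), as.integer(negative), as.integer(epochs),
                  lr, method == "cbow"))
  rownames(vecs) <- vocab
  structure(list(k = as.integer(k), dim = as.integer(dim), tokens = vocab,
                 vectors = vecs, method = method, window = as.integer(window)),
            class = "rm_embedding")
}

#' @export
print.rm_embedding <- function(x, ...) {
  cat("rm_embedding: ", length(x$tokens), " ", x$k, "-mer tokens, dim ",
      x$dim, " (", x$method, ")\n", sep = "")
  invisible(x)
}

#' Embed a token sequence with an embedding table
#'
#' Row i of the result is the vector of token i. Tokens absent from the
#' vocabulary (e.g. N-containing k-mers never seen in pre-training) map to
#' the zero vector under the default policy, or raise an error under
#' `oov = "error"`.
#'
#' @param tokens Character vector of k-mer tokens.
#' @param table `rm_embedding` from [train_word2vec()].
#' @param oov Out-of-vocabulary policy: `"zero"` (default, with a warning) or
#'   `"error"`.
#' @return length(tokens) x dim numeric matrix.
#' @export
embed_sequence <- function(tokens, table, oov = c("zero", "error")) {
  oov <- match.arg(oov)
  idx <- match(tokens, table$tokens)
  if (anyNA(idx)) {
    if (oov == "error") {
      stop("token(s) not in vocabulary: ",
           paste(unique(tokens[is.na(idx)]), collapse = ", "))
    }
    warning(sum(is.na(idx)), " out-of-vocabulary token(s) mapped to the zero vector")
  }
  out <- matrix(0, nrow = length(tokens), ncol = table$dim)
  hit <- !is.na(idx)
  out[hit, ] <- table$vectors[idx[hit], , drop = FALSE]
  out
}

#' Write an embedding table as TSV (token column + one column per dimension)
#' @param table `rm_embedding` object.
#' @param path Output path.
#' @export
write_embedding <- function(table, path) {
  df <- data.frame(token = table$tokens, table$vectors,
                   stringsAsFactors = FALSE, row.names = NULL)
  names(df) <- c("token", paste0("d", seq_len(table$dim)))
  attr(df, "k") <- table$k
  write.table(cbind(k = table$k, method = table$method, df), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an embedding table written by [write_embedding()]
#' @param path Path to the TSV file.
#' @return `rm_embedding` object.
#' @export
read_embedding <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  vecs <- as.matrix(df[, grep("^d[0-9]+$", names(df)), drop = FALSE])
  rownames(vecs) <- df$token
  colnames(vecs) <- NULL
  structure(list(k = df$k[1], dim = ncol(vecs), tokens = df$token,
                 vectors = vecs, method = df$method[1], window = NA_integer_),
            class = "rm_embedding")
}

# deterministic fingerprint tying a checkpoint to its embedding table
embedding_hash <- function(table) {
  if (is.null(table)) return("none")
  sprintf("%d/%d/%.8e", length(table$tokens), table$dim, sum(table$vectors))
}

# ---- batched input tensors (D x B x T arrays for the C++ core) ----

# token-id matrix (B x T) for a character vector of equal-length sequences
token_ids <- function(seqs, table) {
  k <- table$k
  T_ <- nchar(seqs[1]) - k + 1L
  ids <- matrix(NA_integer_, nrow = length(seqs), ncol = T_)
  for (b in seq_along(seqs)) {
    ids[b, ] <- match(tokenize_kmers(seqs[b], k = k), table$tokens)
  }
  ids
}

# ids (B x T, NA = out-of-vocabulary -> zero vector) to array(D, B, T)
embed_ids <- function(ids, table) {
  D <- table$dim
  V <- t(table$vectors)          # D x |vocab|
  V <- cbind(V, 0)               # OOV column
  ids0 <- ids
  ids0[is.na(ids0)] <- ncol(V)
  array(V[, as.vector(ids0)], dim = c(D, nrow(ids), ncol(ids)))
}

# character sequences to one-hot array(4, B, L)
onehot_array <- function(seqs) {
  L <- nchar(seqs[1])
  B <- length(seqs)
  ch <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), nrow = L)  # L x B
  X <- array(0, dim = c(4L, B, L))
  idx <- match(ch, c("A", "C", "G", "U"))  # L*B vector, column-major (L fast)
  hit <- which(!is.na(idx))
  pos_l <- (hit - 1L) %% L + 1L
  pos_b <- (hit - 1L) %/% L + 1L
  X[cbind(idx[hit], pos_b, pos_l)] <- 1
  X
}
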