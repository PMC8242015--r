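# Interpretation of trained models: integrated-gradients attribution at
# nucleotide resolution, per-label attention profiles, motif mining over the
# top-scoring true positives, density-based motif clustering into PWMs, and
# cross-modification association analysis.

# gradient of one label's probability w.r.t. the model input array
input_gradient <- function(model, X, label_idx) {
  fwd <- model_forward(model, X, training = FALSE)
  B <- ncol(fwd$probs) * 0 + nrow(fwd$probs)
  p <- fwd$probs[, label_idx]
  dlogits <- matrix(0, nrow = B, ncol = 12L)
  dlogits[, label_idx] <- p * (1 - p)  # d(prob)/d(logit)
  gr <- model_backward(model, fwd, dlogits)
  list(dX = gr$dX, probs = fwd$probs)
}

#' Integrated-gradients attribution
#'
#' Path-integral attribution along the straight line from a baseline to the
#' input, approximated by a midpoint Riemann sum with `steps` interpolation
#' points. Satisfies completeness: the attributions sum to the output
#' difference between input and baseline, up to a reported residual that
#' shrinks as `steps` grows.
#'
#' For `rm_model` objects the baseline is the all-zero embedding (word2vec
#' pathway) or the all-N one-hot (one-hot pathway), and token-level
#' attributions are projected to nucleotides by splitting each token's score
#' equally over the k nucleotides it covers.
#'
#' @param model A trained `rm_model`, or a function `f(x)` returning
#'   `list(value = , grad = )` for direct use of the estimator.
#' @param ... Passed to methods.
#' @return For `rm_model`: an `rm_attribution` data.frame with columns
#'   `position`, `base`, `score`, and attributes `residual`, `gap`, `label`,
#'   `steps`. For functions: `list(attributions, residual, gap)`.
#' @export
integrated_gradients <- function(model, ...) UseMethod("integrated_gradients")

#' @rdname integrated_gradients
#' @param x Input (any numeric array) for the function method.
#' @param baseline Baseline of the same shape (default all zeros).
#' @param steps Number of interpolation points (default 50).
#' @export
integrated_gradients.function <- function(model, x, baseline = NULL,
                                          steps = 50L, ...) {
  if (steps < 1L) stop("steps must be >= 1")
  f <- model
  if (is.null(baseline)) baseline <- x * 0
  diffs <- x - baseline
  acc <- x * 0
  for (s in seq_len(steps)) {
    xi <- baseline + (s - 0.5) / steps * diffs
    acc <- acc + f(xi)$grad
  }
  attributions <- acc / steps * diffs
  gap <- f(x)$value - f(baseline)$value
  list(attributions = attributions,
       residual = abs(sum(attributions) - gap), gap = gap)
}

# nucleotide coverage of model positions: list mapping each nucleotide to the
# encoder positions (tokens / pooled conv outputs) that read it
position_coverage <- function(model, L, T_) {
  cfg <- model$config
  if (cfg$embedding == "word2vec") {
    k <- cfg$k
    lapply(seq_len(L), function(i) {
      lo <- max(1L, i - k + 1L)
      hi <- min(T_, i)
      if (lo > hi) integer(0) else lo:hi
    })
  } else {
    span <- cfg$conv_pool + cfg$conv_width - 1L
    lapply(seq_len(L), function(i) {
      t_ <- which((seq_len(T_) - 1L) * cfg$conv_pool + 1L <= i &
                    (seq_len(T_) - 1L) * cfg$conv_pool + span >= i)
      t_
    })
  }
}

#' @rdname integrated_gradients
#' @param window A window sequence (string of the model's input length) or a
#'   one-row `rm_windows` data.frame.
#' @param label Modification label to attribute.
#' @export
integrated_gradients.rm_model <- function(model, window, label, steps = 50L,
                                          ...) {
  if (steps < 1L) stop("steps must be >= 1")
  seqs <- if (is.character(window)) window else window$sequence
  stopifnot(length(seqs) == 1L)
  L <- nchar(seqs)
  j <- match(label, rm_label_names())
  if (is.na(j)) stop("unknown label ", label)
  center <- substr(seqs, (L + 1L) %/% 2L, (L + 1L) %/% 2L)
  if (center != rm_labels()$base[j] && center != "N") {
    stop("label ", label, " is not applicable to center base ", center)
  }

  X <- model_input(model, seqs)          # D x 1 x T (or 4 x 1 x L)
  Xb <- X * 0
  D <- dim(X)[1]
  T_ <- dim(X)[3]
  # evaluate all interpolation points as one batch
  Xi <- array(0, dim = c(D, steps, T_))
  for (s in seq_len(steps)) {
    Xi[, s, ] <- ((s - 0.5) / steps) * X[, 1, ]
  }
  gr <- input_gradient(model, Xi, j)
  avg_grad <- apply(gr$dX, c(1, 3), mean)          # D x T
  attr_mat <- avg_grad * X[, 1, ]                   # D x T (baseline is 0)
  pos_scores <- colSums(attr_mat)                   # per encoder position

  ends <- model_forward(model, {
    Xe <- array(0, dim = c(D, 2L, T_)); Xe[, 2, ] <- X[, 1, ]; Xe
  }, training = FALSE)$probs[, j]
  gap <- ends[2] - ends[1]
  residual <- abs(sum(attr_mat) - gap)

  # each encoder position reads `length_share` nucleotides; a nucleotide
  # receives an equal share of every covering position's score
  cov <- position_coverage(model, L, T_)
  share <- length_share(model)
  nt <- vapply(cov, function(tt) {
    if (length(tt) == 0) 0 else sum(pos_scores[tt]) / share
  }, numeric(1))

  out <- data.frame(position = seq_len(L),
                    base = strsplit(seqs, "", fixed = TRUE)[[1]],
                    score = nt, stringsAsFactors = FALSE)
  attr(out, "residual") <- residual
  attr(out, "gap") <- gap
  attr(out, "label") <- label
  attr(out, "steps") <- steps
  attr(out, "position_scores") <- pos_scores
  class(out) <- c("rm_attribution", "data.frame")
  out
}

# how many nucleotides each encoder position reads (equal-split projection)
length_share <- function(model) {
  cfg <- model$config
  if (cfg$embedding == "word2vec") cfg$k else cfg$conv_pool + cfg$conv_width - 1L
}

#' Per-label attention profiles over a window
#'
#' Maps each label's attention distribution over encoder positions to
#' nucleotides (each nucleotide receives the mean weight of the positions
#' covering it) and renormalizes to sum to 1.
#'
#' @param model Trained `rm_model`.
#' @param window Window sequence (string) or one-row `rm_windows`.
#' @return L x 12 matrix; each column is a probability vector over positions.
#' @export
attention_profile <- function(model, window) {
  seqs <- if (is.character(window)) window else window$sequence
  stopifnot(length(seqs) == 1L)
  L <- nchar(seqs)
  X <- model_input(model, seqs)
  fwd <- model_forward(model, X, training = FALSE)
  alpha <- fwd$fw$alpha                  # T x 1 x K
  T_ <- dim(alpha)[1]
  cov <- position_coverage(model, L, T_)
  out <- matrix(0, nrow = L, ncol = 12L,
                dimnames = list(NULL, rm_label_names()))
  for (j in seq_len(12L)) {
    w <- alpha[, 1, j]
    nt <- vapply(cov, function(tt) if (length(tt) == 0) 0 else mean(w[tt]),
                 numeric(1))
    out[, j] <- nt / sum(nt)
  }
  out
}

#' Write an attribution map or attention profile as TSV
#' @param x `rm_attribution` data.frame or matrix from [attention_profile()].
#' @param path Output path.
#' @export
write_attribution <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# greedy non-overlapping window selection over a score vector
select_windows_greedy <- function(scores, w, k_max) {
  L <- length(scores)
  if (L < w) return(NULL)
  means <- vapply(seq_len(L - w + 1L), function(s) mean(scores[s:(s + w - 1L)]),
                  numeric(1))
  blocked <- rep(FALSE, length(means))
  picks <- integer(0)
  for (iter in seq_len(k_max)) {
    if (all(blocked)) break
    cand <- which(!blocked)
    s <- cand[which.max(means[cand])]
    picks <- c(picks, s)
    # mask the selected window and its (w-1)-nt neighborhood on both sides
    lo <- max(1L, s - (w - 1L) - (w - 1L))
    hi <- min(length(means), s + (w - 1L) + (w - 1L))
    blocked[lo:hi] <- TRUE
  }
  picks
}

#' Mine high-attribution motif candidates from true positives
#'
#' Restricts to true positives of the label whose predicted probability lies
#' in the top `top_fraction` (default the top decile), computes an
#' integrated-gradients attribution map per sample, and greedily extracts up
#' to `k_per_sample` non-overlapping windows of width `w` with the highest
#' mean attribution, masking each selected window and its (w-1)-nt
#' neighborhood before the next pick. Candidates need not contain the
#' modified center site itself.
#'
#' @param model Trained `rm_model`.
#' @param windows `rm_windows` evaluation set.
#' @param label Modification label.
#' @param top_fraction Fraction of top-scoring positives kept (default 0.10).
#' @param w Motif window width (default 6).
#' @param k_per_sample Candidates per sample (default 3).
#' @param steps Integrated-gradients steps (default 32).
#' @param cutoff Probability above which a positive counts as predicted
#'   positive (default 0.5).
#' @return `rm_motif_candidates` data.frame: `sample`, `start`, `sequence`,
#'   `mean_score`.
#' @export
mine_motifs <- function(model, windows, label, top_fraction = 0.10, w = 6L,
                        k_per_sample = 3L, steps = 32L, cutoff = 0.5) {
  j <- match(label, rm_label_names())
  if (is.na(j)) stop("unknown label ", label)
  labels <- rm_window_labels(windows)
  pos <- which(labels[, j] == 1L)
  empty <- data.frame(sample = integer(0), start = integer(0),
                      sequence = character(0), mean_score = numeric(0))
  class(empty) <- c("rm_motif_candidates", "data.frame")
  attr(empty, "label") <- label
  attr(empty, "w") <- w
  if (length(pos) == 0) {
    warning("no positive windows for label ", label)
    return(empty)
  }
  probs <- predict(model, windows[pos, , drop = FALSE])[, j]
  tp <- pos[probs >= cutoff]
  tp_probs <- probs[probs >= cutoff]
  if (length(tp) == 0) {
    warning("no true positives for label ", label)
    return(empty)
  }
  thr <- quantile(tp_probs, 1 - top_fraction, type = 1)
  sel <- tp[tp_probs >= thr]

  rows <- list()
  for (i in sel) {
    ig <- integrated_gradients(model, windows$sequence[i], label,
                               steps = steps)
    picks <- select_windows_greedy(ig$score, w, k_per_sample)
    for (s in picks) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = i, start = s,
        sequence = substr(windows$sequence[i], s, s + w - 1L),
        mean_score = mean(ig$score[s:(s + w - 1L)]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  attr(out, "label") <- label
  attr(out, "w") <- w
  class(out) <- c("rm_motif_candidates", "data.frame")
  out
}

# plain DBSCAN on a point matrix (rows = points); 0 labels noise
dbscan_points <- function(x, eps, min_samples) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  labels <- rep(0L, n)
  visited <- rep(FALSE, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    Ni <- nbrs[[i]]
    if (length(Ni) < min_samples) next  # noise (may be claimed later)
    cid <- cid + 1L
    labels[i] <- cid
    queue <- setdiff(Ni, i)
    while (length(queue) > 0) {
      q <- queue[1]
      queue <- queue[-1]
      if (!visited[q]) {
        visited[q] <- TRUE
        Nq <- nbrs[[q]]
        if (length(Nq) >= min_samples) queue <- c(queue, setdiff(Nq, q))
      }
      if (labels[q] == 0L) labels[q] <- cid
    }
  }
  labels
}

pwm_from_sequences <- function(seqs, pseudocount = 0.01) {
  w <- nchar(seqs[1])
  ch <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), nrow = w)
  pwm <- matrix(pseudocount, nrow = 4, ncol = w,
                dimnames = list(c("A", "C", "G", "U"), NULL))
  for (col in seq_len(w)) {
    tab <- table(factor(ch[col, ], levels = c("A", "C", "G", "U")))
    pwm[, col] <- pwm[, col] + as.numeric(tab)
  }
  sweep(pwm, 2, colSums(pwm), "/")
}

#' Cluster motif candidates and aggregate each cluster into a PWM
#'
#' Equal-length candidates are one-hot flattened (they already align, so no
#' multiple alignment is needed), embedded to two dimensions by principal
#' components (coordinates scaled to unit variance), and density-clustered
#' with DBSCAN; noise points are discarded and each cluster is summarized as
#' a column-stochastic position weight matrix with pseudocount 0.01.
#'
#' @param candidates `rm_motif_candidates` from [mine_motifs()] (>= 10 rows).
#' @param eps DBSCAN radius in the scaled embedded space (default 0.5).
#' @param min_samples DBSCAN core-point threshold (default 5).
#' @param pseudocount PWM pseudocount (default 0.01).
#' @return `rm_motif_clusters`: list of clusters, each with `id`, `members`,
#'   `size`, `consensus` and a 4 x w `pwm`.
#' @export
cluster_motifs <- function(candidates, eps = 0.5, min_samples = 5L,
                           pseudocount = 0.01) {
  if (nrow(candidates) < 10L) {
    stop("need at least 10 motif candidates, got ", nrow(candidates))
  }
  seqs <- candidates$sequence
  if (length(unique(nchar(seqs))) != 1L) {
    stop("candidates must have equal length")
  }
  w <- nchar(seqs[1])
  oh <- t(vapply(seqs, function(s) as.vector(one_hot_encode(s)),
                 numeric(4L * w)))
  pc <- prcomp(oh, center = TRUE, scale. = FALSE)
  ndim <- min(2L, ncol(pc$x))
  emb <- pc$x[, seq_len(ndim), drop = FALSE]
  for (dcol in seq_len(ncol(emb))) {
    s <- stats::sd(emb[, dcol])
    if (s > 0) emb[, dcol] <- emb[, dcol] / s
  }
  labels <- dbscan_points(emb, eps, min_samples)
  if (all(labels == 0L)) {
    warning("all motif candidates classified as noise")
    return(structure(list(), class = "rm_motif_clusters"))
  }
  clusters <- lapply(sort(unique(labels[labels > 0L])), function(cid) {
    members <- which(labels == cid)
    pwm <- pwm_from_sequences(seqs[members], pseudocount)
    cons <- paste(rownames(pwm)[apply(pwm, 2, which.max)], collapse = "")
    list(id = cid, members = members, size = length(members),
         consensus = cons, pwm = pwm)
  })
  # largest clusters first
  clusters <- clusters[order(-vapply(clusters, `[[`, integer(1), "size"))]
  structure(clusters, class = "rm_motif_clusters")
}

#' Best-alignment total-variation distance between two PWMs
#'
#' Slides the narrower PWM along the wider one and returns the smallest mean
#' per-column total-variation distance (0.5 * L1) over full-overlap offsets.
#' Zero means identical.
#'
#' @param pwm_a,pwm_b 4 x w column-stochastic matrices (rows A, C, G, U).
#' @return Nonnegative distance; 1 is the maximum per column.
#' @export
pwm_distance <- function(pwm_a, pwm_b) {
  if (ncol(pwm_a) > ncol(pwm_b)) {
    tmp <- pwm_a
    pwm_a <- pwm_b
    pwm_b <- tmp
  }
  wa <- ncol(pwm_a)
  wb <- ncol(pwm_b)
  best <- Inf
  for (off in 0:(wb - wa)) {
    tv <- mean(vapply(seq_len(wa), function(c_) {
      0.5 * sum(abs(pwm_a[, c_] - pwm_b[, c_ + off]))
    }, numeric(1)))
    best <- min(best, tv)
  }
  best
}

#' Cross-modification association from the attention score vectors
#'
#' The 12 additive-attention score vectors (one per modification, jointly
#' learned with the rest of the model) are correlated pairwise: labels whose
#' predictions attend to similar learned sequence features obtain high
#' Pearson correlation. Two-sided p-values come from the exact distribution
#' of the sample correlation coefficient under the null of no correlation.
#'
#' @param model Trained `rm_model`.
#' @return `rm_association`: list with 12 x 12 `rho` and `p` matrices and the
#'   vector length `n`.
#' @export
association_matrix <- function(model) {
  V <- model$params$V                      # attention_dim x 12
  K <- ncol(V)
  labs <- rm_label_names()
  rho <- matrix(NA_real_, K, K, dimnames = list(labs, labs))
  pmat <- matrix(NA_real_, K, K, dimnames = list(labs, labs))
  sds <- apply(V, 2, stats::sd)
  for (a in seq_len(K)) {
    for (b in a:K) {
      if (a == b) {
        rho[a, b] <- 1
        pmat[a, b] <- 0
        next
      }
      if (sds[a] == 0 || sds[b] == 0) next  # correlation undefined -> NA
      ct <- cor.test(V[, a], V[, b], method = "pearson")
      rho[a, b] <- rho[b, a] <- unname(ct$estimate)
      pmat[a, b] <- pmat[b, a] <- ct$p.value
    }
  }
  structure(list(rho = rho, p = pmat, n = nrow(V)), class = "rm_association")
}

#' @export
print.rm_association <- function(x, ...) {
  cat("rm_association: 12 x 12 Pearson correlations of attention score vectors (n =",
      x$n, ")\n")
  print(round(x$rho, 3))
  invisible(x)
}

#' Write an association matrix (correlations and p-values) as TSV
#' @param assoc `rm_association` object.
#' @param path Output path.
#' @export
write_association <- function(assoc, path) {
  df <- data.frame(label = rownames(assoc$rho), assoc$rho,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  pv <- data.frame(label = rownames(assoc$p), assoc$p, check.names = FALSE)
  write.table(pv, sub("(\\.[^.]+)?$", "_pvalues\\1", path, perl = TRUE),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Spatial aggregation of two site sets versus a positional null
#'
#' For every site of set A, the distance to the nearest set-B site on the
#' same sequence is computed; the null repositions the B sites uniformly at
#' random on the same sequences and recomputes the summary, yielding a
#' one-sided empirical p-value for "A sits closer to B than random".
#'
#' @param sites_a,sites_b `rm_sites` data.frames.
#' @param sequences Named character vector of sequences.
#' @param n_shuffles Number of null repositionings (default 100).
#' @param seed Optional integer seed.
#' @return List with `distances`, `observed` (median distance), `null`
#'   (vector of null medians) and `p_value`.
#' @export
site_distance_enrichment <- function(sites_a, sites_b, sequences,
                                     n_shuffles = 100L, seed = NULL) {
  shared <- intersect(unique(sites_a$sequence_id), unique(sites_b$sequence_id))
  if (length(shared) == 0) stop("site sets share no sequences")
  a <- sites_a[sites_a$sequence_id %in% shared, , drop = FALSE]
  b <- sites_b[sites_b$sequence_id %in% shared, , drop = FALSE]
  b_by_seq <- split(b$position, b$sequence_id)

  nearest <- function(b_pos_by_seq) {
    unlist(lapply(shared, function(sid) {
      pa <- a$position[a$sequence_id == sid]
      pb <- b_pos_by_seq[[sid]]
      if (length(pa) == 0 || is.null(pb) || length(pb) == 0) return(numeric(0))
      vapply(pa, function(p) min(abs(p - pb)), numeric(1))
    }), use.names = FALSE)
  }

  obs <- nearest(b_by_seq)
  obs_stat <- median(obs)
  lens <- nchar(sequences)
  null_stats <- with_seed(seed, vapply(seq_len(n_shuffles), function(r) {
    shuf <- lapply(shared, function(sid) {
      nb <- length(b_by_seq[[sid]])
      if (is.null(nb) || nb == 0) return(integer(0))
      sample.int(lens[[sid]], min(nb, lens[[sid]])) - 1L
    })
    names(shuf) <- shared
    median(nearest(shuf))
  }, numeric(1)))
  p <- (1 + sum(null_stats <= obs_stat)) / (n_shuffles + 1)
  list(distances = obs, observed = obs_stat, null = null_stats, p_value = p)
}

#' Write PWMs in MEME minimal motif format
#'
#' @param clusters `rm_motif_clusters`, or a (possibly named) list of 4 x w
#'   PWM matrices.
#' @param path Output path.
#' @param alphabet Output alphabet (default "ACGU").
#' @export
write_meme <- function(clusters, path, alphabet = "ACGU") {
  pwms <- if (inherits(clusters, "rm_motif_clusters")) {
    setNames(lapply(clusters, `[[`, "pwm"),
             vapply(clusters, function(cl) paste0("cluster_", cl$id),
                    character(1)))
  } else clusters
  if (is.null(names(pwms)) && length(pwms) > 0) {
    names(pwms) <- paste0("motif_", seq_along(pwms))
  }
  nsites <- if (inherits(clusters, "rm_motif_clusters")) {
    vapply(clusters, `[[`, integer(1), "size")
  } else rep(20L, length(pwms))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               paste0("ALPHABET= ", alphabet), "",
               "strands: +", "",
               "Background letter frequencies",
               paste(strsplit(alphabet, "")[[1]], "0.25", collapse = " "),
               ""), con)
  for (i in seq_along(pwms)) {
    pwm <- pwms[[i]]
    writeLines(paste0("MOTIF ", names(pwms)[i]), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       ncol(pwm), nsites[i]), con)
    for (c_ in seq_len(ncol(pwm))) {
      writeLines(paste(sprintf("%.6f", pwm[, c_]), collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Render a simple sequence logo of a PWM
#'
#' Stacked-letter logo with letter heights proportional to the column
#' probabilities, written as PNG when a path is given.
#'
#' @param pwm 4 x w column-stochastic matrix (rows A, C, G, U).
#' @param path Optional PNG output path.
#' @param title Plot title.
#' @export
plot_motif_logo <- function(pwm, path = NULL, title = "motif") {
  draw <- function() {
    w <- ncol(pwm)
    cols <- c(A = "#109648", C = "#255C99", G = "#F7B32B", U = "#D62839")
    graphics::plot(NULL, xlim = c(0.5, w + 0.5), ylim = c(0, 1),
                   xlab = "position", ylab = "probability", main = title,
                   xaxt = "n")
    graphics::axis(1, at = seq_len(w))
    for (c_ in seq_len(w)) {
      ord <- order(pwm[, c_])
      y0 <- 0
      for (r in ord) {
        h <- pwm[r, c_]
        if (h > 0.01) {
          graphics::rect(c_ - 0.45, y0, c_ + 0.45, y0 + h,
                         col = grDevices::adjustcolor(cols[r], 0.25),
                         border = NA)
          graphics::text(c_, y0 + h / 2, rownames(pwm)[r], col = cols[r],
                         cex = 0.6 + 2.2 * h, font = 2)
        }
        y0 <- y0 + h
      }
    }
  }
  if (!is.null(path)) {
    grDevices::png(path, width = 120 * ncol(pwm) + 120, height = 360, res = 96)
    on.exit(grDevices::dev.off())
    draw()
  } else {
    draw()
  }
  invisible(pwm)
}

#' Render the association matrix as a heatmap
#'
#' Uses pheatmap when available, otherwise a base-graphics image.
#'
#' @param assoc `rm_association`.
#' @param path Optional PNG output path.
#' @export
plot_association <- function(assoc, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 720, height = 640, res = 96)
    on.exit(grDevices::dev.off())
  }
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(assoc$rho, cluster_rows = TRUE, cluster_cols = TRUE,
                       display_numbers = TRUE, main = "attention-vector correlation")
  } else {
    graphics::image(seq_len(12), seq_len(12), t(assoc$rho[12:1, ]),
                    axes = FALSE, xlab = "", ylab = "",
                    main = "attention-vector correlation")
    graphics::axis(1, at = seq_len(12), labels = colnames(assoc$rho), las = 2)
    graphics::axis(2, at = seq_len(12), labels = rev(rownames(assoc$rho)), las = 2)
  }
  invisible(assoc)
}
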