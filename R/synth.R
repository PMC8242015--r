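# Synthetic multi-label epitranscriptome corpora with planted motifs.
#
# The generator emulates the structure of real base-resolution modification
# corpora: per-label windows centered on a modifiable base, negatives drawn
# from unmodified occurrences of the same base on the same transcripts,
# strongly imbalanced class sizes, and (optionally) one consensus PWM shared
# between labels to encode cross-modification association.

#' Configuration for the synthetic corpus generator
#'
#' @param labels Modification labels to plant (subset of [rm_labels()]).
#' @param n_positives Integer vector (recycled) of planted site counts per
#'   label; unequal counts encode abundance skew.
#' @param n_transcripts Number of transcripts (default 100).
#' @param transcript_length Length of each transcript in nt (default 1500).
#' @param base_comp Background base composition, named numeric over
#'   A, C, G, U (default uniform).
#' @param pwms Optional named list of planted 4 x w PWMs (rows A, C, G, U);
#'   labels without an entry get a random sharp PWM of width `motif_width`.
#' @param motif_width Width of auto-generated PWMs (default 5; allowed 4-8).
#' @param concentration Probability mass of the consensus base in each
#'   auto-generated PWM column (default 0.9); the center column is always
#'   degenerate at the label's original base.
#' @param share Optional list of label pairs (character vectors of length 2)
#'   forced to share one PWM; shared labels must sit on the same original
#'   base so the degenerate center column stays consistent.
#' @param negative_ratio Negatives sampled per positive (default 1).
#' @param seed Integer seed; generation is fully deterministic under it.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(labels = rm_label_names(),
                         n_positives = 500L,
                         n_transcripts = 100L,
                         transcript_length = 1500L,
                         base_comp = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25),
                         pwms = NULL, motif_width = 5L, concentration = 0.9,
                         share = NULL, negative_ratio = 1,
                         seed = 1L) {
  stopifnot(all(labels %in% rm_label_names()))
  if (motif_width < 4L || motif_width > 8L) {
    stop("motif_width must be between 4 and 8")
  }
  stopifnot(all(sort(names(base_comp)) == c("A", "C", "G", "U")),
            abs(sum(base_comp) - 1) < 1e-8)
  n_positives <- rep_len(as.integer(n_positives), length(labels))
  names(n_positives) <- labels
  if (!is.null(share)) {
    for (pair in share) {
      stopifnot(length(pair) == 2L, all(pair %in% labels))
      if (length(unique(rm_label_base(pair))) != 1L) {
        stop("shared labels ", paste(pair, collapse = "/"),
             " must have the same original base")
      }
    }
  }
  structure(list(labels = labels, n_positives = n_positives,
                 n_transcripts = as.integer(n_transcripts),
                 transcript_length = as.integer(transcript_length),
                 base_comp = base_comp[c("A", "C", "G", "U")],
                 pwms = pwms, motif_width = as.integer(motif_width),
                 concentration = concentration, share = share,
                 negative_ratio = negative_ratio, seed = as.integer(seed)),
            class = "synth_config")
}

# random sharp PWM with the center column degenerate at `base`
random_sharp_pwm <- function(width, base, concentration) {
  bases <- c("A", "C", "G", "U")
  center <- (width + 1L) %/% 2L
  pwm <- matrix(0, nrow = 4L, ncol = width, dimnames = list(bases, NULL))
  for (c_ in seq_len(width)) {
    if (c_ == center) {
      pwm[base, c_] <- 1
    } else {
      cons <- sample(bases, 1L)
      pwm[, c_] <- (1 - concentration) / 3
      pwm[cons, c_] <- concentration
    }
  }
  pwm
}

sample_from_pwm <- function(pwm) {
  paste(vapply(seq_len(ncol(pwm)), function(c_) {
    sample(rownames(pwm), 1L, prob = pwm[, c_])
  }, character(1)), collapse = "")
}

#' Generate a synthetic corpus with planted motifs
#'
#' Draws random transcripts from the background composition; for each label,
#' plants `n_positives` motif instances sampled from its PWM at
#' non-overlapping locations (the center column is the modified base), and
#' samples matched negatives from unmodified occurrences of the same base on
#' the same transcripts. The truth record keeps every planted site and PWM.
#'
#' @param config `synth_config`.
#' @return List with `sequences` (named character vector), `sites`
#'   (`rm_sites` of positives), `negatives` (`rm_sites`), and `truth`
#'   (planted PWMs, per-label site records, config echo).
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  with_seed(cfg$seed, {
    bases <- c("A", "C", "G", "U")
    W <- cfg$motif_width
    # capacity: planted spans must fit with room to spare
    demand <- sum(cfg$n_positives) * (W + 2L)
    capacity <- cfg$n_transcripts * (cfg$transcript_length - W)
    if (demand > 0.5 * capacity) {
      stop("infeasible site density: ", sum(cfg$n_positives),
           " planted sites of width ", W, " exceed half the corpus capacity")
    }

    tx_names <- sprintf("tx%04d", seq_len(cfg$n_transcripts))
    seq_mat <- vapply(seq_len(cfg$n_transcripts), function(i) {
      paste(sample(bases, cfg$transcript_length, replace = TRUE,
                   prob = cfg$base_comp), collapse = "")
    }, character(1))
    sequences <- setNames(seq_mat, tx_names)

    pwms <- list()
    shared_pwm <- list()
    if (!is.null(cfg$share)) {
      for (pair in cfg$share) {
        key <- paste(sort(pair, method = "radix"), collapse = "+")
        shared_pwm[[key]] <- random_sharp_pwm(W, rm_label_base(pair[1]),
                                              cfg$concentration)
      }
    }
    for (lab in cfg$labels) {
      if (!is.null(cfg$pwms) && !is.null(cfg$pwms[[lab]])) {
        pwms[[lab]] <- cfg$pwms[[lab]]
        next
      }
      hit <- NULL
      if (!is.null(cfg$share)) {
        for (pair in cfg$share) {
          if (lab %in% pair) hit <- paste(sort(pair, method = "radix"), collapse = "+")
        }
      }
      pwms[[lab]] <- if (!is.null(hit)) shared_pwm[[hit]] else
        random_sharp_pwm(W, rm_label_base(lab), cfg$concentration)
    }

    # non-overlapping implantation bookkeeping per transcript
    taken <- lapply(tx_names, function(x) integer(0))
    names(taken) <- tx_names
    center_off <- (W + 1L) %/% 2L - 1L  # 0-based offset of center in motif
    site_rows <- list()

    for (lab in cfg$labels) {
      n <- cfg$n_positives[[lab]]
      placed <- 0L
      guard <- 0L
      while (placed < n) {
        guard <- guard + 1L
        if (guard > 50L * n) {
          stop("could not place ", n, " non-overlapping sites for ", lab,
               "; corpus too dense")
        }
        tx <- sample(tx_names, 1L)
        start <- sample.int(cfg$transcript_length - W + 1L, 1L) - 1L  # 0-based
        span <- start:(start + W - 1L)
        if (length(intersect(span, taken[[tx]])) > 0) next
        inst <- sample_from_pwm(pwms[[lab]])
        s <- sequences[[tx]]
        substr(s, start + 1L, start + W) <- inst
        sequences[[tx]] <- s
        taken[[tx]] <- c(taken[[tx]], span)
        placed <- placed + 1L
        site_rows[[length(site_rows) + 1L]] <- data.frame(
          sequence_id = tx, position = start + center_off, strand = "+",
          label = lab, stringsAsFactors = FALSE)
      }
    }

    sites <- do.call(rbind, site_rows)
    class(sites) <- c("rm_sites", "data.frame")
    # planted motif spans are off limits for negatives, not just the centers
    blocked <- do.call(rbind, lapply(site_rows, function(r) {
      data.frame(sequence_id = r$sequence_id,
                 position = (r$position - center_off):(r$position - center_off + W - 1L),
                 stringsAsFactors = FALSE)
    }))
    negatives <- sample_negatives(sites, sequences,
                                  ratio = cfg$negative_ratio,
                                  exclusion = blocked)

    truth <- list(pwms = pwms, sites = sites, config = cfg)
    list(sequences = sequences, sites = sites, negatives = negatives,
         truth = truth)
  })
}

#' Write a generated corpus to disk (FASTA + site TSV + JSON truth record)
#'
#' @param corpus Result of [synth_generate()].
#' @param dir Output directory.
#' @export
write_synth <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(corpus$sequences, file.path(dir, "transcripts.fa"))
  all_sites <- rbind(
    corpus$sites[, c("sequence_id", "position", "strand", "label")],
    corpus$negatives[, c("sequence_id", "position", "strand", "label")])
  class(all_sites) <- c("rm_sites", "data.frame")
  write_sites(all_sites, file.path(dir, "sites.tsv"))
  truth <- list(
    pwms = lapply(corpus$truth$pwms, function(p) as.data.frame(t(p))),
    n_sites = nrow(corpus$sites),
    n_negatives = nrow(corpus$negatives),
    seed = corpus$truth$config$seed,
    labels = corpus$truth$config$labels,
    n_positives = as.list(corpus$truth$config$n_positives))
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Evaluate predictions against the planted truth
#'
#' Scores a [predict_sequence()] table (or a per-position probability matrix)
#' against the generator's truth record: per-label binary AUC of planted
#' sites versus unplanted same-base positions, and optionally the distance of
#' mined PWMs from the planted ones.
#'
#' @param predictions Named list of [predict_sequence()] tables, one per
#'   transcript (names matching the truth record's sequence ids).
#' @param truth Truth record from [synth_generate()].
#' @param mined_pwms Optional named list of mined 4 x w PWMs per label.
#' @return A data.frame with one row per label: `auc_b` against planted
#'   truth and `pwm_tv` (NA when no mined PWM given).
#' @export
truth_eval <- function(predictions, truth, mined_pwms = NULL) {
  labs <- truth$config$labels
  out <- data.frame(label = labs, auc_b = NA_real_, pwm_tv = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(labs)) {
    lab <- labs[i]
    base <- rm_label_base(lab)
    pos_scores <- numeric(0)
    neg_scores <- numeric(0)
    planted <- truth$sites[truth$sites$label == lab, , drop = FALSE]
    for (tx in names(predictions)) {
      tab <- predictions[[tx]]
      col <- paste0("prob_", lab)
      if (!col %in% names(tab)) next
      is_base <- tab$base == base
      planted_pos <- planted$position[planted$sequence_id == tx] + 1L
      pos_rows <- is_base & tab$position %in% planted_pos
      # unplanted occurrences of the base (any label's planted centers excluded)
      any_planted <- truth$sites$position[truth$sites$sequence_id == tx] + 1L
      neg_rows <- is_base & !(tab$position %in% any_planted)
      pos_scores <- c(pos_scores, tab[[col]][pos_rows])
      neg_scores <- c(neg_scores, tab[[col]][neg_rows])
    }
    if (length(pos_scores) > 0 && length(neg_scores) > 0) {
      out$auc_b[i] <- auc_b(pos_scores, neg_scores)
    }
    if (!is.null(mined_pwms) && !is.null(mined_pwms[[lab]])) {
      out$pwm_tv[i] <- pwm_distance(mined_pwms[[lab]], truth$pwms[[lab]])
    }
  }
  out
}
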