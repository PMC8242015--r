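# Sequence and site-table input/output, window assembly, negative sampling,
# motif restriction and train/validation/test splitting.
#
# Internal coordinate convention: 0-based offsets on the provided sequence.
# Site tables on disk may declare either convention; readers normalize.

#' Read a multi-record FASTA file of RNA (or DNA) sequences
#'
#' Sequences are uppercased and T is read as U; the internal alphabet is
#' {A,C,G,U,N}. Record names are truncated at the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of RNA sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty FASTA file: ", path)
  seqs <- as_rna(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  check_rna_alphabet(seqs, "FASTA sequence")
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read a base-resolution modification site table
#'
#' The table is a TSV with header columns `sequence_id`, `position`, `strand`
#' and `label` (an optional `base` column is kept if present, as written for
#' sampled negatives). Positions are normalized to the internal 0-based
#' convention.
#'
#' @param path Path to the TSV file.
#' @param coords Coordinate convention used in the file: `"0based"` or
#'   `"1based"`.
#' @return A `rm_sites` data.frame with 0-based positions.
#' @export
read_sites <- function(path, coords = c("0based", "1based")) {
  coords <- match.arg(coords)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- c("sequence_id", "position", "strand", "label")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("site table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  pos <- suppressWarnings(as.integer(df$position))
  if (anyNA(pos)) {
    stop("malformed position in site table at line ",
         which(is.na(pos))[1] + 1L, " of ", path)
  }
  if (coords == "1based") {
    if (any(pos < 1L)) {
      stop("malformed position (< 1 under 1-based coordinates) at line ",
           which(pos < 1L)[1] + 1L, " of ", path)
    }
    pos <- pos - 1L
  } else if (any(pos < 0L)) {
    stop("malformed position (< 0 under 0-based coordinates) at line ",
         which(pos < 0L)[1] + 1L, " of ", path)
  }
  bad_strand <- !(df$strand %in% c("+", "-"))
  if (any(bad_strand)) {
    stop("malformed strand at line ", which(bad_strand)[1] + 1L, " of ", path)
  }
  ok_label <- df$label %in% c(rm_label_names(), "NEGATIVE")
  if (!all(ok_label)) {
    stop("unknown label '", df$label[which(!ok_label)[1]], "' at line ",
         which(!ok_label)[1] + 1L, " of ", path)
  }
  out <- data.frame(sequence_id = df$sequence_id, position = pos,
                    strand = df$strand, label = df$label,
                    stringsAsFactors = FALSE)
  if ("base" %in% names(df)) out$base <- as_rna(df$base)
  class(out) <- c("rm_sites", "data.frame")
  out
}

#' Write a site table
#'
#' @param sites A `rm_sites` data.frame (internal 0-based positions).
#' @param path Output path.
#' @param coords Coordinate convention to write.
#' @export
write_sites <- function(sites, path, coords = c("0based", "1based")) {
  coords <- match.arg(coords)
  out <- as.data.frame(sites)
  if (coords == "1based") out$position <- out$position + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract fixed-length windows centered on modification sites
#'
#' Each site yields an odd-length window of `L` nucleotides centered on the
#' site; flanks that run past the available sequence are filled with N.
#' Minus-strand sites are reverse-complemented before windowing so the center
#' base is the modified base as read 5'-to-3'. Sites at the same
#' (sequence, position, strand) are merged into one window carrying all their
#' labels, giving the 12-slot label matrix of the multi-label task.
#'
#' @param sites `rm_sites` data.frame, e.g. from [read_sites()].
#' @param sequences Named character vector of sequences, e.g. from
#'   [read_fasta()].
#' @param L Odd window length (21, 51, 101 and 1001 are the usual choices).
#' @return A `rm_windows` data.frame with columns `sequence_id`, `position`,
#'   `strand`, `base`, `sequence` and one 0/1 column per modification label.
#' @export
extract_windows <- function(sites, sequences, L = 51L) {
  L <- as.integer(L)
  if (L %% 2L == 0L) stop("window length L must be odd, got ", L)
  flank <- (L - 1L) %/% 2L
  missing_seq <- !(sites$sequence_id %in% names(sequences))
  if (any(missing_seq)) {
    stop("site references unknown sequence: ",
         sites$sequence_id[which(missing_seq)[1]])
  }
  lens <- nchar(sequences)[sites$sequence_id]
  out_of_range <- sites$position < 0L | sites$position >= lens
  if (any(out_of_range)) {
    i <- which(out_of_range)[1]
    stop("site position ", sites$position[i], " outside sequence ",
         sites$sequence_id[i], " (length ", lens[i], ")")
  }

  key <- paste(sites$sequence_id, sites$position, sites$strand, sep = "\r")
  first <- !duplicated(key)
  uk <- sites[first, c("sequence_id", "position", "strand")]
  labmat <- matrix(0L, nrow = nrow(uk), ncol = 12L,
                   dimnames = list(NULL, rm_label_names()))
  pos_rows <- sites$label != "NEGATIVE"
  if (any(pos_rows)) {
    ridx <- match(key[pos_rows], key[first])
    cidx <- match(sites$label[pos_rows], rm_label_names())
    labmat[cbind(ridx, cidx)] <- 1L
  }

  padded <- setNames(paste0(strrep("N", flank), sequences, strrep("N", flank)),
                     names(sequences))
  win <- substr(padded[uk$sequence_id], uk$position + 1L, uk$position + L)
  minus <- uk$strand == "-"
  if (any(minus)) win[minus] <- revcomp_rna(win[minus])
  center <- substr(win, flank + 1L, flank + 1L)

  # positives must sit on their label's original base
  for (j in seq_len(12L)) {
    lab <- rm_label_names()[j]
    bad <- labmat[, j] == 1L & center != rm_labels()$base[j]
    if (any(bad)) {
      i <- which(bad)[1]
      stop("center base ", center[i], " at ", uk$sequence_id[i], ":",
           uk$position[i], " does not match original base ",
           rm_labels()$base[j], " of label ", lab)
    }
  }
  if ("base" %in% names(sites)) {
    declared <- sites$base[first]
    bad <- !is.na(declared) & declared != center
    if (any(bad)) {
      i <- which(bad)[1]
      stop("declared base ", declared[i], " at ", uk$sequence_id[i], ":",
           uk$position[i], " does not match sequence base ", center[i])
    }
  }

  out <- data.frame(sequence_id = uk$sequence_id, position = uk$position,
                    strand = uk$strand, base = center, sequence = unname(win),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(labmat))
  rownames(out) <- NULL
  class(out) <- c("rm_windows", "data.frame")
  out
}

rm_window_labels <- function(windows) {
  as.matrix(windows[, rm_label_names(), drop = FALSE])
}

#' Sample negative sites matched to positive sites
#'
#' For each modification label, negatives are drawn uniformly at random from
#' unmodified occurrences of the label's original base on the same transcripts
#' that carry its positive sites, excluding every positive position (any
#' label) and every position in an optional exclusion list. Transcripts with
#' no eligible position contribute no negatives (with a warning).
#'
#' @param positives `rm_sites` data.frame of positive sites.
#' @param sequences Named character vector of sequences.
#' @param ratio Negatives per positive (default 1).
#' @param exclusion Optional `rm_sites`-like data.frame of positions to
#'   exclude from the negative pool (e.g. lower-confidence reported sites).
#' @param seed Optional integer seed; fixed seed reproduces the same set.
#' @return `rm_sites` data.frame with label `"NEGATIVE"` and a `base` column.
#' @export
sample_negatives <- function(positives, sequences, ratio = 1,
                             exclusion = NULL, seed = NULL) {
  stopifnot(nrow(positives) > 0)
  blocked <- paste(positives$sequence_id, positives$position, sep = "\r")
  if (!is.null(exclusion) && nrow(exclusion) > 0) {
    blocked <- c(blocked, paste(exclusion$sequence_id, exclusion$position,
                                sep = "\r"))
  }
  blocked <- unique(blocked)

  with_seed(seed, {
    res <- list()
    grp_key <- paste(positives$label, positives$strand)
    groups <- split(positives, factor(grp_key,
                                      levels = sort(unique(grp_key),
                                                    method = "radix")))
    n_empty <- 0L
    for (g in groups) {
      lab <- g$label[1]
      strand <- g$strand[1]
      base <- if (lab == "NEGATIVE") g$base[1] else rm_label_base(lab)
      # base as read 5'->3' on the site's strand; on '-' the stored sequence
      # shows its complement
      seek <- if (strand == "+") base else chartr("ACGU", "UGCA", base)
      pool_id <- character(0)
      pool_pos <- integer(0)
      for (tx in sort(unique(g$sequence_id), method = "radix")) {
        hits <- gregexpr(seek, sequences[[tx]], fixed = TRUE)[[1]]
        hits <- if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
        hits <- hits[!(paste(tx, hits, sep = "\r") %in% blocked)]
        if (length(hits) == 0L) {
          n_empty <- n_empty + 1L
          next
        }
        pool_id <- c(pool_id, rep(tx, length(hits)))
        pool_pos <- c(pool_pos, hits)
      }
      n_take <- round(ratio * nrow(g))
      if (length(pool_pos) < n_take) {
        warning("negative pool for ", lab, " (", strand, ") has only ",
                length(pool_pos), " eligible positions; requested ", n_take)
        n_take <- length(pool_pos)
      }
      if (n_take == 0L) next
      pick <- sample.int(length(pool_pos), n_take)
      res[[length(res) + 1L]] <- data.frame(
        sequence_id = pool_id[pick], position = pool_pos[pick],
        strand = strand, label = "NEGATIVE", base = base,
        stringsAsFactors = FALSE)
    }
    if (n_empty > 0L) {
      warning(n_empty, " transcript/label group(s) had no eligible negative position")
    }
    out <- do.call(rbind, res)
    if (is.null(out)) {
      out <- data.frame(sequence_id = character(0), position = integer(0),
                        strand = character(0), label = character(0),
                        base = character(0), stringsAsFactors = FALSE)
    }
    out <- out[!duplicated(paste(out$sequence_id, out$position, out$strand,
                                 out$base, sep = "\r")), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("rm_sites", "data.frame")
    out
  })
}

#' Restrict windows to a label's consensus motif context
#'
#' m6A sites must sit at the A of a DRACH motif (positions -2..+2 around the
#' center, IUPAC D, R, A, C, H) and m6Am sites at the A of a BCA motif
#' (positions -2..0). Windows under any other label pass through unchanged.
#' An N anywhere in the motif context fails the match. Windows too short to
#' read the motif are dropped with a warning.
#'
#' @param windows `rm_windows` data.frame.
#' @param label The label whose motif restriction is applied.
#' @return The filtered `rm_windows` data.frame.
#' @export
apply_motif_filter <- function(windows, label) {
  spec <- switch(label,
    m6A = list(motif = c("D", "R", "A", "C", "H"), offset = -2L),
    m6Am = list(motif = c("B", "C", "A"), offset = -2L),
    NULL)
  if (is.null(spec)) return(windows)
  L <- nchar(windows$sequence)
  center <- (L - 1L) %/% 2L  # 0-based
  lo <- center + spec$offset
  hi <- lo + length(spec$motif) - 1L
  too_short <- lo < 0L | hi >= L
  if (any(too_short)) {
    warning(sum(too_short), " window(s) too short to evaluate the ", label,
            " motif; dropped")
  }
  keep <- logical(nrow(windows))
  for (i in which(!too_short)) {
    ctx <- strsplit(substr(windows$sequence[i], lo[i] + 1L, hi[i] + 1L),
                    "", fixed = TRUE)[[1]]
    keep[i] <- matches_iupac(ctx, spec$motif)
  }
  out <- windows[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rm_windows", "data.frame")
  out
}

window_class <- function(windows) {
  labmat <- rm_window_labels(windows)
  cls <- rep(NA_character_, nrow(windows))
  # abundant labels first so the rarest positive label wins for bookkeeping
  for (j in order(colSums(labmat), decreasing = TRUE)) {
    cls[labmat[, j] == 1L] <- rm_label_names()[j]
  }
  neg <- rowSums(labmat) == 0L
  cls[neg] <- paste0("neg_", windows$base[neg])
  cls
}

#' Split windows into training, validation and test sets
#'
#' Every class (each modification's positives plus the per-base negative
#' pools) contributes exactly `val_per_class` validation and `test_per_class`
#' test windows, sampled without replacement; the remainder forms the
#' (imbalanced) training set. Multi-label windows are assigned to the class of
#' their rarest positive label for bookkeeping.
#'
#' @param windows `rm_windows` data.frame.
#' @param val_per_class,test_per_class Balanced per-class sizes (defaults 150
#'   and 50).
#' @param seed Optional integer seed.
#' @return A `rm_split` list with elements `train`, `validation`, `test`,
#'   `seed` and a per-class `counts` data.frame.
#' @export
split_dataset <- function(windows, val_per_class = 150L, test_per_class = 50L,
                          seed = NULL) {
  cls <- window_class(windows)
  need <- val_per_class + test_per_class
  tab <- table(cls)
  too_small <- tab <= need
  if (any(too_small)) {
    cl <- names(tab)[too_small][1]
    stop("class ", cl, " has ", tab[[cl]], " windows; more than ",
         need, " are required for a ", val_per_class, "/", test_per_class,
         " validation/test split")
  }
  with_seed(seed, {
    set_of <- rep("train", nrow(windows))
    for (cl in sort(names(tab), method = "radix")) {
      idx <- which(cls == cl)
      pick <- sample(idx, need)
      set_of[pick[seq_len(val_per_class)]] <- "validation"
      set_of[pick[val_per_class + seq_len(test_per_class)]] <- "test"
    }
    take <- function(s) {
      out <- windows[set_of == s, , drop = FALSE]
      rownames(out) <- NULL
      class(out) <- c("rm_windows", "data.frame")
      out
    }
    cls_sorted <- sort(names(tab), method = "radix")
    counts <- data.frame(class = cls_sorted,
                         total = as.integer(tab[cls_sorted]),
                         validation = val_per_class, test = test_per_class,
                         stringsAsFactors = FALSE)
    counts$train <- counts$total - need
    structure(list(train = take("train"), validation = take("validation"),
                   test = take("test"), seed = seed, counts = counts),
              class = "rm_split")
  })
}

#' Write a windows table as TSV
#' @param windows `rm_windows` data.frame.
#' @param path Output path.
#' @export
write_windows <- function(windows, path) {
  write.table(as.data.frame(windows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a windows table written by [write_windows()]
#' @param path Path to the TSV file.
#' @return `rm_windows` data.frame.
#' @export
read_windows <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  class(df) <- c("rm_windows", "data.frame")
  df
}

#' Write a dataset split as three TSVs plus a JSON provenance record
#'
#' @param split `rm_split` from [split_dataset()].
#' @param dir Output directory (created if absent).
#' @export
write_split <- function(split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_windows(split$train, file.path(dir, "train.tsv"))
  write_windows(split$validation, file.path(dir, "validation.tsv"))
  write_windows(split$test, file.path(dir, "test.tsv"))
  prov <- list(seed = split$seed, counts = split$counts,
               written = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(dir, "split.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
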