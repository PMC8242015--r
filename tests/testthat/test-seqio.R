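make_sites <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  class(df) <- c("rm_sites", "data.frame")
  df
}

test_that("site tables are normalized to 0-based coordinates on read", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sequence_id\tposition\tstrand\tlabel",
               "tx1\t10\t+\tm6A",
               "tx1\t11\t+\tPsi"), tf)
  s0 <- read_sites(tf, coords = "0based")
  expect_equal(s0$position, c(10L, 11L))
  s1 <- read_sites(tf, coords = "1based")
  expect_equal(s1$position, c(9L, 10L))
  expect_s3_class(s0, "rm_sites")
})

test_that("malformed site rows are rejected with the offending line", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sequence_id\tposition\tstrand\tlabel",
               "tx1\t10\t+\tm6A",
               "tx1\tten\t+\tm6A"), tf)
  expect_error(read_sites(tf), "line 3")
  writeLines(c("sequence_id\tposition\tstrand\tlabel",
               "tx1\t10\t+\tm9X"), tf)
  expect_error(read_sites(tf), "unknown label 'm9X'.*line 2")
  writeLines(c("sequence_id\tposition\tlabel", "tx1\t10\tm6A"), tf)
  expect_error(read_sites(tf), "lacks column")
})

test_that("site tables round-trip through write_sites up to coordinate convention", {
  s <- make_sites(sequence_id = c("tx1", "tx2"), position = c(0L, 41L),
                  strand = c("+", "-"), label = c("m6A", "Psi"))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_sites(s, tf, coords = "1based")
  back <- read_sites(tf, coords = "1based")
  expect_equal(as.data.frame(back), as.data.frame(s))
})

test_that("FASTA reading uppercases, maps T to U, and truncates names", {
  tf <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">tx1 some description", "acgtACGT", ">tx2", "NNNAC"), tf)
  seqs <- read_fasta(tf)
  expect_equal(names(seqs), c("tx1", "tx2"))
  expect_equal(unname(seqs["tx1"]), "ACGUACGU")
  tf2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, tf2)
  expect_equal(read_fasta(tf2), seqs)
})

test_that("windows are centered, N-filled at boundaries, and validated", {
  seqs <- c(tx = paste(rep("C", 51), collapse = ""))
  substr(seqs["tx"], 26, 26) <- "A"
  s <- make_sites(sequence_id = "tx", position = 25L, strand = "+",
                  label = "m6A")
  w <- extract_windows(s, seqs, L = 51)
  expect_equal(w$sequence, unname(seqs["tx"]))  # exact fit
  expect_equal(w$base, "A")
  expect_equal(w$m6A, 1L)

  s0 <- make_sites(sequence_id = "tx2", position = 0L, strand = "+",
                   label = "m6A")
  w0 <- extract_windows(s0, c(tx2 = paste0("A", strrep("G", 30))), L = 21)
  expect_equal(substr(w0$sequence, 1, 10), strrep("N", 10))
  expect_equal(substr(w0$sequence, 11, 11), "A")
  expect_equal(nchar(w0$sequence), 21L)

  expect_error(extract_windows(s, seqs, L = 20), "odd")
  bad <- make_sites(sequence_id = "tx", position = 1L, strand = "+",
                    label = "m6A")  # base C under an A label
  expect_error(extract_windows(bad, seqs, L = 21), "does not match original base")
  oob <- make_sites(sequence_id = "tx", position = 99L, strand = "+",
                    label = "m6A")
  expect_error(extract_windows(oob, seqs, L = 21), "outside sequence")
})

test_that("minus-strand sites are reverse-complemented so the center reads 5'->3'", {
  # U at position 5 of the plus strand is an A site on the minus strand
  seqs <- c(tx = "GGGGGUGGGGG")
  s <- make_sites(sequence_id = "tx", position = 5L, strand = "-",
                  label = "m6A")
  w <- extract_windows(s, seqs, L = 11)
  expect_equal(w$base, "A")
  expect_equal(w$sequence, "CCCCCACCCCC")
})

test_that("multi-label sites at one position merge into a single window", {
  seqs <- c(tx = paste0(strrep("G", 20), "A", strrep("G", 20)))
  s <- make_sites(sequence_id = rep("tx", 2), position = c(20L, 20L),
                  strand = "+", label = c("m6A", "m1A"))
  w <- extract_windows(s, seqs, L = 21)
  expect_equal(nrow(w), 1L)
  expect_equal(w$m6A + w$m1A, 2L)
})

test_that("negative sampling matches base, avoids positives/exclusions, and is seeded", {
  set.seed(1)
  seqs <- c(tx1 = random_rna(1, 400, seed = 5), tx2 = random_rna(1, 400, seed = 6))
  pos <- make_sites(
    sequence_id = rep(c("tx1", "tx2"), each = 5),
    position = c(which(strsplit(seqs[["tx1"]], "")[[1]] == "A")[1:5] - 1L,
                 which(strsplit(seqs[["tx2"]], "")[[1]] == "A")[1:5] - 1L),
    strand = "+", label = "m6A")
  neg <- sample_negatives(pos, seqs, ratio = 1, seed = 42)
  expect_equal(nrow(neg), 10L)
  expect_true(all(neg$label == "NEGATIVE"))
  ch1 <- strsplit(seqs[["tx1"]], "")[[1]]
  ch2 <- strsplit(seqs[["tx2"]], "")[[1]]
  got <- ifelse(neg$sequence_id == "tx1", ch1[neg$position + 1L],
                ch2[neg$position + 1L])
  expect_true(all(got == "A"))
  expect_false(any(paste(neg$sequence_id, neg$position) %in%
                     paste(pos$sequence_id, pos$position)))
  neg2 <- sample_negatives(pos, seqs, ratio = 1, seed = 42)
  expect_identical(neg, neg2)
  neg3 <- sample_negatives(pos, seqs, ratio = 1, seed = 43)
  expect_false(identical(neg, neg3))
})

test_that("a transcript with every eligible base modified contributes no negatives", {
  seqs <- c(tx = "CACAC")
  pos <- make_sites(sequence_id = c("tx", "tx"), position = c(1L, 3L),
                    strand = "+", label = "m6A")
  w <- testthat::capture_warnings(
    neg <- sample_negatives(pos, seqs, ratio = 1, seed = 1))
  expect_true(any(grepl("eligible", w)))
  expect_equal(nrow(neg), 0L)
})

test_that("the DRACH and BCA motif filters keep and drop the right contexts", {
  mk_win <- function(ctx, flank = 8) {
    # place the 5-nt context so its middle base is the window center
    seq <- paste0(strrep("G", flank), ctx, strrep("G", flank))
    df <- data.frame(sequence_id = "tx", position = 10L, strand = "+",
                     base = substr(ctx, 3, 3), sequence = seq,
                     stringsAsFactors = FALSE)
    for (lab in rm_labels()$label) df[[lab]] <- 0L
    df$m6A <- 1L
    class(df) <- c("rm_windows", "data.frame")
    df
  }
  expect_equal(nrow(apply_motif_filter(mk_win("GGACU"), "m6A")), 1L)  # DRACH
  expect_equal(nrow(apply_motif_filter(mk_win("GGAAU"), "m6A")), 0L)  # 4th != C
  expect_equal(nrow(apply_motif_filter(mk_win("GGANU"), "m6A")), 0L)  # N fails
  expect_equal(nrow(apply_motif_filter(mk_win("GGACU"), "m5C")), 1L)  # pass-through
  # BCA: positions -2..0 relative to the center, which is the A itself
  mk_bca <- function(tri) {
    seq <- paste0(strrep("G", 8), tri, strrep("G", 10))
    df <- data.frame(sequence_id = "tx", position = 10L, strand = "+",
                     base = "A", sequence = seq, stringsAsFactors = FALSE)
    for (lab in rm_labels()$label) df[[lab]] <- 0L
    df$m6Am <- 1L
    class(df) <- c("rm_windows", "data.frame")
    df
  }
  expect_equal(nrow(apply_motif_filter(mk_bca("UCA"), "m6Am")), 1L)
  expect_equal(nrow(apply_motif_filter(mk_bca("ACA"), "m6Am")), 0L)  # B excludes A
})

test_that("splits have exact per-class sizes, are disjoint, and reproduce under a seed", {
  win <- fixture_windows()
  split <- split_dataset(win, val_per_class = 60, test_per_class = 30, seed = 7)
  cls_val <- rmnet:::window_class(split$validation)
  cls_test <- rmnet:::window_class(split$test)
  expect_true(all(table(cls_val) == 60))
  expect_true(all(table(cls_test) == 30))
  key <- function(w) paste(w$sequence_id, w$position, w$strand)
  expect_length(intersect(key(split$train), key(split$validation)), 0)
  expect_length(intersect(key(split$train), key(split$test)), 0)
  expect_length(intersect(key(split$validation), key(split$test)), 0)
  split2 <- split_dataset(win, val_per_class = 60, test_per_class = 30, seed = 7)
  expect_identical(split, split2)
})

test_that("an undersized class aborts the split with its name and requirement", {
  win <- fixture_windows()
  small <- win[rmnet:::window_class(win) != "m5C" |
                 seq_len(nrow(win)) %in% head(which(win$m5C == 1L), 200), ]
  class(small) <- c("rm_windows", "data.frame")
  expect_error(split_dataset(small, 150, 50), "m5C.*200")
})

test_that("split sizes and disjointness hold across seeds", {
  win <- fixture_windows()
  key <- function(w) paste(w$sequence_id, w$position, w$strand)
  for (seed in 1:20) {
    sp <- split_dataset(win, val_per_class = 55, test_per_class = 25,
                        seed = seed)
    expect_true(all(table(rmnet:::window_class(sp$validation)) == 55))
    expect_true(all(table(rmnet:::window_class(sp$test)) == 25))
    expect_length(intersect(key(sp$validation), key(sp$test)), 0)
  }
})

test_that("windows and splits round-trip through their TSV writers", {
  win <- fixture_windows()[1:20, ]
  class(win) <- c("rm_windows", "data.frame")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_windows(win, tf)
  expect_equal(as.data.frame(read_windows(tf)), as.data.frame(win))
  dir <- withr::local_tempdir()
  split <- fixture_split()
  write_split(split, dir)
  expect_true(all(file.exists(file.path(dir, c("train.tsv", "validation.tsv",
                                               "test.tsv", "split.json")))))
  prov <- jsonlite::read_json(file.path(dir, "split.json"))
  expect_equal(prov$seed, 7)
})
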