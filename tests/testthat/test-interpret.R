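test_that("the path-integral estimator recovers a linear model exactly", {
  set.seed(7)
  w <- rnorm(10)
  f <- function(x) list(value = sum(w * x), grad = w)
  x <- rnorm(10)
  ig <- integrated_gradients(f, x, steps = 5)
  expect_equal(ig$attributions, w * x, tolerance = 1e-12)
  expect_lt(ig$residual, 1e-12)
  # input equal to the baseline attributes nothing
  ig0 <- integrated_gradients(f, x, baseline = x, steps = 5)
  expect_equal(ig0$attributions, rep(0, 10))
  expect_error(integrated_gradients(f, x, steps = 0), "steps")
})

test_that("model attributions satisfy completeness and vanish at the baseline", {
  model <- fixture_model()
  win <- fixture_split()$test
  apos <- win[win$m6A == 1, ][1:3, ]
  for (i in 1:3) {
    ig <- integrated_gradients(model, apos$sequence[i], "m6A", steps = 50)
    expect_lt(attr(ig, "residual"), 1e-2)
    expect_lt(abs(sum(ig$score) - attr(ig, "gap")), 1e-2)
    expect_equal(nrow(ig), 51L)
  }
  # all-N input IS the zero baseline, so the gap and attributions are zero
  ign <- integrated_gradients(model, strrep("N", 51), "m6A", steps = 8)
  expect_equal(ign$score, rep(0, 51), tolerance = 1e-12)
  expect_equal(attr(ign, "gap"), 0, tolerance = 1e-12)
})

test_that("the completeness residual shrinks as the step count doubles", {
  model <- fixture_model()
  win <- fixture_split()$test
  seqs <- win$sequence[win$m6A == 1][1:4]
  res <- sapply(c(25, 100, 400), function(st) {
    mean(sapply(seqs, function(s) {
      attr(integrated_gradients(model, s, "m6A", steps = st), "residual")
    }))
  })
  # quadrupling the step count tightens the quadrature (the piecewise-smooth
  # network makes the decrease monotone only on average)
  expect_true(res[2] < res[1] || res[2] < 1e-4)
  expect_true(res[3] < res[2] || res[3] < 1e-4)
})

test_that("label/base compatibility is enforced for attribution", {
  model <- fixture_model()
  win <- fixture_split()$test
  cseq <- win$sequence[win$base == "C"][1]
  expect_error(integrated_gradients(model, cseq, "m6A"), "not applicable")
  expect_error(integrated_gradients(model, cseq, "m9X"), "unknown label")
})

test_that("attention profiles are probability vectors over nucleotides", {
  model <- fixture_model()
  win <- fixture_split()$test$sequence[1]
  prof <- attention_profile(model, win)
  expect_equal(dim(prof), c(51L, 12L))
  expect_equal(colSums(prof), setNames(rep(1, 12), rm_labels()$label),
               tolerance = 1e-9)
  expect_true(all(prof >= 0))
})

test_that("uniform token weights map to uniform nucleotide weights", {
  model <- fixture_model()
  model$params$V[] <- 0  # constant scores -> uniform attention
  prof <- attention_profile(model, fixture_split()$test$sequence[1])
  # interior nucleotides (covered by a full complement of tokens) are equal
  interior <- prof[4:48, 1]
  expect_equal(interior, rep(interior[1], length(interior)), tolerance = 1e-9)
})

test_that("greedy window selection picks spikes and masks their neighborhoods", {
  scores <- c(0, 0, 5, 5, 5, 0, 0, 0, 9, 9)
  picks <- rmnet:::select_windows_greedy(scores, w = 2, k_max = 2)
  expect_equal(picks[1], 9L)          # the 9,9 pair
  expect_equal(picks[2], 3L)          # best remaining 5,5 pair
  # single spike: first candidate covers it
  sp <- rmnet:::select_windows_greedy(c(0, 0, 0, 10, 0, 0), w = 3, k_max = 1)
  expect_true(sp[1] %in% 2:4)
  # selected windows never overlap
  set.seed(5)
  for (rep in 1:10) {
    sc <- runif(40)
    p <- rmnet:::select_windows_greedy(sc, w = 6, k_max = 4)
    if (length(p) > 1) {
      expect_true(all(abs(diff(sort(p))) >= 6))
    }
  }
})

test_that("motif mining returns non-overlapping candidates from top positives", {
  model <- fixture_model()
  win <- fixture_split()$test
  cand <- mine_motifs(model, win, "m6A", top_fraction = 0.5, w = 6,
                      k_per_sample = 2, steps = 8)
  expect_s3_class(cand, "rm_motif_candidates")
  expect_true(nrow(cand) > 0)
  expect_true(all(nchar(cand$sequence) == 6L))
  for (s in unique(cand$sample)) {
    starts <- sort(cand$start[cand$sample == s])
    if (length(starts) > 1) expect_true(all(diff(starts) >= 6))
  }
  expect_warning(empty <- mine_motifs(model, win[win$m7G == 1, ], "m7G"),
                 "no positive windows")
  expect_equal(nrow(empty), 0L)
})

test_that("trivially separable candidates cluster into their two consensus PWMs", {
  cand <- data.frame(sample = 1:40, start = 1L,
                     sequence = rep(c("GGACUU", "UUCCGA"), each = 20),
                     mean_score = 1, stringsAsFactors = FALSE)
  class(cand) <- c("rm_motif_candidates", "data.frame")
  cl <- cluster_motifs(cand, min_samples = 5)
  expect_length(cl, 2L)
  expect_setequal(vapply(cl, `[[`, character(1), "consensus"),
                  c("GGACUU", "UUCCGA"))
  for (c_ in cl) {
    expect_equal(colSums(c_$pwm), rep(1, 6), tolerance = 1e-12)
    expect_true(all(apply(c_$pwm, 2, max) > 0.95))
  }
  # a single repeated sequence forms one near-degenerate cluster
  cand1 <- cand
  cand1$sequence <- "GGACUU"
  cl1 <- cluster_motifs(cand1, min_samples = 5)
  expect_length(cl1, 1L)
  expect_true(all(apply(cl1[[1]]$pwm, 2, max) > 0.99))
  expect_error(cluster_motifs(cand[1:5, ]), "at least 10")
})

test_that("PWM distance is zero at identity and aligns different widths", {
  pwm <- rmnet:::pwm_from_sequences(rep("GGACU", 10))
  expect_equal(pwm_distance(pwm, pwm), 0)
  wide <- cbind(matrix(0.25, 4, 1,
                       dimnames = list(c("A", "C", "G", "U"), NULL)),
                pwm)
  expect_lt(pwm_distance(pwm, wide), 1e-12)
  other <- rmnet:::pwm_from_sequences(rep("UUUUU", 10))
  expect_gt(pwm_distance(pwm, other), 0.5)
})

test_that("the association matrix is a valid correlation structure", {
  model <- fixture_model()
  assoc <- association_matrix(model)
  expect_equal(dim(assoc$rho), c(12L, 12L))
  expect_equal(assoc$rho, t(assoc$rho))
  expect_equal(unname(diag(assoc$rho)), rep(1, 12))
  off <- assoc$rho[upper.tri(assoc$rho)]
  expect_true(all(off >= -1 & off <= 1))
  expect_true(all(assoc$p[upper.tri(assoc$p)] >= 0 &
                    assoc$p[upper.tri(assoc$p)] <= 1, na.rm = TRUE))
  # perfectly anti-correlated score vectors
  model$params$V[, 2] <- -model$params$V[, 1]
  a2 <- association_matrix(model)
  expect_equal(a2$rho[1, 2], -1)
  # a zero-variance vector propagates NA rather than a fabricated value
  model$params$V[, 3] <- 0.7
  a3 <- association_matrix(model)
  expect_true(is.na(a3$rho[1, 3]))
})

test_that("site-distance enrichment flags adjacency and identity", {
  seqs <- setNames(random_rna(4, 300, seed = 3), paste0("tx", 1:4))
  set.seed(9)
  a <- data.frame(sequence_id = rep(names(seqs), each = 5),
                  position = as.integer(runif(20, 10, 280)),
                  strand = "+", label = "m6A", stringsAsFactors = FALSE)
  b <- a
  b$position <- b$position + 1L  # adjacent to every a-site
  r <- site_distance_enrichment(a, b, seqs, n_shuffles = 99, seed = 1)
  expect_equal(r$observed, 1)
  expect_lte(r$p_value, 2 / 100)
  ident <- site_distance_enrichment(a, a, seqs, n_shuffles = 19, seed = 2)
  expect_true(all(ident$distances == 0))
  far <- a
  far$sequence_id <- "other"
  expect_error(site_distance_enrichment(a, far, seqs), "share no sequences")
})

test_that("PWMs serialize to MEME minimal format", {
  pwm <- rmnet:::pwm_from_sequences(rep(c("GGACUU", "GGACUA"), 10))
  tf <- withr::local_tempfile(fileext = ".meme")
  write_meme(list(drach_like = pwm), tf)
  lines <- readLines(tf)
  expect_true(any(grepl("^MEME version", lines)))
  expect_true(any(grepl("^ALPHABET= ACGU", lines)))
  expect_true(any(grepl("^MOTIF drach_like", lines)))
  mat_line <- grep("letter-probability matrix", lines)
  expect_length(mat_line, 1L)
  vals <- do.call(rbind, lapply(lines[(mat_line + 1):(mat_line + 6)],
                                function(l) as.numeric(strsplit(l, " ")[[1]])))
  expect_equal(rowSums(vals), rep(1, 6), tolerance = 1e-5)
})
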