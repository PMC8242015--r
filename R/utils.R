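# misc internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a temporary, seeded RNG stream; the caller's RNG state
# is untouched. seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

# reverse complement over the RNA alphabet {A,C,G,U,N}
revcomp_rna <- function(x) {
  comp <- chartr("ACGUN", "UGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# IUPAC degeneracy over RNA; a window character "N" never satisfies a motif
# position (conservative filtering).
iupac_rna <- function() {
  list(A = "A", C = "C", G = "G", U = "U",
       R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
       K = c("G", "U"), M = c("A", "C"),
       B = c("C", "G", "U"), D = c("A", "G", "U"),
       H = c("A", "C", "U"), V = c("A", "C", "G"),
       N = c("A", "C", "G", "U"))
}

matches_iupac <- function(window_chars, motif_chars) {
  tab <- iupac_rna()
  for (i in seq_along(motif_chars)) {
    ch <- window_chars[i]
    if (ch == "N" || !(ch %in% tab[[motif_chars[i]]])) return(FALSE)
  }
  TRUE
}

# normalize an input nucleotide string: uppercase, DNA T read as U
as_rna <- function(x) {
  x <- chartr("t", "U", chartr("T", "U", toupper(x)))
  x
}

check_rna_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGUN]", x)
  if (any(bad)) {
    stop(what, " contains characters outside {A,C,G,U,N} (after T->U): ",
         substr(x[which(bad)[1]], 1, 40))
  }
  invisible(x)
}
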