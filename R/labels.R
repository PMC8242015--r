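#' The twelve supported RNA modification labels
#'
#' Registry of the modification types the model predicts, in the fixed slot
#' order used by every 12-column label matrix and probability matrix in the
#' package. Each modification occurs on exactly one "original" nucleotide:
#' adenosine for m6A, m1A, m6Am, Am and inosine (I, an edited A); cytidine for
#' m5C and Cm; guanosine for m7G and Gm; uridine for Psi (pseudouridine), Um
#' and m5U.
#'
#' @return A data.frame with columns `label` and `base`, 12 rows.
#' @examples
#' rm_labels()
#' @export
rm_labels <- function() {
  data.frame(
    label = c("m6A", "m1A", "m5C", "m5U", "m6Am", "m7G",
              "Psi", "I", "Am", "Cm", "Gm", "Um"),
    base = c("A", "A", "C", "U", "A", "G",
             "U", "A", "A", "C", "G", "U"),
    stringsAsFactors = FALSE
  )
}

#' Original base of a modification label
#'
#' @param label Character vector of modification names.
#' @return Character vector of bases ("A", "C", "G" or "U").
#' @examples
#' rm_label_base(c("m6A", "Psi"))
#' @export
rm_label_base <- function(label) {
  reg <- rm_labels()
  i <- match(label, reg$label)
  if (anyNA(i)) {
    stop("unknown modification label(s): ",
         paste(unique(label[is.na(i)]), collapse = ", "),
         "; supported labels are ", paste(reg$label, collapse = ", "))
  }
  reg$base[i]
}

# slot order used throughout
rm_label_names <- function() rm_labels()$label

# logical mask: which labels are compatible with each center base
rm_base_mask <- function(bases) {
  reg <- rm_labels()
  m <- outer(bases, reg$base, "==")
  colnames(m) <- reg$label
  m
}

# supervision mask for training: a positive window carries supervision only
# for its own label(s) -- in the source corpora each modification's dataset
# lists its own sites, and a site of one modification is never asserted to be
# a negative of another -- while a negative window supervises every task on
# its center base.
rm_supervision_mask <- function(labels, bases) {
  m <- rm_base_mask(bases) * 1
  pos <- rowSums(labels) > 0
  m[pos, ] <- labels[pos, , drop = FALSE]
  m
}
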