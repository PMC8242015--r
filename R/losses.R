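# Multi-task training objectives over masked per-label binary cross-entropy.
#
# Every training window supervises only the tasks whose modification sits on
# its center base (an A-centered window carries supervision for m6A, m1A,
# m6Am, Am and I; the other seven outputs are ignored in the loss). The mask
# matrix M (B x 12) encodes this.
#
# Normalization conventions (they matter for the algebraic identities between
# modes):
#   * "bce", "focal", "effective_number" and OHEM average per-sample means:
#     loss = mean_b [ sum_j M w_j l_bj / n_b ], n_b = number of supervised
#     tasks of sample b. OHEM restricts the outer mean to the top-q fraction
#     of samples by that per-sample loss, so OHEM with q = 1 is exactly "bce".
#   * uncertainty weighting is a task-level objective:
#     loss = sum_j exp(-s_j) L_j + s_j with L_j the masked mean BCE of task j,
#     so frozen s = 0 gives exactly the unweighted task sum.

#' Effective-number class weights
#'
#' The weight of a class with n samples is proportional to (1 - beta) /
#' (1 - beta^n); weights are normalized to mean 1. As beta tends to 0 all
#' classes are weighted equally; as beta tends to 1 the weights approach the
#' inverse class frequencies 1/n.
#'
#' @param n Integer vector of per-class sample counts.
#' @param beta Rebalancing parameter in \[0, 1) (default 0.999).
#' @return Numeric weight vector, mean 1.
#' @export
effective_num_weights <- function(n, beta = 0.999) {
  stopifnot(all(n >= 1), beta >= 0, beta < 1)
  w <- if (beta == 0) rep(1, length(n)) else (1 - beta) / (1 - beta^n)
  w * length(w) / sum(w)
}

clip01 <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Multi-label training loss and its gradient
#'
#' Computes the scalar training objective, its gradient with respect to the
#' pre-sigmoid logits, and (for uncertainty weighting) the gradient with
#' respect to the learnable log-variances.
#'
#' @param probs B x 12 matrix of predicted probabilities.
#' @param labels B x 12 binary matrix.
#' @param mask B x 12 binary matrix marking supervised tasks per sample.
#' @param mode One of `"bce"`, `"bce+ohem"`, `"bce+uw"`, `"bce+ohem+uw"`,
#'   `"focal"`, `"effective_number"`.
#' @param gamma Focal exponent (default 2).
#' @param q OHEM retained fraction of samples per batch (default 0.7).
#' @param log_sigma 12 task log-variances for uncertainty weighting.
#' @param class_weights 12 fixed weights for `"effective_number"`.
#' @return List with `loss` (scalar), `dlogits` (B x 12), `dlog_sigma`
#'   (12 or NULL), `task_losses` (masked mean BCE per task) and `retained`
#'   (row indices kept by OHEM).
#' @export
rm_loss <- function(probs, labels, mask,
                    mode = c("bce", "bce+ohem", "bce+uw", "bce+ohem+uw",
                             "focal", "effective_number"),
                    gamma = 2, q = 0.7, log_sigma = rep(0, 12),
                    class_weights = rep(1, 12)) {
  mode <- match.arg(mode)
  stopifnot(all(dim(probs) == dim(labels)), all(dim(probs) == dim(mask)))
  dimnames(probs) <- dimnames(labels) <- dimnames(mask) <- NULL
  B <- nrow(probs)
  p <- clip01(probs)
  y <- labels
  bce <- -(y * log(p) + (1 - y) * log1p(-p)) * mask
  dbce_dlogit <- (p - y) * mask       # d(BCE)/d(logit), per entry
  n_b <- rowSums(mask)
  live <- n_b > 0
  n_b[!live] <- 1                      # avoid 0/0; dead rows contribute 0

  task_counts <- colSums(mask)
  task_losses <- ifelse(task_counts > 0, colSums(bce) / pmax(task_counts, 1), NA_real_)

  use_ohem <- mode %in% c("bce+ohem", "bce+ohem+uw")
  use_uw <- mode %in% c("bce+uw", "bce+ohem+uw")

  if (mode == "focal") {
    pt <- clip01(ifelse(y == 1, p, 1 - p))
    fl <- -(1 - pt)^gamma * log(pt) * mask
    l_b <- rowSums(fl) / n_b
    loss <- mean(l_b[live])
    # d(fl)/d(pt) then chain through pt and the sigmoid
    dfl_dpt <- (gamma * (1 - pt)^(pmax(gamma - 1, 0)) * log(pt) - (1 - pt)^gamma / pt)
    if (gamma == 0) dfl_dpt <- -1 / pt
    dpt_dp <- ifelse(y == 1, 1, -1)
    dlogits <- dfl_dpt * dpt_dp * p * (1 - p) * mask / (n_b * sum(live))
    return(list(loss = loss, dlogits = dlogits, dlog_sigma = NULL,
                task_losses = task_losses, retained = which(live)))
  }

  w_task <- if (mode == "effective_number") class_weights else rep(1, ncol(p))
  wb <- sweep(bce, 2, w_task, "*")

  if (use_uw) {
    ew <- exp(-log_sigma)
    retained <- which(live)
    if (use_ohem) {
      l_b <- rowSums(sweep(bce, 2, ew, "*")) / n_b
      m <- max(1L, ceiling(q * sum(live)))
      retained <- which(live)[order(l_b[live], decreasing = TRUE)[seq_len(m)]]
    }
    rcount <- colSums(mask[retained, , drop = FALSE])
    Lj <- ifelse(rcount > 0, colSums(bce[retained, , drop = FALSE]) / pmax(rcount, 1), 0)
    loss <- sum(ew * Lj + log_sigma)
    dlogits <- matrix(0, nrow = B, ncol = ncol(p))
    scale <- ifelse(rcount > 0, ew / pmax(rcount, 1), 0)
    dlogits[retained, ] <- sweep(dbce_dlogit[retained, , drop = FALSE], 2, scale, "*")
    dlog_sigma <- -ew * Lj + 1
    return(list(loss = loss, dlogits = dlogits, dlog_sigma = dlog_sigma,
                task_losses = task_losses, retained = retained))
  }

  l_b <- rowSums(wb) / n_b
  retained <- which(live)
  if (use_ohem) {
    m <- max(1L, ceiling(q * sum(live)))
    retained <- which(live)[order(l_b[live], decreasing = TRUE)[seq_len(m)]]
  }
  loss <- mean(l_b[retained])
  dlogits <- matrix(0, nrow = B, ncol = ncol(p))
  dlogits[retained, ] <- sweep(dbce_dlogit[retained, , drop = FALSE], 2, w_task, "*") /
    (n_b[retained] * length(retained))
  list(loss = loss, dlogits = dlogits, dlog_sigma = NULL,
       task_losses = task_losses, retained = retained)
}
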