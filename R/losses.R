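#' Loss hyperparameters for the hybrid Siamese objective
#'
#' Houses the contrastive margin and the task weights of the weighted
#' multi-task objective. The default weighting is contrastive 1.0, abnormality
#' head 2.0 (clinical priority) and body-part head 0.5 (regularizer). The
#' named lambda preset `(0.6, 0.3, 0.1)` is the alternative hybrid weighting
#' in which the three weights sum to one.
#'
#' @param margin Contrastive margin `m > 0`. Default 1.
#' @param contrastive,abnormal,body Non-negative task weights.
#' @param lambda_variant If `TRUE`, use the `(0.6, 0.3, 0.1)` preset
#'   (overrides the three weight arguments).
#' @return A list of class `loss_weights`.
#' @export
loss_weights <- function(margin = 1, contrastive = 1, abnormal = 2,
                         body = 0.5, lambda_variant = FALSE) {
  if (lambda_variant) {
    contrastive <- 0.6; abnormal <- 0.3; body <- 0.1
  }
  if (margin <= 0) stop_input("margin must be > 0")
  if (min(contrastive, abnormal, body) < 0) {
    stop_input("task weights must be >= 0")
  }
  structure(list(margin = margin, contrastive = contrastive,
                 abnormal = abnormal, body = body),
            class = "loss_weights")
}

#' Margin-based contrastive loss over a batch of embedding distances
#'
#' Computes `mean(y * d^2 + (1 - y) * pmax(m - d, 0)^2)` over the batch:
#' similar pairs (`y = 1`) are pulled toward zero distance, dissimilar pairs
#' (`y = 0`) are pushed beyond the margin `m`. The loss is zero exactly when
#' every similar pair is coincident and every dissimilar pair clears the
#' margin.
#'
#' @param d Non-negative Euclidean distances between pair embeddings.
#' @param y Binary similarity labels (1 = similar, 0 = dissimilar).
#' @param margin Margin `m > 0`. Default 1.
#' @return A non-negative scalar.
#' @export
contrastive_loss <- function(d, y, margin = 1) {
  if (length(d) == 0) stop_input("empty batch")
  if (length(d) != length(y)) stop_input("d and y lengths differ")
  if (!all(is.finite(d)) || any(d < 0)) {
    stop_input("distances must be finite and non-negative")
  }
  if (!all(y %in% c(0, 1))) stop_input("y must be binary 0/1")
  if (margin <= 0) stop_input("margin must be > 0")
  mean(y * d^2 + (1 - y) * pmax(margin - d, 0)^2)
}

#' Weighted multi-task objective
#'
#' Combines the contrastive loss with the two classification-head
#' cross-entropies as
#' `w_contrastive * L_con + w_abnormal * L_abn + w_body * L_body`.
#' With defaults this is `L_con + 2.0 * L_abn + 0.5 * L_body`; the lambda
#' preset gives `0.6 * L_con + 0.3 * L_abn + 0.1 * L_body`.
#'
#' @param l_contrastive,l_ce_abnormal,l_ce_body Finite non-negative component
#'   losses.
#' @param weights A [loss_weights()] object.
#' @return A scalar.
#' @export
multitask_loss <- function(l_contrastive, l_ce_abnormal, l_ce_body,
                           weights = loss_weights()) {
  comps <- c(l_contrastive, l_ce_abnormal, l_ce_body)
  if (!all(is.finite(comps))) stop_input("loss components must be finite")
  if (any(comps < 0)) stop_input("loss components must be >= 0")
  stopifnot(inherits(weights, "loss_weights"))
  weights$contrastive * l_contrastive +
    weights$abnormal * l_ce_abnormal +
    weights$body * l_ce_body
}

#' Composite distillation loss
#'
#' Generic fixed-weight combination used for teacher-student distillation:
#' `0.5 * L_CE + 0.3 * L_KL + 0.2 * L_MSE`, where the caller supplies the
#' cross-entropy against teacher soft labels, the KL divergence between output
#' distributions, and the MSE between intermediate embeddings as scalars.
#'
#' @param l_ce,l_kl,l_mse Finite non-negative component losses.
#' @param weights Length-3 non-negative weight vector. Default
#'   `c(0.5, 0.3, 0.2)`.
#' @return A scalar.
#' @export
distillation_loss <- function(l_ce, l_kl, l_mse, weights = c(0.5, 0.3, 0.2)) {
  comps <- c(l_ce, l_kl, l_mse)
  if (!all(is.finite(comps))) stop_input("loss components must be finite")
  if (any(comps < 0)) stop_input("loss components must be >= 0")
  if (length(weights) != 3 || any(weights < 0)) {
    stop_input("weights must be 3 non-negative values")
  }
  sum(weights * comps)
}

# softmax cross-entropy over a logit matrix (rows = samples); labels 1-based.
# Returns mean loss and the gradient wrt logits (already divided by n).
softmax_ce <- function(logits, labels, grad = FALSE) {
  n <- nrow(logits)
  zmax <- apply(logits, 1, max)
  ez <- exp(logits - zmax)
  p <- ez / rowSums(ez)
  eps <- 1e-12
  loss <- -mean(log(p[cbind(seq_len(n), labels)] + eps))
  if (!grad) return(list(loss = loss))
  g <- p
  g[cbind(seq_len(n), labels)] <- g[cbind(seq_len(n), labels)] - 1
  list(loss = loss, grad = g / n)
}
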