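#' Confusion matrix with rows = actual, columns = predicted
#'
#' @param truth,pred Class vectors of equal length.
#' @param levels Class levels (defaults to the union, sorted).
#' @return An integer matrix of counts.
#' @export
confusion_matrix <- function(truth, pred, levels = NULL) {
  if (length(truth) != length(pred)) stop_input("truth/pred lengths differ")
  if (length(truth) == 0) stop_input("empty evaluation set")
  levels <- levels %||% sort(unique(c(truth, pred)))
  tab <- table(factor(truth, levels), factor(pred, levels))
  out <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                dimnames = dimnames(tab))
  out
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is `trace / total`; per-class precision, recall and F1 follow the
#' one-vs-rest definitions, with macro averages across classes. Undefined
#' ratios (empty denominator) are reported as 0.
#'
#' @param cm A square confusion matrix (rows = actual, columns = predicted).
#' @return A tibble with one row per class plus a `"macro"` row; the
#'   `accuracy` column repeats the overall accuracy.
#' @export
metrics_from_confusion <- function(cm) {
  if (nrow(cm) != ncol(cm)) stop_input("confusion matrix must be square")
  total <- sum(cm)
  if (total == 0) stop_input("empty confusion matrix")
  acc <- sum(diag(cm)) / total
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  cls <- rownames(cm) %||% paste0("class", seq_len(nrow(cm)))
  prec <- vapply(seq_len(nrow(cm)), function(i) {
    safe_div(cm[i, i], sum(cm[, i]))
  }, numeric(1))
  rec <- vapply(seq_len(nrow(cm)), function(i) {
    safe_div(cm[i, i], sum(cm[i, ]))
  }, numeric(1))
  f1 <- safe_div(2 * prec * rec, prec + rec)
  out <- tibble::tibble(class = cls, precision = prec, recall = rec, f1 = f1)
  out <- dplyr::bind_rows(out, tibble::tibble(
    class = "macro", precision = mean(prec), recall = mean(rec),
    f1 = mean(f1)))
  out$accuracy <- acc
  out
}

#' Evaluate a trained (or quantized) model on labeled images
#'
#' Predictions come from the abnormality head's argmax; the body-part head is
#' evaluated separately. Deterministic given model and data (eval mode, no
#' dropout).
#'
#' @param model A `siam_fit` or `sonosiam_qmodel`.
#' @param images Named list of raw `[0,1]` pixel matrices.
#' @param manifest Tibble with `id`, `condition`, `body_part` for the images.
#' @return An object of class `siam_eval`: list with `condition_cm`,
#'   `body_cm`, `metrics` (condition-task tibble), `body_metrics`, and
#'   `accuracy`.
#' @export
evaluate_model <- function(model, images, manifest) {
  if (nrow(manifest) == 0) stop_input("empty evaluation subset")
  imgs <- images[manifest$id]
  pred_cond <- predict(model, imgs, type = "condition")
  pred_body <- predict(model, imgs, type = "body_part")
  ccm <- confusion_matrix(manifest$condition, pred_cond,
                          levels = condition_levels)
  bcm <- confusion_matrix(manifest$body_part, pred_body,
                          levels = body_part_levels)
  structure(list(condition_cm = ccm, body_cm = bcm,
                 metrics = metrics_from_confusion(ccm),
                 body_metrics = metrics_from_confusion(bcm),
                 accuracy = sum(diag(ccm)) / sum(ccm)),
            class = "siam_eval")
}

#' @export
print.siam_eval <- function(x, ...) {
  cat("<siam_eval> abnormality accuracy:",
      sprintf("%.4f", x$accuracy), "\n")
  print(x$condition_cm)
  invisible(x)
}

# ---- broom-style tidiers and plots -------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained Siamese fit into its per-epoch training log
#'
#' @param x A `siam_fit`.
#' @param ... Unused.
#' @return The per-epoch log tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.siam_fit <- function(x, ...) x$log

#' One-row summary of a trained Siamese fit
#'
#' @param x A `siam_fit`.
#' @param ... Unused.
#' @return Tibble with parameter count, FP32 size, epochs, and final loss.
#' @export
#' @exportS3Method generics::glance
glance.siam_fit <- function(x, ...) {
  counts <- count_backbone_params(x$spec)
  tibble::tibble(
    n_params = sum(counts$params),
    fp32_mb = model_size_bytes(x$spec, "fp32") / 1e6,
    embedding_dim = utils::tail(x$spec$dense_dims, 1),
    epochs = nrow(x$log),
    final_loss = x$log$loss_total[nrow(x$log)]
  )
}

#' Tidy an evaluation into per-class metric rows
#'
#' @param x A `siam_eval`.
#' @param ... Unused.
#' @return Tibble of per-class and macro metrics for both heads.
#' @export
#' @exportS3Method generics::tidy
tidy.siam_eval <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$metrics, task = "abnormality"),
    dplyr::mutate(x$body_metrics, task = "body_part")
  )
}

#' Training-log loss curves
#'
#' @param object A `siam_fit`.
#' @param ... Unused.
#' @return A ggplot of per-epoch losses, shaded by curriculum stage.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.siam_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$log,
                              dplyr::starts_with("loss_"),
                              names_to = "component", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$stage), size = 2) +
    ggplot2::labs(x = "epoch", y = "mean batch loss",
                  title = "Siamese multi-task training") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
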