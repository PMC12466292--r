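#' Train the Siamese screening network on a phantom manifest
#'
#' Each epoch: the curriculum stage is chosen by [stage_schedule()] (or pairs
#' are drawn uniformly when `pairing = "random"`), image pairs are sampled,
#' both pair members pass through the single shared-weight encoder, the
#' margin-based contrastive loss is computed on pair embedding distances and
#' combined with the two per-image classification-head cross-entropies under
#' the weighted multi-task objective, and all parameters are updated with
#' Adam. Augmentation is applied to abnormal images only, and only here, in
#' the training loop, so test partitions are never augmented. Raw `[0,1]`
#' images are standardized internally with [preprocess_image()] at the spec's
#' input side.
#'
#' @param images Named list of raw `[0,1]` pixel matrices keyed by id.
#' @param manifest Tibble with `id`, `body_part`, `condition`, `source_tag`
#'   rows for the training partition.
#' @param spec A [backbone_spec()]. Default [small_backbone_spec()].
#' @param weights A [loss_weights()].
#' @param epochs Training epochs. Default 15.
#' @param pairs_per_epoch Pairs sampled per epoch. Default
#'   `max(64, round(0.4 * n))`.
#' @param batch_pairs Pairs per minibatch. Default 32.
#' @param lr Adam learning rate. Default 1e-3.
#' @param pairing `"curriculum"` (three-stage schedule) or `"random"`
#'   (balanced similar/dissimilar pairs with no stratum constraints).
#' @param boundaries Curriculum stage boundaries, see [stage_schedule()].
#' @param augment An [augmentation_config()], or `NULL` to disable.
#' @param seed Integer seed covering pair sampling, augmentation, dropout and
#'   initialization.
#' @return A `siam_fit`: the trained `siam_network` plus a per-epoch `log`
#'   tibble (`epoch`, `stage`, `loss_total`, `loss_contrastive`,
#'   `loss_abnormal`, `loss_body`).
#' @export
train_siamese <- function(images, manifest, spec = small_backbone_spec(),
                          weights = loss_weights(), epochs = 15L,
                          pairs_per_epoch = NULL, batch_pairs = 32L,
                          lr = 1e-3, pairing = c("curriculum", "random"),
                          boundaries = c(1 / 3, 2 / 3),
                          augment = augmentation_config(), seed = 1L) {
  pairing <- match.arg(pairing)
  if (length(unique(manifest$condition)) < 2) {
    stop_input("manifest must contain both conditions")
  }
  n <- nrow(manifest)
  pairs_per_epoch <- pairs_per_epoch %||% max(128L, round(0.6 * n))
  model <- siam_network(spec, seed = seed)
  state <- list()
  t_adam <- 0L
  log_rows <- list()
  cond_lab <- match(manifest$condition, condition_levels)
  body_lab <- match(manifest$body_part, body_part_levels)
  names(cond_lab) <- names(body_lab) <- manifest$id

  # pre-standardized image cache at the spec's side
  std <- lapply(images[manifest$id], preprocess_image, side = spec$input_side)

  for (epoch in seq_len(epochs) - 1L) {
    if (pairing == "curriculum") {
      stage <- stage_schedule(epoch, epochs, boundaries)
      pairs <- sample_pairs(manifest, stage, pairs_per_epoch,
                            seed = derive_seed(seed, 500L + epoch))
    } else {
      stage <- "random"
      pairs <- random_pairs(manifest, pairs_per_epoch,
                            seed = derive_seed(seed, 500L + epoch))
    }
    ep_loss <- c(total = 0, con = 0, abn = 0, body = 0)
    n_batches <- 0L
    batch_starts <- seq(1L, nrow(pairs), by = batch_pairs)
    for (bi in seq_along(batch_starts)) {
      rows <- batch_starts[bi]:min(batch_starts[bi] + batch_pairs - 1L,
                                   nrow(pairs))
      pb <- pairs[rows, ]
      ids <- as.vector(rbind(pb$id_a, pb$id_b))  # interleaved a1,b1,a2,b2,...
      nb <- length(ids)

      batch_seed <- derive_seed(seed, 9000L + epoch * 131L + bi)
      imgs <- withr::with_seed(batch_seed, {
        lapply(seq_along(ids), function(j) {
          id <- ids[j]
          if (!is.null(augment) && manifest$condition[
                match(id, manifest$id)] == "abnormal") {
            cfg <- augmentation_config(
              flip_probability = augment$flip_probability,
              max_rotation_deg = augment$max_rotation_deg,
              max_translation_frac = augment$max_translation_frac,
              seed = derive_seed(batch_seed, j))
            raw <- augment_abnormal((std[[id]] + 1) / 2, "abnormal", cfg)
            preprocess_image(raw, side = spec$input_side)
          } else {
            std[[id]]
          }
        })
      })
      x <- array(unlist(imgs, use.names = FALSE),
                 c(spec$input_side, spec$input_side, 1L, nb))

      step <- withr::with_seed(derive_seed(seed, 70000L + epoch * 997L + bi), {
        siam_train_step(model, x, pb$y, cond_lab[ids], body_lab[ids], weights)
      })
      if (!is.finite(step$loss_total)) {
        stop_pipeline("training diverged: non-finite loss at epoch ", epoch)
      }
      t_adam <- t_adam + 1L
      upd <- adam_step(model$params, step$grads, state, lr, t_adam)
      model$params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + c(step$loss_total, step$loss_con,
                             step$loss_abn, step$loss_body)
      n_batches <- n_batches + 1L
    }
    ep_loss <- ep_loss / n_batches
    log_rows[[epoch + 1L]] <- tibble::tibble(
      epoch = epoch, stage = stage,
      loss_total = ep_loss[["total"]], loss_contrastive = ep_loss[["con"]],
      loss_abnormal = ep_loss[["abn"]], loss_body = ep_loss[["body"]])
  }
  structure(list(spec = spec, params = model$params, bn = NULL,
                 weights = weights,
                 log = dplyr::bind_rows(log_rows),
                 config = list(epochs = epochs, lr = lr, pairing = pairing,
                               pairs_per_epoch = pairs_per_epoch,
                               batch_pairs = batch_pairs, seed = seed)),
            class = c("siam_fit", "siam_network"))
}

# one forward/backward pass over an interleaved pair batch
siam_train_step <- function(model, x, y_pair, cond_lab, body_lab, weights) {
  nb <- dim(x)[4]
  fwd <- siam_forward(model, x, train = TRUE, keep_cache = TRUE)
  emb <- fwd$embedding
  ia <- seq(1L, nb, 2L)
  ib <- ia + 1L
  diff <- emb[ia, , drop = FALSE] - emb[ib, , drop = FALSE]
  d <- sqrt(rowSums(diff^2))
  np <- length(d)

  l_con <- contrastive_loss(d, y_pair, weights$margin)
  # d(l_con)/d(emb_a): similar 2*diff/np; dissimilar -2*max(m-d,0)/d*diff/np
  hinge <- pmax(weights$margin - d, 0)
  coef <- ifelse(y_pair == 1, 2, ifelse(d > 0, -2 * hinge / d, 0)) / np
  d_emb <- matrix(0, nb, ncol(emb))
  d_emb[ia, ] <- coef * diff
  d_emb[ib, ] <- -coef * diff

  heads <- predict_heads(model, emb)
  ce_abn <- softmax_ce(heads$abnormality_logits, cond_lab, grad = TRUE)
  ce_body <- softmax_ce(heads$body_part_logits, body_lab, grad = TRUE)

  grads <- list()
  p <- model$params
  ga <- dense_backward(ce_abn$grad, emb, p$head_abn_W)
  gb <- dense_backward(ce_body$grad, emb, p$head_body_W)
  grads$head_abn_W <- weights$abnormal * ga$dW
  grads$head_abn_b <- weights$abnormal * ga$db
  grads$head_body_W <- weights$body * gb$dW
  grads$head_body_b <- weights$body * gb$db

  d_emb_total <- weights$contrastive * d_emb +
    weights$abnormal * ga$dx + weights$body * gb$dx
  grads <- c(grads, siam_backward(model, fwd, d_emb_total))
  list(grads = grads,
       loss_total = multitask_loss(l_con, ce_abn$loss, ce_body$loss, weights),
       loss_con = l_con, loss_abn = ce_abn$loss, loss_body = ce_body$loss)
}

# naive pairing baseline: balanced similar/dissimilar, no stratum constraints
random_pairs <- function(manifest, n_pairs, seed) {
  withr::with_seed(derive_seed(seed, 47L), {
    cond <- manifest$condition
    nimg <- nrow(manifest)
    ia <- rep(seq_len(nimg - 1L), times = (nimg - 1L):1L)
    ib <- sequence((nimg - 1L):1L) + ia
    same <- cond[ia] == cond[ib]
    n_sim <- ceiling(n_pairs / 2)
    pick_s <- which(same)[sample.int(sum(same), n_sim, replace = TRUE)]
    pick_d <- which(!same)[sample.int(sum(!same), n_pairs - n_sim,
                                      replace = TRUE)]
    take <- c(pick_s, pick_d)
    out <- tibble::tibble(id_a = manifest$id[ia[take]],
                          id_b = manifest$id[ib[take]],
                          y = as.numeric(cond[ia[take]] == cond[ib[take]]),
                          stage = "random")
    out[sample(nrow(out)), ]
  })
}

#' Predict conditions, body parts, embeddings or logits for raw images
#'
#' @param object A `siam_fit`.
#' @param images Named list of raw `[0,1]` pixel matrices.
#' @param type What to return: predicted `"condition"`, `"body_part"`, the
#'   `"embedding"` matrix, or both head `"logits"`.
#' @param ... Unused.
#' @return A character vector, matrix, or list of logit matrices.
#' @export
predict.siam_fit <- function(object, images,
                             type = c("condition", "body_part",
                                      "embedding", "logits"), ...) {
  type <- match.arg(type)
  std <- lapply(images, preprocess_image, side = object$spec$input_side)
  emb <- siam_embed(object, std, mode = "eval")
  if (type == "embedding") return(emb)
  heads <- predict_heads(object, emb)
  if (type == "logits") return(heads)
  if (type == "condition") {
    condition_levels[max.col(heads$abnormality_logits, ties.method = "first")]
  } else {
    body_part_levels[max.col(heads$body_part_logits, ties.method = "first")]
  }
}
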