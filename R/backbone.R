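#' Specify the shared-weight Siamese encoder backbone
#'
#' The default reproduces the reference screening architecture: three
#' convolutional blocks (64 filters of 5x5, 128 of 5x5, 256 of 3x3), each
#' followed by ReLU, 2x2 max-pooling and dropout at rates 0.2/0.3/0.4, so a
#' 224x224 single-channel input yields a 256x28x28 feature map; the flattened
#' map passes through dense layers 512 -> 256 -> 128 to a 128-dimensional
#' embedding. Convolutions use "same" zero-padding and stride 1; dense layers
#' use ReLU except the final (linear) embedding layer. Two affine heads map
#' the embedding to 2 abnormality logits and 3 body-part logits.
#'
#' @param conv_blocks List of `c(out_channels, kernel_side, dropout_rate)`
#'   triples, one per block.
#' @param dense_dims Dense layer widths; the last entry is the embedding
#'   dimension.
#' @param input_side Input image side in pixels; must be divisible by
#'   `2^length(conv_blocks)`.
#' @param input_channels Input channel count. Default 1 (grayscale).
#' @return A list of class `backbone_spec`.
#' @export
backbone_spec <- function(conv_blocks = list(c(64, 5, 0.2),
                                             c(128, 5, 0.3),
                                             c(256, 3, 0.4)),
                          dense_dims = c(512, 256, 128),
                          input_side = 224L,
                          input_channels = 1L) {
  for (blk in conv_blocks) {
    if (length(blk) != 3 || blk[2] %% 2 != 1) {
      stop_config("each conv block needs (out_channels, odd kernel, dropout)")
    }
    if (blk[3] < 0 || blk[3] >= 1) stop_config("dropout rate must be in [0, 1)")
  }
  if (input_side %% 2^length(conv_blocks) != 0) {
    stop_config("input_side must be divisible by 2^n_blocks")
  }
  structure(list(conv_blocks = conv_blocks,
                 dense_dims = as.integer(dense_dims),
                 input_side = as.integer(input_side),
                 input_channels = as.integer(input_channels)),
            class = "backbone_spec")
}

#' A small desk-scale backbone for CPU experiments
#'
#' Same block structure as [backbone_spec()] at a size that trains on a CPU in
#' minutes: 8/16/32 filters with 5/3/3 kernels, dense 128 -> 64, 64x64
#' inputs, 64-d embedding.
#'
#' @param input_side Input side in pixels. Default 64.
#' @return A `backbone_spec`.
#' @export
small_backbone_spec <- function(input_side = 64L) {
  backbone_spec(conv_blocks = list(c(8, 5, 0.1), c(16, 3, 0.1), c(32, 3, 0.2)),
                dense_dims = c(128, 64),
                input_side = input_side)
}

# analytic per-layer geometry: returns list with conv output sides, flatten
# size, and per-layer parameter shapes
backbone_geometry <- function(spec) {
  side <- spec$input_side
  cin <- spec$input_channels
  conv <- list()
  for (i in seq_along(spec$conv_blocks)) {
    blk <- spec$conv_blocks[[i]]
    conv[[i]] <- list(cin = cin, cout = blk[1], k = blk[2],
                      dropout = blk[3], side_out = side %/% 2L, side_in = side)
    cin <- blk[1]
    side <- side %/% 2L
  }
  flat <- side * side * cin
  if (length(spec$dense_dims) > 0) {
    dins <- c(flat, utils::head(spec$dense_dims, -1))
    dense <- Map(function(din, dout) list(din = din, dout = dout),
                 dins, spec$dense_dims)
    emb <- utils::tail(spec$dense_dims, 1)
  } else {
    dense <- list()
    emb <- flat
  }
  list(conv = conv, flat = flat, dense = dense, emb = emb,
       feature_side = side)
}

#' Write / read a backbone specification as a JSON config block
#'
#' Round-trips every field of a [backbone_spec()], so architectures can be
#' versioned alongside experiment configs.
#'
#' @param spec A `backbone_spec`.
#' @param path JSON file path.
#' @return `write_backbone_spec()` returns the path invisibly;
#'   `read_backbone_spec()` returns a `backbone_spec`.
#' @export
write_backbone_spec <- function(spec, path) {
  jsonlite::write_json(
    list(conv_blocks = spec$conv_blocks, dense_dims = spec$dense_dims,
         input_side = spec$input_side, input_channels = spec$input_channels),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_backbone_spec
#' @export
read_backbone_spec <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  backbone_spec(conv_blocks = lapply(m$conv_blocks, function(b) unlist(b)),
                dense_dims = unlist(m$dense_dims),
                input_side = m$input_side,
                input_channels = m$input_channels)
}

#' Analytic parameter count of a backbone
#'
#' Counts all trainable parameters (weights and biases) of the convolutional
#' stack, the dense stack and both classification heads, layer by layer,
#' without instantiating weights.
#'
#' @param spec A [backbone_spec()].
#' @return A tibble with columns `layer`, `weights`, `biases`, `params`.
#' @export
count_backbone_params <- function(spec) {
  geo <- backbone_geometry(spec)
  rows <- list()
  for (i in seq_along(geo$conv)) {
    g <- geo$conv[[i]]
    rows[[length(rows) + 1]] <- tibble::tibble(
      layer = paste0("conv", i),
      weights = g$k^2 * g$cin * g$cout, biases = g$cout)
  }
  for (i in seq_along(geo$dense)) {
    g <- geo$dense[[i]]
    rows[[length(rows) + 1]] <- tibble::tibble(
      layer = paste0("dense", i), weights = g$din * g$dout, biases = g$dout)
  }
  if (length(geo$dense) > 0) {
    # heads attach to the dense embedding; a conv-only spec has none
    rows[[length(rows) + 1]] <- tibble::tibble(
      layer = "head_abnormal", weights = geo$emb * 2, biases = 2)
    rows[[length(rows) + 1]] <- tibble::tibble(
      layer = "head_body", weights = geo$emb * 3, biases = 3)
  }
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, params = .data$weights + .data$biases)
}

#' On-disk model size in bytes at a given precision
#'
#' FP32 size is 4 bytes per trainable parameter (weights and biases of the
#' conv stack, dense stack and both heads). INT8 size counts 1 byte per
#' weight, 4 bytes per bias (stored int32), plus quantization metadata: a
#' 4-byte per-output-channel weight scale and an 8-byte per-tensor activation
#' scale/zero-point per layer (plus one for the input). Both are computed
#' analytically from the spec.
#'
#' @param spec A [backbone_spec()].
#' @param precision `"fp32"` or `"int8"`.
#' @return Size in bytes.
#' @export
model_size_bytes <- function(spec, precision = c("fp32", "int8")) {
  precision <- match.arg(precision)
  counts <- count_backbone_params(spec)
  if (precision == "fp32") {
    return(4 * sum(counts$params))
  }
  n_layers <- nrow(counts)
  channels <- counts$biases  # one weight scale per output channel
  sum(counts$weights) + 4 * sum(counts$biases) +
    4 * sum(channels) + 8 * (n_layers + 1)
}

#' Initialize a Siamese network with shared weights
#'
#' He-uniform initialization for conv and dense weights, zero biases. The
#' parameter store is a single flat list: both branch evaluations of an image
#' pair read the same parameters, which is what makes the network Siamese.
#'
#' @param spec A [backbone_spec()].
#' @param seed Integer seed for the initialization draw.
#' @return A list of class `siam_network` with elements `spec` and `params`.
#' @export
siam_network <- function(spec = backbone_spec(), seed = 1L) {
  geo <- backbone_geometry(spec)
  params <- withr::with_seed(derive_seed(seed, 53L), {
    p <- list()
    for (i in seq_along(geo$conv)) {
      g <- geo$conv[[i]]
      fan_in <- g$k^2 * g$cin
      p[[paste0("conv", i, "_W")]] <-
        he_uniform(c(g$k, g$k, g$cin, g$cout), fan_in)
      p[[paste0("conv", i, "_b")]] <- rep(0, g$cout)
    }
    for (i in seq_along(geo$dense)) {
      g <- geo$dense[[i]]
      w <- glorot_uniform(c(g$din, g$dout), g$din, g$dout)
      # the final (linear) embedding layer starts at reduced scale so initial
      # pair distances sit near the contrastive margin instead of far outside
      # it, keeping both loss terms active from the first step
      if (i == length(geo$dense)) w <- w * 0.1
      p[[paste0("dense", i, "_W")]] <- w
      p[[paste0("dense", i, "_b")]] <- rep(0, g$dout)
    }
    p$head_abn_W <- glorot_uniform(c(geo$emb, 2), geo$emb, 2)
    p$head_abn_b <- rep(0, 2)
    p$head_body_W <- glorot_uniform(c(geo$emb, 3), geo$emb, 3)
    p$head_body_b <- rep(0, 3)
    p
  })
  structure(list(spec = spec, params = params, bn = NULL),
            class = "siam_network")
}

# full forward pass. x: (H, W, C, N) standardized pixels. Returns embeddings
# (N, emb), layer caches for backprop (when keep_cache), and conv feature
# dimensions.
siam_forward <- function(model, x, train = FALSE, keep_cache = FALSE) {
  spec <- model$spec
  p <- model$params
  geo <- backbone_geometry(spec)
  if (dim(x)[1] != spec$input_side || dim(x)[2] != spec$input_side) {
    stop_input("input side ", dim(x)[1], " does not match spec input_side ",
               spec$input_side)
  }
  caches <- list()
  conv_dims <- list()
  for (i in seq_along(geo$conv)) {
    W <- p[[paste0("conv", i, "_W")]]
    b <- p[[paste0("conv", i, "_b")]]
    cv <- conv2d_forward(x, W, b, keep_patches = keep_cache)
    y <- cv$out
    if (!is.null(model$bn) && length(model$bn) >= i &&
        !is.null(model$bn[[i]])) {
      bn <- model$bn[[i]]
      f <- bn$gamma / sqrt(bn$var + bn$eps)
      y <- sweep(y, 3, f, "*") + rep(bn$beta - f * bn$mean,
                                     each = dim(y)[1] * dim(y)[2])
    }
    rl <- relu_forward(y)
    pl <- maxpool2_forward(rl$out)
    conv_dims[[i]] <- dim(pl$out)[1:3]  # block output: post-ReLU, post-pool
    dr <- dropout_forward(pl$out, geo$conv[[i]]$dropout, train)
    if (keep_cache) {
      caches[[paste0("conv", i)]] <- list(
        x_dim = dim(x), patches = cv$patches, relu_mask = rl$mask,
        pool = pl, drop_mask = dr$mask)
    }
    x <- dr$out
  }
  n <- dim(x)[4]
  flat <- t(matrix(x, geo$flat, n))  # (N, flat): H,W,C order per image
  h <- flat
  for (i in seq_along(geo$dense)) {
    W <- p[[paste0("dense", i, "_W")]]
    b <- p[[paste0("dense", i, "_b")]]
    z <- dense_forward(h, W, b)
    last <- i == length(geo$dense)
    if (!last) {
      rl <- relu_forward(z)
      if (keep_cache) {
        caches[[paste0("dense", i)]] <- list(x = h, relu_mask = rl$mask)
      }
      h <- rl$out
    } else {
      if (keep_cache) caches[[paste0("dense", i)]] <- list(x = h)
      h <- z
    }
  }
  list(embedding = h, caches = caches, conv_dims = conv_dims,
       flat_dim = geo$flat)
}

# backward pass from embedding gradient; returns flat grad list for all
# backbone parameters (heads handled by the caller).
siam_backward <- function(model, fwd, d_emb) {
  spec <- model$spec
  p <- model$params
  geo <- backbone_geometry(spec)
  grads <- list()
  dh <- d_emb
  for (i in rev(seq_along(geo$dense))) {
    cc <- fwd$caches[[paste0("dense", i)]]
    last <- i == length(geo$dense)
    if (!last) dh <- dh * cc$relu_mask
    bk <- dense_backward(dh, cc$x, p[[paste0("dense", i, "_W")]])
    grads[[paste0("dense", i, "_W")]] <- bk$dW
    grads[[paste0("dense", i, "_b")]] <- bk$db
    dh <- bk$dx
  }
  n <- nrow(dh)
  last_conv <- fwd$caches[[paste0("conv", length(geo$conv))]]
  pooled_dim <- dim(last_conv$pool$out)
  dx <- array(t(dh), c(pooled_dim[1:3], n))
  for (i in rev(seq_along(geo$conv))) {
    cc <- fwd$caches[[paste0("conv", i)]]
    if (!is.null(cc$drop_mask)) dx <- dx * cc$drop_mask
    dx <- maxpool2_backward(dx, cc$pool)
    dx <- dx * cc$relu_mask
    bk <- conv2d_backward(dx, cc$patches, p[[paste0("conv", i, "_W")]],
                          cc$x_dim, compute_dx = i > 1)
    grads[[paste0("conv", i, "_W")]] <- bk$dW
    grads[[paste0("conv", i, "_b")]] <- bk$db
    dx <- bk$dx
  }
  grads
}

#' Embed standardized images with the shared encoder
#'
#' In `eval` mode dropout is disabled and the embedding is deterministic; in
#' `train` mode dropout is active (stochastic under the session RNG).
#'
#' @param model A `siam_network` or `siam_fit`.
#' @param images A list of standardized pixel matrices (or a single matrix)
#'   whose side matches the spec's `input_side`.
#' @param mode `"eval"` or `"train"`.
#' @return A matrix with one 128-d (or `emb`-d) row per image.
#' @export
siam_embed <- function(model, images, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (is.matrix(images)) images <- list(images)
  side <- model$spec$input_side
  for (im in images) {
    if (nrow(im) != side || ncol(im) != side) {
      stop_input("image side ", nrow(im), " does not match spec input_side ",
                 side, " (dense input dimension mismatch)")
    }
  }
  x <- array(unlist(images, use.names = FALSE),
             c(side, side, 1L, length(images)))
  out <- siam_forward(model, x, train = mode == "train")
  emb <- out$embedding
  if (!all(is.finite(emb))) stop_pipeline("non-finite embedding")
  rownames(emb) <- names(images)
  emb
}

#' Classification-head logits from embeddings
#'
#' Affine maps from the embedding to 2 abnormality logits (normal/abnormal)
#' and 3 body-part logits (brain/thorax/abdomen). The argmax of each row is
#' the class prediction.
#'
#' @param model A `siam_network` or `siam_fit`.
#' @param embedding A matrix of embeddings (rows = images).
#' @return List with `abnormality_logits` (n x 2) and `body_part_logits`
#'   (n x 3).
#' @export
predict_heads <- function(model, embedding) {
  if (is.null(dim(embedding))) embedding <- matrix(embedding, nrow = 1)
  if (!all(is.finite(embedding))) stop_input("non-finite embedding")
  p <- model$params
  abn <- dense_forward(embedding, p$head_abn_W, p$head_abn_b)
  body <- dense_forward(embedding, p$head_body_W, p$head_body_b)
  colnames(abn) <- condition_levels
  colnames(body) <- body_part_levels
  list(abnormality_logits = abn, body_part_logits = body)
}
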