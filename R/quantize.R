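# Post-training INT8 quantization engine: parameter derivation, calibration
# observers, integer-simulated kernels, and the PTQ driver.
#
# Conventions (used identically by kernels, oracles and tests):
#   * round = round-half-away-from-zero (round_haz), everywhere;
#   * weights: symmetric per-channel, scale max|W_k|/127, grid [-128, 127],
#     zero-point 0; channel axis = output-channel dimension;
#   * activations: affine per-tensor, unsigned [0, 255] after ReLU, signed
#     [-128, 127] otherwise;
#   * accumulation in 32-bit-integer semantics (held exactly in doubles),
#     bias stored as int32 in accumulator units, requantization multiplier
#     s_w * s_x / s_y applied in floating point.

GRID_SIGNED <- c(-128L, 127L)
GRID_UNSIGNED <- c(0L, 255L)

#' Quantization parameters
#'
#' @param scale Positive scale (scalar, or per-channel vector for symmetric
#'   per-channel weights).
#' @param zero_point Integer zero-point (0 for the symmetric scheme).
#' @param grid Integer range, `c(-128, 127)` or `c(0, 255)`.
#' @param scheme `"affine_per_tensor"` or `"symmetric_per_channel"`.
#' @param channel_axis Channel axis for the per-channel scheme.
#' @return A list of class `quant_params`.
#' @export
quant_params <- function(scale, zero_point = 0L, grid = GRID_SIGNED,
                         scheme = c("affine_per_tensor",
                                    "symmetric_per_channel"),
                         channel_axis = NULL) {
  scheme <- match.arg(scheme)
  if (any(!is.finite(scale)) || any(scale <= 0)) {
    stop_input("scale must be positive and finite")
  }
  if (scheme == "affine_per_tensor") {
    if (zero_point < grid[1] || zero_point > grid[2]) {
      stop_input("zero_point must lie inside the grid")
    }
  } else if (any(zero_point != 0)) {
    stop_input("symmetric scheme requires zero_point 0")
  }
  structure(list(scale = scale, zero_point = as.integer(zero_point),
                 grid = as.integer(grid), scheme = scheme,
                 channel_axis = channel_axis),
            class = "quant_params")
}

#' Affine (asymmetric) quantization parameters from a calibrated range
#'
#' `s = (r_max - r_min) / (q_max - q_min)`, `z = round(q_min - r_min / s)`
#' clipped into the grid. A degenerate range is widened by a minimal epsilon.
#'
#' @param r_min,r_max Calibrated real range, `r_min <= r_max`.
#' @param grid Integer grid, e.g. `c(0, 255)`.
#' @return A `quant_params` (affine per-tensor).
#' @export
affine_qparams <- function(r_min, r_max, grid = GRID_UNSIGNED) {
  if (!is.finite(r_min) || !is.finite(r_max)) {
    stop_input("range must be finite")
  }
  if (r_min > r_max) stop_input("r_min must be <= r_max")
  if (r_max == r_min) {
    r_min <- r_min - 1e-8
    r_max <- r_max + 1e-8
  }
  s <- (r_max - r_min) / (grid[2] - grid[1])
  z <- clip(round_haz(grid[1] - r_min / s), grid[1], grid[2])
  quant_params(scale = s, zero_point = z, grid = grid,
               scheme = "affine_per_tensor")
}

#' Symmetric per-channel weight quantization parameters
#'
#' Per output channel `k`, `s_k = max(|W_k|) / 127` and `z_k = 0`. All-zero
#' channels receive a minimal positive scale so their codes are exactly 0.
#'
#' @param W Weight array; conv `(k, k, c_in, c_out)` or dense `(in, out)`.
#' @param channel_axis Output-channel axis (defaults to the last dimension).
#' @return A `quant_params` (symmetric per-channel) with a vector scale.
#' @export
symmetric_channel_qparams <- function(W, channel_axis = length(dim(W))) {
  if (!all(is.finite(W))) stop_input("weights must be finite")
  amax <- apply(abs(W), channel_axis, max)
  s <- ifelse(amax > 0, amax / 127, 1e-12)
  quant_params(scale = s, zero_point = 0L, grid = GRID_SIGNED,
               scheme = "symmetric_per_channel", channel_axis = channel_axis)
}

#' Quantize a real tensor
#'
#' `q = clip(round(r / s) + z, q_min, q_max)` with round-half-away-from-zero;
#' per-channel scales are broadcast along the channel axis.
#'
#' @param r Numeric array/matrix/vector.
#' @param params A `quant_params`.
#' @return A list of class `quantized_tensor` with integer codes `q` and the
#'   `params`.
#' @export
quantize_tensor <- function(r, params) {
  stopifnot(inherits(params, "quant_params"))
  s <- params$scale
  scaled <- if (length(s) > 1) {
    sweep(r, params$channel_axis %||% length(dim(r)), s, "/")
  } else {
    r / s
  }
  q <- clip(round_haz(scaled) + params$zero_point,
            params$grid[1], params$grid[2])
  structure(list(q = q, params = params), class = "quantized_tensor")
}

#' Dequantize back to real values
#'
#' `r_hat = s * (q - z)`, per-channel aware.
#'
#' @param qt A `quantized_tensor`.
#' @return A numeric array of reconstructed values.
#' @export
dequantize <- function(qt) {
  stopifnot(inherits(qt, "quantized_tensor"))
  s <- qt$params$scale
  centered <- qt$q - qt$params$zero_point
  if (length(s) > 1) {
    sweep(centered, qt$params$channel_axis %||% length(dim(centered)), s, "*")
  } else {
    centered * s
  }
}

#' Fold batch normalization into the preceding layer
#'
#' Per output channel: `W_fold = gamma * W / sqrt(var + eps)` and
#' `b_fold = gamma * (b - mean) / sqrt(var + eps) + beta`, so the folded
#' layer's FP32 output equals conv/linear followed by BN.
#'
#' @param W Conv `(k, k, c_in, c_out)` or dense `(in, out)` weights.
#' @param b Bias vector (length = output channels).
#' @param bn List with per-channel `gamma`, `beta`, `mean`, `var` and scalar
#'   `eps > 0`.
#' @return List with folded `W` and `b`.
#' @export
fold_batchnorm <- function(W, b, bn) {
  ax <- length(dim(W))
  cout <- dim(W)[ax]
  lens <- lengths(bn[c("gamma", "beta", "mean", "var")])
  if (any(lens != cout) || length(b) != cout) {
    stop_input("batch-norm channel counts do not match the layer")
  }
  if (bn$eps <= 0 || any(bn$var < 0)) stop_input("need eps > 0 and var >= 0")
  f <- bn$gamma / sqrt(bn$var + bn$eps)
  list(W = sweep(W, ax, f, "*"), b = f * (b - bn$mean) + bn$beta)
}

# ---- calibration --------------------------------------------------------

#' Calibrated activation range from observed values
#'
#' `minmax` returns the exact observed range; `percentile` the stated pooled
#' percentiles (default 0.1/99.9); `kl` the 2048-bin histogram range that
#' minimizes the KL divergence between the clipped-and-requantized 256-level
#' distribution and the original histogram. For `percentile` and `kl` the
#' returned range never exceeds the observed one, and the KL-chosen range is
#' never worse (in that KL sense) than min-max.
#'
#' @param values Numeric vector of observed activations.
#' @param method `"minmax"`, `"percentile"` or `"kl"`.
#' @param percentile Lower/upper percentile bounds (percent).
#' @param n_bins Source histogram bins for `kl`. Default 2048.
#' @return `c(r_min, r_max)`.
#' @export
calib_range <- function(values, method = c("percentile", "minmax", "kl"),
                        percentile = c(0.1, 99.9), n_bins = 2048L) {
  method <- match.arg(method)
  if (length(values) == 0) stop_input("no observed activation values")
  values <- values[is.finite(values)]
  switch(method,
    minmax = range(values),
    percentile = unname(stats::quantile(values, percentile / 100,
                                        type = 7)),
    kl = kl_optimal_range(values, n_bins = n_bins)
  )
}

# KL-divergence range search (histogram-based): coarse exhaustive search over
# clip thresholds at both tails; the full range is always a candidate, so the
# result is never worse than min-max under the same discretization.
kl_optimal_range <- function(values, n_bins = 2048L, n_levels = 256L) {
  mn <- min(values); mx <- max(values)
  if (mx == mn) return(c(mn, mx))
  edges <- seq(mn, mx, length.out = n_bins + 1L)
  counts <- tabulate(findInterval(values, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  l_cands <- unique(round(seq(1L, max(1L, n_bins %/% 4L), length.out = 24)))
  r_cands <- unique(round(seq(min(n_bins, 3L * n_bins %/% 4L), n_bins,
                              length.out = 24)))
  best <- c(1L, n_bins)
  best_kl <- kl_of_clip(counts, 1L, n_bins, n_levels)
  for (l in l_cands) {
    for (r in r_cands) {
      if (r - l + 1L < n_levels) next
      kl <- kl_of_clip(counts, l, r, n_levels)
      if (kl < best_kl) {
        best_kl <- kl
        best <- c(l, r)
      }
    }
  }
  c(edges[best[1]], edges[best[2] + 1L])
}

kl_of_clip <- function(counts, l, r, n_levels) {
  n_bins <- length(counts)
  p <- counts[l:r]
  p[1] <- p[1] + sum(counts[seq_len(l - 1L)])
  p[length(p)] <- p[length(p)] + sum(counts[seq_len(n_bins - r) + r])
  grp <- cut(seq_along(p), breaks = n_levels, labels = FALSE)
  tot <- tapply(p, grp, sum)
  nz <- tapply(p > 0, grp, sum)
  qv <- ifelse(nz > 0, tot / pmax(nz, 1), 0)[grp]
  qv[p == 0] <- 0
  ps <- p / sum(p)
  qs <- qv / sum(qv)
  keep <- ps > 0
  sum(ps[keep] * log(ps[keep] / pmax(qs[keep], 1e-12)))
}

#' Calibrate per-layer activation quantization parameters
#'
#' Runs forward passes only (no parameter updates) over the calibration
#' images through the FP32 model in eval mode, recording every quantization
#' point's activations: the standardized input, each conv block's post-ReLU
#' feature map (before pooling), each hidden dense layer's post-ReLU output,
#' the linear embedding, and both head logit tensors. Post-ReLU points get
#' the unsigned `[0, 255]` grid, all others the signed `[-128, 127]` grid.
#' The calibrated range is widened, if needed, to include zero so that real
#' zero is exactly representable.
#'
#' @param model A `siam_fit` / `siam_network` (batch norm already folded).
#' @param images Named list of raw `[0,1]` calibration images (>= 1).
#' @param method,percentile,n_bins See [calib_range()].
#' @param batch_size Images per forward batch. Default 32.
#' @return Named list of `quant_params`: `input`, `conv1..`, `dense1..`,
#'   `head_abn`, `head_body`.
#' @export
calibrate_activations <- function(model, images,
                                  method = c("percentile", "minmax", "kl"),
                                  percentile = c(0.1, 99.9), n_bins = 2048L,
                                  batch_size = 32L) {
  method <- match.arg(method)
  if (length(images) == 0) stop_input("need at least one calibration image")
  side <- model$spec$input_side
  std <- lapply(images, preprocess_image, side = side)
  geo <- backbone_geometry(model$spec)
  obs <- list()
  starts <- seq(1L, length(std), by = batch_size)
  for (st in starts) {
    batch <- std[st:min(st + batch_size - 1L, length(std))]
    x <- array(unlist(batch, use.names = FALSE),
               c(side, side, 1L, length(batch)))
    vals <- calib_forward(model, x, geo)
    for (nm in names(vals)) obs[[nm]] <- c(obs[[nm]], vals[[nm]])
  }
  relu_pts <- c(paste0("conv", seq_along(geo$conv)),
                if (length(geo$dense) > 1) {
                  paste0("dense", seq_len(length(geo$dense) - 1))
                })
  out <- list()
  for (nm in names(obs)) {
    rg <- calib_range(obs[[nm]], method, percentile, n_bins)
    rg[1] <- min(rg[1], 0)  # keep real zero representable
    rg[2] <- max(rg[2], 0)
    grid <- if (nm %in% relu_pts) GRID_UNSIGNED else GRID_SIGNED
    out[[nm]] <- affine_qparams(rg[1], rg[2], grid)
  }
  out
}

# instrumented FP32 forward mirroring the quantized execution order
calib_forward <- function(model, x, geo) {
  p <- model$params
  vals <- list(input = as.vector(x))
  for (i in seq_along(geo$conv)) {
    y <- conv2d_forward(x, p[[paste0("conv", i, "_W")]],
                        p[[paste0("conv", i, "_b")]])$out
    y <- relu_forward(y)$out
    vals[[paste0("conv", i)]] <- sample_values(y)
    x <- maxpool2_forward(y)$out
  }
  h <- t(matrix(x, geo$flat, dim(x)[4]))
  for (i in seq_along(geo$dense)) {
    h <- dense_forward(h, p[[paste0("dense", i, "_W")]],
                       p[[paste0("dense", i, "_b")]])
    if (i < length(geo$dense)) h <- relu_forward(h)$out
    vals[[paste0("dense", i)]] <- sample_values(h)
  }
  vals$head_abn <- as.vector(dense_forward(h, p$head_abn_W, p$head_abn_b))
  vals$head_body <- as.vector(dense_forward(h, p$head_body_W, p$head_body_b))
  vals
}

# deterministic thinning keeps observer memory bounded on large feature maps
sample_values <- function(x, cap = 2^20) {
  v <- as.vector(x)
  if (length(v) <= cap) v else v[seq(1L, length(v), length.out = cap)]
}

# ---- integer kernels ----------------------------------------------------

#' Integer-simulated quantized layer (conv or dense)
#'
#' Accumulates `sum((W_q - z_W) * (x_q - z_x))` in 32-bit-integer semantics,
#' adds the bias as `b_int32 = round(b / (s_W * s_x))`, and requantizes with
#' `y_q = clip(round((s_W * s_x / s_y) * acc) + z_y, grid)`, handling
#' per-channel weight scales channel-wise. Zero-padding for convolutions pads
#' with the input zero-point (real zero). With `relu = TRUE` the output is
#' clamped at its zero-point, the integer-domain equivalent of ReLU.
#'
#' @param x_q Input `quantized_tensor`: 4-D `(H, W, C, N)` for conv, matrix
#'   `(N, features)` for dense.
#' @param W_q Weight `quantized_tensor` (symmetric per-channel).
#' @param b FP32 bias vector.
#' @param out_params Affine `quant_params` of the layer output.
#' @param relu Fuse a ReLU into the requantization clamp.
#' @return Output `quantized_tensor`.
#' @export
quantized_forward <- function(x_q, W_q, b, out_params, relu = FALSE) {
  stopifnot(inherits(x_q, "quantized_tensor"),
            inherits(W_q, "quantized_tensor"),
            inherits(out_params, "quant_params"))
  s_x <- x_q$params$scale
  z_x <- x_q$params$zero_point
  s_w <- W_q$params$scale
  s_y <- out_params$scale
  z_y <- out_params$zero_point
  grid <- out_params$grid
  Wq <- W_q$q
  conv <- length(dim(Wq)) == 4
  n_acc <- if (conv) prod(dim(Wq)[1:3]) else nrow(Wq)
  if (n_acc > 2^23) {
    stop_config("accumulator overflow risk: more than 2^23 accumulands")
  }
  b_int32 <- round_haz(b / (s_w * s_x))
  m_scale <- s_w * s_x / s_y
  if (conv) {
    d <- dim(x_q$q)
    k <- dim(Wq)[1]
    if (dim(Wq)[3] != d[3]) stop_config("channel mismatch between x and W")
    Pt <- im2col(x_q$q, k, pad_value = z_x) - z_x
    acc <- crossprod(Pt, matrix(Wq, k * k * d[3], dim(Wq)[4]))
    acc <- acc + rep(b_int32, each = nrow(acc))
    yq <- clip(round_haz(acc * rep(m_scale, each = nrow(acc))) + z_y,
               grid[1], grid[2])
    if (relu) yq <- pmax(yq, z_y)
    out <- aperm(array(yq, c(d[1], d[2], d[4], dim(Wq)[4])), c(1, 2, 4, 3))
  } else {
    if (ncol(x_q$q) != nrow(Wq)) stop_config("shape mismatch between x and W")
    acc <- (x_q$q - z_x) %*% Wq
    acc <- acc + rep(b_int32, each = nrow(acc))
    yq <- clip(round_haz(acc * rep(m_scale, each = nrow(acc))) + z_y,
               grid[1], grid[2])
    if (relu) yq <- pmax(yq, z_y)
    out <- yq
  }
  structure(list(q = out, params = out_params), class = "quantized_tensor")
}

# ---- PTQ driver ---------------------------------------------------------

#' Post-training INT8 quantization of a trained Siamese network
#'
#' Executes the PTQ recipe in order: fuse any batch norm into conv/linear
#' weights, calibrate per-tensor activation ranges on forward passes over the
#' calibration images, derive symmetric per-channel weight parameters
#' (`z = 0`, scale `max|W_k|/127`), quantize weights with
#' `clip(round(W/s), -128, 127)`, store biases as int32 in accumulator units,
#' and assemble integer inference kernels with int32 accumulation and
#' requantization between layers. Post-ReLU activations use the unsigned
#' grid.
#'
#' @param model A trained `siam_fit` (or initialized `siam_network`).
#' @param calib_images Named list of raw `[0,1]` calibration images from the
#'   training distribution.
#' @param method,percentile,n_bins Calibration options, see
#'   [calibrate_activations()].
#' @param batch_size Calibration batch size.
#' @return An object of class `sonosiam_qmodel`.
#' @export
quantize_model <- function(model, calib_images,
                           method = c("percentile", "minmax", "kl"),
                           percentile = c(0.1, 99.9), n_bins = 2048L,
                           batch_size = 32L) {
  method <- match.arg(method)
  if (length(calib_images) == 0) {
    stop_pipeline("missing calibration data")
  }
  geo <- backbone_geometry(model$spec)
  # step 1: fuse BN into the preceding conv so no BN remains at quantize time
  if (!is.null(model$bn)) {
    for (i in seq_along(geo$conv)) {
      if (length(model$bn) >= i && !is.null(model$bn[[i]])) {
        fo <- fold_batchnorm(model$params[[paste0("conv", i, "_W")]],
                             model$params[[paste0("conv", i, "_b")]],
                             model$bn[[i]])
        model$params[[paste0("conv", i, "_W")]] <- fo$W
        model$params[[paste0("conv", i, "_b")]] <- fo$b
      }
    }
    model$bn <- NULL
  }
  # steps 2-3: observers + calibration pass
  act <- calibrate_activations(model, calib_images, method, percentile,
                               n_bins, batch_size)
  # steps 4-5: weight/bias quantization
  layer_names <- c(paste0("conv", seq_along(geo$conv)),
                   paste0("dense", seq_along(geo$dense)),
                   "head_abn", "head_body")
  param_of <- function(nm) {
    if (nm == "head_abn") list(W = model$params$head_abn_W,
                               b = model$params$head_abn_b)
    else if (nm == "head_body") list(W = model$params$head_body_W,
                                     b = model$params$head_body_b)
    else list(W = model$params[[paste0(nm, "_W")]],
              b = model$params[[paste0(nm, "_b")]])
  }
  in_point <- c("input", utils::head(layer_names, -1))
  names(in_point) <- layer_names
  in_point[["head_abn"]] <- paste0("dense", length(geo$dense))
  in_point[["head_body"]] <- paste0("dense", length(geo$dense))
  layers <- list()
  for (i in seq_along(layer_names)) {
    nm <- layer_names[i]
    pw <- param_of(nm)
    dimnames(pw$W) <- NULL
    pw$b <- unname(pw$b)
    wqp <- symmetric_channel_qparams(pw$W)
    layers[[nm]] <- list(
      name = nm,
      type = if (startsWith(nm, "conv")) "conv" else "dense",
      W_q = quantize_tensor(pw$W, wqp),
      b = pw$b,
      in_qp = act[[in_point[[nm]]]],
      out_qp = act[[nm]],
      relu = nm %in% c(paste0("conv", seq_along(geo$conv)),
                       if (length(geo$dense) > 1) {
                         paste0("dense", seq_len(length(geo$dense) - 1))
                       }),
      pool = startsWith(nm, "conv")
    )
  }
  structure(list(spec = model$spec, input_qp = act$input, layers = layers,
                 calibration = list(method = method, percentile = percentile,
                                    n_bins = n_bins,
                                    n_images = length(calib_images))),
            class = "sonosiam_qmodel")
}

# integer end-to-end forward; returns dequantized head logits and embedding
qmodel_forward <- function(qm, x_std) {
  side <- qm$spec$input_side
  n <- dim(x_std)[4]
  xq <- quantize_tensor(x_std, qm$input_qp)
  cur <- xq
  geo <- backbone_geometry(qm$spec)
  for (i in seq_along(geo$conv)) {
    ly <- qm$layers[[paste0("conv", i)]]
    cur <- quantized_forward(cur, ly$W_q, ly$b, ly$out_qp, relu = ly$relu)
    cur$q <- maxpool2_forward(cur$q)$out  # monotone: pool on integer codes
  }
  flatq <- t(matrix(cur$q, geo$flat, n))
  cur <- structure(list(q = flatq, params = cur$params),
                   class = "quantized_tensor")
  for (i in seq_along(geo$dense)) {
    ly <- qm$layers[[paste0("dense", i)]]
    cur <- quantized_forward(cur, ly$W_q, ly$b, ly$out_qp, relu = ly$relu)
  }
  emb_q <- cur
  la <- qm$layers$head_abn
  lb <- qm$layers$head_body
  abn <- dequantize(quantized_forward(emb_q, la$W_q, la$b, la$out_qp))
  body <- dequantize(quantized_forward(emb_q, lb$W_q, lb$b, lb$out_qp))
  colnames(abn) <- condition_levels
  colnames(body) <- body_part_levels
  list(embedding = dequantize(emb_q),
       abnormality_logits = abn,
       body_part_logits = body)
}

#' Predict from a quantized model
#'
#' Runs the full integer-simulated pipeline on standardized inputs and
#' dequantizes only the requested output.
#'
#' @param object A `sonosiam_qmodel`.
#' @param images Named list of raw `[0,1]` pixel matrices.
#' @param type `"condition"`, `"body_part"`, `"embedding"` or `"logits"`.
#' @param batch_size Images per forward batch.
#' @param ... Unused.
#' @export
predict.sonosiam_qmodel <- function(object, images,
                                    type = c("condition", "body_part",
                                             "embedding", "logits"),
                                    batch_size = 64L, ...) {
  type <- match.arg(type)
  side <- object$spec$input_side
  std <- lapply(images, preprocess_image, side = side)
  outs <- list()
  starts <- seq(1L, length(std), by = batch_size)
  for (st in starts) {
    batch <- std[st:min(st + batch_size - 1L, length(std))]
    x <- array(unlist(batch, use.names = FALSE),
               c(side, side, 1L, length(batch)))
    outs[[length(outs) + 1]] <- qmodel_forward(object, x)
  }
  emb <- do.call(rbind, lapply(outs, `[[`, "embedding"))
  abn <- do.call(rbind, lapply(outs, `[[`, "abnormality_logits"))
  body <- do.call(rbind, lapply(outs, `[[`, "body_part_logits"))
  switch(type,
    embedding = emb,
    logits = list(abnormality_logits = abn, body_part_logits = body),
    condition = condition_levels[max.col(abn, ties.method = "first")],
    body_part = body_part_levels[max.col(body, ties.method = "first")]
  )
}

#' Measured byte size of a quantized model
#'
#' One byte per weight code, four per int32 bias, four per per-channel scale,
#' eight per activation scale/zero-point pair (per layer plus the input).
#'
#' @param qm A `sonosiam_qmodel`.
#' @return Payload size in bytes.
#' @export
qmodel_size_bytes <- function(qm) {
  sz <- 8  # input activation params
  for (ly in qm$layers) {
    sz <- sz + length(ly$W_q$q) + 4 * length(ly$b) +
      4 * length(ly$W_q$params$scale) + 8
  }
  sz
}

#' @export
print.sonosiam_qmodel <- function(x, ...) {
  cat("<sonosiam_qmodel> INT8,", length(x$layers), "layers,",
      format(qmodel_size_bytes(x), big.mark = ","), "bytes;",
      "calibration:", x$calibration$method, "\n")
  invisible(x)
}

#' Per-layer quantization summary
#'
#' @param x A `sonosiam_qmodel`.
#' @param ... Unused.
#' @return Tibble with one row per layer: scheme, grids, scale ranges.
#' @export
#' @exportS3Method generics::tidy
tidy.sonosiam_qmodel <- function(x, ...) {
  dplyr::bind_rows(lapply(x$layers, function(ly) {
    tibble::tibble(
      layer = ly$name, type = ly$type,
      n_weights = length(ly$W_q$q),
      n_channels = length(ly$W_q$params$scale),
      w_scale_min = min(ly$W_q$params$scale),
      w_scale_max = max(ly$W_q$params$scale),
      act_scale = ly$out_qp$scale,
      act_zero_point = ly$out_qp$zero_point,
      act_grid = paste0("[", ly$out_qp$grid[1], ",", ly$out_qp$grid[2], "]"),
      relu = ly$relu
    )
  }))
}

#' One-row size/compression summary of a quantized model
#'
#' @param x A `sonosiam_qmodel`.
#' @param ... Unused.
#' @return Tibble with INT8 payload bytes, FP32 bytes, and their ratio.
#' @export
#' @exportS3Method generics::glance
glance.sonosiam_qmodel <- function(x, ...) {
  int8 <- qmodel_size_bytes(x)
  fp32 <- model_size_bytes(x$spec, "fp32")
  tibble::tibble(int8_bytes = int8, fp32_bytes = fp32,
                 compression = fp32 / int8,
                 calibration = x$calibration$method)
}

# ---- serialization ------------------------------------------------------

#' Export a quantized model as an int8 payload plus JSON sidecar
#'
#' Writes `<prefix>.bin` (little-endian int8 weight codes then int32 biases,
#' layer by layer) and `<prefix>.json` (layer topology, dims, schemes,
#' scales, zero-points, grids and payload offsets).
#'
#' @param qm A `sonosiam_qmodel`.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_qmodel <- function(qm, prefix) {
  bin_path <- paste0(prefix, ".bin")
  json_path <- paste0(prefix, ".json")
  con <- file(bin_path, "wb")
  on.exit(close(con))
  meta_layers <- list()
  offset <- 0
  for (ly in qm$layers) {
    wq <- as.integer(ly$W_q$q)
    writeBin(wq, con, size = 1L, endian = "little")
    b32 <- as.integer(round_haz(ly$b / (ly$W_q$params$scale *
                                          ly$in_qp$scale)))
    writeBin(b32, con, size = 4L, endian = "little")
    meta_layers[[ly$name]] <- list(
      name = ly$name, type = ly$type, dims = dim(ly$W_q$q),
      w_scales = ly$W_q$params$scale,
      b_fp32 = ly$b,
      in_qp = unclass(ly$in_qp)[c("scale", "zero_point", "grid", "scheme")],
      out_qp = unclass(ly$out_qp)[c("scale", "zero_point", "grid", "scheme")],
      relu = ly$relu, pool = ly$pool,
      weight_offset = offset, n_weights = length(wq), n_bias = length(b32))
    offset <- offset + length(wq) + 4 * length(b32)
  }
  meta <- list(
    format = "sonosiam-int8-v1",
    spec = list(conv_blocks = qm$spec$conv_blocks,
                dense_dims = qm$spec$dense_dims,
                input_side = qm$spec$input_side,
                input_channels = qm$spec$input_channels),
    input_qp = unclass(qm$input_qp)[c("scale", "zero_point", "grid",
                                      "scheme")],
    calibration = qm$calibration,
    layers = unname(meta_layers))
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(bin_path, json_path))
}

#' Load a quantized model written by [write_qmodel()]
#'
#' @param prefix Path prefix used at export time.
#' @return A `sonosiam_qmodel` that runs the integer pipeline.
#' @export
read_qmodel <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = FALSE)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  spec <- backbone_spec(
    conv_blocks = lapply(meta$spec$conv_blocks, unlist),
    dense_dims = unlist(meta$spec$dense_dims),
    input_side = meta$spec$input_side,
    input_channels = meta$spec$input_channels)
  qp_from <- function(m, channel_axis = NULL) {
    quant_params(scale = unlist(m$scale), zero_point = m$zero_point,
                 grid = unlist(m$grid), scheme = m$scheme,
                 channel_axis = channel_axis)
  }
  layers <- list()
  for (i in seq_along(meta$layers)) {
    lm <- meta$layers[[i]]
    dims <- unlist(lm$dims)
    wq <- readBin(con, integer(), n = prod(dims), size = 1L, signed = TRUE,
                  endian = "little")
    b32 <- readBin(con, integer(), n = lm$n_bias, size = 4L,
                   endian = "little")
    w_scales <- unlist(lm$w_scales)
    wqp <- quant_params(scale = w_scales, zero_point = 0L,
                        grid = GRID_SIGNED,
                        scheme = "symmetric_per_channel",
                        channel_axis = length(dims))
    in_qp <- qp_from(lm$in_qp)
    layers[[lm$name]] <- list(
      name = lm$name, type = lm$type,
      W_q = structure(list(q = array(wq, dims), params = wqp),
                      class = "quantized_tensor"),
      b = unlist(lm$b_fp32),
      in_qp = in_qp, out_qp = qp_from(lm$out_qp),
      relu = isTRUE(lm$relu), pool = isTRUE(lm$pool))
  }
  structure(list(spec = spec, input_qp = qp_from(meta$input_qp),
                 layers = layers, calibration = meta$calibration),
            class = "sonosiam_qmodel")
}
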