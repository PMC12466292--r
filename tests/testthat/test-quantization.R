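test_that("affine parameters follow the range-to-grid formula", {
  p <- affine_qparams(0, 255, c(0, 255))
  expect_equal(p$scale, 1)
  expect_equal(p$zero_point, 0L)
  p2 <- affine_qparams(0, 2.55, c(0, 255))
  expect_equal(p2$scale, 0.01)
  expect_equal(p2$zero_point, 0L)
  p3 <- affine_qparams(-1, 1, c(0, 255))
  expect_equal(p3$scale, 2 / 255)
  expect_equal(p3$zero_point, 128L)
  # degenerate range widens instead of failing
  expect_gt(affine_qparams(0.3, 0.3)$scale, 0)
  expect_error(affine_qparams(NaN, 1), class = "sonosiam_input_error")
})

test_that("symmetric per-channel scales are max|W|/127 with zero-points 0", {
  W <- array(0, c(1, 1, 1, 2))
  W[1, 1, 1, 1] <- 1.27
  W[1, 1, 1, 2] <- -0.5
  p <- symmetric_channel_qparams(W)
  expect_equal(p$scale, c(0.01, 0.5 / 127))
  expect_equal(p$zero_point, 0L)

  W2 <- matrix(c(127, -127, 12.7, 0), 2, 2)   # dense: channels = columns
  p2 <- symmetric_channel_qparams(W2)
  expect_equal(p2$scale, c(1.0, 0.1))

  Wz <- array(0, c(2, 2, 1, 1))               # all-zero channel
  pz <- symmetric_channel_qparams(Wz)
  qt <- quantize_tensor(Wz, pz)
  expect_true(all(qt$q == 0))
  expect_gt(pz$scale, 0)
})

test_that("quantize/dequantize obeys the clip-round formula and its bounds", {
  p <- quant_params(scale = 0.01, zero_point = 0L, grid = c(0L, 255L))
  expect_equal(quantize_tensor(1.00, p)$q, 100)
  expect_equal(quantize_tensor(1e6, p)$q, 255)          # saturation
  pa <- affine_qparams(-1, 1, c(0, 255))
  z <- quantize_tensor(0, pa)
  expect_equal(z$q, pa$zero_point)
  expect_equal(dequantize(z), 0)

  # round-trip error <= s/2 inside the calibrated range, both schemes
  withr::with_seed(5, {
    r <- runif(1000, -1, 1)
    qa <- quantize_tensor(r, pa)
    expect_lte(max(abs(dequantize(qa) - r)), pa$scale / 2 + 1e-12)

    W <- array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
    ps <- symmetric_channel_qparams(W)
    qs <- quantize_tensor(W, ps)
    err <- abs(dequantize(qs) - W)
    lim <- array(rep(ps$scale / 2, each = 18), dim(W))
    expect_true(all(err <= lim + 1e-12))
    # monotonicity in r
    rr <- sort(runif(200, -2, 2))
    qq <- quantize_tensor(rr, pa)$q
    expect_true(all(diff(qq) >= 0))
  })
})

test_that("batch-norm folding preserves the FP32 function", {
  # identity fold
  W <- array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
  b <- rnorm(4)
  bn_id <- list(gamma = sqrt(1:4 + 1e-5), beta = rep(0, 4),
                mean = rep(0, 4), var = 1:4, eps = 1e-5)
  f <- fold_batchnorm(W, b, bn_id)
  expect_equal(f$W, W)
  expect_equal(f$b, b)

  # worked scalar example: W=2, b=0, gamma=1, beta=1, mu=4, var=1, eps->0
  fs <- fold_batchnorm(array(2, c(1, 1, 1, 1)), 0,
                       list(gamma = 1, beta = 1, mean = 4, var = 1,
                            eps = 1e-12))
  expect_equal(as.vector(fs$W), 2, tolerance = 1e-9)
  expect_equal(fs$b, -3, tolerance = 1e-9)

  # random conv layer: folded output == conv -> BN sequential oracle
  withr::with_seed(8, {
    x <- array(rnorm(8 * 8 * 2 * 3), c(8, 8, 2, 3))
    bn <- list(gamma = runif(4, 0.5, 2), beta = rnorm(4),
               mean = rnorm(4), var = runif(4, 0.2, 2), eps = 1e-5)
    seq_out <- sonosiam:::conv2d_forward(x, W, b)$out
    f2 <- bn$gamma / sqrt(bn$var + bn$eps)
    for (c_ in 1:4) {
      seq_out[, , c_, ] <- f2[c_] * (seq_out[, , c_, ] - bn$mean[c_]) +
        bn$beta[c_]
    }
    fd <- fold_batchnorm(W, b, bn)
    fold_out <- sonosiam:::conv2d_forward(x, fd$W, fd$b)$out
    expect_equal(fold_out, seq_out, tolerance = 1e-5)
  })
  expect_error(fold_batchnorm(W, b[1:2], bn_id),
               class = "sonosiam_input_error")
})

test_that("calibration ranges: min-max exact, percentile robust to outliers", {
  v <- 0:255
  expect_equal(calib_range(v, "minmax"), c(0, 255))
  expect_equal(affine_qparams(0, 255, c(0, 255))$scale, 1)

  withr::with_seed(3, {
    v2 <- c(runif(10000), 100)   # one far outlier
    rg <- calib_range(v2, "percentile")
    # sorting oracle: the stated pooled percentile
    expect_equal(rg, unname(quantile(v2, c(0.001, 0.999))))
    expect_lte(rg[2], 1.01)
  })
  expect_error(calib_range(numeric(0)), class = "sonosiam_input_error")
})

test_that("KL calibration never widens past the data and never beats min-max at KL", {
  withr::with_seed(9, {
    for (vals in list(c(rnorm(5000), rnorm(50, 0, 8)),
                      rexp(5000), runif(3000, -2, 5))) {
      rg <- calib_range(vals, "kl")
      expect_gte(rg[1], min(vals) - 1e-9)
      expect_lte(rg[2], max(vals) + 1e-9)
      # exhaustive-search oracle on the same histogram discretization
      n_bins <- 2048L
      counts <- tabulate(findInterval(
        vals, seq(min(vals), max(vals), length.out = n_bins + 1),
        rightmost.closed = TRUE), nbins = n_bins)
      kl_minmax <- sonosiam:::kl_of_clip(counts, 1L, n_bins, 256L)
      edges <- seq(min(vals), max(vals), length.out = n_bins + 1)
      l <- which.min(abs(edges[seq_len(n_bins)] - rg[1]))
      r <- which.min(abs(edges[-1] - rg[2]))
      kl_chosen <- sonosiam:::kl_of_clip(counts, l, r, 256L)
      expect_lte(kl_chosen, kl_minmax + 1e-12)
    }
  })
})

test_that("quantized layers reproduce FP32 arithmetic within one step", {
  # 1x1 "conv" worked example: 1.0 * 2.0 = 2.0
  x <- array(1.0, c(1, 1, 1, 1))
  xq <- quantize_tensor(x, quant_params(scale = 0.01, zero_point = 0L,
                                        grid = c(-128L, 127L)))
  W <- array(2.0, c(1, 1, 1, 1))
  Wq <- quantize_tensor(W, symmetric_channel_qparams(W))
  out_qp <- affine_qparams(0, 4, c(0, 255))
  y <- quantized_forward(xq, Wq, b = 0, out_qp)
  expect_lte(abs(dequantize(y)[1] - 2.0), out_qp$scale / 2 + 1e-12)

  # all-zero weights with zero bias give q == z_y everywhere
  W0 <- array(0, c(3, 3, 2, 4))
  Wq0 <- quantize_tensor(W0, symmetric_channel_qparams(W0))
  xq2 <- quantize_tensor(array(runif(36 * 2), c(6, 6, 2, 1)),
                         affine_qparams(0, 1, c(0, 255)))
  oqp <- affine_qparams(-1, 1, c(-128, 127))
  y0 <- quantized_forward(xq2, Wq0, rep(0, 4), oqp)
  expect_true(all(y0$q == oqp$zero_point))
})

test_that("a random conv layer tracks the FP32 convolution oracle", {
  withr::with_seed(14, {
    x <- array(runif(8 * 8 * 2 * 3, -1, 1), c(8, 8, 2, 3))
    W <- array(rnorm(3 * 3 * 2 * 4, sd = 0.4), c(3, 3, 2, 4))
    b <- rnorm(4, sd = 0.1)
    ref <- sonosiam:::conv2d_forward(x, W, b)$out
    xq <- quantize_tensor(x, affine_qparams(-1, 1, c(-128, 127)))
    Wq <- quantize_tensor(W, symmetric_channel_qparams(W))
    out_qp <- affine_qparams(min(ref), max(ref), c(-128, 127))
    y <- quantized_forward(xq, Wq, b, out_qp)
    err <- abs(dequantize(y) - ref)
    expect_lte(mean(err), 2 * out_qp$scale)

    # fake-quant simulation (dequantize -> float conv -> quantize) agrees to
    # within one integer step
    s_w <- Wq$params$scale
    s_x <- xq$params$scale
    b_int32 <- sonosiam:::round_haz(b / (s_w * s_x))
    fake <- sonosiam:::conv2d_forward(
      dequantize(xq), dequantize(Wq),
      b_int32 * s_w * s_x)$out
    fq <- quantize_tensor(fake, out_qp)
    expect_lte(max(abs(fq$q - y$q)), 1)
    expect_gte(mean(fq$q == y$q), 0.99)
  })
})

test_that("activation calibration assigns grids by activation sign structure", {
  spec <- micro_spec()
  net <- siam_network(spec, seed = 6)
  imgs <- lapply(1:8, function(i) {
    render_phantom(side = 32, seed = i)
  })
  act <- calibrate_activations(net, imgs, method = "minmax")
  expect_named(act, c("input", "conv1", "conv2", "dense1", "dense2",
                      "head_abn", "head_body"), ignore.order = TRUE)
  expect_equal(act$conv1$grid, c(0L, 255L))     # post-ReLU: unsigned
  expect_equal(act$input$grid, c(-128L, 127L))  # standardized input: signed
  expect_equal(act$dense2$grid, c(-128L, 127L)) # linear embedding: signed
  expect_error(calibrate_activations(net, list(), method = "minmax"),
               class = "sonosiam_input_error")
})

test_that("the PTQ driver fuses BN, quantizes all weights and stays faithful", {
  run <- memo("micro_fit", {
    ds <- generate_image_dataset(24, 12, seed = 13, side = 32,
                                 tag_flip_frac = 0.25)
    fit <- train_siamese(ds$images, ds$manifest, spec = micro_spec(),
                         epochs = 3, pairs_per_epoch = 24, batch_pairs = 12,
                         augment = NULL, seed = 2)
    list(ds = ds, fit = fit)
  })
  fit <- run$fit
  ds <- run$ds
  qm <- quantize_model(fit, ds$images[1:16], method = "percentile")
  for (ly in qm$layers) {
    expect_true(all(ly$W_q$q == round(ly$W_q$q)))
    expect_true(all(ly$W_q$q >= -128 & ly$W_q$q <= 127))
    expect_equal(ly$W_q$params$zero_point, 0L)   # symmetric weights
  }
  # INT8 weight payload is ~1/4 of the FP32 weight payload
  counts <- count_backbone_params(fit$spec)
  expect_equal(sum(vapply(qm$layers, function(l) length(l$W_q$q),
                          numeric(1))), sum(counts$weights))
  expect_lt(qmodel_size_bytes(qm), model_size_bytes(fit$spec, "fp32") / 3)

  # quantized predictions track FP32 on the phantom set
  pf <- predict(fit, ds$images, type = "condition")
  pq <- predict(qm, ds$images, type = "condition")
  expect_gte(mean(pf == pq), 0.9)

  # a model with explicit BN gets fused before quantization and the
  # quantized pipeline still tracks the FP32+BN model
  net_bn <- fit
  geo_cout <- vapply(fit$spec$conv_blocks, `[`, numeric(1), 1)
  net_bn$bn <- lapply(geo_cout, function(cc) {
    withr::with_seed(cc, list(gamma = runif(cc, 0.8, 1.2),
                              beta = rnorm(cc, 0, 0.05),
                              mean = rnorm(cc, 0, 0.05),
                              var = runif(cc, 0.8, 1.2), eps = 1e-5))
  })
  ref <- predict(net_bn, ds$images, type = "condition")
  qbn <- quantize_model(net_bn, ds$images[1:16], method = "percentile")
  expect_gte(mean(predict(qbn, ds$images, type = "condition") == ref), 0.9)
  expect_error(quantize_model(fit, list()), class = "sonosiam_pipeline_error")
})

test_that("quantized models survive an export/load round trip", {
  run <- memo("micro_fit", stop("populated by earlier test"))
  qm <- quantize_model(run$fit, run$ds$images[1:12], method = "minmax")
  prefix <- file.path(withr::local_tempdir(), "model_int8")
  write_qmodel(qm, prefix)
  expect_true(file.exists(paste0(prefix, ".bin")))
  back <- read_qmodel(prefix)
  for (nm in names(qm$layers)) {
    expect_equal(back$layers[[nm]]$W_q$q, qm$layers[[nm]]$W_q$q)
    expect_equal(back$layers[[nm]]$out_qp$scale, qm$layers[[nm]]$out_qp$scale)
  }
  p1 <- predict(qm, run$ds$images, type = "logits")
  p2 <- predict(back, run$ds$images, type = "logits")
  expect_equal(p1$abnormality_logits, p2$abnormality_logits,
               tolerance = 1e-10)
  expect_s3_class(tidy(qm), "tbl_df")
  expect_equal(nrow(tidy(qm)), 6)  # 2 conv + 2 dense + 2 heads
  expect_gt(glance(qm)$compression, 3)
})
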