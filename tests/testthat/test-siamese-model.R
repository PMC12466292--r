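test_that("embeddings have the specified dimension and eval determinism", {
  spec <- micro_spec()
  net <- siam_network(spec, seed = 3)
  imgs <- lapply(1:3, function(i) {
    preprocess_image(render_phantom("brain", "normal", "SRC_A",
                                    side = 32, seed = i), side = 32)
  })
  e1 <- siam_embed(net, imgs, mode = "eval")
  expect_equal(dim(e1), c(3L, 16L))
  expect_true(all(is.finite(e1)))
  expect_identical(e1, siam_embed(net, imgs, mode = "eval"))
  # side mismatch is a shape error
  expect_error(siam_embed(net, matrix(0, 16, 16)),
               regexp = "dense input dimension mismatch|does not match")
})

test_that("train-mode dropout perturbs outputs; eval mode does not", {
  spec <- small_backbone_spec(32)
  net <- siam_network(spec, seed = 1)
  img <- preprocess_image(render_phantom(side = 32, seed = 1), side = 32)
  set.seed(10); a <- siam_embed(net, img, mode = "train")
  set.seed(11); b <- siam_embed(net, img, mode = "train")
  expect_false(identical(a, b))
  expect_identical(siam_embed(net, img), siam_embed(net, img))
})

test_that("both branches share one parameter store", {
  spec <- micro_spec()
  net <- siam_network(spec, seed = 2)
  imgs <- lapply(1:2, function(i) {
    preprocess_image(render_phantom(side = 32, seed = i), side = 32)
  })
  before <- siam_embed(net, imgs)
  net$params$conv1_W <- net$params$conv1_W * 1.5
  after <- siam_embed(net, imgs)
  # a single weight update moves the output of *both* branch evaluations
  expect_false(isTRUE(all.equal(before[1, ], after[1, ])))
  expect_false(isTRUE(all.equal(before[2, ], after[2, ])))
})

test_that("head logits have fixed lengths and a zero-head maps to uniform", {
  spec <- micro_spec()
  net <- siam_network(spec, seed = 5)
  emb <- matrix(rnorm(2 * 16), 2, 16)
  out <- predict_heads(net, emb)
  expect_equal(dim(out$abnormality_logits), c(2L, 2L))
  expect_equal(dim(out$body_part_logits), c(2L, 3L))
  net$params$head_abn_W[] <- 0
  net$params$head_body_W[] <- 0
  z <- predict_heads(net, matrix(0, 1, 16))
  expect_equal(as.vector(z$abnormality_logits), c(0, 0))
  expect_equal(as.vector(z$body_part_logits), c(0, 0, 0))
  expect_error(predict_heads(net, matrix(NaN, 1, 16)),
               class = "sonosiam_input_error")
})

test_that("analytic parameter count equals the instantiated count exactly", {
  for (spec in list(micro_spec(), small_backbone_spec(32))) {
    net <- siam_network(spec, seed = 1)
    expect_identical(sum(count_backbone_params(spec)$params),
                     sum(vapply(net$params, length, numeric(1))))
  }
})

test_that("size accounting covers degenerate and default specs", {
  # a single 1x1 conv with one channel and no dense stack: 1 weight + 1 bias
  tiny <- backbone_spec(conv_blocks = list(c(1, 1, 0)),
                        dense_dims = integer(0), input_side = 32)
  expect_equal(model_size_bytes(tiny, "fp32"), 8)
  # int8 is smaller than fp32 whenever weights dominate the metadata
  for (spec in list(micro_spec(), small_backbone_spec(), backbone_spec())) {
    expect_lt(model_size_bytes(spec, "int8"), model_size_bytes(spec, "fp32"))
  }
  # weight-payload ratio approaches 4 with metadata overhead
  counts <- count_backbone_params(backbone_spec())
  expect_equal(4 * sum(counts$params) / sum(counts$weights), 4,
               tolerance = 1e-4)
})

test_that("backbone specs round-trip through their JSON config block", {
  for (spec in list(micro_spec(), small_backbone_spec(), backbone_spec())) {
    path <- withr::local_tempfile(fileext = ".json")
    write_backbone_spec(spec, path)
    back <- read_backbone_spec(path)
    expect_equal(back$conv_blocks, spec$conv_blocks)
    expect_identical(back$dense_dims, spec$dense_dims)
    expect_identical(back$input_side, spec$input_side)
    expect_identical(sum(count_backbone_params(back)$params),
                     sum(count_backbone_params(spec)$params))
  }
})

test_that("backpropagation matches central finite differences", {
  spec <- micro_spec()
  net <- siam_network(spec, seed = 4)
  withr::with_seed(21, {
    imgs <- array(runif(32 * 32 * 4, -1, 1), c(32, 32, 1, 4))
  })
  y_pair <- c(1, 0)
  cond <- c(1L, 1L, 2L, 1L)
  body <- c(1L, 2L, 3L, 1L)
  w <- loss_weights()

  loss_of <- function(model) {
    fwd <- sonosiam:::siam_forward(model, imgs, train = FALSE)
    emb <- fwd$embedding
    d <- sqrt(rowSums((emb[c(1, 3), ] - emb[c(2, 4), ])^2))
    heads <- predict_heads(model, emb)
    multitask_loss(contrastive_loss(d, y_pair, w$margin),
                   sonosiam:::softmax_ce(heads$abnormality_logits, cond)$loss,
                   sonosiam:::softmax_ce(heads$body_part_logits, body)$loss,
                   w)
  }
  step <- sonosiam:::siam_train_step(net, imgs, y_pair, cond, body, w)
  h <- 1e-5
  withr::with_seed(99, {
    for (nm in names(step$grads)) {
      n_check <- min(6, length(net$params[[nm]]))
      for (idx in sample(length(net$params[[nm]]), n_check)) {
        plus <- net; plus$params[[nm]][idx] <- plus$params[[nm]][idx] + h
        minus <- net; minus$params[[nm]][idx] <- minus$params[[nm]][idx] - h
        fd <- (loss_of(plus) - loss_of(minus)) / (2 * h)
        expect_lt(abs(step$grads[[nm]][idx] - fd), 1e-4 * max(1, abs(fd)))
      }
    }
  })
})

test_that("tidy and glance summarize fits; autoplot returns a ggplot", {
  run <- memo("micro_fit", {
    ds <- generate_image_dataset(24, 12, seed = 13, side = 32,
                                 tag_flip_frac = 0.25)
    fit <- train_siamese(ds$images, ds$manifest, spec = micro_spec(),
                         epochs = 3, pairs_per_epoch = 24, batch_pairs = 12,
                         augment = NULL, seed = 2)
    list(ds = ds, fit = fit)
  })
  fit <- run$fit
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 3)
  expect_equal(tidy(fit)$stage, c("easy", "medium", "hard"))
  g <- glance(fit)
  expect_equal(g$n_params, sum(count_backbone_params(micro_spec())$params))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_phantom(run$ds$images[[1]]), "ggplot")
})
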