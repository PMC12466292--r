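# Shared fixtures and memoized heavy runs. Everything is generated in code at
# test time; the expensive end-to-end training runs are computed once per
# session and reused across test files.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# small labeled manifest with both tags and all body parts
toy_manifest <- function() {
  tibble::tibble(
    id = sprintf("p%02d", 1:12),
    body_part = rep(c("brain", "thorax", "abdomen"), 4),
    condition = rep(c("normal", "abnormal"), each = 6),
    source_tag = rep(c("SRC_A", "SRC_B", "SRC_A", "SRC_B"), each = 3)
  )
}

# micro backbone that trains in seconds (32px, two conv blocks)
micro_spec <- function() {
  backbone_spec(conv_blocks = list(c(4, 3, 0), c(8, 3, 0)),
                dense_dims = c(32, 16), input_side = 32L)
}

# the desk-scale screening study: 940/60 phantoms at 64px (seed 7), 80:20
# stratified split, 15 epochs with the default multi-task weights, then PTQ
# with percentile calibration on 8 batches of 32 training images.
screening_study <- function() {
  memo("screening_study", {
    ds <- generate_image_dataset(940, 60, seed = 7, side = 64)
    sp <- stratified_kfold_split(ds$manifest, k = 5, seed = 7)
    part <- fold_partition(sp, 1)
    tr_man <- ds$manifest[ds$manifest$id %in% part$train, ]
    te_man <- ds$manifest[ds$manifest$id %in% part$test, ]
    fit <- train_siamese(ds$images, tr_man, spec = small_backbone_spec(64),
                         weights = loss_weights(), epochs = 15,
                         pairing = "random", augment = NULL, seed = 1)
    calib <- ds$images[tr_man$id[seq_len(256)]]
    qm <- quantize_model(fit, calib, method = "percentile")
    list(ds = ds, train_manifest = tr_man, test_manifest = te_man,
         fit = fit, qmodel = qm,
         fp32_eval = evaluate_model(fit, ds$images, te_man),
         int8_eval = evaluate_model(qm, ds$images, te_man))
  })
}
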