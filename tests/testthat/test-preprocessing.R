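test_that("standardization centers mid-gray and preserves native geometry", {
  raw <- matrix(0.5, 224, 224)
  expect_equal(preprocess_image(raw), matrix(0, 224, 224))
  # 224x224 input: only the affine intensity map, no resampling
  raw2 <- matrix(runif(224 * 224), 224, 224)
  expect_identical(preprocess_image(raw2), (raw2 - 0.5) / 0.5)
  expect_error(preprocess_image(array(0.1, c(4, 4, 2))),
               class = "sonosiam_input_error")
  expect_error(preprocess_image(matrix(c(NA, 0.2, 0.3, 0.4), 2)),
               class = "sonosiam_input_error")
})

test_that("downscaling preserves the centroid of a centered disc", {
  big <- matrix(0, 448, 448)
  cx <- 200; cy <- 260
  ij <- expand.grid(i = 1:448, j = 1:448)
  big[as.matrix(ij[(ij$i - cx)^2 + (ij$j - cy)^2 < 40^2, ])] <- 1
  small <- preprocess_image(big, side = 224)
  expect_equal(dim(small), c(224L, 224L))
  w <- (small + 1) / 2
  centroid <- function(a) {
    c(sum(row(a) * a), sum(col(a) * a)) / sum(a)
  }
  expect_lt(max(abs(centroid(w) - centroid(big) / 2)), 1)
})

test_that("augmentation is the identity on normal images and on a null config", {
  img <- render_phantom("brain", "abnormal", "SRC_A", side = 48, seed = 2)
  for (s in c(1, 10, 99)) {
    cfg <- augmentation_config(seed = s)
    expect_identical(augment_abnormal(img, "normal", cfg), img)
  }
  null_cfg <- augmentation_config(flip_probability = 0, max_rotation_deg = 0,
                                  max_translation_frac = 0, seed = 5)
  expect_identical(augment_abnormal(img, "abnormal", null_cfg), img)
  expect_error(augmentation_config(flip_probability = 1.5),
               class = "sonosiam_input_error")
})

test_that("rotation-only augmentation conserves pixel mass within 1%", {
  # central content: rotation must not push mass outside the support
  ij <- expand.grid(i = 1:64, j = 1:64)
  img <- matrix(0, 64, 64)
  img[as.matrix(ij[(ij$i - 32)^2 + (ij$j - 32)^2 < 20^2, ])] <- 0.8
  for (s in 1:5) {
    cfg <- augmentation_config(flip_probability = 0, max_rotation_deg = 10,
                               max_translation_frac = 0, seed = s)
    out <- augment_abnormal(img, "abnormal", cfg)
    expect_equal(dim(out), dim(img))
    expect_lt(abs(sum(out) - sum(img)) / sum(img), 0.01)
  }
})

test_that("augmentation is deterministic in its config seed", {
  img <- render_phantom("thorax", "abnormal", "SRC_B", side = 48, seed = 4)
  cfg <- augmentation_config(seed = 77)
  expect_identical(augment_abnormal(img, "abnormal", cfg),
                   augment_abnormal(img, "abnormal", cfg))
})

test_that("oversampling balances classes exactly and preserves originals", {
  tab <- generate_tabular_dataset(c(100, 20, 10), p = 6, seed = 3)
  out <- smote_oversample(tab, seed = 1)
  expect_equal(as.vector(table(out$class)), c(100, 100, 100))
  # pairwise 1:1:1 count ratios
  counts <- table(out$class)
  expect_true(all(outer(counts, counts, "/") == 1))
  # original rows verbatim, first
  expect_equal(out[seq_len(nrow(tab)), ], tab, ignore_attr = TRUE)
  # determinism
  expect_identical(smote_oversample(tab, seed = 1), out)
  # balanced input is returned untouched
  bal <- generate_tabular_dataset(c(30, 30), p = 3, seed = 5)
  expect_identical(smote_oversample(bal, seed = 9), bal)
})

test_that("synthetic rows interpolate within the minority class", {
  # 1-D feature, minority {0, 1}, k = 1: synthetic values lie in [0, 1]
  tab <- tibble::tibble(
    x1 = c(rnorm(20, 10), 0, 1),
    class = factor(c(rep("big", 20), "small", "small"))
  )
  out <- smote_oversample(tab, k_neighbors = 1, seed = 2)
  syn <- out$x1[-seq_len(22)]
  expect_length(syn, 18)
  expect_true(all(syn >= 0 & syn <= 1))

  # per-coordinate convex hull on random instances
  for (s in 1:3) {
    tb <- generate_tabular_dataset(c(40, 12), p = 4, seed = s)
    res <- smote_oversample(tb, seed = s)
    syn_rows <- res[-seq_len(52), ]
    minority <- tb[tb$class == "C2", paste0("x", 1:4)]
    for (j in paste0("x", 1:4)) {
      expect_true(all(syn_rows[[j]] >= min(minority[[j]]) - 1e-12))
      expect_true(all(syn_rows[[j]] <= max(minority[[j]]) + 1e-12))
    }
  }
})

test_that("SMOTE-NC handles categorical columns by neighbor mode", {
  tab <- generate_tabular_dataset(c(60, 15), p = 5, n_categorical = 2,
                                  seed = 6)
  out <- smote_oversample(tab, seed = 3)  # k defaults to 3 with categoricals
  expect_equal(as.vector(table(out$class)), c(60, 60))
  syn <- out[-seq_len(75), ]
  expect_true(all(levels(syn$x4) == levels(tab$x4)))
  expect_false(anyNA(syn))
  # categorical entries come from observed minority levels
  expect_true(all(syn$x5 %in% unique(tab$x5[tab$class == "C2"])))
})

test_that("undersized classes produce an error naming the class", {
  tab <- tibble::tibble(x1 = rnorm(23),
                        class = rep(c("A", "B"), c(20, 3)))
  expect_error(smote_oversample(tab, k_neighbors = 5, seed = 1),
               regexp = "'B'", class = "sonosiam_input_error")
})

test_that("stratified folds preserve class ratio and mix sources", {
  ds_man <- generate_image_dataset(940, 60, seed = 7, side = 32,
                                   tag_flip_frac = 0)$manifest
  sp <- stratified_kfold_split(ds_man, k = 5, seed = 1)
  # test folds partition the dataset
  expect_setequal(sp$id, ds_man$id)
  expect_equal(sort(unique(sp$fold)), 1:5)
  for (f in 1:5) {
    part <- fold_partition(sp, f)
    expect_length(intersect(part$train, part$test), 0)
    te <- ds_man[ds_man$id %in% part$test, ]
    expect_equal(sum(te$condition == "normal"), 188)
    expect_equal(sum(te$condition == "abnormal"), 12)
    tr <- ds_man[ds_man$id %in% part$train, ]
    expect_setequal(unique(te$source_tag), c("SRC_A", "SRC_B"))
    expect_setequal(unique(tr$source_tag), c("SRC_A", "SRC_B"))
  }
  # deterministic in (ids, labels, k, seed)
  expect_identical(stratified_kfold_split(ds_man, k = 5, seed = 1), sp)
  expect_false(identical(stratified_kfold_split(ds_man, k = 5, seed = 2)$fold,
                         sp$fold))
})

test_that("fold counts stay within one sample of n_class / k", {
  man <- tibble::tibble(
    id = sprintf("x%03d", 1:103),
    condition = rep(c("normal", "abnormal"), c(71, 32)),
    source_tag = rep(c("SRC_A", "SRC_B"), length.out = 103)
  )
  sp <- stratified_kfold_split(man, k = 4, seed = 3)
  for (f in 1:4) {
    te <- man[man$id %in% fold_partition(sp, f)$test, ]
    expect_lt(abs(sum(te$condition == "normal") - 71 / 4), 1)
    expect_lt(abs(sum(te$condition == "abnormal") - 32 / 4), 1)
  }
})

test_that("tiny two-fold split and undersized classes behave per contract", {
  man <- tibble::tibble(id = c("a", "b", "c", "d"),
                        condition = c("n", "a", "n", "a"))
  sp <- stratified_kfold_split(man, k = 2, seed = 1)
  for (f in 1:2) {
    te <- man[man$id %in% fold_partition(sp, f)$test, ]
    expect_equal(as.vector(table(te$condition)), c(1, 1))
  }
  expect_error(stratified_kfold_split(man, k = 3, seed = 1),
               class = "sonosiam_input_error")
})

test_that("fold assignments export as a long id/fold/partition CSV", {
  man <- toy_manifest()
  sp <- stratified_kfold_split(man, k = 3, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  long <- write_fold_assignments(sp, path)
  got <- utils::read.csv(path)
  expect_equal(nrow(got), 3 * nrow(man))
  expect_equal(sum(got$partition == "test"), nrow(man))
})
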