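#' Standardize a raw grayscale image
#'
#' Resizes to `side x side` with bilinear interpolation (no resampling when
#' the input already has that geometry) and maps intensities through the
#' affine standardization `(v - 0.5) / 0.5`, centering mid-gray at zero so
#' standardized pixels lie in `[-1, 1]`.
#'
#' @param raw Numeric 2-D matrix with finite values in `[0, 1]`.
#' @param side Target side in pixels. Default 224.
#' @return A `side x side` matrix of standardized intensities.
#' @export
preprocess_image <- function(raw, side = 224L) {
  check_pixels(raw, "raw")
  if (nrow(raw) != side || ncol(raw) != side) {
    raw <- EBImage::resize(raw, w = side, h = side, filter = "bilinear")
  }
  (raw - 0.5) / 0.5
}

#' Augmentation configuration for abnormal-only augmentation
#'
#' The three stochastic transforms emulate freehand scanning variability:
#' horizontal flip (probe orientation), small rotation (fetal positioning)
#' and small translation (probe/fetal motion).
#'
#' @param flip_probability Probability of a horizontal flip, in `[0, 1]`.
#' @param max_rotation_deg Maximum absolute rotation in degrees (>= 0).
#' @param max_translation_frac Maximum absolute translation per axis as a
#'   fraction of the image side, in `[0, 1)`.
#' @param seed Integer seed used by [augment_abnormal()].
#' @return A list of class `augmentation_config`.
#' @export
augmentation_config <- function(flip_probability = 0.5,
                                max_rotation_deg = 10,
                                max_translation_frac = 0.10,
                                seed = 1L) {
  if (flip_probability < 0 || flip_probability > 1) {
    stop_input("flip_probability must be in [0, 1]")
  }
  if (max_rotation_deg < 0) stop_input("max_rotation_deg must be >= 0")
  if (max_translation_frac < 0 || max_translation_frac >= 1) {
    stop_input("max_translation_frac must be in [0, 1)")
  }
  structure(list(flip_probability = flip_probability,
                 max_rotation_deg = max_rotation_deg,
                 max_translation_frac = max_translation_frac,
                 seed = as.integer(seed)),
            class = "augmentation_config")
}

#' Augment an image only when its condition is abnormal
#'
#' Normal-condition images are returned bit-identical; abnormal images are
#' passed through, in order: horizontal flip (with `flip_probability`),
#' rotation uniform in `[-max_rotation_deg, +max_rotation_deg]`, and per-axis
#' translation uniform in `+/- max_translation_frac` of the side. Rotation and
#' translation use bilinear interpolation with zero fill outside the support;
#' the output has the input's shape and the labels are untouched.
#'
#' @param img Numeric pixel matrix in `[0, 1]`.
#' @param condition `"normal"` or `"abnormal"`.
#' @param cfg An [augmentation_config()].
#' @return A pixel matrix of the same shape.
#' @export
augment_abnormal <- function(img, condition = c("normal", "abnormal"),
                             cfg = augmentation_config()) {
  condition <- match.arg(condition)
  check_pixels(img, "img")
  stopifnot(inherits(cfg, "augmentation_config"))
  if (condition == "normal") return(img)
  withr::with_seed(cfg$seed, {
    out <- img
    if (stats::runif(1) < cfg$flip_probability) {
      out <- out[, rev(seq_len(ncol(out))), drop = FALSE]  # horizontal flip
    }
    ang <- stats::runif(1, -cfg$max_rotation_deg, cfg$max_rotation_deg)
    if (ang != 0) {
      out <- EBImage::rotate(out, ang, filter = "bilinear",
                             output.dim = dim(out), bg.col = 0)
    }
    tx <- stats::runif(1, -cfg$max_translation_frac, cfg$max_translation_frac)
    ty <- stats::runif(1, -cfg$max_translation_frac, cfg$max_translation_frac)
    if (tx != 0 || ty != 0) {
      out <- EBImage::translate(out, c(tx * nrow(out), ty * ncol(out)),
                                filter = "bilinear", bg.col = 0)
    }
    out <- matrix(clip(as.numeric(out), 0, 1), nrow(img), ncol(img))
    out
  })
}

#' Oversample minority classes by SMOTE / SMOTE-NC interpolation
#'
#' Balances all classes up to the majority count. Original rows are preserved
#' verbatim; each synthetic row interpolates a minority sample `x` toward one
#' of its `k` nearest same-class neighbors `x_nn` as `x + u * (x_nn - x)`,
#' `u ~ U(0, 1)`, on the numeric columns. When categorical columns are present
#' (SMOTE-NC) the distance adds the squared median of the numeric columns'
#' standard deviations for each categorical mismatch, and a synthetic row's
#' categorical entries are the mode among the `k` neighbors.
#'
#' @param data Tibble/data frame with feature columns plus a class column.
#'   Factor or character feature columns are treated as categorical.
#' @param class_col Name of the class column. Default `"class"`.
#' @param k_neighbors Neighborhood size; defaults to 5 for continuous-only
#'   data and 3 when any categorical column is present.
#' @param seed Integer seed.
#' @return A tibble with equal class counts, original rows first.
#' @export
smote_oversample <- function(data, class_col = "class", k_neighbors = NULL,
                             seed = 1L) {
  data <- tibble::as_tibble(data)
  if (!class_col %in% names(data)) {
    stop_input("class column '", class_col, "' not found")
  }
  cls <- as.character(data[[class_col]])
  feat <- data[setdiff(names(data), class_col)]
  is_cat <- vapply(feat, function(x) is.factor(x) || is.character(x),
                   logical(1))
  num <- as.matrix(feat[!is_cat])
  if (anyNA(feat)) stop_input("data contains missing values")
  k <- k_neighbors %||% (if (any(is_cat)) 3L else 5L)
  if (k < 1) stop_input("k_neighbors must be >= 1")

  counts <- table(cls)
  if (length(counts) < 2) stop_input("need at least 2 classes")
  small <- names(counts)[counts < max(counts)]
  for (cl in names(counts)) {
    if (counts[[cl]] <= k && cl %in% small) {
      stop_input("class '", cl, "' has ", counts[[cl]],
                 " samples; needs more than k_neighbors = ", k)
    }
  }
  if (length(small) == 0) return(data)

  # SMOTE-NC distance penalty: squared median of numeric-column SDs per
  # categorical mismatch
  pen <- if (any(is_cat) && ncol(num) > 0) {
    stats::median(apply(num, 2, stats::sd))^2
  } else 0

  new_rows <- list()
  withr::with_seed(derive_seed(seed, 23L), {
    for (cl in small) {
      idx <- which(cls == cl)
      deficit <- max(counts) - length(idx)
      xn <- num[idx, , drop = FALSE]
      d2 <- if (ncol(num) > 0) as.matrix(stats::dist(xn))^2 else
        matrix(0, length(idx), length(idx))
      if (any(is_cat)) {
        for (j in which(is_cat)) {
          vj <- as.character(feat[[j]])[idx]
          d2 <- d2 + pen * outer(vj, vj, "!=")
        }
      }
      diag(d2) <- Inf
      nn <- t(matrix(apply(d2, 1, function(r) order(r)[seq_len(k)]), nrow = k))
      base <- idx[(seq_len(deficit) - 1L) %% length(idx) + 1L]
      base_loc <- match(base, idx)
      pick <- nn[cbind(base_loc, sample.int(k, deficit, replace = TRUE))]
      u <- stats::runif(deficit)
      syn <- feat[base, , drop = FALSE]
      if (ncol(num) > 0) {
        num_syn <- num[base, , drop = FALSE] +
          u * (num[idx[pick], , drop = FALSE] - num[base, , drop = FALSE])
        syn[names(feat)[!is_cat]] <- as.data.frame(num_syn)
      }
      if (any(is_cat)) {
        for (j in which(is_cat)) {
          vj <- as.character(feat[[j]])
          mode_of <- function(vals) names(sort(table(vals), decreasing = TRUE))[1]
          modes <- vapply(base_loc, function(b) {
            mode_of(vj[idx[nn[b, ]]])
          }, character(1))
          if (is.factor(feat[[j]])) {
            syn[[j]] <- factor(modes, levels = levels(feat[[j]]))
          } else {
            syn[[j]] <- modes
          }
        }
      }
      syn[[class_col]] <- data[[class_col]][base]
      new_rows[[cl]] <- syn
    }
  })
  dplyr::bind_rows(data, dplyr::bind_rows(new_rows))
}

#' Stratified mixed-source k-fold split
#'
#' Assigns every id to exactly one test fold so that per-fold class counts
#' differ from `n_class / k` by less than one sample, and, when both source
#' tags exist within a class, the tags are interleaved so each fold receives a
#' proportional share of each source. With the default confounded phantom
#' manifest (all normals one source, all abnormals the other) this guarantees
#' both sources appear in every train and every test partition.
#'
#' @param manifest Tibble with columns `id`, `condition` (the stratification
#'   class) and optionally `source_tag`.
#' @param k Number of folds (>= 2). Default 5.
#' @param seed Integer seed; assignment is a deterministic function of
#'   `(ids, labels, k, seed)`.
#' @return A tibble `id`, `condition`, `source_tag` (if present), `fold`
#'   (1-based test-fold index), of class `fold_split`.
#' @export
stratified_kfold_split <- function(manifest, k = 5L, seed = 1L) {
  if (k < 2) stop_input("k must be >= 2")
  if (!all(c("id", "condition") %in% names(manifest))) {
    stop_input("manifest needs 'id' and 'condition' columns")
  }
  cls_tab <- table(manifest$condition)
  bad <- names(cls_tab)[cls_tab < k]
  if (length(bad)) {
    stop_input("class '", bad[1], "' has fewer than k = ", k, " members")
  }
  has_src <- "source_tag" %in% names(manifest)
  fold <- integer(nrow(manifest))
  withr::with_seed(derive_seed(seed, 31L), {
    for (cl in names(cls_tab)) {
      rows <- which(manifest$condition == cl)
      if (has_src) {
        # shuffle within source, then interleave sources by fractional rank so
        # every fold receives a proportional slice of each source
        key <- numeric(length(rows))
        for (s in unique(manifest$source_tag[rows])) {
          rs <- which(manifest$source_tag[rows] == s)
          ord <- sample(length(rs))
          key[rs[ord]] <- (seq_along(rs) - stats::runif(length(rs))) / length(rs)
        }
        rows <- rows[order(key)]
      } else {
        rows <- rows[sample(length(rows))]
      }
      fold[rows] <- (seq_along(rows) - 1L) %% k + 1L
    }
  })
  out <- tibble::tibble(
    id = manifest$id,
    condition = manifest$condition,
    fold = fold
  )
  if (has_src) out$source_tag <- manifest$source_tag
  structure(out, k = as.integer(k), class = c("fold_split", class(out)))
}

#' Train/test ids for one fold of a [stratified_kfold_split()]
#'
#' @param splits A `fold_split` tibble.
#' @param fold Test-fold index in `1..k`.
#' @return A list with `train` and `test` id vectors.
#' @export
fold_partition <- function(splits, fold) {
  k <- attr(splits, "k")
  if (fold < 1 || fold > k) stop_input("fold must be in 1..", k)
  list(train = splits$id[splits$fold != fold],
       test = splits$id[splits$fold == fold])
}

#' Write fold assignments as a long CSV (id, fold, partition)
#'
#' @param splits A `fold_split` tibble.
#' @param path Output CSV path.
#' @return Invisibly, the long-format tibble written.
#' @export
write_fold_assignments <- function(splits, path) {
  k <- attr(splits, "k")
  long <- dplyr::bind_rows(lapply(seq_len(k), function(f) {
    tibble::tibble(id = splits$id, fold = f,
                   partition = ifelse(splits$fold == f, "test", "train"))
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(long)
}
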