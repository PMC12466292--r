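#' Generate a synthetic tabular health-record dataset
#'
#' Emulates the statistical shape of cardiotocography-style health tables:
#' Gaussian class-conditional numeric features with a stated mean separation,
#' optional categorical columns drawn from class-dependent multinomials, and
#' configurable class imbalance. Used to exercise the oversampling stage
#' without redistributable clinical data.
#'
#' Numeric feature means for class `c` sit at
#' `class_separation * (c - 1) / sqrt(p_num)` on every numeric column (unit
#' variance), so adjacent classes are `class_separation` apart in Euclidean
#' norm. Categorical columns have 3 levels whose favored-level probability
#' scales with `class_separation`; at `class_separation = 0` every feature is
#' uninformative and classifiers perform at chance.
#'
#' @param n_per_class Vector of 2 or 3 class counts, each >= 2.
#' @param p Total number of feature columns (`p >= n_categorical`).
#' @param n_categorical Number of categorical columns (emitted as factors).
#' @param class_separation Non-negative effect size. Default 2.
#' @param seed Integer seed.
#' @return A tibble with `p` feature columns (`x1..xp`; the last
#'   `n_categorical` are factors) and a `class` factor column. The logical
#'   attribute `categorical_mask` marks categorical columns.
#' @export
generate_tabular_dataset <- function(n_per_class, p = 6, n_categorical = 0,
                                     class_separation = 2, seed = 1L) {
  if (!length(n_per_class) %in% c(2L, 3L)) {
    stop_input("n_per_class must have length 2 or 3")
  }
  if (any(n_per_class < 2)) stop_input("every class count must be >= 2")
  if (p < n_categorical || n_categorical < 0) {
    stop_input("need p >= n_categorical >= 0")
  }
  if (class_separation < 0) stop_input("class_separation must be >= 0")
  p_num <- p - n_categorical
  n <- sum(n_per_class)
  k <- length(n_per_class)
  cls <- rep(seq_len(k), n_per_class)

  withr::with_seed(derive_seed(seed, 7L), {
    cols <- list()
    if (p_num > 0) {
      shift <- class_separation * (cls - 1) / sqrt(p_num)
      for (j in seq_len(p_num)) {
        cols[[paste0("x", j)]] <- stats::rnorm(n, mean = shift, sd = 1)
      }
    }
    if (n_categorical > 0) {
      tilt <- 0.27 * min(1, class_separation)
      for (j in seq_len(n_categorical)) {
        lv <- paste0("L", 1:3)
        val <- character(n)
        for (c_ in seq_len(k)) {
          idx <- which(cls == c_)
          pr <- rep((1 - (1 / 3 + tilt)) / 2, 3)
          pr[(c_ - 1L) %% 3L + 1L] <- 1 / 3 + tilt
          val[idx] <- sample(lv, length(idx), replace = TRUE, prob = pr)
        }
        cols[[paste0("x", p_num + j)]] <- factor(val, levels = lv)
      }
    }
    out <- tibble::as_tibble(cols)
    out$class <- factor(paste0("C", cls), levels = paste0("C", seq_len(k)))
    attr(out, "categorical_mask") <-
      c(rep(FALSE, p_num), rep(TRUE, n_categorical))
    out
  })
}
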