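#' Curriculum stage for a training epoch
#'
#' Maps epoch position to the easy/medium/hard pair-sampling stage: easy pairs
#' for the first `b1` fraction of training, medium until `b2`, hard after.
#' The schedule is non-decreasing in epoch.
#'
#' @param epoch 0-based epoch index, `0 <= epoch < total_epochs`.
#' @param total_epochs Total epoch count.
#' @param boundaries Two increasing fractions in `(0, 1)`. Default
#'   `c(1/3, 2/3)`.
#' @return One of `"easy"`, `"medium"`, `"hard"`.
#' @export
stage_schedule <- function(epoch, total_epochs, boundaries = c(1 / 3, 2 / 3)) {
  if (length(boundaries) != 2 || boundaries[1] <= 0 ||
      boundaries[2] >= 1 || boundaries[1] >= boundaries[2]) {
    stop_config("boundaries must satisfy 0 < b1 < b2 < 1")
  }
  if (epoch < 0 || epoch >= total_epochs) {
    stop_input("epoch must be in [0, total_epochs)")
  }
  frac <- epoch / total_epochs
  if (frac < boundaries[1]) "easy"
  else if (frac < boundaries[2]) "medium"
  else "hard"
}

#' Sample curriculum image pairs from a manifest
#'
#' Emits `n_pairs` pairs labeled `y = 1` when the two images share a condition
#' and `y = 0` otherwise. Stage constraints:
#' \describe{
#'   \item{easy}{both members share a source tag; similar pairs are
#'     same-condition, dissimilar pairs cross condition, with no body-part
#'     restriction.}
#'   \item{medium}{every pair spans the two source tags: similar pairs are
#'     cross-source same-condition (forcing source-invariant embeddings),
#'     dissimilar pairs cross-source cross-condition.}
#'   \item{hard}{dissimilar pairs share a body part but differ in condition;
#'     similar pairs are same-condition.}
#' }
#' Where a stage admits both labels, the similar/dissimilar mix is balanced to
#' 50/50 (within one pair). An unsatisfiable stage stratum raises an input
#' error naming the missing stratum.
#'
#' @param manifest Tibble with `id`, `body_part`, `condition`, `source_tag`.
#' @param stage `"easy"`, `"medium"` or `"hard"`.
#' @param n_pairs Number of pairs to emit.
#' @param seed Integer seed; the emitted pair multiset is deterministic.
#' @return A tibble `id_a`, `id_b`, `y`, `stage`.
#' @export
sample_pairs <- function(manifest, stage = c("easy", "medium", "hard"),
                         n_pairs, seed = 1L) {
  stage <- match.arg(stage)
  if (n_pairs < 1) stop_input("n_pairs must be >= 1")
  m <- manifest
  if (length(unique(m$condition)) < 2) {
    stop_input("manifest must contain both condition classes")
  }

  withr::with_seed(derive_seed(seed, 41L), {
    if (stage == "medium") {
      n_sim <- ceiling(n_pairs / 2)
      sim <- sample_stratum(m, n_sim, same_condition = TRUE,
                            cross_source = TRUE,
                            missing = "cross-source same-condition")
      sim$y <- 1
      dis <- if (n_pairs > n_sim) {
        d <- sample_stratum(m, n_pairs - n_sim, same_condition = FALSE,
                            cross_source = TRUE,
                            missing = "cross-source cross-condition")
        d$y <- 0
        d
      } else NULL
      pairs <- dplyr::bind_rows(sim, dis)
    } else if (stage == "easy") {
      n_sim <- ceiling(n_pairs / 2)
      sim <- sample_stratum(m, n_sim, same_condition = TRUE,
                            same_source = TRUE,
                            missing = "same-source same-condition")
      dis <- sample_stratum(m, n_pairs - n_sim, same_condition = FALSE,
                            same_source = TRUE,
                            missing = "same-source cross-condition")
      sim$y <- 1; dis$y <- 0
      pairs <- dplyr::bind_rows(sim, dis)
    } else {
      n_sim <- floor(n_pairs / 2)
      sim <- if (n_sim > 0) {
        s <- sample_stratum(m, n_sim, same_condition = TRUE,
                            missing = "same-condition")
        s$y <- 1
        s
      } else NULL
      dis <- sample_stratum(m, n_pairs - n_sim, same_condition = FALSE,
                            same_body = TRUE,
                            missing = "same-body-part cross-condition")
      dis$y <- 0
      pairs <- dplyr::bind_rows(sim, dis)
    }
    pairs$stage <- stage
    pairs[sample(nrow(pairs)), c("id_a", "id_b", "y", "stage")]
  })
}

# draw n pairs uniformly from the stratum defined by the constraints
sample_stratum <- function(m, n, same_condition,
                           same_source = FALSE, cross_source = FALSE,
                           same_body = FALSE, missing = "requested") {
  if (n == 0) return(NULL)
  # enumerate admissible (a, b) index pairs a < b
  cond <- m$condition
  src <- m$source_tag
  body <- m$body_part
  nimg <- nrow(m)
  ia <- rep(seq_len(nimg - 1L), times = (nimg - 1L):1L)
  ib <- sequence((nimg - 1L):1L) + ia
  ok <- if (same_condition) cond[ia] == cond[ib] else cond[ia] != cond[ib]
  if (same_source) ok <- ok & src[ia] == src[ib]
  if (cross_source) ok <- ok & src[ia] != src[ib]
  if (same_body) ok <- ok & body[ia] == body[ib]
  cand <- which(ok)
  if (length(cand) == 0) {
    stop_input("no ", missing, " pairs available in the manifest")
  }
  take <- cand[sample.int(length(cand), n, replace = TRUE)]
  tibble::tibble(id_a = m$id[ia[take]], id_b = m$id[ib[take]])
}

#' Write a pair list as CSV for audit
#'
#' @param pairs A pair tibble from [sample_pairs()].
#' @param path Output CSV path.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.csv(pairs, path, row.names = FALSE)
  invisible(pairs)
}
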