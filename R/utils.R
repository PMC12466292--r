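# internal helpers shared across modules

#' @importFrom rlang abort
stop_input <- function(...) rlang::abort(paste0(...), class = "sonosiam_input_error")

stop_config <- function(...) rlang::abort(paste0(...), class = "sonosiam_config_error")

stop_pipeline <- function(...) rlang::abort(paste0(...), class = "sonosiam_pipeline_error")

# Deterministic 32-bit-safe seed derivation: every internal RNG stream is a
# pure function of the user seed plus a salt, and stays below 2^31.
derive_seed <- function(seed, salt) {
  ((seed %% 50021) * 39989 + (salt %% 104729) * 7919 + 17) %% 2147483629L + 1L
}

# Round half away from zero. Used by every quantizer and every oracle; base
# round() is round-half-even and must not leak into the integer kernels.
round_haz <- function(x) trunc(x + 0.5 * sign(x))

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_square_image <- function(x) {
  is.matrix(x) && is.numeric(x) && nrow(x) == ncol(x)
}

check_pixels <- function(x, what = "image") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_input(what, " must be a numeric 2-D matrix")
  }
  if (!all(is.finite(x))) stop_input(what, " contains non-finite pixel values")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

body_part_levels <- c("brain", "thorax", "abdomen")
condition_levels <- c("normal", "abnormal")
source_levels <- c("SRC_A", "SRC_B")
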