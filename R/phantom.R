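#' Render a single synthetic ultrasound phantom
#'
#' Draws a grayscale phantom of one of three fetal body parts using parametric
#' templates: concentric ellipses with a midline echo for the brain, rib-like
#' bright arcs around a cardiac shadow for the thorax, and a large oval with a
#' stomach bubble and spine echo for the abdomen. Multiplicative speckle is
#' added everywhere. Abnormal phantoms carry a bright elliptical lesion
#' (10-20% of the image side, +0.3 contrast) placed inside the organ, which
#' makes the two condition classes separable by construction. The source tag
#' adds a tag-specific nuisance texture (fine horizontal banding for
#' `SRC_A`; blocky compression-like noise plus a small brightness offset for
#' `SRC_B`), emulating acquisition artifacts that differ between data sources.
#'
#' Geometry, speckle and lesion are a function of `seed` only, so rendering
#' the same seed under both source tags yields an identical-geometry pair that
#' differs purely in the nuisance texture.
#'
#' @param body_part One of `"brain"`, `"thorax"`, `"abdomen"`.
#' @param condition One of `"normal"`, `"abnormal"`.
#' @param source_tag One of `"SRC_A"`, `"SRC_B"`.
#' @param side Image side in pixels (square, >= 32). Default 224.
#' @param seed Integer seed controlling geometry, speckle and lesion.
#' @return A `side x side` numeric matrix with values in `[0, 1]`.
#' @export
render_phantom <- function(body_part = c("brain", "thorax", "abdomen"),
                           condition = c("normal", "abnormal"),
                           source_tag = c("SRC_A", "SRC_B"),
                           side = 224L, seed = 1L) {
  body_part <- match.arg(body_part)
  condition <- match.arg(condition)
  source_tag <- match.arg(source_tag)
  if (side < 32) stop_input("side must be >= 32, got ", side)
  side <- as.integer(side)

  # normalized coordinates in [-1, 1]
  u <- matrix(rep(seq(-1, 1, length.out = side), side), side, side)
  v <- t(u)

  img <- withr::with_seed(derive_seed(seed, 11L), {
    # per-image geometry jitter: centre shift, scale, template rotation
    cx <- stats::runif(1, -0.03, 0.03)
    cy <- stats::runif(1, -0.03, 0.03)
    sc <- stats::runif(1, 0.95, 1.05)
    th <- stats::runif(1, -pi / 36, pi / 36)
    ur <- ((u - cx) * cos(th) + (v - cy) * sin(th)) / sc
    vr <- (-(u - cx) * sin(th) + (v - cy) * cos(th)) / sc

    base <- matrix(0.08, side, side)
    base <- base + switch(body_part,
      brain = phantom_brain(ur, vr),
      thorax = phantom_thorax(ur, vr),
      abdomen = phantom_abdomen(ur, vr)
    )

    if (condition == "abnormal") {
      # bright lesion inside the organ: semiaxes 5-10% of side per axis,
      # i.e. lesion diameter 10-20% of the image side
      la <- stats::runif(1, 0.10, 0.20)
      lb <- stats::runif(1, 0.10, 0.20)
      ang <- stats::runif(1, 0, pi)
      lr <- stats::runif(1, 0, 0.30)
      lth <- stats::runif(1, 0, 2 * pi)
      lx <- lr * cos(lth)
      ly <- lr * sin(lth)
      ul <- (ur - lx) * cos(ang) + (vr - ly) * sin(ang)
      vl <- -(ur - lx) * sin(ang) + (vr - ly) * cos(ang)
      q <- (ul / la)^2 + (vl / lb)^2
      base <- base + 0.3 * exp(-q^3)   # plateaued +0.3 contrast lesion
    }

    # multiplicative speckle plus a faint additive noise floor
    z <- matrix(stats::rnorm(side * side), side, side)
    z2 <- matrix(stats::rnorm(side * side), side, side)
    base * (1 + 0.10 * z) + 0.02 * abs(z2)
  })

  img <- img + phantom_source_texture(source_tag, side, seed)
  clip(img, 0, 1)
}

# body-part templates on rotated normalized coordinates ------------------

ellipse_ring <- function(u, v, a, b, width, gain) {
  d <- sqrt((u / a)^2 + (v / b)^2)
  gain * exp(-((d - 1) / width)^2)
}

phantom_brain <- function(u, v) {
  out <- ellipse_ring(u, v, 0.82, 0.66, 0.07, 0.72)          # skull
  out <- out + ellipse_ring(u, v, 0.45, 0.34, 0.10, 0.18)    # inner structure
  out <- out + 0.30 * exp(-(u / 0.02)^2) * as.numeric(abs(v) < 0.55) # midline
  out
}

phantom_thorax <- function(u, v) {
  d <- sqrt(u^2 + v^2)
  out <- ellipse_ring(u, v, 0.85, 0.78, 0.06, 0.55)          # chest wall
  ang <- atan2(v, u)
  ribs <- 0
  for (k in 0:5) {                                           # rib-like arcs
    a0 <- -pi + k * pi / 3 + pi / 12
    dang <- abs(((ang - a0 + pi) %% (2 * pi)) - pi)
    ribs <- ribs + 0.55 * exp(-((d - 0.68) / 0.05)^2) * exp(-(dang / 0.22)^2)
  }
  out <- out + ribs
  out + 0.20 * exp(-(((u - 0.12)^2 + (v + 0.08)^2) / 0.06))  # cardiac mass
}

phantom_abdomen <- function(u, v) {
  out <- ellipse_ring(u, v, 0.88, 0.76, 0.07, 0.60)          # abdominal wall
  bub <- ((u + 0.30) / 0.22)^2 + ((v - 0.18) / 0.15)^2        # stomach bubble
  out <- out - 0.06 * exp(-bub^2)
  out + 0.50 * exp(-(((u - 0.05)^2 + (v + 0.55)^2) / 0.01))  # spine echo
}

# tag-specific nuisance textures; deterministic in (seed, tag) -----------
phantom_source_texture <- function(source_tag, side, seed) {
  if (source_tag == "SRC_A") {
    withr::with_seed(derive_seed(seed, 101L), {
      f <- stats::runif(1, 8, 12)
      ph <- stats::runif(1, 0, 2 * pi)
      r <- matrix(rep(seq_len(side), side), side, side) / side
      0.03 * sin(2 * pi * f * r + ph)
    })
  } else {
    withr::with_seed(derive_seed(seed, 211L), {
      blk <- 8L
      nb <- ceiling(side / blk)
      coarse <- matrix(stats::rnorm(nb * nb, sd = 0.04), nb, nb)
      big <- coarse[rep(seq_len(nb), each = blk), rep(seq_len(nb), each = blk)]
      big[seq_len(side), seq_len(side)] + 0.05
    })
  }
}

#' Generate a labeled synthetic phantom image dataset
#'
#' Produces `n_normal + n_abnormal` phantoms with body parts drawn uniformly
#' from brain/thorax/abdomen. By default the dataset reproduces the
#' source-condition confound of mixed-repository screening corpora: every
#' normal image is tagged `SRC_A` and every abnormal image `SRC_B`.
#' `tag_flip_frac` flips that fraction of each condition class to the opposite
#' tag, de-confounding source and condition for ablation studies.
#'
#' @param n_normal,n_abnormal Non-negative image counts.
#' @param seed Integer seed; the whole dataset is a deterministic function of
#'   the arguments.
#' @param side Image side in pixels (>= 32). Default 224.
#' @param tag_flip_frac Fraction in `[0, 1]` of each condition class assigned
#'   the opposite source tag. Default 0 (fully confounded).
#' @return An object of class `phantom_dataset`: a list with `images` (named
#'   list of `[0,1]` matrices) and `manifest` (tibble with columns `id`,
#'   `body_part`, `condition`, `source_tag`).
#' @export
generate_image_dataset <- function(n_normal, n_abnormal, seed = 1L,
                                   side = 224L, tag_flip_frac = 0) {
  if (n_normal < 0 || n_abnormal < 0) {
    stop_input("image counts must be non-negative")
  }
  if (side < 32) stop_input("side must be >= 32, got ", side)
  if (tag_flip_frac < 0 || tag_flip_frac > 1) {
    stop_input("tag_flip_frac must be in [0, 1]")
  }
  n <- n_normal + n_abnormal
  condition <- rep(condition_levels, c(n_normal, n_abnormal))
  meta <- withr::with_seed(derive_seed(seed, 1L), {
    body <- sample(body_part_levels, n, replace = TRUE)
    tag <- ifelse(condition == "normal", "SRC_A", "SRC_B")
    flip_n <- round(tag_flip_frac * n_normal)
    flip_a <- round(tag_flip_frac * n_abnormal)
    if (flip_n > 0) tag[sample(which(condition == "normal"), flip_n)] <- "SRC_B"
    if (flip_a > 0) tag[sample(which(condition == "abnormal"), flip_a)] <- "SRC_A"
    list(body = body, tag = tag)
  })
  ids <- sprintf("img%05d", seq_len(n))
  images <- vector("list", n)
  names(images) <- ids
  for (i in seq_len(n)) {
    images[[i]] <- render_phantom(meta$body[i], condition[i], meta$tag[i],
                                  side = side, seed = derive_seed(seed, 1000L + i))
  }
  manifest <- tibble::tibble(
    id = ids,
    body_part = meta$body,
    condition = condition,
    source_tag = meta$tag
  )
  structure(list(images = images, manifest = manifest),
            side = as.integer(side), class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  m <- x$manifest
  cat("<phantom_dataset> ", nrow(m), " images, side ", attr(x, "side"), "\n",
      sep = "")
  cat("  condition: ", paste(names(table(m$condition)),
                             table(m$condition), collapse = ", "), "\n", sep = "")
  cat("  source:    ", paste(names(table(m$source_tag)),
                             table(m$source_tag), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a phantom dataset to disk as 8-bit PNGs plus a manifest CSV
#'
#' @param dataset A `phantom_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest tibble augmented with a `path` column.
#' @export
write_phantom_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(dataset$manifest$id, ".png"))
  for (i in seq_along(paths)) {
    png::writePNG(dataset$images[[i]], paths[i])
  }
  manifest <- dplyr::mutate(dataset$manifest, path = paths)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a phantom dataset written by [write_phantom_dataset()]
#'
#' @param dir Directory containing `manifest.csv` and the PNGs.
#' @return A `phantom_dataset`.
#' @export
read_phantom_dataset <- function(dir) {
  manifest <- tibble::as_tibble(
    utils::read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  )
  images <- lapply(manifest$path, function(p) {
    img <- png::readPNG(p)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  })
  names(images) <- manifest$id
  side <- nrow(images[[1]])
  structure(list(images = images,
                 manifest = dplyr::select(manifest, -"path")),
            side = as.integer(side), class = "phantom_dataset")
}

#' Plot a phantom image
#'
#' @param pixels A `[0,1]` pixel matrix.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_phantom <- function(pixels, title = NULL) {
  check_pixels(pixels)
  df <- tidyr::expand_grid(col = seq_len(ncol(pixels)),
                           row = seq_len(nrow(pixels)))
  df$value <- as.vector(pixels)  # column-major: row varies fastest
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = "echo") +
    ggplot2::theme_minimal()
}
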