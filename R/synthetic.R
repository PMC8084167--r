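#' Synthetic phase-contrast cell crops
#'
#' Seeded parametric generator for grayscale crops emulating the six hESC
#' morphologies seen in phase-contrast video: (0) cell cluster, (1) debris,
#' (2) unattached cell, (3) attached cell, (4) dynamically blebbing cell,
#' (5) apoptotically blebbing cell.  Classes are separated by the three cues
#' a human annotator uses — shape, intensity and texture — via geometric
#' constructions (summed Gaussian lobes, soft discs, halo rings, boundary
#' bleb bumps, multi-octave value noise) on a mid-gray background (0.5 on
#' the normalized scale).
#'
#' Intensity contrasts scale with `separability`; `noise_sd` adds Gaussian
#' pixel noise on the normalized scale.  Images are emitted in the raw
#' \[0, 255\] domain at the requested size; resizing to the network input
#' size is the data pipeline's job.
#'
#' @param class_id Integer class id in 0..5.
#' @param image_size Side length in pixels (square), at least 16.
#' @param noise_sd Additive Gaussian noise standard deviation on the
#'   normalized \[0, 1\] intensity scale.
#' @param separability Contrast scale in (0, 1]: 1 gives fully separated
#'   class contrasts, smaller values shrink all class-specific intensity
#'   differences toward the background.
#' @param seed Optional integer; when given, the image is a pure function
#'   of the arguments (caller RNG state is preserved).
#' @return A raw-domain [gray_image].
#' @examples
#' img <- generate_class_image(2, 64, noise_sd = 0, seed = 1)
#' max(img) > 128
#' @export
generate_class_image <- function(class_id, image_size = 64, noise_sd = 0.02,
                                 separability = 1.0, seed = NULL) {
  if (!is_count(class_id) || class_id > 5)
    stopf("class_id must be an integer in 0..5")
  if (!is_count(image_size, min = 16L))
    stopf("image_size must be an integer >= 16")
  if (!is.numeric(noise_sd) || noise_sd < 0) stopf("noise_sd must be >= 0")
  if (!is.numeric(separability) || separability <= 0 || separability > 1)
    stopf("separability must lie in (0, 1]")
  with_seed(seed, render_class_image(as.integer(class_id), as.integer(image_size),
                                     noise_sd, separability))
}

# ---- recipe internals -------------------------------------------------------

# multi-octave value noise in [-1, 1]-ish range (Perlin-style texture)
value_noise <- function(s, cells = 8L, octaves = 3L) {
  out <- matrix(0, s, s)
  amp <- 1
  for (o in seq_len(octaves)) {
    n <- cells * 2L^(o - 1L)
    g <- matrix(runif((n + 1L)^2, -1, 1), n + 1L, n + 1L)
    # bilinear upsample of the coarse grid to s x s
    pos <- (seq_len(s) - 0.5) / s * n
    i0 <- pmin(floor(pos), n - 1L); fi <- pos - i0
    a <- g[cbind(rep(i0 + 1L, s), rep(i0 + 1L, each = s))]
    b <- g[cbind(rep(i0 + 2L, s), rep(i0 + 1L, each = s))]
    cc <- g[cbind(rep(i0 + 1L, s), rep(i0 + 2L, each = s))]
    d <- g[cbind(rep(i0 + 2L, s), rep(i0 + 2L, each = s))]
    wr <- rep(fi, s); wc <- rep(fi, each = s)
    layer <- (1 - wr) * (1 - wc) * a + wr * (1 - wc) * b +
             (1 - wr) * wc * cc + wr * wc * d
    out <- out + amp * matrix(layer, s, s)
    amp <- amp / 2
  }
  out / 1.75
}

soft_disc <- function(d, radius, edge) 1 / (1 + exp((d - radius) / edge))

gauss_bump <- function(X, Y, cx, cy, sigma) {
  exp(-((X - cx)^2 + (Y - cy)^2) / (2 * sigma^2))
}

render_class_image <- function(class_id, s, noise_sd, sep) {
  ax <- seq(-1, 1, length.out = s)
  X <- matrix(ax, s, s, byrow = TRUE)  # column coordinate
  Y <- matrix(ax, s, s)                # row coordinate
  cx <- runif(1, -0.06, 0.06); cy <- runif(1, -0.06, 0.06)
  D <- sqrt((X - cx)^2 + (Y - cy)^2)
  img <- matrix(0.5, s, s)

  if (class_id == 0L) {
    # cell cluster: large multi-lobed blob with strong internal texture
    nl <- sample(3:6, 1)
    mask <- matrix(0, s, s)
    for (l in seq_len(nl)) {
      lx <- cx + runif(1, -0.35, 0.35); ly <- cy + runif(1, -0.35, 0.35)
      mask <- pmax(mask, gauss_bump(X, Y, lx, ly, runif(1, 0.22, 0.32)))
    }
    mask <- pmin(mask / 0.6, 1)
    tex <- value_noise(s, 8L, 3L)
    img <- img + mask * (0.16 * sep + 0.12 * sep * tex)
  } else if (class_id == 1L) {
    # debris: small irregular low-contrast fragment
    theta <- atan2(Y - cy, X - cx)
    r0 <- runif(1, 0.10, 0.15)
    rr <- r0 * (1 + 0.35 * sin(3 * theta + runif(1, 0, 2 * pi)) +
                     0.25 * sin(5 * theta + runif(1, 0, 2 * pi)))
    mask <- soft_disc(D - (rr - r0), r0, 0.015)
    tex <- value_noise(s, 6L, 2L)
    img <- img - mask * (0.10 * sep + 0.03 * sep * tex)
  } else if (class_id == 2L) {
    # unattached cell: compact bright disc with a bright halo ring
    r0 <- runif(1, 0.21, 0.27)
    body <- soft_disc(D, r0, 0.02)
    halo <- exp(-((D - (r0 + 0.06))^2) / (2 * 0.035^2))
    img <- img + body * 0.30 * sep + halo * 0.45 * sep
  } else if (class_id == 3L) {
    # attached cell: large, spread, low contrast, blends into background
    ecc <- runif(1, 0.6, 1.0)
    Da <- sqrt(((X - cx) / 1)^2 + ((Y - cy) / ecc)^2)
    mask <- soft_disc(Da, 0.52, 0.16)
    tex <- value_noise(s, 5L, 2L)
    img <- img + mask * (0.07 * sep + 0.035 * sep * tex)
  } else if (class_id == 4L) {
    # dynamically blebbing cell: medium body, 1-4 boundary protrusions
    r0 <- runif(1, 0.19, 0.23)
    body <- soft_disc(D, r0, 0.02)
    img <- img + body * 0.15 * sep
    nb <- sample(1:4, 1)
    ang <- 2 * pi * (seq_len(nb) - 1) / nb + runif(1, 0, 2 * pi)
    for (a in ang) {
      bx <- cx + (r0 + 0.02) * cos(a); by <- cy + (r0 + 0.02) * sin(a)
      img <- img + 0.25 * sep * gauss_bump(X, Y, bx, by, 0.055)
    }
  } else {
    # apoptotically blebbing cell: body covered with many small blebs
    r0 <- runif(1, 0.22, 0.26)
    body <- soft_disc(D, r0, 0.02)
    tex <- value_noise(s, 10L, 2L)
    img <- img + body * (0.12 * sep + 0.05 * sep * tex)
    nb <- sample(8:11, 1)
    ang <- 2 * pi * (seq_len(nb) - 1) / nb + runif(nb, -0.05, 0.05) +
      runif(1, 0, 2 * pi)
    for (a in ang) {
      bx <- cx + r0 * cos(a); by <- cy + r0 * sin(a)
      img <- img + 0.32 * sep * gauss_bump(X, Y, bx, by, 0.04)
    }
  }

  if (noise_sd > 0) img <- img + matrix(rnorm(s * s, 0, noise_sd), s, s)
  gray_image(pmin(pmax(img, 0), 1) * 255, "raw")
}

#' Configuration for the synthetic dataset generator
#'
#' @param image_size Square image side in pixels (>= 16).
#' @param counts_per_class Six non-negative integers: labeled images per
#'   class.
#' @param unlabeled_count Non-negative integer: size of the unlabeled pool,
#'   drawn uniformly from the six class recipes with labels discarded.
#' @param noise_sd,class_separability,seed See [generate_class_image()].
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(image_size = 64, counts_per_class = rep(60L, 6),
                             unlabeled_count = 600L, noise_sd = 0.02,
                             class_separability = 1.0, seed = 1L) {
  if (!is_count(image_size, 16L)) stopf("image_size must be an integer >= 16")
  if (length(counts_per_class) != 6L ||
      !all(vapply(counts_per_class, is_count, logical(1))))
    stopf("counts_per_class must be 6 non-negative integers")
  if (!is_count(unlabeled_count)) stopf("unlabeled_count must be >= 0")
  if (!is.numeric(noise_sd) || noise_sd < 0) stopf("noise_sd must be >= 0")
  if (class_separability <= 0 || class_separability > 1)
    stopf("class_separability must lie in (0, 1]")
  if (!is_count(abs(seed))) stopf("seed must be an integer")
  structure(list(image_size = as.integer(image_size),
                 counts_per_class = as.integer(counts_per_class),
                 unlabeled_count = as.integer(unlabeled_count),
                 noise_sd = noise_sd,
                 class_separability = class_separability,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a labeled and an unlabeled synthetic image pool
#'
#' Draws `counts_per_class[c+1]` images from each class recipe `c` for the
#' labeled pool and `unlabeled_count` images from the six recipes uniformly
#' at random (labels discarded) for the unlabeled pool.  The output is a
#' pure function of the configuration: identical config (including seed)
#' gives bit-identical image sets.
#'
#' @param config A [synthetic_config()].
#' @return List with elements `labeled` ([labeled_dataset]) and `unlabeled`
#'   (`unlabeled_dataset`).
#' @examples
#' ds <- generate_dataset(synthetic_config(
#'   image_size = 16, counts_per_class = rep(2L, 6), unlabeled_count = 4L))
#' length(ds$labeled$images); length(ds$unlabeled$images)
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, as.list(config))
  with_seed(config$seed, {
    images <- list(); labels <- integer(0)
    for (cl in 0:5) {
      nc <- config$counts_per_class[cl + 1L]
      if (nc > 0) {
        images <- c(images, lapply(seq_len(nc), function(i)
          render_class_image(cl, config$image_size, config$noise_sd,
                             config$class_separability)))
        labels <- c(labels, rep.int(cl, nc))
      }
    }
    ucl <- if (config$unlabeled_count > 0)
      sample(0:5, config$unlabeled_count, replace = TRUE) else integer(0)
    uimages <- lapply(ucl, function(cl)
      render_class_image(cl, config$image_size, config$noise_sd,
                         config$class_separability))
    list(labeled = labeled_dataset(images, labels),
         unlabeled = unlabeled_dataset(uimages))
  })
}
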