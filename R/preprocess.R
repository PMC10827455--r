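#' Augmentation configuration
#'
#' Settings for the stochastic geometric augmentations applied to training
#' images (random shifts, flips, rotations) and for mixup. Magnitudes
#' default to mild values suitable for whole-slide crops: shifts up to 10%
#' of each spatial dimension, rotations within +/-15 degrees, both flips
#' with probability 1/2, and mixup Beta(0.2, 0.2).
#'
#' @param shift_fraction maximum shift as a fraction of H and W, in `[0, 0.5]`.
#' @param rotation_degrees maximum absolute rotation angle, in `[0, 180]`.
#' @param hflip,vflip logicals; allow horizontal / vertical flips.
#' @param mixup_alpha positive Beta concentration for mixup.
#' @param seed integer seed for the augmentation stream.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(shift_fraction = 0.1, rotation_degrees = 15,
                           hflip = TRUE, vflip = TRUE,
                           mixup_alpha = 0.2, seed = 1L) {
  if (shift_fraction < 0 || shift_fraction > 0.5)
    abort("`shift_fraction` must be in [0, 0.5]")
  if (rotation_degrees < 0 || rotation_degrees > 180)
    abort("`rotation_degrees` must be in [0, 180]")
  if (mixup_alpha <= 0) abort("`mixup_alpha` must be positive")
  structure(list(shift_fraction = shift_fraction,
                 rotation_degrees = rotation_degrees,
                 hflip = isTRUE(hflip), vflip = isTRUE(vflip),
                 mixup_alpha = mixup_alpha, seed = as.integer(seed)),
            class = "augment_config")
}

#' Standardize an image per channel
#'
#' Centers and scales each color channel to mean 0 and standard deviation 1
#' using that image's own statistics: `(x - mean) / (sd + eps)`. A constant
#' channel maps to all zeros through the `eps` guard.
#'
#' @param img `image_tensor`.
#' @param eps small stabilizer added to the standard deviation.
#' @return A normalized `image_tensor` (flag set).
#' @export
normalize_image <- function(img, eps = 1e-7) {
  px <- img$pixels
  if (!all(is.finite(px))) abort("image contains non-finite pixels")
  d <- dim(px)
  for (c in 1:3) {
    ch <- px[, , c]
    px[, , c] <- (ch - mean(ch)) / (stats::sd(ch) + eps)
  }
  image_tensor(px, id = img$id, normalized = TRUE)
}

to_eb <- function(px) EBImage::Image(aperm(px, c(2L, 1L, 3L)), colormode = "Color")
from_eb <- function(im) aperm(EBImage::imageData(im), c(2L, 1L, 3L))

#' Resize then crop an image
#'
#' Bilinear resize to `resize_to` (height, width) followed by a center or
#' seeded random crop to `crop_to`. The defaults take the 700x460 source
#' frame through 350x240 down to the 224x224 network input.
#'
#' @param img `image_tensor`.
#' @param resize_to integer `(height, width)` after resizing.
#' @param crop_to integer `(height, width)` of the crop; must fit in `resize_to`.
#' @param mode `"center"` (deterministic) or `"random"` (seeded).
#' @param seed integer seed used when `mode = "random"`.
#' @return An `image_tensor` of spatial size `crop_to`.
#' @export
resize_and_crop <- function(img, resize_to = c(240L, 350L), crop_to = c(224L, 224L),
                            mode = c("center", "random"), seed = 1L) {
  mode <- match.arg(mode)
  if (any(crop_to > resize_to)) abort("`crop_to` must fit inside `resize_to`")
  px <- img$pixels
  if (!all(dim(px)[1:2] == resize_to)) {
    px <- from_eb(EBImage::resize(to_eb(px), w = resize_to[2], h = resize_to[1]))
  }
  slack <- resize_to - crop_to
  off <- if (mode == "center") {
    floor(slack / 2)
  } else {
    with_seed(seed, c(sample.int(slack[1] + 1L, 1L), sample.int(slack[2] + 1L, 1L)) - 1L)
  }
  out <- px[off[1] + seq_len(crop_to[1]), off[2] + seq_len(crop_to[2]), , drop = FALSE]
  image_tensor(out, id = img$id, normalized = img$normalized)
}

#' Apply the standard geometric augmentations
#'
#' Seeded random shift, horizontal flip, vertical flip and rotation, each
#' drawn from the ranges in the [augment_config()]. Output shape equals the
#' input shape; regions shifted or rotated in from outside the frame are
#' filled with 0 (the per-channel mean after normalization).
#'
#' @param img `image_tensor` (already resized/cropped).
#' @param cfg `augment_config`.
#' @param seed integer seed; defaults to `cfg$seed`.
#' @return An augmented `image_tensor` of identical shape.
#' @export
standard_augment <- function(img, cfg = augment_config(), seed = cfg$seed) {
  px <- img$pixels
  d <- dim(px)
  draws <- with_seed(seed, list(
    dy = if (cfg$shift_fraction > 0)
      sample.int(2L * floor(cfg$shift_fraction * d[1]) + 1L, 1L) -
        floor(cfg$shift_fraction * d[1]) - 1L else 0L,
    dx = if (cfg$shift_fraction > 0)
      sample.int(2L * floor(cfg$shift_fraction * d[2]) + 1L, 1L) -
        floor(cfg$shift_fraction * d[2]) - 1L else 0L,
    hf = cfg$hflip && runif(1) < 0.5,
    vf = cfg$vflip && runif(1) < 0.5,
    ang = if (cfg$rotation_degrees > 0)
      runif(1, -cfg$rotation_degrees, cfg$rotation_degrees) else 0
  ))
  im <- to_eb(px)
  if (draws$dy != 0L || draws$dx != 0L)
    im <- EBImage::translate(im, v = c(draws$dx, draws$dy), bg.col = 0)
  if (draws$hf) im <- EBImage::flop(im)
  if (draws$vf) im <- EBImage::flip(im)
  if (draws$ang != 0)
    im <- EBImage::rotate(im, draws$ang, output.dim = c(d[2], d[1]), bg.col = 0)
  image_tensor(from_eb(im), id = img$id, normalized = img$normalized)
}

#' Flip an image horizontally
#'
#' Deterministic mirror along the width axis (exported mainly for the
#' flip/normalize commutation property and as a building block).
#'
#' @param img `image_tensor`.
#' @return The mirrored `image_tensor`.
#' @export
flip_horizontal <- function(img) {
  image_tensor(img$pixels[, rev(seq_len(dim(img$pixels)[2])), , drop = FALSE],
               id = img$id, normalized = img$normalized)
}

#' Mixup a batch of images and one-hot labels
#'
#' Convexly combines each image with a permuted partner,
#' `lambda * x_i + (1 - lambda) * x_perm(i)`, with `lambda ~ Beta(alpha, alpha)`
#' drawn per pair and the same `lambda` applied to the one-hot labels, which
#' therefore stay in the probability simplex.
#'
#' @param x `(H, W, 3, N)` array of images, `N >= 2` (a size-1 batch is
#'   returned unchanged with a warning).
#' @param y `N x 2` one-hot (or soft) label matrix.
#' @param alpha positive Beta concentration.
#' @param seed integer seed.
#' @return A list with elements `x`, `y`, `lambda`, `perm`.
#' @export
mixup_batch <- function(x, y, alpha = 0.2, seed = 1L) {
  n <- dim(x)[4]
  if (is.null(n) || nrow(y) != n) abort("`x` and `y` batch sizes must agree")
  if (n < 2L) {
    warn("mixup needs a batch of at least 2; returning the batch unchanged")
    return(list(x = x, y = y, lambda = rep(1, n), perm = seq_len(n)))
  }
  if (alpha <= 0) abort("`alpha` must be positive")
  dr <- with_seed(seed, list(perm = sample.int(n), lambda = rbeta(n, alpha, alpha)))
  lam_px <- rep(dr$lambda, each = prod(dim(x)[1:3]))
  xm <- array(lam_px * as.vector(x) + (1 - lam_px) * as.vector(x[, , , dr$perm, drop = FALSE]),
              dim = dim(x))
  ym <- dr$lambda * y + (1 - dr$lambda) * y[dr$perm, , drop = FALSE]
  list(x = xm, y = ym, lambda = dr$lambda, perm = dr$perm)
}

#' Load and preprocess manifest images into a batch array
#'
#' Reads each record's file, standardizes it per channel, resizes and crops
#' (center crop; the stochastic crop/augmentations belong to the training
#' loop), and stacks the result into an `(H, W, 3, N)` array ordered as the
#' manifest rows.
#'
#' @param manifest a manifest tibble (see [scan_dataset()]).
#' @param resize_to,crop_to spatial sizes passed to [resize_and_crop()].
#' @param normalize logical; apply [normalize_image()].
#' @return An `(crop_to[1], crop_to[2], 3, nrow(manifest))` array.
#' @export
load_images <- function(manifest, resize_to = c(240L, 350L),
                        crop_to = c(224L, 224L), normalize = TRUE) {
  imgs <- purrr::map2(manifest$path, manifest$id, function(p, id) {
    im <- read_image(p, id = id)
    if (normalize) im <- normalize_image(im)
    resize_and_crop(im, resize_to = resize_to, crop_to = crop_to, mode = "center")
  })
  stack_images(imgs)
}
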