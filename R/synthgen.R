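#' Specification of a synthetic two-class histology-like dataset
#'
#' Generates hematoxylin/eosin-palette images of elliptical "nuclei" blobs
#' whose count is Poisson and whose radii are lognormal, across the four
#' magnification tiers and two classes of the BreakHis layout. A single
#' scalar `separation` (delta) controls class separability: malignant
#' images carry `1 + delta` times the benign nucleus density and
#' `1 + delta/4` times the benign radius, so `delta = 0` makes the two
#' class-conditional distributions identical and large `delta` makes them
#' trivially separable (the default, `delta = 2`, gives malignant tissue
#' three times the benign nucleus density). Magnification multiplies blob
#' radii per tier, mimicking optical zoom.
#'
#' @param n_per_cell images per (magnification, class) cell.
#' @param image_size integer `(H, W)`, at least (64, 64) for file output.
#' @param nucleus_density mean benign nucleus count per image.
#' @param nucleus_radius mean benign nucleus radius in pixels.
#' @param separation non-negative effect size delta.
#' @param noise_sd additive Gaussian pixel noise standard deviation.
#' @param magnification_scale named per-tier radius multiplier.
#' @param seed integer master seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_cell = 8L, image_size = c(64L, 64L),
                           nucleus_density = 12, nucleus_radius = 3,
                           separation = 2, noise_sd = 0.04,
                           magnification_scale = c(`40` = 0.6, `100` = 0.85,
                                                   `200` = 1.15, `400` = 1.5),
                           seed = 1L) {
  if (separation < 0) abort("`separation` must be >= 0")
  if (n_per_cell < 1L) abort("`n_per_cell` must be >= 1")
  structure(list(n_per_cell = as.integer(n_per_cell),
                 image_size = as.integer(image_size),
                 nucleus_density = nucleus_density,
                 nucleus_radius = nucleus_radius,
                 separation = separation, noise_sd = noise_sd,
                 magnification_scale = magnification_scale,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# eosin-pink background, hematoxylin-purple nuclei
SYNTH_BG <- c(0.91, 0.79, 0.86)
SYNTH_NUCLEUS <- c(0.38, 0.22, 0.55)

#' Generate one synthetic histology-like image
#'
#' Deterministic given `(spec$seed, class_label, magnification, index)`.
#'
#' @param spec `synthetic_spec`.
#' @param class_label `"benign"` or `"malignant"`.
#' @param magnification one of 40, 100, 200, 400.
#' @param index image index within the (magnification, class) cell.
#' @return An `image_tensor` with pixels in `[0, 1]`.
#' @export
generate_image <- function(spec, class_label, magnification, index = 1L) {
  class_label <- match.arg(class_label, CLASS_LEVELS)
  mi <- match(as.integer(magnification), MAGNIFICATIONS)
  if (is.na(mi)) abort("`magnification` must be one of 40, 100, 200, 400")
  h <- spec$image_size[1]; w <- spec$image_size[2]
  delta <- spec$separation
  dens <- spec$nucleus_density * (if (class_label == "malignant") 1 + delta else 1)
  rad <- spec$nucleus_radius * (if (class_label == "malignant") 1 + delta / 4 else 1) *
    spec$magnification_scale[[as.character(magnification)]]
  sd_seed <- derive_seed(spec$seed, mi, match(class_label, CLASS_LEVELS), index)
  px <- with_seed(sd_seed, {
    img <- array(rep(SYNTH_BG, each = h * w), dim = c(h, w, 3L))
    nb <- rpois(1L, dens)
    ys <- matrix(rep(seq_len(h), w), nrow = h)
    xs <- matrix(rep(seq_len(w), each = h), nrow = h)
    for (k in seq_len(nb)) {
      cy <- runif(1, 1, h); cx <- runif(1, 1, w)
      a <- rad * exp(rnorm(1, 0, 0.25))
      b <- a * runif(1, 0.6, 1)
      th <- runif(1, 0, pi)
      shade <- runif(1, 0.75, 1)
      dy <- ys - cy; dx <- xs - cx
      u <- (dx * cos(th) + dy * sin(th)) / a
      v <- (-dx * sin(th) + dy * cos(th)) / b
      inside <- (u * u + v * v) <= 1
      if (!any(inside)) next
      for (c in 1:3) {
        ch <- img[, , c]
        ch[inside] <- 0.15 * ch[inside] + 0.85 * SYNTH_NUCLEUS[c] * shade
        img[, , c] <- ch
      }
    }
    img + array(rnorm(h * w * 3L, 0, spec$noise_sd), dim = dim(img))
  })
  image_tensor(pmin(pmax(px, 0), 1),
               id = sprintf("%dX_%s_%03d", magnification, class_label, index))
}

#' Write a synthetic dataset in the BreakHis directory layout
#'
#' Emits `root/<magnification>X/<class>/img_<index>.png` for every
#' (magnification, class, index) cell of the spec and returns the manifest
#' that [scan_dataset()] recovers from the same tree.
#'
#' @param spec `synthetic_spec`.
#' @param root output directory (created if needed).
#' @return A manifest tibble (as from [scan_dataset()]).
#' @export
write_dataset <- function(spec, root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root)) abort(paste0("cannot create dataset root: ", root))
  for (mag in MAGNIFICATIONS) for (cls in CLASS_LEVELS) {
    dir <- file.path(root, paste0(mag, "X"), cls)
    for (i in seq_len(spec$n_per_cell)) {
      write_image(generate_image(spec, cls, mag, i),
                  file.path(dir, sprintf("img_%03d.png", i)))
    }
  }
  scan_dataset(root)
}

#' Generate an in-memory synthetic batch
#'
#' Convenience used by tests and simulations: images plus a manifest-like
#' tibble, without touching the filesystem. Images are standardized per
#' channel when `normalize = TRUE` (no resize: the generator already emits
#' network-sized frames).
#'
#' @param spec `synthetic_spec`.
#' @param magnifications subset of tiers to generate (default all four).
#' @param normalize standardize each image per channel?
#' @return A list: `x` (`(H, W, 3, N)` array), `manifest` (tibble with
#'   `id`, `magnification`, `class_label`, `subtype`, `split`, `pool`).
#' @export
synthetic_batch <- function(spec, magnifications = MAGNIFICATIONS, normalize = TRUE) {
  rows <- list(); imgs <- list()
  for (mag in magnifications) for (cls in CLASS_LEVELS) {
    for (i in seq_len(spec$n_per_cell)) {
      im <- generate_image(spec, cls, mag, i)
      if (normalize) im <- normalize_image(im)
      imgs[[length(imgs) + 1L]] <- im
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = im$id, path = NA_character_, magnification = as.integer(mag),
        class_label = cls, subtype = "unknown",
        split = "unassigned", pool = "none")
    }
  }
  list(x = stack_images(imgs), manifest = dplyr::bind_rows(rows))
}
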