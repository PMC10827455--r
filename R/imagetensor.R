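#' Construct an image tensor
#'
#' The package's in-memory image container: an H x W x 3 numeric array with
#' provenance (the originating manifest record id) and a flag recording
#' whether per-channel standardization has been applied.
#'
#' @param pixels numeric H x W x 3 array.
#' @param id provenance token (manifest record id), or `NA`.
#' @param normalized logical; has per-channel standardization been applied?
#' @return An object of class `image_tensor`.
#' @export
image_tensor <- function(pixels, id = NA_character_, normalized = FALSE) {
  pixels <- as.array(pixels)
  if (length(dim(pixels)) == 2L) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    abort("`pixels` must be an H x W x 3 array")
  structure(list(pixels = pixels, id = as.character(id),
                 normalized = isTRUE(normalized)),
            class = "image_tensor")
}

#' @export
print.image_tensor <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_tensor %dx%dx%d id=%s normalized=%s>\n",
              d[1], d[2], d[3], x$id, x$normalized))
  invisible(x)
}

#' @export
dim.image_tensor <- function(x) dim(x$pixels)

#' Read an image file into an image tensor
#'
#' Decodes PNG (and, via EBImage, JPEG/TIFF) files into an `image_tensor`
#' with pixels in `[0, 1]`. Grayscale input is replicated to 3 channels;
#' an alpha channel is dropped.
#'
#' @param path file path.
#' @param id provenance token stored on the tensor.
#' @return An `image_tensor`.
#' @export
read_image <- function(path, id = NA_character_) {
  if (!file.exists(path)) abort(paste0("image file not found: ", path))
  px <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    # EBImage stores images x-major (width, height, channel)
    aperm(EBImage::imageData(EBImage::readImage(path)), c(2L, 1L, 3L))
  }
  if (length(dim(px)) == 3L && dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  image_tensor(px, id = id)
}

#' Write an image tensor to a PNG file
#'
#' @param img `image_tensor` with pixels in `[0, 1]`.
#' @param path output file path (directories created as needed).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  px <- pmin(pmax(img$pixels, 0), 1)
  png::writePNG(px, target = path)
  invisible(path)
}

# stack a list of image tensors into an (H, W, 3, N) array
stack_images <- function(imgs) {
  if (length(imgs) == 0L) abort("cannot stack an empty image list")
  d <- dim(imgs[[1]]$pixels)
  x <- array(0, dim = c(d, length(imgs)))
  for (i in seq_along(imgs)) x[, , , i] <- imgs[[i]]$pixels
  x
}
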