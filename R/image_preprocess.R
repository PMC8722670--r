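# scanpath_image pixels are stored height x width with row 1 at the top;
# EBImage stores width x height. These two helpers are the only place the
# conversion happens.
as_ebimage <- function(image) EBImage::Image(t(image$pixels))
from_ebimage <- function(eb, meta, n_strokes = NA_integer_) {
  px <- t(EBImage::imageData(eb))
  px[px < 0] <- 0; px[px > 1] <- 1
  structure(list(pixels = px, meta = meta, n_strokes = n_strokes),
            class = "scanpath_image")
}

#' Crop the black background from a scanpath image
#'
#' Returns the tight bounding box of all lit pixels, expanded by `margin`
#' pixels on each side and clamped to the image bounds. An all-black image
#' cannot be cropped; it is returned unchanged with `meta$all_black = TRUE`
#' so cohort bookkeeping stays consistent.
#'
#' @param image a `scanpath_image`.
#' @param margin margin in pixels around the content bounding box.
#' @return A cropped `scanpath_image`.
#' @export
crop_background <- function(image, margin = 2L) {
  stopifnot(inherits(image, "scanpath_image"))
  px <- image$pixels
  lit <- which(px > 0, arr.ind = TRUE)
  if (nrow(lit) == 0L) {
    image$meta$all_black <- TRUE
    warning("all-black image: nothing to crop")
    return(image)
  }
  r0 <- max(1L, min(lit[, 1]) - margin); r1 <- min(nrow(px), max(lit[, 1]) + margin)
  c0 <- max(1L, min(lit[, 2]) - margin); c1 <- min(ncol(px), max(lit[, 2]) + margin)
  image$pixels <- px[r0:r1, c0:c1, drop = FALSE]
  image
}

#' Resize a scanpath image to fixed dimensions
#'
#' Bilinear resize to `dims`, applied uniformly to every image regardless of
#' its post-crop aspect ratio (one fixed input geometry for the classifier).
#'
#' @param image a `scanpath_image`.
#' @param dims target `c(width, height)`, default `c(256, 256)`.
#' @return The resized `scanpath_image`.
#' @export
resize_image <- function(image, dims = c(256L, 256L)) {
  stopifnot(inherits(image, "scanpath_image"))
  W <- as.integer(dims[1]); H <- as.integer(dims[2])
  if (ncol(image$pixels) == W && nrow(image$pixels) == H) return(image)
  eb <- EBImage::resize(as_ebimage(image), w = W, h = H)
  from_ebimage(eb, image$meta, image$n_strokes)
}

#' Augment a set of scanpath images with affine jitter
#'
#' Generates exactly `n_per_image` label-preserving variants of each image by
#' a small random affine transform: rotation within `rotation` degrees,
#' translation within `shift` of the image size, and zoom within `zoom`. No
#' horizontal flip is applied (gaze laterality may be diagnostic) and no
#' photometric jitter (it would corrupt the velocity encoding). Variants
#' inherit their source's metadata plus an `augmented_from` index, so
#' participant-wise splits can keep them with their participant. Fully
#' deterministic given `seed`.
#'
#' @param images list of `scanpath_image`.
#' @param n_per_image variants per source image (default 5).
#' @param seed integer RNG seed.
#' @param rotation,shift,zoom jitter half-ranges (degrees, fraction,
#'   fraction).
#' @return list of `n_per_image * length(images)` new `scanpath_image`s
#'   (sources are not included).
#' @export
augment_dataset <- function(images, n_per_image = 5L, seed = 1L,
                            rotation = 10, shift = 0.05, zoom = 0.10) {
  stopifnot(n_per_image >= 0L)
  if (n_per_image == 0L || length(images) == 0L) return(list())
  out <- vector("list", n_per_image * length(images))
  k <- 0L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (i in seq_along(images)) {
    src <- images[[i]]
    eb <- as_ebimage(src)
    W <- ncol(src$pixels); H <- nrow(src$pixels)
    for (j in seq_len(n_per_image)) {
      th <- stats::runif(1, -rotation, rotation) * pi / 180
      f <- 1 + stats::runif(1, -zoom, zoom)
      dx <- stats::runif(1, -shift, shift) * W
      dy <- stats::runif(1, -shift, shift) * H
      A <- f * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
      ctr <- c(W, H) / 2
      off <- ctr + c(dx, dy) - as.vector(A %*% ctr)
      m <- rbind(t(A), off)                     # 3x2: [x y 1] %*% m
      ebv <- EBImage::affine(eb, m, filter = "bilinear", bg.col = 0,
                             antialias = FALSE)
      meta <- src$meta
      meta$augmented_from <- i
      meta$augment_index <- j
      k <- k + 1L
      out[[k]] <- from_ebimage(ebv, meta)
    }
  }
  out
}

#' Crop, resize and (optionally) augment a rendered image set
#'
#' The standard preprocessing chain: background crop, bilinear resize to a
#' fixed size, and seeded affine augmentation.
#'
#' @param images list of `scanpath_image`.
#' @param dims classifier input size `c(width, height)`.
#' @param margin crop margin, px.
#' @param n_per_image augmentation variants per image (0 to disable).
#' @param seed RNG seed for augmentation.
#' @return list with `processed` (resized originals) and `augmented`.
#' @export
preprocess_images <- function(images, dims = c(256L, 256L), margin = 2L,
                              n_per_image = 5L, seed = 1L) {
  processed <- lapply(images, function(im)
    resize_image(suppressWarnings(crop_background(im, margin)), dims))
  augmented <- if (n_per_image > 0L)
    lapply(augment_dataset(processed, n_per_image, seed),
           resize_image, dims = dims)
  else list()
  list(processed = processed, augmented = augmented)
}
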