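#' Segment tissue from a stained-section image
#'
#' Coarse colour-based tissue segmentation: the image is converted from RGB to
#' HSV, the saturation channel is median-blurred, thresholded (Otsu's method
#' on the blurred channel by default, or a fixed value), and the binary mask
#' is refined with a morphological closing to fill small gaps and holes.
#' Stained tissue is saturated while the glass background is near-white
#' (near-zero saturation), so the saturation channel separates the two.
#'
#' @param image RGB raster, numeric h x w x 3 array in \[0, 1\].
#' @param blur_kernel_px median-blur kernel width in pixels (odd; <= 1 skips
#'   the blur).
#' @param sat_threshold fixed saturation threshold in \[0, 1\], or `NULL` for
#'   Otsu's method.
#' @param closing_kernel_px disc diameter of the closing element (<= 1 skips).
#' @param seg_downsample integer factor; segmentation runs on an
#'   area-averaged downsample of the image (1 = native resolution).
#' @return an object of class `tissue_mask`: list with `mask` (logical
#'   matrix) and `downsample` (integer factor relative to the input image).
#' @export
segment_tissue <- function(image, blur_kernel_px = 7L, sat_threshold = NULL,
                           closing_kernel_px = 9L, seg_downsample = 1L) {
  assert_rgb(image)
  if (seg_downsample > 1L) image <- block_mean_rgb(image, seg_downsample)
  h <- nrow(image); w <- ncol(image)
  rgb <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  sat <- matrix(grDevices::rgb2hsv(rgb, maxColorValue = 1)[2, ], h, w)
  if (blur_kernel_px > 1L) {
    sat <- EBImage::medianFilter(sat, size = max(1L, blur_kernel_px %/% 2L))
  }
  thr <- sat_threshold
  if (is.null(thr)) {
    # Otsu needs two populations; an all-equal channel yields an empty mask
    thr <- if (stats::sd(sat) < 1e-8) Inf else
      EBImage::otsu(EBImage::Image(sat), range = c(0, 1))
  }
  mask <- sat > thr
  if (closing_kernel_px > 1L && any(mask)) {
    brush_size <- closing_kernel_px + (1L - closing_kernel_px %% 2L)  # odd
    mask <- EBImage::closing(EBImage::Image(mask * 1),
                             EBImage::makeBrush(brush_size, "disc")) > 0.5
    mask <- matrix(as.logical(mask), h, w)
  }
  structure(list(mask = mask, downsample = as.integer(seg_downsample)),
            class = "tissue_mask")
}

#' Extract fixed-size, non-overlapping tissue patches
#'
#' Tiles the image with a regular grid of `size_px` squares anchored at the
#' origin and keeps a tile when its tissue-mask coverage is at least
#' `min_tissue_frac`. Partial tiles at the right and bottom edges are
#' discarded. Boxes use 0-based, half-open pixel coordinates.
#'
#' @param image RGB raster (h x w x 3) or `NULL` to return refs only.
#' @param mask a [segment_tissue()] result, or a logical matrix at native
#'   resolution.
#' @param size_px patch side length in pixels.
#' @param min_tissue_frac minimum fraction of tissue pixels per kept tile.
#' @param slide_id identifier recorded on every patch.
#' @param magnification_tag magnification string recorded on every patch.
#' @return a list with `refs` (tibble: slide_id, x, y, size_px,
#'   magnification_tag) and `pixels` (list of size_px x size_px x 3 arrays,
#'   or `NULL` when `image` is `NULL`).
#' @export
extract_patches <- function(image, mask, size_px = 256L, min_tissue_frac = 0.5,
                            slide_id = "slide", magnification_tag = "20X") {
  stopifnot(size_px >= 1)
  if (inherits(mask, "tissue_mask")) {
    ds <- mask$downsample
    m <- mask$mask
  } else {
    ds <- 1L
    m <- mask
  }
  h <- if (is.null(image)) nrow(m) * ds else nrow(image)
  w <- if (is.null(image)) ncol(m) * ds else ncol(image)
  nx <- w %/% size_px
  ny <- h %/% size_px
  refs <- tibble::tibble(slide_id = character(), x = integer(), y = integer(),
                         size_px = integer(), magnification_tag = character())
  pixels <- list()
  if (nx >= 1 && ny >= 1) {
    for (iy in seq_len(ny) - 1L) {
      for (ix in seq_len(nx) - 1L) {
        # tile box in mask coordinates (downsample-aware)
        mx0 <- (ix * size_px) %/% ds + 1L
        my0 <- (iy * size_px) %/% ds + 1L
        mx1 <- min(ncol(m), ((ix + 1L) * size_px - 1L) %/% ds + 1L)
        my1 <- min(nrow(m), ((iy + 1L) * size_px - 1L) %/% ds + 1L)
        cov <- mean(m[my0:my1, mx0:mx1])
        if (cov >= min_tissue_frac) {
          refs <- dplyr::bind_rows(refs, tibble::tibble(
            slide_id = slide_id, x = as.integer(ix * size_px),
            y = as.integer(iy * size_px),
            size_px = as.integer(size_px),
            magnification_tag = magnification_tag))
          if (!is.null(image)) {
            pixels[[length(pixels) + 1L]] <-
              image[(iy * size_px + 1L):((iy + 1L) * size_px),
                    (ix * size_px + 1L):((ix + 1L) * size_px), , drop = FALSE]
          }
        }
      }
    }
  }
  list(refs = refs, pixels = if (is.null(image)) NULL else pixels)
}

mag_factor <- c("80X" = 80, "40X" = 40, "20X" = 20, "10X" = 10)

#' Convert an image between magnifications
#'
#' Downsamples by the magnification ratio with area averaging (block means);
#' a 40X image becomes a 20X image at half the pixel size. Upsampling is an
#' error: information cannot be created.
#'
#' @param image RGB raster.
#' @param source_tag,target_tag magnification tags among
#'   "80X", "40X", "20X", "10X".
#' @return the converted raster; identity when the tags match.
#' @export
normalize_magnification <- function(image, source_tag, target_tag = "20X") {
  assert_rgb(image)
  if (!source_tag %in% names(mag_factor) || !target_tag %in% names(mag_factor)) {
    stop("magnification tags must be one of ", paste(names(mag_factor), collapse = ", "))
  }
  ratio <- mag_factor[[source_tag]] / mag_factor[[target_tag]]
  if (ratio == 1) return(image)
  if (ratio < 1) stop("upsampling from ", source_tag, " to ", target_tag,
                      " is not supported")
  if (ratio != round(ratio)) stop("non-integer magnification ratio")
  block_mean_rgb(image, as.integer(ratio))
}

#' Patch size for spatial-transcriptomics spots
#'
#' The spot patch side, in pixels, is the power of two covering 64 microns at
#' the stated resolution: `2 ^ ceiling(log2(64 / mpp))`.
#'
#' @param mpp microns per pixel; must be positive.
#' @return integer patch side in pixels.
#' @examples
#' st_patch_size(1.0)  # 64
#' st_patch_size(0.25) # 256
#' @export
st_patch_size <- function(mpp) {
  if (!is.numeric(mpp) || any(mpp <= 0)) stop("mpp must be > 0")
  as.integer(2^ceiling(log2(64 / mpp)))
}

#' Extract patches centred on spatial-transcriptomics spots
#'
#' Each spot gets the [st_patch_size()] square centred on it; squares that
#' would exit the image are clamped to the boundary (never dropped), which
#' preserves the one-to-one spot-to-patch mapping the association statistics
#' rely on.
#'
#' @param image RGB raster or `NULL` for refs only.
#' @param spots tibble/data.frame with columns `x_px`, `y_px` (1-based spot
#'   centres in image pixels).
#' @param mpp microns per pixel.
#' @param slide_id,magnification_tag recorded on every ref.
#' @return as [extract_patches()]; refs are in spot order.
#' @export
extract_spot_patches <- function(image, spots, mpp, slide_id = "slide",
                                 magnification_tag = "20X") {
  size <- st_patch_size(mpp)
  if (nrow(spots) == 0L) {
    return(list(refs = tibble::tibble(
      slide_id = character(), x = integer(), y = integer(),
      size_px = integer(), magnification_tag = character()), pixels = NULL))
  }
  h <- if (is.null(image)) Inf else nrow(image)
  w <- if (is.null(image)) Inf else ncol(image)
  x0 <- pmax(0L, round(spots$x_px) - size %/% 2L)
  y0 <- pmax(0L, round(spots$y_px) - size %/% 2L)
  if (is.finite(w)) x0 <- pmin(x0, max(0L, w - size))
  if (is.finite(h)) y0 <- pmin(y0, max(0L, h - size))
  refs <- tibble::tibble(slide_id = slide_id, x = as.integer(x0),
                         y = as.integer(y0), size_px = as.integer(size),
                         magnification_tag = magnification_tag)
  pixels <- NULL
  if (!is.null(image)) {
    pixels <- lapply(seq_len(nrow(refs)), function(i) {
      image[(refs$y[i] + 1L):(refs$y[i] + size),
            (refs$x[i] + 1L):(refs$x[i] + size), , drop = FALSE]
    })
  }
  list(refs = refs, pixels = pixels)
}

#' Halve the resolution of a query image
#'
#' Area-averaged two-fold downsample, used to realign a query whose
#' resolution is finer than the database's reference magnification.
#'
#' @param image RGB raster of size at least 2 x 2.
#' @return the downsampled raster.
#' @export
halve_resolution <- function(image) {
  assert_rgb(image)
  if (nrow(image) < 2 || ncol(image) < 2) stop("image must be at least 2 x 2")
  block_mean_rgb(image, 2L)
}
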