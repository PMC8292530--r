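#' Tile image
#'
#' An 8-bit RGB image tile with physical scale metadata. Tiles are the unit
#' consumed by the stain operations, the feature extractor and the tile
#' scorer. The default edge of 299 px at 302/299 um/px reproduces the usual
#' deep-learning tiling geometry (a 302 x 302 um field at ~x10 optical
#' magnification).
#'
#' @param pixels H x W x 3 array of intensities in `[0, 255]`
#' @param microns_per_pixel physical scale, um per pixel (> 0)
#' @param origin `(x, y)` 0-based pixel offset of the tile in its source image
#' @param slide_id id of the slide the tile came from
#' @return an object of class `tile_image`
#' @export
tile_image <- function(pixels, microns_per_pixel = 302 / 299,
                       origin = c(0L, 0L), slide_id = NA_character_) {
  pixels <- check_pixels(pixels)
  if (dim(pixels)[1] != dim(pixels)[2])
    stop("tile must be square; got ", dim(pixels)[1], " x ", dim(pixels)[2])
  if (!is.numeric(microns_per_pixel) || microns_per_pixel <= 0)
    stop("microns_per_pixel must be positive")
  structure(list(pixels = pixels, microns_per_pixel = microns_per_pixel,
                 origin = as.integer(origin), slide_id = slide_id),
            class = "tile_image")
}

#' Region image
#'
#' A larger RGB image (e.g. a downsampled slide or an annotated tumor region)
#' with an optional region-of-interest mask standing in for a pathologist's
#' tumor annotation.
#'
#' @param pixels H x W x 3 array of intensities in `[0, 255]`
#' @param microns_per_pixel physical scale, um per pixel (> 0)
#' @param roi_mask optional H x W logical matrix; `TRUE` marks pixels inside
#'   the region of interest
#' @return an object of class `region_image`
#' @export
region_image <- function(pixels, microns_per_pixel, roi_mask = NULL) {
  pixels <- check_pixels(pixels)
  if (!is.numeric(microns_per_pixel) || microns_per_pixel <= 0)
    stop("microns_per_pixel must be positive")
  if (!is.null(roi_mask)) {
    roi_mask <- as.matrix(roi_mask)
    if (!identical(dim(roi_mask), dim(pixels)[1:2]))
      stop("roi_mask dimensions must match pixels")
    storage.mode(roi_mask) <- "logical"
  }
  structure(list(pixels = pixels, microns_per_pixel = microns_per_pixel,
                 roi_mask = roi_mask),
            class = "region_image")
}

check_pixels <- function(pixels) {
  if (length(dim(pixels)) == 2)                       # promote grayscale
    pixels <- array(rep(pixels, 3), dim = c(dim(pixels), 3))
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    stop("pixels must be an H x W x 3 array")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("intensities must lie in [0, 255]")
  pixels
}

#' @export
print.tile_image <- function(x, ...) {
  cat(sprintf("<tile_image %dx%d px, %.4f um/px, slide %s, origin (%d,%d)>\n",
              dim(x$pixels)[1], dim(x$pixels)[2], x$microns_per_pixel,
              x$slide_id, x$origin[1], x$origin[2]))
  invisible(x)
}

#' @export
print.region_image <- function(x, ...) {
  cat(sprintf("<region_image %dx%d px, %.4f um/px, mask: %s>\n",
              dim(x$pixels)[1], dim(x$pixels)[2], x$microns_per_pixel,
              if (is.null(x$roi_mask)) "none"
              else sprintf("%d px", sum(x$roi_mask))))
  invisible(x)
}

# ---- image file I/O (PNG / TIFF, 8-bit RGB) --------------------------------

#' Read and write 8-bit RGB images
#'
#' Thin wrappers over the png/tiff packages keeping the package's integer
#' `[0, 255]` pixel convention.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`
#' @return `read_image_array()` returns an H x W x 3 array in `[0, 255]`.
#' @export
read_image_array <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext))
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]   # drop alpha
  round(img * 255)
}

#' @rdname read_image_array
#' @param pixels H x W x 3 array in `[0, 255]`
#' @export
write_image_array <- function(pixels, path) {
  pixels <- check_pixels(pixels)
  ext <- tolower(tools::file_ext(path))
  img <- pixels / 255
  switch(ext,
    png  = png::writePNG(img, path),
    tif  = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext))
  invisible(path)
}

# ---- separable resamplers --------------------------------------------------

# 1-D area-average (box integration) weight matrix mapping n_in samples to
# n_out; each output sample is the exact mean of the input interval it covers.
area_weights <- function(n_in, n_out) {
  f <- n_in / n_out
  w <- matrix(0, n_out, n_in)
  for (o in seq_len(n_out)) {
    lo <- (o - 1) * f
    hi <- o * f
    i0 <- floor(lo + 1e-12) + 1
    i1 <- min(ceiling(hi - 1e-12), n_in)
    for (i in i0:i1) {
      ov <- min(hi, i) - max(lo, i - 1)
      if (ov > 0) w[o, i] <- ov / f
    }
  }
  w
}

# 1-D bilinear weight matrix (pixel-center alignment, edge clamped).
bilinear_weights <- function(n_in, n_out) {
  w <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (o in seq_len(n_out)) {
    x <- (o - 0.5) * scale - 0.5          # 0-based input coordinate
    i0 <- floor(x)
    t <- x - i0
    a <- min(max(i0, 0), n_in - 1) + 1
    b <- min(max(i0 + 1, 0), n_in - 1) + 1
    w[o, a] <- w[o, a] + (1 - t)
    w[o, b] <- w[o, b] + t
  }
  w
}

resample_channels <- function(pixels, wr, wc) {
  out <- array(0, dim = c(nrow(wr), nrow(wc), 3))
  for (ch in 1:3) out[, , ch] <- wr %*% pixels[, , ch] %*% t(wc)
  out
}

#' Downsample a region for slide-level statistics
#'
#' Area-average resampling to 5 um per pixel, the scale at which slide-level
#' first- and second-order statistics are computed (about x2 magnification).
#' Sources already at 5 um/px or coarser are returned unchanged with a
#' warning.
#'
#' @param region a [region_image()]
#' @param target_um_per_px target scale; default 5
#' @return a [region_image()] at the target scale
#' @export
downsample_for_slide_stats <- function(region, target_um_per_px = 5) {
  stopifnot(inherits(region, "region_image"))
  if (region$microns_per_pixel >= target_um_per_px) {
    warning("region is already at ", region$microns_per_pixel,
            " um/px (>= ", target_um_per_px, "); returning unchanged")
    return(region)
  }
  d <- dim(region$pixels)
  n_r <- max(1L, floor(d[1] * region$microns_per_pixel / target_um_per_px + 1e-9))
  n_c <- max(1L, floor(d[2] * region$microns_per_pixel / target_um_per_px + 1e-9))
  wr <- area_weights(d[1], n_r)
  wc <- area_weights(d[2], n_c)
  pix <- clip255(round(resample_channels(region$pixels, wr, wc)))
  mask <- NULL
  if (!is.null(region$roi_mask))
    mask <- (wr %*% (region$roi_mask * 1) %*% t(wc)) >= 0.5
  region_image(pix, target_um_per_px, mask)
}

#' Tessellate a region into non-overlapping tiles
#'
#' Resamples the region (bilinear) so that one output pixel covers
#' `tile_edge_um / tile_edge_px` microns, then cuts an axis-aligned,
#' non-overlapping grid of square tiles. A tile is emitted only if at least
#' `min_mask_fraction` of its area lies inside the ROI mask (when present)
#' and it passes the near-white background filter.
#'
#' @param region a [region_image()]
#' @param tile_edge_px tile edge in pixels (default 299)
#' @param tile_edge_um physical tile edge in microns (default 302)
#' @param min_mask_fraction minimum in-mask area fraction (default 1: the
#'   tile must lie fully inside the annotation)
#' @param background_threshold reject tiles whose mean gray intensity
#'   exceeds this near-white threshold (default 230)
#' @return a list of [tile_image()]; empty when the region is smaller than
#'   one tile
#' @export
tessellate <- function(region, tile_edge_px = 299L, tile_edge_um = 302,
                       min_mask_fraction = 1.0, background_threshold = 230) {
  stopifnot(inherits(region, "region_image"))
  if (tile_edge_px < 1 || tile_edge_um <= 0)
    stop("tile edge must be positive")
  target_mpp <- tile_edge_um / tile_edge_px
  scale <- region$microns_per_pixel / target_mpp
  if (scale <= 0) stop("non-positive rescale factor")
  d <- dim(region$pixels)
  n_r <- round(d[1] * scale)
  n_c <- round(d[2] * scale)
  if (n_r < tile_edge_px || n_c < tile_edge_px) return(list())
  if (abs(scale - 1) < 1e-12) {
    pix <- region$pixels
    mask <- region$roi_mask
    n_r <- d[1]; n_c <- d[2]
  } else {
    wr <- bilinear_weights(d[1], n_r)
    wc <- bilinear_weights(d[2], n_c)
    pix <- clip255(round(resample_channels(region$pixels, wr, wc)))
    mask <- if (is.null(region$roi_mask)) NULL
            else (wr %*% (region$roi_mask * 1) %*% t(wc)) >= 0.5
  }
  tiles <- list()
  for (tr in seq_len(n_r %/% tile_edge_px)) {
    for (tc in seq_len(n_c %/% tile_edge_px)) {
      rows <- ((tr - 1) * tile_edge_px + 1):(tr * tile_edge_px)
      cols <- ((tc - 1) * tile_edge_px + 1):(tc * tile_edge_px)
      if (!is.null(mask)) {
        frac <- mean(mask[rows, cols])
        if (frac < min_mask_fraction - 1e-9) next
      }
      block <- pix[rows, cols, , drop = FALSE]
      if (mean(luminance(block)) > background_threshold) next
      tiles[[length(tiles) + 1L]] <- tile_image(
        block, microns_per_pixel = target_mpp,
        origin = c(cols[1] - 1L, rows[1] - 1L))
    }
  }
  tiles
}
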