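# First-order channel statistics and second-order Haralick GLCM features:
# together the 20-value quantitative site signature of a tile or slide.

#' First-order intensity statistics
#'
#' Mean, standard deviation, skewness, kurtosis and entropy of an intensity
#' sample. Central moments use population (1/N) normalization, so
#' skewness = m3 / m2^(3/2) and kurtosis = m4 / m2^2 (not excess kurtosis).
#' Entropy is the Shannon entropy (natural log, nats) of the normalized
#' 256-bin intensity histogram with the convention 0 * log 0 = 0; it is
#' therefore bounded by log(256). On a constant sample skewness and kurtosis
#' are undefined and reported as `NA` rather than raising an error.
#'
#' @param x numeric vector of intensities in `[0, 255]` (length >= 2)
#' @return named numeric vector `mean`, `std`, `skewness`, `kurtosis`,
#'   `entropy`
#' @export
first_order <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) stop("need at least 2 pixels")
  if (anyNA(x) || min(x) < 0 || max(x) > 255)
    stop("intensities must lie in [0, 255]")
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2)
  m3 <- mean(d^3)
  m4 <- mean(d^4)
  skew <- if (m2 > 0) m3 / m2^1.5 else NA_real_
  kurt <- if (m2 > 0) m4 / m2^2 else NA_real_
  counts <- tabulate(round(x) + 1L, nbins = 256L)
  p <- counts[counts > 0] / n
  ent <- -sum(p * log(p))
  c(mean = mu, std = sqrt(m2), skewness = skew, kurtosis = kurt, entropy = ent)
}

glcm_offset <- function(angle, distance) {
  # (d_row, d_col) of the neighbor relative to the reference pixel
  switch(as.character(angle),
    "0"   = c(0L, distance),
    "45"  = c(-distance, distance),
    "90"  = c(-distance, 0L),
    "135" = c(-distance, -distance),
    stop("angle must be one of 0, 45, 90, 135"))
}

#' Gray level co-occurrence matrix
#'
#' Counts ordered (reference, neighbor) gray-level pairs at the given pixel
#' offset over 256 gray levels and normalizes them to probabilities. The
#' matrix is non-symmetric (pairs are ordered), matching the default of the
#' common image-analysis libraries. Marginal means and variances of the
#' reference (i) and neighbor (j) levels are attached.
#'
#' @param gray integer matrix of gray levels in `[0, 255]` (>= 2 x 2)
#' @param distance pixel offset distance (>= 1)
#' @param angle one of 0, 45, 90, 135 degrees
#' @param mask optional logical matrix; pairs are counted only when both
#'   pixels lie inside the mask
#' @return an object of class `glcm`: list with `P` (256 x 256 probability
#'   matrix), `distance`, `angle`, and marginals `mu_i`, `mu_j`,
#'   `var_i`, `var_j`
#' @export
glcm <- function(gray, distance = 1L, angle = 0, mask = NULL) {
  gray <- as.matrix(gray)
  if (length(gray) < 2) stop("grid must contain at least 2 pixels")
  if (min(gray) < 0 || max(gray) > 255) stop("gray levels must lie in [0, 255]")
  if (distance < 1) stop("distance must be >= 1")
  off <- glcm_offset(angle, as.integer(distance))
  nr <- nrow(gray); nc <- ncol(gray)
  if (max(1L, 1L - off[1]) > min(nr, nr - off[1]) ||
      max(1L, 1L - off[2]) > min(nc, nc - off[2]))
    stop("no valid pixel pairs: ", nr, " x ", nc,
         " grid cannot host offset (", off[1], ",", off[2], ")")
  r0 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  c0 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  i <- gray[r0, c0, drop = FALSE]
  j <- gray[r0 + off[1], c0 + off[2], drop = FALSE]
  keep <- TRUE
  if (!is.null(mask)) {
    keep <- mask[r0, c0, drop = FALSE] & mask[r0 + off[1], c0 + off[2], drop = FALSE]
    if (!any(keep)) stop("no valid pixel pairs inside mask")
  }
  idx <- round(i[keep]) * 256L + round(j[keep]) + 1L
  counts <- tabulate(idx, nbins = 256L * 256L)
  P <- matrix(counts / sum(counts), 256L, 256L, byrow = TRUE)  # P[i+1, j+1]
  g <- 0:255
  pi_ <- rowSums(P); pj_ <- colSums(P)
  mu_i <- sum(g * pi_); mu_j <- sum(g * pj_)
  structure(list(P = P, distance = as.integer(distance), angle = angle,
                 mu_i = mu_i, mu_j = mu_j,
                 var_i = sum((g - mu_i)^2 * pi_),
                 var_j = sum((g - mu_j)^2 * pj_)),
            class = "glcm")
}

.gdiff <- outer(0:255, 0:255, "-")
.gdiff2 <- .gdiff^2
.gabs <- abs(.gdiff)
.ghom <- 1 / (1 + .gdiff2)

#' Haralick texture features from a GLCM
#'
#' Contrast, dissimilarity, homogeneity (inverse difference moment), angular
#' second moment (ASM) and correlation, each a sum over all 256 x 256 cells
#' of the co-occurrence matrix. When the image is constant both marginal
#' variances vanish and correlation is defined to be 1.
#'
#' @param g a [glcm()]
#' @return named numeric vector `contrast`, `dissimilarity`, `homogeneity`,
#'   `asm`, `correlation`
#' @export
haralick <- function(g) {
  stopifnot(inherits(g, "glcm"))
  P <- g$P
  corr <- if (g$var_i * g$var_j <= 0) 1
  else sum(P * outer(0:255 - g$mu_i, 0:255 - g$mu_j)) / sqrt(g$var_i * g$var_j)
  c(contrast      = sum(P * .gdiff2),
    dissimilarity = sum(P * .gabs),
    homogeneity   = sum(P * .ghom),
    asm           = sum(P^2),
    correlation   = corr)
}

# Haralick features at distance 1 averaged over the four angles, the
# reporting convention for second-order features.
haralick_angle_averaged <- function(gray, distance = 1L, mask = NULL) {
  feats <- vapply(c(0, 45, 90, 135),
                  function(a) haralick(glcm(gray, distance, a, mask)),
                  numeric(5))
  rowMeans(feats)
}

#' 20-value signature of a tile
#'
#' Five first-order statistics per RGB channel (15 values) plus the four-
#' angle-averaged Haralick features of the ITU-R 601 luminance at distance 1
#' (5 values). This is the feature vector used by the site-heterogeneity
#' report and by the baseline tile scorer.
#'
#' @param tile a [tile_image()] or H x W x 3 pixel array
#' @return named numeric vector of length 20
#' @export
tile_signature <- function(tile) {
  pix <- if (inherits(tile, "tile_image")) tile$pixels else check_pixels(tile)
  fo <- lapply(1:3, function(ch) first_order(as.vector(pix[, , ch])))
  names(fo) <- c("R", "G", "B")
  fo <- unlist(lapply(names(fo), function(ch)
    setNames(fo[[ch]], paste0(ch, "_", names(fo[[ch]])))))
  har <- haralick_angle_averaged(luminance(pix))
  c(fo, setNames(har, paste0("haralick_", names(har))))
}

#' Slide-level image signature
#'
#' Downsamples the region to 5 um per pixel (area averaging), restricts to
#' the ROI mask when present, and computes the 20-value signature: first-
#' order statistics per RGB channel on in-mask pixels and angle-averaged
#' Haralick features on the luminance (pairs fully inside the mask).
#'
#' @param region a [region_image()] carrying um/px metadata
#' @return named numeric vector of length 20
#' @export
slide_signature <- function(region) {
  stopifnot(inherits(region, "region_image"))
  if (region$microns_per_pixel < 5)
    region <- downsample_for_slide_stats(region)
  mask <- region$roi_mask
  if (!is.null(mask) && !any(mask)) stop("ROI mask is empty")
  pix <- region$pixels
  sel <- if (is.null(mask)) rep(TRUE, prod(dim(pix)[1:2])) else as.vector(mask)
  fo <- lapply(1:3, function(ch) first_order(as.vector(pix[, , ch])[sel]))
  names(fo) <- c("R", "G", "B")
  fo <- unlist(lapply(names(fo), function(ch)
    setNames(fo[[ch]], paste0(ch, "_", names(fo[[ch]])))))
  har <- haralick_angle_averaged(luminance(pix), mask = mask)
  c(fo, setNames(har, paste0("haralick_", names(har))))
}
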