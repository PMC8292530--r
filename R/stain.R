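# Stain normalization (Reinhard, Macenko, grayscale variants), HSV
# augmentation, tile standardization, and the artificial stain artifact.

as_tile_pixels <- function(tile) {
  if (inherits(tile, "tile_image")) tile$pixels else check_pixels(tile)
}

rewrap_tile <- function(tile, pixels) {
  if (inherits(tile, "tile_image")) { tile$pixels <- pixels; tile } else pixels
}

#' Reinhard color normalization reference
#'
#' Channel means and standard deviations in the decorrelated log
#' (l-alpha-beta) color space, estimated from a reference tile.
#'
#' @param tile a [tile_image()] or pixel array to derive the reference from
#' @return object of class `reinhard_reference` with fields `mean` and `sd`
#'   (length-3 each)
#' @export
reinhard_reference <- function(tile) {
  lab <- rgb_to_lab_mat(as_tile_pixels(tile))
  sds <- apply(lab, 1, function(v) sqrt(mean((v - mean(v))^2)))
  structure(list(mean = rowMeans(lab), sd = sds), class = "reinhard_reference")
}

#' Reinhard stain normalization
#'
#' Maps the tile to l-alpha-beta space, affinely rescales each channel to
#' the reference mean and standard deviation, and maps back, clipping to
#' `[0, 255]`. A zero-variance source channel is set flat at the reference
#' mean.
#'
#' @param tile a [tile_image()] or pixel array
#' @param ref a [reinhard_reference()]
#' @return normalized tile of the same type as the input
#' @export
reinhard <- function(tile, ref) {
  stopifnot(inherits(ref, "reinhard_reference"))
  if (any(ref$sd <= 0)) stop("reference standard deviations must be positive")
  pix <- as_tile_pixels(tile)
  lab <- rgb_to_lab_mat(pix)
  for (ch in 1:3) {
    v <- lab[ch, ]
    s <- sqrt(mean((v - mean(v))^2))
    lab[ch, ] <- if (s > 1e-12)
      (v - mean(v)) / s * ref$sd[ch] + ref$mean[ch]
    else rep(ref$mean[ch], length(v))
  }
  rewrap_tile(tile, lab_to_rgb_pix(lab, dim(pix)))
}

#' Macenko stain normalization reference
#'
#' Estimates the hematoxylin/eosin stain matrix (unit optical-density
#' vectors) and the 99th-percentile stain concentrations from a reference
#' tile using the Macenko plane-fitting procedure.
#'
#' @param tile a [tile_image()] or pixel array
#' @param beta optical-density threshold below which pixels count as
#'   background (default 0.15)
#' @param alpha robust percentile for the extreme stain angles (default 1,
#'   i.e. the 1st/99th percentiles)
#' @return object of class `macenko_reference` with `stain_matrix` (3 x 2,
#'   unit columns: hematoxylin, eosin) and `max_concentrations` (length 2)
#' @export
macenko_reference <- function(tile, beta = 0.15, alpha = 1) {
  fit <- macenko_fit(as_tile_pixels(tile), beta, alpha)
  structure(list(stain_matrix = fit$stain_matrix,
                 max_concentrations = fit$max_concentrations),
            class = "macenko_reference")
}

# Optical density of 8-bit intensities: background (255) maps to ~0.
optical_density <- function(pixels) -log((pixels + 1) / 256)

macenko_fit <- function(pix, beta = 0.15, alpha = 1) {
  od <- optical_density(pix_to_mat(pix))            # 3 x n
  keep <- apply(od, 2, max) >= beta                 # drop near-white pixels
  if (sum(keep) < 10)
    stop("fewer than 10 estimable pixels above OD ", beta,
         ": tile looks like background")
  odk <- od[, keep, drop = FALSE]
  ctr <- rowMeans(odk)
  ev <- eigen(cov(t(odk)), symmetric = TRUE)$vectors[, 1:2, drop = FALSE]
  # orient the plane so projections are mostly positive
  for (k in 1:2) if (sum(crossprod(ev[, k], odk - ctr)) < 0) ev[, k] <- -ev[, k]
  proj <- crossprod(ev, odk)                        # 2 x n in-plane coords
  phi <- atan2(proj[2, ], proj[1, ])
  qs <- quantile(phi, c(alpha / 100, 1 - alpha / 100), names = FALSE)
  v1 <- ev %*% c(cos(qs[1]), sin(qs[1]))
  v2 <- ev %*% c(cos(qs[2]), sin(qs[2]))
  if (any(v1 < 0)) v1 <- abs(v1)
  if (any(v2 < 0)) v2 <- abs(v2)
  v1 <- v1 / sqrt(sum(v1^2)); v2 <- v2 / sqrt(sum(v2^2))
  # hematoxylin absorbs more in red/blue than eosin: order by first component
  he <- if (v1[1] >= v2[1]) cbind(v1, v2) else cbind(v2, v1)
  dimnames(he) <- list(c("R", "G", "B"), c("H", "E"))
  conc <- solve(crossprod(he), crossprod(he, od))   # least-squares, 2 x n
  maxc <- apply(conc, 1, quantile, probs = 0.99, names = FALSE)
  maxc <- pmax(maxc, 1e-8)
  list(stain_matrix = he, max_concentrations = maxc, concentrations = conc)
}

#' Macenko stain normalization
#'
#' Deconvolves the tile into hematoxylin/eosin concentrations in optical
#' density space, rescales the concentration distributions to the reference
#' maxima, and reconstructs the image with the reference stain vectors.
#'
#' @param tile a [tile_image()] or pixel array containing tissue (an error
#'   is raised when fewer than 10 pixels exceed the OD threshold)
#' @param ref a [macenko_reference()]
#' @param beta,alpha estimation parameters, see [macenko_reference()]
#' @return normalized tile of the same type as the input
#' @export
macenko <- function(tile, ref, beta = 0.15, alpha = 1) {
  stopifnot(inherits(ref, "macenko_reference"))
  pix <- as_tile_pixels(tile)
  fit <- macenko_fit(pix, beta, alpha)
  conc <- fit$concentrations * (ref$max_concentrations / fit$max_concentrations)
  od_new <- ref$stain_matrix %*% conc
  out <- exp(-od_new) * 256 - 1
  rewrap_tile(tile, clip255(round(mat_to_pix(out, dim(pix)))))
}

#' Grayscale conversion and equalized grayscale
#'
#' `grayscale()` replaces all three channels by the ITU-R 601 luminance
#' (direct conversion, idempotent). `grayscale_equalized()` first applies
#' 256-bin histogram equalization to the luminance, flattening the intensity
#' distribution.
#'
#' @param tile a [tile_image()] or pixel array
#' @return tile of the same type with identical R, G and B channels
#' @export
grayscale <- function(tile) {
  pix <- as_tile_pixels(tile)
  g <- luminance(pix)
  rewrap_tile(tile, array(rep(g, 3), dim = dim(pix)))
}

#' @rdname grayscale
#' @export
grayscale_equalized <- function(tile) {
  pix <- as_tile_pixels(tile)
  g <- luminance(pix)
  counts <- tabulate(g + 1L, nbins = 256L)
  cdf <- cumsum(counts) / length(g)
  eq <- round(cdf[g + 1L] * 255)
  rewrap_tile(tile, array(rep(matrix(eq, nrow(g)), 3), dim = dim(pix)))
}

#' HSV color augmentation
#'
#' Random multiplicative jitter of the HSV channels, the standard color
#' augmentation for histology tiles. Light augmentation multiplies each of
#' hue, saturation and value by an independent scalar drawn uniformly from
#' `[0.9, 1.1]`; heavy augmentation multiplies hue and saturation by
#' independent scalars from `[0.7, 1.3]` and leaves value untouched. Hue
#' wraps modulo 1; saturation and value clip to `[0, 1]`.
#'
#' @param tile a [tile_image()] or pixel array
#' @param level `"light"` or `"heavy"`
#' @param seed integer seed making the draw reproducible
#' @return augmented tile of the same type as the input
#' @export
hsv_augment <- function(tile, level = c("light", "heavy"), seed) {
  level <- match.arg(level)
  pix <- as_tile_pixels(tile)
  mult <- with_seed(seed, {
    if (level == "light") runif(3, 0.9, 1.1) else c(runif(2, 0.7, 1.3), 1)
  })
  rewrap_tile(tile, transform_hsv(pix, mult))
}

#' Artificial stain artifact
#'
#' Multiplies hue, saturation and value by `1 + strength`, emulating a
#' site-specific stain shift of up to 5%. Hue wraps modulo 1; saturation
#' and value clip. `strength = 0` is an exact identity.
#'
#' @param tile a [tile_image()] or pixel array
#' @param strength fractional increase in `[0, 0.05]`
#' @param force allow strengths outside the simulated range
#' @return shifted tile of the same type as the input
#' @export
apply_stain_artifact <- function(tile, strength, force = FALSE) {
  if (!force && (strength < 0 || strength > 0.05))
    stop("strength must lie in [0, 0.05] (use force = TRUE to override)")
  rewrap_tile(tile, transform_hsv(as_tile_pixels(tile), rep(1 + strength, 3)))
}

#' Standardize a tile to zero mean and unit variance
#'
#' Jointly over all pixels and channels, as applied to model inputs after
#' normalization/augmentation. Variance uses the population (1/N)
#' convention so the output variance is exactly 1.
#'
#' @param tile a [tile_image()] or pixel array (must not be constant)
#' @return numeric H x W x 3 array with mean 0 and variance 1
#' @export
standardize <- function(tile) {
  pix <- as_tile_pixels(tile)
  mu <- mean(pix)
  s <- sqrt(mean((pix - mu)^2))
  if (s <= 0) stop("cannot standardize a constant tile")
  (pix - mu) / s
}

#' Deterministic synthetic reference tile
#'
#' A reproducible H&E-like two-stain tile (hematoxylin-dark nuclei on an
#' eosin-pink background) generated in code, used to derive the default
#' Reinhard and Macenko references so that normalization runs are
#' reproducible offline. The tile is synthetic, not real histology.
#'
#' @param edge tile edge in pixels
#' @param seed RNG seed
#' @return a [tile_image()]
#' @export
default_reference_tile <- function(edge = 96L, seed = 20210720L) {
  he <- cbind(H = c(0.65, 0.70, 0.29), E = c(0.07, 0.99, 0.11))
  he <- sweep(he, 2, sqrt(colSums(he^2)), "/")
  with_seed(seed, {
    n <- edge * edge
    # eosin-rich background with scattered hematoxylin-rich nuclei
    c_h <- pmax(rnorm(n, 0.15, 0.05), 0)
    c_e <- pmax(rnorm(n, 0.55, 0.10), 0)
    nuc <- matrix(FALSE, edge, edge)
    for (b in seq_len(round(edge^2 / 450))) {
      cx <- runif(1, 4, edge - 3); cy <- runif(1, 4, edge - 3)
      r <- runif(1, 2.5, 4.5)
      xs <- pmax(1, floor(cx - r)):pmin(edge, ceiling(cx + r))
      ys <- pmax(1, floor(cy - r)):pmin(edge, ceiling(cy + r))
      d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
      nuc[ys, xs] <- nuc[ys, xs] | (d2 <= r^2)
    }
    c_h[as.vector(nuc)] <- c_h[as.vector(nuc)] + rnorm(sum(nuc), 0.9, 0.08)
    od <- he %*% rbind(c_h, c_e)
    pix <- clip255(round(mat_to_pix(exp(-od) * 256 - 1, c(edge, edge, 3))))
    tile_image(pix, slide_id = "synthetic-reference")
  })
}
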