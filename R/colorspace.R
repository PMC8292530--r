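# Color-space plumbing shared by the stain operations and the synthetic
# generator. All conversions are vectorized over whole images.

# H x W x 3 numeric array -> 3 x n matrix of channels (R, G, B rows).
pix_to_mat <- function(pixels) {
  rbind(as.vector(pixels[, , 1]), as.vector(pixels[, , 2]), as.vector(pixels[, , 3]))
}

mat_to_pix <- function(m, dim3) {
  array(c(m[1, ], m[2, ], m[3, ]), dim = dim3)
}

# RGB (0..255) -> HSV, all three channels in [0, 1].
rgb_to_hsv_mat <- function(pixels) {
  grDevices::rgb2hsv(pix_to_mat(pixels), maxColorValue = 255)
}

# HSV in [0,1] -> RGB in 0..255 (numeric, not yet rounded).
hsv_to_rgb_mat <- function(h, s, v, dim3) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  array(c(r, g, b), dim = dim3) * 255
}

# Multiplicative HSV transform: hue wraps modulo 1 (hue is circular),
# saturation and value clip to [0, 1]. `mult` is a length-3 multiplier.
# The identity multiplier is an exact no-op (no round trip).
transform_hsv <- function(pixels, mult) {
  stopifnot(length(mult) == 3)
  if (all(mult == 1)) return(pixels)
  hsv <- rgb_to_hsv_mat(pixels)
  h <- (hsv[1, ] * mult[1]) %% 1
  s <- clip01(hsv[2, ] * mult[2])
  v <- clip01(hsv[3, ] * mult[3])
  out <- hsv_to_rgb_mat(h, s, v, dim(pixels))
  clip255(round(out))
}

# ITU-R 601 luma, rounded to the nearest integer gray level.
luminance <- function(pixels) {
  round(0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3])
}

# --- Reinhard's l-alpha-beta space (Ruderman decorrelated log space) -------

.rgb2lms <- matrix(c(0.3811, 0.5783, 0.0402,
                     0.1967, 0.7244, 0.0782,
                     0.0241, 0.1288, 0.8444), 3, 3, byrow = TRUE)
# exact inverse (the published 4-digit inverse is not, and the log/exp round
# trip amplifies the mismatch on dark pixels)
.lms2rgb <- solve(.rgb2lms)
.lms2lab <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2))) %*%
  matrix(c(1, 1, 1, 1, 1, -2, 1, -1, 0), 3, 3, byrow = TRUE)
.lab2lms <- solve(.lms2lab)

# RGB 0..255 -> 3 x n matrix in l-alpha-beta.
rgb_to_lab_mat <- function(pixels) {
  m <- pix_to_mat(pixels) / 255
  lms <- .rgb2lms %*% m
  lms <- pmax(lms, 1e-6)           # guard log of pure black
  .lms2lab %*% log10(lms)
}

lab_to_rgb_pix <- function(lab, dim3) {
  lms <- 10 ^ (.lab2lms %*% lab)
  rgb <- .lms2rgb %*% lms
  clip255(round(mat_to_pix(rgb, dim3) * 255))
}
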