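test_that("first-order statistics hit closed-form values", {
  fo <- first_order(c(rep(0, 10), rep(255, 10)))
  expect_equal(unname(fo), c(127.5, 127.5, 0, 1, log(2)), tolerance = 1e-12)
  expect_equal(unname(first_order(0:255)["entropy"]), log(256), tolerance = 1e-12)
  # constant channel: undefined markers, no error
  fo_const <- first_order(rep(7, 10))
  expect_true(is.na(fo_const["skewness"]) && is.na(fo_const["kurtosis"]))
  expect_equal(unname(fo_const[c("std", "entropy")]), c(0, 0))
})

test_that("first-order statistics match the direct-summation oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- sample(0:255, 64 * 64, replace = TRUE)
    expect_equal(first_order(x), naive_first_order(x), tolerance = 1e-10)
  }
})

test_that("skewness flips sign and kurtosis is invariant under negation", {
  set.seed(2)
  x <- rbinom(500, 255, 0.3)
  a <- first_order(x)
  b <- first_order(255 - x)
  expect_equal(unname(a["skewness"]), -unname(b["skewness"]), tolerance = 1e-12)
  expect_equal(unname(a["kurtosis"]), unname(b["kurtosis"]), tolerance = 1e-12)
})

test_that("GLCM handles the minimal and checkerboard cases exactly", {
  g <- glcm(matrix(c(0, 255), 1, 2), 1, 0)
  expect_equal(g$P[1, 256], 1)                          # single ordered pair
  cb <- matrix(0, 8, 8); cb[(row(cb) + col(cb)) %% 2 == 0] <- 255
  gc <- glcm(cb, 1, 0)
  expect_equal(gc$P[1, 256], 0.5)
  expect_equal(gc$P[256, 1], 0.5)
  h <- haralick(gc)
  expect_equal(unname(h[c("contrast", "dissimilarity", "asm")]),
               c(255^2, 255, 0.5))
  expect_equal(unname(h["homogeneity"]), 1 / (1 + 255^2), tolerance = 1e-15)
  expect_error(glcm(matrix(1, 1, 1), 1, 0), "at least 2")
  expect_error(glcm(matrix(c(1, 2), 2, 1), 1, 0), "offset")
})

test_that("constant images give the degenerate Haralick convention", {
  h <- haralick(glcm(matrix(7, 4, 4), 1, 45))
  expect_equal(unname(h), c(0, 0, 1, 1, 1))
})

test_that("GLCM marginals and normalization are internally consistent", {
  for (seed in 1:5) {
    set.seed(seed)
    gray <- matrix(sample(0:255, 20 * 20, replace = TRUE), 20)
    for (ang in c(0, 45, 90, 135)) {
      g <- glcm(gray, 1, ang)
      expect_equal(sum(g$P), 1, tolerance = 1e-12)
      pi_ <- rowSums(g$P); grid <- 0:255
      expect_equal(g$mu_i, sum(grid * pi_), tolerance = 1e-12)
      expect_equal(g$var_i, sum((grid - g$mu_i)^2 * pi_), tolerance = 1e-12)
    }
  }
})

test_that("Haralick features match the naive double-loop oracle", {
  offs <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0), `135` = c(-1, -1))
  for (seed in 1:6) {
    set.seed(seed)
    gray <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32)
    ang <- c(0, 45, 90, 135)[(seed - 1) %% 4 + 1]
    got <- haralick(glcm(gray, 1, ang))
    want <- naive_glcm_features(gray, offs[[as.character(ang)]][1],
                                offs[[as.character(ang)]][2])
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("angle-averaged Haralick features are invariant to 90-degree rotation", {
  set.seed(9)
  pix <- tissue_tile(32, seed = 9)
  region <- region_image(pix, 5)
  rot <- region_image(array(c(apply(pix[, , 1], 1, rev), apply(pix[, , 2], 1, rev),
                              apply(pix[, , 3], 1, rev)), dim = dim(pix)), 5)
  a <- slide_signature(region)
  b <- slide_signature(rot)
  expect_equal(a[grep("haralick", names(a))], b[grep("haralick", names(b))],
               tolerance = 1e-10)
})

test_that("slide signature downsamples, masks, and matches constant closed forms", {
  region <- region_image(array(rep(c(225, 190, 210), each = 400),
                               dim = c(20, 20, 3)), 5)
  sig <- slide_signature(region)
  expect_equal(unname(sig[c("haralick_contrast", "haralick_asm")]), c(0, 1))
  expect_equal(unname(sig["R_mean"]), 225)
  mask <- matrix(FALSE, 20, 20)
  expect_error(slide_signature(region_image(region$pixels, 5, mask)), "empty")
})
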