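test_that("site-class counts are patient-level with missing patients side-listed", {
  m <- toy_manifest(c(10, 10), pos_per_site = c(5, 5))
  cc <- build_counts(m, "outcome")
  expect_equal(unname(cc$n), rbind(c(5, 5), c(5, 5)), ignore_attr = TRUE)
  # a patient with two slides is counted once; a missing outcome is side-listed
  sl <- m$slides
  sl <- rbind(sl, transform(sl[1, ], slide_id = "dup-slide"))
  sl$outcome[sl$patient_id == sl$patient_id[2]] <- NA
  m2 <- cohort_manifest(sl, m$outcomes)
  cc2 <- build_counts(m2, "outcome")
  expect_equal(sum(cc2$n), 19)
  expect_equal(cc2$missing_patients, sl$patient_id[2])
  sl$outcome <- NA_character_
  expect_error(build_counts(cohort_manifest(sl, m$outcomes), "outcome"),
               "missing for every patient")
})

test_that("quantile binning gives equal bins with deterministic tie-breaks", {
  pt <- data.frame(slide_id = paste0("s", 1:8), patient_id = paste0("p", 1:8),
                   site_id = "A", age = 1:8)
  m <- cohort_manifest(pt, c(age = "continuous"))
  b <- bin_continuous(m, "age", 4)
  expect_equal(unname(table(b$slides$age_bin)), rep(2L, 4), ignore_attr = TRUE)
  pt100 <- data.frame(slide_id = paste0("s", 1:100),
                      patient_id = paste0("p", 1:100),
                      site_id = "A", x = sample(1:100))
  m100 <- cohort_manifest(pt100, c(x = "continuous"))
  b100 <- bin_continuous(m100, "x", 4)
  # bin boundaries at the 25/50/75th percentile positions
  expect_true(all(b100$slides$x_bin[order(b100$slides$x)] ==
                  rep(paste0("Q", 1:4), each = 25)))
  pt$age <- 5
  expect_warning(b1 <- bin_continuous(cohort_manifest(pt, c(age = "continuous")),
                                      "age", 4), "reducing")
  expect_equal(unique(b1$slides$age_bin), "Q1")
})

test_that("stratification error evaluates the quadratic objective exactly", {
  n3 <- matrix(10, 3, 2)
  expect_equal(stratification_error(diag(3), n3, 3), 0)
  n <- rbind(c(20, 0), c(0, 20))
  expect_equal(stratification_error(rbind(c(1, 0), c(0, 1)), n, 2), 400)
  expect_error(stratification_error(rbind(c(1, 1), c(0, 1)), n, 2),
               "exactly one fold")
})

test_that("preserved folds equal the brute-force optimum on random instances", {
  set.seed(42)
  for (i in 1:12) {
    S <- sample(4:8, 1); F <- sample(2:4, 1)
    n <- matrix(rpois(S * F, 8), S, F)
    bf <- brute_force_folds(n, 3)
    pf <- preserved_folds(n, 3, seed = i)
    expect_equal(pf$error, bf$error, tolerance = 1e-9)
    expect_true(pf$optimal)
    expect_true(all(rowSums(pf$m) == 1))                 # assignment constraint
    expect_true(all(colSums(pf$m) >= 1))                 # no empty fold
    expect_equal(pf$error, stratification_error(pf$m, n, 3), tolerance = 1e-9)
  }
})

test_that("perfectly divisible instances reach stratification error zero", {
  expect_equal(preserved_folds(matrix(10, 3, 2), 3)$error, 0)
  n6 <- cbind(rep(30, 6), rep(12, 6))
  expect_equal(preserved_folds(n6, 3)$error, 0)          # two sites per fold
  expect_error(preserved_folds(matrix(5, 2, 2), 3), "at least k")
})

test_that("single-class instances reduce to balanced partition of site sizes", {
  set.seed(11)
  sizes <- rpois(6, 20) + 1
  n <- cbind(sizes)
  pf <- preserved_folds(n, 3, seed = 2)
  # independent oracle: enumerate partitions directly over fold sums
  best <- Inf
  for (a in 1:3) for (b in 1:3) for (c in 1:3) for (d in 1:3) for (e in 1:3) {
    asg <- c(1, a, b, c, d, e)
    if (length(unique(asg)) < 3) next
    sums <- vapply(1:3, function(f) sum(sizes[asg == f]), 1)
    best <- min(best, sum((sums - sum(sizes) / 3)^2))
  }
  expect_equal(pf$error, best, tolerance = 1e-9)
})

test_that("oversized instances are refused by the enumerator with guidance", {
  n <- matrix(1, 16, 2)
  expect_error(brute_force_folds(n, 3), "preserved_folds")
})

test_that("standard stratified folds deal classes round-robin", {
  m <- toy_manifest(c(30, 30), pos_per_site = c(15, 15))
  f <- standard_folds(m, "outcome", 3, seed = 4)
  tab <- table(f$fold, m$slides$outcome[match(f$patient_id, m$slides$patient_id)])
  expect_true(all(tab == 10))
  expect_identical(f, standard_folds(m, "outcome", 3, seed = 4))
  m2 <- toy_manifest(c(64), pos_per_site = c(4))
  f2 <- standard_folds(m2, "outcome", 3, seed = 1)
  lab <- m2$slides$outcome[match(f2$patient_id, m2$slides$patient_id)]
  expect_equal(sort(as.vector(table(f2$fold[lab == "pos"]))), c(1, 1, 2))
})

test_that("site-balanced folds spread every site across folds", {
  m <- toy_manifest(c(9, 9, 9))
  f <- site_balanced_folds(m, 3, seed = 2)
  expect_true(all(table(f$site_id, f$fold) == 3))
  m4 <- toy_manifest(c(4))
  expect_warning(f4 <- site_balanced_folds(m4, 3, seed = 2), NA)
  expect_equal(sort(as.vector(table(f4$fold))), c(1, 1, 2))
})

test_that("preserved fold map sends whole sites (and their missing patients) together", {
  m <- toy_manifest(c(8, 8, 8), pos_per_site = c(4, 4, 4))
  sl <- m$slides
  sl$outcome[1] <- NA
  m <- cohort_manifest(sl, m$outcomes)
  cc <- build_counts(m, "outcome")
  asg <- preserved_folds(cc, 3, seed = 1)
  map <- preserved_fold_map(asg, m)
  expect_equal(nrow(map), 24)
  per_site <- tapply(map$fold, map$site_id, function(x) length(unique(x)))
  expect_true(all(per_site == 1))
})
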