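test_that("rank AUROC matches the concordant-pair oracle, ties at one half", {
  expect_equal(auroc_binary(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE)),
               0.75)
  expect_equal(auroc_binary(c(1, 2, 3, 4), c(F, F, T, T)), 1)
  expect_equal(auroc_binary(rep(0.5, 6), c(T, T, T, F, F, F)), 0.5)
  set.seed(5)
  for (i in 1:10) {
    s <- sample(seq(0, 1, 0.1), 20, replace = TRUE)      # force ties
    y <- sample(c(TRUE, FALSE), 20, replace = TRUE, prob = c(0.4, 0.6))
    if (!any(y) || all(y)) next
    expect_equal(auroc_binary(s, y), naive_auroc(s, y), tolerance = 1e-12)
  }
})

test_that("binary one-vs-rest AUROCs of complementary scores sum to one", {
  set.seed(6)
  sc <- runif(30)
  scores <- cbind(pos = sc, neg = 1 - sc)
  y <- sample(c("pos", "neg"), 30, replace = TRUE)
  r <- ovr_auroc(scores, y)
  expect_equal(unname(r$per_class["pos"] + 1 - r$per_class["neg"]), 1,
               tolerance = 1e-12)
  w <- testthat::capture_warnings(ovr_auroc(scores, rep("pos", 30)))
  expect_true(all(grepl("degenerate", w)) && length(w) >= 1)
})

test_that("cross-validated evaluation aggregates tiles to slides by mean score", {
  preds <- data.frame(
    slide_id = rep(c("a", "b", "c", "d"), each = 2),
    patient_id = rep(c("pa", "pb", "pc", "pd"), each = 2),
    fold = rep(c(1, 1, 2, 2), each = 2),
    label = rep(c("pos", "neg", "pos", "neg"), each = 2),
    score_pos = c(0.2, 0.8, 0.1, 0.3, 0.9, 0.9, 0.2, 0.4),
    score_neg = 1 - c(0.2, 0.8, 0.1, 0.3, 0.9, 0.9, 0.2, 0.4))
  rep_ <- crossval_evaluate(preds)
  # slide a score 0.5 vs b 0.2 in fold 1 -> AUROC 1; fold 2: 0.9 vs 0.3 -> 1
  expect_equal(unname(rep_$fold_auroc), c(1, 1))
  expect_equal(rep_$mean_auroc, 1)
  expect_equal(crossval_evaluate(preds, aggregate = "tile")$mean_auroc,
               mean(c(auroc_binary(c(0.2, 0.8, 0.1, 0.3), c(T, T, F, F)),
                      1)))
})

test_that("bootstrap replicates count reps x folds and collapse for constants", {
  preds <- data.frame(
    slide_id = rep(sprintf("s%d", 1:12), each = 1),
    patient_id = sprintf("p%d", 1:12),
    fold = rep(1:3, each = 4),
    label = rep(c("pos", "pos", "neg", "neg"), 3),
    score_pos = rep(0.5, 12), score_neg = rep(0.5, 12))
  b <- bootstrap_auroc(preds, reps = 10, seed = 1)
  expect_equal(nrow(b), 30)
  expect_true(all(is.na(b$auroc) | b$auroc == 0.5))
})

test_that("fold-level t-tests give the stated dfs and degenerate markers", {
  a <- c(0.9, 0.85, 0.95); b <- c(0.6, 0.55, 0.7)
  paired <- compare_auroc(a, b, "paired_two_sided_df2")
  expect_equal(paired$df, 2)
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(paired$t, unname(tt$statistic), tolerance = 1e-12)
  two <- compare_auroc(a, b, "two_sample_one_sided_df4")
  expect_equal(two$df, 4)
  expect_equal(two$p, unname(t.test(a, b, var.equal = TRUE,
                                    alternative = "greater")$p.value),
               tolerance = 1e-12)
  chance <- compare_auroc(a, mode = "vs_chance_one_sided_df2")
  expect_equal(chance$df, 2)
  expect_equal(compare_auroc(a, a, "paired_two_sided_df2")$note, "exact tie")
  inf <- compare_auroc(c(0.9, 0.9, 0.9), mode = "vs_chance_one_sided_df2")
  expect_equal(inf$t, Inf)
  expect_equal(inf$p, 0)
})

test_that("vs-chance t-test is type-I calibrated on null fold AUROCs", {
  n_sim <- 200
  rej <- 0
  set.seed(77)
  for (s in seq_len(n_sim)) {
    folds <- vapply(1:3, function(f) {
      sc <- runif(30)
      auroc_binary(sc, rep(c(TRUE, FALSE), 15))
    }, 1)
    rej <- rej + (compare_auroc(folds, mode = "vs_chance_one_sided_df2")$p < 0.05)
  }
  band <- qbinom(c(0.005, 0.995), n_sim, 0.05)
  expect_gte(rej, band[1])
  expect_lte(rej, band[2])
})

test_that("tile false-positive chi-squared matches the hand 2x2 Pearson value", {
  mk <- function(fp, tp) {
    n <- fp + tp
    data.frame(slide_id = sprintf("s%d", 1:n), patient_id = sprintf("p%d", 1:n),
               fold = 1, label = rep(c("other", "eur"), c(fp, tp)),
               score_eur = 0.9, score_other = 0.1)
  }
  r <- tile_fp_chi2(mk(30, 70), mk(10, 90), "eur")
  # Pearson 2x2: N (ad - bc)^2 / (r1 r2 c1 c2) on [[30,70],[10,90]]
  expect_equal(r$statistic, 200 * (30 * 90 - 70 * 10)^2 / (100 * 100 * 40 * 160),
               tolerance = 1e-10)
  expect_equal(r$df, 1)
  expect_equal(r$proportions$proportion, c(0.3, 0.1))
  same <- tile_fp_chi2(mk(20, 80), mk(20, 80), "eur")
  expect_equal(same$statistic, 0)
})

test_that("the baseline scorer separates a separable texture signal", {
  set.seed(21)
  n <- 120
  x <- matrix(rnorm(n * 20), n, 20)
  y <- rep(c("a", "b"), each = n / 2)
  x[y == "b", 3] <- x[y == "b", 3] + 3
  tr <- c(1:40, 61:100)
  sc <- baseline_scorer(x[tr, ], y[tr], x[-tr, ], seed = 1)
  expect_equal(colnames(sc), c("a", "b"))
  expect_lt(max(abs(rowSums(sc) - 1)), 1e-6)
  expect_gt(auroc_binary(sc[, "b"], y[-tr] == "b"), 0.95)
  # shuffled labels hover at chance on average, and reruns are deterministic
  set.seed(22)
  null_auc <- vapply(1:5, function(i) {
    ysh <- sample(y[tr])
    auroc_binary(baseline_scorer(x[tr, ], ysh, x[-tr, ], seed = i)[, "b"],
                 y[-tr] == "b")
  }, 1)
  expect_lt(abs(mean(null_auc) - 0.5), 0.15)
  expect_identical(sc, baseline_scorer(x[tr, ], y[tr], x[-tr, ], seed = 1))
  expect_error(baseline_scorer(x[tr, ], rep("a", 80), x[-tr, ]), "single class")
})
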