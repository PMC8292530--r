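# Desk-scale evaluation harness: one-vs-rest AUROC over folds, x10
# bootstrap, fold-level t-tests, tile-level false-positive chi-squared, a
# pluggable baseline tile scorer, and the experiment drivers for the
# confounding and stain-artifact simulations.

#' Rank-based binary AUROC
#'
#' Probability that a random positive outscores a random negative, with
#' ties counted 1/2 (the Mann-Whitney convention).
#'
#' @param scores numeric scores
#' @param is_positive logical vector of the same length
#' @return AUROC in `[0, 1]`, or `NA` when a class is absent
#' @export
auroc_binary <- function(scores, is_positive) {
  is_positive <- as.logical(is_positive)
  n1 <- sum(is_positive)
  n0 <- sum(!is_positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-rest AUROC
#'
#' Per-class one-vs-rest AUROC and its macro average. Classes without both
#' a positive and a negative example are skipped with a warning and
#' excluded from the macro average.
#'
#' @param scores matrix or data.frame of per-class scores (columns named by
#'   class)
#' @param labels true class labels
#' @return list with `per_class` (named vector) and `macro`
#' @export
ovr_auroc <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  classes <- colnames(scores)
  if (is.null(classes)) stop("score columns must be named by class")
  per <- setNames(rep(NA_real_, length(classes)), classes)
  for (cl in classes) {
    pos <- labels == cl
    if (!any(pos) || all(pos)) {
      warning("class '", cl, "' is degenerate in this set; skipped")
      next
    }
    per[cl] <- auroc_binary(scores[, cl], pos)
  }
  list(per_class = per, macro = mean(per, na.rm = TRUE))
}

# score columns of a prediction data.frame, in class order
score_cols <- function(preds) grep("^score_", names(preds), value = TRUE)

pred_classes <- function(preds) sub("^score_", "", score_cols(preds))

# mean tile score per slide; the slide inherits its tiles' label
aggregate_slides <- function(preds) {
  sc <- score_cols(preds)
  agg <- aggregate(preds[sc], by = preds[c("slide_id", "patient_id",
                                           "fold", "label")], FUN = mean)
  agg
}

#' Cross-validated evaluation report
#'
#' Computes the one-vs-rest AUROC of each validation fold — at slide level
#' (tile scores averaged per slide first, the feature-prediction
#' convention) or tile level — and their mean. Folds whose labels are
#' degenerate are skipped with a warning.
#'
#' @param preds prediction data.frame with columns `slide_id`,
#'   `patient_id`, `fold`, `label` and one `score_<class>` column per class
#' @param aggregate `"slide"` or `"tile"`
#' @return object of class `evaluation_report`: list with `fold_auroc`
#'   (named numeric), `mean_auroc`, `per_class` (fold x class matrix),
#'   `aggregate`
#' @export
crossval_evaluate <- function(preds, aggregate = c("slide", "tile")) {
  aggregate <- match.arg(aggregate)
  folds <- sort(unique(preds$fold))
  if (length(folds) < 2) stop("need at least 2 folds")
  ev <- if (aggregate == "slide") aggregate_slides(preds) else preds
  classes <- pred_classes(preds)
  fold_auroc <- setNames(rep(NA_real_, length(folds)), paste0("fold", folds))
  per_class <- matrix(NA_real_, length(folds), length(classes),
                      dimnames = list(paste0("fold", folds), classes))
  for (i in seq_along(folds)) {
    sub <- ev[ev$fold == folds[i], , drop = FALSE]
    if (length(unique(sub$label)) < 2) {
      warning("fold ", folds[i], " has degenerate labels; skipped")
      next
    }
    sc <- as.matrix(sub[score_cols(preds)])
    colnames(sc) <- classes
    r <- ovr_auroc(sc, sub$label)
    fold_auroc[i] <- r$macro
    per_class[i, ] <- r$per_class
  }
  structure(list(fold_auroc = fold_auroc,
                 mean_auroc = mean(fold_auroc, na.rm = TRUE),
                 per_class = per_class, aggregate = aggregate),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report (%s level): mean AUROC %.3f [%s]>\n",
              x$aggregate, x$mean_auroc,
              paste(sprintf("%.3f", x$fold_auroc), collapse = ", ")))
  invisible(x)
}

#' Bootstrap AUROC replicates
#'
#' Per fold, resamples the evaluation units (slides) with replacement
#' `reps` times and recomputes the macro one-vs-rest AUROC, yielding the
#' x`reps` bootstrapped replicate set used for confidence intervals.
#'
#' @param preds prediction data.frame (see [crossval_evaluate()])
#' @param reps replicates per fold (default 10)
#' @param seed resampling seed
#' @param aggregate `"slide"` or `"tile"` (resampling unit is always the
#'   slide)
#' @return data.frame with `fold`, `rep`, `auroc` (`reps * folds` rows)
#' @export
bootstrap_auroc <- function(preds, reps = 10L, seed = 1L,
                            aggregate = c("slide", "tile")) {
  aggregate <- match.arg(aggregate)
  ev <- if (aggregate == "slide") aggregate_slides(preds) else preds
  classes <- pred_classes(preds)
  folds <- sort(unique(ev$fold))
  out <- list()
  with_seed(derive_seed(seed, "bootstrap"), {
    for (f in folds) {
      sub <- ev[ev$fold == f, , drop = FALSE]
      slides <- unique(sub$slide_id)
      for (r in seq_len(reps)) {
        pick <- sample(slides, length(slides), replace = TRUE)
        res <- do.call(rbind, lapply(pick, function(s)
          sub[sub$slide_id == s, , drop = FALSE]))
        a <- if (length(unique(res$label)) < 2) NA_real_ else {
          sc <- as.matrix(res[score_cols(preds)])
          colnames(sc) <- classes
          suppressWarnings(ovr_auroc(sc, res$label)$macro)
        }
        out[[length(out) + 1L]] <- data.frame(fold = f, rep = r, auroc = a)
      }
    }
  })
  do.call(rbind, out)
}

#' Fold-level AUROC comparisons
#'
#' Classical t statistics on fold-level AUROCs with the degrees of freedom
#' implied by threefold cross-validation: a paired two-sided test (df 2), a
#' pooled two-sample one-sided test of `a > b` (df 4), or a one-sample
#' one-sided test against chance (AUROC 0.5, df 2). Degenerate variance is
#' reported as an explicit marker: an exact tie gives `p = 1`; zero
#' variance strictly above the null gives `t = Inf`, `p = 0`.
#'
#' @param a,b numeric vectors of fold AUROCs, or [crossval_evaluate()]
#'   reports (`b` is ignored for the vs-chance mode)
#' @param mode `"paired_two_sided_df2"`, `"two_sample_one_sided_df4"` or
#'   `"vs_chance_one_sided_df2"`
#' @param null chance level for the vs-chance mode (default 0.5)
#' @return list with `t`, `df`, `p`, `note`
#' @export
compare_auroc <- function(a, b = NULL,
                          mode = c("paired_two_sided_df2",
                                   "two_sample_one_sided_df4",
                                   "vs_chance_one_sided_df2"),
                          null = 0.5) {
  mode <- match.arg(mode)
  if (inherits(a, "evaluation_report")) a <- a$fold_auroc
  if (inherits(b, "evaluation_report")) b <- b$fold_auroc
  a <- as.numeric(a[!is.na(a)])
  if (!is.null(b)) b <- as.numeric(b[!is.na(b)])
  tie <- function(df) list(t = NA_real_, df = df, p = 1, note = "exact tie")
  inf_pos <- function(df) list(t = Inf, df = df, p = 0,
                               note = "zero variance above null")
  if (mode == "paired_two_sided_df2") {
    stopifnot(length(a) == length(b), length(a) >= 2)
    d <- a - b
    if (sd(d) == 0) {
      if (all(d == 0)) return(tie(length(a) - 1))
      return(list(t = sign(d[1]) * Inf, df = length(a) - 1, p = 0,
                  note = "zero variance of differences"))
    }
    tt <- t.test(a, b, paired = TRUE)
  } else if (mode == "two_sample_one_sided_df4") {
    stopifnot(length(a) >= 2, length(b) >= 2)
    if (sd(a) == 0 && sd(b) == 0) {
      if (mean(a) > mean(b)) return(inf_pos(length(a) + length(b) - 2))
      if (mean(a) == mean(b)) return(tie(length(a) + length(b) - 2))
      return(list(t = -Inf, df = length(a) + length(b) - 2, p = 1,
                  note = "zero variance below null"))
    }
    tt <- t.test(a, b, var.equal = TRUE, alternative = "greater")
  } else {
    stopifnot(length(a) >= 2)
    if (sd(a) == 0) {
      if (mean(a) > null) return(inf_pos(length(a) - 1))
      if (mean(a) == null) return(tie(length(a) - 1))
      return(list(t = -Inf, df = length(a) - 1, p = 1,
                  note = "zero variance below null"))
    }
    tt <- t.test(a, mu = null, alternative = "greater")
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value), note = "")
}

#' Tile-level false-positive chi-squared
#'
#' Compares the false-positive composition of a target class between two
#' cross-validation schemes: among tiles predicted as `target_class` under
#' each scheme, tabulates false versus true positives and applies a Pearson
#' chi-squared test with one degree of freedom. Also returns each arm's
#' false-positive proportion with its estimated standard deviation (the
#' error-bar convention for proportion plots).
#'
#' @param preds_standard,preds_preserved prediction data.frames covering
#'   the same tiles
#' @param target_class the class whose false positives are compared
#' @return list with `statistic`, `df`, `p`, `proportions` (data.frame with
#'   `arm`, `fp`, `tp`, `proportion`, `sd`)
#' @export
tile_fp_chi2 <- function(preds_standard, preds_preserved, target_class) {
  arm <- function(preds, name) {
    sc <- as.matrix(preds[score_cols(preds)])
    colnames(sc) <- pred_classes(preds)
    if (!target_class %in% colnames(sc))
      stop("no score column for class '", target_class, "'")
    predicted <- colnames(sc)[max.col(sc, ties.method = "first")]
    sel <- predicted == target_class
    fp <- sum(sel & preds$label != target_class)
    tp <- sum(sel & preds$label == target_class)
    if (fp + tp == 0)
      stop("no tiles predicted as '", target_class, "' in the ", name, " arm")
    data.frame(arm = name, fp = fp, tp = tp,
               proportion = fp / (fp + tp),
               sd = sqrt(fp / (fp + tp) * (1 - fp / (fp + tp)) / (fp + tp)))
  }
  props <- rbind(arm(preds_standard, "standard"),
                 arm(preds_preserved, "preserved"))
  tab <- as.matrix(props[, c("fp", "tp")])
  if (identical(tab[1, ], tab[2, ])) {
    return(list(statistic = 0, df = 1L, p = 1, proportions = props))
  }
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value), proportions = props)
}

#' Baseline tile scorer
#'
#' A seeded, class-balanced ridge-regularized linear classifier (glmnet,
#' alpha = 0) on the 20-value tile signature. This is a desk-scale
#' surrogate scorer — explicitly not a reimplementation of a deep
#' convolutional model — sufficient to expose site-driven accuracy
#' inflation. Training tiles are balanced by downsampling every class to
#' the smallest class count before fitting. The default ridge penalty is
#' deliberately small: like the high-capacity network it stands in for,
#' the scorer must be able to memorize per-site signatures, which is the
#' phenomenon under study.
#'
#' @param train_x training feature matrix (tiles x features)
#' @param train_labels training class labels
#' @param test_x test feature matrix
#' @param seed downsampling seed
#' @param lambda ridge penalty at which predictions are taken
#' @return matrix of per-class scores (rows = test tiles, columns = classes,
#'   rows summing to 1)
#' @export
baseline_scorer <- function(train_x, train_labels, test_x, seed = 1L,
                            lambda = 0.001) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  train_labels <- as.character(train_labels)
  classes <- sort(unique(train_labels))
  if (length(classes) < 2) stop("training set contains a single class")
  # class balance by downsampling to the smallest class
  m <- min(table(train_labels))
  keep <- with_seed(derive_seed(seed, "scorer-balance"), {
    unlist(lapply(classes, function(cl) {
      idx <- which(train_labels == cl)
      if (length(idx) > m) sample(idx, m) else idx
    }))
  })
  x <- train_x[keep, , drop = FALSE]
  y <- factor(train_labels[keep], levels = classes)
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  xs <- scale(x, mu, sdv)
  ts <- scale(test_x, mu, sdv)
  lambdas <- exp(seq(log(50), log(lambda), length.out = 25))
  if (length(classes) == 2) {
    fit <- glmnet::glmnet(xs, y, family = "binomial", alpha = 0,
                          lambda = lambdas, standardize = FALSE)
    p2 <- as.numeric(predict(fit, ts, s = lambda, type = "response"))
    scores <- cbind(1 - p2, p2)
  } else {
    fit <- glmnet::glmnet(xs, y, family = "multinomial", alpha = 0,
                          lambda = lambdas, standardize = FALSE)
    pr <- predict(fit, ts, s = lambda, type = "response")
    scores <- pr[, , 1]
  }
  colnames(scores) <- classes
  rownames(scores) <- rownames(test_x)
  scores
}

# ---- feature extraction and cross-validated scoring over a scenario -------

#' Tile-signature table for a rendered cohort
#'
#' Computes the 20-value [tile_signature()] of every tile of every slide
#' and joins slide, patient, site and outcome metadata.
#'
#' @param tiles named list (by slide id) of tile lists, e.g.
#'   `make_confounded_scenario()$tiles`
#' @param manifest the matching [cohort_manifest()]
#' @param outcome outcome column supplying the tile labels
#' @return data.frame: one row per tile with metadata plus feature columns
#' @export
cohort_tile_features <- function(tiles, manifest, outcome = "outcome") {
  sl <- manifest$slides
  rows <- lapply(names(tiles), function(sid) {
    rec <- sl[sl$slide_id == sid, ]
    if (nrow(rec) != 1) stop("slide ", sid, " not in manifest")
    feats <- t(vapply(tiles[[sid]], tile_signature, numeric(20)))
    data.frame(slide_id = sid, patient_id = rec$patient_id,
               site_id = rec$site_id, label = rec[[outcome]],
               tile = seq_len(nrow(feats)), feats,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

feature_matrix <- function(features) {
  as.matrix(features[, setdiff(names(features),
                               c("slide_id", "patient_id", "site_id",
                                 "label", "tile", "fold")), drop = FALSE])
}

#' Cross-validated tile scoring
#'
#' Trains the [baseline_scorer()] on the training folds and scores the
#' held-out fold, for every fold of the given patient-to-fold map.
#'
#' @param features a [cohort_tile_features()] table
#' @param fold_map data.frame with `patient_id`, `fold`
#' @param seed scorer seed
#' @param lambda ridge penalty passed to the scorer
#' @return prediction data.frame suitable for [crossval_evaluate()]
#' @export
crossval_score <- function(features, fold_map, seed = 1L, lambda = 0.001) {
  fold_of <- setNames(fold_map$fold, fold_map$patient_id)
  if (!all(features$patient_id %in% names(fold_of)))
    stop("fold map does not cover every patient")
  features$fold <- unname(fold_of[features$patient_id])
  x <- feature_matrix(features)
  out <- list()
  for (f in sort(unique(features$fold))) {
    tr <- features$fold != f
    scores <- baseline_scorer(x[tr, , drop = FALSE], features$label[tr],
                              x[!tr, , drop = FALSE],
                              seed = derive_seed(seed, paste0("fold", f)),
                              lambda = lambda)
    sub <- features[!tr, c("slide_id", "patient_id", "fold", "label")]
    colnames(scores) <- paste0("score_", colnames(scores))
    out[[length(out) + 1L]] <- cbind(sub, scores)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---- normalization dispatch for the experiment drivers --------------------

apply_normalization <- function(tiles_by_slide, method = c("none", "grayscale",
                                                           "grayscale_equalized",
                                                           "reinhard", "macenko")) {
  method <- match.arg(method)
  if (method == "none") return(tiles_by_slide)
  ref_tile <- default_reference_tile()
  fn <- switch(method,
    grayscale = grayscale,
    grayscale_equalized = grayscale_equalized,
    reinhard = {
      ref <- reinhard_reference(ref_tile)
      function(t) reinhard(t, ref)
    },
    macenko = {
      ref <- macenko_reference(ref_tile)
      function(t) tryCatch(macenko(t, ref), error = function(e) t)
    })
  lapply(tiles_by_slide, function(tl) lapply(tl, fn))
}

# ---- experiment drivers ---------------------------------------------------

#' Confounding experiment: standard versus preserved-site cross-validation
#'
#' Generates a confounded multi-site cohort, trains the baseline scorer
#' under (i) standard outcome-stratified folds and (ii) preserved-site
#' folds from the quadratic program, evaluates both at slide level, and
#' tests the AUROC difference (pooled one-sided t, df 4) plus each arm
#' against chance, with Benjamini-Hochberg correction across the three
#' comparisons. With labels determined by site and a per-site stain shift,
#' standard cross-validation inflates AUROC while preserved-site
#' cross-validation stays near chance.
#'
#' @param n_sites,confounding,stain_strength,seed,n_patients_per_site,tiles_per_slide,tile_edge,texture
#'   scenario parameters, see [make_confounded_scenario()]
#' @param k folds (default 3)
#' @return list with `summary` (one-row data.frame), `standard`,
#'   `preserved` (evaluation reports), `comparisons`, `assignment`, `truth`
#' @export
run_confounding_experiment <- function(n_sites = 12L, confounding = 1,
                                       stain_strength = 1, seed = 1L,
                                       n_patients_per_site = 6L,
                                       tiles_per_slide = 12L, tile_edge = 96L,
                                       texture = texture_params(), k = 3L) {
  scen <- make_confounded_scenario(n_sites, confounding, stain_strength, seed,
                                   n_patients_per_site = n_patients_per_site,
                                   tiles_per_slide = tiles_per_slide,
                                   tile_edge = tile_edge, texture = texture)
  features <- cohort_tile_features(scen$tiles, scen$manifest)
  std_map <- standard_folds(scen$manifest, "outcome", k, seed)
  counts <- build_counts(scen$manifest, "outcome")
  assignment <- preserved_folds(counts, k, seed)
  pres_map <- preserved_fold_map(assignment, scen$manifest)
  preds_std <- crossval_score(features, std_map, seed)
  preds_pres <- crossval_score(features, pres_map, seed)
  rep_std <- suppressWarnings(crossval_evaluate(preds_std))
  rep_pres <- suppressWarnings(crossval_evaluate(preds_pres))
  cmp_gap <- compare_auroc(rep_std, rep_pres, "two_sample_one_sided_df4")
  cmp_std <- compare_auroc(rep_std, mode = "vs_chance_one_sided_df2")
  cmp_pres <- compare_auroc(rep_pres, mode = "vs_chance_one_sided_df2")
  fdr <- bh_fdr(c(cmp_gap$p, cmp_std$p, cmp_pres$p))
  comparisons <- data.frame(
    comparison = c("standard_gt_preserved", "standard_vs_chance",
                   "preserved_vs_chance"),
    t = c(cmp_gap$t, cmp_std$t, cmp_pres$t),
    df = c(cmp_gap$df, cmp_std$df, cmp_pres$df),
    p = fdr$p, q = fdr$q, significant = fdr$significant)
  summary <- data.frame(
    n_sites = n_sites, confounding = confounding,
    stain_strength = stain_strength, seed = seed,
    auroc_standard = rep_std$mean_auroc,
    auroc_preserved = rep_pres$mean_auroc,
    auroc_gap = rep_std$mean_auroc - rep_pres$mean_auroc,
    stratification_error = assignment$error,
    gap_q = fdr$q[1], gap_significant = fdr$significant[1])
  list(summary = summary, standard = rep_std, preserved = rep_pres,
       comparisons = comparisons, assignment = assignment, truth = scen$truth)
}

#' Stain-artifact grid experiment
#'
#' Rebuilds the artificial-artifact simulation at desk scale: a single-site
#' cohort of target and background slides in which a biologic signal (the
#' fraction of target patients whose tiles carry a denser-texture class)
#' and an artificial 5% HSV stain artifact (applied to a fraction of the
#' target slides) are varied independently; target detection is then
#' evaluated with standard threefold cross-validation, optionally after
#' stain normalization. At zero biologic signal the detection AUROC traces
#' the artifact's footprint alone.
#'
#' @param biologic_fracs fractions of target patients given the biologic
#'   texture class
#' @param artifact_fracs fractions of target slides given the stain artifact
#' @param normalization normalization methods to evaluate (subset of
#'   `"none"`, `"grayscale"`, `"grayscale_equalized"`, `"reinhard"`,
#'   `"macenko"`)
#' @param n_target,n_background slides per arm (defaults 23 and 46, the
#'   simulated cohort's composition)
#' @param artifact_strength HSV multiplier increase (default 0.05)
#' @param biologic_effect blob-density multiplier of the biologic class
#' @param tiles_per_slide,tile_edge,seed,k remaining scenario parameters
#' @return data.frame with one row per grid cell: `biologic_frac`,
#'   `artifact_frac`, `normalization`, `mean_auroc`, per-fold AUROCs
#' @export
run_artifact_grid <- function(biologic_fracs = 0,
                              artifact_fracs = c(0, 0.5, 1),
                              normalization = "none",
                              n_target = 23L, n_background = 46L,
                              artifact_strength = 0.05,
                              biologic_effect = 2,
                              tiles_per_slide = 6L, tile_edge = 96L,
                              seed = 1L, k = 3L) {
  profile <- site_profile("LAB01", n_target + n_background)
  # the artifact is folded into the slide's single multiplicative HSV
  # transform (the same transform apply_stain_artifact performs): applying
  # it as a second pass over already-quantized pixels would stamp every
  # artifact slide with a detectable re-quantization footprint unrelated to
  # the stain shift itself
  profile_art <- site_profile("LAB01", n_target + n_background,
                              hsv_shift = rep(1 + artifact_strength, 3))
  out <- list()
  for (bf in biologic_fracs) {
    manifest <- artifact_cohort_manifest(n_target, n_background, bf)
    texture <- texture_params(class_effect = c(ERpos = 1,
                                               ERneg = biologic_effect))
    base_tiles <- list()
    art_tiles <- list()
    for (r in seq_len(nrow(manifest$slides))) {
      rec <- manifest$slides[r, ]
      base_tiles[[rec$slide_id]] <-
        render_tiles(rec, profile, texture, tiles_per_slide, seed,
                     tile_edge, outcome_name = "er")
      if (rec$target == "target")
        art_tiles[[rec$slide_id]] <-
          render_tiles(rec, profile_art, texture, tiles_per_slide, seed,
                       tile_edge, outcome_name = "er")
    }
    target_slides <- manifest$slides$slide_id[manifest$slides$target == "target"]
    for (af in artifact_fracs) {
      n_art <- round(af * length(target_slides))
      shifted <- with_seed(derive_seed(seed, paste0("artifact", af, bf)),
                           sample(target_slides, n_art))
      tiles <- base_tiles
      for (sid in shifted) tiles[[sid]] <- art_tiles[[sid]]
      for (nm in normalization) {
        norm_tiles <- apply_normalization(tiles, nm)
        features <- cohort_tile_features(norm_tiles, manifest, outcome = "target")
        fold_map <- standard_folds(manifest, "target", k, seed)
        preds <- crossval_score(features, fold_map, seed)
        ev <- suppressWarnings(crossval_evaluate(preds))
        row <- data.frame(biologic_frac = bf, artifact_frac = af,
                          normalization = nm, mean_auroc = ev$mean_auroc)
        for (i in seq_along(ev$fold_auroc))
          row[[paste0("auroc_fold", i)]] <- ev$fold_auroc[i]
        out[[length(out) + 1L]] <- row
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Single-site target/background cohort: `target` is the prediction label,
# `er` carries the biologic texture class of each patient.
artifact_cohort_manifest <- function(n_target, n_background, biologic_frac) {
  n_bio <- round(biologic_frac * n_target)
  df <- data.frame(
    slide_id = c(sprintf("LAB01-T%03d-S1", seq_len(n_target)),
                 sprintf("LAB01-B%03d-S1", seq_len(n_background))),
    patient_id = c(sprintf("LAB01-T%03d", seq_len(n_target)),
                   sprintf("LAB01-B%03d", seq_len(n_background))),
    site_id = "LAB01",
    target = rep(c("target", "background"), c(n_target, n_background)),
    er = c(rep(c("ERneg", "ERpos"), c(n_bio, n_target - n_bio)),
           rep("ERpos", n_background)),
    stringsAsFactors = FALSE)
  cohort_manifest(df, c(target = "categorical", er = "categorical"))
}
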