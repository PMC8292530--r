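# Per-site heterogeneity of clinical features (chi-squared + BH FDR) and of
# image features (one-way ANOVA F), the descriptive statistics behind the
# site-signature characterization.

#' Filter sites by minimum slide count
#'
#' Descriptive heterogeneity analyses include only sites submitting at
#' least `min_slides` slides, preventing variance metrics from being driven
#' by small sites. Retained rows are returned unmodified.
#'
#' @param manifest a [cohort_manifest()]
#' @param min_slides inclusion threshold (default 20)
#' @return the filtered [cohort_manifest()]
#' @export
filter_sites <- function(manifest, min_slides = 20L) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  tab <- table(manifest$slides$site_id)
  keep <- names(tab)[tab >= min_slides]
  if (!length(keep)) stop("no site reaches the ", min_slides, "-slide threshold")
  cohort_manifest(manifest$slides[manifest$slides$site_id %in% keep, ,
                                  drop = FALSE],
                  manifest$outcomes)
}

#' Site-by-class contingency table
#'
#' Tabulates non-missing outcome labels per site. Missing outcome values
#' are excluded before tabulation.
#'
#' @param manifest a [cohort_manifest()]
#' @param outcome name of a categorical outcome column
#' @param unit count `"patient"`s (deduplicated) or `"slide"`s
#' @return integer matrix, sites x classes
#' @export
site_class_table <- function(manifest, outcome, unit = c("patient", "slide")) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  unit <- match.arg(unit)
  if (!outcome %in% names(manifest$outcomes))
    stop("undeclared outcome column: ", outcome)
  df <- if (unit == "patient") patient_table(manifest) else manifest$slides
  df <- df[!is.na(df[[outcome]]), , drop = FALSE]
  if (!nrow(df)) stop("outcome '", outcome, "' has no non-missing values")
  as.matrix(table(df$site_id, df[[outcome]]))
}

#' Chi-squared test of site heterogeneity
#'
#' Pearson chi-squared without continuity correction on a sites x classes
#' count table, with df = (rows - 1)(cols - 1). A zero marginal (empty row
#' or column) makes expected counts zero and is rejected with advice to
#' merge classes.
#'
#' @param counts sites x classes matrix of non-negative integers
#' @return list with `statistic`, `df`, `p`
#' @export
chi_squared_heterogeneity <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("need at least 2 sites and 2 classes")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal total; merge or drop empty classes/sites before testing")
  res <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up FDR adjustment; a hypothesis is rejected when its monotone
#' adjusted value q is at most `alpha`.
#'
#' @param pvals p values in `[0, 1]`
#' @param alpha FDR level (default 0.05)
#' @return data.frame with `p`, `q`, `significant`
#' @export
bh_fdr <- function(pvals, alpha = 0.05) {
  pvals <- as.numeric(pvals)
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1)))
    stop("p values must lie in [0, 1]")
  q <- p.adjust(pvals, method = "BH")
  data.frame(p = pvals, q = q, significant = !is.na(q) & q <= alpha)
}

#' One-way ANOVA F across sites
#'
#' Classical one-way ANOVA on one image characteristic grouped by site:
#' F = MS_between / MS_within with df_between = sites - 1 and
#' df_within = N - sites. Degenerate cases return explicit markers instead
#' of erroring: zero within-group and between-group variance gives `F = NA`
#' (undefined); zero within-group variance with real separation gives
#' `F = Inf`, `p = 0`.
#'
#' @param values_by_site named list mapping site to numeric values
#'   (>= 2 sites, each with >= 2 values)
#' @return list with `F`, `df_between`, `df_within`, `p`
#' @export
anova_f <- function(values_by_site) {
  values_by_site <- lapply(values_by_site, function(v) as.numeric(v[!is.na(v)]))
  values_by_site <- values_by_site[vapply(values_by_site, length, 1L) >= 2]
  g <- length(values_by_site)
  if (g < 2) stop("need at least 2 sites with at least 2 values each")
  all_v <- unlist(values_by_site)
  n <- length(all_v)
  grand <- mean(all_v)
  ss_b <- sum(vapply(values_by_site,
                     function(v) length(v) * (mean(v) - grand)^2, 1))
  ss_w <- sum(vapply(values_by_site,
                     function(v) sum((v - mean(v))^2), 1))
  df_b <- g - 1L
  df_w <- n - g
  if (ss_w <= 0 && ss_b <= 0)
    return(list(F = NA_real_, df_between = df_b, df_within = df_w, p = NA_real_))
  if (ss_w <= 0)
    return(list(F = Inf, df_between = df_b, df_within = df_w, p = 0))
  f <- (ss_b / df_b) / (ss_w / df_w)
  list(F = f, df_between = df_b, df_within = df_w,
       p = stats::pf(f, df_b, df_w, lower.tail = FALSE))
}

#' Site-heterogeneity report
#'
#' One row per feature: chi-squared heterogeneity for each declared
#' categorical outcome (sites filtered to `min_slides`), ANOVA F for each
#' numeric column of `features` (one slide per row). Benjamini-Hochberg
#' correction is applied across all rows of the report — the per-report
#' analogue of applying the FDR within one cancer subtype. Features that
#' cannot be tested (all-missing outcome, zero marginal) are kept as
#' explicitly skipped rows, never silently dropped.
#'
#' @param manifest a [cohort_manifest()]
#' @param features optional data.frame with a `slide_id` column and numeric
#'   image-feature columns (e.g. stacked [slide_signature()] rows)
#' @param min_slides site inclusion threshold (default 20)
#' @param alpha FDR level
#' @return data.frame with columns `feature`, `test`, `statistic`, `df`,
#'   `p`, `q`, `significant`, `note`
#' @export
heterogeneity_report <- function(manifest, features = NULL, min_slides = 20L,
                                 alpha = 0.05) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  fm <- filter_sites(manifest, min_slides)
  rows <- list()
  cat_cols <- names(fm$outcomes)[fm$outcomes == "categorical"]
  for (col in cat_cols) {
    res <- tryCatch({
      tab <- site_class_table(fm, col)
      tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
      r <- chi_squared_heterogeneity(tab)
      data.frame(feature = col, test = "chi_squared", statistic = r$statistic,
                 df = r$df, p = r$p, note = "", stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(feature = col, test = "chi_squared", statistic = NA_real_,
                 df = NA_real_, p = NA_real_,
                 note = paste("skipped:", conditionMessage(e)),
                 stringsAsFactors = FALSE))
    rows[[length(rows) + 1L]] <- res
  }
  if (!is.null(features)) {
    if (!"slide_id" %in% names(features)) stop("features must carry slide_id")
    merged <- merge(fm$slides[, c("slide_id", "site_id")], features,
                    by = "slide_id")
    feat_cols <- setdiff(names(features), "slide_id")
    feat_cols <- feat_cols[vapply(features[feat_cols], is.numeric, TRUE)]
    for (col in feat_cols) {
      res <- tryCatch({
        r <- anova_f(split(merged[[col]], merged$site_id))
        data.frame(feature = col, test = "anova", statistic = r$F,
                   df = r$df_between, p = r$p, note = "",
                   stringsAsFactors = FALSE)
      }, error = function(e)
        data.frame(feature = col, test = "anova", statistic = NA_real_,
                   df = NA_real_, p = NA_real_,
                   note = paste("skipped:", conditionMessage(e)),
                   stringsAsFactors = FALSE))
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  adj <- bh_fdr(out$p, alpha)
  out$q <- adj$q
  out$significant <- adj$significant
  out[, c("feature", "test", "statistic", "df", "p", "q", "significant", "note")]
}
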