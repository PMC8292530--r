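# Preserved-site cross-validation: the constrained quadratic program that
# assigns every tissue-submitting site to exactly one of k folds while
# minimizing squared divergence from perfect outcome stratification,
# together with the standard and site-balanced fold builders it is
# compared against.

#' Site-by-class patient counts
#'
#' Builds the integer matrix n (sites x outcome classes) of patients per
#' site per class that the fold optimizer stratifies on. Patients are
#' counted once each regardless of slide count; patients with a missing
#' outcome are excluded from n but listed so they can still follow their
#' site into a fold.
#'
#' @param manifest a [cohort_manifest()]
#' @param outcome a categorical (or pre-binned) outcome column
#' @return object of class `site_class_counts`: list with `n` (matrix),
#'   `site_ids`, `class_labels`, `missing_patients`
#' @export
build_counts <- function(manifest, outcome) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  if (!outcome %in% names(manifest$outcomes))
    stop("undeclared outcome column: ", outcome)
  if (manifest$outcomes[[outcome]] != "categorical")
    stop("outcome '", outcome, "' is continuous; bin it first (bin_continuous)")
  pt <- patient_table(manifest)
  missing <- pt$patient_id[is.na(pt[[outcome]])]
  obs <- pt[!is.na(pt[[outcome]]), , drop = FALSE]
  if (!nrow(obs)) stop("outcome '", outcome, "' is missing for every patient")
  n <- as.matrix(table(factor(obs$site_id, levels = sort(unique(pt$site_id))),
                       obs[[outcome]]))
  if (sum(colSums(n) > 0) < 2)
    stop("need at least 2 outcome classes with positive counts")
  structure(list(n = n, site_ids = rownames(n), class_labels = colnames(n),
                 missing_patients = missing),
            class = "site_class_counts")
}

#' Quantile-bin a continuous outcome
#'
#' Appends a categorical quartile (or n-quantile) column so linear features
#' can be stratified by the fold optimizer. Bins are assigned by rank with
#' ties broken by value then patient id, giving bins as equal as the data
#' allow. When the column has fewer distinct values than bins, the bin
#' count is reduced with a warning.
#'
#' @param manifest a [cohort_manifest()]
#' @param outcome a continuous outcome column
#' @param n_bins number of quantile bins (default 4: quartiles)
#' @return the manifest with an added categorical column `<outcome>_bin`
#' @export
bin_continuous <- function(manifest, outcome, n_bins = 4L) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  if (!outcome %in% names(manifest$outcomes) ||
      manifest$outcomes[[outcome]] != "continuous")
    stop("'", outcome, "' is not a declared continuous outcome")
  pt <- patient_table(manifest)
  v <- pt[[outcome]]
  n_distinct <- length(unique(v[!is.na(v)]))
  if (n_distinct < 1) stop("outcome '", outcome, "' is entirely missing")
  if (n_distinct < n_bins) {
    warning("only ", n_distinct, " distinct value(s); reducing bins from ",
            n_bins, " to ", n_distinct)
    n_bins <- n_distinct
  }
  obs <- which(!is.na(v))
  ord <- obs[order(v[obs], pt$patient_id[obs])]
  bin <- integer(nrow(pt))
  bin[ord] <- ceiling(seq_along(ord) * n_bins / length(ord))
  lab <- ifelse(bin == 0, NA_character_, sprintf("Q%d", bin))
  names(lab) <- pt$patient_id
  col <- paste0(outcome, "_bin")
  slides <- manifest$slides
  slides[[col]] <- unname(lab[slides$patient_id])
  cohort_manifest(slides, c(manifest$outcomes, setNames("categorical", col)))
}

#' Stratification error of a site-to-fold assignment
#'
#' The optimizer's objective: summed (over classes f and folds c) squared
#' divergence of the fold's class count from the ideal equal share,
#' `sum_{f,c} (sum_s m_{s,c} n_{s,f} - sum_s n_{s,f} / k)^2`. Zero means
#' perfect stratification: every fold holds exactly 1/k of each class.
#'
#' @param m sites x k binary matrix; each row must sum to exactly 1 (every
#'   site in exactly one fold)
#' @param counts a [build_counts()] result or a sites x classes matrix
#' @param k number of folds (defaults to `ncol(m)`)
#' @return the error (>= 0)
#' @export
stratification_error <- function(m, counts, k = ncol(m)) {
  n <- if (inherits(counts, "site_class_counts")) counts$n else as.matrix(counts)
  m <- as.matrix(m)
  if (nrow(m) != nrow(n)) stop("m and n disagree on the number of sites")
  if (any(m != 0 & m != 1) || any(rowSums(m) != 1))
    stop("constraint violated: every site must belong to exactly one fold")
  A <- t(m) %*% n                       # k x classes fold totals
  target <- matrix(colSums(n) / k, nrow = k, ncol = ncol(n), byrow = TRUE)
  sum((A - target)^2)
}

new_fold_assignment <- function(m, counts, k, optimal) {
  rownames(m) <- counts$site_ids
  structure(list(m = m, error = stratification_error(m, counts, k),
                 optimal = optimal, site_ids = counts$site_ids, k = k),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("<fold_assignment: %d sites -> %d folds, error %.6g (%s)>\n",
              length(x$site_ids), x$k, x$error,
              if (x$optimal) "proven optimum" else "heuristic"))
  for (c in seq_len(x$k))
    cat(sprintf("  fold %d: %s\n", c,
                paste(x$site_ids[x$m[, c] == 1], collapse = ", ")))
  invisible(x)
}

# error of an assignment given fold-class totals A and per-class targets
.assignment_error <- function(A, target) sum((A - target)^2)

# Continuous lower bound for one class: minimal sum (a_c + x_c - mu)^2 over
# x >= 0, sum x = r (water-filling the lowest fold totals).
waterfill_bound <- function(a, r, mu) {
  if (r <= 0) return(sum((a - mu)^2))
  o <- order(a)
  a_s <- a[o]
  k <- length(a)
  for (j in seq_len(k)) {
    lvl <- (r + sum(a_s[seq_len(j)])) / j
    if (j == k || lvl <= a_s[j + 1] + 1e-12) {
      filled <- sum((lvl - mu)^2 * j)
      rest <- if (j < k) sum((a_s[(j + 1):k] - mu)^2) else 0
      return(filled + rest)
    }
  }
  sum((a - mu)^2)                        # unreachable
}

#' Preserved-site fold assignment by constrained quadratic optimization
#'
#' Assigns each site to exactly one of `k` folds minimizing the
#' [stratification_error()]. For instances up to `exact_threshold` sites the
#' returned assignment is the proven global optimum, found by depth-first
#' branch-and-bound with fold-symmetry breaking and a per-class continuous
#' relaxation (water-filling) lower bound. Larger instances fall back to a
#' seeded multi-start local search (single-site moves and pairwise swaps)
#' and are flagged `optimal = FALSE`. Every fold is required to receive at
#' least one site, since an empty validation fold is meaningless for
#' cross-validation.
#'
#' @param counts a [build_counts()] result (or sites x classes matrix)
#' @param k number of folds (default 3)
#' @param seed seed for the heuristic phase
#' @param exact_threshold largest site count solved exactly (default 15)
#' @param restarts local-search restarts beyond the threshold
#' @return a `fold_assignment`: list with binary matrix `m`, `error`,
#'   `optimal`, `site_ids`, `k`
#' @export
preserved_folds <- function(counts, k = 3L, seed = 1L, exact_threshold = 15L,
                            restarts = 1000L) {
  if (!inherits(counts, "site_class_counts"))
    counts <- structure(list(n = as.matrix(counts),
                             site_ids = rownames(counts) %||%
                               paste0("site", seq_len(nrow(counts))),
                             class_labels = colnames(counts),
                             missing_patients = character()),
                        class = "site_class_counts")
  n <- counts$n
  S <- nrow(n)
  if (S < k) stop("need at least k = ", k, " sites, got ", S)
  ord <- order(-rowSums(n), counts$site_ids)     # big sites first: tight bounds
  n_ord <- n[ord, , drop = FALSE]
  target <- colSums(n) / k
  seed_assign <- local_search_folds(n_ord, k, target, seed, restarts = min(restarts, 200L))
  if (S <= exact_threshold) {
    res <- branch_and_bound_folds(n_ord, k, target,
                                  incumbent = seed_assign$assign,
                                  incumbent_error = seed_assign$error)
    assign_ord <- res$assign
    optimal <- TRUE
  } else {
    res <- local_search_folds(n_ord, k, target, seed, restarts = restarts)
    assign_ord <- res$assign
    optimal <- FALSE
  }
  assign <- integer(S)
  assign[ord] <- assign_ord
  m <- matrix(0L, S, k)
  m[cbind(seq_len(S), assign)] <- 1L
  new_fold_assignment(m, counts, k, optimal)
}

branch_and_bound_folds <- function(n, k, target, incumbent, incumbent_error) {
  S <- nrow(n)
  F <- ncol(n)
  best_assign <- incumbent
  best_err <- incumbent_error + 1e-9
  assign <- integer(S)
  A <- matrix(0, k, F)
  rem_after <- rbind(apply(n, 2, function(col) rev(cumsum(rev(col))))[-1, ,
                                                                      drop = FALSE],
                     matrix(0, 1, F))   # class mass remaining after site i
  recurse <- function(i, max_used) {
    if (i > S) {
      err <- .assignment_error(A, matrix(target, k, F, byrow = TRUE))
      if (err < best_err - 1e-12) {
        best_err <<- err
        best_assign <<- assign[seq_len(S)]
      }
      return(invisible())
    }
    # feasibility: enough sites left to populate unopened folds
    if (k - max_used > S - i + 1) return(invisible())
    for (c in seq_len(min(max_used + 1L, k))) {
      A[c, ] <<- A[c, ] + n[i, ]
      assign[i] <<- c
      rem <- rem_after[i, ]
      lb <- 0
      for (f in seq_len(F))
        lb <- lb + waterfill_bound(A[, f], rem[f], target[f])
      if (lb < best_err - 1e-12)
        recurse(i + 1L, max(max_used, c))
      A[c, ] <<- A[c, ] - n[i, ]
    }
    invisible()
  }
  recurse(1L, 0L)
  list(assign = best_assign, error = best_err)
}

local_search_folds <- function(n, k, target, seed, restarts = 1000L) {
  S <- nrow(n)
  F <- ncol(n)
  tmat <- matrix(target, k, F, byrow = TRUE)
  eval_assign <- function(a) {
    A <- matrix(0, k, F)
    for (c in seq_len(k)) if (any(a == c))
      A[c, ] <- colSums(n[a == c, , drop = FALSE])
    .assignment_error(A, tmat)
  }
  improve <- function(a) {
    err <- eval_assign(a)
    repeat {
      improved <- FALSE
      for (s in seq_len(S)) {
        for (c in seq_len(k)) {
          if (a[s] == c || sum(a == a[s]) == 1L) next
          cand <- a; cand[s] <- c
          e2 <- eval_assign(cand)
          if (e2 < err - 1e-12) { a <- cand; err <- e2; improved <- TRUE }
        }
      }
      for (s1 in seq_len(S - 1)) for (s2 in (s1 + 1):S) {
        if (a[s1] == a[s2]) next
        cand <- a; cand[c(s1, s2)] <- a[c(s2, s1)]
        e2 <- eval_assign(cand)
        if (e2 < err - 1e-12) { a <- cand; err <- e2; improved <- TRUE }
      }
      if (!improved) break
    }
    list(assign = a, error = err)
  }
  with_seed(derive_seed(seed, "local-search"), {
    # greedy start: deal sorted sites to the currently lightest fold
    greedy <- integer(S)
    A <- matrix(0, k, F)
    for (s in seq_len(S)) {
      c <- if (s <= k) s else which.min(rowSums(A))
      greedy[s] <- c
      A[c, ] <- A[c, ] + n[s, ]
    }
    best <- improve(greedy)
    for (r in seq_len(restarts)) {
      if (best$error <= 1e-12) break
      a <- c(sample(k), sample(k, S - k, replace = TRUE))[seq_len(S)]
      res <- improve(a)
      if (res$error < best$error - 1e-12) best <- res
    }
    best
  })
}

#' Exhaustive fold-assignment oracle
#'
#' Enumerates every assignment of sites to `k` folds (after fixing the
#' first site to fold 1, which loses nothing by fold symmetry), keeping
#' only assignments with no empty fold, and returns the global minimum of
#' the [stratification_error()]. Ties are broken by the lexicographically
#' smallest per-site fold-index vector. Intended as the independent test
#' oracle for [preserved_folds()].
#'
#' @param counts a [build_counts()] result or sites x classes matrix
#' @param k number of folds
#' @return a `fold_assignment` with `optimal = TRUE`
#' @export
brute_force_folds <- function(counts, k = 3L) {
  if (!inherits(counts, "site_class_counts"))
    counts <- structure(list(n = as.matrix(counts),
                             site_ids = rownames(counts) %||%
                               paste0("site", seq_len(nrow(counts))),
                             class_labels = colnames(counts),
                             missing_patients = character()),
                        class = "site_class_counts")
  n <- counts$n
  S <- nrow(n)
  if (S < k) stop("need at least k sites")
  if (k^(S - 1) > 1e7)
    stop("instance too large to enumerate; use preserved_folds()")
  grids <- as.matrix(expand.grid(rep(list(seq_len(k)), S - 1)))
  best_err <- Inf
  best <- NULL
  target <- matrix(colSums(n) / k, k, ncol(n), byrow = TRUE)
  for (r in seq_len(nrow(grids))) {
    # expand.grid varies its first variable fastest; reversing the row makes
    # the enumeration lexicographic in the per-site fold-index vector
    a <- c(1L, rev(as.integer(grids[r, ])))
    if (length(unique(a)) < k) next
    A <- matrix(0, k, ncol(n))
    for (c in seq_len(k)) A[c, ] <- colSums(n[a == c, , drop = FALSE])
    err <- .assignment_error(A, target)
    if (err < best_err - 1e-12) { best_err <- err; best <- a }
  }
  m <- matrix(0L, S, k)
  m[cbind(seq_len(S), best)] <- 1L
  new_fold_assignment(m, counts, k, optimal = TRUE)
}

#' Patient-to-fold map from a site assignment
#'
#' Expands a [preserved_folds()] assignment to the patient level: every
#' patient (including those with missing outcomes) inherits the fold of
#' their site.
#'
#' @param assignment a `fold_assignment`
#' @param manifest the [cohort_manifest()] the counts were built from
#' @return data.frame with `patient_id`, `site_id`, `fold`
#' @export
preserved_fold_map <- function(assignment, manifest) {
  stopifnot(inherits(assignment, "fold_assignment"),
            inherits(manifest, "cohort_manifest"))
  site_fold <- apply(assignment$m, 1, which.max)
  names(site_fold) <- assignment$site_ids
  pt <- patient_table(manifest)
  if (!all(pt$site_id %in% names(site_fold)))
    stop("manifest contains sites absent from the assignment")
  data.frame(patient_id = pt$patient_id, site_id = pt$site_id,
             fold = unname(site_fold[pt$site_id]), stringsAsFactors = FALSE)
}

#' Standard stratified k-fold split (site-agnostic)
#'
#' All sites are merged; within each outcome class, patients are shuffled by
#' the seed and dealt round-robin to folds 1..k, so each fold's class
#' proportions are within one patient of the cohort's. Patients with a
#' missing outcome are dealt as their own group with a warning.
#'
#' @param manifest a [cohort_manifest()]
#' @param outcome a categorical outcome column
#' @param k number of folds (default 3)
#' @param seed shuffle seed
#' @return data.frame with `patient_id`, `site_id`, `fold`
#' @export
standard_folds <- function(manifest, outcome, k = 3L, seed = 1L) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  if (manifest$outcomes[[outcome]] != "categorical")
    stop("outcome must be categorical")
  pt <- patient_table(manifest)
  lab <- pt[[outcome]]
  if (anyNA(lab)) {
    warning(sum(is.na(lab)), " patient(s) with missing outcome dealt as ",
            "their own group")
    lab[is.na(lab)] <- ".missing"
  }
  fold <- integer(nrow(pt))
  with_seed(derive_seed(seed, "standard-folds"), {
    for (cl in sort(unique(lab))) {
      idx <- which(lab == cl)
      if (length(idx) < k)
        warning("class '", cl, "' has fewer than k patients")
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  data.frame(patient_id = pt$patient_id, site_id = pt$site_id, fold = fold,
             stringsAsFactors = FALSE)
}

#' Site-balanced k-fold split
#'
#' Represents every site equally in all folds: within each site, patients
#' are shuffled by the seed and dealt round-robin across folds. This is the
#' split used for site-prediction experiments (the opposite extreme of
#' preserved-site folds).
#'
#' @param manifest a [cohort_manifest()]
#' @param k number of folds (default 3)
#' @param seed shuffle seed
#' @return data.frame with `patient_id`, `site_id`, `fold`
#' @export
site_balanced_folds <- function(manifest, k = 3L, seed = 1L) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  pt <- patient_table(manifest)
  fold <- integer(nrow(pt))
  with_seed(derive_seed(seed, "site-balanced-folds"), {
    for (s in sort(unique(pt$site_id))) {
      idx <- which(pt$site_id == s)
      if (length(idx) < k)
        warning("site '", s, "' has fewer than k patients")
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  data.frame(patient_id = pt$patient_id, site_id = pt$site_id, fold = fold,
             stringsAsFactors = FALSE)
}
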