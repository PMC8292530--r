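# Independent brute-force oracles and small fixture builders. Oracles are
# written as plain direct summations so they share no code path with the
# package implementations they check.

rand_pixels <- function(edge = 32, seed = 1, lo = 0, hi = 255) {
  withr_seed(seed)
  array(sample(lo:hi, edge * edge * 3, replace = TRUE), dim = c(edge, edge, 3))
}

withr_seed <- function(seed) set.seed(seed)

# first-order statistics by direct summation
naive_first_order <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  m4 <- sum((x - m)^4) / n
  counts <- rep(0, 256)
  for (v in x) counts[round(v) + 1] <- counts[round(v) + 1] + 1
  ent <- 0
  for (c in counts) if (c > 0) { p <- c / n; ent <- ent - p * log(p) }
  c(mean = m, std = sqrt(m2), skewness = m3 / m2^1.5,
    kurtosis = m4 / m2^2, entropy = ent)
}

# GLCM by explicit pixel-pair loops, Haralick by a full 256x256 double loop
naive_glcm_counts <- function(gray, dr, dc) {
  P <- matrix(0, 256, 256)
  nr <- nrow(gray); nc <- ncol(gray)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc)
      P[gray[r, c] + 1, gray[r2, c2] + 1] <- P[gray[r, c] + 1, gray[r2, c2] + 1] + 1
  }
  P / sum(P)
}

naive_haralick <- function(P) {
  mu_i <- mu_j <- 0
  for (i in 0:255) for (j in 0:255) {
    mu_i <- mu_i + i * P[i + 1, j + 1]
    mu_j <- mu_j + j * P[i + 1, j + 1]
  }
  var_i <- var_j <- 0
  for (i in 0:255) for (j in 0:255) {
    var_i <- var_i + (i - mu_i)^2 * P[i + 1, j + 1]
    var_j <- var_j + (j - mu_j)^2 * P[i + 1, j + 1]
  }
  con <- dis <- hom <- asm <- cor <- 0
  for (i in 0:255) for (j in 0:255) {
    p <- P[i + 1, j + 1]
    con <- con + p * (i - j)^2
    dis <- dis + p * abs(i - j)
    hom <- hom + p / (1 + (i - j)^2)
    asm <- asm + p^2
    cor <- cor + p * (i - mu_i) * (j - mu_j)
  }
  cor <- if (var_i * var_j > 0) cor / sqrt(var_i * var_j) else 1
  c(contrast = con, dissimilarity = dis, homogeneity = hom,
    asm = asm, correlation = cor)
}

naive_glcm_features <- function(gray, dr, dc) naive_haralick(naive_glcm_counts(gray, dr, dc))

# AUROC by exhaustive concordant-pair counting
naive_auroc <- function(scores, pos) {
  s1 <- scores[pos]; s0 <- scores[!pos]
  tot <- 0
  for (a in s1) for (b in s0)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(s1) * length(s0))
}

# a small manifest with configurable site sizes and binary outcome
toy_manifest <- function(site_sizes, pos_per_site = NULL, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (i in seq_along(site_sizes)) {
    n <- site_sizes[i]
    npos <- if (is.null(pos_per_site)) rbinom(1, n, 0.5) else pos_per_site[i]
    pid <- sprintf("S%02d-P%03d", i, seq_len(n))
    rows[[i]] <- data.frame(
      slide_id = paste0(pid, "-S1"), patient_id = pid,
      site_id = sprintf("S%02d", i),
      outcome = rep(c("pos", "neg"), c(npos, n - npos)),
      stringsAsFactors = FALSE)
  }
  cohort_manifest(do.call(rbind, rows), c(outcome = "categorical"))
}

# tissue-like random tile (mid-range intensities, non-degenerate channels)
tissue_tile <- function(edge = 48, seed = 1) {
  set.seed(seed)
  array(sample(60:230, edge * edge * 3, replace = TRUE), dim = c(edge, edge, 3))
}

# two-stain optical-density tile from known hematoxylin/eosin vectors
he_matrix <- function() {
  he <- cbind(H = c(0.65, 0.70, 0.29), E = c(0.07, 0.99, 0.11))
  sweep(he, 2, sqrt(colSums(he^2)), "/")
}

# tissue-like mixture with near-pure hematoxylin and eosin regions (dense
# nuclei / bare stroma) — the regime in which the extreme-angle estimation
# of the plane-fitting method is defined
synthetic_stain_tile <- function(edge = 48, seed = 1) {
  set.seed(seed)
  he <- he_matrix()
  n <- edge * edge
  kind <- sample(1:3, n, replace = TRUE, prob = c(0.3, 0.3, 0.4))
  c_h <- ifelse(kind == 1, runif(n, 0.6, 1.2),
         ifelse(kind == 2, runif(n, 0, 0.04), runif(n, 0.2, 0.5)))
  c_e <- ifelse(kind == 2, runif(n, 0.5, 1.0),
         ifelse(kind == 1, runif(n, 0, 0.04), runif(n, 0.2, 0.5)))
  conc <- rbind(pmax(c_h, 0.005), pmax(c_e, 0.005))
  od <- he %*% conc
  pix <- pmin(pmax(round(exp(-od) * 256 - 1), 0), 255)
  array(c(pix[1, ], pix[2, ], pix[3, ]), dim = c(edge, edge, 3))
}

angle_deg <- function(u, v) acos(min(1, abs(sum(u * v)))) * 180 / pi
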