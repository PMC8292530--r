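# Synthetic multi-site cohorts: controllable site stain signatures,
# class-dependent texture, and site-outcome confounding. Every downstream
# module is testable against this generator's ground-truth log.

#' Site profile for the synthetic generator
#'
#' Describes one tissue-submitting site: how many patients it contributes,
#' its stain signature (a multiplicative HSV shift applied to every tile it
#' submits), and its outcome prevalence.
#'
#' @param site_id site identifier
#' @param n_patients number of patients contributed (> 0)
#' @param hsv_shift length-3 multiplier on (hue, saturation, value); the
#'   default range check keeps components within `[0.90, 1.10]`, enclosing
#'   the simulated 0-5% shift band
#' @param outcome_prevalence named probabilities per outcome class, summing
#'   to 1
#' @param check_range set `FALSE` to allow shifts outside `[0.90, 1.10]`
#' @return an object of class `site_profile`
#' @export
site_profile <- function(site_id, n_patients,
                         hsv_shift = c(1, 1, 1),
                         outcome_prevalence = c(pos = 0.5, neg = 0.5),
                         check_range = TRUE) {
  if (n_patients < 1) stop("n_patients must be positive")
  if (length(hsv_shift) != 3) stop("hsv_shift must have 3 components")
  if (check_range && (any(hsv_shift < 0.90) || any(hsv_shift > 1.10)))
    stop("hsv_shift components outside [0.90, 1.10]; ",
         "pass check_range = FALSE to override")
  if (is.null(names(outcome_prevalence)))
    stop("outcome_prevalence must be named by class")
  if (abs(sum(outcome_prevalence) - 1) > 1e-8)
    stop("outcome_prevalence must sum to 1")
  structure(list(site_id = as.character(site_id),
                 n_patients = as.integer(n_patients),
                 hsv_shift = as.numeric(hsv_shift),
                 outcome_prevalence = outcome_prevalence),
            class = "site_profile")
}

#' Texture parameters for synthetic tiles
#'
#' The tile model is a minimal, classifier-learnable stand-in for histology:
#' dark elliptical "nuclei" blobs scattered on a pink background with
#' Gaussian noise. The outcome class modulates blob density through
#' `class_effect`, giving a controllable biologic (texture) signal that is
#' independent of any stain shift.
#'
#' @param blob_density expected blobs per tile (> 0)
#' @param blob_radius_mean,blob_radius_sd mean and spread of blob radius, px
#' @param blob_aspect range of the blob minor/major axis ratio
#' @param base_rgb background color (eosin-pink default)
#' @param blob_rgb blob color (hematoxylin-purple default)
#' @param noise_sd per-pixel Gaussian noise standard deviation
#' @param class_effect named per-class multiplier on `blob_density`
#' @return an object of class `texture_params`
#' @export
texture_params <- function(blob_density = 12, blob_radius_mean = 4,
                           blob_radius_sd = 1,
                           blob_aspect = c(0.6, 1),
                           base_rgb = c(225, 190, 210),
                           blob_rgb = c(110, 70, 140),
                           noise_sd = 8,
                           class_effect = c(pos = 1, neg = 1)) {
  if (blob_density <= 0 || blob_radius_mean <= 0)
    stop("densities and radii must be strictly positive")
  structure(list(blob_density = blob_density,
                 blob_radius_mean = blob_radius_mean,
                 blob_radius_sd = blob_radius_sd,
                 blob_aspect = blob_aspect,
                 base_rgb = base_rgb, blob_rgb = blob_rgb,
                 noise_sd = noise_sd, class_effect = class_effect),
            class = "texture_params")
}

#' Generate a multi-site cohort manifest
#'
#' Draws each site's patients and their outcome labels from the site's
#' declared prevalence. Each site uses its own random stream keyed by
#' `(seed, site_id)`, so identical seeds yield byte-identical manifests and
#' adding a site never perturbs the others.
#'
#' @param profiles list of [site_profile()]
#' @param slides_per_patient slides contributed per patient
#' @param seed master integer seed
#' @param outcome_name name of the categorical outcome column
#' @return a [cohort_manifest()]
#' @export
generate_cohort <- function(profiles, slides_per_patient = 1L, seed,
                            outcome_name = "outcome") {
  if (length(profiles) < 1) stop("need at least one site profile")
  stopifnot(all(vapply(profiles, inherits, TRUE, "site_profile")))
  rows <- lapply(profiles, function(p) {
    labels <- with_seed(derive_seed(seed, paste0("cohort:", p$site_id)), {
      prev <- p$outcome_prevalence
      sample(names(prev), p$n_patients, replace = TRUE, prob = prev)
    })
    pid <- sprintf("%s-P%03d", p$site_id, seq_len(p$n_patients))
    do.call(rbind, lapply(seq_len(p$n_patients), function(i) {
      data.frame(slide_id = sprintf("%s-S%d", pid[i], seq_len(slides_per_patient)),
                 patient_id = pid[i], site_id = p$site_id,
                 outcome = labels[i], stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, rows)
  names(df)[names(df) == "outcome"] <- outcome_name
  cohort_manifest(df, setNames("categorical", outcome_name))
}

#' Render synthetic tiles for one slide
#'
#' Draws the base texture (blob count Poisson in the class-modulated,
#' per-slide-jittered density — tumor cellularity varies between sections),
#' applies a per-slide stain jitter (small random HSV multipliers emulating
#' section-thickness and stain-intensity variation), then the site's
#' `hsv_shift` — via the same multiplicative HSV transform as
#' [apply_stain_artifact()]. The whole render is a pure function of
#' `(slide_id, seed)`; its ground-truth log (blob counts, jitters, applied
#' multiplier) is attached as attribute `"ground_truth"`.
#'
#' @param record one-row data.frame or list with `slide_id` and the outcome
#'   label column
#' @param profile the slide's [site_profile()]
#' @param texture a [texture_params()]
#' @param n_tiles number of tiles to render (>= 1)
#' @param seed master integer seed
#' @param tile_edge tile edge in pixels (desk-scale default 96)
#' @param outcome_name outcome column holding the class label
#' @param jitter_hs,jitter_v uniform ranges of the per-slide stain jitter
#'   multipliers for hue/saturation and value; the value range is wider
#'   because section thickness and stain intensity move brightness much
#'   more than they move color balance
#' @return list of [tile_image()] with attribute `ground_truth`
#' @export
render_tiles <- function(record, profile, texture, n_tiles, seed,
                         tile_edge = 96L, outcome_name = "outcome",
                         jitter_hs = c(0.985, 1.015), jitter_v = c(0.94, 1.06)) {
  if (n_tiles < 1) stop("n_tiles must be >= 1")
  stopifnot(inherits(profile, "site_profile"), inherits(texture, "texture_params"))
  slide_id <- as.character(record[["slide_id"]])
  class <- as.character(record[[outcome_name]])
  if (!class %in% names(texture$class_effect))
    stop("outcome class '", class, "' has no entry in class_effect")
  dens <- texture$blob_density * texture$class_effect[[class]]
  with_seed(derive_seed(seed, paste0("render:", slide_id)), {
    jit <- c(runif(2, jitter_hs[1], jitter_hs[2]),
             runif(1, jitter_v[1], jitter_v[2]))
    mult <- profile$hsv_shift * jit
    dens <- dens * runif(1, 0.8, 1.2)
    texture$noise_sd <- texture$noise_sd * runif(1, 0.85, 1.15)
    blob_counts <- integer(n_tiles)
    tiles <- vector("list", n_tiles)
    for (t in seq_len(n_tiles)) {
      pix <- render_base_tile(tile_edge, texture, dens)
      blob_counts[t] <- attr(pix, "n_blobs")
      pix <- transform_hsv(clip255(round(pix)), mult)
      tiles[[t]] <- tile_image(pix, slide_id = slide_id)
    }
    attr(tiles, "ground_truth") <- list(
      slide_id = slide_id, class = class, site_id = profile$site_id,
      hsv_shift = profile$hsv_shift, slide_jitter = jit,
      applied_multiplier = mult, slide_blob_density = dens,
      slide_noise_sd = texture$noise_sd,
      blob_counts = blob_counts)
    tiles
  })
}

# One unshifted base tile; returns array with attr n_blobs. Runs inside the
# caller's seeded stream.
render_base_tile <- function(edge, texture, density) {
  pix <- array(rnorm(edge * edge * 3, rep(texture$base_rgb, each = edge * edge),
                     texture$noise_sd),
               dim = c(edge, edge, 3))
  n_b <- rpois(1, density)
  for (b in seq_len(n_b)) {
    cx <- runif(1, 1, edge); cy <- runif(1, 1, edge)
    a <- max(1.2, rnorm(1, texture$blob_radius_mean, texture$blob_radius_sd))
    bmin <- a * runif(1, texture$blob_aspect[1], texture$blob_aspect[2])
    th <- runif(1, 0, pi)
    r <- ceiling(a) + 1L
    xs <- max(1, floor(cx - r)):min(edge, ceiling(cx + r))
    ys <- max(1, floor(cy - r)):min(edge, ceiling(cy + r))
    dx <- outer(rep(1, length(ys)), xs - cx)
    dy <- outer(ys - cy, rep(1, length(xs)))
    u <- (dx * cos(th) + dy * sin(th)) / a
    v <- (-dx * sin(th) + dy * cos(th)) / bmin
    inside <- (u^2 + v^2) <= 1
    for (ch in 1:3) {
      block <- pix[ys, xs, ch]
      block[inside] <- texture$blob_rgb[ch] + rnorm(sum(inside), 0, 4)
      pix[ys, xs, ch] <- block
    }
  }
  pix <- clip255(pix)
  attr(pix, "n_blobs") <- n_b
  pix
}

# Per-site HSV stain signatures for a confounded cohort. Site signatures
# live in the chroma plane (hue, saturation): stain formulation differences
# shift color balance, while brightness (value) varies slide to slide
# within every site. Each site draws an independent chroma shift, so sites
# are individually identifiable but no global stain axis is built into the
# outcome groups. The hue and saturation spans are chosen for comparable
# pixel-level effect (a saturation multiplier moves channel values much
# less than an equal hue multiplier at histology-like colors); both stay
# inside the site-profile band of +/- 10%.
site_shift_matrix <- function(n_sites, stain_strength, seed) {
  mult <- matrix(1, n_sites, 3)
  if (stain_strength == 0) return(mult)
  span <- c(h = 0.045, s = 0.09)
  for (i in seq_len(n_sites))
    mult[i, 1:2] <- 1 + stain_strength * span *
      with_seed(derive_seed(seed, paste0("shift:", i)), runif(2, -1, 1))
  pmin(pmax(mult, 0.90), 1.10)
}

# Per-site acquisition texture: sites differ not only in stain but in how
# specimens were fixed, sectioned and digitized. Each site draws its own
# noise level, nucleus size/eccentricity and stain darkness around the base
# texture, giving the site signature the multi-factor character real
# repositories show (stain + processing + scanner).
site_texture_variant <- function(texture, site_id, seed) {
  with_seed(derive_seed(seed, paste0("acq:", site_id)), {
    texture$noise_sd <- runif(1, 4, 13)
    texture$blob_radius_mean <- runif(1, 2.5, 6)
    texture$blob_aspect <- c(runif(1, 0.45, 0.95), 1)
    texture$blob_rgb <- pmin(pmax(texture$blob_rgb * runif(1, 0.7, 1.3), 0), 255)
  })
  texture
}

#' Build a confounded multi-site scenario
#'
#' Generates a cohort in which the strength of the site-outcome association
#' and of the per-site stain signature are both dials. `confounding = 1`
#' makes the outcome a deterministic function of site (alternate sites are
#' all-positive / all-negative); `confounding = 0` makes outcome independent
#' of site. `stain_strength` scales each site's HSV shift linearly from no
#' shift up to 5% multipliers, giving every site a distinct stain direction;
#' outcome-group stain means are balanced by construction (mirrored pair
#' offsets), so any stain-label association a model finds is pure
#' site memorization. The returned ground-truth description records every
#' generating parameter.
#'
#' @param n_sites number of sites (>= 2)
#' @param confounding site-outcome association strength in `[0, 1]`
#' @param stain_strength stain-signature strength in `[0, 1]`
#' @param seed master integer seed
#' @param n_patients_per_site patients per site
#' @param slides_per_patient slides per patient
#' @param tiles_per_slide tiles rendered per slide
#' @param tile_edge tile edge in pixels
#' @param texture a [texture_params()] (base texture; see `site_variation`)
#' @param site_variation when `TRUE` (default) each site renders with its
#'   own acquisition-texture variant of `texture` (noise level, nucleus
#'   size and eccentricity, stain darkness), emulating the processing and
#'   digitization components of a site signature
#' @param out_dir optional directory; when given, writes `manifest.csv`,
#'   `tiles/<slide>_<k>.png` and `ground_truth.yaml`
#' @return list with `manifest` (a [cohort_manifest()]), `tiles` (named list
#'   of tile lists, one per slide), `profiles`, and `truth` (the
#'   ground-truth description)
#' @export
make_confounded_scenario <- function(n_sites, confounding, stain_strength,
                                     seed, n_patients_per_site = 6L,
                                     slides_per_patient = 1L,
                                     tiles_per_slide = 6L, tile_edge = 96L,
                                     texture = texture_params(),
                                     site_variation = TRUE,
                                     out_dir = NULL) {
  if (n_sites < 2) stop("need at least 2 sites")
  if (confounding < 0 || confounding > 1) stop("confounding must lie in [0, 1]")
  if (stain_strength < 0 || stain_strength > 1)
    stop("stain_strength must lie in [0, 1]")
  site_ids <- sprintf("SITE%02d", seq_len(n_sites))
  shifts <- site_shift_matrix(n_sites, stain_strength, seed)
  profiles <- lapply(seq_len(n_sites), function(i) {
    p_pos <- if (i %% 2 == 1) 0.5 + confounding / 2 else 0.5 - confounding / 2
    site_profile(site_ids[i], n_patients_per_site,
                 hsv_shift = shifts[i, ],
                 outcome_prevalence = c(pos = p_pos, neg = 1 - p_pos))
  })
  names(profiles) <- site_ids
  site_textures <- lapply(site_ids, function(sid)
    if (site_variation) site_texture_variant(texture, sid, seed) else texture)
  names(site_textures) <- site_ids
  manifest <- generate_cohort(profiles, slides_per_patient, seed)
  tiles <- list()
  logs <- list()
  for (r in seq_len(nrow(manifest$slides))) {
    rec <- manifest$slides[r, ]
    tl <- render_tiles(rec, profiles[[rec$site_id]], site_textures[[rec$site_id]],
                       tiles_per_slide, seed, tile_edge)
    tiles[[rec$slide_id]] <- tl
    logs[[rec$slide_id]] <- attr(tl, "ground_truth")
  }
  truth <- list(
    n_sites = n_sites, confounding = confounding,
    stain_strength = stain_strength, seed = seed,
    n_patients_per_site = n_patients_per_site,
    slides_per_patient = slides_per_patient,
    tiles_per_slide = tiles_per_slide, tile_edge = tile_edge,
    site_prevalence = lapply(profiles, `[[`, "outcome_prevalence"),
    site_hsv_shift = lapply(profiles, `[[`, "hsv_shift"),
    site_texture = lapply(site_textures, unclass),
    slides = logs)
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "tiles"), recursive = TRUE, showWarnings = FALSE)
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
    for (sid in names(tiles))
      for (k in seq_along(tiles[[sid]]))
        write_image_array(tiles[[sid]][[k]]$pixels,
                          file.path(out_dir, "tiles",
                                    sprintf("%s_%02d.png", sid, k)))
    yaml::write_yaml(truth, file.path(out_dir, "ground_truth.yaml"))
  }
  list(manifest = manifest, tiles = tiles, profiles = profiles, truth = truth)
}
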