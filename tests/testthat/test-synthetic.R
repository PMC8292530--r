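test_that("cohort generation respects counts, prevalence and determinism", {
  profiles <- lapply(c("A", "B", "C"), site_profile, n_patients = 20,
                     outcome_prevalence = c(pos = 1))
  m <- generate_cohort(profiles, seed = 7)
  expect_equal(nrow(m$slides), 60)
  expect_equal(unname(table(m$slides$site_id)), rep(20L, 3), ignore_attr = TRUE)
  expect_true(all(m$slides$outcome == "pos"))          # degenerate prevalence
  m2 <- generate_cohort(profiles, seed = 7)
  expect_identical(m$slides, m2$slides)                # byte-identical rerun
  expect_error(site_profile("A", 5, outcome_prevalence = c(pos = 0.6, neg = 0.3)),
               "sum to 1")
})

test_that("tile rendering is a pure function of slide id and seed", {
  tp <- texture_params()
  prof <- site_profile("A", 2)
  rec <- list(slide_id = "A-P001-S1", outcome = "pos")
  t1 <- render_tiles(rec, prof, tp, 3, seed = 7, tile_edge = 48)
  t2 <- render_tiles(rec, prof, tp, 3, seed = 7, tile_edge = 48)
  expect_identical(t1[[2]]$pixels, t2[[2]]$pixels)
  expect_error(render_tiles(list(slide_id = "x", outcome = "unknown"),
                            prof, tp, 1, 1), "class_effect")
})

test_that("class effect doubles realized blob counts per the ground-truth log", {
  tp <- texture_params(class_effect = c(pos = 2, neg = 1))
  prof <- site_profile("A", 2)
  counts <- sapply(c("pos", "neg"), function(cl) {
    tot <- 0
    for (i in 1:25) {
      tl <- render_tiles(list(slide_id = sprintf("A-%s-%d", cl, i), outcome = cl),
                         prof, tp, 4, seed = 3, tile_edge = 32)
      tot <- tot + sum(attr(tl, "ground_truth")$blob_counts)
    }
    tot
  })
  expect_equal(unname(counts["pos"] / counts["neg"]), 2, tolerance = 0.15)
})

test_that("the ground-truth log reproduces the applied stain multiplier", {
  scen <- make_confounded_scenario(4, 1, 1, seed = 5, n_patients_per_site = 2,
                                   tiles_per_slide = 1, tile_edge = 32)
  gt <- scen$truth$slides[[1]]
  expect_equal(gt$applied_multiplier,
               scen$truth$site_hsv_shift[[gt$site_id]] * gt$slide_jitter)
  # every generating parameter is recorded
  expect_true(all(c("site_prevalence", "site_hsv_shift", "site_texture",
                    "confounding", "stain_strength", "seed") %in%
                  names(scen$truth)))
})

test_that("confounding dial spans independence to determinism", {
  scen1 <- make_confounded_scenario(4, 1, 1, seed = 2, n_patients_per_site = 8,
                                    tiles_per_slide = 1, tile_edge = 32)
  lab <- scen1$manifest$slides
  by_site <- split(lab$outcome, lab$site_id)
  expect_true(all(vapply(by_site, function(x) length(unique(x)) == 1, TRUE)))
  expect_error(make_confounded_scenario(1, 0, 0, 1), "at least 2")
  # stain_strength = 1 keeps multipliers inside the simulated 10% band,
  # strength 0 is exactly no shift
  expect_true(all(abs(unlist(scen1$truth$site_hsv_shift) - 1) <= 0.1))
  scen0 <- make_confounded_scenario(4, 0, 0, seed = 2, n_patients_per_site = 2,
                                    tiles_per_slide = 1, tile_edge = 32)
  expect_true(all(unlist(scen0$truth$site_hsv_shift) == 1))
})

test_that("null cohorts give calibrated chi-squared type-I error", {
  profiles <- lapply(sprintf("S%d", 1:6), site_profile, n_patients = 20)
  rej <- 0
  n_sim <- 200
  for (s in seq_len(n_sim)) {
    m <- generate_cohort(profiles, seed = 1000 + s)
    r <- chi_squared_heterogeneity(site_class_table(m, "outcome"))
    rej <- rej + (r$p < 0.05)
  }
  band <- qbinom(c(0.005, 0.995), n_sim, 0.05)
  expect_gte(rej, band[1])
  expect_lte(rej, band[2])
})

test_that("scenario files round-trip through disk", {
  dir <- withr::local_tempdir()
  scen <- make_confounded_scenario(2, 0, 0.5, seed = 9, n_patients_per_site = 1,
                                   tiles_per_slide = 1, tile_edge = 32,
                                   out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.yaml")))
  pngs <- list.files(file.path(dir, "tiles"), pattern = "\\.png$")
  expect_length(pngs, 2)
  back <- read_manifest(file.path(dir, "manifest.csv"), c(outcome = "categorical"))
  expect_identical(back$slides, scen$manifest$slides)
})
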