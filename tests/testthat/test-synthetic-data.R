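test_that("scene generation honours counts, positions and seed determinism", {
  cfg <- tiny_scene(seed = 5)
  scene <- generate_scene(cfg)
  expect_length(scene$samples, 16)
  organs <- vapply(scene$samples, `[[`, character(1), "organ")
  expect_equal(unname(table(organs)[c("leaf", "stem", "root")]),
               c(6L, 6L, 4L), ignore_attr = TRUE)
  pos <- vapply(scene$samples, `[[`, character(1), "position")
  expect_true(all(pos[organs == "root"] == "n/a"))
  expect_setequal(unique(pos[organs == "leaf"]), c("upper", "middle", "lower"))
  # bit-identical regeneration under the same seed
  scene2 <- generate_scene(cfg)
  expect_identical(scene$samples[[3]]$raw$data, scene2$samples[[3]]$raw$data)
  expect_identical(scene$samples[[3]]$pixel_tnc, scene2$samples[[3]]$pixel_tnc)
  scene3 <- generate_scene(tiny_scene(seed = 6))
  expect_false(identical(scene$samples[[3]]$raw$data, scene3$samples[[3]]$raw$data))
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(42); before <- rnorm(3)
  set.seed(42); invisible(generate_scene(tiny_scene())); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("sample-level TNC is the ROI mean of the pixel field, inside the organ range", {
  scene <- generate_scene(tiny_scene(seed = 2))
  cfg <- scene$config
  for (s in scene$samples) {
    expect_equal(mean(s$pixel_tnc[s$roi_mask]), s$tnc_true)
    rng <- cfg$organ_tnc_ranges[[s$organ]]
    expect_gte(s$tnc_true, rng[1])
    expect_lte(s$tnc_true, rng[2])
    # generator contract on the triplet
    d <- s$white$data - s$raw$data
    expect_true(all(d[as.vector(s$roi_mask)] >= 0))
    expect_true(all(s$raw$data >= s$dark$data - 1e-9))
  }
})

test_that("organ means order leaf > root > stem; positions descend within leaf and stem", {
  tab <- simulate_spectra_table(scene_config(rng_seed = 8, n_leaf = 60, n_stem = 60,
                                             n_root = 20, n_bands = 16,
                                             image_shape = c(6, 6)))
  means <- tapply(tab$y, tab$organ, mean)
  expect_gt(means[["leaf"]], means[["root"]])
  expect_gt(means[["root"]], means[["stem"]])
  for (org in c("leaf", "stem")) {
    m <- tapply(tab$y[tab$organ == org], tab$position[tab$organ == org], mean)
    expect_gt(m[["upper"]], m[["middle"]])
    expect_gt(m[["middle"]], m[["lower"]])
  }
})

test_that("noise-free triplets calibrate back to the designed reflectance exactly", {
  cfg <- tiny_scene(seed = 3, pixel_noise_sd = 0, scatter_sd = 0)
  scene <- generate_scene(cfg)
  wl <- scene$samples[[1]]$raw$wavelengths
  A <- hypernitro:::.absorption_profile(cfg$band_effects, wl)
  for (s in scene$samples[c(1, 8, 15)]) {
    refl <- calibrate(s$raw, s$white, s$dark)
    base <- hypernitro:::.organ_baseline(s$organ, wl)
    for (px in which(s$roi_mask)[c(1, 5)]) {
      i <- (px - 1) %% nrow(s$roi_mask) + 1
      j <- (px - 1) %/% nrow(s$roi_mask) + 1
      designed <- base - s$pixel_tnc[i, j] * A
      expect_equal(refl$data[i, j, ], designed, tolerance = 1e-12)
    }
  }
})

test_that("with zero noise the mean spectrum is affine in TNC and 1-LV PLSR is exact", {
  cfg <- scene_config(rng_seed = 4, n_leaf = 10, n_stem = 0, n_root = 0,
                      n_bands = 24, image_shape = c(8, 8),
                      pixel_noise_sd = 0, scatter_sd = 0)
  tab <- simulate_spectra_table(cfg)
  # at an absorption band the reflectance is an exact affine function of TNC
  band <- which.min(abs(tab$wavelengths - 650))
  fit <- lm(tab$x[, band] ~ tab$y)
  expect_lt(sigma(fit), 1e-10)
  # a single latent variable reconstructs y exactly
  m <- fit_plsr(tab, ncomp = 1)
  ev <- evaluate_model(m, tab, tab$y)
  expect_lt(ev$rmse, 1e-8)
  expect_equal(ev$r, 1, tolerance = 1e-8)
})

test_that("streamed spectra match extraction from the retained scene objects", {
  cfg <- tiny_scene(seed = 9)
  tab <- simulate_spectra_table(cfg, keep_cubes = c("leaf_002", "root_001"))
  kept <- attr(tab, "kept_samples")
  expect_named(kept, c("leaf_002", "root_001"))
  for (id in names(kept)) {
    s <- kept[[id]]
    spec <- mean_roi_spectrum(calibrate(s$raw, s$white, s$dark), s$roi_mask)
    expect_equal(unname(tab$x[match(id, tab$sample_id), ]), unname(spec))
  }
  # and the whole table agrees with the full scene pathway
  scene <- generate_scene(cfg)
  s4 <- scene$samples[[4]]
  expect_equal(unname(tab$x[4, ]),
               unname(mean_roi_spectrum(calibrate(s4$raw, s4$white, s4$dark), s4$roi_mask)))
})

test_that("reference tables round-trip with one row per sample", {
  scene <- generate_scene(tiny_scene(seed = 7))
  path <- file.path(tempdir(), "ref.csv")
  write_reference_table(scene, path)
  back <- read_reference_table(path)
  expect_equal(nrow(back), length(scene$samples))
  expect_equal(back$tnc_percent,
               vapply(scene$samples, `[[`, numeric(1), "tnc_true"))
  expect_identical(back$organ, vapply(scene$samples, `[[`, character(1), "organ"))
  expect_error(write_reference_table(list(), tempfile()), "non-empty")
})

test_that("invalid scene configurations name the offending field", {
  expect_error(scene_config(n_bands = 1), "n_bands")
  expect_error(scene_config(organ_tnc_ranges = list(leaf = c(3, 2), stem = c(0.5, 2),
                                                    root = c(0.8, 1.5))),
               "organ_tnc_ranges")
  expect_error(scene_config(pixel_noise_sd = -1), "noise")
  expect_error(scene_config(band_effects = data.frame(center = c(600, 500),
                                                      width = 10, depth = 0.1)),
               "band_effects")
  expect_error(scene_config(band_start = 1000, band_end = 400), "band_grid")
})
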