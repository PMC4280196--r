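#' Synthetic hyperspectral scene configuration
#'
#' Describes a seed-reproducible cohort of leaf, stem and root samples
#' whose pixel spectra carry nitrogen-dependent absorption features. Each
#' sample's reflectance is built as an organ-specific smooth baseline
#' continuum, minus Gaussian absorption bands whose depths scale linearly
#' with the pixel's total nitrogen content (TNC), times a per-pixel
#' multiplicative scatter factor, plus additive noise; the result is then
#' "un-calibrated" into a raw/white/dark count triplet that [calibrate()]
#' inverts exactly.
#'
#' Default sample counts (120 leaves, 120 stems, 40 roots), the
#' 380-1030 nm / 512-band grid, and the per-organ TNC envelopes are the
#' cohort conditions the pipeline is designed for. Within leaves and stems,
#' upper/middle/lower canopy positions receive descending TNC means.
#'
#' @param rng_seed integer seed; the whole scene is a pure function of it.
#' @param n_leaf,n_stem,n_root sample counts per organ.
#' @param image_shape integer `c(rows, cols)` of every sample image.
#' @param band_start,band_end wavelength grid endpoints in nm.
#' @param n_bands number of bands; the grid is uniform and inclusive of
#'   both endpoints.
#' @param organ_tnc_ranges named list of `c(min, max)` TNC envelopes (%)
#'   for `leaf`, `stem`, `root`.
#' @param pixel_noise_sd additive reflectance noise s.d. per pixel/band.
#' @param scatter_sd s.d. of the log multiplicative scatter factor per
#'   pixel.
#' @param band_effects data frame with columns `center` (nm), `width`
#'   (Gaussian s.d., nm) and `depth` (reflectance absorption per unit
#'   TNC %). Defaults place bands near 550, 650, 760 and 970 nm —
#'   chlorophyll, red, red-edge shoulder and the O-H water feature.
#' @param within_sample_cv amplitude of the smooth within-sample TNC
#'   field, as a fraction of the sample mean.
#' @return An object of class `"scene_config"`.
#' @export
scene_config <- function(rng_seed = 1L,
                         n_leaf = 120L, n_stem = 120L, n_root = 40L,
                         image_shape = c(16L, 16L),
                         band_start = 380, band_end = 1030, n_bands = 512L,
                         organ_tnc_ranges = list(leaf = c(2.264, 4.871),
                                                 stem = c(0.556, 2.135),
                                                 root = c(0.847, 1.470)),
                         pixel_noise_sd = 0.005, scatter_sd = 0.03,
                         band_effects = data.frame(
                           center = c(550, 650, 760, 970),
                           width = c(25, 25, 30, 35),
                           depth = c(0.020, 0.030, 0.025, 0.015)),
                         within_sample_cv = 0.10) {
  .assert_scalar_number(rng_seed, "rng_seed")
  for (f in c("n_leaf", "n_stem", "n_root")) {
    v <- get(f)
    .assert_scalar_number(v, f, lower = 0)
  }
  if (n_leaf + n_stem + n_root < 1) .config_stop("n_leaf", "scene needs >= 1 sample")
  if (length(image_shape) != 2L || any(image_shape < 2)) {
    .config_stop("image_shape", "must be c(rows, cols) with both >= 2")
  }
  .assert_scalar_number(n_bands, "n_bands", lower = 2)
  if (!(band_start < band_end)) .config_stop("band_grid", "band_start must be < band_end")
  if (!is.list(organ_tnc_ranges) ||
      !all(c("leaf", "stem", "root") %in% names(organ_tnc_ranges))) {
    .config_stop("organ_tnc_ranges", "must name leaf, stem and root")
  }
  for (org in c("leaf", "stem", "root")) {
    r <- organ_tnc_ranges[[org]]
    if (length(r) != 2L || any(r <= 0) || r[1L] >= r[2L]) {
      .config_stop("organ_tnc_ranges", sprintf("%s range must be positive with min < max", org))
    }
  }
  .assert_scalar_number(pixel_noise_sd, "noise", lower = 0)
  .assert_scalar_number(scatter_sd, "noise", lower = 0)
  be <- as.data.frame(band_effects)
  if (!all(c("center", "width", "depth") %in% names(be)) || nrow(be) < 1L) {
    .config_stop("band_effects", "must have columns center, width, depth")
  }
  if (any(diff(be$center) <= 0)) {
    .config_stop("band_effects", "band centers must be strictly increasing")
  }
  if (any(be$width <= 0) || any(be$depth < 0)) {
    .config_stop("band_effects", "widths must be > 0 and depths >= 0")
  }
  .assert_scalar_number(within_sample_cv, "within_sample_cv", lower = 0)
  structure(
    list(rng_seed = as.integer(rng_seed),
         n_leaf = as.integer(n_leaf), n_stem = as.integer(n_stem),
         n_root = as.integer(n_root),
         image_shape = as.integer(image_shape),
         band_start = band_start, band_end = band_end,
         n_bands = as.integer(n_bands),
         organ_tnc_ranges = organ_tnc_ranges,
         pixel_noise_sd = pixel_noise_sd, scatter_sd = scatter_sd,
         band_effects = be, within_sample_cv = within_sample_cv),
    class = "scene_config"
  )
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf(
    "<scene_config> %d leaf + %d stem + %d root samples, %dx%d px, %d bands (%g-%g nm), seed %d\n",
    x$n_leaf, x$n_stem, x$n_root, x$image_shape[1L], x$image_shape[2L],
    x$n_bands, x$band_start, x$band_end, x$rng_seed
  ))
  invisible(x)
}

# Position-level TNC means and s.d. as fractions of the organ envelope, so
# that custom ranges rescale coherently. The fractions reproduce the
# reported cohort structure: descending upper/middle/lower means within
# leaves and stems, and organ means ordered leaf > root > stem.
.position_fracs <- data.frame(
  organ    = c("leaf", "leaf", "leaf", "stem", "stem", "stem", "root"),
  position = c("upper", "middle", "lower", "upper", "middle", "lower", "n/a"),
  mean_frac = c(0.686, 0.332, 0.168, 0.528, 0.186, 0.114, 0.544),
  sd_frac   = c(0.191, 0.123, 0.125, 0.232, 0.111, 0.065, 0.230),
  stringsAsFactors = FALSE
)

.split_positions <- function(n) {
  base <- n %/% 3L
  extra <- n %% 3L
  counts <- rep(base, 3L) + c(extra >= 1L, extra >= 2L, FALSE)
  rep(c("upper", "middle", "lower"), counts)
}

# Sample frame with TNC draws; consumes RNG (call under .with_seed).
.scene_frame <- function(config) {
  organ <- c(rep("leaf", config$n_leaf), rep("stem", config$n_stem),
             rep("root", config$n_root))
  position <- c(
    if (config$n_leaf) .split_positions(config$n_leaf),
    if (config$n_stem) .split_positions(config$n_stem),
    if (config$n_root) rep("n/a", config$n_root)
  )
  id <- sprintf("%s_%03d", organ, unlist(lapply(
    c(config$n_leaf, config$n_stem, config$n_root), seq_len
  ), use.names = FALSE))
  tnc <- numeric(length(organ))
  for (k in seq_len(nrow(.position_fracs))) {
    row <- .position_fracs[k, ]
    sel <- organ == row$organ & position == row$position
    if (!any(sel)) next
    rng <- config$organ_tnc_ranges[[row$organ]]
    span <- rng[2L] - rng[1L]
    tnc[sel] <- .rtruncnorm(sum(sel),
                            mean = rng[1L] + row$mean_frac * span,
                            sd = row$sd_frac * span,
                            lower = rng[1L], upper = rng[2L])
  }
  data.frame(sample_id = id, organ = organ, position = position, tnc = tnc,
             stringsAsFactors = FALSE)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Smooth organ baseline continua: green vegetation (leaf, stem) with a
# red edge near 700-720 nm and a water dip near 965 nm; a flat soil-like
# continuum for roots. Background pixels get a bright board spectrum.
.organ_baseline <- function(organ, wl) {
  switch(organ,
    leaf = 0.22 + 0.28 * .sigmoid((wl - 715) / 18) +
      0.09 * exp(-(wl - 555)^2 / (2 * 35^2)) -
      0.045 * exp(-(wl - 965)^2 / (2 * 35^2)),
    stem = 0.30 + 0.26 * .sigmoid((wl - 705) / 25) +
      0.05 * exp(-(wl - 555)^2 / (2 * 45^2)) -
      0.040 * exp(-(wl - 965)^2 / (2 * 35^2)),
    root = 0.28 + 0.00030 * (wl - 380) -
      0.030 * exp(-(wl - 965)^2 / (2 * 40^2)),
    stop("unknown organ: ", organ)
  )
}

.background_spectrum <- function(wl) 0.45 + 0.00005 * (wl - 380)

# Per-unit-TNC absorption profile over the wavelength grid.
.absorption_profile <- function(band_effects, wl) {
  A <- numeric(length(wl))
  for (k in seq_len(nrow(band_effects))) {
    A <- A + band_effects$depth[k] *
      exp(-(wl - band_effects$center[k])^2 / (2 * band_effects$width[k]^2))
  }
  A
}

.roi_mask <- function(organ, shape) {
  r <- shape[1L]; cc <- shape[2L]
  ri <- (seq_len(r) - (r + 1) / 2) / (r / 2)
  ci <- (seq_len(cc) - (cc + 1) / 2) / (cc / 2)
  R <- matrix(ri, r, cc)
  C <- matrix(ci, r, cc, byrow = TRUE)
  switch(organ,
    leaf = (R / 0.85)^2 + (C / 0.72)^2 <= 1,
    stem = abs(C) <= 0.22 & abs(R) <= 0.90,
    root = (R / 0.70)^2 + (C / 0.55)^2 <= 1
  )
}

# Smooth within-sample TNC field: long-axis gradient for stems, radial
# blade field for leaves (with a midrib ridge on lower leaves), radial
# for roots. Centered so the ROI mean equals the sample-level TNC exactly.
.pixel_tnc_field <- function(organ, position, shape, mask, tnc, cv) {
  r <- shape[1L]; cc <- shape[2L]
  R <- matrix((seq_len(r) - (r + 1) / 2) / (r / 2), r, cc)
  C <- matrix((seq_len(cc) - (cc + 1) / 2) / (cc / 2), r, cc, byrow = TRUE)
  g <- switch(organ,
    stem = R,
    leaf = {
      base <- 1 - (R^2 + C^2)
      if (identical(position, "lower")) base <- base + 0.8 * exp(-(C / 0.12)^2)
      base
    },
    root = sqrt(R^2 + C^2) - 0.5
  )
  g <- g - mean(g[mask])
  mx <- max(abs(g[mask]))
  if (mx > 0) g <- g / mx
  field <- tnc * (1 + cv * g)
  field[!mask] <- NA_real_
  field
}

# Build the raw/white/dark triplet for one sample; consumes RNG.
.build_sample <- function(config, id, organ, position, tnc, wl, A) {
  shape <- config$image_shape
  npx <- shape[1L] * shape[2L]
  nb <- length(wl)
  mask <- .roi_mask(organ, shape)
  field <- .pixel_tnc_field(organ, position, shape, mask, tnc,
                            config$within_sample_cv)
  tvec <- as.vector(field)
  refl <- matrix(.background_spectrum(wl), npx, nb, byrow = TRUE)
  in_roi <- as.vector(mask)
  base <- .organ_baseline(organ, wl)
  refl[in_roi, ] <- matrix(base, sum(in_roi), nb, byrow = TRUE) -
    outer(tvec[in_roi], A)
  if (config$scatter_sd > 0) {
    refl <- refl * exp(stats::rnorm(npx, 0, config$scatter_sd))
  }
  if (config$pixel_noise_sd > 0) {
    refl <- refl + stats::rnorm(npx * nb, 0, config$pixel_noise_sd)
  }
  refl <- pmin(pmax(refl, 1e-4), 0.9999)
  # white: flat high-count field with a mild column pattern; dark: small
  # constant (plus camera noise when noise is on); raw reconstructed so
  # that (raw - dark)/(white - dark) recovers `refl` exactly.
  col_idx <- as.vector(matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE))
  white <- matrix(3000 * (1 + 0.02 * sin(2 * pi * col_idx / shape[2L])), npx, nb)
  dark <- matrix(100, npx, nb)
  if (config$pixel_noise_sd > 0) {
    dark <- dark + matrix(stats::rnorm(npx * nb, 0, 1), npx, nb)
  }
  raw <- dark + refl * (white - dark)
  to_cube <- function(m, reflectance = FALSE) {
    hypercube(array(m, c(shape[1L], shape[2L], nb)), wl, reflectance = reflectance)
  }
  structure(
    list(sample_id = id, organ = organ, position = position, tnc_true = tnc,
         raw = to_cube(raw), white = to_cube(white), dark = to_cube(dark),
         roi_mask = mask, pixel_tnc = field),
    class = "synthetic_sample"
  )
}

#' @export
print.synthetic_sample <- function(x, ...) {
  cat(sprintf("<synthetic_sample> %s (%s/%s), TNC %.3f %%, %d ROI px\n",
              x$sample_id, x$organ, x$position, x$tnc_true, sum(x$roi_mask)))
  invisible(x)
}

#' Generate a synthetic hyperspectral scene
#'
#' Produces the full collection of [synthetic sample][scene_config()]
#' objects, each holding its raw/white/dark cube triplet, ROI mask and
#' per-pixel TNC truth. Bit-identical for equal seeds. Memory grows with
#' `n_samples * prod(image_shape) * n_bands`; for large cohorts where only
#' sample-level spectra are needed, use [simulate_spectra_table()], which
#' streams through the same generator.
#'
#' @param config a [scene_config()].
#' @return An object of class `"hyper_scene"`: a list with elements
#'   `samples` (list of `synthetic_sample`) and `config`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  wl <- seq(config$band_start, config$band_end, length.out = config$n_bands)
  A <- .absorption_profile(config$band_effects, wl)
  .with_seed(config$rng_seed, {
    frame <- .scene_frame(config)
    samples <- lapply(seq_len(nrow(frame)), function(i) {
      .build_sample(config, frame$sample_id[i], frame$organ[i],
                    frame$position[i], frame$tnc[i], wl, A)
    })
    structure(list(samples = samples, config = config), class = "hyper_scene")
  })
}

#' @export
print.hyper_scene <- function(x, ...) {
  cat(sprintf("<hyper_scene> %d samples, seed %d\n",
              length(x$samples), x$config$rng_seed))
  invisible(x)
}

#' @export
length.hyper_scene <- function(x) length(x$samples)

#' Simulate the sample-level spectra table for a scene
#'
#' Streams through the scene generator sample by sample: builds the cube
#' triplet, calibrates it with [calibrate()], takes the ROI mean spectrum
#' with [mean_roi_spectrum()], and discards the cubes. For equal seeds the
#' result corresponds exactly to running the same extraction on
#' [generate_scene()] output.
#'
#' @param config a [scene_config()].
#' @param keep_cubes character vector of sample ids (or integer indices)
#'   whose full `synthetic_sample` objects are retained, e.g. for chemical
#'   imaging; stored in the `"kept_samples"` attribute of the result.
#' @return A [spectra_table()] with `y = tnc_true`.
#' @export
simulate_spectra_table <- function(config, keep_cubes = NULL) {
  stopifnot(inherits(config, "scene_config"))
  wl <- seq(config$band_start, config$band_end, length.out = config$n_bands)
  A <- .absorption_profile(config$band_effects, wl)
  .with_seed(config$rng_seed, {
    frame <- .scene_frame(config)
    keep_idx <- if (is.numeric(keep_cubes)) as.integer(keep_cubes) else
      match(keep_cubes, frame$sample_id)
    kept <- list()
    x <- matrix(NA_real_, nrow(frame), config$n_bands)
    for (i in seq_len(nrow(frame))) {
      s <- .build_sample(config, frame$sample_id[i], frame$organ[i],
                         frame$position[i], frame$tnc[i], wl, A)
      x[i, ] <- mean_roi_spectrum(calibrate(s$raw, s$white, s$dark), s$roi_mask)
      if (i %in% keep_idx) kept[[s$sample_id]] <- s
    }
    tab <- spectra_table(x, frame$tnc, wl, frame$sample_id, frame$organ,
                         frame$position)
    attr(tab, "kept_samples") <- kept
    tab
  })
}

#' Write / read the reference TNC table
#'
#' One row per sample with columns `sample_id, organ, position,
#' tnc_percent` — the stand-in for reference-chemistry nitrogen
#' measurements.
#'
#' @param x a `hyper_scene`, a list of `synthetic_sample`, or a
#'   [spectra_table()].
#' @param path CSV destination / source.
#' @return `write_reference_table`: `path` invisibly;
#'   `read_reference_table`: a data frame.
#' @export
write_reference_table <- function(x, path) {
  if (inherits(x, "hyper_scene")) x <- x$samples
  if (inherits(x, "spectra_table")) {
    df <- data.frame(sample_id = x$sample_id, organ = x$organ,
                     position = x$position,
                     tnc_percent = formatC(x$y, digits = 17, format = "g"),
                     stringsAsFactors = FALSE)
  } else {
    if (!is.list(x) || length(x) == 0L ||
        !all(vapply(x, inherits, logical(1), "synthetic_sample"))) {
      stop("'x' must be a non-empty scene, sample list or spectra_table",
           call. = FALSE)
    }
    df <- data.frame(
      sample_id = vapply(x, `[[`, character(1), "sample_id"),
      organ = vapply(x, `[[`, character(1), "organ"),
      position = vapply(x, `[[`, character(1), "position"),
      tnc_percent = formatC(vapply(x, `[[`, numeric(1), "tnc_true"),
                            digits = 17, format = "g"),
      stringsAsFactors = FALSE
    )
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "organ", "position", "tnc_percent")
  if (!all(need %in% colnames(df))) {
    stop("reference table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}
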