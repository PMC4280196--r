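# End-to-end orchestration: simulate -> calibrate/extract -> split ->
# select -> fit -> map, from one configuration object, with seed control
# and a hash manifest for reproducibility checks.

#' Pipeline configuration
#'
#' Bundles the sub-configurations of every stage. Two profiles are
#' provided: `"reduced"` (the default; 24/24/12 samples, 500 frog
#' iterations, 5 runs) finishes in minutes and is what the test suite
#' exercises; `"paper"` uses the full cohort scale this pipeline is
#' designed around (120/120/40 samples, 10,000 iterations, 50 runs).
#' Any component can be overridden explicitly.
#'
#' @param profile `"reduced"` or `"paper"`.
#' @param scene a [scene_config()]; built from the profile if `NULL`.
#' @param frog a [frog_config()]; built from the profile if `NULL`.
#' @param trim wavelength interval kept for modelling, nm.
#' @param calibration_fraction SPXY calibration fraction.
#' @param per_organ stratify the SPXY split by organ.
#' @param k named vector: number of selected wavelengths per target.
#' @param max_lvs latent-variable cap for model fitting.
#' @param n_map_samples number of retained samples rendered as chemical
#'   maps.
#' @param rng_seed master seed; scene and frog seeds derive from it when
#'   not given explicitly.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(profile = c("reduced", "paper"), scene = NULL,
                            frog = NULL, trim = c(420, 1000),
                            calibration_fraction = 0.75, per_organ = TRUE,
                            k = c(leaf = 10, stem = 9, root = 7, whole_plant = 8),
                            max_lvs = 20, n_map_samples = 4, rng_seed = 1L) {
  profile <- match.arg(profile)
  if (is.null(scene)) {
    scene <- if (profile == "paper") {
      scene_config(rng_seed = rng_seed)
    } else {
      scene_config(rng_seed = rng_seed, n_leaf = 24L, n_stem = 24L, n_root = 12L)
    }
  }
  if (is.null(frog)) {
    frog <- if (profile == "paper") {
      frog_config(rng_seed = rng_seed + 1L)
    } else {
      frog_config(iterations = 500L, n_runs = 5L, rng_seed = rng_seed + 1L)
    }
  }
  stopifnot(inherits(scene, "scene_config"), inherits(frog, "frog_config"))
  if (length(trim) != 2L || trim[1L] >= trim[2L]) {
    .config_stop("trim", "must be c(low, high) with low < high")
  }
  if (any(k < 1)) .config_stop("k", "all k must be >= 1")
  need <- c("leaf", "stem", "root", "whole_plant")
  if (!all(need %in% names(k))) {
    .config_stop("k", paste("must name", paste(need, collapse = ", ")))
  }
  structure(
    list(profile = profile, scene = scene, frog = frog, trim = trim,
         calibration_fraction = calibration_fraction, per_organ = per_organ,
         k = k, max_lvs = max_lvs, n_map_samples = as.integer(n_map_samples),
         rng_seed = as.integer(rng_seed)),
    class = "pipeline_config"
  )
}

# Sample identities of a scene (no RNG involved).
.scene_ids <- function(config) {
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
  data.frame(sample_id = id, organ = organ, position = position,
             stringsAsFactors = FALSE)
}

#' Write / read the linear form of a PLSR model as JSON
#'
#' Stores intercept, per-wavelength coefficients and the wavelength list —
#' everything chemical imaging needs.
#'
#' @param model a [fit_plsr()] model.
#' @param path JSON destination / source.
#' @return `write_model_json`: `path` invisibly; `read_model_json`: a
#'   minimal `"plsr_fit"` usable for prediction.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "plsr_fit"))
  obj <- list(intercept = model$intercept,
              wavelengths = model$wavelengths,
              coefficients = unname(model$coefficients),
              ncomp = model$ncomp_used)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- stats::setNames(obj$coefficients,
                          format(obj$wavelengths, trim = TRUE, digits = 10))
  structure(
    list(coefficients = beta, intercept = obj$intercept,
         wavelengths = obj$wavelengths, ncomp = obj$ncomp,
         ncomp_used = obj$ncomp, p = length(beta)),
    class = "plsr_fit"
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Simulates the scene, extracts and trims calibrated mean ROI spectra,
#' SPXY-splits them, runs Random-frog selection per target (leaf, stem,
#' root, whole-plant), fits F-PLSR and RF-PLSR per target (8 model fits),
#' renders chemical maps of the retained samples with the whole-plant
#' RF-PLSR model, and writes a manifest with seeds and md5 hashes of
#' every artifact. Identical seeds give byte-identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @param out_dir writable output directory.
#' @param quiet suppress per-stage log messages.
#' @return Invisibly, the manifest (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ file.create(probe, showWarnings = FALSE) }, error = function(e) FALSE)
  if (!isTRUE(ok)) stop("output directory is not writable: ", out_dir, call. = FALSE)
  unlink(probe)
  log_line <- function(stage, msg) {
    if (!quiet) message(sprintf("[%s] seed=%d %s", stage, config$rng_seed, msg))
  }
  artifacts <- character(0)
  add_artifact <- function(path) artifacts <<- c(artifacts, path)

  # simulate + extract --------------------------------------------------
  ids <- .scene_ids(config$scene)
  keep <- unlist(lapply(split(ids$sample_id, paste(ids$organ, ids$position)),
                        `[`, 1L), use.names = FALSE)
  keep <- utils::head(keep, config$n_map_samples)
  table_full <- .stage("simulate", simulate_spectra_table(config$scene, keep_cubes = keep))
  kept <- attr(table_full, "kept_samples")
  ref_path <- file.path(out_dir, "reference_tnc.csv")
  write_reference_table(table_full, ref_path); add_artifact(ref_path)
  log_line("simulate", sprintf("%d samples generated", nrow(table_full$x)))

  table <- .stage("extract", trim_bands(table_full, config$trim[1L], config$trim[2L]))
  spectra_path <- file.path(out_dir, "spectra.csv")
  write_spectra_csv(table, spectra_path); add_artifact(spectra_path)
  log_line("extract", sprintf("trimmed to %d bands in [%g, %g] nm",
                              length(table$wavelengths), config$trim[1L], config$trim[2L]))

  # split ----------------------------------------------------------------
  split <- .stage("split", spxy_split(table, config$calibration_fraction,
                                      per_organ = config$per_organ))
  split_path <- file.path(out_dir, "split.json")
  write_split_json(split, split_path); add_artifact(split_path)
  log_line("split", sprintf("%d calibration / %d prediction",
                            length(split$calibration), length(split$prediction)))

  # select + fit per target ----------------------------------------------
  targets <- c("leaf", "stem", "root", "whole_plant")
  metrics <- list()
  frog_files <- list()
  comparisons <- list()
  for (ti in seq_along(targets)) {
    target <- targets[ti]
    sel_ids <- if (target == "whole_plant") table$sample_id else
      table$sample_id[table$organ == target]
    sub <- subset_samples(table, sel_ids)
    sub_split <- structure(
      list(calibration = intersect(split$calibration, sel_ids),
           prediction = intersect(split$prediction, sel_ids),
           calibration_fraction = config$calibration_fraction,
           per_organ = FALSE, per_organ_counts = list()),
      class = "spxy_split")
    fcfg <- config$frog
    fcfg$rng_seed <- fcfg$rng_seed + ti - 1L  # decorrelate targets
    frog <- .stage(paste0("select:", target), random_frog(
      subset_samples(sub, sub_split$calibration), fcfg))
    fpath <- file.path(out_dir, sprintf("frog_%s.json", target))
    write_frog_json(frog, fpath); add_artifact(fpath)
    frog_files[[target]] <- basename(fpath)
    log_line(paste0("select:", target),
             sprintf("top wavelength %.0f nm", frog$ranking[1L]))

    cmp <- .stage(paste0("fit:", target), full_vs_selected_report(
      sub, sub_split, frog, k = config$k[[target]],
      max_lvs = config$max_lvs, label = target))
    comparisons[[target]] <- cmp
    for (mdl in c("full", "selected")) {
      m <- cmp[[mdl]]
      metrics[[length(metrics) + 1L]] <- data.frame(
        target = target, model = if (mdl == "full") "F-PLSR" else "RF-PLSR",
        n_wavelengths = if (mdl == "full") cmp$n_full else cmp$k,
        lvs = m$lvs, r_c = m$r_c, rmsec = m$rmsec, r_cv = m$r_cv,
        rmsecv = m$rmsecv, r_p = m$r_p, rmsep = m$rmsep,
        stringsAsFactors = FALSE
      )
    }
    mp <- file.path(out_dir, sprintf("model_%s_full.json", target))
    write_model_json(cmp$full_model, mp); add_artifact(mp)
    mp <- file.path(out_dir, sprintf("model_%s_selected.json", target))
    write_model_json(cmp$selected_model, mp); add_artifact(mp)
    log_line(paste0("fit:", target),
             sprintf("RF-PLSR R_P = %.3f, RMSEP = %.3f", cmp$selected$r_p,
                     cmp$selected$rmsep))
  }
  metrics <- do.call(rbind, metrics)
  metrics_path <- file.path(out_dir, "metrics.csv")
  utils::write.csv(metrics, metrics_path, row.names = FALSE)
  add_artifact(metrics_path)

  # map -------------------------------------------------------------------
  wp_model <- comparisons$whole_plant$selected_model
  maps <- .stage("map", {
    out <- list()
    for (s in kept) {
      refl <- trim_bands(calibrate(s$raw, s$white, s$dark),
                         config$trim[1L], config$trim[2L])
      out[[s$sample_id]] <- predict_map(refl, s$roi_mask, wp_model,
                                        organ = s$organ)
    }
    out
  })
  legend <- render_maps(maps, file.path(out_dir, "maps"))
  for (nm in names(legend)) {
    add_artifact(file.path(out_dir, "maps", legend[[nm]]$png))
    add_artifact(file.path(out_dir, "maps", legend[[nm]]$raster))
  }
  add_artifact(file.path(out_dir, "maps", "legend.json"))
  log_line("map", sprintf("%d chemical maps rendered", length(maps)))

  # manifest --------------------------------------------------------------
  hashes <- as.list(tools::md5sum(artifacts))
  names(hashes) <- vapply(names(hashes), function(p) {
    sub("^/*", "", sub(normalizePath(out_dir), "", normalizePath(p), fixed = TRUE))
  }, character(1))
  manifest <- list(
    package_version = as.character(utils::packageVersion("hypernitro")),
    rng_seed = config$rng_seed,
    scene_seed = config$scene$rng_seed,
    frog_seed = config$frog$rng_seed,
    profile = config$profile,
    k = as.list(config$k),
    whole_plant_selected_wavelengths = comparisons$whole_plant$selected_wavelengths,
    frog_files = frog_files,
    n_model_fits = 2L * length(targets),
    hashes = hashes
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
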