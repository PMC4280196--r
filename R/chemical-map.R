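#' Pixel-wise chemical map from a linear spectral model
#'
#' Applies the explicit linear form of a fitted PLSR model to every ROI
#' pixel of a calibrated cube: `TNC = b0 + sum_i b_i * R(lambda_i)`. Model
#' wavelengths are matched to the nearest cube band; a model wavelength
#' farther than one grid step from every band is an error. Background
#' pixels, and pixels with an invalid (NA) reflectance at any used band,
#' become nodata.
#'
#' @param cube a reflectance [hypercube()].
#' @param mask logical ROI matrix.
#' @param model a [fit_plsr()] model.
#' @param organ organ tag carried by the map (for per-organ colour
#'   scales); default `"leaf"`.
#' @return Object of class `"chemical_map"`: `values` (rows x cols, NA on
#'   nodata), `nodata` mask, `organ`, `scale_bounds`.
#' @export
predict_map <- function(cube, mask, model, organ = "leaf") {
  stopifnot(inherits(cube, "hypercube"), inherits(model, "plsr_fit"))
  d <- dim(cube$data)
  if (!is.logical(mask) || !identical(dim(mask), d[1:2])) {
    stop("'mask' must be a logical matrix matching the cube", call. = FALSE)
  }
  step <- max(diff(cube$wavelengths))
  band_idx <- vapply(model$wavelengths, function(wl) {
    j <- which.min(abs(cube$wavelengths - wl))
    if (abs(cube$wavelengths[j] - wl) > step) {
      stop(sprintf("model wavelength %.1f nm is farther than one grid step from any band",
                   wl), call. = FALSE)
    }
    j
  }, integer(1))
  px <- matrix(cube$data, nrow = d[1L] * d[2L])[, band_idx, drop = FALSE]
  pred <- model$intercept + drop(px %*% model$coefficients)
  values <- matrix(pred, d[1L], d[2L])
  nodata <- !mask | matrix(rowSums(is.na(px)) > 0, d[1L], d[2L])
  values[nodata] <- NA_real_
  finite <- values[!nodata]
  bounds <- if (length(finite) && max(finite) > min(finite)) {
    range(finite)
  } else if (length(finite)) {
    finite[1L] + c(-0.5, 0.5)  # constant map: centre the scale on the value
  } else {
    c(0, 1)
  }
  structure(list(values = values, nodata = nodata, organ = organ,
                 scale_bounds = bounds),
            class = "chemical_map")
}

#' @export
print.chemical_map <- function(x, ...) {
  cat(sprintf("<chemical_map> %dx%d px (%s), %d ROI px, TNC %.3f-%.3f %%\n",
              nrow(x$values), ncol(x$values), x$organ, sum(!x$nodata),
              x$scale_bounds[1L], x$scale_bounds[2L]))
  invisible(x)
}

# Linear low-to-high colour ramp: blue -> cyan -> yellow -> red, with the
# exact endpoint colours at the scale bounds.
.map_ramp <- grDevices::colorRamp(c("#0000FF", "#00FFFF", "#FFFF00", "#FF0000"))

.map_rgb <- function(map, bounds, nodata_grey = 0.8) {
  v <- (map$values - bounds[1L]) / (bounds[2L] - bounds[1L])
  v <- pmin(pmax(v, 0), 1)
  rgb <- array(nodata_grey, c(nrow(v), ncol(v), 3L))
  ok <- !map$nodata
  cols <- .map_ramp(v[ok]) / 255
  for (ch in 1:3) {
    plane <- rgb[, , ch]
    plane[ok] <- cols[, ch]
    rgb[, , ch] <- plane
  }
  rgb
}

#' Render chemical maps to PNG with per-organ colour scales
#'
#' Writes, for every map, a PNG rendering (linear blue-to-red ramp, grey
#' nodata), a plain-text numeric raster of the predicted values
#' (tab-separated, `NA` for nodata), and a JSON legend sidecar with the
#' scale bounds. By default each organ gets its own linear colour scale,
#' spanning the min/max predicted TNC over that organ's maps; with
#' `per_organ_scales = FALSE` a single global scale is shared.
#'
#' @param maps named list of [predict_map()] results; names become file
#'   stems.
#' @param dir output directory (created if needed).
#' @param per_organ_scales logical; see above.
#' @param scale_override optional named list `organ -> c(min, max)`
#'   overriding the computed bounds.
#' @return Invisibly, the legend metadata (also written to
#'   `legend.json`).
#' @export
render_maps <- function(maps, dir, per_organ_scales = TRUE,
                        scale_override = NULL) {
  if (length(maps) == 0L) stop("no maps to render", call. = FALSE)
  stopifnot(all(vapply(maps, inherits, logical(1), "chemical_map")))
  if (is.null(names(maps)) || any(!nzchar(names(maps)))) {
    names(maps) <- sprintf("map_%03d", seq_along(maps))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  organs <- vapply(maps, `[[`, character(1), "organ")
  group_of <- if (per_organ_scales) organs else rep("all", length(maps))
  bounds_of <- lapply(split(maps, group_of), function(ms) {
    vals <- unlist(lapply(ms, function(m) m$values[!m$nodata]))
    if (length(vals) == 0L) return(c(0, 1))
    b <- range(vals)
    if (b[1L] == b[2L]) b <- b + c(-0.5, 0.5)
    b
  })
  if (!is.null(scale_override)) {
    for (nm in names(scale_override)) bounds_of[[nm]] <- scale_override[[nm]]
  }
  legend <- list()
  for (nm in names(maps)) {
    m <- maps[[nm]]
    b <- bounds_of[[group_of[[nm]]]]
    png_file <- file.path(dir, paste0(nm, ".png"))
    png::writePNG(.map_rgb(m, b), png_file)
    raster_file <- file.path(dir, paste0(nm, "_values.tsv"))
    vals_out <- m$values
    vals_out[m$nodata] <- NA_real_
    utils::write.table(vals_out, raster_file, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
    legend[[nm]] <- list(organ = m$organ, scale_min = b[1L], scale_max = b[2L],
                         png = basename(png_file), raster = basename(raster_file))
  }
  jsonlite::write_json(legend, file.path(dir, "legend.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(legend)
}

#' @export
plot.chemical_map <- function(x, ...) {
  b <- x$scale_bounds
  pal <- grDevices::rgb(.map_ramp(seq(0, 1, length.out = 256)) / 255)
  graphics::image(t(x$values[nrow(x$values):1, , drop = FALSE]),
                  col = pal, zlim = b, axes = FALSE,
                  main = sprintf("%s TNC map (%.2f-%.2f %%)", x$organ, b[1L], b[2L]),
                  ...)
  invisible(x)
}
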