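#' Pairwise joint x-y distances for SPXY partitioning
#'
#' Euclidean distances on the spectra (`d_x`) and on the response
#' (`d_y`), each normalised by its maximum over all pairs, then summed:
#' `d_xy = d_x / max(d_x) + d_y / max(d_y)`. Entries therefore lie in
#' `[0, 2]` with a zero diagonal. If either distance is identically zero
#' (all spectra equal, or all responses equal) that term is dropped with
#' a warning.
#'
#' @param table a [spectra_table()] with at least two samples.
#' @return Symmetric `n x n` matrix of joint distances.
#' @export
pairwise_joint_distances <- function(table) {
  stopifnot(inherits(table, "spectra_table"))
  n <- nrow(table$x)
  if (n < 2L) stop("need at least two samples", call. = FALSE)
  dx <- as.matrix(stats::dist(table$x))
  dy <- as.matrix(stats::dist(table$y))
  mx <- max(dx)
  my <- max(dy)
  if (mx == 0) {
    warning("all spectra identical: x-distance term dropped from joint distance")
    dx[] <- 0
  } else {
    dx <- dx / mx
  }
  if (my == 0) {
    warning("all responses identical: y-distance term dropped from joint distance")
    dy[] <- 0
  } else {
    dy <- dy / my
  }
  dx + dy
}

# Kennard-Stone-style selection on a precomputed distance matrix.
# Seed with the maximal-distance pair; then repeatedly add the sample
# whose minimum distance to the already-selected set is maximal. Ties are
# broken toward the lowest sample index. Returns the selection order.
.ks_sequence <- function(d, n_select) {
  n <- nrow(d)
  sel <- integer(n_select)
  # seed pair: maximal distance, lowest-index pair on ties
  upper <- which(upper.tri(d), arr.ind = TRUE)
  dv <- d[upper]
  best <- upper[which(dv == max(dv))[1L], ]
  sel[1:2] <- c(best[1L], best[2L])
  in_sel <- logical(n)
  in_sel[sel[1:2]] <- TRUE
  # min distance from each remaining sample to the selected set
  mind <- pmin(d[, sel[1L]], d[, sel[2L]])
  k <- 2L
  while (k < n_select) {
    mind_masked <- ifelse(in_sel, -Inf, mind)
    cand <- which(mind_masked == max(mind_masked))[1L]
    k <- k + 1L
    sel[k] <- cand
    in_sel[cand] <- TRUE
    mind <- pmin(mind, d[, cand])
  }
  sel
}

#' SPXY calibration / prediction partitioning
#'
#' Sample set partitioning based on joint x-y distances: Kennard-Stone
#' selection on [pairwise_joint_distances()], so the calibration set
#' spans both the spectral space and the response range. The procedure is
#' fully deterministic. By default it runs independently within each organ
#' stratum, so per-organ calibration counts are exactly proportional; a
#' global (unstratified) mode is available.
#'
#' The calibration quota per stratum is `round(fraction * n)` with
#' half-counts rounded up (toward calibration).
#'
#' @param table a [spectra_table()].
#' @param calibration_fraction fraction of samples assigned to the
#'   calibration set, in (0, 1); default 0.75.
#' @param per_organ run SPXY independently within each organ stratum
#'   (default `TRUE`).
#' @return An object of class `"spxy_split"`: calibration and prediction
#'   sample ids, the selection order, per-organ counts and the fraction
#'   used.
#' @examples
#' cfg <- scene_config(n_leaf = 8, n_stem = 8, n_root = 4, n_bands = 16,
#'                     image_shape = c(6, 6))
#' tab <- simulate_spectra_table(cfg)
#' spxy_split(tab, 0.75)
#' @export
spxy_split <- function(table, calibration_fraction = 0.75, per_organ = TRUE) {
  stopifnot(inherits(table, "spectra_table"))
  if (!is.numeric(calibration_fraction) || length(calibration_fraction) != 1L ||
      calibration_fraction <= 0 || calibration_fraction >= 1) {
    stop("'calibration_fraction' must lie strictly between 0 and 1", call. = FALSE)
  }
  strata <- if (per_organ) split(seq_along(table$y), table$organ) else
    list(all = seq_along(table$y))
  cal_idx <- integer(0)
  order_idx <- integer(0)
  for (nm in names(strata)) {
    idx <- strata[[nm]]
    n <- length(idx)
    quota <- floor(calibration_fraction * n + 0.5)  # ties toward calibration
    if (n < 2L || quota < 2L || quota >= n) {
      stop(sprintf(
        "stratum '%s' too small for quota: n = %d, calibration quota = %d",
        nm, n, quota), call. = FALSE)
    }
    d <- pairwise_joint_distances(subset_samples(table, idx))
    sel <- .ks_sequence(d, quota)
    cal_idx <- c(cal_idx, idx[sel])
    order_idx <- c(order_idx, idx[sel])
  }
  pred_idx <- setdiff(seq_along(table$y), cal_idx)
  counts <- lapply(split(seq_along(table$y), table$organ), function(idx) {
    c(calibration = sum(idx %in% cal_idx), prediction = sum(idx %in% pred_idx))
  })
  structure(
    list(calibration = table$sample_id[sort(cal_idx)],
         prediction = table$sample_id[sort(pred_idx)],
         selection_order = table$sample_id[order_idx],
         per_organ_counts = counts,
         calibration_fraction = calibration_fraction,
         per_organ = per_organ),
    class = "spxy_split"
  )
}

#' @export
print.spxy_split <- function(x, ...) {
  cat(sprintf("<spxy_split> %d calibration / %d prediction (fraction %.2f, %s)\n",
              length(x$calibration), length(x$prediction),
              x$calibration_fraction,
              if (x$per_organ) "per organ" else "global"))
  for (nm in names(x$per_organ_counts)) {
    ct <- x$per_organ_counts[[nm]]
    cat(sprintf("  %-5s cal %3d / pred %3d\n", nm, ct[1L], ct[2L]))
  }
  invisible(x)
}

#' Write / read a split as JSON
#'
#' @param split a [spxy_split()] result.
#' @param path JSON destination / source.
#' @return `write_split_json`: `path` invisibly; `read_split_json`: a
#'   `"spxy_split"` object.
#' @export
write_split_json <- function(split, path) {
  stopifnot(inherits(split, "spxy_split"))
  jsonlite::write_json(unclass(split), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_split_json
#' @export
read_split_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$per_organ_counts <- lapply(obj$per_organ_counts, unlist)
  class(obj) <- "spxy_split"
  obj
}
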