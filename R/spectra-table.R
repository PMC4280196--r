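#' Table of sample spectra and reference nitrogen values
#'
#' The central tabular container of the pipeline: the `n x p` matrix `X`
#' of mean ROI reflectance spectra, the response vector `Y` of reference
#' total nitrogen content (TNC, % of dry matter), the per-band wavelengths,
#' and per-sample identity labels (organ and, for leaves/stems, canopy
#' position).
#'
#' @param x numeric `n x p` matrix of reflectance spectra (rows = samples).
#' @param y numeric length-`n` vector of TNC values (%), strictly positive.
#' @param wavelengths numeric length-`p` vector, nm, strictly increasing.
#' @param sample_id character length-`n` unique sample identifiers.
#' @param organ character length-`n`, each one of `"leaf"`, `"stem"`,
#'   `"root"`.
#' @param position character length-`n`, each one of `"upper"`, `"middle"`,
#'   `"lower"`, `"n/a"`.
#' @return An object of class `"spectra_table"`.
#' @export
spectra_table <- function(x, y, wavelengths, sample_id,
                          organ = rep("leaf", length(y)),
                          position = rep("n/a", length(y))) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  wavelengths <- as.numeric(wavelengths)
  n <- nrow(x)
  if (length(y) != n || length(sample_id) != n || length(organ) != n ||
      length(position) != n) {
    stop("rows of 'x', 'y' and label vectors must align", call. = FALSE)
  }
  if (ncol(x) != length(wavelengths)) {
    stop("columns of 'x' must equal the number of wavelengths", call. = FALSE)
  }
  if (length(wavelengths) >= 2L && any(diff(wavelengths) <= 0)) {
    stop("'wavelengths' must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("reflectance values must be finite", call. = FALSE)
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("'y' (TNC %) must be finite and > 0", call. = FALSE)
  }
  if (anyDuplicated(sample_id)) stop("'sample_id' must be unique", call. = FALSE)
  if (!all(organ %in% c("leaf", "stem", "root"))) {
    stop("'organ' entries must be leaf, stem or root", call. = FALSE)
  }
  if (!all(position %in% c("upper", "middle", "lower", "n/a"))) {
    stop("'position' entries must be upper, middle, lower or n/a", call. = FALSE)
  }
  colnames(x) <- format(wavelengths, trim = TRUE, digits = 10)
  rownames(x) <- sample_id
  structure(
    list(x = x, y = y, wavelengths = wavelengths,
         sample_id = as.character(sample_id), organ = as.character(organ),
         position = as.character(position)),
    class = "spectra_table"
  )
}

#' @export
print.spectra_table <- function(x, ...) {
  cat(sprintf(
    "<spectra_table> %d samples x %d wavelengths (%.1f-%.1f nm)\n",
    nrow(x$x), ncol(x$x), min(x$wavelengths), max(x$wavelengths)
  ))
  tab <- table(x$organ)
  cat("  organs:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  TNC range: %.3f-%.3f %%\n", min(x$y), max(x$y)))
  invisible(x)
}

#' @export
dim.spectra_table <- function(x) dim(x$x)

#' Subset a spectra table by sample
#'
#' @param table a [spectra_table()].
#' @param idx integer or logical sample index, or character sample ids.
#' @return A [spectra_table()] with the selected samples.
#' @export
subset_samples <- function(table, idx) {
  stopifnot(inherits(table, "spectra_table"))
  if (is.character(idx)) idx <- match(idx, table$sample_id)
  spectra_table(table$x[idx, , drop = FALSE], table$y[idx], table$wavelengths,
                table$sample_id[idx], table$organ[idx], table$position[idx])
}

#' @export
trim_bands.spectra_table <- function(x, low_nm, high_nm) {
  keep <- .trim_idx(x$wavelengths, low_nm, high_nm)
  spectra_table(x$x[, keep, drop = FALSE], x$y, x$wavelengths[keep],
                x$sample_id, x$organ, x$position)
}

#' Write / read a spectra table as CSV
#'
#' Columns: `sample_id, organ, position, tnc_percent`, then one column per
#' wavelength (header = wavelength in nm). The round trip is value-exact
#' to full double precision.
#'
#' @param table a [spectra_table()].
#' @param path CSV destination / source.
#' @return `write_spectra_csv`: `path` invisibly; `read_spectra_csv`: a
#'   [spectra_table()].
#' @export
write_spectra_csv <- function(table, path) {
  stopifnot(inherits(table, "spectra_table"))
  # 17 significant digits so the numeric round trip is bit-exact
  df <- data.frame(
    sample_id = table$sample_id, organ = table$organ, position = table$position,
    tnc_percent = formatC(table$y, digits = 17, format = "g"),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  spec <- as.data.frame(matrix(formatC(table$x, digits = 17, format = "g"),
                               nrow = nrow(table$x)), check.names = FALSE)
  colnames(spec) <- format(table$wavelengths, trim = TRUE, digits = 10)
  utils::write.csv(cbind(df, spec), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "organ", "position", "tnc_percent")
  if (!all(need %in% colnames(df)[1:4])) {
    stop("spectra CSV must start with columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  wl_cols <- setdiff(colnames(df), need)
  wl <- as.numeric(wl_cols)
  if (any(is.na(wl))) stop("non-numeric wavelength column header in spectra CSV",
                           call. = FALSE)
  spectra_table(as.matrix(df[wl_cols]), df$tnc_percent, wl,
                df$sample_id, df$organ, df$position)
}
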