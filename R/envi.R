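# ENVI-format cube I/O: flat binary cube plus a plain-text header.
# Header fields honoured: samples (columns), lines (rows), bands,
# header offset, data type, interleave (bsq|bil|bip), byte order,
# wavelength = { ... }. Data types supported: 2 (int16), 4 (float32),
# 5 (float64).

.envi_dtypes <- list(
  `2` = list(what = "integer", size = 2L),
  `4` = list(what = "double",  size = 4L),
  `5` = list(what = "double",  size = 8L)
)

# Permutations mapping an R [row, col, band] array onto ENVI file order
# (fastest-varying axis first): BSQ = sample,line,band; BIL =
# sample,band,line; BIP = band,sample,line.
.envi_perm <- list(bsq = c(2L, 1L, 3L), bil = c(2L, 3L, 1L), bip = c(3L, 2L, 1L))

#' Write a hypercube in ENVI format
#'
#' @param cube a [hypercube()].
#' @param cube_path destination for the flat binary cube.
#' @param header_path destination for the text header; defaults to
#'   `<cube_path>.hdr`.
#' @param interleave `"bsq"`, `"bil"` or `"bip"`.
#' @param data_type ENVI data-type code: 2 (int16), 4 (float32) or
#'   5 (float64).
#' @return `cube_path`, invisibly.
#' @export
write_envi <- function(cube, cube_path, header_path = paste0(cube_path, ".hdr"),
                       interleave = c("bil", "bsq", "bip"), data_type = 5) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  dt <- .envi_dtypes[[as.character(data_type)]]
  if (is.null(dt)) stop("unsupported ENVI data type: ", data_type, call. = FALSE)
  d <- dim(cube$data)
  vals <- as.vector(aperm(cube$data, .envi_perm[[interleave]]))
  if (dt$what == "integer") vals <- as.integer(round(vals))
  con <- file(cube_path, "wb")
  on.exit(close(con))
  writeBin(vals, con, size = dt$size, endian = "little")
  hdr <- c(
    "ENVI",
    paste0("samples = ", d[2L]),
    paste0("lines = ", d[1L]),
    paste0("bands = ", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", data_type),
    paste0("interleave = ", interleave),
    "byte order = 0",
    "wavelength = {",
    paste0(" ", paste(format(cube$wavelengths, trim = TRUE, digits = 10),
                      collapse = ", ")),
    "}"
  )
  writeLines(hdr, header_path)
  invisible(cube_path)
}

.parse_envi_header <- function(header_path) {
  txt <- paste(readLines(header_path, warn = FALSE), collapse = "\n")
  fields <- list()
  # brace-delimited values (possibly multi-line), e.g. wavelength = { ... }
  m <- gregexpr("([a-zA-Z ]+?)\\s*=\\s*\\{([^}]*)\\}", txt)
  for (hit in regmatches(txt, m)[[1L]]) {
    key <- tolower(trimws(sub("\\s*=.*$", "", hit)))
    val <- sub("^[^{]*\\{", "", hit)
    val <- sub("\\}\\s*$", "", val)
    fields[[key]] <- trimws(strsplit(val, ",")[[1L]])
  }
  txt_flat <- gsub("\\{[^}]*\\}", "", txt)
  for (line in strsplit(txt_flat, "\n")[[1L]]) {
    if (!grepl("=", line, fixed = TRUE)) next
    key <- tolower(trimws(sub("=.*$", "", line)))
    val <- trimws(sub("^[^=]*=", "", line))
    if (nzchar(key) && nzchar(val)) fields[[key]] <- val
  }
  fields
}

#' Read an ENVI-format hypercube
#'
#' @param cube_path path to the flat binary cube.
#' @param header_path path to the text header; defaults to
#'   `<cube_path>.hdr`.
#' @return A [hypercube()]; reflectance flag is not stored by ENVI and is
#'   left `FALSE`.
#' @export
read_envi <- function(cube_path, header_path = paste0(cube_path, ".hdr")) {
  h <- .parse_envi_header(header_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  missing_f <- setdiff(need, names(h))
  if (length(missing_f)) {
    stop("ENVI header missing field(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  ns <- as.integer(h$samples); nl <- as.integer(h$lines); nb <- as.integer(h$bands)
  interleave <- tolower(h$interleave)
  if (!interleave %in% names(.envi_perm)) {
    stop("unsupported interleave: ", interleave, call. = FALSE)
  }
  dt <- .envi_dtypes[[as.character(as.integer(h[["data type"]]))]]
  if (is.null(dt)) stop("unsupported ENVI data type: ", h[["data type"]], call. = FALSE)
  if (is.null(h$wavelength)) stop("ENVI header missing field(s): wavelength", call. = FALSE)
  wl <- as.numeric(h$wavelength)
  if (length(wl) != nb) {
    stop(sprintf("header declares %d bands but lists %d wavelengths", nb, length(wl)),
         call. = FALSE)
  }
  endian <- if (identical(h[["byte order"]], "1")) "big" else "little"
  offset <- if (is.null(h[["header offset"]])) 0L else as.integer(h[["header offset"]])
  n_vals <- ns * nl * nb
  expected <- offset + n_vals * dt$size
  if (file.size(cube_path) != expected) {
    stop(sprintf("cube file size (%d bytes) does not match header (%d bytes expected)",
                 file.size(cube_path), expected), call. = FALSE)
  }
  con <- file(cube_path, "rb")
  on.exit(close(con))
  if (offset > 0L) readBin(con, "raw", n = offset)
  vals <- readBin(con, dt$what, n = n_vals, size = dt$size, endian = endian)
  perm <- .envi_perm[[interleave]]
  dims_file <- c(nl, ns, nb)[perm]
  arr <- aperm(array(as.numeric(vals), dims_file), order(perm))
  hypercube(arr, wl)
}
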