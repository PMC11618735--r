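# Spectrum containers. 2D: DQ rows x direct columns, axes stored high->low
# ppm (NMR display convention). 1D: ppm axis + intensity vector.

#' Construct a 2D spectrum
#'
#' A processed 2D INADEQUATE (or JRES) spectrum: a calibrated direct-dimension
#' ppm axis, a double-quantum (or J) axis, and an intensity matrix with one
#' row per indirect-axis value and one column per direct-axis value. Axes are
#' stored high-to-low ppm; ascending input is flipped (with the matrix) to
#' the canonical orientation.
#'
#' @param direct_ppm Numeric vector, strictly monotonic, direct (acquisition)
#'   dimension chemical shifts in ppm.
#' @param dq_ppm Numeric vector, strictly monotonic, indirect
#'   (double-quantum) dimension values in ppm.
#' @param intensity Numeric matrix, `length(dq_ppm)` rows by
#'   `length(direct_ppm)` columns, all values finite.
#' @return A `spectrum2d` object.
#' @export
#' @examples
#' sp <- new_spectrum2d(c(30, 20, 10), c(100, 50), matrix(0, 2, 3))
new_spectrum2d <- function(direct_ppm, dq_ppm, intensity) {
  direct_ppm <- as.numeric(direct_ppm)
  dq_ppm <- as.numeric(dq_ppm)
  intensity <- as.matrix(intensity)
  if (!all(is.finite(direct_ppm)) || !all(is.finite(dq_ppm)) ||
      !all(is.finite(intensity))) {
    stop("spectrum contains non-finite values", call. = FALSE)
  }
  dd <- diff(direct_ppm); dq <- diff(dq_ppm)
  if (length(dd) > 0 && !(all(dd > 0) || all(dd < 0))) {
    stop("direct axis must be strictly monotonic", call. = FALSE)
  }
  if (length(dq) > 0 && !(all(dq > 0) || all(dq < 0))) {
    stop("double-quantum axis must be strictly monotonic", call. = FALSE)
  }
  if (nrow(intensity) != length(dq_ppm) ||
      ncol(intensity) != length(direct_ppm)) {
    stop("intensity matrix must be length(dq_ppm) x length(direct_ppm)",
         call. = FALSE)
  }
  if (length(dd) > 0 && dd[1] > 0) {
    direct_ppm <- rev(direct_ppm)
    intensity <- intensity[, rev(seq_len(ncol(intensity))), drop = FALSE]
  }
  if (length(dq) > 0 && dq[1] > 0) {
    dq_ppm <- rev(dq_ppm)
    intensity <- intensity[rev(seq_len(nrow(intensity))), , drop = FALSE]
  }
  structure(list(direct_ppm = direct_ppm, dq_ppm = dq_ppm,
                 intensity = intensity),
            class = "spectrum2d")
}

#' Construct a 1D spectrum
#'
#' @param ppm Strictly monotonic chemical-shift axis (ppm); stored
#'   high-to-low.
#' @param intensity Numeric vector of the same length, all values finite.
#' @return A `spectrum1d` object.
#' @export
new_spectrum1d <- function(ppm, intensity) {
  ppm <- as.numeric(ppm); intensity <- as.numeric(intensity)
  if (!all(is.finite(ppm)) || !all(is.finite(intensity))) {
    stop("spectrum contains non-finite values", call. = FALSE)
  }
  if (length(ppm) != length(intensity)) {
    stop("axis and intensity lengths differ", call. = FALSE)
  }
  d <- diff(ppm)
  if (length(d) > 0 && !(all(d > 0) || all(d < 0))) {
    stop("axis must be strictly monotonic", call. = FALSE)
  }
  if (length(d) > 0 && d[1] > 0) {
    ppm <- rev(ppm); intensity <- rev(intensity)
  }
  structure(list(ppm = ppm, intensity = intensity), class = "spectrum1d")
}

#' @export
print.spectrum2d <- function(x, ...) {
  cat(sprintf(
    "<spectrum2d> %d x %d points; direct %.2f..%.2f ppm; DQ %.2f..%.2f ppm\n",
    nrow(x$intensity), ncol(x$intensity),
    max(x$direct_ppm), min(x$direct_ppm), max(x$dq_ppm), min(x$dq_ppm)))
  invisible(x)
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf("<spectrum1d> %d points; %.2f..%.2f ppm\n",
              length(x$ppm), max(x$ppm), min(x$ppm)))
  invisible(x)
}

#' Read a 2D spectrum
#'
#' Reads a processed 2D spectrum from either the package's plain-text matrix
#' dialect or an NMRPipe 2D frequency-domain file. With `dialect = "auto"`
#' the format is detected from the file content.
#'
#' The text dialect is: a first line `#inadnet-spectrum 2`, a line
#' `#direct_ppm` followed by the direct-axis grid, a line `#dq_ppm` followed
#' by the indirect-axis grid, then one whitespace-separated intensity row per
#' indirect-axis value. For NMRPipe files the ppm axes are computed from the
#' observe frequency, sweep width and origin header fields of each dimension.
#'
#' @param path File path.
#' @param dialect `"auto"`, `"text"` or `"nmrpipe"`.
#' @return A [new_spectrum2d()] object.
#' @export
read_spectrum_2d <- function(path, dialect = c("auto", "text", "nmrpipe")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("spectrum file not found: ", path,
                               call. = FALSE)
  if (dialect == "auto") {
    dialect <- if (is_nmrpipe_file(path)) "nmrpipe" else "text"
  }
  if (dialect == "nmrpipe") return(read_nmrpipe_2d(path))
  read_spectrum_text(path, ndim = 2)
}

#' Read a 1D spectrum (text dialect)
#'
#' @param path File path to a `#inadnet-spectrum 1` text file.
#' @return A [new_spectrum1d()] object.
#' @export
read_spectrum_1d <- function(path) {
  read_spectrum_text(path, ndim = 1)
}

read_spectrum_text <- function(path, ndim) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2 || !grepl("^#inadnet-spectrum", lines[1])) {
    stop("format error: not an inadnet text spectrum: ", path, call. = FALSE)
  }
  file_dim <- as.integer(sub("^#inadnet-spectrum\\s+", "", lines[1]))
  if (!identical(file_dim, as.integer(ndim))) {
    stop("dimensionality error: file is ", file_dim, "D, expected ", ndim,
         "D: ", path, call. = FALSE)
  }
  parse_axis <- function(tag) {
    i <- grep(paste0("^#", tag, "\\b"), lines)
    if (length(i) != 1) stop("format error: missing axis line #", tag,
                             call. = FALSE)
    as.numeric(strsplit(trimws(sub(paste0("^#", tag, "\\s*"), "", lines[i])),
                        "\\s+")[[1]])
  }
  data_lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (ndim == 1) {
    ppm <- parse_axis("ppm")
    vals <- as.numeric(strsplit(trimws(paste(data_lines, collapse = " ")),
                                "\\s+")[[1]])
    return(new_spectrum1d(ppm, vals))
  }
  direct <- parse_axis("direct_ppm")
  dq <- parse_axis("dq_ppm")
  if (length(data_lines) != length(dq)) {
    stop("format error: expected ", length(dq), " intensity rows, found ",
         length(data_lines), call. = FALSE)
  }
  rows <- lapply(data_lines, function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  if (any(vapply(rows, length, integer(1)) != length(direct))) {
    stop("format error: row length does not match direct axis", call. = FALSE)
  }
  new_spectrum2d(direct, dq, do.call(rbind, rows))
}

#' Write a spectrum in the package text dialect
#'
#' @param spec A `spectrum2d` or `spectrum1d` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_text <- function(spec, path) {
  fmt <- function(x) paste(format(x, digits = 15, trim = TRUE,
                                  scientific = FALSE), collapse = " ")
  if (inherits(spec, "spectrum2d")) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("#inadnet-spectrum 2", con)
    writeLines(paste("#direct_ppm", fmt(spec$direct_ppm)), con)
    writeLines(paste("#dq_ppm", fmt(spec$dq_ppm)), con)
    writeLines(apply(spec$intensity, 1, fmt), con)
  } else if (inherits(spec, "spectrum1d")) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("#inadnet-spectrum 1", con)
    writeLines(paste("#ppm", fmt(spec$ppm)), con)
    writeLines(fmt(spec$intensity), con)
  } else {
    stop("not a spectrum object", call. = FALSE)
  }
  invisible(path)
}
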