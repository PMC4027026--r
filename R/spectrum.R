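#' One-dimensional spectrum container
#'
#' `spectrum1d()` is the carrier object every analysis function in the package
#' consumes: a sampled 1D spectrum with an explicit abscissa unit and a
#' nucleus/detection-mode label. The axis is always stored ascending; files
#' written in descending (conventional NMR display) order are normalized on
#' read and the original order recorded in `metadata$original_order`.
#'
#' @param axis numeric abscissa, strictly monotonic after sorting. At least 16
#'   points.
#' @param intensity numeric intensities, same length as `axis`.
#' @param unit abscissa unit: one of `"kHz"`, `"Hz"`, `"ppm"`, `"Gauss"`.
#' @param mode nucleus or detection mode: `"2H"`, `"31P"`, `"ESR-derivative"`,
#'   or `"1H"`.
#' @param temperature sample temperature in Kelvin, or `NULL`.
#' @param metadata free-form named list.
#' @return An object of class `spectrum1d`.
#' @export
spectrum1d <- function(axis, intensity,
                       unit = c("kHz", "Hz", "ppm", "Gauss"),
                       mode = c("2H", "31P", "ESR-derivative", "1H"),
                       temperature = NULL, metadata = list()) {
  unit <- match.arg(unit)
  mode <- match.arg(mode)
  axis <- as.numeric(axis)
  intensity <- as.numeric(intensity)
  if (length(axis) != length(intensity))
    .stop_class("axis and intensity must have the same length", "size_error")
  if (length(axis) < 16L)
    .stop_class(sprintf("spectrum has %d points; at least 16 required", length(axis)),
                "size_error")
  if (anyNA(axis) || anyNA(intensity))
    .stop_class("axis/intensity contain missing values", "parse_error")
  if (is.unsorted(axis, strictly = FALSE)) {
    o <- order(axis)
    if (identical(o, rev(seq_along(axis)))) metadata$original_order <- "descending"
    else metadata$original_order <- "unsorted"
    axis <- axis[o]
    intensity <- intensity[o]
  }
  if (any(diff(axis) <= 0))
    .stop_class("axis is not strictly monotonic (duplicated abscissa values)",
                "axis_error")
  structure(list(axis = axis, intensity = intensity, unit = unit, mode = mode,
                 temperature = temperature, metadata = metadata),
            class = "spectrum1d")
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf("<spectrum1d> %s spectrum, %d points, axis %.4g..%.4g %s%s\n",
              x$mode, length(x$axis), min(x$axis), max(x$axis), x$unit,
              if (!is.null(x$temperature)) sprintf(", T = %g K", x$temperature) else ""))
  invisible(x)
}

#' @export
as.data.frame.spectrum1d <- function(x, ...) {
  data.frame(axis = x$axis, intensity = x$intensity)
}

is.spectrum1d <- function(x) inherits(x, "spectrum1d")

.check_spectrum <- function(s, unit = NULL, mode = NULL, what = "spectrum") {
  if (!is.spectrum1d(s))
    .stop_class(sprintf("%s must be a spectrum1d object", what), "argument_error")
  if (!is.null(unit) && !(s$unit %in% unit))
    .stop_class(sprintf("%s axis unit is '%s'; expected %s", what, s$unit,
                        paste(unit, collapse = "/")), "unit_error")
  if (!is.null(mode) && !(s$mode %in% mode))
    .stop_class(sprintf("%s mode is '%s'; expected %s", what, s$mode,
                        paste(mode, collapse = "/")), "unit_error")
  invisible(s)
}

.valid_units <- list(
  "2H" = c("kHz", "Hz"),
  "31P" = c("ppm", "Hz", "kHz"),
  "ESR-derivative" = "Gauss",
  "1H" = c("ppm", "Hz")
)

#' Read a 1D spectrum from a two-column text or CSV file
#'
#' Files hold two numeric columns (abscissa, intensity); lines starting with
#' `#` are header comments and `# key: value` pairs are parsed into metadata.
#'
#' @param path file path.
#' @param dialect `"two-column"` (whitespace separated) or `"csv"`.
#' @param unit,mode axis unit and nucleus/mode label (see [spectrum1d()]);
#'   header metadata values, when present, take precedence only if the
#'   arguments are missing.
#' @return A [spectrum1d()] with `metadata$source` recording the path.
#' @export
read_spectrum <- function(path, dialect = c("two-column", "csv"),
                          unit = NULL, mode = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    .stop_class(sprintf("file not found: %s", path), "io_error")
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  is_comment <- grepl("^\\s*#", lines)
  for (ln in lines[is_comment]) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([A-Za-z0-9_.-]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- trimws(m[3])
  }
  body <- lines[!is_comment & nzchar(trimws(lines))]
  if (length(body) == 0L)
    .stop_class(sprintf("no data rows in %s", path), "size_error")
  sep <- if (dialect == "csv") "," else "[[:space:]]+"
  toks <- strsplit(trimws(body), sep)
  nf <- lengths(toks)
  if (any(nf != 2L)) {
    bad <- which(nf != 2L)[1]
    .stop_class(sprintf("malformed row at data line %d of %s: expected 2 columns, got %d",
                        bad, path, nf[bad]), "parse_error")
  }
  vals <- suppressWarnings(vapply(toks, function(t) as.numeric(t), numeric(2)))
  if (anyNA(vals)) {
    bad <- which(colSums(is.na(vals)) > 0)[1]
    .stop_class(sprintf("non-numeric value at data line %d of %s", bad, path),
                "parse_error")
  }
  if (is.null(unit)) unit <- meta$unit
  if (is.null(mode)) mode <- meta$mode
  if (is.null(unit) || is.null(mode))
    .stop_class("unit and mode must be given (argument or '# unit:' / '# mode:' header)",
                "argument_error")
  if (!is.null(.valid_units[[mode]]) && !(unit %in% .valid_units[[mode]]))
    .stop_class(sprintf("unit '%s' is not valid for mode '%s'", unit, mode),
                "unit_error")
  temperature <- if (!is.null(meta$temperature)) as.numeric(meta$temperature) else NULL
  meta$unit <- meta$mode <- meta$temperature <- NULL
  meta$source <- path
  spectrum1d(vals[1, ], vals[2, ], unit = unit, mode = mode,
             temperature = temperature, metadata = meta)
}

#' Write a 1D spectrum to a two-column text or CSV file
#'
#' Lossless to at least 9 significant digits; metadata is preserved as
#' `# key: value` header comments so that `read_spectrum()` round-trips.
#'
#' @param s a [spectrum1d()].
#' @param path output path.
#' @param dialect `"two-column"` or `"csv"`.
#' @export
write_spectrum <- function(s, path, dialect = c("two-column", "csv")) {
  dialect <- match.arg(dialect)
  .check_spectrum(s)
  hdr <- c(sprintf("# unit: %s", s$unit), sprintf("# mode: %s", s$mode))
  if (!is.null(s$temperature))
    hdr <- c(hdr, sprintf("# temperature: %.10g", s$temperature))
  for (k in names(s$metadata)) {
    v <- s$metadata[[k]]
    if (is.atomic(v) && length(v) == 1L)
      hdr <- c(hdr, sprintf("# %s: %s", k, format(v, digits = 12)))
  }
  sep <- if (dialect == "csv") "," else " "
  rows <- paste(formatC(s$axis, format = "g", digits = 12),
                formatC(s$intensity, format = "g", digits = 12), sep = sep)
  out <- tryCatch(writeLines(c(hdr, rows), path),
                  error = function(e) .stop_class(
                    sprintf("cannot write %s: %s", path, conditionMessage(e)), "io_error"),
                  warning = function(w) .stop_class(
                    sprintf("cannot write %s: %s", path, conditionMessage(w)), "io_error"))
  invisible(path)
}

#' Convert the abscissa unit of a spectrum
#'
#' ppm and frequency units interconvert through the spectrometer operating
#' frequency (1 ppm at `reference_frequency` MHz equals `reference_frequency`
#' Hz). Magnetic-field (Gauss) axes never convert.
#'
#' @param s a [spectrum1d()].
#' @param target_unit one of `"kHz"`, `"Hz"`, `"ppm"`.
#' @param reference_frequency operating frequency in MHz; required whenever
#'   ppm is involved.
#' @return A [spectrum1d()] with the rescaled axis; intensity untouched.
#' @export
convert_axis <- function(s, target_unit, reference_frequency = NULL) {
  .check_spectrum(s)
  if (!target_unit %in% c("kHz", "Hz", "ppm", "Gauss"))
    .stop_class(sprintf("unknown unit '%s'", target_unit), "argument_error")
  if (identical(s$unit, target_unit)) return(s)
  if (s$unit == "Gauss" || target_unit == "Gauss")
    .stop_class("field-swept (Gauss) axes do not convert to frequency/shift units",
                "unsupported_conversion")
  needs_ref <- xor(s$unit == "ppm", target_unit == "ppm")
  if (needs_ref && is.null(reference_frequency))
    .stop_class("reference_frequency (MHz) required for ppm conversions",
                "argument_error")
  to_hz <- switch(s$unit,
                  Hz = s$axis,
                  kHz = s$axis * 1e3,
                  ppm = s$axis * reference_frequency)
  axis <- switch(target_unit,
                 Hz = to_hz,
                 kHz = to_hz / 1e3,
                 ppm = to_hz / reference_frequency)
  out <- s
  out$axis <- axis
  out$unit <- target_unit
  out$metadata$converted_from <- s$unit
  out
}

#' Read/write a keyed series table (CSV with a header row naming units)
#'
#' Series tables carry a strictly monotonic key column (molar fraction,
#' concentration, or temperature) plus observable columns; column names embed
#' the unit, e.g. `"T_K,CSA_ppm"`.
#'
#' @param path CSV path.
#' @return `read_series`: a data.frame.
#' @export
read_series <- function(path) {
  if (!file.exists(path)) .stop_class(sprintf("file not found: %s", path), "io_error")
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (ncol(df) < 2L) .stop_class("series table needs a key and one observable column",
                                 "parse_error")
  key <- df[[1]]
  if (anyNA(df)) .stop_class("missing values in series table", "parse_error")
  if (any(diff(key) <= 0) && any(diff(key) >= 0) && is.unsorted(key) && is.unsorted(rev(key)))
    .stop_class("series key column must be monotonic", "axis_error")
  df
}

#' @rdname read_series
#' @param df data.frame to write.
#' @export
write_series <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
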