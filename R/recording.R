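#' Build a unipolar recording container
#'
#' Couples a multichannel unipolar electrogram matrix with its electrode
#' grid and sampling rate. Amplitudes are stored in microvolts (uV)
#' internally; readers convert declared units on ingest.
#'
#' @param grid an `electrode_grid`.
#' @param data numeric matrix, samples x channels, with one column per grid
#'   electrode in row-major label order (`A1, A2, ..., B1, ...`). A matrix
#'   with matching but permuted column names is reordered.
#' @param fs sampling rate in Hz (> 0).
#' @param meta named list of free-form provenance (pacing rate, seed,
#'   generator parameters, ground-truth wavefront angle, ...).
#'
#' @return An object of class `unipolar_recording`: list with `grid`, `fs`,
#'   `data` (samples x channels, uV, columns named by electrode label) and
#'   `meta`.
#' @export
unipolar_recording <- function(grid, data, fs, meta = list()) {
  stopifnot(inherits(grid, "electrode_grid"))
  data <- as.matrix(data)
  n_el <- grid$rows * grid$cols
  if (ncol(data) != n_el) {
    stop(sprintf("channel/grid mismatch: %d channels but grid has %d electrodes",
                 ncol(data), n_el))
  }
  if (!is.null(colnames(data))) {
    if (!setequal(colnames(data), grid$labels)) {
      stop("channel/grid mismatch: column names do not match grid labels")
    }
    data <- data[, grid$labels, drop = FALSE]
  } else {
    colnames(data) <- grid$labels
  }
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number (Hz)")
  }
  if (!all(is.finite(data))) stop("amplitudes must be finite")
  structure(
    list(grid = grid, fs = as.numeric(fs), data = data, meta = meta),
    class = "unipolar_recording"
  )
}

#' @export
print.unipolar_recording <- function(x, ...) {
  cat(sprintf(
    "<unipolar_recording> %d channels x %d samples @ %g Hz (%.1f ms), grid %dx%d pitch %g mm\n",
    ncol(x$data), nrow(x$data), x$fs, 1000 * nrow(x$data) / x$fs,
    x$grid$rows, x$grid$cols, x$grid$pitch))
  invisible(x)
}

#' Time axis of a recording
#'
#' @param rec a `unipolar_recording`.
#' @return Sample times in ms, starting at 0.
#' @export
recording_times <- function(rec) {
  stopifnot(inherits(rec, "unipolar_recording"))
  (seq_len(nrow(rec$data)) - 1) * 1000 / rec$fs
}

unit_scale_to_uv <- function(units) {
  switch(units,
         "uV" = 1, "µV" = 1, "mV" = 1e3, "V" = 1e6,
         stop("format error in field 'units': unsupported unit '", units, "'"))
}

#' Write a recording to disk
#'
#' The on-disk container is a two-file pair designed to be inspectable and
#' language-neutral: `<path>.csv` holds the samples x channels numeric
#' matrix with a header row of electrode labels (full 17-significant-digit
#' precision), and `<path>.json` is a sidecar with `fs`, `rows`, `cols`,
#' `pitch`, `units` and the free-form `meta` list.
#'
#' @param rec a `unipolar_recording`.
#' @param path base path without extension; `.csv` and `.json` are appended.
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "unipolar_recording"))
  csv <- paste0(path, ".csv")
  side <- paste0(path, ".json")
  txt <- apply(rec$data, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(c(paste(colnames(rec$data), collapse = ","), txt), csv)
  header <- list(
    fs = rec$fs, rows = rec$grid$rows, cols = rec$grid$cols,
    pitch = rec$grid$pitch, units = "uV", meta = rec$meta
  )
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA,
                              null = "null"), side)
  invisible(path)
}

#' Read a recording from disk
#'
#' Reads the two-file container written by [write_recording()]. Amplitudes
#' declared in `mV` or `V` are converted to uV on ingest; the write/read
#' round trip reproduces the data to floating-point precision and the
#' metadata exactly.
#'
#' @param path base path without extension (expects `<path>.csv` and
#'   `<path>.json`).
#' @return A `unipolar_recording`.
#' @export
read_recording <- function(path) {
  csv <- paste0(path, ".csv")
  side <- paste0(path, ".json")
  if (!file.exists(csv)) stop("recording matrix not found: ", csv)
  if (!file.exists(side)) stop("recording sidecar not found: ", side)
  header <- jsonlite::fromJSON(readLines(side), simplifyVector = TRUE)
  for (f in c("fs", "rows", "cols", "pitch", "units")) {
    if (is.null(header[[f]])) stop("format error: sidecar missing field '", f, "'")
  }
  fs <- as.numeric(header$fs)
  if (!is.finite(fs) || fs <= 0) stop("format error in field 'fs': must be > 0")
  grid <- make_grid(header$rows, header$cols, header$pitch)
  mat <- as.matrix(utils::read.csv(csv, check.names = FALSE))
  if (ncol(mat) != grid$rows * grid$cols) {
    stop(sprintf(
      "format error in field 'data': %d channels but sidecar declares %dx%d grid",
      ncol(mat), header$rows, header$cols))
  }
  mode(mat) <- "numeric"
  if (anyNA(mat)) stop("format error in field 'data': non-numeric or missing samples")
  mat <- mat * unit_scale_to_uv(header$units)
  meta <- header$meta
  if (is.null(meta)) meta <- list()
  unipolar_recording(grid, mat, fs, as.list(meta))
}
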