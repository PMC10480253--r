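#' Construct a rectangular electrode grid
#'
#' Defines the geometry of a rows x cols multielectrode array with a fixed
#' interelectrode pitch. Rows are lettered `A`, `B`, `C`, ... from top to
#' bottom and columns numbered `1`, `2`, ... from left to right, so an
#' electrode label reads e.g. `"B3"`. The coordinate frame has x increasing
#' with the column number and y increasing towards row `A` (row `A` has the
#' greatest y, the bottom-left electrode sits at the origin). Under this
#' convention the vertical bipole `u_A1 - u_B1` points in the +y direction.
#'
#' @param rows number of electrode rows (>= 2, at most 26 for lettering).
#' @param cols number of electrode columns (>= 2).
#' @param pitch interelectrode spacing in mm (> 0).
#'
#' @return An object of class `electrode_grid`: a list with `rows`, `cols`,
#'   `pitch` (mm), `labels` (row-major character vector `A1, A2, ...`) and
#'   `positions`, a data.frame with columns `label`, `row`, `col`, `x`, `y`
#'   (mm).
#'
#' @examples
#' g <- make_grid(2, 2, 1)
#' g$positions   # A1 = (0, 1), B2 = (1, 0)
#' @export
make_grid <- function(rows, cols, pitch) {
  if (length(rows) != 1L || length(cols) != 1L || length(pitch) != 1L ||
      !is.finite(rows) || !is.finite(cols) || !is.finite(pitch)) {
    stop("invalid geometry: rows, cols and pitch must be finite scalars")
  }
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 2L || cols < 2L) {
    stop("invalid geometry: need rows >= 2 and cols >= 2 to form a clique")
  }
  if (rows > 26L) stop("invalid geometry: at most 26 lettered rows supported")
  if (pitch <= 0) stop("invalid geometry: pitch must be positive")

  ri <- rep(seq_len(rows), each = cols)
  ci <- rep(seq_len(cols), times = rows)
  labels <- paste0(LETTERS[ri], ci)
  positions <- data.frame(
    label = labels,
    row = ri,
    col = ci,
    x = (ci - 1) * pitch,
    y = (rows - ri) * pitch,
    stringsAsFactors = FALSE
  )
  structure(
    list(rows = rows, cols = cols, pitch = pitch,
         labels = labels, positions = positions),
    class = "electrode_grid"
  )
}

#' @export
print.electrode_grid <- function(x, ...) {
  cat(sprintf("<electrode_grid> %d x %d, pitch %g mm (%d electrodes)\n",
              x$rows, x$cols, x$pitch, x$rows * x$cols))
  invisible(x)
}

#' Look up electrode coordinates
#'
#' @param grid an `electrode_grid`.
#' @param labels character vector of electrode labels (e.g. `"A1"`).
#' @return A two-column matrix of (x, y) positions in mm, one row per label.
#' @export
grid_position <- function(grid, labels) {
  stopifnot(inherits(grid, "electrode_grid"))
  idx <- match(labels, grid$positions$label)
  if (anyNA(idx)) {
    stop("unknown electrode label(s): ",
         paste(labels[is.na(idx)], collapse = ", "))
  }
  cbind(x = grid$positions$x[idx], y = grid$positions$y[idx])
}

label_index <- function(grid, labels) {
  idx <- match(labels, grid$labels)
  if (anyNA(idx)) {
    stop("channel lookup failed for label(s): ",
         paste(labels[is.na(idx)], collapse = ", "))
  }
  idx
}
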