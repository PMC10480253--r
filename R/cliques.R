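#' Clique configuration names
#'
#' The five bipole arrangements of a 2x2 electrode cell: four triangular
#' configurations named by the corner carrying both bipoles (lower-left
#' `"t_ll"`, lower-right `"t_lr"`, upper-left `"t_ul"`, upper-right
#' `"t_ur"`) and the cross/diagonal configuration `"x"`.
#'
#' @format Character vector of length 5.
#' @export
CLIQUE_CONFIGS <- c("t_ll", "t_lr", "t_ul", "t_ur", "x")

#' Enumerate 2x2 cliques at a given spacing
#'
#' A clique is an axis-aligned square cell of four electrodes. Larger
#' interelectrode distances on one physical array are realised by index
#' subsampling: at spacing `k` the corners are `k` grid steps (`k * pitch`
#' mm) apart. All overlapping cliques are kept; on an `R x C` grid there
#' are `(R - k) * (C - k)` of them, returned in row-major order of the
#' top-left corner.
#'
#' Corner roles are per-clique: `a1` top-left, `a2` top-right, `b1`
#' bottom-left, `b2` bottom-right of the cell, regardless of the corners'
#' global labels.
#'
#' @param grid an `electrode_grid`.
#' @param spacing_k integer grid steps between corners (>= 1).
#' @return A data.frame with one row per clique: `clique_id`, corner labels
#'   `a1`, `a2`, `b1`, `b2`, `spacing_k`, `spacing_mm`, and the cell-centre
#'   coordinates `cx`, `cy` (mm). Zero rows when the spacing exceeds the
#'   grid.
#'
#' @examples
#' nrow(enumerate_cliques(make_grid(8, 16, 1), 1))  # 105
#' @export
enumerate_cliques <- function(grid, spacing_k) {
  stopifnot(inherits(grid, "electrode_grid"))
  spacing_k <- as.integer(spacing_k)
  if (spacing_k < 1L) stop("spacing_k must be >= 1")
  top <- seq_len(max(grid$rows - spacing_k, 0L))
  left <- seq_len(max(grid$cols - spacing_k, 0L))
  if (length(top) == 0L || length(left) == 0L) {
    return(data.frame(clique_id = character(), a1 = character(),
                      a2 = character(), b1 = character(), b2 = character(),
                      spacing_k = integer(), spacing_mm = numeric(),
                      cx = numeric(), cy = numeric(),
                      stringsAsFactors = FALSE))
  }
  ri <- rep(top, each = length(left))
  ci <- rep(left, times = length(top))
  lab <- function(r, c) paste0(LETTERS[r], c)
  a1 <- lab(ri, ci)
  out <- data.frame(
    clique_id = sprintf("%s_k%d", a1, spacing_k),
    a1 = a1,
    a2 = lab(ri, ci + spacing_k),
    b1 = lab(ri + spacing_k, ci),
    b2 = lab(ri + spacing_k, ci + spacing_k),
    spacing_k = spacing_k,
    spacing_mm = spacing_k * grid$pitch,
    cx = (ci - 1 + spacing_k / 2) * grid$pitch,
    cy = (grid$rows - ri - spacing_k / 2) * grid$pitch,
    stringsAsFactors = FALSE
  )
  out
}

#' Cartesian bipole pair of a clique
#'
#' Subtracts unipolar channels to form the orthogonal bipole pair
#' `(b_x, b_y)` of one clique under a chosen configuration. With per-cell
#' corner roles A1 (top-left), A2 (top-right), B1 (bottom-left), B2
#' (bottom-right):
#'
#' * `t_ll`: `b_x = u_B2 - u_B1`, `b_y = u_A1 - u_B1`
#' * `t_lr`: `b_x = u_B2 - u_B1`, `b_y = u_A2 - u_B2`
#' * `t_ul`: `b_x = u_A2 - u_A1`, `b_y = u_A1 - u_B1`
#' * `t_ur`: `b_x = u_A2 - u_A1`, `b_y = u_A2 - u_B2`
#' * `x`:    diagonals `b_1 = u_A2 - u_B1`, `b_2 = u_A1 - u_B2`, then a
#'   counterclockwise pi/4 rotation aligns the diagonal frame with the
#'   Cartesian axes:
#'   `b_x = cos(pi/4) b_1 - sin(pi/4) b_2`,
#'   `b_y = sin(pi/4) b_1 + cos(pi/4) b_2`.
#'
#' The rotation preserves the per-sample Euclidean norm; no renormalisation
#' of the sqrt(2)-longer diagonal baseline is applied (the effective bipole
#' spacing of `x` is `sqrt(2) * spacing_mm`, reported in the result).
#'
#' @param rec a `unipolar_recording`.
#' @param clique one row of [enumerate_cliques()] (or a list with `a1`,
#'   `a2`, `b1`, `b2`, `spacing_mm`).
#' @param config one of `"t_ll"`, `"t_lr"`, `"t_ul"`, `"t_ur"`, `"x"`.
#' @return An object of class `bipole_pair`: list with `b_x`, `b_y` (uV
#'   series), `raw_diagonals` (list `b_1`, `b_2`; `x` only, else NULL),
#'   `config`, `clique`, `bipole_spacing_mm` and `fs`.
#' @export
clique_bipoles <- function(rec, clique, config) {
  stopifnot(inherits(rec, "unipolar_recording"))
  config <- match.arg(config, CLIQUE_CONFIGS)
  if (is.data.frame(clique)) {
    stopifnot(nrow(clique) == 1L)
    clique <- as.list(clique)
  }
  idx <- label_index(rec$grid, c(clique$a1, clique$a2, clique$b1, clique$b2))
  uA1 <- rec$data[, idx[1]]; uA2 <- rec$data[, idx[2]]
  uB1 <- rec$data[, idx[3]]; uB2 <- rec$data[, idx[4]]

  raw <- NULL
  spacing <- clique$spacing_mm
  if (config == "t_ll") {
    b_x <- uB2 - uB1; b_y <- uA1 - uB1
  } else if (config == "t_lr") {
    b_x <- uB2 - uB1; b_y <- uA2 - uB2
  } else if (config == "t_ul") {
    b_x <- uA2 - uA1; b_y <- uA1 - uB1
  } else if (config == "t_ur") {
    b_x <- uA2 - uA1; b_y <- uA2 - uB2
  } else {
    b_1 <- uA2 - uB1
    b_2 <- uA1 - uB2
    c45 <- cos(pi / 4); s45 <- sin(pi / 4)
    b_x <- c45 * b_1 - s45 * b_2
    b_y <- s45 * b_1 + c45 * b_2
    raw <- list(b_1 = b_1, b_2 = b_2)
    spacing <- clique$spacing_mm * sqrt(2)
  }
  structure(
    list(b_x = b_x, b_y = b_y, raw_diagonals = raw,
         config = config, clique = clique,
         bipole_spacing_mm = spacing, fs = rec$fs),
    class = "bipole_pair"
  )
}

#' @export
print.bipole_pair <- function(x, ...) {
  cat(sprintf("<bipole_pair> config %s, clique %s, %d samples, bipole spacing %.3g mm\n",
              x$config, x$clique$clique_id %||% "?", length(x$b_x),
              x$bipole_spacing_mm))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
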