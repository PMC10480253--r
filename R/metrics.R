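#' oEGM-to-residuum ratio (ORR)
#'
#' Ratio between the signed peak amplitude of the estimated omnipole
#' `o_hat(t)` and the peak absolute amplitude of the residual `r(t)` over
#' the analysis window. Higher is better: a reliable omnipole concentrates
#' the activation energy along the propagation direction and leaves little
#' in the orthogonal residual.
#'
#' @param est an `omnipole_estimate`.
#' @param window optional integer sample indices (default: whole series).
#' @param eps_rel relative floor on the residual peak; below it the ratio
#'   is returned capped with attribute `degenerate = TRUE`.
#' @return A single dimensionless ratio; attribute `degenerate` flags a
#'   capped (essentially zero-residual) result.
#' @export
orr <- function(est, window = NULL, eps_rel = 1e-9) {
  o <- est$o_hat; r <- est$residual
  if (!is.null(window)) { o <- o[window]; r <- r[window] }
  scale <- max(abs(o), abs(r))
  if (scale == 0) stop("degenerate input: omnipole and residual both zero")
  peak_o <- max(o)
  peak_r <- max(abs(r))
  degenerate <- peak_r <= eps_rel * scale
  out <- peak_o / max(peak_r, eps_rel * scale)
  attr(out, "degenerate") <- degenerate
  out
}

#' Area enclosed by a planar loop trajectory
#'
#' Area of the closed polyline `(x_n, y_n)` via trapezoidal integration of
#' the Green's-theorem line integral `0.5 * |sum(x dy - y dx)|`, with the
#' final segment closing the loop back to the first point. For a
#' self-intersecting loop this is the magnitude of the net signed area.
#' Collinear trajectories have zero area; fewer than 3 points are
#' degenerate and return 0 with attribute `degenerate = TRUE`.
#'
#' @param x,y numeric coordinate vectors of equal length, or `x` a
#'   two-column matrix.
#' @return The enclosed area (units of x*y).
#'
#' @examples
#' loop_area(c(0, 1, 1, 0), c(0, 0, 1, 1))  # unit square: 1
#' @export
loop_area <- function(x, y = NULL) {
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  nxt <- c(seq_len(n)[-1], 1L)
  dx <- x[nxt] - x
  dy <- y[nxt] - y
  # trapezoidal x dy - y dx over each segment: midpoint coordinates
  xm <- (x + x[nxt]) / 2
  ym <- (y + y[nxt]) / 2
  out <- abs(sum(xm * dy - ym * dx)) / 2
  attr(out, "degenerate") <- FALSE
  out
}

#' Normalised loop area (NLA)
#'
#' Area of the electric-field loop traced by the bipole pair in the
#' `b_x`-`b_y` plane after normalising both components by the peak
#' omnipole amplitude `P = max(o_hat)`. A planar homogeneous wave crossing
#' an infinitesimally small clique traces a straight line (area 0); wider
#' loops indicate delayed, less reliable bipole pairs, so lower NLA is
#' better. Invariant to jointly rescaling `b_x`, `b_y` and `o_hat`.
#'
#' @param pair a `bipole_pair`.
#' @param est the `omnipole_estimate` obtained from `pair` (supplies the
#'   normalisation peak).
#' @param window optional integer sample indices.
#' @param eps_rel relative floor below which the peak is considered zero.
#' @return Dimensionless area; attribute `undefined = TRUE` when the peak
#'   omnipole amplitude is not positive.
#' @export
nla <- function(pair, est, window = NULL, eps_rel = 1e-12) {
  bx <- pair$b_x; by <- pair$b_y; o <- est$o_hat
  if (!is.null(window)) { bx <- bx[window]; by <- by[window]; o <- o[window] }
  P <- max(o)
  if (!is.finite(P) || P <= eps_rel * max(abs(bx), abs(by), 1e-300)) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  out <- loop_area(bx / P, by / P)
  attributes(out) <- NULL
  attr(out, "undefined") <- FALSE
  out
}

#' Pulse width (PW)
#'
#' Elapsed time between the leading and trailing edges of the omnipole's
#' dominant deflection: the first and last crossings of
#' `threshold_frac * peak` within the window, located with linear
#' sub-sample interpolation. For a clean unimodal pulse at the default
#' threshold 0.5 this is the full width at half maximum; merged or notched
#' activations (delayed subtractions) widen it. Shorter is better.
#'
#' @param est an `omnipole_estimate` (or list with `o_hat` and `fs`).
#' @param threshold_frac fraction of the peak defining the edges, in (0, 1).
#' @param window optional integer sample indices.
#' @return Width in ms; attribute `undefined = TRUE` (value `NA`) when the
#'   omnipole has no positive peak.
#' @export
pulse_width <- function(est, threshold_frac = 0.5, window = NULL) {
  stopifnot(threshold_frac > 0, threshold_frac < 1)
  o <- est$o_hat
  if (!is.null(window)) o <- o[window]
  peak <- max(o)
  if (!is.finite(peak) || peak <= 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  thr <- threshold_frac * peak
  above <- o >= thr
  idx <- which(above)
  first <- idx[1]; last <- idx[length(idx)]
  # linear interpolation of the crossing instants, in samples
  t_first <- if (first > 1) {
    (first - 1) + (thr - o[first - 1]) / (o[first] - o[first - 1]) - 1
  } else 0
  t_last <- if (last < length(o)) {
    (last - 1) + (thr - o[last]) / (o[last + 1] - o[last])
  } else length(o) - 1
  out <- (t_last - t_first) * 1000 / est$fs
  attr(out, "undefined") <- FALSE
  out
}

#' Derivative-based reference omnipole
#'
#' Under planar homogeneous propagation with identical unipolar waveforms,
#' the true omnipole at a site equals the negative time derivative of the
#' unipolar electrogram there. This builds a clique-level reference: each
#' corner's `-du/dt` (central differences, one-sided at the ends, in
#' uV/ms), aligned to the first corner by integer-lag cross-correlation
#' and averaged. Averaging the four aligned derivatives also attenuates
#' common interference and independent channel noise (by about a factor 2
#' for 4 independent channels).
#'
#' @param rec a `unipolar_recording`.
#' @param clique one row of [enumerate_cliques()].
#' @param window optional integer sample indices; alignment and averaging
#'   are performed inside it.
#' @param max_lag_frac maximum allowed alignment lag as a fraction of the
#'   window length; beyond it the channel is flagged.
#' @return An object of class `reference_omnipole`: list with `o_ref`
#'   (uV/ms series over the window), `o_ij` (4-column matrix of unaligned
#'   per-electrode derivatives), `lags` (samples, relative to corner a1),
#'   `alignment_ok` (logical, per corner), `fs`, `window`.
#' @export
reference_omnipole <- function(rec, clique, window = NULL,
                               max_lag_frac = 0.5) {
  stopifnot(inherits(rec, "unipolar_recording"))
  if (is.data.frame(clique)) {
    stopifnot(nrow(clique) == 1L)
    clique <- as.list(clique)
  }
  idx <- label_index(rec$grid, c(clique$a1, clique$a2, clique$b1, clique$b2))
  if (is.null(window)) window <- seq_len(nrow(rec$data))
  u <- rec$data[window, idx, drop = FALSE]
  n <- nrow(u)
  # -du/dt, uV/ms
  o_ij <- apply(u, 2, function(col) -central_diff(col) * rec$fs / 1000)
  max_lag <- floor(max_lag_frac * n)
  lags <- integer(4)
  ok <- rep(TRUE, 4)
  aligned <- o_ij
  for (k in 2:4) {
    lag <- best_xcorr_lag(o_ij[, 1], o_ij[, k], max_lag)
    lags[k] <- lag
    if (abs(lag) >= max_lag) ok[k] <- FALSE
    aligned[, k] <- shift_series(o_ij[, k], lag)
  }
  o_ref <- rowMeans(aligned[, ok, drop = FALSE])
  structure(
    list(o_ref = o_ref, o_ij = o_ij, lags = lags, alignment_ok = ok,
         fs = rec$fs, window = window),
    class = "reference_omnipole"
  )
}

central_diff <- function(x) {
  n <- length(x)
  d <- numeric(n)
  if (n < 2) return(d)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  d[1] <- x[2] - x[1]
  d[n] <- x[n] - x[n - 1]
  d
}

best_xcorr_lag <- function(ref, x, max_lag) {
  # integer lag maximising sum(ref[t] * x[t + lag])
  n <- length(ref)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(l) {
    if (l >= 0) sum(ref[seq_len(n - l)] * x[seq_len(n - l) + l])
    else sum(ref[seq_len(n + l) - l] * x[seq_len(n + l)])
  }, numeric(1))
  lags[which.max(cc)]
}

shift_series <- function(x, lag) {
  # shift so that x_shifted[t] = x[t + lag]; zero-padded ends
  n <- length(x)
  out <- numeric(n)
  if (lag >= 0) out[seq_len(n - lag)] <- x[seq_len(n - lag) + lag]
  else out[seq_len(n + lag) - lag] <- x[seq_len(n + lag)]
  out
}

#' Morphology distortion (MD)
#'
#' Root-mean-squared error between the estimated omnipole and the
#' derivative-based reference after normalising each signal by its own
#' peak absolute amplitude (scale is removed; shape differences remain).
#' By default the two normalised signals are time-aligned at their
#' dominant (maximum absolute) peaks before the RMSE; cross-correlation
#' alignment or no alignment can be selected. Symmetric in its two inputs
#' and exactly 0 for identical or rescaled signals. Lower is better.
#'
#' @param est an `omnipole_estimate`.
#' @param ref a `reference_omnipole` (or any list with an `o_ref` series
#'   over the same window).
#' @param window optional integer sample indices into the estimate series;
#'   must have the same length as `ref$o_ref` when given.
#' @param align `"peak"` (default), `"xcorr"` or `"none"`.
#' @return Dimensionless RMSE; attribute `undefined = TRUE` when either
#'   signal is identically zero.
#' @export
morphology_distortion <- function(est, ref, window = NULL,
                                  align = c("peak", "xcorr", "none")) {
  align <- match.arg(align)
  o <- est$o_hat
  if (!is.null(window)) o <- o[window]
  r <- ref$o_ref
  if (length(o) != length(r)) {
    stop("estimate window and reference must have the same length")
  }
  po <- max(abs(o)); pr <- max(abs(r))
  if (po == 0 || pr == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  o <- o / po; r <- r / pr
  lag <- switch(align,
    none = 0L,
    peak = which.max(abs(r)) - which.max(abs(o)),
    xcorr = best_xcorr_lag(o, r, floor(length(o) / 2))
  )
  r_al <- shift_series(r, lag)
  keep <- if (lag >= 0) seq_len(length(o) - lag) else seq_len(length(o) + lag) - lag
  out <- sqrt(mean((o[keep] - r_al[keep])^2))
  attr(out, "undefined") <- FALSE
  out
}
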