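# Independent oracles and small fixtures shared across tests.

# Classic shoelace polygon area: sum of cross products of consecutive
# vertices. Algebraically equal to the package's trapezoidal Green's-theorem
# line integral, but computed by a different route.
shoelace_area <- function(x, y) {
  n <- length(x)
  nxt <- c(2:n, 1L)
  abs(sum(x * y[nxt] - x[nxt] * y)) / 2
}

# Random simple (star-shaped) polygon around the origin.
random_polygon <- function(n_vertices) {
  ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
  rad <- stats::runif(n_vertices, 0.2, 2)
  list(x = rad * cos(ang), y = rad * sin(ang))
}

# Exhaustive search of the projection-ratio objective on a fixed angle
# grid; plain per-angle evaluation, independent of the package's search.
exhaustive_theta <- function(bx, by, step_deg = 0.01, eps_rel = 1e-9) {
  th <- seq(-pi, pi - step_deg * pi / 180, by = step_deg * pi / 180)
  floor_den <- eps_rel * max(abs(bx), abs(by))
  best_v <- -Inf; best_t <- NA_real_
  # chunked to keep memory flat; max over time computed per angle
  for (start in seq(1, length(th), by = 4000)) {
    tt <- th[start:min(start + 3999, length(th))]
    O <- outer(cos(tt), bx) - outer(sin(tt), by)
    R <- abs(outer(sin(tt), bx) + outer(cos(tt), by))
    num <- apply(O, 1, max)
    den <- pmax(apply(R, 1, max), floor_den)
    v <- num / den
    i <- which.max(v)
    if (v[i] > best_v) { best_v <- v[i]; best_t <- tt[i] }
  }
  list(theta = best_t, value = best_v)
}

# Random smooth bipole pair: moving-average filtered white noise, with an
# optional near-proportional mode that exercises the residual-dip regime.
random_pair <- function(n = 80, proportional = FALSE) {
  smooth <- function() {
    as.numeric(stats::filter(stats::rnorm(n + 10), rep(1 / 5, 5),
                             sides = 2))[6:(n + 5)]
  }
  bx <- smooth()
  by <- if (proportional) {
    stats::runif(1, -2, 2) * bx + 0.01 * smooth()
  } else {
    smooth()
  }
  structure(list(b_x = bx, b_y = by, config = "t_ll",
                 clique = list(clique_id = "synthetic"), fs = 1000),
            class = "bipole_pair")
}

# Circular distance between two directions in degrees.
circ_err_deg <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# Template bipole pair aligned with a known angle. The pulse has a
# dominant positive peak (like an omnipole activation), so the signed-max
# numerator disambiguates the 180-degree direction.
template_pair <- function(ratio_y_over_x = 0, n = 201, width_ms = 2) {
  t_ms <- seq(-10, 10, length.out = n)
  w <- 1000 * exp(-t_ms^2 / (2 * width_ms^2)) * (1 - t_ms^2 / width_ms^2)
  structure(list(b_x = w, b_y = ratio_y_over_x * w, config = "t_ll",
                 clique = list(clique_id = "synthetic"), fs = 1000),
            class = "bipole_pair")
}

default_grid <- function() make_grid(8, 16, 1)

# One-beat noiseless planar recording at a given angle, default conditions.
planar_rec <- function(psi, ...) {
  generate_planar_wave(default_grid(),
                       planar_wave_params(psi_w_deg = psi, n_beats = 1, ...))
}

# Direction estimate for one clique/config of a recording.
estimate_direction <- function(rec, clique, config = "x") {
  w <- segment_activations(rec)
  pair <- clique_bipoles(rec, clique, config)
  estimate_omnipole(pair, window = w$start[1]:w$end[1])$direction_deg
}
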