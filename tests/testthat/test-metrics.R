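fake_estimate <- function(o_hat, residual = NULL, fs = 1000) {
  structure(list(o_hat = o_hat,
                 residual = residual %||% numeric(length(o_hat)),
                 theta_o = 0, fs = fs),
            class = "omnipole_estimate")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("ORR is the peak quotient with a capped degenerate branch", {
  t_ms <- seq(-10, 10, by = 1)
  o <- 2 * exp(-t_ms^2 / 8)
  r <- 0.5 * sin(t_ms)
  v <- orr(fake_estimate(o, r))
  expect_equal(as.numeric(v), max(o) / max(abs(r)))
  expect_equal(as.numeric(orr(fake_estimate(c(0, 2, 0), c(0, -0.5, 0.3)))), 4)
  expect_false(attr(v, "degenerate"))

  v0 <- orr(fake_estimate(o, numeric(21)))
  expect_true(attr(v0, "degenerate"))
  expect_gt(as.numeric(v0), 1e8)

  # ORR is maximal at the optimised angle (restatement of the objective)
  set.seed(21)
  p <- random_pair(100)
  est <- estimate_theta(p)
  best <- as.numeric(orr(project_omnipole(p, est$theta_o)))
  for (th in seq(-pi, pi, length.out = 73)) {
    expect_lte(as.numeric(orr(project_omnipole(p, th))), best * (1 + 1e-9))
  }
})

test_that("loop_area matches known polygon areas and flags degenerate input", {
  expect_equal(as.numeric(loop_area(c(0, 1, 1, 0), c(0, 0, 1, 1))), 1)
  # collinear trajectory
  x <- seq(-3, 3, by = 0.1)
  expect_equal(as.numeric(loop_area(x, 0.7 * x)), 0)
  # ellipse, 3600 samples
  phi <- seq(0, 2 * pi, length.out = 3601)[-3601]
  expect_equal(as.numeric(loop_area(cos(phi), 0.5 * sin(phi))),
               pi * 0.5, tolerance = 1e-4 / (pi * 0.5))
  d <- loop_area(c(0, 1), c(0, 1))
  expect_equal(as.numeric(d), 0)
  expect_true(attr(d, "degenerate"))
})

test_that("loop_area agrees with the shoelace oracle on random polygons", {
  set.seed(22)
  for (i in 1:200) {
    p <- random_polygon(sample(3:40, 1))
    a <- as.numeric(loop_area(p$x, p$y))
    b <- shoelace_area(p$x, p$y)
    expect_lt(abs(a - b) / b, 1e-9)
  }
})

test_that("NLA: proportional bipoles are 0, quadrature pair gives pi", {
  w <- unipolar_waveform(seq(-10, 10, by = 0.1))
  pair <- structure(list(b_x = w, b_y = 0.3 * w, fs = 1000),
                    class = "bipole_pair")
  est <- fake_estimate(w)
  expect_equal(as.numeric(nla(pair, est)), 0)

  # unit-circle loop normalised by its own peak
  phi <- seq(0, 2 * pi, length.out = 1001)[-1001]
  P <- 3.7
  qpair <- structure(list(b_x = P * cos(phi), b_y = P * sin(phi), fs = 1000),
                     class = "bipole_pair")
  qest <- fake_estimate(P * cos(phi))
  expect_equal(as.numeric(nla(qpair, qest)), pi, tolerance = 1e-4)

  # invariant under joint positive rescaling
  for (s in c(0.01, 1, 250)) {
    spair <- structure(list(b_x = s * qpair$b_x, b_y = s * qpair$b_y,
                            fs = 1000), class = "bipole_pair")
    expect_equal(as.numeric(nla(spair, fake_estimate(s * P * cos(phi)))),
                 as.numeric(nla(qpair, qest)), tolerance = 1e-12)
  }

  # non-positive peak omnipole is undefined
  u <- nla(qpair, fake_estimate(-abs(cos(phi)) - 1))
  expect_true(attr(u, "undefined"))
  expect_true(is.na(as.numeric(u)))
})

test_that("pulse width reproduces closed forms and shift/scale invariance", {
  fs <- 1000
  t_ms <- seq(0, 100, by = 1000 / fs)
  # symmetric triangular pulse, base 10 ms -> half-height width 5 ms
  tri <- pmax(0, 1 - abs(t_ms - 50) / 5)
  expect_equal(as.numeric(pulse_width(fake_estimate(tri, fs = fs))), 5,
               tolerance = 1e-9)
  # Gaussian: FWHM = 2 sigma sqrt(2 ln 2)
  for (sigma in c(2, 4)) {
    gauss <- exp(-(t_ms - 50)^2 / (2 * sigma^2))
    expect_equal(as.numeric(pulse_width(fake_estimate(gauss, fs = fs))),
                 2 * sigma * sqrt(2 * log(2)), tolerance = 1000 / fs)
  }
  # amplitude scaling and time shift do not change PW
  g1 <- exp(-(t_ms - 30)^2 / 8)
  g2 <- 17 * exp(-(t_ms - 60)^2 / 8)
  expect_equal(as.numeric(pulse_width(fake_estimate(g1, fs = fs))),
               as.numeric(pulse_width(fake_estimate(g2, fs = fs))),
               tolerance = 1e-9)
  # summed delayed copies widen the pulse
  one <- exp(-(t_ms - 40)^2 / 8)
  two <- one + exp(-(t_ms - 52)^2 / 8)
  expect_gt(as.numeric(pulse_width(fake_estimate(two, fs = fs))),
            as.numeric(pulse_width(fake_estimate(one, fs = fs))))
  # no positive peak -> undefined
  u <- pulse_width(fake_estimate(-exp(-(t_ms - 50)^2 / 8), fs = fs))
  expect_true(attr(u, "undefined"))
})

test_that("reference omnipole averages aligned derivatives", {
  g <- make_grid(2, 2, 1)
  fs <- 1000
  t_ms <- seq(0, 120, by = 1000 / fs)
  w <- unipolar_waveform(t_ms - 60)
  # four identical channels: o_ref = -du/dt of any one
  rec <- unipolar_recording(g, cbind(A1 = w, A2 = w, B1 = w, B2 = w), fs)
  cl <- enumerate_cliques(g, 1)
  ref <- reference_omnipole(rec, cl)
  d1 <- -omnipolar:::central_diff(w) * fs / 1000
  expect_equal(ref$o_ref, d1)
  expect_equal(ref$lags, rep(0L, 4))

  # four delayed copies: alignment recovers the common derivative shape
  delays <- c(0, 3, 5, 8)
  u <- sapply(delays, function(d) unipolar_waveform(t_ms - 60 - d))
  colnames(u) <- c("A1", "A2", "B1", "B2")
  rec2 <- unipolar_recording(g, u, fs)
  ref2 <- reference_omnipole(rec2, cl)
  expect_equal(ref2$lags, as.integer(delays))
  core <- 20:100   # away from zero-padded edges
  expect_equal(ref2$o_ref[core], d1[core], tolerance = 1e-6)
})

test_that("averaging four channels halves independent noise", {
  g <- make_grid(2, 2, 1)
  fs <- 1000
  t_ms <- seq(0, 120, by = 1000 / fs)
  w <- unipolar_waveform(t_ms - 60)
  set.seed(33)
  sd_single <- sd_avg <- numeric(60)
  for (i in 1:60) {
    u <- sapply(1:4, function(k) w + rnorm(length(w), 0, 30))
    colnames(u) <- c("A1", "A2", "B1", "B2")
    rec <- unipolar_recording(g, u, fs)
    ref <- reference_omnipole(rec, enumerate_cliques(g, 1))
    quiet <- 1:30   # pre-activation segment: noise only
    sd_avg[i] <- sd(ref$o_ref[quiet])
    sd_single[i] <- sd(ref$o_ij[quiet, 1])
  }
  expect_equal(mean(sd_single) / mean(sd_avg), 2, tolerance = 0.15)
})

test_that("morphology distortion is zero for rescaled signals, symmetric, shift-exact", {
  t_ms <- seq(0, 100, by = 1)
  o <- exp(-(t_ms - 50)^2 / 18) - 0.4 * exp(-(t_ms - 58)^2 / 30)
  est <- fake_estimate(o)
  expect_equal(as.numeric(morphology_distortion(est, list(o_ref = o))), 0)
  expect_equal(as.numeric(morphology_distortion(est, list(o_ref = 3 * o))), 0)

  # symmetry in the two normalised arguments
  r <- exp(-(t_ms - 47)^2 / 25)
  m1 <- morphology_distortion(est, list(o_ref = r))
  m2 <- morphology_distortion(fake_estimate(r), list(o_ref = o))
  expect_equal(as.numeric(m1), as.numeric(m2), tolerance = 1e-12)

  # known shift with alignment disabled equals the closed-form RMS
  shift <- 7
  o2 <- exp(-(t_ms - 50 - shift)^2 / 18)
  o1 <- exp(-(t_ms - 50)^2 / 18)
  md_none <- morphology_distortion(fake_estimate(o1), list(o_ref = o2),
                                   align = "none")
  expect_equal(as.numeric(md_none), sqrt(mean((o1 - o2)^2)),
               tolerance = 1e-12)
  # peak alignment removes the shift entirely
  md_peak <- morphology_distortion(fake_estimate(o1), list(o_ref = o2),
                                   align = "peak")
  expect_lt(as.numeric(md_peak), 1e-10)

  u <- morphology_distortion(fake_estimate(numeric(101)), list(o_ref = o))
  expect_true(attr(u, "undefined"))
})
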