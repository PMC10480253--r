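#' Segment per-beat activation windows
#'
#' Splits a paced recording into one analysis window per beat, either from
#' known pacing metadata (windows centred on the expected activation times
#' `beat_t0 + mean delay`, as recorded by the synthetic generator) or by
#' detection: the array-mean absolute derivative `mean_ij |du_ij/dt|` is
#' thresholded and peaks separated by a refractory period of half the
#' pacing period become beat centres.
#'
#' @param rec a `unipolar_recording`.
#' @param policy `"meta"` (use generator metadata; falls back to detection
#'   with a warning if absent) or `"detect"`.
#' @param half_width_ms half-width of each window in ms.
#' @param threshold_frac detection threshold as a fraction of the peak
#'   array-mean absolute derivative.
#' @return A data.frame with one row per beat: `beat`, `start`, `end`
#'   (half-open sample range, 1-based), `centre_ms`, `score`. Zero rows
#'   (with a warning) when nothing is detected.
#' @export
segment_activations <- function(rec, policy = c("meta", "detect"),
                                half_width_ms = 60, threshold_frac = 0.5) {
  policy <- match.arg(policy)
  n <- nrow(rec$data)
  hw <- round(half_width_ms * rec$fs / 1000)

  if (policy == "meta") {
    if (is.null(rec$meta$beat_t0_ms)) {
      warning("no pacing metadata found; falling back to derivative detection")
      policy <- "detect"
    } else {
      centre_ms <- unlist(rec$meta$beat_t0_ms) +
        (rec$meta$mean_delay_ms %||% 0)
      score <- rep(NA_real_, length(centre_ms))
    }
  }
  if (policy == "detect") {
    dabs <- abs(apply(rec$data, 2, central_diff)) * rec$fs / 1000
    act <- rowMeans(dabs)
    if (max(act) <= 0) {
      warning("no activation found in recording")
      return(data.frame(beat = integer(), start = integer(), end = integer(),
                        centre_ms = numeric(), score = numeric()))
    }
    thr <- threshold_frac * max(act)
    pacing_hz <- rec$meta$pacing_hz %||% 4
    refractory <- round(0.5 * rec$fs / pacing_hz)
    centres <- integer(0)
    score <- numeric(0)
    cand <- order(act, decreasing = TRUE)
    for (i in cand) {
      if (act[i] < thr) break
      if (length(centres) == 0 || all(abs(centres - i) >= refractory)) {
        centres <- c(centres, i)
        score <- c(score, act[i])
      }
    }
    ord <- order(centres)
    centres <- centres[ord]; score <- score[ord]
    centre_ms <- (centres - 1) * 1000 / rec$fs
  }
  if (length(centre_ms) == 0) {
    warning("no activation found in recording")
    return(data.frame(beat = integer(), start = integer(), end = integer(),
                      centre_ms = numeric(), score = numeric()))
  }
  centre <- round(centre_ms * rec$fs / 1000) + 1L
  start <- pmax(centre - hw, 1L)
  end <- pmin(centre + hw, n)
  keep <- start < end
  data.frame(beat = seq_len(sum(keep)), start = start[keep], end = end[keep],
             centre_ms = centre_ms[keep], score = score[keep])
}

#' Evaluate omnipole reliability over recordings, configurations, spacings
#'
#' Full factorial sweep: for every recording x spacing x clique x
#' configuration x beat, the bipole pair is built, the projection angle
#' estimated on the beat window, and ORR, NLA, PW and MD computed. Rows
#' never abort the sweep: degenerate or undefined cells are flagged in the
#' `flags` column and carry `NA` where the metric is undefined.
#'
#' @param recs a `unipolar_recording` or list of them (optionally named;
#'   names become `rec_id`).
#' @param configs character vector of clique configurations, see
#'   [CLIQUE_CONFIGS].
#' @param spacings integer vector of clique spacings in grid steps.
#' @param window_policy,half_width_ms passed to [segment_activations()].
#' @param max_cliques optional cap on the number of cliques per
#'   (recording, spacing) cell, taken evenly spaced over the row-major
#'   enumeration (keeps large sweeps tractable); `Inf` keeps all.
#' @param pw_threshold_frac pulse-width edge threshold.
#' @return A tidy data.frame, one row per
#'   (rec_id, clique_id, config, spacing, beat): columns `rec_id`,
#'   `clique_id`, `config`, `spacing_k`, `spacing_mm`,
#'   `bipole_spacing_mm`, `beat`, `theta_o`, `direction_deg`, `ratio`,
#'   `orr`, `nla`, `pw_ms`, `md`, `flags` (`;`-separated, empty when
#'   clean).
#' @export
evaluate_recordings <- function(recs, configs = CLIQUE_CONFIGS,
                                spacings = 1:4,
                                window_policy = "meta",
                                half_width_ms = 60,
                                max_cliques = Inf,
                                pw_threshold_frac = 0.5) {
  if (inherits(recs, "unipolar_recording")) recs <- list(recs)
  if (is.null(names(recs))) {
    names(recs) <- sprintf("rec%02d", seq_along(recs))
  }
  configs <- match.arg(configs, CLIQUE_CONFIGS, several.ok = TRUE)
  out <- vector("list", 0L)
  for (rid in names(recs)) {
    rec <- recs[[rid]]
    windows <- segment_activations(rec, policy = window_policy,
                                   half_width_ms = half_width_ms)
    for (k in spacings) {
      cl <- enumerate_cliques(rec$grid, k)
      if (nrow(cl) == 0) next
      if (is.finite(max_cliques) && nrow(cl) > max_cliques) {
        pick <- unique(round(seq(1, nrow(cl), length.out = max_cliques)))
        cl <- cl[pick, , drop = FALSE]
      }
      for (ci in seq_len(nrow(cl))) {
        clique <- cl[ci, ]
        for (cfg in configs) {
          pair <- clique_bipoles(rec, clique, cfg)
          for (bi in seq_len(nrow(windows))) {
            win <- windows$start[bi]:windows$end[bi]
            out[[length(out) + 1L]] <-
              eval_one(rec, pair, clique, cfg, rid, bi, win,
                       pw_threshold_frac)
          }
        }
      }
    }
  }
  if (length(out) == 0) {
    stop("empty sweep: no cliques fit the requested spacings")
  }
  do.call(rbind, out)
}

eval_one <- function(rec, pair, clique, cfg, rid, beat, win,
                     pw_threshold_frac) {
  flags <- character(0)
  row <- data.frame(
    rec_id = rid, clique_id = clique$clique_id, config = cfg,
    spacing_k = clique$spacing_k, spacing_mm = clique$spacing_mm,
    bipole_spacing_mm = pair$bipole_spacing_mm, beat = beat,
    theta_o = NA_real_, direction_deg = NA_real_, ratio = NA_real_,
    orr = NA_real_, nla = NA_real_, pw_ms = NA_real_, md = NA_real_,
    flags = "", stringsAsFactors = FALSE
  )
  est <- tryCatch(estimate_omnipole(pair, window = win),
                  error = function(e) NULL)
  if (is.null(est)) {
    row$flags <- "degenerate_pair"
    return(row)
  }
  row$theta_o <- est$theta_o
  row$direction_deg <- est$direction_deg
  row$ratio <- est$ratio_at_optimum
  if (isTRUE(est$capped)) flags <- c(flags, "orr_capped")

  v <- orr(est, window = win)
  row$orr <- as.numeric(v)
  if (isTRUE(attr(v, "degenerate"))) flags <- c(flags, "orr_degenerate")

  v <- nla(pair, est, window = win)
  row$nla <- as.numeric(v)
  if (isTRUE(attr(v, "undefined"))) flags <- c(flags, "nla_undefined")

  v <- pulse_width(est, threshold_frac = pw_threshold_frac, window = win)
  row$pw_ms <- as.numeric(v)
  if (isTRUE(attr(v, "undefined"))) flags <- c(flags, "pw_undefined")

  ref <- tryCatch(reference_omnipole(rec, clique, window = win),
                  error = function(e) NULL)
  if (is.null(ref)) {
    flags <- c(flags, "ref_failed")
  } else {
    if (!all(ref$alignment_ok)) flags <- c(flags, "alignment_failure")
    v <- morphology_distortion(est, ref, window = win)
    row$md <- as.numeric(v)
    if (isTRUE(attr(v, "undefined"))) flags <- c(flags, "md_undefined")
  }
  row$flags <- paste(flags, collapse = ";")
  row
}

#' Summarise a metrics table
#'
#' Aggregates the tidy table of [evaluate_recordings()] into one row per
#' (config, spacing, metric) with mean, SD, median, IQR and n, mirroring a
#' per-configuration x per-distance results table. Rows whose `flags`
#' mark the metric as degenerate/undefined (or whose value is `NA`) are
#' excluded from that metric's cell; cells left empty are dropped with a
#' warning.
#'
#' @param table output of [evaluate_recordings()].
#' @param metrics which metric columns to summarise.
#' @return A data.frame with columns `config`, `spacing_mm`, `metric`,
#'   `mean`, `sd`, `median`, `iqr`, `n`.
#' @export
aggregate_metrics <- function(table,
                              metrics = c("orr", "nla", "pw_ms", "md")) {
  if (nrow(table) == 0) stop("empty metrics table")
  bad_flag <- list(
    orr = c("orr_capped", "orr_degenerate", "degenerate_pair"),
    nla = c("nla_undefined", "degenerate_pair"),
    pw_ms = c("pw_undefined", "degenerate_pair"),
    md = c("md_undefined", "ref_failed", "alignment_failure",
           "degenerate_pair")
  )
  flag_list <- strsplit(table$flags, ";", fixed = TRUE)
  cells <- unique(table[, c("config", "spacing_mm")])
  cells <- cells[order(cells$config, cells$spacing_mm), ]
  out <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- table$config == cells$config[i] &
      table$spacing_mm == cells$spacing_mm[i]
    for (m in metrics) {
      drop <- vapply(flag_list[sel],
                     function(f) any(f %in% bad_flag[[m]]), logical(1))
      v <- table[[m]][sel][!drop]
      v <- v[is.finite(v)]
      if (length(v) == 0) {
        warning(sprintf("all values flagged for %s / %g mm / %s; cell omitted",
                        cells$config[i], cells$spacing_mm[i], m))
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        config = cells$config[i], spacing_mm = cells$spacing_mm[i],
        metric = m, mean = mean(v), sd = stats::sd(v),
        median = stats::median(v),
        iqr = stats::IQR(v), n = length(v), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Run the default synthetic reliability sweep
#'
#' The package's standard validation experiment: one synthetic planar-wave
#' recording per wavefront angle, evaluated over all five clique
#' configurations and a range of interelectrode spacings. The default
#' angle set covers the circle every 15 degrees but is offset by 7.5
#' degrees from the grid symmetry axes: at exact multiples of 45 degrees a
#' noiseless planar wave makes one diagonal bipole identically zero, the
#' residual vanishes and ORR degenerates to a capped sentinel rather than
#' a measurement.
#'
#' @param angles_deg wavefront directions to simulate.
#' @param spacings clique spacings in grid steps.
#' @param configs clique configurations.
#' @param grid electrode grid (default the 128-electrode 8 x 16, 1 mm
#'   array).
#' @param noise_sd_uv additive noise SD in uV (0 = noiseless).
#' @param seed base RNG seed; recording for angle i uses `seed + i`.
#' @param max_cliques cap on cliques per (recording, spacing), evenly
#'   sampled; keeps the sweep tractable.
#' @param ... further arguments to [planar_wave_params()].
#' @return The tidy metrics table of [evaluate_recordings()] with an extra
#'   `psi_w_deg` column carrying the ground-truth angle.
#' @export
reliability_sweep <- function(angles_deg = seq(7.5, 352.5, by = 15),
                              spacings = 1:4,
                              configs = CLIQUE_CONFIGS,
                              grid = make_grid(8, 16, 1),
                              noise_sd_uv = 0, seed = 1L,
                              max_cliques = 8, ...) {
  out <- vector("list", length(angles_deg))
  for (i in seq_along(angles_deg)) {
    rec <- generate_planar_wave(
      grid, planar_wave_params(psi_w_deg = angles_deg[i],
                               noise_sd_uv = noise_sd_uv,
                               seed = as.integer(seed) + i, ...))
    tab <- evaluate_recordings(rec, configs = configs, spacings = spacings,
                               max_cliques = max_cliques)
    tab$rec_id <- sprintf("psi%g", angles_deg[i])
    tab$psi_w_deg <- angles_deg[i]
    out[[i]] <- tab
  }
  do.call(rbind, out)
}

#' Render a summary as a distance-by-configuration text grid
#'
#' @param summary output of [aggregate_metrics()].
#' @param digits significant digits for mean and SD.
#' @return A character vector of lines (also printed), one block per
#'   spacing with one `mean +/- sd` entry per configuration and metric.
#' @export
format_summary_table <- function(summary, digits = 3) {
  configs <- sort(unique(summary$config))
  lines <- character(0)
  for (s in sort(unique(summary$spacing_mm))) {
    lines <- c(lines, sprintf("%g mm", s))
    block <- summary[summary$spacing_mm == s, ]
    for (m in unique(block$metric)) {
      vals <- vapply(configs, function(cf) {
        r <- block[block$config == cf & block$metric == m, ]
        if (nrow(r) == 0) return("   --   ")
        sprintf("%.*f +/- %.*f", digits, r$mean, digits, r$sd)
      }, character(1))
      lines <- c(lines,
                 sprintf("  %-6s %s", m,
                         paste(sprintf("%-18s", vals), collapse = " ")))
    }
  }
  header <- sprintf("  %-6s %s", "",
                    paste(sprintf("%-18s", configs), collapse = " "))
  lines <- c(header, lines)
  cat(lines, sep = "\n")
  invisible(lines)
}
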