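# Synthetic single-cell FUCCI trace generator.
#
# Reporter kinetics are modelled piecewise: mCherry-Cdt1 is high through G0/G1,
# declines linearly across the G1/S overlap window while mVenus-geminin rises
# linearly to its plateau, mVenus stays high through S/G2(/M), and the exit is
# fate specific: a sharp linear collapse at mitosis (division, binucleation) or
# a slow exponential decay with mCherry re-accumulation before mVenus is lost
# (G2-arrested polyploidization). Phase durations are log-normal.

# Fraction-of-peak level that defines the generator's ground-truth onset/offset
# times. It matches the default classifier setting but is a generator constant:
# truth does not depend on classifier configuration.
.BOUNDARY_FRAC <- 0.2

FATE_LEVELS <- c("noncycling", "division", "binucleation", "polyploidization")

#' Kinetics parameters for synthetic FUCCI traces
#'
#' Defaults encode the study conditions: 20-min sampling over 72 h, and mean
#' S/G2(/M) durations of 16.38 h (division), 17.29 h (binucleation) and 24.5 h
#' (polyploidization). The G1 duration has no measured reference value and is a
#' free parameter (12 h default).
#'
#' @param g1_duration_mean_h mean G1 duration before mVenus onset (hours).
#' @param sg2m_duration_mean_h named numeric: mean S/G2(/M) duration per
#'   cycling fate (hours).
#' @param duration_cv coefficient of variation of the log-normal duration draws.
#' @param onset_overlap_h width of the G1/S window where both reporters are
#'   above threshold (the YELLOW phase), hours.
#' @param sharp_drop_h duration of the mVenus collapse at mitosis, hours.
#' @param slow_decay_tau_h exponential decay constant of mVenus in G2 arrest,
#'   hours; must exceed `sharp_drop_h`.
#' @param intensity_scale reporter plateau intensity, a.u.
#' @param noise_sd_frac multiplicative Gaussian noise SD as a fraction of the
#'   signal (plus an additive component scaled by `background_level`).
#' @param background_level imaging background, a.u.
#' @param sampling_interval_h frame interval, hours (default 1/3 = 20 min).
#' @param total_h length of the movie, hours.
#' @param mcherry_reaccum_h time for mCherry to re-accumulate after mitosis or
#'   during G2 arrest, hours.
#' @return A validated list of class `kinetics_params`.
#' @export
kinetics_params <- function(g1_duration_mean_h = 12,
                            sg2m_duration_mean_h = c(division = 16.38,
                                                     binucleation = 17.29,
                                                     polyploidization = 24.5),
                            duration_cv = 0.15,
                            onset_overlap_h = 2,
                            sharp_drop_h = 0.5,
                            slow_decay_tau_h = 8,
                            intensity_scale = 1000,
                            noise_sd_frac = 0.1,
                            background_level = 50,
                            sampling_interval_h = 1 / 3,
                            total_h = 72,
                            mcherry_reaccum_h = 6) {
  p <- list(g1_duration_mean_h = g1_duration_mean_h,
            sg2m_duration_mean_h = sg2m_duration_mean_h,
            duration_cv = duration_cv,
            onset_overlap_h = onset_overlap_h,
            sharp_drop_h = sharp_drop_h,
            slow_decay_tau_h = slow_decay_tau_h,
            intensity_scale = intensity_scale,
            noise_sd_frac = noise_sd_frac,
            background_level = background_level,
            sampling_interval_h = sampling_interval_h,
            total_h = total_h,
            mcherry_reaccum_h = mcherry_reaccum_h)
  durs <- c(g1_duration_mean_h, sg2m_duration_mean_h, onset_overlap_h,
            sharp_drop_h, slow_decay_tau_h, sampling_interval_h, total_h)
  if (any(durs <= 0)) stop("all durations must be > 0")
  if (!all(c("division", "binucleation", "polyploidization") %in%
           names(sg2m_duration_mean_h)))
    stop("sg2m_duration_mean_h must name division, binucleation, polyploidization")
  if (sharp_drop_h >= slow_decay_tau_h)
    stop("sharp_drop_h must be smaller than slow_decay_tau_h")
  if (noise_sd_frac < 0 || noise_sd_frac >= 1)
    stop("noise_sd_frac must be in [0, 1)")
  structure(p, class = "kinetics_params")
}

#' Fate mixture for trace cohorts
#'
#' Default probabilities encode the observed outcome of 570 tracked
#' cardiomyocytes (90.4% non-cycling, 5.1% division, 3.2% binucleation,
#' 1.4% polyploidization), renormalized to sum exactly to one.
#'
#' @param p_noncycling,p_division,p_binucleation,p_polyploidization
#'   fate probabilities.
#' @param normalize divide by the sum when it is within 0.005 of 1 (printed
#'   percentages rarely sum exactly).
#' @return Named numeric of class `fate_mixture`.
#' @export
fate_mixture <- function(p_noncycling = 0.904, p_division = 0.051,
                         p_binucleation = 0.032, p_polyploidization = 0.014,
                         normalize = TRUE) {
  p <- c(noncycling = p_noncycling, division = p_division,
         binucleation = p_binucleation, polyploidization = p_polyploidization)
  if (any(p < 0) || any(p > 1)) stop("fate probabilities must lie in [0, 1]")
  s <- sum(p)
  if (normalize && abs(s - 1) <= 5e-3 && s > 0) p <- p / s
  if (abs(sum(p) - 1) > 1e-9) stop("fate probabilities must sum to 1")
  structure(p, class = "fate_mixture")
}

# duration draw with geometric feasibility clamps (see generate_trace)
.draw_durations <- function(fate, params) {
  d_g1 <- rlnorm_mean_cv(1, params$g1_duration_mean_h, params$duration_cv)
  d_g1 <- min(max(d_g1, 1), 40)
  d_s <- rlnorm_mean_cv(1, params$sg2m_duration_mean_h[[fate]],
                        params$duration_cv)
  rise <- params$onset_overlap_h
  min_s <- if (fate == "polyploidization") {
    (1 - .BOUNDARY_FRAC) * rise +
      params$slow_decay_tau_h * log(1 / .BOUNDARY_FRAC) + 0.5
  } else {
    (1 - .BOUNDARY_FRAC) * (rise + params$sharp_drop_h) + 0.5
  }
  d_s <- max(d_s, min_s)
  t_on <- d_g1 + .BOUNDARY_FRAC * rise
  # keep the offset observable inside the movie
  d_s <- min(d_s, params$total_h - 2 - t_on)
  list(d_g1 = d_g1, d_s = d_s, t_on = t_on, t_off = t_on + d_s)
}

# piecewise linear interpolation through (x, y) knots, constant outside;
# knots beyond the movie end are clamped (late events may be censored)
.pw <- function(t, x, y) {
  x <- pmin(x, max(t))
  ok <- !duplicated(x)
  stats::approx(x[ok], y[ok], xout = t, rule = 2, ties = "ordered")$y
}

#' Generate one synthetic FUCCI trace
#'
#' @param fate one of `"noncycling"`, `"division"`, `"binucleation"`,
#'   `"polyploidization"`.
#' @param params a [kinetics_params()] object.
#' @param seed integer seed; the trace is a pure function of (fate, params,
#'   seed).
#' @param cell_id identifier stored on the trace.
#' @return A `cell_trace`: list with `time_h`, `mcherry`, `mvenus`,
#'   `background` (all background-subtracted a.u., which may be negative under
#'   noise), the `post_mitosis_daughters` annotation (`"2-separate"` for
#'   division, `"2-same-cell"` for binucleation, `NA` otherwise) and a `truth`
#'   list (fate, onset/offset times, S/G2/M duration) that no analysis stage
#'   reads.
#' @export
generate_trace <- function(fate, params = kinetics_params(), seed = 1L,
                           cell_id = "cell_1") {
  if (!is.character(fate) || length(fate) != 1 || !(fate %in% FATE_LEVELS))
    stop("unknown fate label: ", paste(fate, collapse = ", "))
  set.seed(seed)
  dt <- params$sampling_interval_h
  t <- seq(0, params$total_h, by = dt)
  scale <- params$intensity_scale
  rise <- params$onset_overlap_h
  f <- .BOUNDARY_FRAC

  truth <- list(fate = fate, t_onset_h = NA_real_, t_offset_h = NA_real_,
                sg2m_duration_h = NA_real_, g1_duration_h = NA_real_,
                mcherry_reentry = FALSE)
  daughters <- NA_character_

  if (fate == "noncycling") {
    mv <- rep(0, length(t))
    mc <- rep(scale, length(t))
  } else {
    d <- .draw_durations(fate, params)
    a <- d$d_g1                       # start of the mVenus rise
    truth$g1_duration_h <- d$d_g1
    truth$t_onset_h <- d$t_on
    truth$t_offset_h <- d$t_off
    truth$sg2m_duration_h <- d$d_s

    if (fate %in% c("division", "binucleation")) {
      s_drop <- params$sharp_drop_h
      t_drop <- d$t_off - (1 - f) * s_drop   # offset = t_drop + 0.8*s_drop
      mv <- .pw(t, c(0, a, a + rise, t_drop, t_drop + s_drop, params$total_h),
                c(0, 0, scale, scale, 0, 0))
      t_re <- t_drop + s_drop                # daughters re-enter G1
      mc <- .pw(t, c(0, a, a + rise, t_re, t_re + params$mcherry_reaccum_h,
                     params$total_h),
                c(scale, scale, 0, 0, scale, scale))
      daughters <- if (fate == "division") "2-separate" else "2-same-cell"
    } else {                                  # polyploidization: G2 arrest
      tau <- params$slow_decay_tau_h
      t_dec <- d$t_off - tau * log(1 / f)    # exp decay hits f*peak at t_off
      mv <- .pw(t, c(0, a, a + rise, t_dec), c(0, 0, scale, scale))
      decay <- t > t_dec
      mv[decay] <- scale * exp(-(t[decay] - t_dec) / tau)
      # Cdt1 re-accumulates during arrest, before mVenus is lost
      mc <- .pw(t, c(0, a, a + rise, t_dec, t_dec + params$mcherry_reaccum_h,
                     params$total_h),
                c(scale, scale, 0, 0, scale, scale))
      truth$mcherry_reentry <- TRUE
    }
  }

  nf <- params$noise_sd_frac
  bg <- rep(params$background_level, length(t))
  if (nf > 0) {
    n <- length(t)
    mv <- mv * (1 + stats::rnorm(n, 0, nf)) +
      stats::rnorm(n, 0, nf * params$background_level)
    mc <- mc * (1 + stats::rnorm(n, 0, nf)) +
      stats::rnorm(n, 0, nf * params$background_level)
    bg <- bg + stats::rnorm(n, 0, nf * params$background_level)
  }

  structure(list(cell_id = cell_id, time_h = t, mcherry = mc, mvenus = mv,
                 background = bg, post_mitosis_daughters = daughters,
                 true_fate = fate, truth = truth),
            class = "cell_trace")
}

#' Generate a cohort of fate-labelled traces
#'
#' Fates are drawn i.i.d. from `mixture`; each cell gets its own substream seed
#' derived from the cohort seed by counter, so the cohort is a pure function of
#' `(n, mixture, params, seed)`.
#'
#' @inheritParams generate_trace
#' @param n number of cells (>= 1).
#' @param mixture a [fate_mixture()].
#' @return A `cell_trace_cohort`: list of traces plus a `truth` data.frame.
#' @export
generate_trace_cohort <- function(n, mixture = fate_mixture(),
                                  params = kinetics_params(), seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  if (!inherits(mixture, "fate_mixture")) mixture <- do.call(fate_mixture, as.list(mixture))
  set.seed(derive_seed(seed, "fates"))
  fates <- sample(FATE_LEVELS, n, replace = TRUE, prob = as.numeric(mixture))
  traces <- lapply(seq_len(n), function(i) {
    generate_trace(fates[i], params, seed = derive_seed(seed, i),
                   cell_id = sprintf("cell_%04d", i))
  })
  truth <- data.frame(
    cell_id = vapply(traces, `[[`, "", "cell_id"),
    true_fate = fates,
    t_onset_h = vapply(traces, function(x) x$truth$t_onset_h, 0),
    t_offset_h = vapply(traces, function(x) x$truth$t_offset_h, 0),
    sg2m_duration_h = vapply(traces, function(x) x$truth$sg2m_duration_h, 0),
    stringsAsFactors = FALSE)
  structure(list(traces = traces, truth = truth, seed = seed),
            class = "cell_trace_cohort")
}

#' Convert traces to a long-format data.frame (cell_id, time_h, mcherry,
#' mvenus, background)
#' @param x a `cell_trace`, `cell_trace_cohort`, or list of traces.
#' @return long-format data.frame.
#' @export
traces_to_df <- function(x) {
  if (inherits(x, "cell_trace")) x <- list(x)
  if (inherits(x, "cell_trace_cohort")) x <- x$traces
  do.call(rbind, lapply(x, function(tr) {
    data.frame(cell_id = tr$cell_id, time_h = tr$time_h, mcherry = tr$mcherry,
               mvenus = tr$mvenus, background = tr$background,
               stringsAsFactors = FALSE)
  }))
}

#' Rebuild `cell_trace` objects from a long-format data.frame
#' @param df long-format trace table as written by [write_traces_csv()].
#' @param annotations optional data.frame (cell_id, post_mitosis_daughters).
#' @return list of `cell_trace` objects (no ground truth attached).
#' @export
df_to_traces <- function(df, annotations = NULL) {
  lapply(split(df, df$cell_id), function(d) {
    d <- d[order(d$time_h), ]
    ann <- NA_character_
    if (!is.null(annotations)) {
      m <- match(d$cell_id[1], annotations$cell_id)
      if (!is.na(m)) ann <- annotations$post_mitosis_daughters[m]
    }
    structure(list(cell_id = d$cell_id[1], time_h = d$time_h,
                   mcherry = d$mcherry, mvenus = d$mvenus,
                   background = d$background %||% rep(0, nrow(d)),
                   post_mitosis_daughters = ann,
                   true_fate = NA_character_, truth = NULL),
              class = "cell_trace")
  })
}

#' @export
print.cell_trace <- function(x, ...) {
  cat("<cell_trace>", x$cell_id, "-", length(x$time_h), "frames,",
      "fate:", x$true_fate %||% "unknown", "\n")
  invisible(x)
}

#' @export
print.cell_trace_cohort <- function(x, ...) {
  cat("<cell_trace_cohort>", length(x$traces), "traces; true fates:\n")
  print(table(x$truth$true_fate))
  invisible(x)
}
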