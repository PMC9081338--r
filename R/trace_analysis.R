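# Single-cell FUCCI trace analysis: peak alignment, phase-boundary detection,
# fate classification (non-cycling / division / binucleation / polyploidization)
# and S/G2(/M) duration estimation.
#
# All decision rules are relative to the trace's own mVenus peak, so
# classification is invariant to uniform intensity rescaling. Division and
# binucleation are kinetically indistinguishable from intensities alone; they
# are separated by the post-mitosis daughter-object annotation, and a mitotic
# trace without it is reported as "mitotic-unresolved" rather than guessed.

#' Configuration for the trace fate classifier
#'
#' @param onset_frac mVenus onset defined as the first upward crossing of this
#'   fraction of the trace's peak (default 0.2).
#' @param offset_frac mVenus offset defined as the last downward crossing of
#'   this fraction of the peak after the peak (default 0.2).
#' @param sharp_drop_max_h a drop from half-peak to offset faster than this is
#'   "sharp" (mitotic); hours.
#' @param slow_decay_min_h a drop slower than this is "slow" (G2 arrest); hours.
#' @param alignment_window_h width of the peak-aligned plotting window, hours.
#' @param noise_floor_mult a trace is called cycling only if its smoothed
#'   mVenus peak exceeds this multiple of the trace's robust noise level (MAD).
#' @return list of class `fate_classifier_config`.
#' @export
fate_classifier_config <- function(onset_frac = 0.2, offset_frac = 0.2,
                                   sharp_drop_max_h = 1.0,
                                   slow_decay_min_h = 5.0,
                                   alignment_window_h = 40,
                                   noise_floor_mult = 10) {
  if (onset_frac <= 0 || onset_frac >= 1 || offset_frac <= 0 || offset_frac >= 1)
    stop("onset_frac and offset_frac must lie in (0, 1)")
  if (sharp_drop_max_h >= slow_decay_min_h)
    stop("sharp_drop_max_h must be smaller than slow_decay_min_h")
  structure(list(onset_frac = onset_frac, offset_frac = offset_frac,
                 sharp_drop_max_h = sharp_drop_max_h,
                 slow_decay_min_h = slow_decay_min_h,
                 alignment_window_h = alignment_window_h,
                 noise_floor_mult = noise_floor_mult),
            class = "fate_classifier_config")
}

.validate_trace <- function(trace) {
  if (!inherits(trace, "cell_trace")) stop("expected a cell_trace")
  t <- trace$time_h
  if (length(t) < 3 || any(diff(t) <= 0)) stop("time must be strictly increasing")
  if (max(abs(diff(diff(t)))) > 1e-6) stop("time grid must be uniform")
  if (length(trace$mvenus) != length(t) || length(trace$mcherry) != length(t))
    stop("channel lengths must equal the time grid length")
  invisible(trace)
}

# centered 3-point median filter: removes single-frame spikes without moving
# threshold crossings by more than one sampling interval
.smooth3 <- function(y) stats::runmed(y, 3, endrule = "keep")

#' Detect mVenus phase boundaries on a single trace
#'
#' Onset is the first upward crossing of `onset_frac * peak`, offset the last
#' downward crossing of `offset_frac * peak` after the peak (both linearly
#' interpolated on the median-smoothed trace). `drop_sharpness_h` is the time
#' from the last half-peak crossing to the offset. `mcherry_reentry` is TRUE if
#' mCherry, having fallen below 20% of its own maximum, rises above it again
#' before the mVenus offset.
#'
#' A trace whose smoothed mVenus peak does not exceed
#' `noise_floor_mult * MAD(mVenus)` has no defined boundaries (non-cycling
#' upstream).
#'
#' @param trace a `cell_trace`.
#' @param config a [fate_classifier_config()].
#' @return list: `t_onset_h`, `t_offset_h`, `sg2m_duration_h`,
#'   `drop_sharpness_h`, `mcherry_reentry`, `censored`.
#' @export
detect_phase_boundaries <- function(trace, config = fate_classifier_config()) {
  .validate_trace(trace)
  t <- trace$time_h
  mv <- .smooth3(trace$mvenus)
  mc <- .smooth3(trace$mcherry)
  out <- list(t_onset_h = NA_real_, t_offset_h = NA_real_,
              sg2m_duration_h = NA_real_, drop_sharpness_h = NA_real_,
              mcherry_reentry = NA, censored = FALSE)

  peak <- max(mv)
  # noise level from first differences of the raw trace: slow reporter
  # kinetics cancel, so the estimate is not inflated by sustained signal
  # (e.g. a long G2-arrest decay), and the raw series keeps the noise i.i.d.
  sigma_hat <- stats::mad(diff(trace$mvenus)) / sqrt(2)
  if (!(peak > 0) || peak <= config$noise_floor_mult * sigma_hat)
    return(out)                                   # mVenus never leaves noise

  ip <- which.max(mv)
  # reference level for fraction-of-peak thresholds: median of the near-peak
  # plateau rather than the raw maximum, which is inflated by noise extremes
  peak_ref <- stats::median(mv[mv >= 0.8 * peak])
  out$t_onset_h <- cross_up_time(t, mv, config$onset_frac * peak_ref)
  t_off <- cross_down_time(t, mv, config$offset_frac * peak_ref, from = ip)
  if (is.na(t_off)) {                              # still high at movie end
    out$censored <- TRUE
    return(out)
  }
  out$t_offset_h <- t_off
  out$sg2m_duration_h <- t_off - out$t_onset_h
  t_half <- cross_down_time(t, mv, 0.5 * peak_ref, from = ip)
  out$drop_sharpness_h <- t_off - t_half

  thr_mc <- 0.2 * max(mc)
  win <- which(t > out$t_onset_h & t <= t_off)
  out$mcherry_reentry <- FALSE
  if (length(win) > 1) {
    w <- mc[win]
    below <- which(w < thr_mc)
    if (length(below) && any(w[min(below):length(w)] >= thr_mc))
      out$mcherry_reentry <- TRUE
  }
  out
}

#' Classify the cell-cycle outcome of one trace
#'
#' Rules, applied to the boundary detection output: no onset -> `noncycling`;
#' drop sharpness >= `slow_decay_min_h`, or mCherry re-entry before the offset
#' without a sharp drop -> `polyploidization`; otherwise mitotic, split into
#' `division` (annotation `"2-separate"`) vs `binucleation`
#' (`"2-same-cell"`); a mitotic trace without a daughter annotation, or a
#' cycling trace whose offset is censored by the movie end, is
#' `mitotic-unresolved`.
#'
#' @inheritParams detect_phase_boundaries
#' @return list of class `fate_call` with `fate`, boundary times, duration,
#'   `drop_sharpness_h` and `mcherry_reentry_before_offset`.
#' @export
classify_fate <- function(trace, config = fate_classifier_config()) {
  b <- detect_phase_boundaries(trace, config)
  fate <- if (is.na(b$t_onset_h)) {
    "noncycling"
  } else if (b$censored) {
    "mitotic-unresolved"
  } else if (b$drop_sharpness_h >= config$slow_decay_min_h ||
             (isTRUE(b$mcherry_reentry) &&
              b$drop_sharpness_h > config$sharp_drop_max_h)) {
    "polyploidization"
  } else {
    ann <- trace$post_mitosis_daughters
    if (identical(ann, "2-separate")) "division"
    else if (identical(ann, "2-same-cell")) "binucleation"
    else "mitotic-unresolved"
  }
  structure(list(cell_id = trace$cell_id, fate = fate,
                 t_onset_h = b$t_onset_h, t_offset_h = b$t_offset_h,
                 sg2m_duration_h = b$sg2m_duration_h,
                 drop_sharpness_h = b$drop_sharpness_h,
                 mcherry_reentry_before_offset = b$mcherry_reentry),
            class = "fate_call")
}

#' Classify every trace of a cohort (blind to ground truth)
#' @param cohort a `cell_trace_cohort` or list of `cell_trace`.
#' @inheritParams detect_phase_boundaries
#' @return data.frame with one row per cell.
#' @export
classify_cohort <- function(cohort, config = fate_classifier_config()) {
  traces <- if (inherits(cohort, "cell_trace_cohort")) cohort$traces else cohort
  calls <- lapply(traces, classify_fate, config = config)
  data.frame(
    cell_id = vapply(calls, `[[`, "", "cell_id"),
    fate = vapply(calls, `[[`, "", "fate"),
    t_onset_h = vapply(calls, `[[`, 0, "t_onset_h"),
    t_offset_h = vapply(calls, `[[`, 0, "t_offset_h"),
    sg2m_duration_h = vapply(calls, `[[`, 0, "sg2m_duration_h"),
    drop_sharpness_h = vapply(calls, `[[`, 0, "drop_sharpness_h"),
    mcherry_reentry_before_offset =
      vapply(calls, function(x) isTRUE(x$mcherry_reentry_before_offset), TRUE),
    stringsAsFactors = FALSE)
}

#' Align traces on their mVenus peak
#'
#' Each trace is shifted so that its (smoothed) mVenus peak sits at t = 0,
#' cropped to +/- `alignment_window_h / 2`, and the per-timepoint mean and SEM
#' over non-missing entries are returned for both channels.
#'
#' @param traces list of `cell_trace` (or a cohort).
#' @inheritParams detect_phase_boundaries
#' @return list: `time_rel_h`, matrices `mvenus` and `mcherry` (cells x time),
#'   and `profile` data.frame (time, mean and sem per channel).
#' @export
align_traces <- function(traces, config = fate_classifier_config()) {
  if (inherits(traces, "cell_trace_cohort")) traces <- traces$traces
  if (!length(traces)) stop("align_traces: empty input")
  dt <- diff(traces[[1]]$time_h[1:2])
  half <- config$alignment_window_h / 2
  rel <- seq(-half, half, by = dt)
  grab <- function(tr) {
    ip <- which.max(.smooth3(tr$mvenus))
    shifted <- tr$time_h - tr$time_h[ip]
    idx <- round((rel - shifted[1]) / dt) + 1L
    ok <- idx >= 1L & idx <= length(shifted)
    mv <- mc <- rep(NA_real_, length(rel))
    mv[ok] <- tr$mvenus[idx[ok]]
    mc[ok] <- tr$mcherry[idx[ok]]
    list(mv = mv, mc = mc)
  }
  rows <- lapply(traces, grab)
  mv <- do.call(rbind, lapply(rows, `[[`, "mv"))
  mc <- do.call(rbind, lapply(rows, `[[`, "mc"))
  rownames(mv) <- rownames(mc) <- vapply(traces, `[[`, "", "cell_id")
  col_stats <- function(m) {
    n <- colSums(!is.na(m))
    mean <- colMeans(m, na.rm = TRUE)
    sd <- apply(m, 2, stats::sd, na.rm = TRUE)
    sem <- ifelse(n > 1, sd / sqrt(n), NA_real_)
    list(mean = mean, sem = sem, n = n)
  }
  smv <- col_stats(mv); smc <- col_stats(mc)
  profile <- data.frame(time_rel_h = rel,
                        mvenus_mean = smv$mean, mvenus_sem = smv$sem,
                        mcherry_mean = smc$mean, mcherry_sem = smc$sem,
                        n = smv$n)
  list(time_rel_h = rel, mvenus = mv, mcherry = mc, profile = profile)
}

#' Summarize a cohort of fate calls
#'
#' @param calls data.frame from [classify_cohort()] (or list of `fate_call`).
#' @return list: `n`, `fractions` (over all calls, in percent), and
#'   `durations` data.frame (per cycling fate: n, mean, sd, sem of the
#'   estimated S/G2(/M) duration).
#' @export
cohort_summary <- function(calls) {
  if (!is.data.frame(calls)) {
    stopifnot(length(calls) >= 1)
    calls <- data.frame(fate = vapply(calls, `[[`, "", "fate"),
                        sg2m_duration_h = vapply(calls, `[[`, 0, "sg2m_duration_h"),
                        stringsAsFactors = FALSE)
  }
  if (nrow(calls) < 1) stop("cohort_summary: no calls")
  n <- nrow(calls)
  lev <- c(FATE_LEVELS, "mitotic-unresolved")
  counts <- table(factor(calls$fate, levels = lev))
  fractions <- 100 * as.numeric(counts) / n
  names(fractions) <- lev
  cyc <- calls[calls$fate %in% c("division", "binucleation", "polyploidization") &
                 !is.na(calls$sg2m_duration_h), ]
  durations <- do.call(rbind, lapply(split(cyc, cyc$fate), function(d) {
    data.frame(fate = d$fate[1], n = nrow(d),
               mean_h = mean(d$sg2m_duration_h),
               sd_h = stats::sd(d$sg2m_duration_h),
               sem_h = stats::sd(d$sg2m_duration_h) / sqrt(nrow(d)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(durations))
    durations <- data.frame(fate = character(), n = integer(), mean_h = numeric(),
                            sd_h = numeric(), sem_h = numeric())
  rownames(durations) <- NULL
  list(n = n, fractions = fractions, durations = durations)
}
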