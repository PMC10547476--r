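# Waveform decomposition of detrended trace segments. The six parameters:
# period (mean peak-to-peak interval, min), active duration A_D (time above
# 50% of peak amplitude), pulse duration P_D (time above the near-baseline
# level, covering the Ca2+-extrusion tail), silent duration S_D = period -
# A_D, plateau fraction P_F = A_D / period, and peak. Segments that plateau
# get P_F = 1, period = 0, A_D = P_D = segment length; segments that fall
# silent get P_F = 0, A_D = P_D = 0, period = segment length.

#' Detrending settings
#'
#' @param method `"moving_median"` or `"linear"` (least-squares line). The
#'   moving-median trend is a running median of width `window` applied to a
#'   one-cycle running-mean pre-smooth (width `window / 3`, i.e. one dominant
#'   period): the pre-smooth cancels the oscillation itself — a plain running
#'   median of a square wave near 50% duty flips between the two plateau
#'   levels — and the median stage keeps the trend robust to spikes and
#'   transients without flattening plateaus. The linear fit is exact for a
#'   pure linear trend and idempotent on its own output.
#' @param window Moving-median window in minutes. `NULL` picks 3x the
#'   segment's dominant period (periodogram argmax), falling back to 10 min
#'   for aperiodic segments; the auto-selected window is clipped to a quarter
#'   of the segment. Any window must span at least 5 sampling intervals and at
#'   most half the segment.
#' @param preserve_mean Restore the segment's original mean after removing the
#'   trend (default `TRUE`).
#' @return List of class `detrend_settings`.
#' @export
detrend_settings <- function(method = c("moving_median", "linear"),
                             window = NULL, preserve_mean = TRUE) {
  method <- match.arg(method)
  structure(list(method = method, window = window,
                 preserve_mean = preserve_mean),
            class = "detrend_settings")
}

# Dominant period (minutes) from the periodogram argmax; NA when the segment
# carries essentially no power (flat traces).
estimate_dominant_period <- function(trace) {
  n <- length(trace$time)
  if (n < 32L || stats::var(trace$values) < 1e-12) return(NA_real_)
  sp <- power_spectrum(trace)
  if (max(sp$power) <= 0) return(NA_real_)
  1 / sp$freq[which.max(sp$power)]
}

#' Remove the slow trend from a trace segment
#'
#' @param trace An [islet_trace()] (one segment).
#' @param settings A [detrend_settings()].
#' @return The detrended [islet_trace()].
#' @export
detrend_segment <- function(trace, settings = detrend_settings()) {
  v <- trace$values
  n <- length(v)
  if (settings$method == "linear") {
    tt <- trace$time - trace$time[1L]
    fit <- stats::lm.fit(cbind(1, tt), v)
    res <- fit$residuals
  } else {
    dt <- trace_dt(trace)
    window <- settings$window
    if (is.null(window)) {
      p <- estimate_dominant_period(trace)
      window <- if (is.na(p)) 10 else 3 * p
      # noise-dominated segments can report a dominant period near the
      # segment length; only the auto-selected window is clipped
      window <- min(window, n * dt / 4)
    }
    if (window < 5 * dt) stop("moving-median window must span at least 5 sampling intervals")
    k <- max(3L, round(window / dt))
    if (k %% 2L == 0L) k <- k + 1L
    if (n < 2L * k) stop("segment too short for the moving-median window")
    # one-cycle running mean cancels the oscillation before the median stage
    k1 <- max(2L, round(window / (3 * dt)))
    sm <- as.numeric(stats::filter(v, rep(1 / k1, k1), sides = 2))
    idx <- which(!is.na(sm))
    if (idx[1L] > 1L) sm[seq_len(idx[1L] - 1L)] <- sm[idx[1L]]
    last <- idx[length(idx)]
    if (last < n) sm[(last + 1L):n] <- sm[last]
    trend <- stats::runmed(sm, k, endrule = "median")
    res <- v - trend
  }
  if (settings$preserve_mean) res <- res + mean(v) - mean(res)
  islet_trace(trace$time, res, islet_id = trace$islet_id,
              strain = trace$strain, sex = trace$sex, animal = trace$animal)
}

# Linear-interpolated time at which v crosses `level` between frames i and
# i+1.
cross_time <- function(time, v, i, level) {
  denom <- v[i + 1L] - v[i]
  if (abs(denom) < 1e-300) return(time[i])
  time[i] + (time[i + 1L] - time[i]) * (level - v[i]) / denom
}

#' Detect oscillation pulses in a detrended segment
#'
#' A pulse is a maximal run of frames at or above `baseline + threshold_frac *
#' amplitude`, where baseline and robust peak are the 5th and 95th percentiles
#' of the detrended segment and amplitude is their difference (percentiles
#' keep single-frame spikes out of the reference levels while staying valid
#' for duty cycles between roughly 10% and 90%). When the percentile spread
#' falls below `amplitude_floor` but the 99.5th percentile still rises at
#' least `2 * amplitude_floor` above baseline, the segment holds sparse bursts
#' (e.g. a single pulse in 40 min) and that upper percentile is used as the
#' robust peak instead; a run must
#' contain a local maximum with prominence at least `min_prominence_frac *
#' amplitude`. A run holding several local maxima is a single pulse whose peak
#' is the largest maximum (earlier on an exact tie). If the amplitude falls
#' below `amplitude_floor` the segment is treated as flat and no pulses are
#' returned. Zero pulses is a valid outcome (plateau or silent segment).
#'
#' @param trace Detrended [islet_trace()] segment.
#' @param min_prominence_frac Minimum peak prominence, as a fraction of
#'   amplitude (default 0.25).
#' @param threshold_frac Active-phase crossing level as a fraction of
#'   amplitude (0.5: the signal counts as active while above 50% of peak
#'   amplitude).
#' @param pd_frac Near-baseline crossing level, as a fraction of amplitude,
#'   bounding the pulse duration (default 0.1).
#' @param amplitude_floor Minimum amplitude (ratio units) for a segment to be
#'   considered oscillating at all (default 0.05).
#' @return Data frame of pulse records (interpolated threshold-crossing times
#'   `start_time`/`end_time`, peak time/value, prominence, pulse-duration
#'   bounds `pd_start_time`/`pd_end_time`, and `complete` flags for pulses not
#'   truncated by the segment edges), ordered in time, with attributes
#'   `baseline`, `peak`, `amplitude`, `threshold`.
#' @export
detect_oscillations <- function(trace, min_prominence_frac = 0.25,
                                threshold_frac = 0.5, pd_frac = 0.1,
                                amplitude_floor = 0.05) {
  v <- trace$values
  time <- trace$time
  n <- length(v)
  baseline <- stats::quantile(v, 0.05, names = FALSE)
  peak_r <- stats::quantile(v, 0.95, names = FALSE)
  amp <- peak_r - baseline
  if (amp < amplitude_floor) {
    # sparse bursts: too few active frames to register in the 95th percentile
    peak_hi <- stats::quantile(v, 0.995, names = FALSE)
    if (peak_hi - baseline >= 2 * amplitude_floor) {
      peak_r <- peak_hi
      amp <- peak_r - baseline
    }
  }
  empty <- data.frame(start_idx = integer(), end_idx = integer(),
                      start_time = numeric(), end_time = numeric(),
                      peak_idx = integer(), peak_time = numeric(),
                      peak_value = numeric(), prominence = numeric(),
                      complete = logical(), pd_start_time = numeric(),
                      pd_end_time = numeric(), pd_complete = logical())
  decorate <- function(df) {
    attr(df, "baseline") <- baseline
    attr(df, "peak") <- peak_r
    attr(df, "amplitude") <- amp
    attr(df, "threshold") <- baseline + threshold_frac * amp
    df
  }
  if (amp < amplitude_floor) return(decorate(empty))
  thr <- baseline + threshold_frac * amp
  lower <- baseline + pd_frac * amp
  above <- v >= thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_s <- starts[r$values]
  run_e <- ends[r$values]
  if (!length(run_s)) return(decorate(empty))
  low <- rle(v >= lower)
  low_e <- cumsum(low$lengths)
  low_s <- low_e - low$lengths + 1L
  low_s <- low_s[low$values]; low_e <- low_e[low$values]
  rows <- lapply(seq_along(run_s), function(j) {
    s <- run_s[j]; e <- run_e[j]
    seg <- v[s:e]
    pk_rel <- which(seg == max(seg))[1L]
    pk <- s + pk_rel - 1L
    left_min <- if (j > 1L) min(v[run_e[j - 1L]:s]) else
      if (s > 1L) min(v[1L:s]) else NA_real_
    right_min <- if (j < length(run_s)) min(v[e:run_s[j + 1L]]) else
      if (e < n) min(v[e:n]) else NA_real_
    ref <- suppressWarnings(max(left_min, right_min, na.rm = TRUE))
    if (!is.finite(ref)) ref <- baseline
    prom <- v[pk] - ref
    st <- if (s > 1L) cross_time(time, v, s - 1L, thr) else time[1L]
    en <- if (e < n) cross_time(time, v, e, thr) else time[n]
    klow <- which(low_s <= pk & low_e >= pk)[1L]
    ls <- low_s[klow]; le <- low_e[klow]
    pst <- if (ls > 1L) cross_time(time, v, ls - 1L, lower) else time[1L]
    pen <- if (le < n) cross_time(time, v, le, lower) else time[n]
    data.frame(start_idx = s, end_idx = e, start_time = st, end_time = en,
               peak_idx = pk, peak_time = time[pk], peak_value = v[pk],
               prominence = prom, complete = (s > 1L && e < n),
               pd_start_time = pst, pd_end_time = pen,
               pd_complete = (ls > 1L && le < n))
  })
  out <- do.call(rbind, rows)
  out <- out[out$prominence >= min_prominence_frac * amp, , drop = FALSE]
  rownames(out) <- NULL
  decorate(out)
}

#' Compute waveform parameters for one segment
#'
#' With two or more complete pulses: period = mean peak-to-peak interval, A_D
#' = mean per-pulse time above the 50% threshold, P_D = mean time between the
#' near-baseline crossings bounding each pulse, S_D = period - A_D (exact by
#' construction), P_F = A_D / period. A segment with exactly one complete
#' pulse gets its durations from that pulse but a missing (NA) period, S_D and
#' P_F, since a period needs two peaks. With zero pulses the segment is coded
#' `plateau` (mean at or above `baseline_ref + 0.5 * amplitude_floor`): P_F =
#' 1, period = 0, A_D = P_D = segment length; otherwise `silent`: P_F = 0,
#' A_D = P_D = 0, period = S_D = segment length.
#'
#' @param pulses Pulse table from [detect_oscillations()] on the same segment.
#' @param segment The (detrended) [islet_trace()] segment.
#' @param segment_length Segment length in minutes (default: frame count times
#'   sampling interval).
#' @param baseline_ref Reference basal level for the plateau-versus-silent
#'   call, typically the 5th percentile of the same islet's basal (2G)
#'   segment; defaults to this segment's own detected baseline.
#' @param amplitude_floor Minimum amplitude (ratio units) separating an
#'   elevated plateau from basal silence.
#' @param raw_segment Optional un-detrended segment; its mean is reported as
#'   `avg_signal_raw`.
#' @return One-row data frame: `regime`, `speed_class`, `peak`, `amplitude`,
#'   `period_min`, `active_min`, `pulse_min`, `silent_min`,
#'   `plateau_fraction`, `avg_signal`, `avg_signal_raw`, `n_pulses`.
#' @export
compute_waveform_params <- function(pulses, segment, segment_length = NULL,
                                    baseline_ref = NULL,
                                    amplitude_floor = 0.05,
                                    raw_segment = NULL) {
  dt <- trace_dt(segment)
  if (is.null(segment_length)) segment_length <- length(segment$time) * dt
  avg <- mean(segment$values)
  avg_raw <- if (is.null(raw_segment)) avg else mean(raw_segment$values)
  baseline <- attr(pulses, "baseline")
  base_ref <- baseline_ref %||% baseline
  out <- function(regime, peak, amplitude, period, a_d, p_d, s_d, p_f) {
    data.frame(regime = regime,
               speed_class = classify_speed(period, regime),
               peak = peak, amplitude = amplitude, period_min = period,
               active_min = a_d, pulse_min = p_d, silent_min = s_d,
               plateau_fraction = p_f, avg_signal = avg,
               avg_signal_raw = avg_raw, n_pulses = nrow(pulses),
               stringsAsFactors = FALSE)
  }
  if (nrow(pulses) == 0L) {
    if (avg >= base_ref + 0.5 * amplitude_floor) {
      return(out("plateau", peak = avg, amplitude = avg - base_ref,
                 period = 0, a_d = segment_length, p_d = segment_length,
                 s_d = 0, p_f = 1))
    }
    return(out("silent", peak = avg, amplitude = 0,
               period = segment_length, a_d = 0, p_d = 0,
               s_d = segment_length, p_f = 0))
  }
  cp <- pulses[pulses$complete, , drop = FALSE]
  peak <- mean(pulses$peak_value)
  amplitude <- peak - baseline
  if (nrow(cp) == 0L) {
    return(out("oscillating", peak, amplitude, NA_real_, NA_real_, NA_real_,
               NA_real_, NA_real_))
  }
  a_d <- mean(cp$end_time - cp$start_time)
  pdc <- cp[cp$pd_complete, , drop = FALSE]
  p_d <- if (nrow(pdc)) mean(pdc$pd_end_time - pdc$pd_start_time) else NA_real_
  if (nrow(cp) >= 2L) {
    period <- mean(diff(cp$peak_time))
    s_d <- period - a_d
    p_f <- a_d / period
  } else {
    period <- s_d <- p_f <- NA_real_
  }
  out("oscillating", peak, amplitude, period, a_d, p_d, s_d, p_f)
}

#' Classify oscillation speed from the period
#'
#' Oscillating records with period below `fast_cutoff` are `fast`; periods in
#' `[fast_cutoff, slow_upper]` are `slow`; anything else (plateau, silent,
#' missing period, or period above `slow_upper`) is `none`.
#'
#' @param period Period(s) in minutes (vectorised).
#' @param regime Matching regime label(s) (`"oscillating"`, `"plateau"`,
#'   `"silent"`).
#' @param fast_cutoff Fast/slow boundary in minutes (default 2).
#' @param slow_upper Upper bound of the slow band in minutes (default 10).
#' @return Character vector: `"fast"`, `"slow"`, or `"none"`.
#' @export
classify_speed <- function(period, regime, fast_cutoff = 2, slow_upper = 10) {
  res <- rep("none", length(period))
  osc <- regime == "oscillating" & !is.na(period)
  res[osc & period < fast_cutoff] <- "fast"
  res[osc & period >= fast_cutoff & period <= slow_upper] <- "slow"
  res
}

#' Extract waveform parameters for every islet and segment
#'
#' Runs the full per-segment decomposition: slice each trace by the schedule,
#' detrend, detect pulses, and compute parameters. The plateau-versus-silent
#' reference baseline is taken from the islet's basal segment
#' (`basal_label`, 5th percentile of its detrended values) when that segment is in
#' the schedule.
#'
#' @param x An `islet_cohort` or list of ratio [islet_trace()] objects.
#' @param schedule A [segment_schedule()] (taken from the cohort if `x` is
#'   one).
#' @param detrend A [detrend_settings()].
#' @param threshold_frac,min_prominence_frac,pd_frac,amplitude_floor Passed to
#'   [detect_oscillations()] / [compute_waveform_params()].
#' @param fast_cutoff,slow_upper Passed to [classify_speed()].
#' @param basal_label Label of the basal segment (default `"2G"`).
#' @return Data frame, one row per islet x segment: `islet_id, strain, sex,
#'   animal, segment, regime, speed_class, peak, amplitude, period_min,
#'   active_min, pulse_min, silent_min, plateau_fraction, avg_signal,
#'   avg_signal_raw, n_pulses`.
#' @export
extract_params <- function(x, schedule = NULL, detrend = detrend_settings(),
                           threshold_frac = 0.5, min_prominence_frac = 0.25,
                           pd_frac = 0.1, amplitude_floor = 0.05,
                           fast_cutoff = 2, slow_upper = 10,
                           basal_label = "2G") {
  if (inherits(x, "islet_cohort")) {
    schedule <- schedule %||% x$schedule
    traces <- x$traces
  } else {
    traces <- x
  }
  if (is.null(schedule)) stop("a segment schedule is required")
  rows <- lapply(traces, function(tr) {
    segs <- segment_trace(tr, schedule)
    base_ref <- if (basal_label %in% names(segs)) {
      # detrended like the segments it is compared against, else drift alone
      # can push a silent islet past the plateau criterion
      bs <- detrend_segment(segs[[basal_label]], detrend)
      stats::quantile(bs$values, 0.05, names = FALSE)
    } else NULL
    seg_rows <- lapply(names(segs), function(lab) {
      seg <- segs[[lab]]
      det <- detrend_segment(seg, detrend)
      pulses <- detect_oscillations(det,
                                    min_prominence_frac = min_prominence_frac,
                                    threshold_frac = threshold_frac,
                                    pd_frac = pd_frac,
                                    amplitude_floor = amplitude_floor)
      p <- compute_waveform_params(pulses, det,
                                   segment_length = length(seg$time) * trace_dt(seg),
                                   baseline_ref = base_ref,
                                   amplitude_floor = amplitude_floor,
                                   raw_segment = seg)
      p$speed_class <- classify_speed(p$period_min, p$regime,
                                      fast_cutoff, slow_upper)
      cbind(data.frame(islet_id = tr$islet_id, strain = tr$strain,
                       sex = tr$sex, animal = tr$animal, segment = lab,
                       stringsAsFactors = FALSE),
            p)
    })
    do.call(rbind, seg_rows)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Animal-level averages of waveform parameters
#'
#' Unweighted mean over islets within each animal, per parameter and segment.
#' Edge-case numeric codes (plateau/silent 0 and segment-length assignments)
#' enter the mean as ordinary numbers; missing values (e.g. the period of a
#' one-pulse segment) are dropped from their average.
#'
#' @param params Islet-level parameter table from [extract_params()].
#' @param value_cols Numeric columns to average (default: all waveform
#'   parameters present).
#' @return Data frame keyed by `strain, sex, animal, segment` plus the
#'   averaged columns and `n_islets`.
#' @export
summarize_animal <- function(params, value_cols = NULL) {
  value_cols <- value_cols %||% intersect(
    c("peak", "amplitude", "period_min", "active_min", "pulse_min",
      "silent_min", "plateau_fraction", "avg_signal", "avg_signal_raw",
      "freq1_per_min", "amp1", "freq2_per_min", "amp2"),
    names(params))
  keys <- params[c("strain", "sex", "animal", "segment")]
  agg <- stats::aggregate(params[value_cols], by = keys,
                          FUN = function(v) mean(v, na.rm = TRUE))
  for (cc in value_cols) agg[[cc]][is.nan(agg[[cc]])] <- NA_real_  # all-NA cells
  cnt <- stats::aggregate(list(n_islets = params$islet_id), by = keys, FUN = length)
  out <- merge(agg, cnt, by = c("strain", "sex", "animal", "segment"),
               sort = TRUE)
  out[order(out$strain, out$sex, out$animal, out$segment), , drop = FALSE]
}

#' Animal-by-trait matrix from animal-level summaries
#'
#' Reshapes animal-level averages into one row per animal with one column per
#' `<segment>_<metric>` trait (e.g. `8G_active_min`, `2G_avg`); `avg_signal`
#' is shortened to `avg`. Spectral summaries, if given, contribute
#' `<segment>_freq1` style columns.
#'
#' @param animal_params Output of [summarize_animal()].
#' @param animal_spectra Optional animal-level spectral summary (same keys).
#' @return Data frame: `strain, sex, animal` plus numeric trait columns.
#' @export
animal_trait_matrix <- function(animal_params, animal_spectra = NULL) {
  rename <- c(avg_signal = "avg", avg_signal_raw = "avg_raw",
              period_min = "period_min", active_min = "active_min",
              pulse_min = "pulse_min", silent_min = "silent_min",
              plateau_fraction = "plateau_fraction", peak = "peak",
              amplitude = "amplitude", freq1_per_min = "freq1",
              amp1 = "amp1", freq2_per_min = "freq2", amp2 = "amp2")
  widen <- function(df) {
    vals <- intersect(names(rename), names(df))
    long <- NULL
    for (vc in vals) {
      piece <- data.frame(strain = df$strain, sex = df$sex, animal = df$animal,
                          trait = paste0(df$segment, "_", rename[[vc]]),
                          value = df[[vc]], stringsAsFactors = FALSE)
      long <- rbind(long, piece)
    }
    long
  }
  long <- widen(animal_params)
  if (!is.null(animal_spectra)) long <- rbind(long, widen(animal_spectra))
  wide <- stats::reshape(long, idvar = c("strain", "sex", "animal"),
                         timevar = "trait", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide[order(wide$strain, wide$sex, wide$animal), , drop = FALSE]
}

#' Default focus parameters for candidate flagging
#'
#' The six parameters most strongly tied to insulin secretion and plasma
#' insulin: basal average Ca2+ and the 8G active, 8G pulse, and 8G / 8G+QLA /
#' 8G+QLA+GIP silent durations.
#'
#' @param basal_label Basal segment label (default `"2G"`).
#' @return Character vector of trait column names as produced by
#'   [animal_trait_matrix()].
#' @export
default_focus_params <- function(basal_label = "2G") {
  c(paste0(basal_label, "_avg"),
    "8G_active_min", "8G_pulse_min", "8G_silent_min",
    "8G/QLA_silent_min", "8G/QLA/GIP_silent_min")
}
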