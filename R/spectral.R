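# Mean-removed rectangular-window periodogram, one-sided, scaled so the bin
# powers sum to the (population) variance of the segment. Segments are short
# (400 frames), so no Welch averaging by default.

#' One-sided power spectrum of a trace segment
#'
#' Frequencies are `k / (N * dt)` for `k = 1 .. floor(N/2)` (zero frequency
#' excluded after mean removal); the summed power equals the signal variance
#' (Parseval identity for this estimator).
#'
#' @param trace An [islet_trace()] on a uniform grid with at least 32 frames.
#' @return List of class `islet_spectrum`: `freq` (min^-1), `power`,
#'   `resolution` (bin spacing `1/(N*dt)`, min^-1).
#' @export
power_spectrum <- function(trace) {
  v <- trace$values
  n <- length(v)
  if (n < 32L) stop("power_spectrum needs at least 32 frames")
  dt <- trace_dt(trace)
  x <- stats::fft(v - mean(v))
  m <- n %/% 2L
  p2 <- Mod(x)^2 / n^2          # two-sided
  power <- 2 * p2[2:(m + 1L)]
  if (n %% 2L == 0L) power[m] <- p2[m + 1L]  # Nyquist bin is unpaired
  structure(list(freq = (1:m) / (n * dt), power = power,
                 resolution = 1 / (n * dt)),
            class = "islet_spectrum")
}

#' Top two spectral components
#'
#' The first component is the periodogram argmax (ties resolved toward the
#' lower frequency); the second is the argmax over bins at least
#' `min_separation` bins away from the first, so a leakage sidelobe of the
#' dominant peak is not reported as an independent component. Amplitudes are
#' the periodogram powers at the selected bins (not square-rooted). Flat
#' segments yield `amp1` near zero rather than missing values.
#'
#' @param spectrum An `islet_spectrum` from [power_spectrum()].
#' @param min_separation Guard band around the first component, in bins.
#' @return One-row data frame: `freq1_per_min, amp1, freq2_per_min, amp2,
#'   resolution_per_min` (`freq2`/`amp2` are `NA` when no bin lies outside
#'   the guard band).
#' @export
top_components <- function(spectrum, min_separation = 2) {
  pw <- spectrum$power
  k1 <- which.max(pw)  # first max = lowest frequency on an exact tie
  ok <- which(abs(seq_along(pw) - k1) >= min_separation)
  if (length(ok)) {
    k2 <- ok[which.max(pw[ok])]
    f2 <- spectrum$freq[k2]; a2 <- pw[k2]
  } else {
    f2 <- NA_real_; a2 <- NA_real_
  }
  data.frame(freq1_per_min = spectrum$freq[k1], amp1 = pw[k1],
             freq2_per_min = f2, amp2 = a2,
             resolution_per_min = spectrum$resolution)
}

#' Spectral summaries for every islet and segment
#'
#' Each segment is linearly detrended before the transform, making the
#' component frequencies invariant to constant offsets and linear drift, then
#' summarised by its top two component frequencies and amplitudes.
#'
#' @param x An `islet_cohort` or list of ratio [islet_trace()] objects.
#' @param schedule A [segment_schedule()] (taken from the cohort if `x` is
#'   one).
#' @param min_separation Guard band passed to [top_components()].
#' @param detrend Detrending applied before the transform (default linear,
#'   without mean preservation; mean removal is part of the estimator).
#' @return Data frame, one row per islet x segment: `islet_id, strain, sex,
#'   animal, segment, freq1_per_min, amp1, freq2_per_min, amp2,
#'   resolution_per_min`.
#' @export
compute_spectra <- function(x, schedule = NULL, min_separation = 2,
                            detrend = detrend_settings("linear",
                                                       preserve_mean = FALSE)) {
  if (inherits(x, "islet_cohort")) {
    schedule <- schedule %||% x$schedule
    traces <- x$traces
  } else {
    traces <- x
  }
  if (is.null(schedule)) stop("a segment schedule is required")
  rows <- lapply(traces, function(tr) {
    segs <- segment_trace(tr, schedule)
    seg_rows <- lapply(names(segs), function(lab) {
      det <- detrend_segment(segs[[lab]], detrend)
      cbind(data.frame(islet_id = tr$islet_id, strain = tr$strain,
                       sex = tr$sex, animal = tr$animal, segment = lab,
                       stringsAsFactors = FALSE),
            top_components(power_spectrum(det), min_separation))
    })
    do.call(rbind, seg_rows)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}
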