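#' Construct an islet trace
#'
#' A trace is one islet's Ca2+ signal on a uniform time grid, in minutes, with
#' ratio-unit values (or raw bound/free channel intensities before ratioing)
#' plus cohort metadata.
#'
#' @param time Numeric vector, minutes, strictly increasing uniform grid.
#' @param values Numeric vector of ratio values (may be `NULL` for a raw
#'   two-channel trace).
#' @param islet_id Trace label.
#' @param strain,sex,animal Optional cohort metadata.
#' @param bound,free Optional raw channel intensity vectors (bound = 405-nm
#'   excited, free = 488-nm excited).
#' @return An object of class `islet_trace`.
#' @export
islet_trace <- function(time, values, islet_id,
                        strain = NA_character_, sex = NA_character_,
                        animal = NA_character_, bound = NULL, free = NULL) {
  time <- as.numeric(time)
  if (length(time) < 2L) stop("trace needs at least two frames")
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (max(abs(dt - dt[1L])) > 1e-9 * max(abs(dt[1L]), 1)) {
    stop("time grid is not uniform")
  }
  if (!is.null(values)) {
    values <- as.numeric(values)
    if (length(values) != length(time)) stop("time and values differ in length")
    if (anyNA(values)) stop("trace contains missing values (gaps are an error)")
  }
  structure(
    list(islet_id = as.character(islet_id), time = time, values = values,
         strain = strain, sex = sex, animal = as.character(animal),
         bound = bound, free = free),
    class = "islet_trace")
}

#' @export
print.islet_trace <- function(x, ...) {
  cat(sprintf("<islet_trace> %s: %d frames, %.4g-%.4g min (dt = %.4g min)\n",
              x$islet_id, length(x$time), x$time[1L],
              x$time[length(x$time)], trace_dt(x)))
  invisible(x)
}

#' Sampling interval of a trace, in minutes
#' @param trace An `islet_trace`.
#' @return Sampling interval (minutes).
#' @export
trace_dt <- function(trace) trace$time[2L] - trace$time[1L]

#' Construct a condition-segment schedule
#'
#' Ordered, non-overlapping stimulus windows. Frames are assigned by half-open
#' membership `start <= t < end`, so a frame exactly on a boundary belongs to
#' the later segment.
#'
#' @param label Character vector of condition names.
#' @param start_min,end_min Numeric vectors of segment bounds in minutes.
#' @return A `data.frame` of class `segment_schedule` with columns
#'   `segment`, `label`, `start_min`, `end_min`.
#' @export
segment_schedule <- function(label, start_min, end_min) {
  if (length(label) != length(start_min) || length(label) != length(end_min)) {
    stop("label, start_min, end_min must have equal length")
  }
  sched <- data.frame(segment = seq_along(label), label = as.character(label),
                      start_min = as.numeric(start_min),
                      end_min = as.numeric(end_min),
                      stringsAsFactors = FALSE)
  if (nrow(sched) > 0L) {
    if (any(sched$end_min <= sched$start_min)) stop("each segment end must exceed its start")
    o <- order(sched$start_min)
    if (any(sched$start_min[o][-1L] < sched$end_min[o][-length(o)] - 1e-9)) {
      stop("segments overlap")
    }
  }
  class(sched) <- c("segment_schedule", "data.frame")
  sched
}

#' Default four-condition stimulus schedule
#'
#' Four consecutive 40-min solution windows: 8 mM glucose (8G), 8G plus
#' glutamine/leucine/alanine (8G/QLA), plus 10 nM GIP (8G/QLA/GIP), then basal
#' 2 mM glucose (2G).
#'
#' @param segment_length Minutes per condition window (default 40).
#' @return A `segment_schedule`.
#' @export
default_schedule <- function(segment_length = 40) {
  labs <- c("8G", "8G/QLA", "8G/QLA/GIP", "2G")
  starts <- (seq_along(labs) - 1L) * segment_length
  segment_schedule(labs, starts, starts + segment_length)
}
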