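# Ingestion starts at exported ROI intensity tables; no image processing here.
# Two-channel columns are recognised by the `_b` (bound) / `_f` (free) suffix
# convention; a column without a channel suffix is taken as a precomputed
# ratio.

#' Read an ROI intensity table
#'
#' Wide layout: first column is time in minutes (`time_min` or `time`), one
#' column per islet (`<id>` for a ratio trace, or the pair `<id>_b` / `<id>_f`
#' for bound/free channels). Long layout: columns `time`, `islet`, `channel`
#' (`ratio`, `b`, or `f`), `value`. Islet ids of the form
#' `strain_sex_animal_islet` have their metadata re-derived.
#'
#' @param path CSV (or TSV, by file extension) path.
#' @param layout `"wide"` or `"long"`.
#' @return Named list of [islet_trace()] objects; two-channel traces carry
#'   `bound`/`free` and `values = NULL` until [as_ratio_trace()] is applied.
#' @export
read_roi_table <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (layout == "wide") {
    tcol <- intersect(c("time_min", "time"), names(df))
    if (!length(tcol)) stop("no time column (time_min or time) found")
    time <- df[[tcol[1L]]]
    check_time(time)
    cols <- setdiff(names(df), tcol[1L])
    ids <- sub("_[bf]$", "", cols)
    if (anyDuplicated(ids[!grepl("_[bf]$", cols)])) stop("duplicated islet id")
    out <- list()
    for (id in unique(ids)) {
      sub <- cols[ids == id]
      if (all(sub == id)) {
        out[[id]] <- make_meta_trace(time, values = df[[id]], id = id)
      } else {
        b <- paste0(id, "_b"); f <- paste0(id, "_f")
        if (!all(c(b, f) %in% sub)) {
          stop("islet ", id, " has an unpaired channel column")
        }
        out[[id]] <- make_meta_trace(time, id = id,
                                     bound = df[[b]], free = df[[f]])
      }
    }
    out
  } else {
    need <- c("time", "islet", "channel", "value")
    if (!all(need %in% names(df))) {
      stop("long layout needs columns: ", paste(need, collapse = ", "))
    }
    out <- list()
    for (id in unique(df$islet)) {
      sub <- df[df$islet == id, , drop = FALSE]
      chans <- unique(sub$channel)
      if (identical(chans, "ratio")) {
        sub <- sub[order(sub$time), , drop = FALSE]
        check_time(sub$time)
        out[[id]] <- make_meta_trace(sub$time, values = sub$value, id = id)
      } else if (setequal(chans, c("b", "f"))) {
        b <- sub[sub$channel == "b", , drop = FALSE]; b <- b[order(b$time), ]
        f <- sub[sub$channel == "f", , drop = FALSE]; f <- f[order(f$time), ]
        if (!isTRUE(all.equal(b$time, f$time))) {
          stop("bound/free time grids differ for islet ", id)
        }
        check_time(b$time)
        out[[id]] <- make_meta_trace(b$time, id = id, bound = b$value,
                                     free = f$value)
      } else {
        stop("islet ", id, " has unrecognised channels: ",
             paste(chans, collapse = ", "))
      }
    }
    out
  }
}

check_time <- function(time) {
  if (anyNA(time)) stop("missing time values")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  invisible(time)
}

make_meta_trace <- function(time, values = NULL, id, bound = NULL, free = NULL) {
  parts <- strsplit(id, "_", fixed = TRUE)[[1L]]
  meta <- if (length(parts) >= 4L) {
    k <- length(parts)
    list(strain = paste(parts[seq_len(k - 3L)], collapse = "_"),
         sex = parts[k - 2L],
         animal = paste(parts[seq_len(k - 1L)], collapse = "_"))
  } else {
    list(strain = NA_character_, sex = NA_character_, animal = NA_character_)
  }
  islet_trace(time, values, islet_id = id, strain = meta$strain,
              sex = meta$sex, animal = meta$animal, bound = bound, free = free)
}

#' Write traces to a CSV table
#'
#' Wide layout writes `time_min` plus one column per islet id (ratio traces)
#' or `<id>_b`/`<id>_f` pairs (two-channel traces); all traces must share one
#' time grid. Long layout stacks `time, islet, channel, value` rows.
#'
#' @param traces List of [islet_trace()] objects (or an `islet_cohort`).
#' @param path Output CSV path.
#' @param layout `"wide"` or `"long"`.
#' @return Invisibly, `path`.
#' @export
write_roi_table <- function(traces, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (inherits(traces, "islet_cohort")) traces <- traces$traces
  if (layout == "wide") {
    time <- traces[[1L]]$time
    cols <- list(time_min = time)
    for (tr in traces) {
      if (!isTRUE(all.equal(tr$time, time))) {
        stop("wide layout needs a shared time grid")
      }
      if (!is.null(tr$values)) {
        cols[[tr$islet_id]] <- tr$values
      } else {
        cols[[paste0(tr$islet_id, "_b")]] <- tr$bound
        cols[[paste0(tr$islet_id, "_f")]] <- tr$free
      }
    }
    df <- as.data.frame(cols, check.names = FALSE, optional = TRUE)
    names(df) <- names(cols)
  } else {
    rows <- lapply(traces, function(tr) {
      if (!is.null(tr$values)) {
        data.frame(time = tr$time, islet = tr$islet_id, channel = "ratio",
                   value = tr$values, stringsAsFactors = FALSE)
      } else {
        rbind(data.frame(time = tr$time, islet = tr$islet_id, channel = "b",
                         value = tr$bound, stringsAsFactors = FALSE),
              data.frame(time = tr$time, islet = tr$islet_id, channel = "f",
                         value = tr$free, stringsAsFactors = FALSE))
      }
    })
    df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a condition-segment schedule CSV
#'
#' Columns `segment, label, start_min, end_min`; times in minutes.
#'
#' @param path CSV path.
#' @return [segment_schedule()] (reader) or `path`, invisibly (writer).
#' @export
read_schedule <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  segment_schedule(df$label, df$start_min, df$end_min)
}

#' @rdname read_schedule
#' @param schedule A [segment_schedule()].
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Compute the Fura ratio from bound and free channel intensities
#'
#' Ratio = bound / free, elementwise, oriented so the ratio rises with Ca2+
#' (bound dye excited at 405 nm in the numerator, free dye excited at 488 nm
#' in the denominator).
#'
#' @param bound,free Equal-length numeric intensity vectors; `free` must be
#'   strictly positive.
#' @return Numeric ratio vector.
#' @export
compute_fura_ratio <- function(bound, free) {
  if (length(bound) != length(free)) stop("bound and free differ in length")
  if (any(!is.na(free) & free <= 0)) stop("free-channel intensities must be positive")
  bound / free
}

#' Convert a two-channel trace to a ratio trace
#'
#' @param trace An [islet_trace()] carrying `bound`/`free` channels.
#' @return The trace with `values` set to the Fura ratio.
#' @export
as_ratio_trace <- function(trace) {
  if (!is.null(trace$values)) return(trace)
  islet_trace(trace$time, compute_fura_ratio(trace$bound, trace$free),
              islet_id = trace$islet_id, strain = trace$strain,
              sex = trace$sex, animal = trace$animal)
}

#' Slice a trace into condition segments
#'
#' Frames are assigned by half-open membership `start <= t < end`, so a frame
#' exactly on a boundary belongs to the later segment and concatenating the
#' segments of a contiguous schedule reproduces the trace.
#'
#' @param trace An [islet_trace()].
#' @param schedule A [segment_schedule()]; must lie within the trace's span
#'   (a segment may end up to one sampling interval past the last frame).
#' @return Named list (by segment label) of [islet_trace()] segments.
#' @export
segment_trace <- function(trace, schedule) {
  if (nrow(schedule) == 0L) return(stats::setNames(list(), character()))
  dt <- trace_dt(trace)
  t0 <- trace$time[1L]; t1 <- trace$time[length(trace$time)]
  tol <- 1e-9 * max(1, abs(t1))
  if (any(schedule$start_min < t0 - tol) ||
      any(schedule$end_min > t1 + dt + tol)) {
    stop("schedule extends outside the trace time span")
  }
  out <- vector("list", nrow(schedule))
  names(out) <- schedule$label
  for (k in seq_len(nrow(schedule))) {
    sel <- trace$time >= schedule$start_min[k] - tol &
      trace$time < schedule$end_min[k] - tol
    out[[k]] <- islet_trace(trace$time[sel], trace$values[sel],
                            islet_id = trace$islet_id, strain = trace$strain,
                            sex = trace$sex, animal = trace$animal)
  }
  out
}
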