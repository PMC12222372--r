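#' Acquisition frame schedule
#'
#' Describes the time binning of a dynamic PET acquisition as contiguous,
#' non-overlapping frames. The default schedule used throughout the package is
#' the 24-frame protocol 14 x 5 s, 3 x 10 s, 3 x 20 s, 4 x 30 s, covering
#' 280 s from injection-synchronised scan start.
#'
#' @param frame_start numeric vector of frame start times in seconds.
#' @param frame_end numeric vector of frame end times in seconds.
#' @return An object of class `frame_schedule`.
#' @export
frame_schedule <- function(frame_start, frame_end) {
  if (length(frame_start) < 1L || length(frame_start) != length(frame_end))
    stop("frame_start and frame_end must be non-empty and of equal length")
  if (any(frame_end <= frame_start))
    stop("every frame must have positive duration")
  if (is.unsorted(frame_start, strictly = TRUE))
    stop("frame schedule must be strictly increasing")
  if (length(frame_start) > 1L &&
      any(abs(frame_start[-1L] - frame_end[-length(frame_end)]) > 1e-9))
    stop("frames must be contiguous and non-overlapping")
  structure(
    list(frame_start = as.numeric(frame_start),
         frame_end = as.numeric(frame_end)),
    class = "frame_schedule"
  )
}

#' @rdname frame_schedule
#' @export
default_frame_schedule <- function() {
  dur <- c(rep(5, 14), rep(10, 3), rep(20, 3), rep(30, 4))
  ends <- cumsum(dur)
  frame_schedule(ends - dur, ends)
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule: %d frames, 0-%g s>\n",
              n_frames(x), max(x$frame_end)))
  invisible(x)
}

#' @rdname frame_schedule
#' @param schedule a `frame_schedule`.
#' @export
n_frames <- function(schedule) length(schedule$frame_start)

#' @rdname frame_schedule
#' @export
frame_midpoints <- function(schedule) {
  (schedule$frame_start + schedule$frame_end) / 2
}

#' @rdname frame_schedule
#' @export
frame_durations <- function(schedule) {
  schedule$frame_end - schedule$frame_start
}

voi_labels <- c("aorta", "portal_vein", "liver", "spleen", "model")

#' Per-frame time-activity curve
#'
#' A measured (or frame-averaged) activity concentration per acquisition
#' frame, in Bq/mL, for one volume of interest. Decay- and scatter-corrected
#' PET data can go slightly negative; negative values are rejected unless
#' `allow_negative = TRUE`.
#'
#' @param schedule a [frame_schedule()].
#' @param values numeric activity per frame, Bq/mL.
#' @param label role tag, one of `"aorta"`, `"portal_vein"`, `"liver"`,
#'   `"spleen"`, `"model"`.
#' @param allow_negative permit negative activities.
#' @return An object of class `frame_tac`.
#' @export
frame_tac <- function(schedule, values, label = "model",
                      allow_negative = FALSE) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (length(values) == 0L) stop("empty TAC")
  if (length(values) != n_frames(schedule))
    stop("values length must equal the number of frames")
  if (!all(is.finite(values))) stop("TAC values must be finite")
  if (!allow_negative && any(values < 0))
    stop("negative activities; pass allow_negative = TRUE to keep them")
  label <- match.arg(label, voi_labels)
  structure(
    list(schedule = schedule, values = as.numeric(values), label = label),
    class = "frame_tac"
  )
}

#' @export
print.frame_tac <- function(x, ...) {
  cat(sprintf("<frame_tac '%s': %d frames, peak %.4g Bq/mL>\n",
              x$label, n_frames(x$schedule), max(x$values)))
  invisible(x)
}

#' Activity curve on the 1-second grid
#'
#' Activity concentration at t = 1, 2, ..., T seconds (default T = 280). By
#' convention the curve is zero at and before t = 0; all model recursions
#' operate on this grid.
#'
#' @param values numeric activity at t = 1..T, Bq/mL.
#' @param label role tag (see [frame_tac()]).
#' @return An object of class `sampled_curve`.
#' @export
sampled_curve <- function(values, label = "model") {
  if (length(values) == 0L) stop("empty curve")
  if (!all(is.finite(values))) stop("curve values must be finite")
  label <- match.arg(label, voi_labels)
  structure(list(values = as.numeric(values), label = label),
            class = "sampled_curve")
}

#' @export
print.sampled_curve <- function(x, ...) {
  cat(sprintf("<sampled_curve '%s': t = 1..%d s, peak %.4g Bq/mL>\n",
              x$label, length(x$values), max(x$values)))
  invisible(x)
}

#' Interpolate a frame TAC to the 1-second grid
#'
#' Each frame value is anchored at the frame's temporal midpoint (the
#' standard unbiased anchor for a frame mean), with a zero anchor at t = 0.
#' Values are linear between anchors and constant from the last midpoint to
#' `t_max`.
#'
#' @param tac a [frame_tac()].
#' @param t_max final grid second; default 280.
#' @return A [sampled_curve()] on t = 1..`t_max`.
#' @export
interpolate_to_seconds <- function(tac, t_max = 280L) {
  stopifnot(inherits(tac, "frame_tac"))
  if (max(tac$schedule$frame_end) > t_max)
    stop("schedule extends past t_max")
  mids <- frame_midpoints(tac$schedule)
  out <- stats::approx(x = c(0, mids), y = c(0, tac$values),
                       xout = seq_len(t_max), rule = 2)$y
  sampled_curve(out, tac$label)
}

#' Frame-average a sampled curve onto a schedule
#'
#' The inverse-direction operation of [interpolate_to_seconds()]: each frame
#' value is the arithmetic mean of the 1-s samples with
#' frame_start < t <= frame_end. Used both by the synthetic generator and by
#' the frame-level error metrics, which compare on the original acquisition
#' frames.
#'
#' @param curve a [sampled_curve()].
#' @param schedule a [frame_schedule()].
#' @return A [frame_tac()].
#' @export
frame_average <- function(curve, schedule) {
  stopifnot(inherits(curve, "sampled_curve"),
            inherits(schedule, "frame_schedule"))
  if (max(schedule$frame_end) > length(curve$values))
    stop("schedule extends past the curve")
  vals <- vapply(seq_len(n_frames(schedule)), function(i) {
    t <- seq.int(floor(schedule$frame_start[i]) + 1L,
                 floor(schedule$frame_end[i]))
    mean(curve$values[t])
  }, numeric(1))
  frame_tac(schedule, vals, curve$label, allow_negative = TRUE)
}

#' Shift a sampled curve right by an integer delay
#'
#' Implements the delay arguments of the kinetic models:
#' output(i) = input(i - delta), zero-padded on the left. Delays are integer
#' seconds by construction (the delay grid is integer-valued).
#'
#' @param curve a [sampled_curve()].
#' @param delta non-negative integer delay in seconds.
#' @return A [sampled_curve()] of the same length and label.
#' @export
shift_curve <- function(curve, delta) {
  stopifnot(inherits(curve, "sampled_curve"))
  if (length(delta) != 1L || !is.finite(delta) || delta < 0 ||
      delta != round(delta))
    stop("delta must be a single non-negative integer")
  sampled_curve(lag_values(curve$values, as.integer(delta)), curve$label)
}

# out[i] = x[i - lag], zeros before the data start; lag >= 0
lag_values <- function(x, lag) {
  n <- length(x)
  if (lag == 0L) return(x)
  if (lag >= n) return(numeric(n))
  c(numeric(lag), x[seq_len(n - lag)])
}

#' Read and write time-activity curve tables
#'
#' TAC tables are TSV with columns `frame_start_s`, `frame_end_s`,
#' `activity_Bq_per_mL`, and optionally a `voi` column holding the role tag
#' when several VOIs share one file.
#'
#' @param path file path.
#' @param allow_negative permit negative activities when reading.
#' @return `read_tacs()` returns a named list of [frame_tac()] objects (one
#'   per `voi` value, or a single unnamed-role entry named `"model"`).
#' @export
read_tacs <- function(path, allow_negative = TRUE) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("frame_start_s", "frame_end_s", "activity_Bq_per_mL")
  if (!all(need %in% names(df)))
    stop("TAC table must have columns: ", paste(need, collapse = ", "))
  if (!"voi" %in% names(df)) df$voi <- "model"
  out <- lapply(split(df, df$voi), function(d) {
    d <- d[order(d$frame_start_s), ]
    frame_tac(frame_schedule(d$frame_start_s, d$frame_end_s),
              d$activity_Bq_per_mL, d$voi[1L],
              allow_negative = allow_negative)
  })
  out
}

#' @rdname read_tacs
#' @param tacs a named list of [frame_tac()] objects.
#' @export
write_tacs <- function(tacs, path) {
  if (inherits(tacs, "frame_tac")) tacs <- stats::setNames(list(tacs), tacs$label)
  rows <- lapply(tacs, function(tac) {
    data.frame(voi = tac$label,
               frame_start_s = tac$schedule$frame_start,
               frame_end_s = tac$schedule$frame_end,
               activity_Bq_per_mL = tac$values)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_tacs
#' @param curve a [sampled_curve()].
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "sampled_curve"))
  df <- data.frame(t_s = seq_along(curve$values),
                   activity_Bq_per_mL = curve$values)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
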