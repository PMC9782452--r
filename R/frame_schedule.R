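#' PET frame schedules
#'
#' A frame schedule is an ordered set of non-overlapping acquisition frames,
#' each defined by its start time and duration in seconds.  Frame values are
#' taken to represent the time-average of the (decay-corrected) activity over
#' the frame, and the frame mid-time (in minutes) is used whenever a single
#' time point must stand for the frame.
#'
#' @param start_s numeric vector of frame start times (seconds).
#' @param dur_s numeric vector of frame durations (seconds); must be positive.
#' @return A data frame of class `frame_schedule` with columns `start_s`,
#'   `dur_s`, `end_s` and `mid_min`.
#' @examples
#' fs_thorax()              # 4x15, 6x20, 2x60, 2x150, 6x300 s over 0-40 min
#' frame_schedule(0, 600)   # one static 10-min frame
#' @export
frame_schedule <- function(start_s, dur_s) {
  if (length(start_s) != length(dur_s))
    stop("'start_s' and 'dur_s' must have the same length", call. = FALSE)
  if (length(start_s) == 0L)
    stop("a frame schedule needs at least one frame", call. = FALSE)
  if (any(!is.finite(start_s)) || any(!is.finite(dur_s)))
    stop("frame times must be finite", call. = FALSE)
  if (any(dur_s <= 0))
    stop("frame durations must be positive", call. = FALSE)
  o <- order(start_s)
  start_s <- start_s[o]
  dur_s <- dur_s[o]
  end_s <- start_s + dur_s
  if (length(start_s) > 1L && any(start_s[-1L] < end_s[-length(end_s)] - 1e-9))
    stop("frames must not overlap", call. = FALSE)
  out <- data.frame(start_s = start_s, dur_s = dur_s, end_s = end_s,
                    mid_min = (start_s + dur_s / 2) / 60)
  class(out) <- c("frame_schedule", "data.frame")
  out
}

## build a schedule from (count, duration) blocks starting at t0_s
fs_blocks <- function(counts, dur_s, t0_s = 0) {
  durs <- rep(dur_s, counts)
  starts <- t0_s + cumsum(c(0, durs))[seq_along(durs)]
  frame_schedule(starts, durs)
}

#' Frame-schedule presets
#'
#' Presets matching the acquisition protocol the simulator emulates: a
#' dynamic thoracic scan over 0--40 min (4x15, 6x20, 2x60, 2x150 and
#' 6x300 s frames), 3x300 s dynamic blocks for the upper abdomen
#' (40--55 min) and the thighs (55--70 min), and single 600 s static frames
#' for the neck (70--80 min) and the brain (80--90 min).
#'
#' @param start_s start of the first frame in seconds; the defaults place the
#'   blocks back to back in the order thorax, abdomen, thigh, neck, brain.
#' @param dur_s static frame duration in seconds.
#' @return A [frame_schedule()].
#' @export
fs_thorax <- function(start_s = 0)
  fs_blocks(c(4L, 6L, 2L, 2L, 6L), c(15, 20, 60, 150, 300), start_s)

#' @rdname fs_thorax
#' @export
fs_abdomen <- function(start_s = 2400) fs_blocks(3L, 300, start_s)

#' @rdname fs_thorax
#' @export
fs_thigh <- function(start_s = 3300) fs_blocks(3L, 300, start_s)

#' @rdname fs_thorax
#' @export
fs_static <- function(start_s, dur_s = 600) frame_schedule(start_s, dur_s)

#' Time-activity curves
#'
#' A time-activity curve (TAC) attaches one activity value (kBq/mL,
#' decay-corrected) to every frame of a schedule.
#'
#' @param schedule a [frame_schedule()].
#' @param activity numeric vector of frame activities (kBq/mL), one per frame.
#' @param region optional region name.
#' @return A data frame of class `tac` with the schedule columns plus
#'   `activity`; the region name is kept in attribute `"region"`.
#' @export
tac <- function(schedule, activity, region = NA_character_) {
  if (!inherits(schedule, "frame_schedule"))
    stop("'schedule' must be a frame_schedule", call. = FALSE)
  if (length(activity) != nrow(schedule))
    stop("'activity' must have one value per frame", call. = FALSE)
  out <- cbind(as.data.frame(schedule), activity = as.numeric(activity))
  attr(out, "region") <- region
  class(out) <- c("tac", "data.frame")
  out
}

#' Average a continuous curve over the frames of a schedule
#'
#' Each frame value is the mean of the curve over the frame,
#' (1/duration) * integral over [start, end], evaluated by composite
#' Simpson quadrature with `subdiv` subintervals per frame (exact for
#' polynomials up to degree 3; for smooth tracer curves the default is
#' accurate to well below 1e-6 relative).
#'
#' @param f a vectorized function of time in minutes returning activity in
#'   kBq/mL, defined over all frames.
#' @param schedule a [frame_schedule()].
#' @param subdiv even number of Simpson subintervals per frame.
#' @param region optional region name passed to [tac()].
#' @return A [tac()].
#' @export
frame_average <- function(f, schedule, subdiv = 64L, region = NA_character_) {
  if (!inherits(schedule, "frame_schedule"))
    stop("'schedule' must be a frame_schedule", call. = FALSE)
  if (subdiv < 2L || subdiv %% 2L != 0L)
    stop("'subdiv' must be a positive even integer", call. = FALSE)
  vals <- vapply(seq_len(nrow(schedule)), function(i) {
    a <- schedule$start_s[i] / 60
    b <- schedule$end_s[i] / 60
    simpson_mean(f, a, b, subdiv)
  }, numeric(1))
  tac(schedule, vals, region = region)
}

## mean of f over [a, b] by composite Simpson with n subintervals (n even)
simpson_mean <- function(f, a, b, n) {
  x <- seq(a, b, length.out = n + 1L)
  y <- f(x)
  h <- (b - a) / n
  w <- rep(c(4, 2), length.out = n - 1L)
  integral <- h / 3 * (y[1L] + sum(w * y[2:n]) + y[n + 1L])
  integral / (b - a)
}

#' Add frame-duration-scaled noise to a time-activity curve
#'
#' Gaussian noise on frame means with standard deviation
#' `scale * sqrt(activity / duration_min)`, the usual count-statistics
#' approximation in which variance scales with the activity level and
#' inversely with frame duration.  `scale` is a unitless level; 0 disables
#' noise.  Negative noisy values are kept unless `clamp_nonneg = TRUE`.
#'
#' @param x a [tac()].
#' @param scale noise scale (>= 0).
#' @param clamp_nonneg truncate noisy values at zero.
#' @return A [tac()] with perturbed activities.
#' @export
tac_add_noise <- function(x, scale, clamp_nonneg = FALSE) {
  if (!inherits(x, "tac")) stop("'x' must be a tac", call. = FALSE)
  if (scale < 0) stop("'scale' must be nonnegative", call. = FALSE)
  if (scale == 0) return(x)
  sd <- scale * sqrt(pmax(x$activity, 0) / (x$dur_s / 60))
  x$activity <- x$activity + stats::rnorm(nrow(x), 0, sd)
  if (clamp_nonneg) x$activity <- pmax(x$activity, 0)
  x
}
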