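#' Input functions: plasma tracer concentration over time
#'
#' An `input_function` holds the arterial(ized) plasma tracer curve
#' \eqn{C_p(t)} as ordered knots, each flagged with its provenance
#' (`"idif"` for the image-derived segment, `"plasma"` for arterialized
#' samples), linear interpolation between knots, an implicit origin at
#' `(0, 0)` when the first knot is after time zero (there is no tracer
#' before the injection), and a mono-exponential tail fitted to the last
#' `tail_n` plasma knots for extrapolation beyond the data.
#'
#' @param time sorted, unique, nonnegative knot times (min from injection).
#' @param activity nonnegative knot activities (kBq/mL, decay-corrected).
#' @param source character vector of knot provenance, `"idif"` or
#'   `"plasma"` (recycled).
#' @param tail_n number of trailing plasma knots used for the tail fit.
#' @return An object of class `input_function` with elements `time`,
#'   `activity`, `source` and `tail` (list with `a0`, `lambda`, `t0`, or
#'   `NULL` when no tail could be fitted).
#' @export
input_function <- function(time, activity, source = "plasma", tail_n = 3L) {
  if (length(time) != length(activity))
    stop("'time' and 'activity' must have the same length", call. = FALSE)
  if (length(time) < 2L)
    stop("an input function needs at least 2 knots", call. = FALSE)
  if (any(time < 0)) stop("knot times must be nonnegative", call. = FALSE)
  if (is.unsorted(time, strictly = TRUE))
    stop("knot times must be sorted and unique", call. = FALSE)
  if (any(activity < 0))
    stop("knot activities must be nonnegative", call. = FALSE)
  source <- rep_len(as.character(source), length(time))
  if (!all(source %in% c("idif", "plasma")))
    stop("'source' must be \"idif\" or \"plasma\"", call. = FALSE)
  obj <- structure(list(time = as.numeric(time),
                        activity = as.numeric(activity),
                        source = source, tail = NULL),
                   class = "input_function")
  obj$tail <- fit_exp_tail(obj, tail_n)
  obj
}

## mono-exponential tail C(t) = a0 * exp(-lambda * (t - t0)) fitted by
## log-linear least squares to the last n plasma knots (all knots if no
## plasma knots exist); NULL when fewer than 2 positive knots are available
## or the fitted slope is nonnegative (no decaying tail).
fit_exp_tail <- function(f, n = 3L) {
  idx <- which(f$source == "plasma")
  if (length(idx) < 2L) idx <- seq_along(f$time)
  idx <- utils::tail(idx, n)
  t <- f$time[idx]
  a <- f$activity[idx]
  keep <- a > 0
  if (sum(keep) < 2L) return(NULL)
  t <- t[keep]
  a <- a[keep]
  co <- stats::lm.fit(cbind(1, t), log(a))$coefficients
  lambda <- -co[[2L]]
  if (!is.finite(lambda) || lambda <= 0) return(NULL)
  t0 <- utils::tail(f$time, 1L)
  list(a0 = exp(co[[1L]] - lambda * t0), lambda = lambda, t0 = t0)
}

#' Evaluate an input function
#'
#' Linear interpolation between knots; linear from the implicit `(0, 0)`
#' origin below the first knot; mono-exponential tail beyond the last knot
#' (an error if no tail could be fitted).  Values are never negative.
#'
#' @param object an [input_function()].
#' @param times evaluation times (min).
#' @param ... unused.
#' @return Activities (kBq/mL) at `times`.
#' @export
predict.input_function <- function(object, times, ...) {
  kt <- object$time
  ka <- object$activity
  if (kt[1L] > 0) {
    kt <- c(0, kt)
    ka <- c(0, ka)
  }
  out <- numeric(length(times))
  inside <- times <= kt[length(kt)]
  if (any(inside))
    out[inside] <- stats::approx(kt, ka, xout = times[inside],
                                 rule = 2)$y
  if (any(!inside)) {
    if (is.null(object$tail))
      stop("evaluation beyond the last knot requires a fitted tail",
           call. = FALSE)
    tl <- object$tail
    out[!inside] <- tl$a0 * exp(-tl$lambda * (times[!inside] - tl$t0))
  }
  pmax(out, 0)
}

#' Assemble the hybrid input function
#'
#' Combines an image-derived input function (IDIF; e.g. a left-ventricle
#' time-activity curve) used from time 0 up to `switch_time` with
#' arterialized plasma samples used from `switch_time` onward.  At the
#' switch time itself the plasma value wins (blood sampling is the
#' reference measurement).  By default the image-derived segment is used
#' as measured; `calibrate = TRUE` rescales it multiplicatively so that
#' its interpolated value matches the first plasma sample.
#'
#' @param idif a [tac()] of the blood-pool region; frame mid-times become
#'   knot times.
#' @param samples data frame with columns `time_min` and
#'   `activity_kbq_per_ml` (arterialized plasma), sorted in time.
#' @param switch_time minutes; knots before it come from the IDIF, knots at
#'   or after it from plasma.  Default 4.5 min.
#' @param calibrate rescale the IDIF segment to the first plasma sample.
#' @param max_gap_min largest tolerated gap (min) between the last IDIF
#'   knot and the first plasma knot around the switch.
#' @return An [input_function()].
#' @export
build_hybrid_input <- function(idif, samples, switch_time = 4.5,
                               calibrate = FALSE, max_gap_min = 5) {
  if (!inherits(idif, "tac")) stop("'idif' must be a tac", call. = FALSE)
  need <- c("time_min", "activity_kbq_per_ml")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("'samples' is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  st <- samples$time_min
  sa <- samples$activity_kbq_per_ml
  if (is.unsorted(st, strictly = TRUE))
    stop("plasma samples must be sorted with unique times", call. = FALSE)
  if (idif$start_s[1L] / 60 > 1e-9 || idif$mid_min[1L] >= switch_time)
    stop("'idif' must cover [0, switch_time]", call. = FALSE)
  keep_p <- st >= switch_time
  if (sum(keep_p) < 2L)
    stop("need at least 2 plasma samples at or after 'switch_time'",
         call. = FALSE)
  keep_i <- idif$mid_min < switch_time
  ti <- idif$mid_min[keep_i]
  ai <- idif$activity[keep_i]
  tp <- st[keep_p]
  ap <- sa[keep_p]
  if (tp[1L] - utils::tail(ti, 1L) > max_gap_min)
    stop("coverage gap at the switch time between IDIF and plasma samples",
         call. = FALSE)
  if (calibrate) {
    ## reference from the full image-derived curve (which usually extends
    ## past the switch), so no flat extrapolation across the junction
    ref <- stats::approx(idif$mid_min, idif$activity, xout = tp[1L],
                         rule = 2)$y
    if (ref > 0) ai <- ai * ap[1L] / ref
  }
  input_function(c(ti, tp), c(ai, ap),
                 source = rep(c("idif", "plasma"),
                              c(length(ti), length(tp))))
}

#' Area under an input function
#'
#' Trapezoidal integral of the piecewise-linear knot curve (including the
#' implicit `(0, 0)` origin) between `t_start` and `t_end`.  With
#' `extrapolate = TRUE`, integration beyond the last knot (including to
#' `t_end = Inf`) uses the fitted mono-exponential tail; without it, such a
#' request is an error.  Computed as `AUC(0, t_end) - AUC(0, t_start)`, so
#' adjacent intervals add exactly.
#'
#' @param f an [input_function()], or a plain function of minutes (then
#'   integrated numerically with [stats::integrate()]).
#' @param t_end,t_start integration bounds (min), `t_end >= t_start >= 0`.
#' @param extrapolate allow the tail beyond the last knot.
#' @return The integral in kBq min/mL.
#' @export
auc <- function(f, t_end, t_start = 0, extrapolate = FALSE) {
  UseMethod("auc")
}

#' @export
auc.input_function <- function(f, t_end, t_start = 0, extrapolate = FALSE) {
  if (t_end < t_start || t_start < 0)
    stop("need 0 <= t_start <= t_end", call. = FALSE)
  auc0(f, t_end, extrapolate) - auc0(f, t_start, extrapolate)
}

#' @export
auc.function <- function(f, t_end, t_start = 0, extrapolate = FALSE) {
  if (t_end < t_start || t_start < 0)
    stop("need 0 <= t_start <= t_end", call. = FALSE)
  stats::integrate(f, t_start, t_end, rel.tol = 1e-10,
                   subdivisions = 1000L)$value
}

## AUC(0, t) of the knot polyline, with tail beyond the last knot
auc0 <- function(f, t, extrapolate) {
  kt <- f$time
  ka <- f$activity
  if (kt[1L] > 0) {
    kt <- c(0, kt)
    ka <- c(0, ka)
  }
  tmax <- kt[length(kt)]
  if (t > tmax && !extrapolate)
    stop("'t' is beyond the last knot; set extrapolate = TRUE",
         call. = FALSE)
  tcap <- min(t, tmax)
  keep <- kt < tcap
  tt <- c(kt[keep], tcap)
  aa <- c(ka[keep], stats::approx(kt, ka, xout = tcap)$y)
  base <- if (length(tt) > 1L)
    sum(diff(tt) * (utils::head(aa, -1L) + utils::tail(aa, -1L)) / 2)
  else 0
  if (t <= tmax) return(base)
  if (is.null(f$tail))
    stop("no mono-exponential tail could be fitted", call. = FALSE)
  tl <- f$tail
  base + tl$a0 / tl$lambda *
    (exp(-tl$lambda * (tmax - tl$t0)) -
       (if (is.finite(t)) exp(-tl$lambda * (t - tl$t0)) else 0))
}
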