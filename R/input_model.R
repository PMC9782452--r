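#' Parametric arterial input model
#'
#' Tri-exponential bolus model with a linear ramp term and an appearance
#' delay, the standard parametric description of an FDG arterial plasma
#' curve.  With `u = t - delay`,
#' \deqn{C_p(t) = (A_1 u - A_2 - A_3) e^{\lambda_1 u}
#'              + A_2 e^{\lambda_2 u} + A_3 e^{\lambda_3 u}, \quad u \ge 0,}
#' and 0 before the delay.  The convention here is decaying exponentials
#' with negative rate constants, `l1 <= l2 <= l3 < 0` (1/min); `a1` carries
#' units kBq/mL/min and `a2`, `a3` kBq/mL.  The curve is continuous at the
#' delay (value 0) and, for the default parameters, nonnegative on
#' `[0, Inf)`; tiny negative excursions for other parameter choices are
#' clipped to zero.
#'
#' The defaults describe a sharp bolus with a fast distribution phase and a
#' slow terminal phase whose 0-to-infinity integral is about
#' 193 kBq min/mL, consistent with a ~156 MBq injection and a whole-body
#' plasma clearance typical of an insulin-stimulated study.
#'
#' @param a1,a2,a3 amplitudes (a1 in kBq/mL/min, a2 and a3 in kBq/mL); all
#'   nonnegative.
#' @param l1,l2,l3 rate constants (1/min), `l1 <= l2 <= l3 < 0`.
#' @param delay appearance delay (min), nonnegative.
#' @return An object of class `input_model_params`.
#' @export
input_model_params <- function(a1 = 600, a2 = 6, a3 = 1.6,
                               l1 = -4, l2 = -0.25, l3 = -0.012,
                               delay = 0.5) {
  if (any(c(a1, a2, a3) < 0))
    stop("amplitudes must be nonnegative", call. = FALSE)
  if (!(l1 <= l2 && l2 <= l3 && l3 < 0))
    stop("rate constants must satisfy l1 <= l2 <= l3 < 0", call. = FALSE)
  if (delay < 0) stop("'delay' must be nonnegative", call. = FALSE)
  structure(list(a1 = a1, a2 = a2, a3 = a3, l1 = l1, l2 = l2, l3 = l3,
                 delay = delay),
            class = "input_model_params")
}

#' Evaluate the parametric input curve
#'
#' @param params an [input_model_params()].
#' @param times sorted, nonnegative times (min from injection).
#' @return Activity values (kBq/mL) at `times`; 0 before the delay.
#' @export
generate_input_curve <- function(params, times) {
  stopifnot(inherits(params, "input_model_params"))
  if (length(times) && any(!is.finite(times)))
    stop("'times' must be finite", call. = FALSE)
  if (any(times < 0)) stop("'times' must be nonnegative", call. = FALSE)
  if (is.unsorted(times)) stop("'times' must be sorted", call. = FALSE)
  u <- times - params$delay
  v <- ifelse(u < 0, 0,
              (params$a1 * u - params$a2 - params$a3) * exp(params$l1 * u) +
                params$a2 * exp(params$l2 * u) +
                params$a3 * exp(params$l3 * u))
  pmax(v, 0)
}

#' @rdname generate_input_curve
#' @return `input_curve_fn` returns a vectorized function of time (min).
#' @export
input_curve_fn <- function(params) {
  stopifnot(inherits(params, "input_model_params"))
  force(params)
  function(t) {
    u <- t - params$delay
    v <- ifelse(u < 0, 0,
                (params$a1 * u - params$a2 - params$a3) * exp(params$l1 * u) +
                  params$a2 * exp(params$l2 * u) +
                  params$a3 * exp(params$l3 * u))
    pmax(v, 0)
  }
}

#' Analytic 0-to-infinity integral of the parametric input curve
#'
#' @param params an [input_model_params()].
#' @return The integral in kBq min/mL (delay does not change it).
#' @export
input_curve_auc_inf <- function(params) {
  stopifnot(inherits(params, "input_model_params"))
  with(params, a1 / l1^2 + (a2 + a3) / l1 - a2 / l2 - a3 / l3)
}
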