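#' Two-tissue irreversible compartment model parameters
#'
#' Parameters of the irreversible two-tissue compartment model that
#' underlies Patlak-Gjedde analysis of FDG: transport `K1` (mL plasma /
#' mL tissue / min), efflux `k2` (1/min), phosphorylation (trapping) `k3`
#' (1/min) and the fractional blood volume `vb` in \[0, 1\].  The trapping
#' influx constant is `Ki = K1 k3 / (k2 + k3)` (0 when `k3 = 0`).
#'
#' @param k1,k2,k3 rate constants, all nonnegative.
#' @param vb blood volume fraction in \[0, 1\].
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(k1, k2, k3, vb = 0) {
  if (any(c(k1, k2, k3) < 0))
    stop("rate constants must be nonnegative", call. = FALSE)
  if (vb < 0 || vb > 1) stop("'vb' must be in [0, 1]", call. = FALSE)
  structure(list(k1 = k1, k2 = k2, k3 = k3, vb = vb),
            class = "kinetic_params")
}

#' @rdname kinetic_params
#' @param kp a `kinetic_params` object.
#' @export
ki_true <- function(kp) {
  stopifnot(inherits(kp, "kinetic_params"))
  if (kp$k3 == 0) 0 else kp$k1 * kp$k3 / (kp$k2 + kp$k3)
}

## coerce the various input representations to a plain function of minutes
as_input_fn <- function(input) {
  if (is.function(input)) return(input)
  if (inherits(input, "input_model_params")) return(input_curve_fn(input))
  if (inherits(input, "input_function"))
    return(function(t) predict(input, t))
  stop("'input' must be a function, input_model_params or input_function",
       call. = FALSE)
}

#' Simulate a tissue time-activity curve
#'
#' Integrates the irreversible two-tissue compartment model
#' \deqn{dC_1/dt = K_1 C_p - (k_2 + k_3) C_1, \qquad dC_2/dt = k_3 C_1,}
#' with `C1(0) = C2(0) = 0`, and returns the measurable tissue activity
#' \deqn{C_T(t) = (1 - V_b)(C_1 + C_2) + V_b C_p(t).}
#' The system is solved with [deSolve::lsoda()] at relative tolerance
#' `rtol` and absolute tolerance `atol` (defaults 1e-8 / 1e-10, far below
#' any measurement noise considered here).
#'
#' @param kp a [kinetic_params()].
#' @param input the plasma input: a function of time (min) returning
#'   kBq/mL, an [input_model_params()] or an `input_function`.
#' @param times sorted nonnegative evaluation times (min); the input must be
#'   defined on `[0, max(times)]`.
#' @param rtol,atol solver tolerances.
#' @return Numeric vector of tissue activities (kBq/mL) at `times`.
#' @export
simulate_tissue_curve <- function(kp, input, times, rtol = 1e-8,
                                  atol = 1e-10) {
  stopifnot(inherits(kp, "kinetic_params"))
  if (any(times < 0)) stop("'times' must be nonnegative", call. = FALSE)
  if (is.unsorted(times)) stop("'times' must be sorted", call. = FALSE)
  cp <- as_input_fn(input)
  tt <- times
  prepend0 <- length(tt) == 0L || tt[1L] > 0
  if (prepend0) tt <- c(0, tt)
  if (kp$k1 == 0) {
    c1 <- c2 <- rep(0, length(tt))
  } else {
    deriv <- function(t, y, parms) {
      cpt <- cp(t)
      list(c(kp$k1 * cpt - (kp$k2 + kp$k3) * y[1L], kp$k3 * y[1L]))
    }
    sol <- deSolve::lsoda(c(0, 0), tt, deriv, parms = NULL,
                          rtol = rtol, atol = atol)
    c1 <- sol[, 2L]
    c2 <- sol[, 3L]
  }
  ct <- (1 - kp$vb) * (c1 + c2) + kp$vb * cp(tt)
  if (prepend0) ct <- ct[-1L]
  ct
}
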