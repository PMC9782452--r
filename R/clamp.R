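#' Hyperinsulinemic-euglycemic clamp record
#'
#' A clamp record is a time series (minutes from the start of the insulin
#' infusion) of the glucose infusion rate (GIR, umol/kg/min), plasma
#' glucose (mmol/L) and optionally plasma insulin (pmol/L) and free fatty
#' acids (FFA, mmol/L), together with the steady-state window over which
#' whole-body indices are computed.
#'
#' @param time_min sorted sampling times (min).
#' @param gir glucose infusion rate (umol/kg/min), nonnegative.
#' @param glucose plasma glucose (mmol/L).
#' @param insulin plasma insulin (pmol/L), optional.
#' @param ffa plasma free fatty acids (mmol/L), optional.
#' @param window numeric `c(start, end)` of the steady-state window (min),
#'   within the record span.
#' @return A data frame of class `clamp_record` with the window in
#'   attribute `"window"`.
#' @export
clamp_record <- function(time_min, gir, glucose, insulin = NA_real_,
                         ffa = NA_real_, window) {
  if (is.unsorted(time_min))
    stop("'time_min' must be sorted", call. = FALSE)
  if (any(gir < 0)) stop("GIR must be nonnegative", call. = FALSE)
  if (length(window) != 2L || window[1L] >= window[2L])
    stop("'window' must be c(start, end) with start < end", call. = FALSE)
  if (window[1L] < min(time_min) - 1e-9 ||
      window[2L] > max(time_min) + 1e-9)
    stop("'window' must lie within the record span", call. = FALSE)
  out <- data.frame(time_min = time_min, gir = gir, glucose = glucose,
                    insulin = insulin, ffa = ffa)
  attr(out, "window") <- as.numeric(window)
  class(out) <- c("clamp_record", "data.frame")
  out
}

#' M value from a clamp record
#'
#' The whole-body insulin sensitivity index M is the mean glucose infusion
#' rate over the steady-state window, corrected for the change of the
#' glucose space and for urinary glucose loss:
#' \deqn{M = \overline{GIR} - SC - UC,}
#' where the space correction is
#' `SC = (G_end - G_start) [umol/L] * vd / window length` (per kg, since
#' the distribution volume `vd` is given in L/kg) and the urinary
#' correction is `UC = urinary_glucose / (weight * window length)`.
#' A rising glucose trend therefore lowers M.  `M_ffm` rescales M to fat-
#' free mass: `M_ffm = M * weight / ffm`.
#'
#' @param rec a [clamp_record()].
#' @param weight body weight (kg), > 0.
#' @param ffm fat-free mass (kg), > 0.
#' @param urinary_glucose glucose lost in urine over the window (umol);
#'   default 0.
#' @param vd glucose distribution volume (L/kg); default 0.19.
#' @return List with `m` (umol/kg/min), `m_ffm` (umol/kg FFM/min),
#'   `mean_gir`, `space_correction`, `urinary_correction` and the window.
#' @export
m_value <- function(rec, weight, ffm, urinary_glucose = 0, vd = 0.19) {
  if (!inherits(rec, "clamp_record"))
    stop("'rec' must be a clamp_record", call. = FALSE)
  if (weight <= 0 || ffm <= 0)
    stop("'weight' and 'ffm' must be positive", call. = FALSE)
  w <- attr(rec, "window")
  idx <- which(rec$time_min >= w[1L] - 1e-9 & rec$time_min <= w[2L] + 1e-9)
  if (length(idx) < 2L)
    stop("empty steady-state window: fewer than 2 samples inside it",
         call. = FALSE)
  t_in <- rec$time_min[idx]
  span <- t_in[length(idx)] - t_in[1L]
  mean_gir <- mean(rec$gir[idx])
  sc <- (rec$glucose[idx[length(idx)]] - rec$glucose[idx[1L]]) * 1000 *
    vd / span
  uc <- urinary_glucose / (weight * span)
  m <- mean_gir - sc - uc
  list(m = m, m_ffm = m * weight / ffm, mean_gir = mean_gir,
       space_correction = sc, urinary_correction = uc, window = w)
}

#' Tracer balance of an FDG injection
#'
#' @param injected_mbq injected dose (MBq), > 0.
#' @param urinary_mbq cumulative urinary activity (MBq), in
#'   `[0, injected_mbq]`.
#' @param weight_kg body weight (kg), > 0.
#' @return An object of class `tracer_balance`.
#' @export
tracer_balance <- function(injected_mbq, urinary_mbq = 0, weight_kg) {
  if (injected_mbq <= 0) stop("'injected_mbq' must be positive",
                              call. = FALSE)
  if (urinary_mbq < 0 || urinary_mbq > injected_mbq)
    stop("'urinary_mbq' must be in [0, injected dose]", call. = FALSE)
  if (weight_kg <= 0) stop("'weight_kg' must be positive", call. = FALSE)
  structure(list(injected_mbq = injected_mbq, urinary_mbq = urinary_mbq,
                 weight_kg = weight_kg),
            class = "tracer_balance")
}

#' Rate of disappearance of glucose from tracer kinetics
#'
#' The plasma clearance of the tracer is the retained dose divided by the
#' total plasma exposure,
#' \deqn{CL\ [L/min] = (injected - urinary) / AUC(0, \infty),}
#' with the plasma curve extrapolated to infinity by its mono-exponential
#' tail (MBq divided by kBq min/mL is numerically L/min).  The glucose
#' rate of disappearance follows by scaling with the steady-state glucose
#' concentration and a whole-body lumped constant:
#' \deqn{R_d = CL \times glucose\ [\mu mol/L] / (LC_{wb} \times weight).}
#' Rescaling the plasma curve and the dose by a common factor leaves
#' `Rd` unchanged.
#'
#' @param tb a [tracer_balance()].
#' @param f the plasma [input_function()]; its tail must be fittable.
#' @param glucose_ss steady-state plasma glucose (mmol/L), > 0.
#' @param lc_wb whole-body lumped constant; default 1.0, which keeps Rd in
#'   glucose equivalents.
#' @return Rd in umol/kg/min.
#' @export
rd_from_tracer <- function(tb, f, glucose_ss, lc_wb = 1.0) {
  if (!inherits(tb, "tracer_balance"))
    stop("'tb' must be a tracer_balance", call. = FALSE)
  if (glucose_ss <= 0)
    stop("'glucose_ss' must be positive", call. = FALSE)
  a <- auc(f, Inf, extrapolate = TRUE)
  if (!is.finite(a) || a <= 0)
    stop("extrapolated plasma AUC(0, Inf) is not finite and positive",
         call. = FALSE)
  cl <- (tb$injected_mbq - tb$urinary_mbq) / a
  cl * glucose_ss * 1000 / (lc_wb * tb$weight_kg)
}

#' Endogenous glucose production
#'
#' Under the clamp, endogenous glucose production is the rate of
#' disappearance minus the exogenous glucose infusion rate,
#' `EGP = Rd - GIR`.  Negative values indicate suppression below the
#' infusion rate and are expected under hyperinsulinemia.
#'
#' @param rd rate of disappearance (umol/kg/min).
#' @param gir_ss steady-state glucose infusion rate (umol/kg/min).
#' @return EGP (umol/kg/min).
#' @export
egp <- function(rd, gir_ss) {
  if (!is.finite(rd) || !is.finite(gir_ss))
    stop("'rd' and 'gir_ss' must be finite", call. = FALSE)
  rd - gir_ss
}

#' Matsuda insulin sensitivity index
#'
#' `10000 / sqrt(G0 * I0 * Gmean * Imean)` with glucose in mg/dL and
#' insulin in uU/mL.  Inputs are taken in SI units and converted with the
#' conventional factors (glucose x 18.016 mmol/L to mg/dL, insulin / 6.0
#' pmol/L to uU/mL).
#'
#' @param g0,i0 fasting plasma glucose (mmol/L) and insulin (pmol/L).
#' @param g_mean,i_mean mean OGTT glucose (mmol/L) and insulin (pmol/L).
#' @param glucose_factor,insulin_factor unit-conversion constants.
#' @return The unitless index.
#' @export
matsuda_isi <- function(g0, i0, g_mean, i_mean,
                        glucose_factor = 18.016, insulin_factor = 6.0) {
  vals <- c(g0, i0, g_mean, i_mean)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all glucose and insulin values must be positive", call. = FALSE)
  10000 / sqrt(g0 * glucose_factor * (i0 / insulin_factor) *
                 g_mean * glucose_factor * (i_mean / insulin_factor))
}

#' HbA1c unit conversion (IFCC mmol/mol to NGSP percent)
#'
#' The master equation `NGSP% = 0.09148 * IFCC + 2.152` and its algebraic
#' inverse.
#'
#' @param hba1c HbA1c in mmol/mol (IFCC), > 0.
#' @param pct HbA1c in percent (NGSP), > 2.152.
#' @return The converted value (unrounded; round as needed for reporting).
#' @export
ifcc_to_ngsp <- function(hba1c) {
  if (any(!is.finite(hba1c)) || any(hba1c <= 0))
    stop("'hba1c' must be positive", call. = FALSE)
  0.09148 * hba1c + 2.152
}

#' @rdname ifcc_to_ngsp
#' @export
ngsp_to_ifcc <- function(pct) {
  if (any(!is.finite(pct)) || any(pct <= 2.152))
    stop("'pct' must exceed 2.152", call. = FALSE)
  (pct - 2.152) / 0.09148
}

#' Free fatty acid suppression during the clamp
#'
#' Percent suppression of circulating FFA by insulin,
#' `100 * (1 - clamp / fasting)`.  Values above the fasting level give a
#' negative percentage.
#'
#' @param fasting_ffa fasting FFA (mmol/L), > 0.
#' @param clamp_ffa FFA during the clamp (mmol/L).
#' @return Suppression in percent.
#' @export
ffa_suppression <- function(fasting_ffa, clamp_ffa) {
  if (any(!is.finite(fasting_ffa)) || any(fasting_ffa <= 0))
    stop("'fasting_ffa' must be positive", call. = FALSE)
  100 * (1 - clamp_ffa / fasting_ffa)
}
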