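#' Patlak-Gjedde graphical analysis
#'
#' Estimates the influx constant Ki of an irreversibly trapped tracer by
#' ordinary least squares on the Patlak-Gjedde linearization: for every
#' frame with mid-time \eqn{t_j \ge t^*},
#' \deqn{y_j = C_T(t_j)/C_p(t_j), \qquad x_j = \int_0^{t_j} C_p / C_p(t_j),}
#' and \eqn{y = K_i x + V}.  The slope is the influx constant (1/min), the
#' intercept the effective distribution volume.  The fit start `t_star`
#' must be late enough for the exchangeable compartment to have
#' equilibrated; the transient decays as `exp(-(k2 + k3) t)`, so slowly
#' exchanging tissues need a later start (or a late acquisition window)
#' for an unbiased slope.
#'
#' @param x a [tac()] with the regional tissue curve.
#' @param f the plasma input: an [input_function()] or a plain function of
#'   minutes.
#' @param t_star fit start (min); frames with mid-time >= `t_star` enter
#'   the regression.  Default 10 min.
#' @param weights optional per-frame regression weights, `"duration"` for
#'   frame-duration weighting, or `NULL` (default) for unweighted OLS.
#' @param extrapolate passed to [auc()] for frames beyond the input knots.
#' @return A `rate_estimate` with `method = "patlak"`: elements `rate`
#'   (Ki, 1/min), `se`, `intercept`, `r_squared`, `n_points`, `t_star`.
#' @export
patlak_fit <- function(x, f, t_star = 10, weights = NULL,
                       extrapolate = FALSE) {
  if (!inherits(x, "tac")) stop("'x' must be a tac", call. = FALSE)
  use <- x$mid_min >= t_star - 1e-9
  if (sum(use) < 2L)
    stop("Patlak fit needs at least 2 frames with mid-time >= t_star",
         call. = FALSE)
  tm <- x$mid_min[use]
  ct <- x$activity[use]
  cp <- eval_input(f, tm)
  if (any(cp <= 0))
    stop("plasma activity is zero at a frame used in the fit",
         call. = FALSE)
  xx <- vapply(tm, function(t) auc(f, t, extrapolate = extrapolate),
               numeric(1)) / cp
  yy <- ct / cp
  w <- if (identical(weights, "duration")) x$dur_s[use] else weights
  fit <- stats::lm(yy ~ xx, weights = w)
  sm <- suppressWarnings(summary(fit))  # silence perfect-fit notices
  structure(list(method = "patlak",
                 rate = unname(stats::coef(fit)[2L]),
                 se = unname(sm$coefficients[2L, 2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = sm$r.squared,
                 n_points = sum(use),
                 t_star = t_star),
            class = "rate_estimate")
}

eval_input <- function(f, t) {
  if (inherits(f, "input_function")) predict(f, t) else f(t)
}

#' Fractional uptake rate (FUR)
#'
#' The late-time approximation of the Patlak influx constant: tissue
#' activity at time `T` divided by the plasma integral from 0 to `T`,
#' \deqn{FUR = C_T(T) / \int_0^T C_p.}
#' `T` is conventionally the mid-time of the static frame.  FUR exceeds Ki
#' by `V * Cp(T) / AUC(0, T)`, which shrinks as `T` grows.
#'
#' @param static_value tissue activity `C_T(T)` (kBq/mL).
#' @param t_mid the static frame mid-time `T` (min), > 0.
#' @param f the plasma input (as in [patlak_fit()]).
#' @param extrapolate passed to [auc()].
#' @return A `rate_estimate` with `method = "fur"`.
#' @export
fur <- function(static_value, t_mid, f, extrapolate = FALSE) {
  if (t_mid <= 0) stop("'t_mid' must be positive", call. = FALSE)
  a <- auc(f, t_mid, extrapolate = extrapolate)
  if (a <= 0)
    stop("plasma integral is zero; FUR undefined", call. = FALSE)
  structure(list(method = "fur", rate = static_value / a, se = NA_real_,
                 intercept = NA_real_, r_squared = NA_real_,
                 n_points = 1L, t_star = t_mid),
            class = "rate_estimate")
}

#' @rdname fur
#' @param x a [tac()]; the last frame supplies `static_value` and `t_mid`.
#' @export
fur_from_tac <- function(x, f, extrapolate = FALSE) {
  if (!inherits(x, "tac")) stop("'x' must be a tac", call. = FALSE)
  n <- nrow(x)
  fur(x$activity[n], x$mid_min[n], f, extrapolate = extrapolate)
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%s estimate: rate = %.5g 1/min", x$method, x$rate))
  if (x$method == "patlak")
    cat(sprintf(" (se %.3g), intercept = %.4g, R2 = %.4f, n = %d, t* = %g",
                x$se, x$intercept, x$r_squared, x$n_points, x$t_star))
  cat("\n")
  invisible(x)
}

#' Tissue registry: lumped constants and densities
#'
#' Lumped constants convert FDG flux to glucose flux: 1.2 for skeletal
#' muscle, 1.0 for liver and 1.14 for adipose tissue (VAT, abdominal and
#' femoral SAT, BAT).  The brain entry (0.65) and the myocardium entry
#' (1.0) are literature-standard conventions, not values fixed by the
#' clamp-PET protocol this package models: override them as needed.
#' Densities (kg/L) are literature-standard: muscle 1.06, liver 1.05,
#' adipose 0.925, brain 1.04, myocardium 1.05; whole body is 1.0/1.0 so
#' whole-body rates stay in glucose equivalents.
#'
#' @return A data frame with columns `tissue`, `lc`, `density`.
#' @export
tissue_registry <- function() {
  data.frame(
    tissue = c("muscle", "liver", "vat", "sat_abdominal", "sat_femoral",
               "bat", "adipose", "brain", "myocardium", "whole_body"),
    lc = c(1.2, 1.0, 1.14, 1.14, 1.14, 1.14, 1.14, 0.65, 1.0, 1.0),
    density = c(1.06, 1.05, 0.925, 0.925, 0.925, 0.925, 0.925, 1.04,
                1.05, 1.0))
}

#' Glucose uptake from a fractional uptake rate
#'
#' Tissue-specific glucose uptake is the rate (Ki or FUR) multiplied by the
#' plasma glucose concentration during scanning and divided by the tissue
#' density and the lumped constant:
#' \deqn{GU\ [\mu mol/kg/min] = rate\ [1/min] \times glucose\ [\mu mol/L]
#'       / (LC \times density\ [kg/L]).}
#'
#' @param est a `rate_estimate` or a plain rate (1/min).
#' @param plasma_glucose plasma glucose during scanning (mmol/L), > 0.
#' @param tissue tissue name, looked up in `registry`.
#' @param registry a data frame as from [tissue_registry()].
#' @return An object of class `glucose_uptake`: `tissue`, `gu` (umol/kg
#'   tissue/min), `rate`, `lc`, `density`.
#' @export
gu_from_rate <- function(est, plasma_glucose, tissue,
                         registry = tissue_registry()) {
  rate <- if (inherits(est, "rate_estimate")) est$rate else est
  if (!is.finite(rate)) stop("rate must be finite", call. = FALSE)
  if (plasma_glucose <= 0)
    stop("'plasma_glucose' must be positive", call. = FALSE)
  i <- match(tissue, registry$tissue)
  if (is.na(i))
    stop("unknown tissue '", tissue, "': not in the registry",
         call. = FALSE)
  lc <- registry$lc[i]
  dens <- registry$density[i]
  structure(list(tissue = tissue,
                 gu = rate * plasma_glucose * 1000 / (lc * dens),
                 rate = rate, lc = lc, density = dens),
            class = "glucose_uptake")
}

#' Depot-specific glucose uptake
#'
#' Per-mass glucose uptake multiplied by the depot mass, giving the total
#' uptake of the depot in umol/min.
#'
#' @param gu a `glucose_uptake` or a per-mass rate (umol/kg/min).
#' @param mass depot mass (kg), nonnegative.
#' @return Depot glucose uptake (umol/min).
#' @export
depot_gu <- function(gu, mass) {
  if (mass < 0) stop("'mass' must be nonnegative", call. = FALSE)
  g <- if (inherits(gu, "glucose_uptake")) gu$gu else gu
  g * mass
}
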