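#' Group specifications for the synthetic cohort
#'
#' A group specification gives, for one risk group, the number of subjects
#' and a `(mean, sd, lower)` triple for every subject-level variable.
#' Variables are sampled independently from normal distributions truncated
#' below at `lower` (so masses, concentrations and doses cannot go
#' negative).  `lr_group_spec()` and `hr_group_spec()` carry the default
#' parameterization of the low-risk (n = 22) and high-risk (n = 19) study
#' groups: anthropometrics, fasting and steady-state chemistry, M value,
#' EGP and clamp FFA use the published cohort means and SDs; per-tissue
#' glucose uptake targets are depot uptake divided by depot mass where
#' both are published, and plausible insulin-stimulated values otherwise
#' (liver, myocardium, BAT); the dose is 156 +/- 10 MBq; the urinary
#' fraction and the tissue kinetic constants behind the targets are
#' synthetic conventions (see the methods vignette).
#'
#' @param label group label, e.g. `"LR"` or `"HR"`.
#' @param n number of subjects, >= 0.
#' @param vars named list of numeric triples `c(mean, sd, lower)`.
#' @param ... in `lr_group_spec`/`hr_group_spec`: named triples replacing
#'   individual default entries.
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(label, n, vars) {
  if (n < 0) stop("'n' must be nonnegative", call. = FALSE)
  for (v in names(vars)) {
    x <- vars[[v]]
    if (length(x) != 3L || !all(is.finite(x)))
      stop("variable '", v, "' must be c(mean, sd, lower)", call. = FALSE)
    if (x[2L] < 0)
      stop("variable '", v, "' has negative sd", call. = FALSE)
    if (x[2L] == 0 && x[1L] < x[3L])
      stop("variable '", v,
           "': mean below the truncation bound with sd 0 is impossible",
           call. = FALSE)
  }
  structure(list(label = label, n = as.integer(n), vars = vars),
            class = "group_spec")
}

#' @rdname group_spec
#' @export
lr_group_spec <- function(n = 22, ...) {
  vars <- list(
    age = c(23, 3, 18), weight = c(70.3, 7.5, 45),
    ffm = c(59.2, 6.6, 35),
    fasting_glucose = c(4.9, 0.5, 2.5),
    fasting_insulin = c(38.7, 21.0, 5),
    fasting_ffa = c(0.3, 0.1, 0.05),
    ogtt_glucose_2h = c(4.8, 1.0, 2),
    ogtt_insulin_2h = c(160.7, 140.1, 15),
    hba1c_ifcc = c(29, 2, 15),
    ss_glucose = c(5.3, 0.2, 4), ss_insulin = c(510.5, 76.8, 200),
    m_value = c(58.0, 14.7, 5), egp = c(-3.4, 6.7, -30),
    clamp_ffa = c(0.03, 0.01, 0.005),
    dose_mbq = c(156, 10, 120), urine_frac = c(0.12, 0.04, 0.02),
    mass_brain = c(1.7, 0.2, 1.0), mass_muscle = c(5.6, 0.6, 3),
    mass_vat = c(1.4, 0.7, 0.2), mass_sat_abdominal = c(2.7, 1.0, 0.5),
    mass_sat_femoral = c(2.1, 0.7, 0.5),
    gu_brain = c(151.8, 27.2, 40), gu_muscle = c(52.2, 14.3, 8),
    gu_liver = c(20, 6, 4), gu_vat = c(30.1, 13.1, 4),
    gu_sat_abdominal = c(19.3, 8.6, 3),
    gu_sat_femoral = c(19.0, 9.1, 3), gu_bat = c(14, 6, 2),
    gu_myocardium = c(450, 120, 100))
  vars[names(list(...))] <- list(...)
  group_spec("LR", n, vars)
}

#' @rdname group_spec
#' @export
hr_group_spec <- function(n = 19, ...) {
  vars <- list(
    age = c(27, 4, 18), weight = c(90.1, 9.3, 45),
    ffm = c(62.8, 5.7, 35),
    fasting_glucose = c(5.5, 0.4, 2.5),
    fasting_insulin = c(61.8, 20.8, 5),
    fasting_ffa = c(0.3, 0.1, 0.05),
    ogtt_glucose_2h = c(5.9, 1.4, 2),
    ogtt_insulin_2h = c(328.2, 236.5, 15),
    hba1c_ifcc = c(32, 3, 15),
    ss_glucose = c(5.3, 0.3, 4), ss_insulin = c(581.7, 94.9, 200),
    m_value = c(38.7, 13.7, 5), egp = c(0.9, 6.0, -30),
    clamp_ffa = c(0.05, 0.03, 0.005),
    dose_mbq = c(156, 10, 120), urine_frac = c(0.12, 0.04, 0.02),
    mass_brain = c(1.7, 0.1, 1.0), mass_muscle = c(5.8, 0.5, 3),
    mass_vat = c(3.7, 1.2, 0.2), mass_sat_abdominal = c(6.8, 2.4, 0.5),
    mass_sat_femoral = c(2.8, 0.8, 0.5),
    gu_brain = c(158.9, 25.4, 40), gu_muscle = c(34.5, 13.0, 4),
    gu_liver = c(15, 5, 3), gu_vat = c(18.6, 7.3, 3),
    gu_sat_abdominal = c(11.7, 5.1, 2),
    gu_sat_femoral = c(11.3, 5.2, 2), gu_bat = c(9, 4, 1),
    gu_myocardium = c(430, 120, 100))
  vars[names(list(...))] <- list(...)
  group_spec("HR", n, vars)
}

## lower-truncated normal sampling by inverse-CDF (exact, vectorizable)
rnorm_trunc <- function(n, mean, sd, lower = -Inf) {
  if (sd == 0) return(rep(mean, n))
  p0 <- stats::pnorm(lower, mean, sd)
  if (p0 >= 1)
    stop("truncation bound leaves no probability mass", call. = FALSE)
  stats::qnorm(p0 + stats::runif(n) * (1 - p0), mean, sd)
}

#' Sample subject-level metadata for a two-group cohort
#'
#' Draws every variable of both group specifications from its truncated
#' normal distribution.  This is the fast, metadata-only part of
#' [simulate_cohort()]; it contains all clamp/uptake target values but no
#' time series.
#'
#' @param lr,hr [group_spec()]s; both must define the same variables.
#' @param seed optional integer seed (`NULL` continues the current RNG
#'   stream).
#' @return A data frame with columns `id`, `group` and one column per
#'   variable.
#' @export
simulate_metadata <- function(lr = lr_group_spec(), hr = hr_group_spec(),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!setequal(names(lr$vars), names(hr$vars)))
    stop("the two group specs must define the same variables",
         call. = FALSE)
  one <- function(spec) {
    cols <- lapply(names(lr$vars), function(v) {
      x <- spec$vars[[v]]
      rnorm_trunc(spec$n, x[1L], x[2L], x[3L])
    })
    names(cols) <- names(lr$vars)
    df <- data.frame(
      id = sprintf("%s%02d", spec$label, seq_len(spec$n)),
      group = rep(spec$label, spec$n), stringsAsFactors = FALSE)
    if (spec$n == 0L) df <- df[0L, ]
    cbind(df, as.data.frame(cols)[seq_len(spec$n), , drop = FALSE])
  }
  out <- rbind(one(lr), one(hr))
  rownames(out) <- NULL
  out
}

## fixed tissue table: estimation method and acquisition window per region
cohort_tissue_table <- function() {
  data.frame(
    tissue = c("myocardium", "liver", "vat", "sat_abdominal", "muscle",
               "sat_femoral", "bat", "brain"),
    method = c("patlak", "patlak", "fur", "fur", "patlak", "fur", "fur",
               "fur"),
    schedule = c("thorax", "abdomen", "abdomen", "abdomen", "thigh",
                 "thigh", "neck", "brain"),
    mass_var = c(NA, NA, "mass_vat", "mass_sat_abdominal", "mass_muscle",
                 "mass_sat_femoral", NA, "mass_brain"),
    stringsAsFactors = FALSE)
}

#' Simulate a two-group FDG-PET clamp cohort
#'
#' Generates a fully synthetic but internally consistent cohort: for every
#' subject, a parametric arterial input curve whose scale is set by the
#' injected dose, the urinary loss fraction and the tracer clearance
#' implied by the subject's target Rd (= EGP + M); an image-derived input
#' TAC on the thoracic schedule; sparse arterialized plasma samples; one
#' TAC per tissue from the irreversible two-tissue compartment model with
#' K1 back-solved so that the subject's target glucose uptake is honored
#' (k2, k3 and vb fixed at the configured per-tissue defaults); and a
#' clamp record whose steady-state GIR equals the target M value.
#' Gaussian frame noise with variance proportional to activity over frame
#' duration is applied at the configured scale.  All activities are
#' decay-corrected by construction (no isotope decay is simulated).
#'
#' The same seed reproduces the cohort bit for bit.
#'
#' @param lr,hr [group_spec()]s.
#' @param seed integer seed.
#' @param config a configuration list as from [default_config()].
#' @param tacs generate per-subject time series (`FALSE` gives metadata
#'   only, much faster).
#' @return An object of class `fdg_cohort`: `meta` (data frame),
#'   `subjects` (named list with `tacs`, `plasma`, `clamp` per subject),
#'   `config`, `seed`.
#' @export
simulate_cohort <- function(lr = lr_group_spec(), hr = hr_group_spec(),
                            seed = 1L, config = default_config(),
                            tacs = TRUE) {
  validate_config(config)
  set.seed(seed)
  meta <- simulate_metadata(lr, hr, seed = NULL)
  meta$urinary_mbq <- if (nrow(meta)) meta$dose_mbq * meta$urine_frac
                      else numeric(0)
  subjects <- list()
  if (tacs && nrow(meta)) {
    base <- config_input_params(config)
    base_auc <- input_curve_auc_inf(base)
    scheds <- lapply(config$schedules, schedule_from_config)
    tt <- cohort_tissue_table()
    reg <- config$registry
    kin <- config$tissue_kinetics
    nz <- config$noise
    for (i in seq_len(nrow(meta))) {
      s <- meta[i, ]
      rd_t <- max(s$egp + s$m_value, 0.5)
      cl <- rd_t * config$lc_whole_body * s$weight / (s$ss_glucose * 1000)
      auc_target <- s$dose_mbq * (1 - s$urine_frac) / cl
      sc <- auc_target / base_auc
      ip <- input_model_params(base$a1 * sc, base$a2 * sc, base$a3 * sc,
                               base$l1, base$l2, base$l3, base$delay)
      cp <- input_curve_fn(ip)
      ## the blood-pool curve feeds the input function, which must stay
      ## nonnegative, so its noise is truncated at zero
      idif <- tac_add_noise(
        frame_average(cp, scheds$thorax, region = "idif"), nz$tac_scale,
        clamp_nonneg = TRUE)
      pt <- config$plasma_sample_min
      plasma <- data.frame(
        time_min = pt,
        activity_kbq_per_ml = pmax(
          cp(pt) * (1 + stats::rnorm(length(pt), 0, nz$plasma_cv)), 0))
      tac_list <- list(idif = idif)
      for (j in seq_len(nrow(tt))) {
        tis <- tt$tissue[j]
        ki <- s[[paste0("gu_", tis)]] * reg[[tis]]$lc *
          reg[[tis]]$density / (s$ss_glucose * 1000)
        kj <- kin[[tis]]
        ## the Patlak slope of the measured curve is (1 - vb) * Ki, so the
        ## back-solved K1 carries a 1/(1 - vb) factor to honor the target
        k1 <- ki / (1 - kj$vb) * (kj$k2 + kj$k3) / kj$k3
        kp <- kinetic_params(k1, kj$k2, kj$k3, kj$vb)
        sched <- scheds[[tt$schedule[j]]]
        tmax <- max(sched$end_s) / 60
        grid <- unique(c(seq(0, min(5, tmax), by = 0.02),
                         seq(min(5, tmax), tmax, by = 0.1), tmax))
        ct <- simulate_tissue_curve(kp, cp, grid)
        fn <- stats::approxfun(grid, ct, rule = 2)
        tac_list[[tis]] <- tac_add_noise(
          frame_average(fn, sched, region = tis), nz$tac_scale)
      }
      cc <- config$clamp
      ctimes <- seq(0, cc$duration_min, by = cc$step_min)
      ramp <- pmin(ctimes / cc$ramp_min, 1)
      clamp <- clamp_record(
        time_min = ctimes,
        gir = pmax(s$m_value * ramp +
                     stats::rnorm(length(ctimes), 0, nz$gir_sd) *
                     (ctimes > 0), 0),
        glucose = s$ss_glucose +
          stats::rnorm(length(ctimes), 0, nz$glucose_sd),
        insulin = pmax(s$ss_insulin * pmin(ctimes / (cc$ramp_min / 4), 1) +
                         stats::rnorm(length(ctimes), 0, nz$insulin_sd), 0),
        ffa = pmax(s$clamp_ffa + (s$fasting_ffa - s$clamp_ffa) *
                     exp(-ctimes / 30) +
                     stats::rnorm(length(ctimes), 0, nz$ffa_sd), 0),
        window = cc$window)
      subjects[[s$id]] <- list(tacs = tac_list, plasma = plasma,
                               clamp = clamp)
    }
  }
  structure(list(meta = meta, subjects = subjects, config = config,
                 seed = seed),
            class = "fdg_cohort")
}

#' @export
print.fdg_cohort <- function(x, ...) {
  cat(sprintf("fdg_cohort: %d subjects (%s), %s, seed %d\n",
              nrow(x$meta),
              paste(sprintf("%s n=%d", names(table(x$meta$group)),
                            table(x$meta$group)), collapse = ", "),
              if (length(x$subjects)) "with time series"
              else "metadata only",
              x$seed))
  invisible(x)
}
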