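#' Pipeline configuration
#'
#' All tunable constants of the quantification pipeline and the
#' synthetic-data generator in one nested list: frame-schedule presets,
#' the lumped-constant/density registry, the Patlak fit start, the
#' IDIF-to-plasma switch time, the glucose distribution volume for the
#' M-value space correction, unit-conversion constants, the FDR level,
#' the parametric input-model defaults, the per-tissue kinetic constants
#' used by the simulator, and the noise model.
#'
#' Constants that come from the acquisition and analysis protocol this
#' package models: the frame schedules, the 4.5-min switch time, the
#' lumped constants 1.2 (muscle), 1.0 (liver) and 1.14 (adipose).
#' Everything else (tissue densities, brain and myocardium lumped
#' constants, the glucose distribution volume, the per-tissue k2/k3/vb of
#' the simulator, the noise scales) are conventions or synthetic-data
#' choices, documented in the methods vignette, and freely configurable.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    switch_time_min = 4.5,
    t_star_min = 10,
    vd_l_per_kg = 0.19,
    lc_whole_body = 1.0,
    fdr_q = 0.05,
    glucose_mg_per_mmol = 18.016,
    insulin_pmol_per_uu = 6.0,
    input_model = list(a1 = 600, a2 = 6, a3 = 1.6,
                       l1 = -4, l2 = -0.25, l3 = -0.012, delay = 0.5),
    schedules = list(
      thorax = list(counts = c(4L, 6L, 2L, 2L, 6L),
                    dur_s = c(15, 20, 60, 150, 300), start_s = 0),
      abdomen = list(counts = 3L, dur_s = 300, start_s = 2400),
      thigh = list(counts = 3L, dur_s = 300, start_s = 3300),
      neck = list(counts = 1L, dur_s = 600, start_s = 4200),
      brain = list(counts = 1L, dur_s = 600, start_s = 4800)),
    plasma_sample_min = c(4.5, 7.5, 10, 20, 30, 47.5, 62.5, 75, 85),
    registry = list(
      muscle = list(lc = 1.2, density = 1.06),
      liver = list(lc = 1.0, density = 1.05),
      vat = list(lc = 1.14, density = 0.925),
      sat_abdominal = list(lc = 1.14, density = 0.925),
      sat_femoral = list(lc = 1.14, density = 0.925),
      bat = list(lc = 1.14, density = 0.925),
      brain = list(lc = 0.65, density = 1.04),
      myocardium = list(lc = 1.0, density = 1.05),
      whole_body = list(lc = 1.0, density = 1.0)),
    tissue_kinetics = list(
      muscle = list(k2 = 0.20, k3 = 0.05, vb = 0.03),
      liver = list(k2 = 0.60, k3 = 0.04, vb = 0.25),
      vat = list(k2 = 0.15, k3 = 0.02, vb = 0.02),
      sat_abdominal = list(k2 = 0.15, k3 = 0.02, vb = 0.02),
      sat_femoral = list(k2 = 0.15, k3 = 0.02, vb = 0.02),
      bat = list(k2 = 0.15, k3 = 0.03, vb = 0.04),
      brain = list(k2 = 0.25, k3 = 0.06, vb = 0.04),
      myocardium = list(k2 = 0.80, k3 = 0.12, vb = 0.30)),
    noise = list(tac_scale = 0.05, plasma_cv = 0.01, gir_sd = 2.0,
                 glucose_sd = 0.04, insulin_sd = 15, ffa_sd = 0.004),
    clamp = list(step_min = 5, duration_min = 170, ramp_min = 80,
                 window = c(110, 170)),
    seed = 1L)
}

#' Read or write a configuration file
#'
#' Configurations serialize to YAML and round-trip losslessly.
#'
#' @param path file path.
#' @param config a configuration list as from [default_config()].
#' @return `read_config` returns the configuration list; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(config, path, precision = 15L)
  invisible(path)
}

validate_config <- function(config) {
  need <- c("switch_time_min", "t_star_min", "vd_l_per_kg",
            "lc_whole_body", "fdr_q", "input_model", "schedules",
            "plasma_sample_min", "registry", "tissue_kinetics", "noise",
            "clamp")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("configuration is missing field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  pos <- c(config$switch_time_min, config$t_star_min, config$vd_l_per_kg,
           config$lc_whole_body, config$fdr_q)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("configuration constants must be positive", call. = FALSE)
  for (tis in names(config$registry)) {
    r <- config$registry[[tis]]
    if (r$lc <= 0 || r$density <= 0)
      stop("registry entry '", tis, "' needs positive lc and density",
           call. = FALSE)
  }
  config
}

## registry list -> data.frame for gu_from_rate()
registry_df <- function(config) {
  reg <- config$registry
  data.frame(tissue = names(reg),
             lc = vapply(reg, function(r) r$lc, numeric(1)),
             density = vapply(reg, function(r) r$density, numeric(1)),
             row.names = NULL)
}

## schedule preset list -> frame_schedule
schedule_from_config <- function(sch)
  fs_blocks(sch$counts, sch$dur_s, sch$start_s)

config_input_params <- function(config) {
  im <- config$input_model
  input_model_params(im$a1, im$a2, im$a3, im$l1, im$l2, im$l3, im$delay)
}
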