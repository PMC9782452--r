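#' Run the full quantification pipeline on a cohort
#'
#' Chains every stage on each subject of a (simulated or on-disk) cohort:
#' hybrid input function from the image-derived left-ventricle TAC and
#' the arterialized plasma samples; Patlak-Gjedde fits for myocardium,
#' liver and femoral skeletal muscle; FUR for VAT, abdominal and femoral
#' SAT, BAT and brain; conversion to per-mass and depot glucose uptake
#' with the configured lumped constants and densities and the measured
#' steady-state glucose; M value (with space correction), tracer-based
#' Rd, EGP = Rd - GIR, FFA suppression, Matsuda index (from fasting and
#' 2-h OGTT samples) and HbA1c conversion.  The per-subject table is then
#' compared between groups (Student t-tests with Benjamini-Hochberg
#' adjustment across variables) and the M value is correlated with the
#' age-adjusted uptake of every tissue, overall and within groups.
#'
#' The pipeline is deterministic: the same cohort gives byte-identical
#' outputs.
#'
#' @param cohort an `fdg_cohort` (from [simulate_cohort()] or
#'   [read_cohort()]) or a directory path understood by [read_cohort()].
#' @param config configuration list; defaults to the cohort's own.
#' @param out_dir optional directory; when given, the result tables are
#'   written there as CSV together with a manifest.
#' @return A list of class `fdg_results`: `subjects` (one row per subject
#'   with all derived measures), `comparisons` (group statistics per
#'   variable), `correlations` (M value vs age-adjusted tissue uptake).
#' @export
run_pipeline <- function(cohort, config = NULL, out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "fdg_cohort"))
  if (is.null(config)) config <- cohort$config
  validate_config(config)
  reg_df <- registry_df(config)
  tt <- cohort_tissue_table()
  rows <- list()
  for (id in names(cohort$subjects)) {
    rows[[id]] <- tryCatch(
      pipeline_subject(cohort$meta[cohort$meta$id == id, ],
                       cohort$subjects[[id]], config, reg_df, tt),
      error = function(e)
        stop("subject ", id, ", stage ", conditionMessage(e),
             call. = FALSE))
  }
  subjects <- if (length(rows)) do.call(rbind, rows) else
    empty_subject_table(tt)
  rownames(subjects) <- NULL
  comparisons <- pipeline_comparisons(subjects, config)
  correlations <- pipeline_correlations(subjects)
  res <- structure(list(subjects = subjects, comparisons = comparisons,
                        correlations = correlations,
                        seed = cohort$seed),
                   class = "fdg_results")
  if (!is.null(out_dir)) write_results(res, cohort, config, out_dir)
  res
}

pipeline_subject <- function(meta, sub, config, reg_df, tt) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(name, ": ", conditionMessage(e), call. = FALSE))
  }
  f <- stage("input_function",
             build_hybrid_input(sub$tacs$idif, sub$plasma,
                                switch_time = config$switch_time_min))
  w <- attr(sub$clamp, "window")
  in_w <- sub$clamp$time_min >= w[1L] & sub$clamp$time_min <= w[2L]
  glucose_ss <- mean(sub$clamp$glucose[in_w])
  out <- data.frame(id = meta$id, group = meta$group, age = meta$age,
                    weight = meta$weight, ffm = meta$ffm,
                    glucose_ss = glucose_ss, stringsAsFactors = FALSE)
  for (j in seq_len(nrow(tt))) {
    tis <- tt$tissue[j]
    x <- sub$tacs[[tis]]
    est <- stage(paste0("kinetics/", tis),
                 if (tt$method[j] == "patlak")
                   patlak_fit(x, f, t_star = config$t_star_min,
                              extrapolate = TRUE)
                 else fur_from_tac(x, f, extrapolate = TRUE))
    gu <- stage(paste0("gu/", tis),
                gu_from_rate(est, glucose_ss, tis, registry = reg_df))
    out[[paste0("ki_", tis)]] <- est$rate
    out[[paste0("gu_", tis)]] <- gu$gu
    mv <- tt$mass_var[j]
    out[[paste0("depot_gu_", tis)]] <-
      if (!is.na(mv)) depot_gu(gu, meta[[mv]]) else NA_real_
  }
  mres <- stage("m_value",
                m_value(sub$clamp, meta$weight, meta$ffm,
                        vd = config$vd_l_per_kg))
  tb <- tracer_balance(meta$dose_mbq, meta$urinary_mbq, meta$weight)
  rd <- stage("rd_from_tracer",
              rd_from_tracer(tb, f, glucose_ss,
                             lc_wb = config$lc_whole_body))
  out$m_value <- mres$m
  out$m_value_ffm <- mres$m_ffm
  out$rd <- rd
  out$egp <- egp(rd, mres$mean_gir)
  out$egp_ffm <- out$egp * meta$weight / meta$ffm
  out$ffa_suppression <- ffa_suppression(meta$fasting_ffa, meta$clamp_ffa)
  out$matsuda_isi <- matsuda_isi(
    meta$fasting_glucose, meta$fasting_insulin,
    (meta$fasting_glucose + meta$ogtt_glucose_2h) / 2,
    (meta$fasting_insulin + meta$ogtt_insulin_2h) / 2,
    glucose_factor = config$glucose_mg_per_mmol,
    insulin_factor = config$insulin_pmol_per_uu)
  out$hba1c_pct <- ifcc_to_ngsp(meta$hba1c_ifcc)
  out
}

empty_subject_table <- function(tt) {
  cols <- c("id", "group", "age", "weight", "ffm", "glucose_ss",
            as.vector(rbind(paste0("ki_", tt$tissue),
                            paste0("gu_", tt$tissue),
                            paste0("depot_gu_", tt$tissue))),
            "m_value", "m_value_ffm", "rd", "egp", "egp_ffm",
            "ffa_suppression", "matsuda_isi", "hba1c_pct")
  df <- as.data.frame(stats::setNames(
    lapply(cols, function(x) if (x %in% c("id", "group")) character(0)
           else numeric(0)), cols))
  df
}

pipeline_comparisons <- function(subjects, config) {
  empty <- data.frame(variable = character(0), test = character(0),
                      statistic = numeric(0), p = numeric(0),
                      p_adjusted = numeric(0), mean_1 = numeric(0),
                      mean_2 = numeric(0), n_1 = integer(0),
                      n_2 = integer(0))
  if (!nrow(subjects)) return(empty)
  tabulated <- table(subjects$group)
  if (length(tabulated) != 2L || any(tabulated < 2L)) return(empty)
  vars <- setdiff(names(subjects), c("id", "group"))
  res <- lapply(vars, function(v) {
    if (all(is.na(subjects[[v]]))) return(NULL)
    gc <- compare_groups(subjects[[v]], subjects$group, test = "t")
    data.frame(variable = v, test = "t", statistic = gc$statistic,
               p = gc$p, p_adjusted = NA_real_,
               mean_1 = gc$estimate[1L], mean_2 = gc$estimate[2L],
               n_1 = gc$n[1L], n_2 = gc$n[2L])
  })
  out <- do.call(rbind, res)
  if (is.null(out)) return(empty)
  out$p_adjusted <- bh_fdr(out$p, q = config$fdr_q)$adjusted
  rownames(out) <- NULL
  out
}

pipeline_correlations <- function(subjects) {
  empty <- data.frame(variable = character(0), stratum = character(0),
                      n = integer(0), r = numeric(0), p = numeric(0))
  if (nrow(subjects) < 3L) return(empty)
  tissues <- sub("^gu_", "", grep("^gu_", names(subjects), value = TRUE))
  res <- lapply(tissues, function(tis) {
    v <- subjects[[paste0("gu_", tis)]]
    ok <- !is.na(v) & !is.na(subjects$m_value)
    if (sum(ok) < 3L) return(NULL)
    adj <- age_adjust(v[ok], subjects$age[ok])
    groups <- subjects$group[ok]
    by_group <- length(unique(groups)) == 2L &&
      all(table(groups) >= 3L)
    co <- correlate(subjects$m_value[ok], adj,
                    groups = if (by_group) groups)
    cbind(data.frame(variable = paste0("gu_", tis)), co)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

write_results <- function(res, cohort, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$subjects, file.path(out_dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(res$comparisons, file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(res$correlations,
                   file.path(out_dir, "correlations.csv"),
                   row.names = FALSE)
  write_config(config, file.path(out_dir, "config.yaml"))
  manifest <- list(
    seed = cohort$seed,
    config_md5 = unname(tools::md5sum(file.path(out_dir, "config.yaml"))),
    package_version = as.character(utils::packageVersion("fdgclamp")),
    tables = c("subjects.csv", "comparisons.csv", "correlations.csv"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.fdg_results <- function(x, ...) {
  cat(sprintf("fdg_results: %d subjects, %d group comparisons, %d correlation rows\n",
              nrow(x$subjects), nrow(x$comparisons),
              nrow(x$correlations)))
  invisible(x)
}
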