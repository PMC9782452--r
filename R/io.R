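#' Read and write time-activity curve tables
#'
#' The TAC interchange format is a plain CSV with the frame columns
#' `frame_start_s` and `frame_end_s` followed by one activity column per
#' region named `<region>_kbq_per_ml`.  All regions in one file share the
#' frame schedule; frames must be positive-duration, sorted and
#' non-overlapping.
#'
#' @param path CSV file path.
#' @return `read_tac_table` returns a named list of [tac()] objects, one
#'   per region.
#' @export
read_tac_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  miss <- setdiff(c("frame_start_s", "frame_end_s"), names(df))
  if (length(miss))
    stop("TAC table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  sched <- frame_schedule(df$frame_start_s,
                          df$frame_end_s - df$frame_start_s)
  rcols <- setdiff(names(df), c("frame_start_s", "frame_end_s"))
  if (!length(rcols))
    stop("TAC table has no region activity columns", call. = FALSE)
  out <- lapply(rcols, function(cn)
    tac(sched, df[[cn]], region = sub("_kbq_per_ml$", "", cn)))
  names(out) <- sub("_kbq_per_ml$", "", rcols)
  out
}

#' @rdname read_tac_table
#' @param tacs a named list of [tac()]s sharing one schedule, or a single
#'   `tac`.
#' @export
write_tac_table <- function(tacs, path) {
  if (inherits(tacs, "tac")) {
    nm <- attr(tacs, "region")
    tacs <- stats::setNames(list(tacs), if (is.na(nm)) "region" else nm)
  }
  first <- tacs[[1L]]
  df <- data.frame(frame_start_s = first$start_s,
                   frame_end_s = first$end_s)
  for (nm in names(tacs)) {
    if (!isTRUE(all.equal(tacs[[nm]]$start_s, first$start_s)))
      stop("all TACs in one table must share the schedule", call. = FALSE)
    df[[paste0(nm, "_kbq_per_ml")]] <- tacs[[nm]]$activity
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write and read a simulated cohort directory
#'
#' `write_cohort` lays a cohort out as plain CSV files: per subject one
#' TAC table per acquisition window (`<id>_tac_<window>.csv`), the plasma
#' samples (`<id>_plasma.csv`) and the clamp record (`<id>_clamp.csv`),
#' plus `metadata.csv`, the configuration as `config.yaml` and a
#' `manifest.json` carrying the seed, the MD5 hash of the configuration
#' file, the package version and the file list.  `read_cohort` restores
#' the cohort from such a directory.
#'
#' @param cohort an `fdg_cohort`.
#' @param dir target directory (created if needed).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns
#'   an `fdg_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fdg_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put <- function(fn) files[[length(files) + 1L]] <<- fn
  windows <- list(thorax = c("idif", "myocardium"),
                  abdomen = c("liver", "vat", "sat_abdominal"),
                  thigh = c("muscle", "sat_femoral"),
                  neck = "bat", brain = "brain")
  for (id in names(cohort$subjects)) {
    sub <- cohort$subjects[[id]]
    for (w in names(windows)) {
      regs <- intersect(windows[[w]], names(sub$tacs))
      if (!length(regs)) next
      fn <- sprintf("%s_tac_%s.csv", id, w)
      write_tac_table(sub$tacs[regs], file.path(dir, fn))
      put(fn)
    }
    fn <- sprintf("%s_plasma.csv", id)
    utils::write.csv(sub$plasma, file.path(dir, fn), row.names = FALSE)
    put(fn)
    fn <- sprintf("%s_clamp.csv", id)
    cl <- as.data.frame(sub$clamp)
    names(cl) <- c("time_min", "gir_umol_kg_min", "glucose_mmol_l",
                   "insulin_pmol_l", "ffa_mmol_l")
    utils::write.csv(cl, file.path(dir, fn), row.names = FALSE)
    put(fn)
  }
  utils::write.csv(cohort$meta, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  put("metadata.csv")
  write_config(cohort$config, file.path(dir, "config.yaml"))
  put("config.yaml")
  manifest <- list(
    seed = cohort$seed,
    config_md5 = unname(tools::md5sum(file.path(dir, "config.yaml"))),
    package_version = as.character(utils::packageVersion("fdgclamp")),
    files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path))
    stop("no metadata.csv in ", dir, call. = FALSE)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  config <- read_config(file.path(dir, "config.yaml"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  subjects <- list()
  for (id in meta$id) {
    tac_files <- list.files(dir, sprintf("^%s_tac_.*\\.csv$", id),
                            full.names = TRUE)
    tacs <- list()
    for (fp in tac_files) tacs <- c(tacs, read_tac_table(fp))
    if (!length(tacs)) next
    plasma <- utils::read.csv(file.path(dir, sprintf("%s_plasma.csv", id)))
    cl <- utils::read.csv(file.path(dir, sprintf("%s_clamp.csv", id)))
    clamp <- clamp_record(cl$time_min, cl$gir_umol_kg_min,
                          cl$glucose_mmol_l, cl$insulin_pmol_l,
                          cl$ffa_mmol_l,
                          window = unlist(config$clamp$window))
    subjects[[id]] <- list(tacs = tacs, plasma = plasma, clamp = clamp)
  }
  structure(list(meta = meta, subjects = subjects, config = config,
                 seed = as.integer(manifest$seed)),
            class = "fdg_cohort")
}
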