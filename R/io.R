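# File formats are fixed dialects (UTF-8, dot decimal, no sniffing):
#  - spectra CSV: `#key=value` metadata lines, then a header row
#    `wavelength_nm,<cond1>,<cond2>,...` and one row per wavelength;
#  - trajectory / exchange-log / predictor / reference tables: plain TSV
#    with a header row.

#' Read a denaturation spectra series from CSV
#'
#' The expected dialect is comma-separated with leading metadata lines
#' `#condition_kind=` (`temperature` or `denaturant`) and `#direction=`
#' (`unfolding` or `refolding`), then a header `wavelength_nm` plus one
#' column per condition named by its numeric value (K or M). Instrument
#' exports must be pre-converted to this layout.
#'
#' @param path Path to the CSV file.
#' @return A [denaturation_series()].
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  meta_idx <- grep("^#", lines)
  if (length(meta_idx) && any(meta_idx != seq_along(meta_idx)))
    stop("metadata lines must precede the header", call. = FALSE)
  meta <- list()
  for (ln in lines[meta_idx]) {
    kv <- sub("^#", "", ln)
    key <- sub("=.*$", "", kv)
    meta[[trimws(key)]] <- trimws(sub("^[^=]*=", "", kv))
  }
  for (key in c("condition_kind", "direction"))
    if (is.null(meta[[key]]))
      stop("missing metadata line '#", key, "='", call. = FALSE)
  if (!meta$condition_kind %in% c("temperature", "denaturant"))
    stop("unknown condition kind: ", meta$condition_kind, call. = FALSE)

  body <- lines[-meta_idx]
  if (length(meta_idx) == 0L) body <- lines
  tab <- utils::read.csv(text = paste(body, collapse = "\n"),
                         check.names = FALSE, colClasses = "numeric")
  if (!"wavelength_nm" %in% names(tab))
    stop("missing wavelength column 'wavelength_nm'", call. = FALSE)
  cond_names <- setdiff(names(tab), "wavelength_nm")
  if (length(cond_names) == 0L)
    stop("no condition columns found", call. = FALSE)
  cond_values <- suppressWarnings(as.numeric(cond_names))
  if (anyNA(cond_values))
    stop("condition column names must be numeric values", call. = FALSE)
  if (any(diff(tab$wavelength_nm) <= 0))
    stop("non-monotonic wavelength grid", call. = FALSE)
  denaturation_series(
    wavelength_nm = tab$wavelength_nm,
    intensities = as.matrix(tab[cond_names]),
    condition_values = cond_values,
    condition_kind = meta$condition_kind,
    direction = meta$direction
  )
}

#' Write a denaturation spectra series to CSV
#'
#' Inverse of [read_spectra_csv()]; numeric values are written with 10
#' significant digits so the round trip is lossless for fitting purposes.
#'
#' @param series A [denaturation_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(series, path) {
  stopifnot(inherits(series, "denaturation_series"))
  if (n_conditions(series) == 0L)
    stop("cannot write an empty series", call. = FALSE)
  fmt <- function(x) format(x, digits = 10, trim = TRUE, scientific = FALSE)
  header <- c(
    paste0("#condition_kind=", series$condition_kind),
    paste0("#direction=", series$direction),
    paste(c("wavelength_nm", fmt(series$condition_values)), collapse = ",")
  )
  rows <- vapply(seq_along(series$wavelength_nm), function(i) {
    paste(c(fmt(series$wavelength_nm[i]), fmt(series$intensities[i, ])),
          collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read a replica-exchange trajectory table (TSV)
#'
#' @param path Trajectory TSV with columns `step`, `replica_id`,
#'   `temperature_K`, `energy_kcal_mol`, `rg_angstrom`, `helix_fraction`.
#' @param exchange_path Optional exchange-log TSV with columns `step`,
#'   `replica_a`, `replica_b`, `accepted`.
#' @return A [rex_dataset()].
#' @export
read_trajectory_table <- function(path, exchange_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  frames <- utils::read.delim(path, check.names = FALSE)
  xlog <- NULL
  if (!is.null(exchange_path)) {
    if (!file.exists(exchange_path))
      stop("file not found: ", exchange_path, call. = FALSE)
    xlog <- utils::read.delim(exchange_path, check.names = FALSE)
  }
  rex_dataset(frames, xlog)
}

#' Write a replica-exchange dataset to TSV
#'
#' @param data A [rex_dataset()].
#' @param path Trajectory output path.
#' @param exchange_path Optional output path for the exchange log.
#' @return `path`, invisibly.
#' @export
write_trajectory_table <- function(data, path, exchange_path = NULL) {
  stopifnot(inherits(data, "rex_dataset"))
  utils::write.table(data$frames, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(exchange_path)) {
    if (is.null(data$exchange_log))
      stop("dataset has no exchange log to write", call. = FALSE)
    xl <- data$exchange_log
    xl$accepted <- as.integer(xl$accepted)
    utils::write.table(xl, exchange_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a predictor ddG table (TSV)
#'
#' One row per (mutation, tool) pair with the predicted change in folding
#' free energy, sign convention dGWT - dGMUT (negative = destabilizing).
#' Duplicate (mutation, tool) keys are rejected.
#'
#' @param path TSV with columns `mutation`, `tool`, `ddg_kcal_mol`.
#' @return A data frame of class `predictor_table`.
#' @export
read_predictor_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = c("character", "character", "numeric"))
  predictor_table(tab)
}

#' Construct/validate a predictor ddG table
#'
#' @param tab Data frame with columns `mutation`, `tool`, `ddg_kcal_mol`.
#' @return The validated table, classed `predictor_table`.
#' @export
predictor_table <- function(tab) {
  required <- c("mutation", "tool", "ddg_kcal_mol")
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop("missing predictor columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  tab <- as.data.frame(tab)[required]
  tab$ddg_kcal_mol <- as.numeric(tab$ddg_kcal_mol)
  if (anyNA(tab$ddg_kcal_mol))
    stop("non-numeric ddg_kcal_mol values", call. = FALSE)
  key <- paste(tab$mutation, tab$tool, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- tab[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate (mutation, tool) entry: (%s, %s)",
                 dup$mutation, dup$tool), call. = FALSE)
  }
  if (nrow(tab) == 0L)
    warning("predictor table is empty", call. = FALSE)
  class(tab) <- c("predictor_table", "data.frame")
  tab
}

#' Read reference pathogenicity scores (TSV)
#'
#' @param path TSV with columns `mutation`, `score`.
#' @return Named numeric vector of scores, names = mutation labels.
#' @export
read_reference_scores <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = c("character", "numeric"))
  miss <- setdiff(c("mutation", "score"), names(tab))
  if (length(miss))
    stop("missing reference columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(tab$mutation))
    stop("duplicate mutation in reference scores", call. = FALSE)
  stats::setNames(tab$score, tab$mutation)
}

#' Read a pipeline run configuration (YAML)
#'
#' The configuration mirrors [run_pipeline()]'s arguments: input paths by
#' role (`spectra`, `trajectory`, `exchange_log`, `predictors`,
#' `reference`), fit options, WHAM options (`bins`, `tol`), impact
#' options (`predictor_rule`, `chemical_delta`) and `seed`.
#'
#' @param path YAML file path.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  run_config(cfg)
}

#' Validate a run configuration list
#'
#' @param cfg Named list (see [read_run_config()]).
#' @return The list with defaults filled in, classed `run_config`.
#' @export
run_config <- function(cfg = list()) {
  defaults <- list(
    inputs = list(),
    channel_thermal = "peak_intensity",
    channel_chemical = "lambda_max",
    fit_temperature_K = 298.15,
    wham_bins = 200L,
    wham_tol = 1e-7,
    predictor_rule = "mean",
    predictor_tool = NULL,
    chemical_delta = "wt_vs_mutant",
    seed = 0L
  )
  cfg <- utils::modifyList(defaults, as.list(cfg))
  channels <- c("lambda_max", "peak_intensity", "integrated_intensity")
  if (!cfg$channel_thermal %in% channels ||
      !cfg$channel_chemical %in% channels)
    stop("observable channel must be one of: ",
         paste(channels, collapse = ", "), call. = FALSE)
  if (!cfg$chemical_delta %in% c("wt_vs_mutant", "hysteresis"))
    stop("chemical_delta must be 'wt_vs_mutant' or 'hysteresis'", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  if (is.na(cfg$seed) || cfg$seed < 0L)
    stop("seed must be a non-negative integer", call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}
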