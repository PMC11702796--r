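#' Run the full stability-impact pipeline
#'
#' Executes the stages in dependency order: ingest (or synthesize)
#' spectra and replica-exchange data, reduce spectra to signal curves and
#' fit the two-state models, compute the WHAM thermodynamics per variant,
#' convert every effect to kcal/mol and aggregate the normalized overall
#' impact, then correlate with reference scores. Stages whose inputs are
#' absent are skipped with a notice; the returned report marks the
#' impact section incomplete when any component is missing.
#'
#' @param config A [run_config()] (or list coerced by it). Input roles
#'   under `config$inputs`: `spectra` (list of entries with `variant`,
#'   `path`; kind and direction are read from the file), `trajectories`
#'   (entries with `variant`, `path`, optional `exchange_log`),
#'   `predictors` (TSV path), `reference` (TSV path).
#' @param synthetic Use the built-in [synthetic_study()] cohort instead
#'   of file inputs (seeded from `config$seed`).
#' @param out_dir Optional directory for stage output tables
#'   (`thermal_fits.tsv`, `chemical_fits.tsv`, `stability_deltas.tsv`,
#'   `rex_summary.tsv`, `impact.tsv`). Files carry no timestamps, so a
#'   fixed seed reproduces them byte for byte.
#' @param rex_frames Frames per replica for synthetic replica-exchange
#'   runs (passed to [synthetic_study()]).
#' @param verbose Log stage progress via `message()`.
#' @return A list of class `run_report` with elements `config`, `seed`,
#'   `thermal_fits`, `chemical_fits`, `deltas`, `rex` (per-variant Tm,
#'   exchange rates), `impact` (an `impact_table` or `NULL`),
#'   `impact_complete`, `pearson`, and `notes` (skipped stages).
#' @export
run_pipeline <- function(config = run_config(), synthetic = FALSE,
                         out_dir = NULL, rex_frames = 20000L,
                         verbose = TRUE) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  say <- function(...) if (verbose) message("[stabscan] ", sprintf(...))
  notes <- character()

  spectra_series <- list()   # variant -> list of denaturation_series
  rex_data <- list()         # variant -> rex_dataset
  predictors <- NULL
  reference <- NULL

  if (synthetic) {
    say("stage ingest: generating synthetic study (seed %d)", config$seed)
    study <- synthetic_study(seed = config$seed, rex_frames = rex_frames)
    for (v in study$variants) {
      spectra_series[[v]] <- lapply(study$spectra[[v]], simulate_spectra_series)
      rex_data[[v]] <- simulate_rex_zimm_bragg(study$rex[[v]])
    }
    predictors <- study$predictors
    reference <- study$reference
    wt <- study$wt_label
  } else {
    say("stage ingest: reading inputs")
    wt <- config$wt_label %||% "WT"
    for (entry in config$inputs$spectra) {
      series <- read_spectra_csv(entry$path)
      key <- if (series$condition_kind == "temperature") "thermal"
             else paste0("chemical_", series$direction)
      spectra_series[[entry$variant]][[key]] <- series
    }
    for (entry in config$inputs$trajectories) {
      rex_data[[entry$variant]] <-
        read_trajectory_table(entry$path, entry$exchange_log)
    }
    if (!is.null(config$inputs$predictors))
      predictors <- read_predictor_table(config$inputs$predictors)
    if (!is.null(config$inputs$reference))
      reference <- read_reference_scores(config$inputs$reference)
  }

  # --- denaturation fits -------------------------------------------------
  thermal_fits <- list()
  chemical_fits <- list()
  if (length(spectra_series)) {
    say("stage fits: %d variants", length(spectra_series))
    for (v in names(spectra_series)) {
      sl <- spectra_series[[v]]
      if (!is.null(sl$thermal)) {
        curve <- build_signal_curve(sl$thermal, config$channel_thermal)
        thermal_fits[[v]] <- fit_thermal(curve)
        if (!thermal_fits[[v]]$converged)
          notes <- c(notes, sprintf("thermal fit not converged: %s", v))
      }
      for (dir in c("unfolding", "refolding")) {
        key <- paste0("chemical_", dir)
        if (!is.null(sl[[key]])) {
          curve <- build_signal_curve(sl[[key]], config$channel_chemical)
          chemical_fits[[v]][[dir]] <-
            fit_chemical(curve, T_K = config$fit_temperature_K)
        }
      }
    }
  } else {
    notes <- c(notes, "no spectra inputs: fit stage skipped")
    say("stage fits: skipped (no spectra)")
  }

  deltas <- NULL
  if (length(thermal_fits) || length(chemical_fits)) {
    deltas <- stability_deltas(
      thermal = if (length(thermal_fits)) thermal_fits else NULL,
      chemical = if (length(chemical_fits)) chemical_fits else NULL,
      wt_label = wt)
  }

  # --- replica-exchange thermodynamics -----------------------------------
  rex_report <- NULL
  if (length(rex_data)) {
    say("stage rex: WHAM over %d variants", length(rex_data))
    per_variant <- lapply(names(rex_data), function(v) {
      dat <- rex_data[[v]]
      wh <- wham_solve(dat, bins = config$wham_bins, tol = config$wham_tol)
      curves <- compute_cv(wh)
      rates <- if (!is.null(dat$exchange_log))
        exchange_rate_summary(dat) else NULL
      list(variant = v, wham = wh, curves = curves,
           Tm_K = attr(curves, "Tm_K"), rates = rates)
    })
    names(per_variant) <- names(rex_data)
    curves_list <- lapply(per_variant, `[[`, "curves")
    dtm <- if (wt %in% names(curves_list)) delta_tm(curves_list, wt) else NULL
    rex_report <- list(per_variant = per_variant, delta_Tm = dtm)
  } else {
    notes <- c(notes, "no trajectory inputs: rex stage skipped")
    say("stage rex: skipped (no trajectories)")
  }

  # --- impact ------------------------------------------------------------
  impact <- NULL
  pearson <- NULL
  mutants <- setdiff(
    unique(c(names(thermal_fits), names(chemical_fits), names(rex_data),
             if (!is.null(predictors)) unique(predictors$mutation))),
    wt)
  have_all <- length(mutants) > 0 && !is.null(predictors) &&
    wt %in% names(thermal_fits) &&
    !is.null(chemical_fits[[wt]]$unfolding) &&
    !is.null(rex_report) && wt %in% names(rex_data)
  if (have_all) {
    say("stage impact: %d mutants", length(mutants))
    ddg_pt <- aggregate_predictor_ddg(
      predictors, rule = config$predictor_rule, tool = config$predictor_tool)
    wt_thermal <- thermal_fits[[wt]]
    wt_chem <- chemical_fits[[wt]]$unfolding
    wt_rex <- rex_report$per_variant[[wt]]
    dHm_rex <- cv_peak_enthalpy(wt_rex$curves)
    rows <- lapply(mutants, function(v) {
      dtm_td <- if (v %in% names(thermal_fits))
        wt_thermal$Tm_K - thermal_fits[[v]]$Tm_K else NA_real_
      dtm_rex <- if (!is.null(rex_report$delta_Tm) &&
                     v %in% names(rex_report$delta_Tm))
        rex_report$delta_Tm[[v]] else NA_real_
      dd <- if (!is.null(chemical_fits[[v]]$unfolding)) {
        if (config$chemical_delta == "wt_vs_mutant")
          wt_chem$D_half - chemical_fits[[v]]$unfolding$D_half
        else if (!is.null(chemical_fits[[v]]$refolding))
          chemical_fits[[v]]$unfolding$D_half -
            chemical_fits[[v]]$refolding$D_half
        else NA_real_
      } else NA_real_
      data.frame(
        mutation = v,
        ddg_pt = if (v %in% names(ddg_pt)) ddg_pt[[v]] else NA_real_,
        ddg_rex = if (is.na(dtm_rex)) NA_real_ else
          ddg_from_tm_shift(dHm_rex, dtm_rex, wt_rex$Tm_K),
        ddg_td = if (is.na(dtm_td)) NA_real_ else
          ddg_from_tm_shift(wt_thermal$dH_app, dtm_td, wt_thermal$Tm_K),
        ddg_cd = if (is.na(dd)) NA_real_ else
          ddg_from_chemical(wt_chem$m_value, dd))
    })
    components <- do.call(rbind, rows)
    impact <- overall_impact(components, allow_partial = anyNA(components))
    if (!is.null(reference)) {
      pearson <- tryCatch(correlate_with_reference(impact, reference),
                          error = function(e) {
                            notes <<- c(notes, conditionMessage(e))
                            NULL
                          })
    }
  } else {
    notes <- c(notes, "impact section incomplete: missing inputs")
    say("stage impact: incomplete (missing inputs)")
  }

  report <- structure(
    list(config = config, seed = config$seed,
         thermal_fits = thermal_fits, chemical_fits = chemical_fits,
         deltas = deltas, rex = rex_report, impact = impact,
         impact_complete = have_all, pearson = pearson, notes = notes),
    class = "run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report_tables(report, out_dir)
    say("stage report: tables written to %s", out_dir)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Flat TSV views of a run report (no timestamps: byte-reproducible).
write_report_tables <- function(report, out_dir) {
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (length(report$thermal_fits)) {
    tf <- do.call(rbind, lapply(names(report$thermal_fits), function(v) {
      f <- report$thermal_fits[[v]]
      data.frame(variant = v, dH_app = f$dH_app, Tm_K = f$Tm_K, Yn = f$Yn,
                 Yd = f$Yd, se_Tm_K = f$se[["Tm_K"]], rss = f$rss,
                 converged = f$converged, channel = f$channel)
    }))
    wt(tf, "thermal_fits.tsv")
  }
  if (length(report$chemical_fits)) {
    cf <- do.call(rbind, lapply(names(report$chemical_fits), function(v) {
      do.call(rbind, lapply(names(report$chemical_fits[[v]]), function(dir) {
        f <- report$chemical_fits[[v]][[dir]]
        data.frame(variant = v, direction = dir, dG_app = f$dG_app,
                   m_value = f$m_value, D_half = f$D_half, Yn = f$Yn,
                   Yd = f$Yd, rss = f$rss, converged = f$converged,
                   channel = f$channel)
      }))
    }))
    wt(cf, "chemical_fits.tsv")
  }
  if (!is.null(report$deltas)) wt(report$deltas, "stability_deltas.tsv")
  if (!is.null(report$rex)) {
    rs <- do.call(rbind, lapply(report$rex$per_variant, function(pv) {
      data.frame(variant = pv$variant, Tm_K = pv$Tm_K,
                 delta_Tm = if (!is.null(report$rex$delta_Tm))
                   report$rex$delta_Tm[[pv$variant]] else NA_real_,
                 min_exchange_rate = if (!is.null(pv$rates))
                   attr(pv$rates, "min_rate") else NA_real_,
                 max_exchange_rate = if (!is.null(pv$rates))
                   attr(pv$rates, "max_rate") else NA_real_)
    }))
    wt(rs, "rex_summary.tsv")
  }
  if (!is.null(report$impact)) {
    imp <- report$impact
    imp$scaling_factor <- attr(report$impact, "scaling_factor")
    if (!is.null(report$pearson)) {
      imp$pearson_r <- report$pearson$r
      imp$n_shared <- report$pearson$n_shared
    }
    wt(imp, "impact.tsv")
  }
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  seed: %d\n", x$seed))
  cat(sprintf("  thermal fits: %d, chemical fits: %d\n",
              length(x$thermal_fits), length(x$chemical_fits)))
  if (!is.null(x$rex))
    cat(sprintf("  rex variants: %d\n", length(x$rex$per_variant)))
  if (!is.null(x$impact)) {
    cat(sprintf("  impact: %d mutations (scaling factor %.3f kcal/mol)\n",
                nrow(x$impact), attr(x$impact, "scaling_factor")))
  } else cat("  impact: incomplete\n")
  if (!is.null(x$pearson))
    cat(sprintf("  Pearson r vs reference: %.3f (n = %d)\n",
                x$pearson$r, x$pearson$n_shared))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}
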