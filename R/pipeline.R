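#' Pipeline configuration
#'
#' Collects every input path and tolerance of the three-stage workflow
#' (feature finding, PFAS-evidence prioritization, reporting) in one list.
#' Exactly one feature source must be given: either a sample mzML (internal
#' feature finding) or an external feature table CSV (in which case an mzML
#' may still be supplied so MS2 spectra can be aligned to the table rows).
#' `sample` and `blank` accept either file paths or in-memory `ms_run`
#' objects.
#'
#' Defaults: 10 ppm / 2000 counts for feature finding; 5 mDa and 0.2 min for
#' MS2 alignment; 2 mDa, 0.1 min, fivefold for blank correction; m/C > 30
#' and MD/C < +0.003 cutoffs; 2 mDa KMD tolerance with at least 3
#' homologues; 2 mDa fragment tolerance at 2000-count MS2 noise; 4 mDa
#' suspect tolerance.
#'
#' @param sample Sample mzML path or `ms_run` (or `NULL` with `feature_csv`).
#' @param blank Optional blank mzML path or `ms_run`.
#' @param feature_csv Optional external feature table CSV.
#' @param suspects Optional suspect list: CSV path or data frame
#'   (see [read_suspect_csv()]).
#' @param fragments Diagnostic fragment list: CSV path, data frame, or
#'   `NULL` for the built-in list at the run polarity.
#' @param differences Mass-difference list: CSV path, data frame, or `NULL`
#'   for the built-in list.
#' @param polarity `"-"` or `"+"`.
#' @param adducts Adduct labels for suspect screening (default chosen by
#'   polarity).
#' @param repeating_units Character vector of Kendrick repeating units
#'   (default `c("CF2")`).
#' @param output_dir Optional directory for the results CSV.
#' @param ... Tolerance overrides: `mass_error_ppm`, `intensity_threshold`,
#'   `min_fwhm`, `max_fwhm`, `min_isotope_traces`, `ms2_mz_tol`,
#'   `ms2_rt_tol`, `blank_mz_tol`, `blank_rt_tol`, `blank_fold`, `mc_min`,
#'   `mdc_max`, `kmd_tol`, `kmd_min_members`, `frag_tol`, `ms2_noise`,
#'   `min_df_hits`, `min_diff_hits`, `suspect_tol`.
#' @return List of settings, class `pipeline_config`.
#' @export
pipeline_config <- function(sample = NULL, blank = NULL, feature_csv = NULL,
                            suspects = NULL, fragments = NULL,
                            differences = NULL, polarity = "-",
                            adducts = NULL, repeating_units = "CF2",
                            output_dir = NULL, ...) {
  if (is.null(sample) && is.null(feature_csv))
    stop("provide a sample mzML or an external feature table")
  if (!is.null(feature_csv) && is.null(sample)) {
    ## table-only mode: MS2-dependent stages are skipped
  }
  cfg <- list(
    sample = sample, blank = blank, feature_csv = feature_csv,
    suspects = suspects, fragments = fragments, differences = differences,
    polarity = polarity,
    adducts = adducts %||% (if (polarity == "-") "[M-H]-" else c("[M+H]+", "[M]+")),
    repeating_units = repeating_units, output_dir = output_dir,
    mass_error_ppm = 10, intensity_threshold = 2000,
    min_fwhm = 1, max_fwhm = 1, min_isotope_traces = 2L,
    ms2_mz_tol = 0.005, ms2_rt_tol = 0.2,
    blank_mz_tol = 0.002, blank_rt_tol = 0.1, blank_fold = 5,
    mc_min = 30, mdc_max = 0.003,
    kmd_tol = 0.002, kmd_min_members = 3L,
    frag_tol = 0.002, ms2_noise = 2000, min_df_hits = 1L, min_diff_hits = 1L,
    suspect_tol = 0.004
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop(sprintf("unknown pipeline_config field(s): %s",
                                paste(bad, collapse = ", ")))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

.resolve_run <- function(x) {
  if (is.null(x) || inherits(x, "ms_run")) x else read_mzml(x)
}

#' Run the full prioritization workflow
#'
#' Stages, in order: feature detection (or external table ingestion), blank
#' correction, MS2 alignment, carbon estimation and MD/C - m/C computation
#' and filtering, Kendrick homologous-series detection, MS2
#' diagnostic-fragment and fragment-difference matching, and suspect
#' screening. Evidence accumulates as flag columns; no feature is dropped
#' from the table, so the funnel stays auditable. Per-stage counts are
#' logged via [message()].
#'
#' The MS2 spectra assigned to features are extracted into the returned
#' state, so the prioritization stages can be re-run with different cutoffs
#' via [reprioritize()] without touching the raw file again.
#'
#' @param cfg A [pipeline_config()].
#' @return Pipeline state (list): `results` (the results table), `funnel`
#'   (named stage counts), `series` (homologous series per repeating unit),
#'   `suspect_matches`, `features_raw`, `ms2_spectra`, `cfg`, and
#'   `results_path` when `output_dir` was set.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  run <- .resolve_run(cfg$sample)
  funnel <- c()

  ## stage 1: features
  if (!is.null(cfg$feature_csv)) {
    feats <- features_from_table(read_feature_csv(cfg$feature_csv))
    message(sprintf("[features] external table: %d features", nrow(feats)))
  } else {
    p <- feature_finder_params(cfg$mass_error_ppm, cfg$intensity_threshold,
                               cfg$min_fwhm, cfg$max_fwhm,
                               cfg$min_isotope_traces)
    feats <- detect_features(run, p)
    message(sprintf("[features] detected %d features", nrow(feats)))
  }
  funnel["detected"] <- nrow(feats)

  ## stage 2: blank correction
  if (!is.null(cfg$blank)) {
    blank_run <- .resolve_run(cfg$blank)
    blank_feats <- if (inherits(blank_run, "ms_run")) {
      detect_features(blank_run,
                      feature_finder_params(cfg$mass_error_ppm,
                                            cfg$intensity_threshold,
                                            cfg$min_fwhm, cfg$max_fwhm,
                                            cfg$min_isotope_traces))
    } else blank_run
    feats <- blank_correct(feats, blank_feats, cfg$blank_mz_tol,
                           cfg$blank_rt_tol, cfg$blank_fold)
    message(sprintf("[blank] %d of %d features flagged as blank background",
                    sum(feats$blank_removed), nrow(feats)))
  } else {
    feats$blank_removed <- FALSE
    message("[blank] no blank provided; stage skipped")
  }
  funnel["after_blank"] <- sum(!feats$blank_removed)

  ## stage 3: MS2 alignment (+ spectrum extraction for stage caching)
  ms2_spectra <- list()
  if (!is.null(run)) {
    feats <- align_ms2(feats, run, cfg$ms2_mz_tol, cfg$ms2_rt_tol)
    assigned <- which(!is.na(feats$ms2_scan))
    for (i in assigned)
      ms2_spectra[[as.character(feats$ms2_scan[i])]] <-
        get_spectrum(run, feats$ms2_scan[i])
    message(sprintf("[ms2] %d features received an MS2 spectrum",
                    length(assigned)))
  } else {
    feats$ms2_scan <- NA_integer_
    message("[ms2] no raw run available; MS2 stages skipped")
  }

  state <- list(features_raw = feats, ms2_spectra = ms2_spectra,
                polarity = if (!is.null(run)) run$polarity else cfg$polarity,
                funnel = funnel, cfg = cfg)
  reprioritize(state, cfg)
}

#' Re-run the prioritization stages on cached pipeline state
#'
#' Applies the MD/C - m/C filter, homologous-series detection, MS2 matching
#' and suspect screening to an existing pipeline state with (possibly
#' changed) cutoffs; the raw spectra are never re-read, supporting the
#' iterative tune-and-rerun working style.
#'
#' @param state State returned by [run_pipeline()] or `reprioritize()`.
#' @param cfg A [pipeline_config()]; feature-finding fields are ignored.
#' @return Updated pipeline state.
#' @export
reprioritize <- function(state, cfg) {
  feats <- state$features_raw
  funnel <- state$funnel[c("detected", "after_blank")]

  ## stage 4: carbon + MD/C - m/C
  feats <- compute_mdc_mc(add_carbon_estimate(feats))
  feats <- filter_mdc_mc(feats, cfg$mc_min, cfg$mdc_max)
  feats$mdc_mc_pass <- feats$mdc_mc_pass & !feats$blank_removed
  funnel["mdc_mc_pass"] <- sum(feats$mdc_mc_pass)
  message(sprintf("[mdc_mc] %d of %d features pass m/C > %s, MD/C < %s",
                  sum(feats$mdc_mc_pass), sum(!feats$blank_removed),
                  format(cfg$mc_min %||% -Inf), format(cfg$mdc_max %||% Inf)))

  ## stage 5: homologous series on the surviving features
  sub <- feats[feats$mdc_mc_pass, , drop = FALSE]
  feats$hs_ids <- ""
  all_series <- list()
  for (ru_name in cfg$repeating_units) {
    ru <- repeating_unit(ru_name)
    series <- detect_homologous_series(sub, ru, cfg$kmd_tol,
                                       cfg$kmd_min_members)
    all_series[[ru_name]] <- series
    feats <- add_hs_ids(feats, series)
    message(sprintf("[kmd] %s: %d homologous series", ru_name,
                    length(series)))
  }
  funnel["series"] <- sum(lengths(all_series))

  ## stage 6: MS2 evidence
  dfs <- cfg$fragments
  if (is.null(dfs)) dfs <- pfas_diagnostic_fragments(state$polarity)
  else if (is.character(dfs)) dfs <- read_fragment_csv(dfs)
  dfs <- dfs[dfs$polarity == state$polarity, , drop = FALSE]
  diffs <- cfg$differences
  if (is.null(diffs)) diffs <- pfas_mass_differences()
  else if (is.character(diffs)) diffs <- read_difference_csv(diffs)

  feats$n_df_hits <- 0L; feats$n_diff_hits <- 0L
  feats$df_hit <- FALSE; feats$diff_hit <- FALSE
  for (i in which(!is.na(feats$ms2_scan) & feats$mdc_mc_pass)) {
    sp <- state$ms2_spectra[[as.character(feats$ms2_scan[i])]]
    if (is.null(sp)) next
    dm <- match_diagnostic_fragments(sp, dfs, cfg$frag_tol, cfg$ms2_noise,
                                     cfg$min_df_hits)
    fm <- match_fragment_differences(sp, diffs, cfg$frag_tol, cfg$ms2_noise,
                                     cfg$min_diff_hits)
    feats$n_df_hits[i] <- nrow(dm$hits)
    feats$n_diff_hits[i] <- nrow(fm$hits)
    feats$df_hit[i] <- dm$flagged
    feats$diff_hit[i] <- fm$flagged
  }
  funnel["df_flagged"] <- sum(feats$df_hit)
  funnel["diff_flagged"] <- sum(feats$diff_hit)
  message(sprintf("[ms2-match] %d DF-flagged, %d difference-flagged spectra",
                  sum(feats$df_hit), sum(feats$diff_hit)))

  ## stage 7: suspect screening
  feats$suspect_hits <- ""
  feats$suspect_hit <- FALSE
  suspect_matches <- NULL
  if (!is.null(cfg$suspects)) {
    suspects <- if (is.character(cfg$suspects)) read_suspect_csv(cfg$suspects)
    else cfg$suspects
    sub <- feats[feats$mdc_mc_pass, , drop = FALSE]
    suspect_matches <- suspect_screen(sub, suspects, cfg$adducts,
                                      cfg$suspect_tol, state$polarity)
    for (fid in unique(suspect_matches$feature_id)) {
      i <- which(feats$feature_id == fid)
      feats$suspect_hit[i] <- TRUE
      feats$suspect_hits[i] <- paste(
        unique(suspect_matches$name[suspect_matches$feature_id == fid]),
        collapse = ";")
    }
    message(sprintf("[suspects] %d matches over %d features",
                    nrow(suspect_matches), sum(feats$suspect_hit)))
  } else {
    message("[suspects] no suspect list provided; stage skipped")
  }
  funnel["suspect_features"] <- sum(feats$suspect_hit)

  state$results <- feats
  state$funnel <- funnel
  state$series <- all_series
  state$suspect_matches <- suspect_matches
  state$cfg <- cfg
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    state$results_path <- file.path(cfg$output_dir, "results.csv")
    write_results(feats, state$results_path)
    message(sprintf("[write] results written to %s", state$results_path))
  }
  state
}

#' Text summary of the prioritization funnel
#'
#' @param state Pipeline state from [run_pipeline()].
#' @return Character vector of report lines (also printed).
#' @export
summarize_results <- function(state) {
  f <- state$funnel
  n0 <- max(f["detected"], 1)
  lines <- c(
    sprintf("features detected:            %d", f[["detected"]]),
    sprintf("after blank correction:       %d (%.1f%%)", f[["after_blank"]],
            100 * f[["after_blank"]] / n0),
    sprintf("passing MD/C-m/C cutoffs:     %d (%.1f%%)", f[["mdc_mc_pass"]],
            100 * f[["mdc_mc_pass"]] / n0),
    sprintf("homologous series:            %d", f[["series"]]),
    sprintf("DF-flagged spectra:           %d", f[["df_flagged"]]),
    sprintf("difference-flagged spectra:   %d", f[["diff_flagged"]]),
    sprintf("features with suspect hits:   %d", f[["suspect_features"]])
  )
  cat(lines, sep = "\n")
  invisible(lines)
}
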