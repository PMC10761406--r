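#' Read a centroided mzML run
#'
#' Loads every MS1 and MS2 scan of an mzML file into an `ms_run` object.
#' Retention times are converted from seconds to minutes on read. Polarity is
#' taken from scan metadata; a file mixing polarities is rejected, as is one
#' whose spectra are stored in profile mode (centroid first, e.g. with
#' msconvert peak picking). If MS2 scans carry more than one collision
#' energy, only scans at the first observed energy are kept, with a warning.
#'
#' @param path Path to an mzML file with centroided spectra.
#' @return An `ms_run`: list with `header` (data frame: `ms_level`, `rt`
#'   minutes, `precursor_mz`, `precursor_intensity`, `tic`), `peaks` (list of
#'   two-column matrices `mz`, `intensity`), `polarity` (`"+"` or `"-"`) and
#'   `path`.
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh), add = TRUE)
  hd <- mzR::header(fh)
  if (nrow(hd) == 0L) stop(sprintf("no spectra in %s", path))
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)

  if (any(!is.na(hd$centroided) & !hd$centroided))
    stop("profile-mode spectra detected; centroid the file before reading")
  if (any(is.na(hd$centroided)) && .looks_profile(pk, hd))
    stop("spectra look profile-mode (dense peak spacing); centroid the file first")

  pol <- unique(hd$polarity[hd$polarity %in% c(0L, 1L)])
  if (length(pol) > 1L)
    stop("mixed polarity run; split the file into one polarity per run")
  polarity <- if (length(pol) == 0L) {
    warning("polarity missing from scan metadata; assuming negative mode")
    "-"
  } else if (pol == 1L) "+" else "-"

  is2 <- hd$msLevel == 2L
  if (any(is2)) {
    ces <- unique(hd$collisionEnergy[is2 & !is.na(hd$collisionEnergy)])
    if (length(ces) > 1L) {
      warning(sprintf("multiple collision energies (%s); keeping %s",
                      paste(ces, collapse = ", "), ces[1]))
      drop <- is2 & !is.na(hd$collisionEnergy) & hd$collisionEnergy != ces[1]
      hd <- hd[!drop, , drop = FALSE]
      pk <- pk[!drop]
    }
  }

  header <- data.frame(
    ms_level = hd$msLevel,
    rt = hd$retentionTime / 60,
    precursor_mz = ifelse(hd$msLevel == 2L, hd$precursorMZ, NA_real_),
    precursor_intensity = ifelse(hd$msLevel == 2L, hd$precursorIntensity,
                                 NA_real_),
    tic = hd$totIonCurrent
  )
  peaks <- lapply(pk, function(m) {
    m <- m[order(m[, 1]), , drop = FALSE]
    colnames(m) <- c("mz", "intensity")
    m
  })
  structure(list(header = header, peaks = peaks, polarity = polarity,
                 path = path),
            class = "ms_run")
}

## Heuristic profile-mode detector: in the densest scan, profile data shows
## many consecutive points a few mDa apart; centroids are sparse.
.looks_profile <- function(pk, hd) {
  i <- which.max(hd$peaksCount)
  m <- pk[[i]]
  if (nrow(m) < 50L) return(FALSE)
  d <- diff(m[, 1])
  mean(d < 0.01) > 0.5
}

#' @export
print.ms_run <- function(x, ...) {
  n1 <- sum(x$header$ms_level == 1L)
  n2 <- sum(x$header$ms_level == 2L)
  cat(sprintf("ms_run (%s): %d MS1 + %d MS2 scans, RT %.2f-%.2f min, polarity %s\n",
              basename(x$path %||% "<memory>"), n1, n2,
              min(x$header$rt), max(x$header$rt), x$polarity))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an `ms_run` to mzML
#'
#' Emits a minimal standard-compliant mzML (spectrum list, scan start times,
#' m/z and intensity arrays, precursor information for MS2 scans) so any
#' conformant reader can consume the file. Used chiefly by the synthetic-data
#' generator.
#'
#' @param run An `ms_run`.
#' @param path Output path (`.mzML`).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  stopifnot(inherits(run, "ms_run"))
  hd <- run$header
  n <- nrow(hd)
  pol <- if (run$polarity == "+") 1L else 0L
  pk <- lapply(run$peaks, function(m) {
    m <- m[, c("mz", "intensity"), drop = FALSE]
    colnames(m) <- NULL
    m
  })
  bp <- vapply(seq_len(n), function(i) {
    m <- run$peaks[[i]]
    if (nrow(m) == 0L) c(0, 0) else c(m[which.max(m[, 2]), 1], max(m[, 2]))
  }, numeric(2))
  rng <- vapply(seq_len(n), function(i) {
    m <- run$peaks[[i]]
    if (nrow(m) == 0L) c(0, 0) else range(m[, 1])
  }, numeric(2))
  is2 <- hd$ms_level == 2L
  mzr_header <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = as.integer(hd$ms_level), polarity = pol,
    peaksCount = vapply(pk, nrow, integer(1)),
    totIonCurrent = vapply(run$peaks, function(m) sum(m[, 2]), numeric(1)),
    retentionTime = hd$rt * 60,
    basePeakMZ = bp[1, ], basePeakIntensity = bp[2, ],
    collisionEnergy = ifelse(is2, 30, NA_real_),
    ionisationEnergy = 0, lowMZ = rng[1, ], highMZ = rng[2, ],
    precursorScanNum = ifelse(is2, NA_integer_, NA_integer_),
    precursorMZ = ifelse(is2, hd$precursor_mz, NA_real_),
    precursorCharge = ifelse(is2, 1L, NA_integer_),
    precursorIntensity = ifelse(is2, hd$precursor_intensity, NA_real_),
    mergedScan = NA_integer_, mergedResultScanNum = NA_integer_,
    mergedResultStartScanNum = NA_integer_, mergedResultEndScanNum = NA_integer_,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = ifelse(is2, hd$precursor_mz, NA_real_),
    isolationWindowLowerOffset = ifelse(is2, 0.5, NA_real_),
    isolationWindowUpperOffset = ifelse(is2, 0.5, NA_real_),
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_
  )
  mzR::writeMSData(pk, file = path, header = mzr_header, outformat = "mzml")
  invisible(path)
}

#' Read an external feature table
#'
#' Entry point for feature lists produced by other software: a CSV holding at
#' least the m/z and retention time of each feature plus the apex intensities
#' of the monoisotopic peak and its M+1 isotopologue. Column names are
#' configurable through `col_map`. Extra columns are carried through
#' untouched.
#'
#' @param path CSV path.
#' @param col_map Named character vector mapping the required logical names
#'   (`mz`, `rt`, `intensity_M`, `intensity_M1`) to the file's column headers.
#' @return Data frame with standardized required columns first.
#' @export
read_feature_csv <- function(path,
                             col_map = c(mz = "mz", rt = "rt",
                                         intensity_M = "intensity_M",
                                         intensity_M1 = "intensity_M1")) {
  need <- c("mz", "rt", "intensity_M", "intensity_M1")
  stopifnot(all(need %in% names(col_map)))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (k in need) {
    cn <- col_map[[k]]
    if (!cn %in% names(df))
      stop(sprintf("feature table %s is missing required column '%s'",
                   path, cn))
    v <- df[[cn]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      if (any(is.na(vn) & !is.na(v)))
        stop(sprintf("non-numeric value in column '%s', row %d", cn,
                     which(is.na(vn) & !is.na(v))[1]))
      v <- vn
    }
    df[[cn]] <- v
  }
  extras <- setdiff(names(df), unname(col_map[need]))
  out <- df[, unname(col_map[need]), drop = FALSE]
  names(out) <- need
  if (any(out$intensity_M1 > out$intensity_M * 1.2, na.rm = TRUE))
    warning("some rows have intensity_M1 > 1.2 * intensity_M; check the isotope assignment")
  cbind(out, df[, extras, drop = FALSE])
}

#' Write a prioritization results table to CSV
#'
#' One row per feature with every evidence column, in a fixed column order,
#' so identical inputs always produce byte-identical files.
#'
#' @param table Results data frame (see [run_pipeline()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  lead <- intersect(
    c("feature_id", "mz", "rt", "area", "intensity_M", "intensity_M1",
      "fwhm", "n_isotope_traces", "carbon_est", "md", "mdc", "m_over_c",
      "hs_ids", "ms2_scan", "n_df_hits", "n_diff_hits", "suspect_hits",
      "blank_removed", "mdc_mc_pass", "df_hit", "diff_hit", "suspect_hit"),
    names(table))
  table <- table[, c(lead, setdiff(names(table), lead)), drop = FALSE]
  utils::write.csv(format_results_numeric(table), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

## Fixed-format numeric rendering so CSV output is byte-stable across
## platforms and locale settings.
format_results_numeric <- function(table) {
  for (cn in names(table)) {
    v <- table[[cn]]
    if (is.double(v)) table[[cn]] <- formatC(v, format = "g", digits = 10)
  }
  table
}
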