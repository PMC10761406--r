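#' Feature finder parameters
#'
#' Defaults follow common practice for QTOF non-target acquisition: 10 ppm
#' mass error, 2000-count MS1 intensity threshold, chromatographic FWHM
#' between 1 s and 1 min, and at least two isotopologue traces (the
#' monoisotopic trace plus a coeluting M+1).
#'
#' @param mass_error_ppm Mass tolerance for EIC tracing, ppm.
#' @param intensity_threshold Minimum MS1 centroid intensity to seed a
#'   feature, counts.
#' @param min_fwhm Minimum chromatographic full width at half maximum, s.
#' @param max_fwhm Maximum FWHM, min.
#' @param min_isotope_traces Minimum number of coeluting isotopologue traces
#'   (including the monoisotopic trace).
#' @return List of parameters, class `feature_finder_params`.
#' @export
feature_finder_params <- function(mass_error_ppm = 10,
                                  intensity_threshold = 2000,
                                  min_fwhm = 1,
                                  max_fwhm = 1,
                                  min_isotope_traces = 2L) {
  stopifnot(mass_error_ppm > 0, intensity_threshold > 0,
            min_fwhm > 0, max_fwhm > 0, min_fwhm < max_fwhm * 60,
            min_isotope_traces >= 1L)
  structure(list(mass_error_ppm = mass_error_ppm,
                 intensity_threshold = intensity_threshold,
                 min_fwhm = min_fwhm, max_fwhm = max_fwhm,
                 min_isotope_traces = as.integer(min_isotope_traces)),
            class = "feature_finder_params")
}

#' Detect MS1 features in a centroided run
#'
#' A transparent greedy EIC tracer: the most intense unclaimed centroid above
#' the intensity threshold seeds an extracted ion chromatogram that is
#' extended across adjacent scans within the ppm tolerance (one missing scan
#' is bridged); the trace must form a chromatographic peak with FWHM inside
#' the configured window and be accompanied by a coeluting isotopologue trace
#' at +1.0033548 Da (13C spacing). The M+1/M apex ratio must additionally lie
#' within +/-50% of the isotopologue expectation for the implied carbon
#' count, rejecting traces with implausible isotope envelopes. Claimed
#' centroids are never reused, so each chromatographic peak is reported once.
#'
#' @param run An `ms_run` (see [read_mzml()]); needs at least 3 MS1 scans.
#' @param params A [feature_finder_params()].
#' @return Feature data frame sorted by decreasing area: `feature_id`, `mz`
#'   (intensity-weighted apex m/z), `rt` (apex, min), `area` (trapezoidal,
#'   counts x min), `intensity_M`, `intensity_M1` (apex counts), `fwhm` (s),
#'   `n_isotope_traces`.
#' @export
detect_features <- function(run, params = feature_finder_params()) {
  stopifnot(inherits(run, "ms_run"))
  ms1 <- which(run$header$ms_level == 1L)
  if (length(ms1) < 3L) stop("run has fewer than 3 MS1 scans")
  rt <- run$header$rt[ms1]
  scans <- run$peaks[ms1]
  nper <- vapply(scans, nrow, integer(1))
  if (sum(nper) == 0L) return(.empty_features())

  scan_of <- rep.int(seq_along(scans), nper)
  mz_all <- unlist(lapply(scans, function(m) m[, 1]), use.names = FALSE)
  int_all <- unlist(lapply(scans, function(m) m[, 2]), use.names = FALSE)
  offset <- c(0L, cumsum(nper))  # flat id of centroid j in scan i: offset[i]+j
  claimed <- logical(length(mz_all))

  ## nearest unclaimed centroid to `target` in scan i within +/- tol, flat id
  find_in_scan <- function(i, target, tol) {
    n <- nper[i]
    if (n == 0L) return(NA_integer_)
    mzv <- scans[[i]][, 1]
    j <- findInterval(target, mzv)
    best <- NA_integer_; bestd <- tol
    for (k in c(j, j + 1L, j - 1L, j + 2L)) {
      if (k < 1L || k > n) next
      id <- offset[i] + k
      if (claimed[id]) next
      d <- abs(mzv[k] - target)
      if (d <= bestd) { bestd <- d; best <- id }
    }
    best
  }

  ## trace an EIC around (seed_scan, seed_mz); returns flat ids per scan
  trace_eic <- function(seed_scan, seed_mz, tol) {
    ids <- integer(0); sc <- integer(0)
    for (dir in c(1L, -1L)) {
      i <- seed_scan + (dir == -1L) * 0L
      if (dir == -1L) i <- seed_scan - 1L
      gap <- 0L
      while (i >= 1L && i <= length(scans)) {
        id <- find_in_scan(i, seed_mz, tol)
        if (is.na(id)) {
          gap <- gap + 1L
          if (gap > 1L) break
        } else {
          gap <- 0L
          ids <- c(ids, id); sc <- c(sc, i)
        }
        i <- i + dir
      }
    }
    o <- order(sc)
    list(ids = ids[o], scans = sc[o])
  }

  ord <- order(int_all, decreasing = TRUE)
  ord <- ord[int_all[ord] >= params$intensity_threshold]
  feats <- vector("list", 64L); nf <- 0L

  for (s in ord) {
    if (claimed[s]) next
    seed_scan <- scan_of[s]
    seed_mz <- mz_all[s]
    tol <- seed_mz * params$mass_error_ppm * 1e-6
    tr <- trace_eic(seed_scan, seed_mz, tol)
    if (!s %in% tr$ids) { tr$ids <- c(s, tr$ids); tr$scans <- c(seed_scan, tr$scans)
                          o <- order(tr$scans); tr$ids <- tr$ids[o]; tr$scans <- tr$scans[o] }
    claimed[tr$ids] <- TRUE
    if (length(tr$ids) < 3L) next

    ti <- int_all[tr$ids]
    trts <- rt[tr$scans]
    a <- which.max(ti)
    fwhm_s <- .fwhm_seconds(trts, ti, a)
    if (is.na(fwhm_s) || fwhm_s < params$min_fwhm ||
        fwhm_s > params$max_fwhm * 60) next

    wmz <- sum(mz_all[tr$ids] * ti) / sum(ti)
    area <- .trapz(trts, ti)
    apex_scan <- tr$scans[a]

    ## coeluting isotopologue traces at +k * 13C spacing
    iso_int <- numeric(2); iso_pts <- integer(2); iso_ids <- list(integer(0), integer(0))
    for (k in 1:2) {
      target <- wmz + k * .C13_DELTA
      ids_k <- integer(0); int_apex <- 0
      for (idx in seq_along(tr$scans)) {
        i <- tr$scans[idx]
        id <- find_in_scan(i, target, tol)
        if (!is.na(id)) {
          ids_k <- c(ids_k, id)
          if (i == apex_scan) int_apex <- int_all[id]
        }
      }
      if (length(ids_k) >= 3L && int_apex > 0) {
        iso_int[k] <- int_apex; iso_pts[k] <- length(ids_k); iso_ids[[k]] <- ids_k
      } else break
    }
    n_traces <- 1L + sum(iso_pts > 0L)
    if (n_traces < params$min_isotope_traces) next

    if (iso_int[1] > 0) {
      ratio <- iso_int[1] / ti[a]
      c_imp <- max(1, round(ratio / 0.011145))
      expected <- c_imp * .ISO_ABUND$C[2] / .ISO_ABUND$C[1]
      if (abs(ratio - expected) / expected > 0.5) next
    }
    for (k in 1:2) claimed[iso_ids[[k]]] <- TRUE

    nf <- nf + 1L
    if (nf > length(feats)) feats <- c(feats, vector("list", length(feats)))
    feats[[nf]] <- data.frame(
      mz = wmz, rt = trts[a], area = area,
      intensity_M = ti[a], intensity_M1 = iso_int[1],
      fwhm = fwhm_s, n_isotope_traces = n_traces
    )
  }
  if (nf == 0L) return(.empty_features())
  out <- do.call(rbind, feats[seq_len(nf)])
  out <- out[order(-out$area), , drop = FALSE]
  rownames(out) <- NULL
  cbind(feature_id = seq_len(nrow(out)), out)
}

.empty_features <- function() {
  data.frame(feature_id = integer(0), mz = numeric(0), rt = numeric(0),
             area = numeric(0), intensity_M = numeric(0),
             intensity_M1 = numeric(0), fwhm = numeric(0),
             n_isotope_traces = integer(0))
}

## FWHM by linear interpolation of the half-max crossings around apex `a`;
## rt in minutes, result in seconds. Falls back to the trace limits when a
## flank never drops below half maximum.
.fwhm_seconds <- function(rt_min, int, a) {
  half <- int[a] / 2
  left <- rt_min[1]
  if (a > 1L) {
    below <- which(int[seq_len(a - 1L)] <= half)
    if (length(below) > 0L) {
      i <- max(below)
      left <- rt_min[i] + (rt_min[i + 1L] - rt_min[i]) *
        (half - int[i]) / (int[i + 1L] - int[i])
    }
  }
  right <- rt_min[length(rt_min)]
  if (a < length(int)) {
    below <- which(int[(a + 1L):length(int)] <= half) + a
    if (length(below) > 0L) {
      i <- min(below)
      right <- rt_min[i - 1L] + (rt_min[i] - rt_min[i - 1L]) *
        (int[i - 1L] - half) / (int[i - 1L] - int[i])
    }
  }
  (right - left) * 60
}

.trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

#' Estimate the carbon number from the M+1/M isotopologue ratio
#'
#' `C ~ (I_M+1 / I_M) / 0.011145`: the relative abundance of the M+1
#' isotopologue grows almost linearly with the number of carbon atoms, so a
#' single intensity ratio gives a serviceable carbon estimate for every
#' feature without any formula assignment. Returns `NA` where the M+1
#' intensity is zero or missing; such features are excluded from
#' carbon-normalized filters downstream.
#'
#' @param intensity_M Apex intensity of the monoisotopic peak (vectorized).
#' @param intensity_M1 Apex intensity of the M+1 isotopologue.
#' @return Estimated carbon count (float).
#' @examples
#' estimate_carbon(1e5, 1e5 * 0.08916)  # 8 carbons
#' @export
estimate_carbon <- function(intensity_M, intensity_M1) {
  stopifnot(all(intensity_M > 0, na.rm = TRUE))
  out <- (intensity_M1 / intensity_M) / 0.011145
  out[is.na(intensity_M1) | intensity_M1 <= 0] <- NA_real_
  out
}

#' Add the carbon-number estimate column to a feature table
#'
#' @param features Feature data frame with `intensity_M`, `intensity_M1`.
#' @return Same table with a `carbon_est` column.
#' @export
add_carbon_estimate <- function(features) {
  features$carbon_est <- estimate_carbon(features$intensity_M,
                                         features$intensity_M1)
  features
}

#' Assign MS2 spectra to features
#'
#' Each data-dependent MS2 scan whose precursor m/z and RT fall within the
#' tolerances of a feature apex is a candidate; on conflict a scan goes to
#' the nearest-m/z feature. Each feature then keeps at most one spectrum, the
#' one with the highest precursor intensity (ties: nearest precursor m/z,
#' then earlier scan).
#'
#' @param features Feature data frame.
#' @param run The `ms_run` holding the MS2 scans.
#' @param mz_tol Precursor m/z tolerance, Da (default 5 mDa).
#' @param rt_tol RT tolerance, min (default 0.2).
#' @return `features` with an `ms2_scan` column (row index into
#'   `run$header`, `NA` if no spectrum assigned).
#' @export
align_ms2 <- function(features, run, mz_tol = 0.005, rt_tol = 0.2) {
  stopifnot(inherits(run, "ms_run"))
  features$ms2_scan <- NA_integer_
  ms2 <- which(run$header$ms_level == 2L)
  if (length(ms2) == 0L || nrow(features) == 0L) return(features)
  pmz <- run$header$precursor_mz[ms2]
  prt <- run$header$rt[ms2]
  pint <- run$header$precursor_intensity[ms2]
  pint[is.na(pint)] <- 0

  ## scan -> feature (nearest m/z among in-tolerance features)
  feat_of <- rep(NA_integer_, length(ms2))
  for (i in seq_along(ms2)) {
    dmz <- abs(features$mz - pmz[i])
    cand <- which(dmz <= mz_tol & abs(features$rt - prt[i]) <= rt_tol)
    if (length(cand) > 0L) feat_of[i] <- cand[which.min(dmz[cand])]
  }
  ## feature -> best scan
  for (f in unique(feat_of[!is.na(feat_of)])) {
    idx <- which(feat_of == f)
    o <- order(-pint[idx], abs(pmz[idx] - features$mz[f]), ms2[idx])
    features$ms2_scan[f] <- ms2[idx[o[1]]]
  }
  features
}

#' Blank correction of a feature table
#'
#' A sample feature is flagged as blank background when some blank feature
#' matches it within the m/z and RT tolerances and the sample abundance
#' (area) is less than `fold` times the blank abundance. Flagged features are
#' retained in the table (`blank_removed = TRUE`) for auditability;
#' downstream stages operate on the unflagged rows.
#'
#' @param sample Feature data frame for the sample.
#' @param blank Feature data frame for the blank (or `NULL`).
#' @param mz_tol m/z tolerance, Da (default 2 mDa).
#' @param rt_tol RT tolerance, min (default 0.1).
#' @param fold Required sample/blank abundance ratio to keep a matched
#'   feature (default 5).
#' @return `sample` with a logical `blank_removed` column.
#' @export
blank_correct <- function(sample, blank, mz_tol = 0.002, rt_tol = 0.1,
                          fold = 5) {
  sample$blank_removed <- FALSE
  if (is.null(blank) || nrow(blank) == 0L) {
    warning("blank feature list empty; skipping blank correction")
    return(sample)
  }
  for (i in seq_len(nrow(sample))) {
    hit <- abs(blank$mz - sample$mz[i]) <= mz_tol &
      abs(blank$rt - sample$rt[i]) <= rt_tol
    if (any(hit) && sample$area[i] < fold * max(blank$area[hit]))
      sample$blank_removed[i] <- TRUE
  }
  sample
}

#' Convert an external feature table to the internal feature format
#'
#' External tables carry apex intensities but no peak area or width; the
#' monoisotopic apex intensity is used as the abundance measure wherever
#' area would be (blank correction, sorting).
#'
#' @param df Data frame from [read_feature_csv()].
#' @return Feature data frame.
#' @export
features_from_table <- function(df) {
  out <- data.frame(
    feature_id = seq_len(nrow(df)),
    mz = df$mz, rt = df$rt,
    area = df$intensity_M,
    intensity_M = df$intensity_M,
    intensity_M1 = df$intensity_M1,
    fwhm = rep(NA_real_, nrow(df)),
    n_isotope_traces = ifelse(df$intensity_M1 > 0, 2L, 1L)
  )
  extras <- setdiff(names(df), c("mz", "rt", "intensity_M", "intensity_M1"))
  if (length(extras) > 0L) out <- cbind(out, df[, extras, drop = FALSE])
  out
}
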