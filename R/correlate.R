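#' Extract an ion chromatogram
#'
#' Per MS1 scan in the RT range, the intensity is the sum of centroids
#' within `mz +/- width` (the width is a half-window: an extraction width of
#' 5 mDa spans a 10 mDa window in total); scans with no centroid in the
#' window contribute zero. The time grid is the run's MS1 scan times
#' restricted to the requested range.
#'
#' @param run An `ms_run`.
#' @param mz Target m/z, Da.
#' @param width Half-window, Da (default 5 mDa).
#' @param rt_range Length-2 numeric RT range in minutes, or `NULL` for the
#'   whole run.
#' @return Data frame with `rt` (min) and `intensity`, plus attributes
#'   `target_mz` and `width`; class `eic`.
#' @export
extract_eic <- function(run, mz, width = 0.005, rt_range = NULL) {
  stopifnot(inherits(run, "ms_run"), width > 0)
  ms1 <- which(run$header$ms_level == 1L)
  rt <- run$header$rt[ms1]
  if (!is.null(rt_range)) {
    sel <- rt >= rt_range[1] & rt <= rt_range[2]
    if (!any(sel)) stop("no MS1 scans in the requested RT range")
    ms1 <- ms1[sel]; rt <- rt[sel]
  }
  intensity <- vapply(ms1, function(i) {
    m <- run$peaks[[i]]
    if (nrow(m) == 0L) return(0)
    sum(m[m[, 1] >= mz - width & m[, 1] <= mz + width, 2])
  }, numeric(1))
  structure(data.frame(rt = rt, intensity = intensity),
            target_mz = mz, width = width, class = c("eic", "data.frame"))
}

#' Extract a ladder of EICs spaced by a repeating unit
#'
#' Targets `base_mz + k * exact_mass(ru)` for `k = 0..n-1`; used to verify
#' the systematic retention-time shift of a suspected homologous series.
#'
#' @inheritParams extract_eic
#' @param base_mz m/z of the first homologue, Da.
#' @param ru A [repeating_unit()].
#' @param n Number of EICs (>= 1).
#' @return Named list of `eic` objects (names are the target m/z values).
#' @export
extract_series_eics <- function(run, base_mz, ru, n, width = 0.005,
                                rt_range = NULL) {
  stopifnot(inherits(ru, "repeating_unit"), n >= 1L)
  targets <- base_mz + (seq_len(n) - 1L) * ru$exact_mass
  out <- lapply(targets, extract_eic, run = run, width = width,
                rt_range = rt_range)
  names(out) <- sprintf("%.5f", targets)
  out
}

## Small built-in table of adduct/in-source-loss mass offsets used to label
## members of a correlation group; offsets relative to the seed ion.
.GROUP_DELTA_LABELS <- function() {
  d <- c(
    "-HF" = -monoisotopic_mass("HF"),
    "-2HF" = -2 * monoisotopic_mass("HF"),
    "-CO2" = -monoisotopic_mass("CO2"),
    "-H2O" = -monoisotopic_mass("H2O"),
    "-CF2" = -monoisotopic_mass("CF2"),
    "+CF2" = monoisotopic_mass("CF2"),
    "+HCl" = monoisotopic_mass("HCl"),       # [M+Cl]- vs [M-H]-
    "+HBr" = monoisotopic_mass("HBr"),
    "+CH2O2" = monoisotopic_mass("CH2O2"),   # formate vs deprotonated
    "+C2H4O2" = monoisotopic_mass("C2H4O2")  # acetate vs deprotonated
  )
  data.frame(label = names(d), delta = unname(d))
}

#' Group coeluting ions by EIC correlation
#'
#' Correlates the seed feature's EIC with the EIC of every feature whose
#' apex elutes within the RT window of the seed, over the shared MS1 scan
#' grid spanning `seed RT +/- rt_window`. Members with squared Pearson
#' correlation at or above the threshold form the group; this collects
#' in-source fragments and adducts, which share the parent's elution profile
#' exactly. Candidate EICs with fewer than 5 nonzero grid points are treated
#' as undefined and excluded. Mass differences to the seed matching a small
#' built-in adduct/loss table (HF, Cl-H, acetate, ...) are labelled.
#'
#' @param run An `ms_run`.
#' @param features Feature data frame.
#' @param seed_mz m/z of the seed feature; a feature must exist within
#'   2 mDa, otherwise an error names the nearest one.
#' @param rt_window Half-window around the seed apex, seconds (default 25).
#' @param r2_threshold Minimum squared Pearson correlation (default 0.95).
#' @param width EIC extraction half-window, Da (default 5 mDa).
#' @return List (`correlation_group`): `seed_mz`, `seed_rt`, `members`
#'   (data frame `feature_id`, `mz`, `rt`, `r_squared`, `delta_to_seed`,
#'   `label`), `rt_window`, `r2_threshold`.
#' @export
correlate_coeluting <- function(run, features, seed_mz, rt_window = 25,
                                r2_threshold = 0.95, width = 0.005) {
  d <- abs(features$mz - seed_mz)
  if (min(d) > 0.002)
    stop(sprintf("no feature within 2 mDa of %.5f; nearest is %.5f",
                 seed_mz, features$mz[which.min(d)]))
  seed <- which.min(d)
  seed_rt <- features$rt[seed]
  win_min <- rt_window / 60
  rng <- c(seed_rt - win_min, seed_rt + win_min)
  cand <- which(abs(features$rt - seed_rt) <= win_min)

  seed_eic <- extract_eic(run, features$mz[seed], width, rng)$intensity
  labels <- .GROUP_DELTA_LABELS()
  rows <- list()
  for (i in cand) {
    y <- extract_eic(run, features$mz[i], width, rng)$intensity
    if (i == seed) {
      r2 <- 1
    } else {
      if (sum(y > 0) < 5L || sum(seed_eic > 0) < 5L) next
      if (stats::sd(y) == 0 || stats::sd(seed_eic) == 0) next
      r2 <- stats::cor(seed_eic, y)^2
    }
    if (r2 < r2_threshold) next
    delta <- features$mz[i] - features$mz[seed]
    dl <- abs(labels$delta - delta)
    lab <- if (i != seed && min(dl) <= 0.002) labels$label[which.min(dl)] else ""
    rows[[length(rows) + 1L]] <- data.frame(
      feature_id = features$feature_id[i], mz = features$mz[i],
      rt = features$rt[i], r_squared = r2, delta_to_seed = delta,
      label = lab, stringsAsFactors = FALSE)
  }
  members <- do.call(rbind, rows)
  members <- members[order(members$mz), , drop = FALSE]
  rownames(members) <- NULL
  structure(list(seed_mz = features$mz[seed], seed_rt = seed_rt,
                 members = members, rt_window = rt_window,
                 r2_threshold = r2_threshold),
            class = "correlation_group")
}

#' @export
print.correlation_group <- function(x, ...) {
  cat(sprintf("Correlation group around m/z %.5f (RT %.2f min, r2 >= %.2f):\n",
              x$seed_mz, x$seed_rt, x$r2_threshold))
  print(x$members, digits = 6)
  invisible(x)
}
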