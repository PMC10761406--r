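#' Configuration for the synthetic run generator
#'
#' Describes a ground-truthed centroided HRMS acquisition in negative mode:
#' chromatographic Gaussian elution profiles on a uniform MS1 scan grid,
#' M/M+1 isotopologue traces at the natural 13C envelope ratio of each
#' planted ion formula, CF2-spaced perfluoroalkyl homologue ladders with a
#' systematic per-homologue RT increment, hydrocarbon-type matrix features,
#' shared blank contaminants, a coeluting in-source fragment/adduct family,
#' and data-dependent MS2 spectra carrying diagnostic fragments and CF2/HF
#' fragment ladders. Every planted species carries an exact formula, so all
#' ground-truth quantities (m/z, isotope ratio, m/C, MD/C) are recomputable
#' from the chemistry layer.
#'
#' Presets: `"full"` (everything), `"matrix"` (20 isolated matrix peaks,
#' no blank), `"series"` (homologue ladders only), `"family"` (in-source
#' family plus 30 decoys).
#'
#' @param seed Integer RNG seed; a fixed seed gives identical output.
#' @param preset Scenario preset (see above).
#' @param ... Overrides for individual fields (e.g. `mz_jitter_ppm = 0`,
#'   `intensity_noise_sd = 0`, `n_matrix_features = 100`).
#' @return List of generator settings, class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         preset = c("full", "matrix", "series", "family"),
                         ...) {
  preset <- match.arg(preset)
  cfg <- list(
    seed = as.integer(seed),
    preset = preset,
    rt_start = 0.5, rt_end = 8.5,          # min
    scan_interval = 0.5,                   # s
    mz_jitter_ppm = 2,                     # SD of centroid m/z jitter
    intensity_noise_sd = 0.05,             # multiplicative intensity noise
    intensity_floor = 20,                  # counts below which no centroid
    n_matrix_features = 50L,
    matrix_rt_range = c(1.0, 8.0),
    blank_overlap_fraction = 0.5,
    series = list(
      list(class = "PFCA", n_range = 4:10, rt_start = 2.0, rt_step = 0.55,
           apex = 2e5, apex_decay = 0.9, sigma_s = 2.5),
      list(class = "PFSA", n_range = 4:8, rt_start = 2.3, rt_step = 0.5,
           apex = 1.5e5, apex_decay = 0.9, sigma_s = 2.5)
    ),
    family = list(parent = "C8H5F13O3S", rt = 6.8, apex = 3e5, sigma_s = 2.5,
                  deltas = c("-HF", "+Cl", "+Ac"),
                  scales = c(0.4, 0.25, 0.15)),
    table_n_matrix = 100L,
    table_n_pfas = 10L
  )
  if (preset == "matrix") {
    cfg$n_matrix_features <- 20L; cfg$series <- list(); cfg$family <- NULL
    cfg$blank_overlap_fraction <- 0
  } else if (preset == "series") {
    cfg$n_matrix_features <- 0L; cfg$family <- NULL
    cfg$blank_overlap_fraction <- 0
  } else if (preset == "family") {
    cfg$n_matrix_features <- 30L; cfg$series <- list()
    cfg$blank_overlap_fraction <- 0
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop(sprintf("unknown synth_config field(s): %s",
                                paste(bad, collapse = ", ")))
  cfg[names(dots)] <- dots
  for (s in cfg$series) {
    last_rt <- s$rt_start + (length(s$n_range) - 1L) * s$rt_step
    if (last_rt > cfg$rt_end - 0.2)
      stop(sprintf("series '%s' runs past the RT range (last homologue at %.2f min)",
                   s$class, last_rt))
  }
  structure(cfg, class = "synth_config")
}

## Neutral formula of a perfluoroalkyl homologue with n carbons.
.series_formula <- function(class, n) {
  switch(class,
         PFCA = sprintf("C%dHF%dO2", n, 2L * n - 1L),
         PFSA = sprintf("C%dHF%dO3S", n, 2L * n + 1L),
         stop(sprintf("unknown series class '%s'", class)))
}

## Ion description (element counts + exact m/z) for the supported
## negative-mode species; `delta` names in-source/adduct variants of [M-H]-.
.ion_for <- function(neutral, delta = NULL) {
  f <- parse_formula(neutral)
  m <- monoisotopic_mass(f)
  if (is.null(delta)) {
    ion <- formula_subtract(f, parse_formula("H"))
    return(list(formula = ion, mz = m - .PROTON_MASS))
  }
  switch(delta,
    "-HF" = {
      ion <- formula_subtract(formula_subtract(f, parse_formula("HF")),
                              parse_formula("H"))
      list(formula = ion, mz = m - monoisotopic_mass("HF") - .PROTON_MASS)
    },
    "+Cl" = {
      ion <- formula_add(f, parse_formula("Cl"))
      list(formula = ion,
           mz = m + monoisotopic_mass("Cl") + .ELECTRON_MASS)
    },
    "+Ac" = {
      ion <- formula_add(f, parse_formula("C2H3O2"))
      list(formula = ion,
           mz = m + monoisotopic_mass("C2H3O2") + .ELECTRON_MASS)
    },
    stop(sprintf("unknown family delta '%s'", delta)))
}

## Random hydrocarbon-type matrix neutral formula with ion m/C in [12, 26].
.random_matrix_formula <- function() {
  repeat {
    c_n <- sample(8:35, 1L)
    h_n <- sample(seq.int(c_n, 2L * c_n + 2L), 1L)
    target_mc <- stats::runif(1, 12.5, 25)
    o_n <- max(0L, round((target_mc * c_n - 12 * c_n - 1.008 * h_n) / 16))
    o_n <- min(o_n, 25L)
    f <- paste0("C", c_n, "H", h_n, if (o_n > 0L) paste0("O", o_n) else "")
    mz <- monoisotopic_mass(f) - .PROTON_MASS
    if (mz >= 110 && mz <= 1650 && mz / c_n <= 26) return(list(formula = f, carbon = c_n, mz = mz))
  }
}

## Assemble the ground-truth species table for a run configuration.
.build_truth <- function(cfg) {
  rows <- list()
  add <- function(kind, name, neutral, adduct, delta, rt, apex, sigma,
                  carbon, series_id, family_id, in_blank, has_ms2) {
    ion <- .ion_for(neutral, delta)
    pat <- isotope_pattern(ion$formula, 3L)
    r1 <- if (nrow(pat) >= 2) pat$abundance[2] / pat$abundance[1] else 0
    r2 <- if (nrow(pat) >= 3) pat$abundance[3] / pat$abundance[1] else 0
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, name = name, formula_neutral = neutral,
      formula_ion = format_formula(ion$formula), adduct = adduct,
      mz = ion$mz, rt = rt, apex_intensity = apex, sigma_s = sigma,
      carbon = carbon, iso_ratio_m1 = r1, iso_ratio_m2 = r2,
      series_id = series_id, family_id = family_id,
      in_blank = in_blank, has_ms2 = has_ms2, stringsAsFactors = FALSE)
  }

  sid <- 0L
  for (s in cfg$series) {
    sid <- sid + 1L
    for (i in seq_along(s$n_range)) {
      n <- s$n_range[i]
      add("pfas", sprintf("%s_C%d", s$class, n), .series_formula(s$class, n),
          "[M-H]-", NULL, s$rt_start + (i - 1L) * s$rt_step,
          s$apex * s$apex_decay^(i - 1L), s$sigma_s, n, sid, NA_integer_,
          FALSE, TRUE)
    }
  }
  if (!is.null(cfg$family)) {
    fam <- cfg$family
    add("family", "family_parent", fam$parent, "[M-H]-", NULL, fam$rt,
        fam$apex, fam$sigma_s, parse_formula(fam$parent)[["C"]],
        NA_integer_, 1L, FALSE, TRUE)
    for (i in seq_along(fam$deltas)) {
      add("family", paste0("family", fam$deltas[i]), fam$parent,
          paste0("[M", fam$deltas[i], "]-"), fam$deltas[i], fam$rt,
          fam$apex * fam$scales[i], fam$sigma_s,
          parse_formula(fam$parent)[["C"]], NA_integer_, 1L, FALSE, FALSE)
    }
  }
  truth <- if (length(rows)) do.call(rbind, rows) else NULL

  ## matrix features: keep every species pair resolvable (30 mDa or
  ## 0.3 min apart) and keep clear of the in-source family window
  n_blank <- round(cfg$n_matrix_features * cfg$blank_overlap_fraction)
  if (cfg$n_matrix_features > 0L) {
    placed_mz <- if (is.null(truth)) numeric(0) else truth$mz
    placed_rt <- if (is.null(truth)) numeric(0) else truth$rt
    fam_rt <- if (!is.null(cfg$family)) cfg$family$rt else NA_real_
    for (i in seq_len(cfg$n_matrix_features)) {
      repeat {
        mf <- .random_matrix_formula()
        rt <- stats::runif(1, cfg$matrix_rt_range[1], cfg$matrix_rt_range[2])
        if (!is.na(fam_rt) && abs(rt - fam_rt) < 45 / 60) next
        clash <- abs(placed_mz - mf$mz) < 0.03 & abs(placed_rt - rt) < 0.3
        if (!any(clash)) break
      }
      placed_mz <- c(placed_mz, mf$mz); placed_rt <- c(placed_rt, rt)
      in_blank <- i <= n_blank
      add(if (in_blank) "contaminant" else "matrix",
          sprintf("%s_%02d", if (in_blank) "contam" else "matrix", i),
          mf$formula, "[M-H]-", NULL, rt,
          10^stats::runif(1, 3.8, 5.3), stats::runif(1, 1.8, 3.5),
          mf$carbon, NA_integer_, NA_integer_, in_blank, FALSE)
    }
    truth <- do.call(rbind, rows)
  }
  if (is.null(truth)) stop("configuration plants no species")
  truth$species_id <- seq_len(nrow(truth))
  truth[, c("species_id", setdiff(names(truth), "species_id"))]
}

## Render MS1 scans for a species table; `scale` multiplies apex intensities
## (used for the blank run).
.render_ms1 <- function(truth, cfg, scale = NULL) {
  times <- seq(cfg$rt_start, cfg$rt_end, by = cfg$scan_interval / 60)
  jitter_sd <- cfg$mz_jitter_ppm * 1e-6
  noise_sd <- cfg$intensity_noise_sd
  scan_mz <- vector("list", length(times))
  scan_int <- vector("list", length(times))
  for (j in seq_len(nrow(truth))) {
    sp <- truth[j, ]
    apex <- sp$apex_intensity * (if (is.null(scale)) 1 else scale[j])
    sig_min <- sp$sigma_s / 60
    sel <- which(abs(times - sp$rt) <= 4 * sig_min)
    if (length(sel) == 0L) next
    prof <- apex * exp(-(times[sel] - sp$rt)^2 / (2 * sig_min^2))
    for (k in 1:3) {
      ratio <- c(1, sp$iso_ratio_m1, sp$iso_ratio_m2)[k]
      if (ratio <= 0) next
      ints <- prof * ratio
      if (noise_sd > 0) ints <- ints * pmax(0.1, 1 + stats::rnorm(length(ints), 0, noise_sd))
      keep <- ints >= cfg$intensity_floor
      if (!any(keep)) next
      mzs <- rep(sp$mz + (k - 1L) * .C13_DELTA, sum(keep))
      if (jitter_sd > 0) mzs <- mzs * (1 + stats::rnorm(length(mzs), 0, jitter_sd))
      for (idx in seq_along(which(keep))) {
        s <- sel[which(keep)[idx]]
        scan_mz[[s]] <- c(scan_mz[[s]], mzs[idx])
        scan_int[[s]] <- c(scan_int[[s]], ints[which(keep)[idx]])
      }
    }
  }
  list(times = times, mz = scan_mz, int = scan_int)
}

## Planted MS2 fragment peaks for a perfluoroalkyl precursor: diagnostic
## CnF2n+1- ions (CF2/C2F4-spaced ladder) plus one peak an HF above the
## C2F5- fragment, all well above typical MS2 noise.
.ms2_fragments <- function(carbon) {
  kmax <- max(3L, min(carbon - 1L, 6L))
  frag_mz <- vapply(2:kmax, function(k)
    monoisotopic_mass(sprintf("C%dF%d", k, 2L * k + 1L)) + .ELECTRON_MASS,
    numeric(1))
  hf_peak <- frag_mz[1] + monoisotopic_mass("HF")
  mz <- c(frag_mz, hf_peak)
  int <- c(5e4 * 0.8^(seq_along(frag_mz) - 1L), 1.5e4)
  o <- order(mz)
  cbind(mz = mz[o], intensity = int[o])
}

#' Generate a synthetic centroided run with ground truth
#'
#' Builds the sample run (and, when the configuration plants shared
#' contaminants, a blank run) described by a [synth_config()]. With the seed
#' fixed the output is fully reproducible. When `dir` is given, the runs are
#' written as mzML (`sample.mzML`, `blank.mzML`) together with
#' `ground_truth.csv`.
#'
#' @param cfg A [synth_config()].
#' @param dir Optional output directory.
#' @return List: `run` (`ms_run`), `blank` (`ms_run` or `NULL`), `truth`
#'   (ground-truth data frame), `paths` (when written).
#' @export
generate_run <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  truth <- .build_truth(cfg)

  ms1 <- .render_ms1(truth, cfg)
  n1 <- length(ms1$times)

  ## assemble MS1 + interleaved ddMS2 scans, ordered by RT
  rt <- ms1$times
  level <- rep(1L, n1)
  peaks <- vector("list", n1)
  pre_mz <- rep(NA_real_, n1); pre_int <- rep(NA_real_, n1)
  for (i in seq_len(n1)) {
    mzv <- ms1$mz[[i]] %||% numeric(0)
    iv <- ms1$int[[i]] %||% numeric(0)
    o <- order(mzv)
    peaks[[i]] <- cbind(mz = mzv[o], intensity = iv[o])
  }
  ms2_rows <- which(truth$has_ms2)
  for (j in ms2_rows) {
    sp <- truth[j, ]
    frag <- .ms2_fragments(sp$carbon)
    apex_scan <- which.min(abs(ms1$times - sp$rt))
    rt <- c(rt, ms1$times[apex_scan] + cfg$scan_interval / 120)
    level <- c(level, 2L)
    peaks <- c(peaks, list(frag))
    pre_mz <- c(pre_mz, sp$mz)
    pre_int <- c(pre_int, sp$apex_intensity)
  }
  o <- order(rt, level)
  run <- structure(list(
    header = data.frame(ms_level = level[o], rt = rt[o],
                        precursor_mz = pre_mz[o],
                        precursor_intensity = pre_int[o],
                        tic = vapply(peaks[o], function(m) sum(m[, 2]), numeric(1))),
    peaks = peaks[o], polarity = "-", path = "<synthetic>"),
    class = "ms_run")

  blank <- NULL
  if (any(truth$in_blank)) {
    bt <- truth[truth$in_blank, , drop = FALSE]
    scale <- stats::runif(nrow(bt), 0.7, 1.1)
    bm <- .render_ms1(bt, cfg, scale = scale)
    bpeaks <- vector("list", length(bm$times))
    for (i in seq_along(bm$times)) {
      mzv <- bm$mz[[i]] %||% numeric(0)
      iv <- bm$int[[i]] %||% numeric(0)
      oo <- order(mzv)
      bpeaks[[i]] <- cbind(mz = mzv[oo], intensity = iv[oo])
    }
    blank <- structure(list(
      header = data.frame(ms_level = rep(1L, length(bm$times)), rt = bm$times,
                          precursor_mz = NA_real_, precursor_intensity = NA_real_,
                          tic = vapply(bpeaks, function(m) sum(m[, 2]), numeric(1))),
      peaks = bpeaks, polarity = "-", path = "<synthetic blank>"),
      class = "ms_run")
  }

  out <- list(run = run, blank = blank, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(sample = file.path(dir, "sample.mzML"),
                  truth = file.path(dir, "ground_truth.csv"))
    write_mzml(run, paths$sample)
    if (!is.null(blank)) {
      paths$blank <- file.path(dir, "blank.mzML")
      write_mzml(blank, paths$blank)
    }
    utils::write.csv(truth, paths$truth, row.names = FALSE)
    out$paths <- paths
  }
  out
}

#' Generate a synthetic external feature table with ground truth
#'
#' Tabular analogue of [generate_run()]: no raw spectra, just feature rows
#' with `mz`, `rt`, `intensity_M` and `intensity_M1`, where the M+1
#' intensity encodes the carbon count through
#' `intensity_M1 = intensity_M * 0.011145 * C * (1 + noise)`. Plants
#' `table_n_matrix` hydrocarbon-type rows and `table_n_pfas` perfluoroalkyl
#' rows (random PFCA/PFSA chains, F/C >= 1.5).
#'
#' @param cfg A [synth_config()]; uses `table_n_matrix`, `table_n_pfas`,
#'   `intensity_noise_sd` and `seed`.
#' @param path Optional CSV output path.
#' @return List: `table` (feature rows), `truth` (with `is_pfas`, `formula`,
#'   `carbon`).
#' @export
generate_feature_csv <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 1L)
  rows <- list()
  for (i in seq_len(cfg$table_n_matrix)) {
    mf <- .random_matrix_formula()
    rows[[length(rows) + 1L]] <- data.frame(
      formula = mf$formula, carbon = mf$carbon, mz = mf$mz, is_pfas = FALSE)
  }
  classes <- c("PFCA", "PFSA")
  for (i in seq_len(cfg$table_n_pfas)) {
    cl <- classes[1L + (i %% 2L)]
    n <- sample(4:14, 1L)
    f <- .series_formula(cl, n)
    rows[[length(rows) + 1L]] <- data.frame(
      formula = f, carbon = n, mz = monoisotopic_mass(f) - .PROTON_MASS,
      is_pfas = TRUE)
  }
  truth <- do.call(rbind, rows)
  truth$rt <- stats::runif(nrow(truth), 1, 8)
  truth$intensity_M <- 10^stats::runif(nrow(truth), 3.5, 6)
  noise <- if (cfg$intensity_noise_sd > 0)
    stats::rnorm(nrow(truth), 0, cfg$intensity_noise_sd) else 0
  table <- data.frame(
    mz = truth$mz, rt = truth$rt, intensity_M = truth$intensity_M,
    intensity_M1 = truth$intensity_M * 0.011145 * truth$carbon * (1 + noise))
  if (!is.null(path)) utils::write.csv(table, path, row.names = FALSE)
  list(table = table, truth = truth)
}
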