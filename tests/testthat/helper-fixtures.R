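## Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

## Noise-free "full" scenario: matrix + contaminants + 2 PFAS ladders +
## in-source family, with a blank run and ground truth.
full_fixture <- function() {
  if (is.null(.fixture_env$full)) {
    cfg <- synth_config(seed = 1, preset = "full",
                        mz_jitter_ppm = 0, intensity_noise_sd = 0)
    .fixture_env$full <- c(generate_run(cfg), list(cfg = cfg))
  }
  .fixture_env$full
}

## Noise-free matrix-only scenario: 20 isolated peaks.
matrix_fixture <- function() {
  if (is.null(.fixture_env$matrix)) {
    cfg <- synth_config(seed = 7, preset = "matrix",
                        mz_jitter_ppm = 0, intensity_noise_sd = 0)
    .fixture_env$matrix <- c(generate_run(cfg), list(cfg = cfg))
  }
  .fixture_env$matrix
}

## Suspect list derived from the planted PFAS of the full fixture.
fixture_suspects <- function(truth) {
  pf <- truth[truth$kind == "pfas", , drop = FALSE]
  data.frame(name = pf$name, smiles = NA_character_,
             formula = pf$formula_neutral,
             exact_mass = vapply(pf$formula_neutral, monoisotopic_mass,
                                 numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

## Map planted species to detected features: index of the (unique) feature
## within 5 ppm and 0.05 min of each truth row, NA when unmatched.
match_truth <- function(features, truth, ppm = 5, rt_tol = 0.05) {
  vapply(seq_len(nrow(truth)), function(i) {
    hit <- which(abs(features$mz - truth$mz[i]) / truth$mz[i] * 1e6 <= ppm &
                   abs(features$rt - truth$rt[i]) <= rt_tol)
    if (length(hit) == 1L) hit else if (length(hit) == 0L) NA_integer_ else -1L
  }, integer(1))
}

## Minimal in-memory ms_run builder for hand-constructed scan layouts.
make_run <- function(rt, level, peaks, precursor_mz = NULL,
                     precursor_intensity = NULL, polarity = "-") {
  n <- length(rt)
  structure(list(
    header = data.frame(
      ms_level = as.integer(level), rt = rt,
      precursor_mz = precursor_mz %||% rep(NA_real_, n),
      precursor_intensity = precursor_intensity %||% rep(NA_real_, n),
      tic = vapply(peaks, function(m) sum(m[, 2]), numeric(1))),
    peaks = lapply(peaks, function(m) {
      m <- m[order(m[, 1]), , drop = FALSE]
      colnames(m) <- c("mz", "intensity")
      m
    }),
    polarity = polarity, path = "<test>"), class = "ms_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Gaussian MS1 peak train for one species across a scan grid (no isotopes
## unless ratio_m1 > 0); returns the per-scan peak matrices.
gaussian_scans <- function(times, mz, rt, apex, sigma_min, ratio_m1 = 0) {
  lapply(times, function(t) {
    i <- apex * exp(-(t - rt)^2 / (2 * sigma_min^2))
    if (i < 1) return(cbind(mz = numeric(0), intensity = numeric(0)))
    if (ratio_m1 > 0)
      cbind(mz = c(mz, mz + 1.0033548), intensity = c(i, i * ratio_m1))
    else cbind(mz = mz, intensity = i)
  })
}
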