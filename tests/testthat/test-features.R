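test_that("feature finder recovers isolated planted peaks exactly once", {
  fx <- matrix_fixture()
  feats <- detect_features(fx$run)
  expect_equal(nrow(feats), nrow(fx$truth))
  m <- match_truth(feats, fx$truth)
  expect_true(all(!is.na(m)))      # every planted peak found
  expect_true(all(m != -1L))       # ... by exactly one feature
  expect_equal(sort(m), seq_len(nrow(feats)))  # and no extras
  ## areas sorted decreasing
  expect_true(all(diff(feats$area) <= 0))
})

test_that("peaks without an M+1 trace or with sub-second width are rejected", {
  times <- seq(1, 2, by = 1 / 120)  # 0.5 s scans
  ## species A: proper peak with isotope trace; B: no M+1; C: 2-scan spike
  pk_a <- gaussian_scans(times, 300.1, 1.5, 1e5, 2.5 / 60, ratio_m1 = 0.1)
  pk_b <- gaussian_scans(times, 400.1, 1.5, 1e5, 2.5 / 60, ratio_m1 = 0)
  spike <- which.min(abs(times - 1.8))
  peaks <- lapply(seq_along(times), function(i) {
    m <- rbind(pk_a[[i]], pk_b[[i]])
    if (i %in% c(spike, spike + 1L))
      m <- rbind(m, cbind(mz = 500.1, intensity = 5e4))
    m
  })
  run <- make_run(times, rep(1L, length(times)), peaks)
  feats <- detect_features(run)
  expect_equal(nrow(feats), 1L)
  expect_equal(feats$mz, 300.1, tolerance = 1e-3)
  expect_equal(feats$n_isotope_traces, 2L)
})

test_that("carbon estimation inverts the 0.011145 factor and handles zeros", {
  expect_equal(estimate_carbon(1, 0.08916), 8, tolerance = 1e-3)
  expect_equal(estimate_carbon(1, 0.011145), 1, tolerance = 1e-12)
  expect_true(is.na(estimate_carbon(1e5, 0)))
  ## vectorized and exact on noise-free constructed ratios
  C <- 1:60
  est <- estimate_carbon(rep(1, 60), 0.011145 * C)
  expect_equal(est, as.numeric(C), tolerance = 1e-9)
})

test_that("carbon estimate stays tight under counting noise at SNR 100", {
  ## shot-noise model: apex 1e4 counts so SNR = I/sqrt(I) = 100
  set.seed(19)
  C <- 12
  I_M <- 1e4
  n <- 2000
  iM <- I_M + rnorm(n, 0, sqrt(I_M))
  iM1 <- I_M * 0.011145 * C + rnorm(n, 0, sqrt(I_M * 0.011145 * C))
  est <- estimate_carbon(iM, iM1)
  expect_lt(sd(est) / mean(est), 0.10)
  expect_gte(mean(abs(est - C) <= 1), 0.95)
})

test_that("MS2 spectra go to the most intense precursor, one per feature", {
  times <- seq(1, 2, by = 1 / 120)
  peaks <- gaussian_scans(times, 300.1, 1.5, 1e5, 2.5 / 60, ratio_m1 = 0.1)
  run <- make_run(
    c(times, 1.5, 1.52, 1.54),
    c(rep(1L, length(times)), 2L, 2L, 2L),
    c(peaks, list(cbind(mz = 119, intensity = 1e4),
                  cbind(mz = 119, intensity = 1e4),
                  cbind(mz = 119, intensity = 1e4))),
    precursor_mz = c(rep(NA, length(times)), 300.1, 300.1001, 300.107),
    precursor_intensity = c(rep(NA, length(times)), 1e4, 1e5, 1e6))
  run$header <- run$header[order(run$header$rt), ]
  feats <- detect_features(run)
  feats <- align_ms2(feats, run)
  assigned <- run$header[feats$ms2_scan, ]
  ## the 6 mDa-off scan (highest intensity) must NOT win; the 1e5 one does
  expect_equal(assigned$precursor_intensity, 1e5)
})

test_that("blank correction applies the fivefold rule and is order-stable", {
  sample <- data.frame(feature_id = 1:3,
                       mz = c(200.05, 300.05, 400.05),
                       rt = c(2, 3, 4),
                       area = c(1e6, 2e5, 5e4))
  blank <- data.frame(feature_id = 1:2,
                      mz = c(200.0505, 300.0495),
                      rt = c(2.05, 3.05),
                      area = c(1e5, 1e5))
  out <- blank_correct(sample, blank)
  expect_equal(out$blank_removed, c(FALSE, TRUE, FALSE))  # 10x kept, 2x removed

  ## order-independence w.r.t. blank rows and idempotence
  out2 <- blank_correct(sample, blank[2:1, ])
  expect_equal(out2$blank_removed, out$blank_removed)
  out3 <- blank_correct(out, blank)
  expect_equal(out3$blank_removed, out$blank_removed)

  expect_warning(blank_correct(sample, NULL), "empty")
})

test_that("planted contaminants are removed exactly, sample-only kept", {
  fx <- full_fixture()
  sample_feats <- detect_features(fx$run)
  blank_feats <- detect_features(fx$blank)
  out <- blank_correct(sample_feats, blank_feats)
  m <- match_truth(out, fx$truth)
  expect_true(all(!is.na(m)))
  removed_names <- fx$truth$name[out$blank_removed[m]]
  expect_setequal(removed_names, fx$truth$name[fx$truth$kind == "contaminant"])
})

test_that("feature recovery stays above 95% under realistic noise", {
  cfg <- synth_config(seed = 5, preset = "full")  # 2 ppm jitter, 5% noise
  g <- generate_run(cfg)
  feats <- detect_features(g$run)
  m <- match_truth(feats, g$truth, ppm = 10, rt_tol = 0.05)
  expect_gte(mean(!is.na(m) & m != -1L), 0.95)
  expect_true(all(m != -1L, na.rm = TRUE))  # no duplicate reports
})
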