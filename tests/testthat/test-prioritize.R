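## Feature row for a known neutral formula measured as [M-H]- with an exact
## (noise-free) isotope-ratio-encoded carbon count.
.row_for <- function(formula, id = 1L) {
  f <- parse_formula(formula)
  mz <- adduct_mz(monoisotopic_mass(f), "[M-H]-")
  data.frame(feature_id = id, mz = mz, rt = 1, area = 1e5,
             intensity_M = 1e5, intensity_M1 = 1e5 * 0.011145 * f[["C"]])
}

test_that("MD/C and m/C reproduce the printed reference compounds", {
  ## neutral-mass stand-ins with exact carbon counts
  cases <- list(c("C16H9F26O4P", 49), c("C8HF15O2", 51),
                c("C15H19F13N2O4S", 38), c("C17H18F3NO", 18))
  for (cs in cases) {
    f <- parse_formula(cs[[1]])
    feat <- data.frame(feature_id = 1L, mz = monoisotopic_mass(f),
                       intensity_M = 1, intensity_M1 = 0.011145 * f[["C"]])
    feat <- compute_mdc_mc(add_carbon_estimate(feat))
    expect_equal(floor(feat$m_over_c), as.numeric(cs[[2]]))
  }
  ## a pure (CH2)n composition sits at m/C = 14
  f <- data.frame(feature_id = 1L, mz = 20 * monoisotopic_mass("CH2"),
                  intensity_M = 1, intensity_M1 = 0.011145 * 20)
  f <- compute_mdc_mc(add_carbon_estimate(f))
  expect_equal(round(f$m_over_c), 14)
  ## missing carbon estimate -> NA coordinates
  g <- data.frame(feature_id = 1L, mz = 413.9737, intensity_M = 1,
                  intensity_M1 = 0)
  g <- compute_mdc_mc(add_carbon_estimate(g))
  expect_true(is.na(g$m_over_c) && is.na(g$mdc))
})

test_that("the m/C > 30, MD/C < +0.003 filter separates planted classes", {
  cfg <- synth_config(seed = 2, preset = "full", intensity_noise_sd = 0,
                      table_n_matrix = 90L, table_n_pfas = 10L)
  g <- generate_feature_csv(cfg)
  feats <- compute_mdc_mc(add_carbon_estimate(features_from_table(g$table)))
  feats <- filter_mdc_mc(feats)
  expect_equal(sum(feats$mdc_mc_pass), 10L)
  expect_equal(feats$mdc_mc_pass, g$truth$is_pfas)

  ## borderline: high m/C but positive MD/C fails
  one <- data.frame(feature_id = 1L, mz = 400, rt = 1, carbon_est = 10,
                    md = 0.04, mdc = 0.004, m_over_c = 40)
  expect_false(filter_mdc_mc(one)$mdc_mc_pass)
  ## empty in, empty out
  empty <- compute_mdc_mc(add_carbon_estimate(features_from_table(
    data.frame(mz = numeric(0), rt = numeric(0), intensity_M = numeric(0),
               intensity_M1 = numeric(0)))))
  expect_equal(nrow(filter_mdc_mc(empty)), 0L)
})

test_that("exact CF2 ladders form one series; outliers are excluded", {
  ru <- repeating_unit("CF2")
  ladder <- do.call(rbind, lapply(4:10, function(n)
    .row_for(sprintf("C%dHF%dO2", n, 2 * n - 1), id = n)))
  hs <- detect_homologous_series(ladder, ru)
  expect_length(hs, 1L)
  expect_equal(length(hs[[1]]$member_mz), 7L)
  expect_setequal(hs[[1]]$member_feature_ids, 4:10)

  ## +5 mDa perturbation expels that member
  pert <- ladder
  pert$mz[3] <- pert$mz[3] + 0.005
  hs2 <- detect_homologous_series(pert, ru)
  expect_length(hs2, 1L)
  expect_equal(length(hs2[[1]]$member_mz), 6L)
  expect_false(6 %in% hs2[[1]]$member_feature_ids)

  ## two members never qualify at min_members = 3
  expect_length(detect_homologous_series(ladder[1:2, ], ru), 0L)

  ## post-hoc invariant: all pairs inside a series are integer multiples
  for (h in hs) {
    d <- outer(h$member_mz, h$member_mz, "-")
    d <- d[d > 0]
    expect_true(all(abs(d - round(d / ru$exact_mass) * ru$exact_mass) <= 0.002))
  }
})

test_that("planted homologous series are recovered exactly from raw data", {
  fx <- full_fixture()
  feats <- compute_mdc_mc(add_carbon_estimate(detect_features(fx$run)))
  feats$blank_removed <- FALSE
  feats <- filter_mdc_mc(feats)
  sub <- feats[feats$mdc_mc_pass, ]
  hs <- detect_homologous_series(sub, repeating_unit("CF2"))
  expect_length(hs, 2L)
  m <- match_truth(feats, fx$truth)
  for (sid in 1:2) {
    planted <- fx$truth$mz[!is.na(fx$truth$series_id) &
                             fx$truth$series_id == sid]
    rec <- hs[[sid]]$member_mz
    expect_equal(length(rec), length(planted))
    expect_lt(max(abs(sort(rec) - sort(planted))), 1e-3)
  }
})

test_that("diagnostic fragment matching respects tolerance, noise and polarity", {
  dfs <- pfas_diagnostic_fragments("-")
  c2f5 <- monoisotopic_mass("C2F5") + 0.00054858
  c3f7 <- monoisotopic_mass("C3F7") + 0.00054858
  sp <- list(mz = c(c2f5, c3f7), intensity = c(1e4, 1e4), polarity = "-")
  res <- match_diagnostic_fragments(sp, dfs)
  expect_equal(nrow(res$hits), 2L)
  expect_setequal(res$hits$label, c("C2F5-", "C3F7-"))
  expect_true(res$flagged)

  ## below the noise threshold: nothing
  sp_low <- list(mz = sp$mz, intensity = c(500, 500), polarity = "-")
  expect_equal(nrow(match_diagnostic_fragments(sp_low, dfs)$hits), 0L)

  ## 3 mDa off at 2 mDa tolerance: nothing
  sp_off <- list(mz = sp$mz + 0.003, intensity = c(1e4, 1e4), polarity = "-")
  expect_equal(nrow(match_diagnostic_fragments(sp_off, dfs)$hits), 0L)

  expect_error(match_diagnostic_fragments(sp, pfas_diagnostic_fragments("+")),
               "polarity")
})

test_that("fragment difference matching finds CF2 and HF gaps", {
  diffs <- pfas_mass_differences()
  sp <- list(mz = c(118.9926, 168.9894), intensity = c(1e4, 1e4))
  res <- match_fragment_differences(sp, diffs)
  expect_equal(nrow(res$hits), 1L)
  expect_equal(res$hits$label, "CF2")
  expect_equal(res$hits$delta, 49.9968, tolerance = 1e-4)

  sp_hf <- list(mz = c(100.0, 100.0 + monoisotopic_mass("HF")),
                intensity = c(1e4, 1e4))
  res_hf <- match_fragment_differences(sp_hf, diffs)
  expect_equal(res_hf$hits$label, "HF")

  single <- list(mz = 118.9926, intensity = 1e4)
  expect_equal(nrow(match_fragment_differences(single, diffs)$hits), 0L)
})

test_that("difference matching agrees with a brute-force double loop", {
  diffs <- pfas_mass_differences()
  set.seed(77)
  for (rep in 1:100) {
    n <- sample(5:200, 1)
    mz <- sort(runif(n, 60, 900))
    ## plant a few true differences so the oracle has positives
    k <- sample(1:5, 1)
    mz <- sort(c(mz, mz[sample(n, k)] + sample(diffs$delta, k, replace = TRUE)))
    sp <- list(mz = mz, intensity = rep(1e4, length(mz)))
    got <- match_fragment_differences(sp, diffs, tol = 0.002, noise = 2000)$hits
    ## independent brute-force oracle
    oracle <- list()
    for (i in seq_along(mz)) for (j in seq_along(mz)) {
      if (j <= i) next
      for (q in seq_len(nrow(diffs))) {
        if (abs((mz[j] - mz[i]) - diffs$delta[q]) <= 0.002)
          oracle[[length(oracle) + 1L]] <- sprintf("%.6f|%.6f|%s",
                                                   mz[i], mz[j], diffs$label[q])
      }
    }
    got_keys <- sprintf("%.6f|%.6f|%s", got$mz_low, got$mz_high, got$label)
    expect_setequal(got_keys, unlist(oracle))
  }
})

test_that("formula propagation walks fragment ladders element-wise", {
  ## single-seed fragment list so only propagation can explain the others
  c2f5 <- monoisotopic_mass("C2F5") + 0.00054858
  dfs <- data.frame(label = "C2F5-", formula = "C2F5", mz = c2f5,
                    polarity = "-")
  diffs <- pfas_mass_differences()
  c4f9o <- c2f5 + monoisotopic_mass("C2F4O")
  f_anion <- c2f5 - monoisotopic_mass("C2F4")   # C2F5 - C2F4 = F
  sp <- list(mz = c(f_anion, c2f5, c4f9o), intensity = rep(1e4, 3),
             polarity = "-")
  ann0 <- match_diagnostic_fragments(sp, dfs)$hits
  ann <- propagate_formulas(sp, ann0, diffs)
  expect_true("F" %in% ann$formula)        # subtraction to a bare fluoride
  expect_true("C4F9O" %in% ann$formula)    # addition of an ether unit
  prop <- ann[ann$source == "propagated", ]
  expect_equal(nrow(prop), 2L)
  expect_true(all(prop$partner_mz == c2f5))
  ## propagated masses stay consistent with their formulas
  for (i in seq_len(nrow(ann))) {
    m_ion <- monoisotopic_mass(ann$formula[i]) + 0.00054858
    expect_lt(abs(m_ion - ann$fragment_mz[i]), 0.002 + 5e-4)
  }
  ## no seeds, no propagation
  none <- propagate_formulas(sp, ann0[0, ], diffs)
  expect_equal(nrow(none), 0L)
})

test_that("a rejected subtraction never yields negative element counts", {
  diffs <- data.frame(label = "CF2O", formula = "CF2O",
                      delta = monoisotopic_mass("CF2O"))
  cf3 <- monoisotopic_mass("CF3") + 0.00054858
  sp <- list(mz = c(cf3 - monoisotopic_mass("CF2O"), cf3),
             intensity = c(1e4, 1e4), polarity = "-")
  ann0 <- data.frame(peak_mz = cf3, formula = "CF3")
  ann <- propagate_formulas(sp, ann0, diffs)
  ## CF3 - CF2O would need a negative oxygen count: must not be annotated
  expect_equal(nrow(ann), 1L)
})

test_that("suspect screening matches adduct-corrected masses within 4 mDa", {
  suspects <- data.frame(name = c("PFOA", "decoy"),
                         formula = c("C8HF15O2", "C10HF19O2"),
                         exact_mass = c(413.97370, 513.96700 + 0.010))
  feats <- data.frame(feature_id = 1:2, mz = c(412.9664, 512.9601))
  hits <- suspect_screen(feats, suspects, "[M-H]-", tol = 0.004,
                         polarity = "-")
  expect_equal(hits$name, "PFOA")  # decoy mass off by 10 mDa: no hit

  ## [M]+ match in positive mode is electron-corrected
  sus_pos <- data.frame(name = "betaine", formula = "C10H20N",
                        exact_mass = monoisotopic_mass("C10H20N"))
  f_pos <- data.frame(feature_id = 1L,
                      mz = monoisotopic_mass("C10H20N") - 0.00054858)
  hp <- suspect_screen(f_pos, sus_pos, c("[M+H]+", "[M]+"), polarity = "+")
  expect_true("[M]+" %in% hp$adduct)
  expect_lt(abs(hp$delta_mda[hp$adduct == "[M]+"]), 0.01)

  expect_error(suspect_screen(feats, suspects, "[M+H]+", polarity = "-"),
               "inconsistent")
})

test_that("list readers validate masses against formulas", {
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(name = "PFOA", smiles = "", formula = "C8HF15O2",
                       exact_mass = 413.99), p, row.names = FALSE)
  expect_warning(sl <- read_suspect_csv(p), "deviates")
  expect_equal(sl$exact_mass, monoisotopic_mass("C8HF15O2"))

  write.csv(data.frame(label = "C2F5-", formula = "C2F5", mz = 118.95,
                       polarity = "-"), p, row.names = FALSE)
  expect_error(read_fragment_csv(p), "inconsistent")

  write.csv(data.frame(label = "CF2", formula = "CF2"), p, row.names = FALSE)
  dl <- read_difference_csv(p)
  expect_equal(dl$delta, monoisotopic_mass("CF2"))
})
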