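test_that("formula parsing handles standard PFAS formulas and round-trips", {
  expect_equal(unclass(parse_formula("C8HF15O2"))[c("C", "H", "F", "O")],
               c(C = 8L, H = 1L, F = 15L, O = 2L))
  expect_equal(unclass(parse_formula("CF2"))[c("C", "F")], c(C = 1L, F = 2L))
  f <- parse_formula("C15H19F13N2O4S")
  expect_equal(unclass(f)[c("C", "H", "F", "N", "O", "S")],
               c(C = 15L, H = 19L, F = 13L, N = 2L, O = 4L, S = 1L))

  set.seed(42)
  for (i in 1:25) {
    syms <- sample(c("C", "H", "F", "N", "O", "P", "S", "Cl", "Br"),
                   sample(2:6, 1))
    counts <- sample(1:30, length(syms), replace = TRUE)
    names(counts) <- syms
    txt <- format_formula(counts)
    back <- parse_formula(txt)
    expect_equal(sort(unclass(back)), sort(counts[counts > 0]),
                 ignore_attr = TRUE)
  }
})

test_that("malformed and unknown formulas are rejected with the offending token", {
  expect_error(parse_formula("C8H(F3)2"), "unparseable token")
  expect_error(parse_formula("c8h"), "unparseable token")
  expect_error(parse_formula("C8Xx2"), "unknown element symbol 'Xx'")
  expect_error(parse_formula(""), "non-empty")
})

test_that("monoisotopic masses match independent hand sums and are additive", {
  ## hand sums from the atomic mass table: 12 + 2*18.998403, etc.
  expect_equal(monoisotopic_mass("CF2"), 49.996806, tolerance = 1e-5)
  expect_equal(monoisotopic_mass("H"), 1.0078250, tolerance = 1e-6)
  expect_equal(monoisotopic_mass("C8HF15O2"), 413.97370, tolerance = 1e-4)

  set.seed(11)
  for (i in 1:20) {
    a <- structure(c(C = sample(1:20, 1), F = sample(1:30, 1)),
                   class = "element_counts")
    b <- structure(c(H = sample(1:20, 1), O = sample(1:10, 1),
                     S = sample(0:3, 1)), class = "element_counts")
    expect_equal(monoisotopic_mass(formula_add(a, b)),
                 monoisotopic_mass(a) + monoisotopic_mass(b),
                 tolerance = 1e-12)
  }
})

test_that("mass defect uses the nearest-integer wrap convention", {
  expect_equal(round(mass_defect(monoisotopic_mass("F")), 4), -0.0016)
  expect_equal(round(mass_defect(monoisotopic_mass("H")), 4), +0.0078)
  expect_equal(mass_defect(100.0), 0)
  ## periodicity: MD(m + k) = MD(m)
  set.seed(3)
  m <- runif(50, 50, 900)
  for (k in c(1, 7, 250)) {
    expect_equal(mass_defect(m + k), mass_defect(m), tolerance = 1e-9)
  }
  ## wrap: a heavy hydrocarbon with true defect > +0.5 folds negative
  hc <- monoisotopic_mass("C60H122")
  expect_lt(mass_defect(hc), 0)
  expect_gt(mass_defect(hc), -0.5)
})

test_that("Kendrick mass defect is invariant within a homologous series", {
  ru <- repeating_unit("CF2")
  expect_equal(ru$nominal_mass, 50L)
  pfoa_ion <- adduct_mz(monoisotopic_mass("C8HF15O2"), "[M-H]-")
  ## independent hand computation: KM = m * 50 / exact(CF2)
  km <- pfoa_ion * 50 / monoisotopic_mass("CF2")
  expect_equal(kendrick_mass_defect(pfoa_ion, ru), round(km) - km,
               tolerance = 1e-12)
  pfna_ion <- pfoa_ion + monoisotopic_mass("CF2")
  expect_lt(abs(kendrick_mass_defect(pfoa_ion, ru) -
                  kendrick_mass_defect(pfna_ion, ru)), 2e-4)
  expect_equal(kendrick_mass_defect(ru$exact_mass, ru), 0, tolerance = 1e-12)
  ## exact-arithmetic homologue invariance up to 20 repeat units
  for (j in 1:20) {
    expect_lt(abs(kendrick_mass_defect(pfoa_ion + j * ru$exact_mass, ru) -
                    kendrick_mass_defect(pfoa_ion, ru)), 1e-9)
  }
})

test_that("adduct m/z arithmetic is electron-correct", {
  expect_equal(adduct_mz(413.97370, "[M-H]-"), 412.96642, tolerance = 1e-5)
  expect_equal(adduct_mz(413.97370, "[M+H]+"), 414.98098, tolerance = 1e-5)
  expect_equal(adduct_mz(300.00000, "[M]+"), 299.99945, tolerance = 1e-5)
  expect_error(adduct_mz(300, "[M+Na]+"), "supported")
})

test_that("isotope patterns follow the binomial carbon envelope", {
  p <- isotope_pattern("C10", 2)
  expect_equal(p$abundance[2], 10 * 0.0107 / 0.9893, tolerance = 0.01)
  expect_equal(nrow(isotope_pattern("F10", 3)), 1L)  # fluorine monoisotopic
  p3 <- isotope_pattern("C8HF15O2", 3)
  expect_equal(p3$abundance[2], 0.088, tolerance = 0.003 / 0.088)
  ## binomial limit: M+1/M within 1% of nC * a13/a12 up to 60 carbons
  for (nc in c(1, 5, 20, 40, 60)) {
    p <- isotope_pattern(sprintf("C%d", nc), 2)
    ## independent binomial oracle
    oracle <- choose(nc, 1) * 0.0107^1 * 0.9893^(nc - 1) / 0.9893^nc
    expect_equal(p$abundance[2], oracle, tolerance = 0.01)
  }
  expect_true(all(diff(p3$mz) > 0))
  expect_equal(max(p3$abundance), 1)
})
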