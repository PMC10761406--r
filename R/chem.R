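#' @keywords internal
"_PACKAGE"

## Monoisotopic (most abundant isotope) atomic masses, IUPAC 2021, Da.
## Single source of truth for all exact-mass arithmetic in the package.
.MONO_MASS <- c(
  H  = 1.007825,
  C  = 12.000000,
  N  = 14.003074,
  O  = 15.994915,
  F  = 18.998403,
  Na = 22.989769,
  Si = 27.976927,
  P  = 30.973762,
  S  = 31.972071,
  Cl = 34.968853,
  K  = 38.963707,
  Br = 78.918338,
  I  = 126.904473
)

## Integer nominal masses of the same isotopes (Kendrick scaling denominators).
.NOMINAL_MASS <- c(
  H = 1L, C = 12L, N = 14L, O = 16L, F = 19L, Na = 23L, Si = 28L,
  P = 31L, S = 32L, Cl = 35L, K = 39L, Br = 79L, I = 127L
)

#' Physical constants used in adduct and ion-mass arithmetic
#'
#' Proton and electron rest masses in Da. The proton mass (not the hydrogen
#' atom mass) is used for protonation/deprotonation so that ion masses are
#' electron-correct.
#' @keywords internal
.PROTON_MASS <- 1.0072765
.ELECTRON_MASS <- 0.00054858

## 13C - 12C mass difference: spacing of the M+1 isotopologue trace.
.C13_DELTA <- 1.0033548

## Per-element isotope distributions (nominal-mass offset 0,1,2,... from the
## principal isotope; relative abundances). Monoisotopic elements omitted.
.ISO_ABUND <- list(
  H  = c(0.999885, 0.000115),
  C  = c(0.9893, 0.0107),
  N  = c(0.99636, 0.00364),
  O  = c(0.99757, 0.00038, 0.00205),
  S  = c(0.9499, 0.0075, 0.0425, 0.0000, 0.0001),
  Cl = c(0.7576, 0.0000, 0.2424),
  Br = c(0.5069, 0.0000, 0.4931)
)

#' Parse a chemical formula into element counts
#'
#' Accepts Hill-style formulas such as `"C8HF15O2"`: element symbols (one
#' upper-case letter optionally followed by one lower-case letter) each
#' followed by an optional positive integer count. Isotope labels, charges
#' and parentheses are not supported.
#'
#' @param text Formula string.
#' @return Named integer vector of element counts (class `element_counts`).
#' @examples
#' parse_formula("C8HF15O2")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string")
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", text)) {
    prefix <- regmatches(text, regexpr("^([A-Z][a-z]?[0-9]*)*", text))
    stop(sprintf("malformed formula '%s': unparseable token at '%s'", text,
                 substr(text, nchar(prefix) + 1L, nchar(prefix) + 4L)))
  }
  parts <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  counts <- integer(0)
  for (p in parts) {
    sym <- sub("[0-9]*$", "", p)
    num <- sub("^[A-Za-z]+", "", p)
    n <- if (nzchar(num)) as.integer(num) else 1L
    if (!sym %in% names(.MONO_MASS))
      stop(sprintf("unknown element symbol '%s' in formula '%s'", sym, text))
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  counts <- counts[counts > 0L]
  if (length(counts) == 0L) stop("formula contains no atoms")
  structure(counts, class = "element_counts")
}

#' Format element counts as a Hill-order formula string
#'
#' Carbon first, then hydrogen, then remaining elements alphabetically.
#' `parse_formula(format_formula(x))` round-trips.
#'
#' @param f Named integer vector of element counts.
#' @return Formula string.
#' @export
format_formula <- function(f) {
  f <- f[f > 0]
  syms <- names(f)
  ord <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  paste0(vapply(ord, function(s) {
    if (f[[s]] == 1L) s else paste0(s, f[[s]])
  }, character(1)), collapse = "")
}

## Element-wise formula arithmetic; subtraction returns NULL if any count
## would go negative (used by MS2 formula propagation).
formula_add <- function(a, b) {
  syms <- union(names(a), names(b))
  out <- vapply(syms, function(s) {
    (if (s %in% names(a)) a[[s]] else 0L) + (if (s %in% names(b)) b[[s]] else 0L)
  }, integer(1))
  structure(out[out > 0L], class = "element_counts")
}

formula_subtract <- function(a, b) {
  syms <- union(names(a), names(b))
  out <- vapply(syms, function(s) {
    (if (s %in% names(a)) a[[s]] else 0L) - (if (s %in% names(b)) b[[s]] else 0L)
  }, integer(1))
  if (any(out < 0L)) return(NULL)
  out <- out[out > 0L]
  if (length(out) == 0L) return(NULL)
  structure(out, class = "element_counts")
}

#' Monoisotopic mass of a formula
#'
#' Sum of most-abundant-isotope atomic masses.
#'
#' @param f An `element_counts` vector or a formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C8HF15O2")  # PFOA, 413.9737
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  sum(.MONO_MASS[names(f)] * as.numeric(f))
}

#' Mass defect with nearest-integer wrap
#'
#' `MD = m - round(m)`, so MD lies in (-0.5, +0.5]. The wrap is deliberate:
#' heavy hydrocarbons whose cumulative defect exceeds +0.5 Da fold over to
#' negative MD, which is exactly how they appear in MD/C-m/C space and why
#' the m/C axis is needed to separate them from fluorinated compounds.
#'
#' @param m Mass or m/z in Da (vectorized).
#' @return Mass defect in Da.
#' @examples
#' mass_defect(18.998403)  # fluorine atom, -0.0016
#' mass_defect(1.007825)   # hydrogen atom, +0.0078
#' @export
mass_defect <- function(m) {
  stopifnot(all(m > 0))
  md <- m - round(m)
  ## round() half-to-even can leave md == -0.5; fold onto +0.5 to keep (-0.5, 0.5]
  md[md <= -0.5] <- md[md <= -0.5] + 1
  md
}

#' Build a repeating-unit descriptor for Kendrick analysis
#'
#' @param formula Formula string or `element_counts`, e.g. `"CF2"`.
#' @return List with `formula`, `exact_mass` (Da) and `nominal_mass` (integer
#'   Da), class `repeating_unit`.
#' @examples
#' repeating_unit("CF2")
#' @export
repeating_unit <- function(formula) {
  f <- if (is.character(formula)) parse_formula(formula) else formula
  structure(list(
    formula = f,
    label = format_formula(f),
    exact_mass = monoisotopic_mass(f),
    nominal_mass = sum(.NOMINAL_MASS[names(f)] * as.numeric(f))
  ), class = "repeating_unit")
}

#' @export
print.repeating_unit <- function(x, ...) {
  cat(sprintf("Repeating unit %s: exact %0.6f Da, nominal %d Da\n",
              x$label, x$exact_mass, x$nominal_mass))
  invisible(x)
}

#' Kendrick mass defect under a repeating unit
#'
#' The Kendrick mass `KM = m * nominal(RU) / exact(RU)` rescales the mass
#' axis so the repeating unit becomes integer-valued; the defect is then
#' `KMD = round(KM) - KM`. Members of a homologous series differing by
#' integer multiples of the unit share the same KMD up to measurement error.
#' With this sign convention CH2-type series carry a small positive KMD.
#'
#' @param m Mass or m/z in Da (vectorized).
#' @param ru A [repeating_unit()].
#' @return KMD in Da.
#' @examples
#' kendrick_mass_defect(412.96643, repeating_unit("CF2"))
#' @export
kendrick_mass_defect <- function(m, ru) {
  stopifnot(inherits(ru, "repeating_unit"), all(m > 0))
  km <- m * ru$nominal_mass / ru$exact_mass
  round(km) - km
}

.ADDUCTS <- list(
  "[M-H]-" = list(label = "[M-H]-", mass_delta = -.PROTON_MASS, charge = -1L,
                  polarity = "-"),
  "[M+H]+" = list(label = "[M+H]+", mass_delta = +.PROTON_MASS, charge = +1L,
                  polarity = "+"),
  "[M]+"   = list(label = "[M]+", mass_delta = -.ELECTRON_MASS, charge = +1L,
                  polarity = "+")
)

#' Supported ionization adducts
#'
#' `[M-H]-` for negative polarity; `[M+H]+` and `[M]+` for positive polarity
#' (radical/intact cations such as quaternary betaines common in AFFF
#' formulations appear as `[M]+`). All singly charged.
#'
#' @param label Adduct label.
#' @return List with `label`, `mass_delta` (Da), `charge`, `polarity`.
#' @export
adduct_spec <- function(label) {
  if (!label %in% names(.ADDUCTS))
    stop(sprintf("unknown adduct '%s'; supported: %s", label,
                 paste(names(.ADDUCTS), collapse = ", ")))
  .ADDUCTS[[label]]
}

#' m/z of a neutral mass under an adduct
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (vectorized).
#' @param adduct Adduct label or [adduct_spec()].
#' @return Singly charged m/z in Da.
#' @examples
#' adduct_mz(413.97370, "[M-H]-")  # PFOA anion, 412.96643
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  if (is.character(adduct)) adduct <- adduct_spec(adduct)
  stopifnot(all(neutral_mass > 0))
  neutral_mass + adduct$mass_delta
}

#' Theoretical isotope pattern of a formula
#'
#' Aggregated nominal-mass isotopologue envelope obtained by convolving the
#' per-element isotope distributions; fine structure within one nominal mass
#' is not resolved. Abundances are normalized to the base peak; peak m/z
#' values are spaced by the 13C-12C mass difference from the monoisotopic
#' mass, which is the dominant contributor for organic formulas.
#'
#' @param f `element_counts` or formula string.
#' @param n_peaks Number of isotopologue peaks to return (>= 1).
#' @return Data frame with columns `mz`, `abundance` (base peak = 1).
#' @examples
#' isotope_pattern("C10", 2)
#' @export
isotope_pattern <- function(f, n_peaks = 3L) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(n_peaks >= 1L)
  env <- 1
  for (s in names(f)) {
    d <- .ISO_ABUND[[s]]
    if (is.null(d)) next  # monoisotopic element
    for (i in seq_len(f[[s]])) {
      env <- convolve_trunc(env, d, n_peaks)
    }
  }
  env <- env[seq_len(min(n_peaks, length(env)))]
  mono <- monoisotopic_mass(f)
  data.frame(
    mz = mono + (seq_along(env) - 1L) * .C13_DELTA,
    abundance = env / max(env)
  )
}

## Polynomial convolution truncated to the first n terms.
convolve_trunc <- function(a, b, n) {
  out <- numeric(min(n, length(a) + length(b) - 1L))
  for (i in seq_along(a)) {
    jmax <- min(length(b), length(out) - i + 1L)
    if (jmax < 1L) break
    idx <- i + seq_len(jmax) - 1L
    out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
  }
  out
}
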