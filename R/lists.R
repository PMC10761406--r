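#' Built-in PFAS diagnostic fragment list
#'
#' A curated starter list of well-known PFAS MS2 fragment ions; every m/z is
#' computed from the ion formula (electron-mass corrected), never typed in.
#' Negative mode covers the perfluoroalkyl anion series CnF2n+1- together
#' with common sulfonate/phosphate head-group and ether fragments; positive
#' mode the CnF2n-1+ / CnF2n+1+ carbocation series. Users with larger
#' literature collections can load them with [read_fragment_csv()].
#'
#' @param polarity `"-"`, `"+"` or `"both"`.
#' @return Data frame: `label`, `formula`, `mz`, `polarity`.
#' @export
pfas_diagnostic_fragments <- function(polarity = c("-", "+", "both")) {
  polarity <- match.arg(polarity)
  neg_formulas <- c(
    sprintf("C%dF%d", 1:12, 2 * (1:12) + 1),   # CF3-, C2F5-, ... C12F25-
    "F", "SO3", "HSO3", "FSO3", "PO3", "PO2",
    "C2F5O", "C3F7O", "C2F3O2", "C3F5O2",      # perfluoro ether / acid frags
    "C8F17SO3", "C4F9SO3",                     # perfluorosulfonate anions
    "C2H4SO3", "CHF2SO3"
  )
  pos_formulas <- c(
    sprintf("C%dF%d", 2:8, 2 * (2:8) - 1),     # C2F3+, C3F5+, ... C8F15+
    sprintf("C%dHF%d", 2:6, 2 * (2:6)),        # CnHF2n+
    "CF3", "C2F5", "C3F7"
  )
  rows <- list()
  if (polarity %in% c("-", "both")) {
    rows[[1]] <- data.frame(
      label = paste0(neg_formulas, "-"), formula = neg_formulas,
      mz = vapply(neg_formulas, function(f)
        monoisotopic_mass(f) + .ELECTRON_MASS, numeric(1)),
      polarity = "-", stringsAsFactors = FALSE)
  }
  if (polarity %in% c("+", "both")) {
    rows[[length(rows) + 1L]] <- data.frame(
      label = paste0(pos_formulas, "+"), formula = pos_formulas,
      mz = vapply(pos_formulas, function(f)
        monoisotopic_mass(f) - .ELECTRON_MASS, numeric(1)),
      polarity = "+", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Built-in PFAS fragment mass-difference list
#'
#' Characteristic mass gaps between product ions (or between MS1 species)
#' of fluorinated compounds: the chain units CF2 and C2F4, the HF loss, the
#' ether units CF2O and C2F4O, the combined HF+CO2 loss of fluorotelomer
#' acids, and the C10H3F17 difference seen between fluorotelomer chain
#' variants. All deltas are computed from formulas.
#'
#' @return Data frame: `label`, `formula`, `delta` (Da).
#' @export
pfas_mass_differences <- function() {
  f <- c(CF2 = "CF2", C2F4 = "C2F4", HF = "HF", CF2O = "CF2O",
         C2F4O = "C2F4O", `HF+CO2` = "CHFO2", C10H3F17 = "C10H3F17")
  data.frame(label = names(f), formula = unname(f),
             delta = vapply(unname(f), monoisotopic_mass, numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a diagnostic fragment list from CSV
#'
#' Columns: `label`, `formula` (ion formula, may be empty), `mz` (may be
#' empty when `formula` is given; then computed electron-corrected from the
#' formula and the row polarity), `polarity` (`+`/`-`). A populated `mz`
#' inconsistent with its formula by more than 0.5 mDa is rejected.
#'
#' @param path CSV path.
#' @return Data frame: `label`, `formula`, `mz`, `polarity`.
#' @export
read_fragment_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cn in c("label", "polarity")) {
    if (!cn %in% names(df)) stop(sprintf("fragment list missing column '%s'", cn))
  }
  if (!"formula" %in% names(df)) df$formula <- NA_character_
  if (!"mz" %in% names(df)) df$mz <- NA_real_
  df$mz <- suppressWarnings(as.numeric(df$mz))
  if (!all(df$polarity %in% c("+", "-")))
    stop("fragment list polarity must be '+' or '-'")
  for (i in seq_len(nrow(df))) {
    hasf <- !is.na(df$formula[i]) && nzchar(df$formula[i])
    if (hasf) {
      m <- monoisotopic_mass(df$formula[i]) -
        ifelse(df$polarity[i] == "+", .ELECTRON_MASS, -.ELECTRON_MASS)
      if (is.na(df$mz[i])) df$mz[i] <- m
      else if (abs(df$mz[i] - m) > 5e-4)
        stop(sprintf("fragment '%s': mz %.5f inconsistent with formula %s (%.5f)",
                     df$label[i], df$mz[i], df$formula[i], m))
    } else if (is.na(df$mz[i])) {
      stop(sprintf("fragment '%s' has neither formula nor mz", df$label[i]))
    }
  }
  df[, c("label", "formula", "mz", "polarity")]
}

#' Read a fragment mass-difference list from CSV
#'
#' Columns: `label`, `formula`; the delta is always recomputed from the
#' formula so list files cannot drift from the mass scale.
#'
#' @param path CSV path.
#' @return Data frame: `label`, `formula`, `delta`.
#' @export
read_difference_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cn in c("label", "formula")) {
    if (!cn %in% names(df)) stop(sprintf("difference list missing column '%s'", cn))
  }
  df$delta <- vapply(df$formula, monoisotopic_mass, numeric(1))
  df[, c("label", "formula", "delta")]
}

#' Read a suspect list from CSV
#'
#' Columns: `name`, `smiles` (optional), `formula`, `exact_mass` (neutral
#' monoisotopic, Da). The exact mass is recomputed from the formula on load;
#' a mismatch above 1 mDa triggers a warning naming the entry (guards
#' corrupted lists) and the formula-derived mass is used.
#'
#' @param path CSV path.
#' @return Data frame: `name`, `smiles`, `formula`, `exact_mass`.
#' @export
read_suspect_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cn in c("name", "formula", "exact_mass")) {
    if (!cn %in% names(df)) stop(sprintf("suspect list missing column '%s'", cn))
  }
  if (!"smiles" %in% names(df)) df$smiles <- NA_character_
  df$exact_mass <- suppressWarnings(as.numeric(df$exact_mass))
  calc <- vapply(df$formula, monoisotopic_mass, numeric(1))
  bad <- !is.na(df$exact_mass) & abs(df$exact_mass - calc) > 1e-3
  if (any(bad))
    warning(sprintf("suspect exact_mass deviates >1 mDa from formula for: %s; using formula mass",
                    paste(df$name[bad], collapse = ", ")))
  df$exact_mass <- ifelse(is.na(df$exact_mass) | bad, calc, df$exact_mass)
  df[, c("name", "smiles", "formula", "exact_mass")]
}
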