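#' Compute mass defect and carbon-normalized coordinates
#'
#' Adds `md` (nearest-integer mass defect of the feature m/z), `mdc`
#' (= md / estimated carbon number) and `m_over_c` (= m/z / estimated carbon
#' number) columns. Highly fluorinated compounds sit at high m/C (fluorine
#' dominates the mass, ~50 for perfluoroalkyl chains) with near-zero or
#' negative MD/C, while hydrocarbons cluster around m/C ~ 14-25 with
#' positive MD/C, so the two populations separate cleanly in this plane.
#' Features without a carbon estimate get `NA` coordinates.
#'
#' @param features Feature data frame with a `carbon_est` column (see
#'   [add_carbon_estimate()]).
#' @return `features` with `md`, `mdc`, `m_over_c` columns.
#' @export
compute_mdc_mc <- function(features) {
  if (!"carbon_est" %in% names(features))
    stop("run add_carbon_estimate() first")
  features$md <- if (nrow(features)) mass_defect(features$mz) else numeric(0)
  features$mdc <- features$md / features$carbon_est
  features$m_over_c <- features$mz / features$carbon_est
  features
}

#' Filter features in the MD/C - m/C plane
#'
#' Keeps features with `m_over_c > mc_min` and `mdc < mdc_max`; either cutoff
#' may be disabled by passing `NULL`. Failing features are flagged
#' (`mdc_mc_pass = FALSE`) rather than dropped, preserving the audit trail;
#' features without carbon estimates never pass.
#'
#' @param features Feature data frame after [compute_mdc_mc()].
#' @param mc_min Minimum m/C, Da per carbon (default 30).
#' @param mdc_max Maximum MD/C, Da per carbon (default +0.003).
#' @return `features` with a logical `mdc_mc_pass` column.
#' @export
filter_mdc_mc <- function(features, mc_min = 30, mdc_max = 0.003) {
  pass <- rep(TRUE, nrow(features))
  if (!is.null(mc_min)) pass <- pass & features$m_over_c > mc_min
  if (!is.null(mdc_max)) pass <- pass & features$mdc < mdc_max
  pass[is.na(pass)] <- FALSE
  features$mdc_mc_pass <- pass
  features
}

#' Detect homologous series by Kendrick mass defect
#'
#' Two features are homologue candidates when their m/z difference is an
#' integer multiple (>= 1) of the repeating-unit exact mass within the mass
#' tolerance — equivalently, when they share a Kendrick mass defect under
#' that unit. Series are the connected components of this relation with at
#' least `min_members` members; a bridging feature can therefore merge two
#' chains into one series. Retention-time ordering is deliberately not
#' enforced; RT-shift verification is left to visual inspection of the
#' extracted chromatograms (see [extract_series_eics()]).
#'
#' @param features Feature data frame.
#' @param ru A [repeating_unit()] (e.g. `repeating_unit("CF2")`).
#' @param mass_tol Mass tolerance, Da (default 2 mDa).
#' @param min_members Minimum homologues per series (default 3).
#' @param max_multiple Largest multiple of the repeating unit considered
#'   between two members (default 50).
#' @return List of `homologous_series` objects, each with `hs_id`,
#'   `repeating_unit`, `member_feature_ids`, `member_mz`, `kmd_centroid`.
#' @export
detect_homologous_series <- function(features, ru, mass_tol = 0.002,
                                     min_members = 3L, max_multiple = 50L) {
  stopifnot(inherits(ru, "repeating_unit"))
  n <- nrow(features)
  if (n < min_members) return(list())
  mz <- features$mz
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  o <- order(mz)
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      d <- mz[o[b]] - mz[o[a]]
      k <- round(d / ru$exact_mass)
      if (k > max_multiple) break
      if (k >= 1L && abs(d - k * ru$exact_mass) <= mass_tol) {
        ra <- find(o[a]); rb <- find(o[b])
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- split(seq_len(n), roots)
  comps <- comps[vapply(comps, length, integer(1)) >= min_members]
  if (length(comps) == 0L) return(list())
  comps <- comps[order(vapply(comps, function(i) min(mz[i]), numeric(1)))]
  out <- vector("list", length(comps))
  for (i in seq_along(comps)) {
    idx <- comps[[i]][order(mz[comps[[i]]])]
    out[[i]] <- structure(list(
      hs_id = i,
      repeating_unit = ru,
      member_feature_ids = features$feature_id[idx],
      member_mz = mz[idx],
      kmd_centroid = mean(kendrick_mass_defect(mz[idx], ru))
    ), class = "homologous_series")
  }
  out
}

#' @export
print.homologous_series <- function(x, ...) {
  cat(sprintf("HS %d (%s): %d members, m/z %.4f-%.4f, KMD centroid %+.5f\n",
              x$hs_id, x$repeating_unit$label, length(x$member_mz),
              min(x$member_mz), max(x$member_mz), x$kmd_centroid))
  invisible(x)
}

#' Annotate features with their homologous-series memberships
#'
#' @param features Feature data frame.
#' @param series List from [detect_homologous_series()].
#' @param prefix Label prefix for the series ids (defaults to the repeating
#'   unit label so series from different units stay distinguishable).
#' @return `features` with an `hs_ids` character column (`;`-separated).
#' @export
add_hs_ids <- function(features, series, prefix = NULL) {
  if (!"hs_ids" %in% names(features)) features$hs_ids <- ""
  for (hs in series) {
    lab <- paste0(prefix %||% paste0(hs$repeating_unit$label, ":"), hs$hs_id)
    sel <- features$feature_id %in% hs$member_feature_ids
    features$hs_ids[sel] <- ifelse(nzchar(features$hs_ids[sel]),
                                   paste(features$hs_ids[sel], lab, sep = ";"),
                                   lab)
  }
  features
}

#' Extract one spectrum of a run
#'
#' @param run An `ms_run`.
#' @param i Scan index (row of `run$header`).
#' @return List with `ms_level`, `rt`, `mz`, `intensity`, `precursor_mz`,
#'   `precursor_intensity`, `polarity`; class `spectrum`.
#' @export
get_spectrum <- function(run, i) {
  stopifnot(inherits(run, "ms_run"), i >= 1L, i <= nrow(run$header))
  h <- run$header[i, ]
  m <- run$peaks[[i]]
  structure(list(ms_level = h$ms_level, rt = h$rt, mz = m[, 1],
                 intensity = m[, 2], precursor_mz = h$precursor_mz,
                 precursor_intensity = h$precursor_intensity,
                 polarity = run$polarity),
            class = "spectrum")
}

#' Match diagnostic fragments against an MS2 spectrum
#'
#' Peaks at or above the noise threshold are compared with a diagnostic
#' fragment list at the given mass tolerance. The spectrum is flagged a
#' potential PFAS hit when at least `min_hits` distinct matches are found.
#'
#' @param spectrum A `spectrum` (see [get_spectrum()]) or list with `mz`,
#'   `intensity`, `polarity`.
#' @param dfs Fragment list (see [pfas_diagnostic_fragments()]).
#' @param tol Mass tolerance, Da (default 2 mDa).
#' @param noise MS2 intensity threshold, counts (default 2000).
#' @param min_hits Matches needed to flag the spectrum (default 1).
#' @return List: `hits` (data frame `peak_mz`, `peak_intensity`, `label`,
#'   `formula`, `frag_mz`), `flagged` (logical).
#' @export
match_diagnostic_fragments <- function(spectrum, dfs, tol = 0.002,
                                       noise = 2000, min_hits = 1L) {
  if (!is.null(spectrum$polarity) &&
      !all(dfs$polarity == spectrum$polarity))
    stop(sprintf("fragment list polarity does not match spectrum polarity (%s)",
                 spectrum$polarity))
  keep <- spectrum$intensity >= noise
  mz <- spectrum$mz[keep]; int <- spectrum$intensity[keep]
  rows <- list()
  for (j in seq_len(nrow(dfs))) {
    d <- abs(mz - dfs$mz[j])
    for (i in which(d <= tol)) {
      rows[[length(rows) + 1L]] <- data.frame(
        peak_mz = mz[i], peak_intensity = int[i], label = dfs$label[j],
        formula = dfs$formula[j], frag_mz = dfs$mz[j],
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peak_mz = numeric(0), peak_intensity = numeric(0),
               label = character(0), formula = character(0),
               frag_mz = numeric(0))
  list(hits = hits, flagged = nrow(hits) >= min_hits)
}

#' Match pairwise fragment mass differences in an MS2 spectrum
#'
#' All pairwise m/z differences among peaks at or above the noise threshold
#' are matched against a list of characteristic mass differences. This
#' detects PFAS-typical fragment ladders (CF2, HF, ...) without knowing any
#' fragment mass in advance.
#'
#' @inheritParams match_diagnostic_fragments
#' @param diffs Difference list (see [pfas_mass_differences()]).
#' @param min_hits Matches needed to flag the spectrum (default 1).
#' @return List: `hits` (data frame `mz_low`, `mz_high`, `delta`, `label`),
#'   `flagged`.
#' @export
match_fragment_differences <- function(spectrum, diffs, tol = 0.002,
                                       noise = 2000, min_hits = 1L) {
  keep <- spectrum$intensity >= noise
  mz <- sort(spectrum$mz[keep])
  rows <- list()
  if (length(mz) >= 2L) {
    pairs <- utils::combn(length(mz), 2L)
    d <- mz[pairs[2, ]] - mz[pairs[1, ]]
    for (j in seq_len(nrow(diffs))) {
      for (i in which(abs(d - diffs$delta[j]) <= tol)) {
        rows[[length(rows) + 1L]] <- data.frame(
          mz_low = mz[pairs[1, i]], mz_high = mz[pairs[2, i]],
          delta = d[i], label = diffs$label[j], stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mz_low = numeric(0), mz_high = numeric(0),
               delta = numeric(0), label = character(0))
  if (nrow(hits) > 0L)
    hits <- hits[order(hits$mz_low, hits$mz_high, hits$label), , drop = FALSE]
  rownames(hits) <- NULL
  list(hits = hits, flagged = nrow(hits) >= min_hits)
}

#' Propagate chemical formulas across fragment mass differences
#'
#' Starting from the formula-bearing diagnostic fragment matches of a
#' spectrum, any unannotated peak lying at an annotated peak's m/z plus or
#' minus a listed mass difference (within tolerance) inherits the annotated
#' formula with the difference formula added or subtracted element-wise.
#' Subtractions that would need negative element counts are rejected. The
#' rule is applied to a fixed point, so formulas chain along whole fragment
#' ladders.
#'
#' @param spectrum A `spectrum`.
#' @param annotations `hits` data frame from [match_diagnostic_fragments()]
#'   (rows with empty formulas are ignored as seeds).
#' @param diffs Difference list.
#' @param tol Mass tolerance, Da (default 2 mDa).
#' @param noise MS2 intensity threshold, counts (default 2000).
#' @return Data frame: `fragment_mz`, `formula`, `source`
#'   (`df_list`/`propagated`), `partner_mz`, `via`.
#' @export
propagate_formulas <- function(spectrum, annotations, diffs, tol = 0.002,
                               noise = 2000) {
  keep <- spectrum$intensity >= noise
  mz <- sort(spectrum$mz[keep])
  seeds <- annotations[!is.na(annotations$formula) &
                         nzchar(annotations$formula), , drop = FALSE]
  ann <- data.frame(fragment_mz = seeds$peak_mz, formula = seeds$formula,
                    source = rep("df_list", nrow(seeds)),
                    partner_mz = rep(NA_real_, nrow(seeds)),
                    via = rep(NA_character_, nrow(seeds)),
                    stringsAsFactors = FALSE)
  ann <- ann[!duplicated(ann$fragment_mz), , drop = FALSE]
  if (nrow(ann) == 0L) return(ann)
  repeat {
    grew <- FALSE
    for (p in mz) {
      if (any(abs(ann$fragment_mz - p) <= 1e-9)) next
      done <- FALSE
      for (a in seq_len(nrow(ann))) {
        fa <- parse_formula(ann$formula[a])
        for (j in seq_len(nrow(diffs))) {
          fd <- parse_formula(diffs$formula[j])
          if (abs(p - (ann$fragment_mz[a] + diffs$delta[j])) <= tol) {
            newf <- formula_add(fa, fd)
          } else if (abs(p - (ann$fragment_mz[a] - diffs$delta[j])) <= tol) {
            newf <- formula_subtract(fa, fd)
            if (is.null(newf)) next
          } else next
          ann <- rbind(ann, data.frame(
            fragment_mz = p, formula = format_formula(newf),
            source = "propagated", partner_mz = ann$fragment_mz[a],
            via = diffs$label[j], stringsAsFactors = FALSE))
          grew <- TRUE; done <- TRUE
          break
        }
        if (done) break
      }
    }
    if (!grew) break
  }
  rownames(ann) <- NULL
  ann[order(ann$fragment_mz), , drop = FALSE]
}

#' Suspect screening by accurate mass
#'
#' Each feature m/z is compared with the expected m/z of every suspect under
#' every selected adduct; all matches within the tolerance are reported (a
#' feature may hit several suspects and vice versa). Adducts must be
#' consistent with the run polarity.
#'
#' @param features Feature data frame.
#' @param suspects Suspect list (see [read_suspect_csv()]).
#' @param adducts Character vector of adduct labels; subset of
#'   `"[M-H]-"`, `"[M+H]+"`, `"[M]+"`.
#' @param tol Mass tolerance, Da (default 4 mDa).
#' @param polarity Run polarity (`"+"`/`"-"`), checked against the adducts.
#' @return Data frame: `feature_id`, `feature_mz`, `name`, `formula`,
#'   `adduct`, `expected_mz`, `delta_mda`.
#' @export
suspect_screen <- function(features, suspects, adducts = "[M-H]-",
                           tol = 0.004, polarity = "-") {
  specs <- lapply(adducts, adduct_spec)
  pols <- vapply(specs, `[[`, character(1), "polarity")
  if (!all(pols == polarity))
    stop(sprintf("adduct(s) %s inconsistent with run polarity '%s'",
                 paste(adducts[pols != polarity], collapse = ", "), polarity))
  rows <- list()
  for (a in specs) {
    exp_mz <- adduct_mz(suspects$exact_mass, a)
    for (j in seq_along(exp_mz)) {
      d <- features$mz - exp_mz[j]
      for (i in which(abs(d) <= tol)) {
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = features$feature_id[i], feature_mz = features$mz[i],
          name = suspects$name[j], formula = suspects$formula[j],
          adduct = a$label, expected_mz = exp_mz[j],
          delta_mda = d[i] * 1000, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature_id = integer(0), feature_mz = numeric(0),
               name = character(0), formula = character(0),
               adduct = character(0), expected_mz = numeric(0),
               delta_mda = numeric(0))
  out[order(out$feature_id, out$name), , drop = FALSE]
}
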