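#' Extracted ion chromatogram
#'
#' A dense per-cycle intensity vector for one feature across a DIA run.
#' Cycle indices are 1-based; unobserved cycles hold zero. The apex is the
#' earliest cycle attaining the maximum intensity.
#'
#' @param values Numeric vector of length \code{k} (total cycles in the run),
#'   all values non-negative.
#' @return An object of class \code{"xic"} with elements \code{values},
#'   \code{k}, \code{apex_index} and \code{support} (indices with positive
#'   intensity).
#' @seealso \code{\link{build_xic}} for construction from sparse
#'   (cycle, intensity) observations.
#' @export
xic <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("an XIC needs at least one cycle")
  if (any(!is.finite(values)) || any(values < 0))
    stop("XIC intensities must be finite and non-negative")
  support <- which(values > 0)
  apex <- if (length(support)) which.max(values) else NA_integer_
  structure(list(values = values, k = length(values),
                 apex_index = apex, support = support),
            class = "xic")
}

#' @export
print.xic <- function(x, ...) {
  cat(sprintf("XIC over %d cycles, %d observed, apex at cycle %s\n",
              x$k, length(x$support),
              if (is.na(x$apex_index)) "NA" else x$apex_index))
  invisible(x)
}

#' Single charge proteoform feature (SCPF)
#'
#' One charge state of a proteoform feature: its neutral monoisotopic mass,
#' charge, m/z and per-cycle chromatogram. The total intensity is the sum of
#' the XIC and the cycle count is the number of cycles with signal.
#'
#' @param scpf_id,parent_feature_id Character identifiers (parent is the
#'   multi-charge proteoform feature this charge state belongs to).
#' @param charge Positive integer charge state.
#' @param neutral_mass Neutral monoisotopic mass (Da).
#' @param mz Mass-to-charge ratio (Th); must agree with \code{neutral_mass}
#'   and \code{charge} within 0.1 Da under the proton convention.
#' @param xic An \code{\link{xic}} object.
#' @param window_id Assigned isolation window, or \code{NA} if unassigned.
#' @param proton_mass Proton mass (Da) for the consistency check.
#' @return An object of class \code{"scpf"}.
#' @export
scpf <- function(scpf_id, parent_feature_id, charge, neutral_mass, mz, xic,
                 window_id = NA_character_, proton_mass = 1.007276) {
  stopifnot(inherits(xic, "xic"))
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1) stop("charge must be a positive integer")
  if (length(xic$support) < 1L)
    stop("an SCPF must be observed in at least one cycle")
  implied <- charge * (mz - proton_mass)
  if (abs(implied - neutral_mass) > 0.1)
    stop(sprintf("neutral_mass %.4f inconsistent with mz %.4f at charge %d",
                 neutral_mass, mz, charge))
  structure(list(scpf_id = as.character(scpf_id),
                 parent_feature_id = as.character(parent_feature_id),
                 charge = charge, neutral_mass = neutral_mass, mz = mz,
                 xic = xic, total_intensity = sum(xic$values),
                 cycle_count = length(xic$support),
                 window_id = as.character(window_id)),
            class = "scpf")
}

#' Deconvoluted fragment feature
#'
#' A fragment mass trace extracted from one isolation window's LC-MS/MS map.
#'
#' @param frag_id Character identifier.
#' @param window_id Isolation window the feature was extracted from.
#' @param neutral_mass Neutral monoisotopic mass (Da), positive.
#' @param charge Representative charge state.
#' @param xic An \code{\link{xic}} object; must carry positive total
#'   intensity.
#' @return An object of class \code{"fragment_feature"}.
#' @export
fragment_feature <- function(frag_id, window_id, neutral_mass, charge, xic) {
  stopifnot(inherits(xic, "xic"))
  if (neutral_mass <= 0) stop("fragment neutral_mass must be positive")
  total <- sum(xic$values)
  if (total <= 0) stop("fragment total_intensity must be positive")
  structure(list(frag_id = as.character(frag_id),
                 window_id = as.character(window_id),
                 neutral_mass = neutral_mass, charge = as.integer(charge),
                 xic = xic, total_intensity = total),
            class = "fragment_feature")
}

#' Pseudo MS/MS spectrum
#'
#' A demultiplexed precursor with the fragment masses assigned to it.
#' Fragments are kept sorted by ascending neutral mass and may not repeat a
#' fragment-feature id.
#'
#' @param spectrum_id,scpf_id,window_id Character identifiers.
#' @param precursor_mass Neutral monoisotopic precursor mass (Da).
#' @param precursor_charge Integer charge.
#' @param precursor_intensity Total SCPF intensity.
#' @param rt_range Length-2 numeric, retention range of the precursor.
#' @param fragments Data frame with columns \code{frag_id}, \code{mass},
#'   \code{intensity}, \code{charge} (possibly zero rows).
#' @return An object of class \code{"pseudo_spectrum"}.
#' @export
pseudo_spectrum <- function(spectrum_id, scpf_id, precursor_mass,
                            precursor_charge, precursor_intensity,
                            window_id, rt_range, fragments) {
  if (is.null(fragments) || nrow(fragments) == 0L) {
    fragments <- data.frame(frag_id = character(), mass = numeric(),
                            intensity = numeric(), charge = integer(),
                            stringsAsFactors = FALSE)
  } else {
    need <- c("frag_id", "mass", "intensity", "charge")
    if (!all(need %in% names(fragments)))
      stop("fragments must have columns frag_id, mass, intensity, charge")
    if (anyDuplicated(fragments$frag_id))
      stop("duplicate frag_id in pseudo spectrum")
    fragments <- fragments[order(fragments$mass), need, drop = FALSE]
    rownames(fragments) <- NULL
  }
  structure(list(spectrum_id = as.character(spectrum_id),
                 scpf_id = as.character(scpf_id),
                 precursor_mass = precursor_mass,
                 precursor_charge = as.integer(precursor_charge),
                 precursor_intensity = precursor_intensity,
                 window_id = as.character(window_id),
                 rt_range = as.numeric(rt_range),
                 fragments = fragments),
            class = "pseudo_spectrum")
}

#' @export
print.pseudo_spectrum <- function(x, ...) {
  cat(sprintf("Pseudo spectrum %s: precursor %.4f Da (z=%d), %d fragments\n",
              x$spectrum_id, x$precursor_mass, x$precursor_charge,
              nrow(x$fragments)))
  invisible(x)
}

#' Centroided spectrum
#'
#' A centroided MS1 or MS/MS scan: peak list plus acquisition coordinates.
#' Peaks are stored sorted by ascending m/z. The noise level \code{h} is NA
#' until set by \code{\link{noise_level}} / \code{\link{filter_peaks}}.
#'
#' @param scan_id Identifier.
#' @param ms_level 1 or 2.
#' @param retention_time Minutes.
#' @param cycle_index 1-based cycle position.
#' @param peaks Data frame with columns \code{mz} (> 0) and
#'   \code{intensity} (>= 0).
#' @param window_id Isolation window (MS2 only; must be absent for MS1).
#' @return An object of class \code{"centroid_spectrum"}.
#' @export
centroid_spectrum <- function(scan_id, ms_level, retention_time, cycle_index,
                              peaks, window_id = NA_character_) {
  ms_level <- as.integer(ms_level)
  if (!ms_level %in% c(1L, 2L)) stop("ms_level must be 1 or 2")
  if (ms_level == 1L && !is.na(window_id))
    stop("MS1 spectra carry no isolation window")
  if (cycle_index < 1) stop("cycle_index must be >= 1")
  if (nrow(peaks)) {
    if (any(peaks$mz <= 0)) stop("peak mz must be positive")
    if (any(peaks$intensity < 0)) stop("peak intensity must be non-negative")
    peaks <- peaks[order(peaks$mz), c("mz", "intensity"), drop = FALSE]
    rownames(peaks) <- NULL
  }
  structure(list(scan_id = as.character(scan_id), ms_level = ms_level,
                 retention_time = retention_time,
                 cycle_index = as.integer(cycle_index),
                 window_id = as.character(window_id),
                 peaks = peaks, noise_level = NA_real_),
            class = "centroid_spectrum")
}

#' Isolation window table
#'
#' Builds a validated table of non-overlapping isolation windows. Intervals
#' are treated as half-open \code{[mz_low, mz_high)} so a boundary peak
#' belongs to exactly one window.
#'
#' @param window_id Character vector of identifiers.
#' @param mz_low,mz_high Numeric window bounds (Th), \code{mz_low < mz_high}.
#' @return Data frame with class \code{c("isolation_windows", "data.frame")},
#'   sorted by \code{mz_low}.
#' @export
isolation_windows <- function(window_id, mz_low, mz_high) {
  if (any(mz_low >= mz_high)) stop("each window needs mz_low < mz_high")
  w <- data.frame(window_id = as.character(window_id),
                  mz_low = mz_low, mz_high = mz_high,
                  stringsAsFactors = FALSE)
  w <- w[order(w$mz_low), , drop = FALSE]
  if (nrow(w) > 1L && any(w$mz_high[-nrow(w)] > w$mz_low[-1] + 1e-9))
    stop("isolation windows must not overlap")
  rownames(w) <- NULL
  class(w) <- c("isolation_windows", "data.frame")
  w
}

#' Proteoform record table
#'
#' Builds the flat table of identified proteoforms consumed by the
#' deduplication and merging utilities.
#'
#' @param protein_accession Character vector.
#' @param proteoform_mass Neutral monoisotopic masses (Da), positive.
#' @param e_value Downstream search score, smaller is better (>= 0).
#' @param scpf_intensity Abundance used for duplicate ranking.
#' @param run_id Run identifier.
#' @return A data frame with one row per proteoform identification.
#' @export
proteoform_records <- function(protein_accession, proteoform_mass,
                               e_value = 0, scpf_intensity, run_id = "run1") {
  if (any(proteoform_mass <= 0)) stop("proteoform_mass must be positive")
  if (any(e_value < 0)) stop("e_value must be non-negative")
  data.frame(protein_accession = as.character(protein_accession),
             proteoform_mass = proteoform_mass,
             e_value = e_value,
             scpf_intensity = scpf_intensity,
             run_id = as.character(run_id),
             stringsAsFactors = FALSE)
}
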