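# Duplicate-proteoform removal, multi-run merging, spectral averaging and
# S/N reporting.

#' Are two proteoform identifications duplicates?
#'
#' Two identifications are duplicates when they come from the same protein
#' and the minimum of |m1 - m2|, |m1 - m2 - shift| and |m1 - m2 + shift| is
#' at most \code{ppm} parts per million, where the shift (1.00235 Da by
#' default) is the common one-neutron error of isotopic-envelope
#' deconvolution. The ppm tolerance is taken relative to the smaller of the
#' two masses.
#'
#' @param accession1,accession2 Protein accessions.
#' @param m1,m2 Neutral monoisotopic masses (Da), positive.
#' @param ppm Tolerance in ppm.
#' @param shift Tolerated mass shift (Da).
#' @return Logical.
#' @export
is_duplicate <- function(accession1, m1, accession2, m2, ppm = 10,
                         shift = 1.00235) {
  if (m1 <= 0 || m2 <= 0) stop("masses must be positive")
  if (!identical(as.character(accession1), as.character(accession2)))
    return(FALSE)
  d <- m1 - m2
  min(abs(d), abs(d - shift), abs(d + shift)) <= ppm * 1e-6 * min(m1, m2)
}

#' Remove duplicate proteoform identifications
#'
#' Ranks the records by decreasing SCPF intensity and, following that
#' order, drops each record that duplicates any better-ranked record
#' (kept or not).
#'
#' @param records A proteoform table (see
#'   \code{\link{proteoform_records}}).
#' @param ppm,shift Passed to \code{\link{is_duplicate}}.
#' @return The surviving records, ranked by decreasing
#'   \code{scpf_intensity}.
#' @export
remove_duplicates <- function(records, ppm = 10, shift = 1.00235) {
  if (nrow(records) < 2L) return(records)
  rec <- records[order(-records$scpf_intensity), , drop = FALSE]
  keep <- rep(TRUE, nrow(rec))
  for (i in 2:nrow(rec)) {
    for (j in 1:(i - 1L)) {
      if (is_duplicate(rec$protein_accession[i], rec$proteoform_mass[i],
                       rec$protein_accession[j], rec$proteoform_mass[j],
                       ppm, shift)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge proteoform identifications from multiple runs
#'
#' Concatenates the per-run tables and removes duplicates across the pool
#' with \code{\link{remove_duplicates}}. Used to combine the runs of a
#' gas-phase-fractionated acquisition, where each run covers a different
#' precursor m/z range.
#'
#' @param per_run_lists List of proteoform tables.
#' @param ppm,shift Passed to \code{\link{is_duplicate}}.
#' @return A single deduplicated proteoform table.
#' @export
merge_runs <- function(per_run_lists, ppm = 10, shift = 1.00235) {
  remove_duplicates(do.call(rbind, per_run_lists), ppm, shift)
}

#' Average centroided spectra by peak merging
#'
#' Pools the peaks of all input spectra, sorts them by m/z, and greedily
#' clusters left to right: a peak joins the current cluster when it lies
#' within \code{tol} of the previous peak (so a chain of close peaks can
#' merge beyond \code{tol} end to end). Each cluster becomes one output
#' peak at the intensity-weighted mean m/z with the summed intensity.
#'
#' @param spectra Non-empty list of \code{\link{centroid_spectrum}}
#'   objects.
#' @param tol m/z merge tolerance (Th).
#' @return A \code{\link{centroid_spectrum}} holding the averaged peak
#'   list (scan id \code{"averaged"}; coordinates from the first input).
#' @export
average_spectrum <- function(spectra, tol = 0.01) {
  if (length(spectra) == 0L) stop("average_spectrum needs >= 1 spectrum")
  pool <- do.call(rbind, lapply(spectra, `[[`, "peaks"))
  first <- spectra[[1L]]
  if (nrow(pool) == 0L)
    return(centroid_spectrum("averaged", first$ms_level,
                             first$retention_time, first$cycle_index,
                             pool, first$window_id))
  pool <- pool[order(pool$mz), , drop = FALSE]
  cluster <- cumsum(c(1, diff(pool$mz) > tol))
  mz <- vapply(split(seq_len(nrow(pool)), cluster), function(i)
    sum(pool$mz[i] * pool$intensity[i]) / sum(pool$intensity[i]),
    numeric(1))
  int <- vapply(split(pool$intensity, cluster), sum, numeric(1))
  centroid_spectrum("averaged", first$ms_level, first$retention_time,
                    first$cycle_index,
                    data.frame(mz = unname(mz), intensity = unname(int)),
                    first$window_id)
}

#' Signal-to-noise ratio of matched fragment ions
#'
#' Each matched ion's signal is the sum of its isotopic-peak intensities;
#' the spectrum S/N ratio is the mean ion signal divided by the spectrum
#' noise level \code{h}.
#'
#' @param spectrum A \code{\link{centroid_spectrum}}; its
#'   \code{noise_level} is used when already set, otherwise estimated with
#'   \code{\link{noise_level}}.
#' @param matched_ion_peaks List with one numeric vector of isotopic-peak
#'   intensities per matched fragment ion.
#' @return The S/N ratio.
#' @export
snr_ratio <- function(spectrum, matched_ion_peaks) {
  if (length(matched_ion_peaks) == 0L)
    stop("S/N ratio undefined without matched ions")
  h <- spectrum$noise_level
  if (is.na(h)) h <- noise_level(spectrum)
  signals <- vapply(matched_ion_peaks, sum, numeric(1))
  mean(signals) / h
}

#' Overlap coefficient of two identification sets
#'
#' |A intersect B| / min(|A|, |B|): the reproducibility measure used to
#' compare proteoform lists between technical replicates.
#'
#' @param a,b Vectors of identifiers.
#' @return Overlap coefficient in [0, 1].
#' @export
overlap_coefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("overlap coefficient undefined for an empty set")
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Pearson correlation of log2 feature abundances
#'
#' Matches two named abundance vectors on their common identifiers and
#' returns the Pearson correlation of the log2 abundances — the standard
#' quantitative-reproducibility measure between replicate runs.
#'
#' @param x,y Named numeric vectors of positive abundances.
#' @return Pearson correlation coefficient.
#' @export
log2_abundance_pcc <- function(x, y) {
  common <- intersect(names(x), names(y))
  if (length(common) < 3L)
    stop("need at least 3 shared identifiers")
  stats::cor(log2(x[common]), log2(y[common]), method = "pearson")
}
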