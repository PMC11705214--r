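#' Spectrum noise level from the peak-intensity histogram
#'
#' Estimates the noise intensity \code{h} of a centroided spectrum as the
#' midpoint of the most populated bin of a histogram of all peak
#' intensities. Equal-width bins span the intensity range; the bin count
#' defaults to \code{ceiling(sqrt(N))} for \code{N} peaks (minimum 1).
#' Frequency ties are broken toward the lower-intensity bin. With a single
#' occupied bin (e.g. all intensities equal) the midpoint of that bin is
#' returned.
#'
#' @param spectrum A \code{\link{centroid_spectrum}} with at least one peak.
#' @param n_bins Number of histogram bins; \code{NULL} for the square-root
#'   default.
#' @return The noise intensity \code{h}.
#' @export
noise_level <- function(spectrum, n_bins = NULL) {
  stopifnot(inherits(spectrum, "centroid_spectrum"))
  x <- spectrum$peaks$intensity
  n <- length(x)
  if (n == 0L) stop("noise level undefined for an empty spectrum")
  if (is.null(n_bins)) n_bins <- max(1L, ceiling(sqrt(n)))
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(lo)           # degenerate: all intensities equal
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  best <- which.max(counts)          # ties go to the lower-intensity bin
  (breaks[best] + breaks[best + 1L]) / 2
}

#' Signal-to-noise peak filtering
#'
#' Removes from a spectrum every peak whose intensity is strictly less than
#' \code{ratio * h}, where \code{h} is the spectrum noise level. Peaks
#' exactly at the threshold are retained. The MS1 and MS2 ratios are taken
#' from the configuration when \code{ratio} is not given.
#'
#' @param spectrum A \code{\link{centroid_spectrum}}.
#' @param ratio S/N ratio \code{r}; defaults to \code{config$r1} for MS1
#'   spectra and \code{config$r2} for MS2 spectra.
#' @param config A \code{\link{pipeline_config}}.
#' @param h Noise level; estimated with \code{\link{noise_level}} when
#'   missing.
#' @return The spectrum with sub-threshold peaks removed and
#'   \code{noise_level} set to \code{h}.
#' @export
filter_peaks <- function(spectrum, ratio = NULL, config = pipeline_config(),
                         h = NULL) {
  stopifnot(inherits(spectrum, "centroid_spectrum"))
  if (is.null(ratio))
    ratio <- if (spectrum$ms_level == 1L) config$r1 else config$r2
  if (ratio < 0) stop("S/N ratio must be non-negative")
  if (is.null(h)) h <- noise_level(spectrum)
  keep <- spectrum$peaks$intensity >= ratio * h
  spectrum$peaks <- spectrum$peaks[keep, , drop = FALSE]
  rownames(spectrum$peaks) <- NULL
  spectrum$noise_level <- h
  spectrum
}
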