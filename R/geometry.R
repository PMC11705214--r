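#' Build an XIC from sparse per-cycle observations
#'
#' Expands (cycle, intensity) observations into the dense per-cycle vector
#' used everywhere downstream. Unobserved cycles are zero; the apex is the
#' earliest cycle attaining the maximum.
#'
#' @param cycles Integer vector of 1-based cycle indices, all in
#'   \code{[1, k]}.
#' @param intensities Numeric vector of the same length.
#' @param k Total number of cycles in the run.
#' @return An \code{\link{xic}} object of length \code{k}.
#' @examples
#' build_xic(c(2, 3), c(5, 9), k = 5)
#' @export
build_xic <- function(cycles, intensities, k) {
  if (length(cycles) != length(intensities))
    stop("cycles and intensities must have equal length")
  cycles <- as.integer(cycles)
  if (length(cycles) && (any(cycles < 1L) || any(cycles > k)))
    stop(sprintf("cycle index outside [1, %d]", k))
  if (anyDuplicated(cycles)) stop("duplicate cycle index")
  v <- numeric(k)
  v[cycles] <- intensities
  xic(v)
}

#' Apex cycle distance between two features
#'
#' Absolute difference between the cycle indices at which the two
#' chromatograms reach their maximum intensity.
#'
#' @param x1,x2 \code{\link{xic}} objects with non-empty support.
#' @return Non-negative integer.
#' @export
apex_cycle_distance <- function(x1, x2) {
  stopifnot(inherits(x1, "xic"), inherits(x2, "xic"))
  if (is.na(x1$apex_index) || is.na(x2$apex_index))
    stop("apex cycle distance undefined for an empty XIC")
  abs(x1$apex_index - x2$apex_index)
}

#' Assign an SCPF to an isolation window
#'
#' An SCPF belongs to the window that contains strictly more than half of
#' the summed intensity of its isotopic peaks; if no window does, the SCPF
#' is left unassigned. Window intervals are half-open
#' \code{[mz_low, mz_high)}.
#'
#' @param isotopic_peaks Data frame with columns \code{mz} and
#'   \code{intensity}: the SCPF's isotopic peaks pooled over scans.
#' @param windows An \code{\link{isolation_windows}} table.
#' @return The \code{window_id} holding > 50\% of the intensity, or
#'   \code{NA_character_} when none does.
#' @export
assign_window <- function(isotopic_peaks, windows) {
  stopifnot(inherits(windows, "isolation_windows"))
  total <- sum(isotopic_peaks$intensity)
  if (total <= 0) return(NA_character_)
  for (i in seq_len(nrow(windows))) {
    inside <- isotopic_peaks$mz >= windows$mz_low[i] &
      isotopic_peaks$mz < windows$mz_high[i]
    if (sum(isotopic_peaks$intensity[inside]) > 0.5 * total)
      return(windows$window_id[i])
  }
  NA_character_
}
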