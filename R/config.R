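#' Pipeline configuration
#'
#' Collects every tunable constant of the demultiplexing pipeline in one
#' validated list. Defaults are the operating values used throughout the
#' package.
#'
#' @param r1 MS1 signal-to-noise ratio; MS1 peaks below \code{r1 * h} are
#'   removed, where \code{h} is the spectrum noise level.
#' @param r2 MS2 signal-to-noise ratio, used the same way for MS/MS spectra.
#' @param t Apex cycle distance cap for round-1 filtering; the effective
#'   threshold for an SCPF observed in \code{c} cycles is
#'   \code{min(t, floor(c / 2))}.
#' @param score_cutoff Logistic-model score threshold for round-2 filtering,
#'   in (0, 1).
#' @param min_keep Fallback quota for round 2 (top-\code{min_keep} fragments
#'   reported when fewer pass the cutoff) and low-mass quota for round 3.
#' @param low_mass_boundary Mass (Da) separating the low- and high-mass
#'   fragment groups in round 3.
#' @param avg_residue_mass Average amino-acid residue mass (Da) of the
#'   Averagine model, used to estimate proteoform length from precursor mass.
#' @param dup_ppm Mass tolerance (ppm) for duplicate-proteoform detection.
#' @param isotope_shift Mass (Da) of the common one-neutron deconvolution
#'   error tolerated when comparing proteoform masses.
#' @param proton_mass Proton mass (Da) used in all m/z conversions.
#' @param merge_mz_tol m/z tolerance (Th) for peak merging when averaging
#'   centroided spectra.
#'
#' @return A list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(r1 = 3, r2 = 1, t = 3,
                            score_cutoff = 0.55, min_keep = 25,
                            low_mass_boundary = 1500,
                            avg_residue_mass = 111.1254,
                            dup_ppm = 10, isotope_shift = 1.00235,
                            proton_mass = 1.007276,
                            merge_mz_tol = 0.01) {
  cfg <- list(r1 = r1, r2 = r2, t = t, score_cutoff = score_cutoff,
              min_keep = min_keep, low_mass_boundary = low_mass_boundary,
              avg_residue_mass = avg_residue_mass, dup_ppm = dup_ppm,
              isotope_shift = isotope_shift, proton_mass = proton_mass,
              merge_mz_tol = merge_mz_tol)
  num <- vapply(cfg, function(x) is.numeric(x) && length(x) == 1L && x >= 0,
                logical(1))
  if (!all(num))
    stop("all pipeline_config fields must be single non-negative numbers")
  if (score_cutoff <= 0 || score_cutoff >= 1)
    stop("score_cutoff must lie in (0, 1)")
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Demultiplexing pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-18s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Neutral mass from m/z and charge
#'
#' Converts a mass-to-charge ratio to a neutral monoisotopic mass under the
#' proton convention: \code{mass = charge * (mz - proton_mass)}.
#'
#' @param mz Mass-to-charge ratio (Th).
#' @param charge Positive integer charge state.
#' @param proton_mass Proton mass in Da.
#' @return Neutral mass in Da.
#' @examples
#' neutral_mass(850.007, 14) # ~11885.99 Da
#' @export
neutral_mass <- function(mz, charge, proton_mass = 1.007276) {
  if (any(charge < 1)) stop("charge must be a positive integer")
  if (any(mz <= proton_mass)) stop("mz must exceed the proton mass")
  charge * (mz - proton_mass)
}

#' m/z from neutral mass and charge
#'
#' Inverse of \code{\link{neutral_mass}}.
#'
#' @inheritParams neutral_mass
#' @param mass Neutral monoisotopic mass (Da).
#' @return m/z in Th.
#' @export
mass_to_mz <- function(mass, charge, proton_mass = 1.007276) {
  if (any(charge < 1)) stop("charge must be a positive integer")
  mass / charge + proton_mass
}
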