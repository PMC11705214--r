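# Three-round filtering cascade and greedy per-window pseudo-spectrum
# generation.

#' Round 1: apex cycle distance gate
#'
#' Keeps the fragments whose apex cycle distance to the SCPF is at most
#' \code{min(t, floor(c / 2))}, where \code{c} is the number of cycles in
#' which the SCPF is observed.
#'
#' @param scpf An \code{\link{scpf}}.
#' @param pool List of \code{\link{fragment_feature}} objects.
#' @param t Apex-distance cap (non-negative).
#' @return The surviving sublist \code{L} of \code{pool}.
#' @export
round1_filter <- function(scpf, pool, t = 3) {
  if (t < 0) stop("t must be non-negative")
  pool[.round1_select(scpf, pool, t)]
}

.round1_select <- function(scpf, pool, t) {
  thr <- min(t, floor(scpf$cycle_count / 2))
  d <- vapply(pool, function(f) apex_cycle_distance(scpf$xic, f$xic),
              numeric(1))
  which(d <= thr)
}

# index selection for round 2 on a score vector
.round2_select <- function(scores, cutoff, min_keep) {
  pass <- which(scores > cutoff)
  if (length(pass) >= min_keep) return(pass)
  n <- length(scores)
  sort(order(-scores)[seq_len(min(min_keep, n))])
}

#' Round 2: logistic score filter with a top-k fallback
#'
#' Scores every fragment of the round-1 list \code{L} against the SCPF and
#' keeps those scoring strictly above \code{cutoff}. When fewer than
#' \code{min_keep} pass, the \code{min(min_keep, |L|)} top-scoring members
#' of \code{L} are reported instead, without score filtering.
#'
#' @param L List of \code{\link{fragment_feature}} objects (round-1
#'   survivors).
#' @param scpf The \code{\link{scpf}} being processed.
#' @param model A fitted \code{"pair_model"}.
#' @param cutoff Score threshold.
#' @param min_keep Fallback quota.
#' @return The surviving sublist of \code{L}.
#' @export
round2_filter <- function(L, scpf, model, cutoff = 0.55, min_keep = 25) {
  if (length(L) == 0L) return(L)
  scores <- score_pair(pair_features(scpf, L), model)
  L[.round2_select(scores, cutoff, min_keep)]
}

# index selection for round 3 given masses and scores
.round3_select <- function(masses, scores, T_budget, boundary, low_quota) {
  if (T_budget < 0) stop("fragment budget must be non-negative")
  low_q <- min(low_quota, T_budget)
  high_q <- max(T_budget - low_quota, 0)
  low <- which(masses < boundary)
  high <- which(masses >= boundary)
  keep_low <- low[order(-scores[low])][seq_len(min(low_q, length(low)))]
  keep_high <- high[order(-scores[high])][seq_len(min(high_q, length(high)))]
  sort(c(keep_low, keep_high))
}

#' Round 3: mass-stratified fragment budget
#'
#' Splits the fragments into a low-mass group (mass below \code{boundary})
#' and a high-mass group, then keeps up to \code{min(low_quota, T)}
#' top-scoring low-mass fragments and up to \code{max(T - low_quota, 0)}
#' top-scoring high-mass fragments. A group with fewer candidates than its
#' quota is kept whole.
#'
#' @param masses Numeric fragment neutral masses (Da).
#' @param scores Matching numeric model scores.
#' @param T_budget Estimated total number of theoretical terminal fragment
#'   masses (see \code{\link{estimate_budget}}).
#' @param boundary Low/high mass boundary (Da).
#' @param low_quota Estimated number of theoretical fragment masses below
#'   the boundary.
#' @return Sorted integer indices of the kept fragments.
#' @export
round3_filter <- function(masses, scores, T_budget, boundary = 1500,
                          low_quota = 25) {
  if (length(masses) != length(scores))
    stop("masses and scores must have equal length")
  .round3_select(masses, scores, T_budget, boundary, low_quota)
}

#' Averagine fragment budget for a precursor
#'
#' Estimates the proteoform residue length as the precursor mass divided by
#' the Averagine average residue mass (rounded, floored at 2) and sets the
#' round-3 budget to \code{T = 2 * (l - 1)}, the number of theoretical b-
#' and y-ion masses of a length-\code{l} proteoform.
#'
#' @param precursor_mass Neutral precursor mass (Da), positive.
#' @param avg_residue_mass Averagine average residue mass (Da).
#' @return List with elements \code{l} (estimated length) and \code{T}
#'   (fragment budget).
#' @export
estimate_budget <- function(precursor_mass, avg_residue_mass = 111.1254) {
  if (precursor_mass <= 0) stop("precursor_mass must be positive")
  l <- max(2, round(precursor_mass / avg_residue_mass))
  list(l = l, T = 2 * (l - 1))
}

#' Bundle one isolation window's SCPFs and fragment pool
#'
#' Groups the inputs of the greedy generator for one window. SCPFs are
#' sorted by decreasing total intensity (ties by ascending scpf_id), the
#' order in which pseudo spectra are generated.
#'
#' @param window_id Window identifier.
#' @param scpfs List of \code{\link{scpf}} objects assigned to the window.
#' @param fragments List of \code{\link{fragment_feature}} objects
#'   extracted from the window's LC-MS/MS map.
#' @return An object of class \code{"window_bundle"}.
#' @export
window_bundle <- function(window_id, scpfs, fragments) {
  window_id <- as.character(window_id)
  for (s in scpfs)
    if (!identical(s$window_id, window_id))
      stop(sprintf("SCPF %s is not assigned to window %s", s$scpf_id,
                   window_id))
  for (f in fragments)
    if (!identical(f$window_id, window_id))
      stop(sprintf("fragment %s is not from window %s", f$frag_id,
                   window_id))
  int <- vapply(scpfs, `[[`, numeric(1), "total_intensity")
  ids <- vapply(scpfs, `[[`, character(1), "scpf_id")
  structure(list(window_id = window_id,
                 scpfs = scpfs[order(-int, ids)],
                 fragments = fragments),
            class = "window_bundle")
}

.is_sorted_scpfs <- function(scpfs) {
  if (length(scpfs) < 2L) return(TRUE)
  int <- vapply(scpfs, `[[`, numeric(1), "total_intensity")
  ids <- vapply(scpfs, `[[`, character(1), "scpf_id")
  identical(order(-int, ids), seq_along(scpfs))
}

#' Greedy pseudo-spectrum generation for one isolation window
#'
#' Walks the window's SCPFs in decreasing intensity order. For each SCPF
#' the current fragment pool is filtered through the three rounds (apex
#' distance gate, logistic score with top-k fallback, mass-stratified
#' budget); the survivors form the SCPF's pseudo spectrum and are removed
#' from the pool before the next SCPF is processed. One pseudo spectrum is
#' emitted per SCPF, possibly empty.
#'
#' @param bundle A \code{\link{window_bundle}} (SCPFs must be sorted by
#'   decreasing total intensity; the constructor guarantees this).
#' @param model A fitted \code{"pair_model"}.
#' @param config A \code{\link{pipeline_config}}.
#' @return List of \code{\link{pseudo_spectrum}} objects, one per SCPF.
#' @export
generate_pseudo_spectra <- function(bundle, model,
                                    config = pipeline_config()) {
  stopifnot(inherits(bundle, "window_bundle"))
  if (!.is_sorted_scpfs(bundle$scpfs))
    stop("bundle SCPFs must be sorted by decreasing total intensity")
  pool <- bundle$fragments
  out <- vector("list", length(bundle$scpfs))
  for (i in seq_along(bundle$scpfs)) {
    s <- bundle$scpfs[[i]]
    idx1 <- .round1_select(s, pool, config$t)
    L <- pool[idx1]
    if (length(L)) {
      scores <- score_pair(pair_features(s, L), model)
      sel2 <- .round2_select(scores, config$score_cutoff, config$min_keep)
      masses <- vapply(L[sel2], `[[`, numeric(1), "neutral_mass")
      budget <- estimate_budget(s$neutral_mass, config$avg_residue_mass)
      sel3 <- sel2[.round3_select(masses, scores[sel2], budget$T,
                                  config$low_mass_boundary,
                                  config$min_keep)]
      kept <- L[sel3]
    } else kept <- list()
    frags <- if (length(kept))
      data.frame(frag_id = vapply(kept, `[[`, character(1), "frag_id"),
                 mass = vapply(kept, `[[`, numeric(1), "neutral_mass"),
                 intensity = vapply(kept, `[[`, numeric(1),
                                    "total_intensity"),
                 charge = vapply(kept, `[[`, integer(1), "charge"),
                 stringsAsFactors = FALSE)
    else NULL
    out[[i]] <- pseudo_spectrum(
      spectrum_id = paste0("ps_", s$scpf_id), scpf_id = s$scpf_id,
      precursor_mass = s$neutral_mass, precursor_charge = s$charge,
      precursor_intensity = s$total_intensity,
      window_id = bundle$window_id,
      rt_range = range(s$xic$support), fragments = frags)
    if (length(kept)) {
      used <- vapply(kept, `[[`, character(1), "frag_id")
      pool_ids <- vapply(pool, `[[`, character(1), "frag_id")
      pool <- pool[!pool_ids %in% used]
    }
  }
  out
}

#' Group SCPFs and fragments into per-window bundles
#'
#' @param scpfs List of \code{\link{scpf}} objects; those with \code{NA}
#'   window assignment are dropped.
#' @param fragments List of \code{\link{fragment_feature}} objects.
#' @return Named list of \code{\link{window_bundle}} objects, one per
#'   window that has at least one assigned SCPF, sorted by window id.
#' @export
make_bundles <- function(scpfs, fragments) {
  sw <- vapply(scpfs, `[[`, character(1), "window_id")
  fw <- vapply(fragments, `[[`, character(1), "window_id")
  wins <- sort(unique(sw[!is.na(sw)]))
  out <- lapply(wins, function(w)
    window_bundle(w, scpfs[which(sw == w)], fragments[which(fw == w)]))
  names(out) <- wins
  out
}

#' Demultiplex a full DIA run
#'
#' Runs \code{\link{generate_pseudo_spectra}} on every isolation window's
#' bundle (windows processed in sorted id order; windows are independent,
#' so the output does not depend on processing order) and concatenates the
#' results. Spectrum ids are derived from SCPF ids and therefore unique
#' across the run.
#'
#' @param bundles List of \code{\link{window_bundle}} objects, or the
#'   output of \code{\link{make_bundles}}.
#' @param model A fitted \code{"pair_model"}.
#' @param config A \code{\link{pipeline_config}}.
#' @param verbose Emit per-window spectrum/fragment counts via
#'   \code{message()}.
#' @return List of \code{\link{pseudo_spectrum}} objects.
#' @export
run_demux <- function(bundles, model, config = pipeline_config(),
                      verbose = FALSE) {
  ord <- order(vapply(bundles, `[[`, character(1), "window_id"))
  out <- list()
  for (b in bundles[ord]) {
    sp <- generate_pseudo_spectra(b, model, config)
    if (verbose)
      message(sprintf("window %s: %d SCPFs, %d fragments assigned",
                      b$window_id, length(sp),
                      sum(vapply(sp, function(p) nrow(p$fragments),
                                 integer(1)))))
    out <- c(out, sp)
  }
  out
}
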