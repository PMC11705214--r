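# End-to-end glue: candidate-pair construction for training and the
# file-level demultiplexing driver.

#' Build labeled training pairs from a run with known identifications
#'
#' Pairs every SCPF with the fragment features of its isolation window
#' whose apex cycle distance passes the round-1 gate (a fragment may pair
#' with several SCPFs), computes the three model attributes for each pair,
#' and labels pairs positive when the fragment mass matches a theoretical
#' b/y mass of the SCPF's identified sequence within \code{tol_ppm}.
#'
#' @param scpfs List of \code{\link{scpf}} objects with window
#'   assignments.
#' @param fragments List of \code{\link{fragment_feature}} objects.
#' @param sequences Named character vector, \code{scpf_id} to residue
#'   sequence (unmodified identifications only).
#' @param config A \code{\link{pipeline_config}} (supplies the apex cap
#'   \code{t}).
#' @param tol_ppm Labeling mass tolerance.
#' @return Labeled pair data frame suitable for
#'   \code{\link{train_pair_model}}.
#' @export
build_training_pairs <- function(scpfs, fragments, sequences,
                                 config = pipeline_config(),
                                 tol_ppm = 10) {
  bundles <- make_bundles(scpfs, fragments)
  out <- list()
  for (b in bundles) {
    for (s in b$scpfs) {
      if (!s$scpf_id %in% names(sequences)) next
      L <- round1_filter(s, b$fragments, config$t)
      if (length(L) == 0L) next
      out[[length(out) + 1L]] <- pair_features(s, L)
    }
  }
  if (length(out) == 0L)
    stop("no candidate pairs: check window assignments and sequences")
  label_pairs(do.call(rbind, out), sequences, tol_ppm)
}

#' Demultiplex feature tables into a pseudo-spectrum file
#'
#' File-level driver: reads the SCPF and fragment tables, groups them into
#' per-window bundles, runs the greedy three-round cascade with the given
#' model, and writes the msalign-style output.
#'
#' @param scpf_path,fragment_path Feature-table paths.
#' @param model A \code{"pair_model"} or the path to a model file.
#' @param out_path Output msalign-style file.
#' @param config A \code{\link{pipeline_config}}.
#' @param drop_empty Omit pseudo spectra with no fragments.
#' @param verbose Log per-window counts.
#' @return The list of pseudo spectra, invisibly.
#' @export
demux_files <- function(scpf_path, fragment_path, model, out_path,
                        config = pipeline_config(), drop_empty = FALSE,
                        verbose = FALSE) {
  if (is.character(model)) model <- read_pair_model(model)
  scpfs <- read_feature_table(scpf_path, "scpf")
  frags <- read_feature_table(fragment_path, "fragment")
  spectra <- run_demux(make_bundles(scpfs, frags), model, config,
                       verbose = verbose)
  write_pseudo_spectra(spectra, out_path, drop_empty = drop_empty)
  invisible(spectra)
}
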