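# Synthetic DIA-run generator with ground-truth provenance, and the
# evaluation of demultiplexing output against that truth.

#' Simulation configuration
#'
#' Parameters of the synthetic DIA run. The default layout mirrors a
#' gas-phase-fractionated acquisition: one MS1 plus 20 MS/MS scans per
#' cycle, 4 m/z isolation windows tiling one 80 m/z fraction.
#'
#' @param seed Integer seed; fixes the run byte-for-byte.
#' @param n_cycles Total cycles \code{k} in the run.
#' @param n_windows Number of isolation windows.
#' @param window_width Window width (Th); windows must tile \code{mz_range}
#'   exactly.
#' @param mz_range Precursor m/z range of the fraction, length 2.
#' @param n_proteoforms Number of simulated proteoforms (one SCPF each).
#' @param seq_len_range Residue-length range for the random sequences.
#' @param elution_sigma Gaussian elution width (cycles).
#' @param charge_range Allowed precursor charge states.
#' @param decoy_fragment_rate Decoy fragments generated per detected true
#'   fragment (1 = a 1:1 decoy pool).
#' @param decoy_coelute_prob Fraction of decoys that co-elute near the
#'   precursor apex (interference from other species in the multiplexed
#'   window); the rest elute at uniform random positions.
#' @param intensity_lognormal_params Meanlog and sdlog of the precursor
#'   total-intensity distribution.
#' @param frag_lognormal_params Meanlog and sdlog of the per-fragment
#'   relative intensity factor.
#' @param frag_detect_prob Probability that a theoretical b/y fragment is
#'   detected as a fragment feature.
#' @param apex_offset_sd Standard deviation (cycles) of the rounded
#'   Gaussian apex offset between a fragment and its precursor; 0 gives
#'   exact co-apex elution.
#' @param mass_noise_ppm Gaussian mass error (ppm) applied to detected
#'   fragment masses.
#' @param min_apex_separation Minimum apex separation (cycles) enforced
#'   between precursors sharing an isolation window; co-isolated precursors
#'   rarely share an elution apex in practice, and the pipeline's known
#'   failure mode under exact precursor co-elution is studied separately.
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1, n_cycles = 120, n_windows = 20,
                       window_width = 4, mz_range = c(720, 800),
                       n_proteoforms = 25, seq_len_range = c(70, 140),
                       elution_sigma = 2, charge_range = c(5, 30),
                       decoy_fragment_rate = 1,
                       decoy_coelute_prob = 0.3,
                       intensity_lognormal_params = c(16, 1),
                       frag_lognormal_params = c(-3, 1),
                       frag_detect_prob = 0.8,
                       apex_offset_sd = 1, mass_noise_ppm = 2,
                       min_apex_separation = 8) {
  if (abs(n_windows * window_width - diff(mz_range)) > 1e-9)
    stop("isolation windows must tile mz_range exactly")
  if (n_cycles < 2 * ceiling(3 * elution_sigma) + 2)
    stop("n_cycles too small for the elution width")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

.sim_profile <- function(mu, sigma, k, total) {
  lo <- max(1L, as.integer(round(mu - 3 * sigma)))
  hi <- min(k, as.integer(round(mu + 3 * sigma)))
  cyc <- lo:hi
  v <- stats::dnorm(cyc, mu, sigma)
  list(cycles = cyc, intensities = v / sum(v) * total)
}

#' Simulate a DIA run with ground-truth provenance
#'
#' Draws random unmodified proteoform sequences, places each precursor at
#' an m/z inside one isolation window, gives it a Gaussian elution profile
#' over cycles, samples detected true fragments from its theoretical b/y
#' masses (with small mass error, near-co-apex elution and intensities
#' proportional to the precursor), and adds decoy fragments with random
#' masses and elution at \code{decoy_fragment_rate} per true fragment.
#' A fixed seed makes the output (and the tables written from it)
#' byte-identical across calls.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return List with elements \code{scpfs} (list of \code{\link{scpf}}),
#'   \code{fragments} (list of \code{\link{fragment_feature}}),
#'   \code{windows} (an \code{\link{isolation_windows}} table) and
#'   \code{truth}: \code{provenance} (named vector, frag_id to scpf_id or
#'   \code{NA} for decoys), \code{sequences}, \code{scpf_windows} and
#'   \code{by_masses} per SCPF.
#' @export
simulate_run <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  proton <- 1.007276
  k <- cfg$n_cycles
  bounds <- seq(cfg$mz_range[1], cfg$mz_range[2], by = cfg$window_width)
  windows <- isolation_windows(sprintf("W%02d", seq_len(cfg$n_windows)),
                               bounds[-length(bounds)], bounds[-1])
  margin <- ceiling(3 * cfg$elution_sigma) + 1L
  residues <- names(.residue_masses)
  scpfs <- vector("list", cfg$n_proteoforms)
  frag_list <- list()
  provenance <- character(0)
  sequences <- character(0)
  scpf_windows <- character(0)
  by_masses <- list()
  window_apexes <- stats::setNames(vector("list", nrow(windows)),
                                   windows$window_id)
  frag_n <- 0L
  for (i in seq_len(cfg$n_proteoforms)) {
    # redraw sequences whose mass admits no integer charge inside the
    # precursor m/z range (short sequences can fall between charge states)
    z_cands <- integer(0)
    for (try in 1:200) {
      len <- sample(cfg$seq_len_range[1]:cfg$seq_len_range[2], 1L)
      seqstr <- paste(sample(residues, len, replace = TRUE), collapse = "")
      m <- sequence_mass(seqstr)
      z_lo <- max(floor(m / (cfg$mz_range[2] - proton)) + 1L,
                  cfg$charge_range[1])
      z_hi <- min(floor(m / (cfg$mz_range[1] - proton)),
                  cfg$charge_range[2])
      if (z_lo <= z_hi) {
        z_cands <- z_lo:z_hi
        break
      }
    }
    if (length(z_cands) == 0L)
      stop("infeasible m/z placement: adjust seq_len_range or charge_range")
    z <- if (length(z_cands) == 1L) z_cands else sample(z_cands, 1L)
    mz <- m / z + proton
    win <- windows$window_id[findInterval(mz, bounds,
                                          rightmost.closed = FALSE)]
    apex <- NA_integer_
    for (try in 1:200) {
      cand <- sample(margin:(k - margin), 1L)
      if (all(abs(cand - window_apexes[[win]]) >= cfg$min_apex_separation)) {
        apex <- cand
        break
      }
    }
    if (is.na(apex))
      stop("infeasible apex placement: too many precursors per window")
    window_apexes[[win]] <- c(window_apexes[[win]], apex)
    prec_int <- stats::rlnorm(1, cfg$intensity_lognormal_params[1],
                              cfg$intensity_lognormal_params[2])
    prof <- .sim_profile(apex, cfg$elution_sigma, k, prec_int)
    sid <- sprintf("P%03d", i)
    scpfs[[i]] <- scpf(sid, paste0("feat_", sid), z, m, mz,
                       build_xic(prof$cycles, prof$intensities, k),
                       window_id = win)
    sequences[sid] <- seqstr
    scpf_windows[sid] <- win
    theo <- theoretical_by_masses(seqstr)
    by_masses[[sid]] <- theo
    detected <- theo[stats::runif(length(theo)) < cfg$frag_detect_prob]
    n_true <- length(detected)
    for (fm in detected) {
      frag_n <- frag_n + 1L
      fid <- sprintf("F%05d", frag_n)
      obs_mass <- fm * (1 + stats::rnorm(1, 0, cfg$mass_noise_ppm * 1e-6))
      offset <- as.integer(round(stats::rnorm(1, 0, cfg$apex_offset_sd)))
      mu_f <- min(max(apex + offset, 1L), k)
      sig_f <- cfg$elution_sigma * stats::runif(1, 0.9, 1.1)
      fint <- prec_int * stats::rlnorm(1, cfg$frag_lognormal_params[1],
                                       cfg$frag_lognormal_params[2])
      fprof <- .sim_profile(mu_f, sig_f, k, fint)
      fz <- max(1L, min(z, as.integer(round(obs_mass / m * z))))
      frag_list[[frag_n]] <- fragment_feature(
        fid, win, obs_mass, fz,
        build_xic(fprof$cycles, fprof$intensities, k))
      provenance[fid] <- sid
    }
    n_decoy <- round(cfg$decoy_fragment_rate * n_true)
    if (n_decoy > 0) for (d in seq_len(n_decoy)) {
      frag_n <- frag_n + 1L
      fid <- sprintf("F%05d", frag_n)
      dmass <- stats::runif(1, 200, m)
      dapex <- if (stats::runif(1) < cfg$decoy_coelute_prob)
        min(max(apex + as.integer(round(stats::rnorm(1, 0, 2))), 1L), k)
      else sample(margin:(k - margin), 1L)
      dint <- prec_int * stats::rlnorm(1, cfg$frag_lognormal_params[1],
                                       cfg$frag_lognormal_params[2])
      dprof <- .sim_profile(dapex, cfg$elution_sigma, k, dint)
      dz <- max(1L, min(z, as.integer(round(dmass / m * z))))
      frag_list[[frag_n]] <- fragment_feature(
        fid, win, dmass, dz,
        build_xic(dprof$cycles, dprof$intensities, k))
      provenance[fid] <- NA_character_
    }
  }
  list(scpfs = scpfs, fragments = frag_list, windows = windows,
       truth = list(provenance = provenance, sequences = sequences,
                    scpf_windows = scpf_windows, by_masses = by_masses))
}

#' Write a simulated run to a directory
#'
#' Emits \code{scpf.tsv} and \code{fragment.tsv} in the feature-table
#' format of \code{\link{read_feature_table}}, plus
#' \code{ground_truth.tsv} (fragment provenance) and
#' \code{sequences.tsv} (per-SCPF sequence and true window).
#'
#' @param sim Output of \code{\link{simulate_run}}.
#' @param dir Output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_sim_run <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_feature_table(sim$scpfs, file.path(dir, "scpf.tsv"), "scpf")
  write_feature_table(sim$fragments, file.path(dir, "fragment.tsv"),
                      "fragment")
  pv <- sim$truth$provenance
  writeLines(c("frag_id\tsource_scpf",
               sprintf("%s\t%s", names(pv), ifelse(is.na(pv), "decoy", pv))),
             file.path(dir, "ground_truth.tsv"))
  sq <- sim$truth$sequences
  writeLines(c("scpf_id\twindow_id\tsequence",
               sprintf("%s\t%s\t%s", names(sq),
                       sim$truth$scpf_windows[names(sq)], sq)),
             file.path(dir, "sequences.tsv"))
  invisible(dir)
}

#' Score demultiplexing output against simulator ground truth
#'
#' For every non-empty pseudo spectrum, the matched-fragment fraction is
#' the share of its assigned fragments whose true provenance is the
#' spectrum's SCPF. Aggregate precision is matched / assigned over all
#' spectra; recall is matched / all true fragments in the run. The pool's
#' true-fragment fraction (non-decoy share of the multiplexed fragment
#' pool) is reported as the undemultiplexed baseline.
#'
#' @param pseudo List of \code{\link{pseudo_spectrum}} objects.
#' @param truth The \code{truth} element of \code{\link{simulate_run}}
#'   output.
#' @return List with \code{per_spectrum} (data frame: spectrum, scpf,
#'   assigned, matched, matched_fraction), \code{mean_matched_fraction},
#'   \code{precision}, \code{recall} and \code{pool_true_fraction}.
#' @export
evaluate_demux <- function(pseudo, truth) {
  pv <- truth$provenance
  rows <- lapply(pseudo, function(sp) {
    if (!sp$scpf_id %in% names(truth$sequences))
      stop(sprintf("unknown scpf_id %s", sp$scpf_id))
    fids <- sp$fragments$frag_id
    if (length(fids) && any(!fids %in% names(pv)))
      stop("pseudo spectrum references unknown fragment ids")
    matched <- sum(!is.na(pv[fids]) & pv[fids] == sp$scpf_id)
    data.frame(spectrum_id = sp$spectrum_id, scpf_id = sp$scpf_id,
               assigned = length(fids), matched = matched,
               matched_fraction = if (length(fids)) matched / length(fids)
                                  else NA_real_,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  assigned <- sum(per$assigned)
  matched <- sum(per$matched)
  n_true <- sum(!is.na(pv))
  list(per_spectrum = per,
       mean_matched_fraction = mean(per$matched_fraction, na.rm = TRUE),
       precision = if (assigned) matched / assigned else NA_real_,
       recall = if (n_true) matched / n_true else NA_real_,
       pool_true_fraction = mean(!is.na(pv)))
}
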