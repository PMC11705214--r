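# Shared fixtures: compact feature constructors, a hand-set scoring model,
# a cached trained model, and random-instance generators.

PROTON <- 1.007276

# SCPF with a triangular elution profile peaking at `apex`, observed in
# `c_cycles` cycles, total intensity `total`.
mk_scpf <- function(id, apex, c_cycles = 5, k = 30, total = 1000,
                    mass = 9000, charge = 10, window = "W01") {
  half <- (c_cycles - 1) %/% 2
  cyc <- (apex - half):(apex - half + c_cycles - 1)
  v <- pmax(1, half + 1 - abs(cyc - apex))
  v <- v / sum(v) * total
  scpf(id, paste0("feat_", id), charge, mass, mass / charge + PROTON,
       build_xic(cyc, v, k), window_id = window)
}

mk_frag <- function(id, apex, n_cycles = 3, k = 30, total = 100,
                    mass = 800, charge = 1, window = "W01") {
  half <- (n_cycles - 1) %/% 2
  cyc <- (apex - half):(apex - half + n_cycles - 1)
  v <- pmax(1, half + 1 - abs(cyc - apex))
  v <- v / sum(v) * total
  fragment_feature(id, window, mass, charge, build_xic(cyc, v, k))
}

# Deterministic hand-set logistic model (no training needed).
mk_model <- function(w = c(-1, 0.5, 3), b = -1) {
  structure(list(weights = stats::setNames(w, c("norm_intensity_rank",
                                                "norm_cycle_number",
                                                "shared_xic")),
                 bias = b,
                 features = c("norm_intensity_rank", "norm_cycle_number",
                              "shared_xic"),
                 fit = NULL, metrics = NULL),
            class = "pair_model")
}

.fixture_env <- new.env(parent = emptyenv())

# Model trained once on a simulated run with known sequences; cached for
# the whole test session.
trained_model <- function() {
  if (is.null(.fixture_env$model)) {
    sim <- simulate_run(sim_config(seed = 4242, n_proteoforms = 15))
    pairs <- build_training_pairs(sim$scpfs, sim$fragments,
                                  sim$truth$sequences)
    .fixture_env$model <- train_pair_model(pairs, seed = 4242)
  }
  .fixture_env$model
}

# Random window instance for oracle-equivalence checks: small masses so
# the round-3 budget binds, varied config regimes.
random_instance <- function(seed) {
  set.seed(seed)
  k <- 30
  n_s <- sample(1:5, 1)
  n_f <- sample(5:50, 1)
  scpfs <- lapply(seq_len(n_s), function(i)
    mk_scpf(sprintf("S%02d", i), apex = sample(8:(k - 8), 1),
            c_cycles = sample(3:9, 1), k = k,
            total = stats::runif(1, 100, 10000),
            mass = stats::runif(1, 1500, 4000),
            charge = sample(2:5, 1)))
  frags <- lapply(seq_len(n_f), function(i)
    mk_frag(sprintf("F%02d", i), apex = sample(5:(k - 5), 1),
            n_cycles = sample(1:7, 1), k = k,
            total = stats::runif(1, 10, 5000),
            mass = stats::runif(1, 300, 3500),
            charge = sample(1:3, 1)))
  cfg <- pipeline_config(t = sample(0:4, 1),
                         score_cutoff = sample(c(0.3, 0.55, 0.8), 1),
                         min_keep = sample(c(3, 5, 25), 1))
  list(bundle = window_bundle("W01", scpfs, frags), cfg = cfg)
}

# Independent step-by-step oracle of the greedy three-round cascade.
# Deliberately naive: explicit loops, apex positions recomputed from raw
# vectors, logistic evaluated by hand. Returns, per SCPF id, the sorted
# fragment ids assigned to it.
oracle_demux <- function(scpfs, frags, model, cfg) {
  ints <- sapply(scpfs, function(s) s$total_intensity)
  ids <- sapply(scpfs, function(s) s$scpf_id)
  scpfs <- scpfs[order(-ints, ids)]
  pool <- frags
  res <- list()
  for (s in scpfs) {
    apex_s <- which.max(s$xic$values)
    thr <- min(cfg$t, floor(sum(s$xic$values > 0) / 2))
    L <- Filter(function(f)
      abs(apex_s - which.max(f$xic$values)) <= thr, pool)
    kept <- list()
    if (length(L)) {
      n <- length(L)
      fint <- sapply(L, function(f) f$total_intensity)
      fid <- sapply(L, function(f) f$frag_id)
      rk <- integer(n); rk[order(-fint, fid)] <- seq_len(n)
      sc <- numeric(n)
      for (j in seq_len(n)) {
        x <- c(rk[j] / n,
               sum(L[[j]]$xic$values > 0) / sum(s$xic$values > 0),
               shared_xic(s$xic, L[[j]]$xic))
        sc[j] <- 1 / (1 + exp(-(model$bias + sum(model$weights * x))))
      }
      keep2 <- which(sc > cfg$score_cutoff)
      if (length(keep2) < cfg$min_keep)
        keep2 <- sort(order(-sc)[seq_len(min(cfg$min_keep, n))])
      Tb <- 2 * (max(2, round(s$neutral_mass / cfg$avg_residue_mass)) - 1)
      m2 <- sapply(L[keep2], function(f) f$neutral_mass)
      s2 <- sc[keep2]
      low <- which(m2 < cfg$low_mass_boundary)
      high <- which(m2 >= cfg$low_mass_boundary)
      kl <- low[order(-s2[low])][seq_len(min(min(cfg$min_keep, Tb),
                                             length(low)))]
      kh <- high[order(-s2[high])][seq_len(min(max(Tb - cfg$min_keep, 0),
                                               length(high)))]
      kept <- L[keep2[sort(c(kl, kh))]]
    }
    res[[s$scpf_id]] <- if (length(kept))
      sort(sapply(kept, function(f) f$frag_id)) else character(0)
    if (length(kept)) {
      used <- sapply(kept, function(f) f$frag_id)
      pool <- Filter(function(f) !(f$frag_id %in% used), pool)
    }
  }
  res
}

# Assigned fragment ids per SCPF from pseudo spectra, in oracle form.
assigned_ids <- function(pseudo) {
  res <- lapply(pseudo, function(sp)
    if (nrow(sp$fragments)) sort(sp$fragments$frag_id) else character(0))
  names(res) <- sapply(pseudo, function(sp) sp$scpf_id)
  res
}
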