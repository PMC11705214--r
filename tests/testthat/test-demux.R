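test_that("round 1 threshold is min(t, floor(c/2)) on an exhaustive grid", {
  k <- 40
  for (t in 0:5) {
    for (c_cycles in 1:12) {
      s <- mk_scpf("P1", apex = 20, c_cycles = c_cycles, k = k)
      thr <- min(t, floor(c_cycles / 2))
      for (d in 0:8) {
        pool <- list(mk_frag("F1", apex = 20 + d, k = k))
        kept <- round1_filter(s, pool, t)
        expect_equal(length(kept), as.integer(d <= thr),
                     info = sprintf("t=%d c=%d d=%d", t, c_cycles, d))
      }
    }
  }
  # distance 0 is kept for any t and c
  s <- mk_scpf("P1", apex = 20, c_cycles = 1)
  expect_length(round1_filter(s, list(mk_frag("F1", 20)), t = 0), 1)
})

test_that("round 2 keeps above-cutoff scores with a top-k fallback", {
  sel <- diademux:::.round2_select
  # 40 features all scoring 0.9: all pass
  expect_equal(sel(rep(0.9, 40), 0.55, 25), 1:40)
  # 30 features, 10 above cutoff: fallback reports the top 25 by score
  sc <- c(runif(20, 0.1, 0.5), runif(10, 0.6, 0.9))
  set.seed(41); sc <- sample(sc)
  kept <- sel(sc, 0.55, 25)
  expect_length(kept, 25)
  expect_setequal(kept, order(-sc)[1:25])
  # |L| = 8 and nothing above cutoff: all 8 come back
  expect_setequal(sel(runif(8, 0, 0.4), 0.55, 25), 1:8)

  # exhaustive small grid against a direct enumeration oracle
  set.seed(42)
  for (n in c(1, 5, 24, 25, 26, 40)) {
    for (cutoff in c(0.3, 0.55, 0.8)) {
      for (min_keep in c(3, 25)) {
        sc <- runif(n)
        kept <- sel(sc, cutoff, min_keep)
        pass <- which(sc > cutoff)
        if (length(pass) >= min_keep) expect_identical(kept, pass)
        else {
          expect_length(kept, min(min_keep, n))
          # kept are the highest-scoring members of L
          expect_true(min(sc[kept]) >= max(sc[-kept], -Inf))
        }
      }
    }
  }
})

test_that("round 2 fallback operates through the public interface", {
  s <- mk_scpf("P1", apex = 20, c_cycles = 7, k = 40)
  pool <- lapply(1:30, function(i) mk_frag(sprintf("F%02d", i), apex = 20,
                                           n_cycles = 3, k = 40,
                                           total = i * 10))
  # weights 0 with large negative bias: every score ~0, fallback engages
  kept <- round2_filter(pool, s, mk_model(w = c(0, 0, 0), b = -5),
                        cutoff = 0.55, min_keep = 25)
  expect_length(kept, 25)
  # high bias: everything passes
  kept2 <- round2_filter(pool, s, mk_model(w = c(0, 0, 0), b = 5),
                         cutoff = 0.55, min_keep = 25)
  expect_length(kept2, 30)
})

test_that("round 3 quotas split the budget across mass groups", {
  # T=60 with 30 low + 50 high candidates: 25 low + 35 high survive
  set.seed(43)
  masses <- c(runif(30, 300, 1499), runif(50, 1500, 9000))
  scores <- runif(80)
  kept <- round3_filter(masses, scores, T_budget = 60)
  expect_length(kept, 60)
  expect_equal(sum(masses[kept] < 1500), 25)
  expect_equal(sum(masses[kept] >= 1500), 35)
  # the survivors are the top scorers of each group
  expect_setequal(kept[masses[kept] < 1500],
                  which(masses < 1500)[order(-scores[masses < 1500])][1:25])

  # under budget: everything kept
  m2 <- c(runif(5, 300, 1000), runif(5, 2000, 5000))
  expect_length(round3_filter(m2, runif(10), T_budget = 60), 10)

  # T=20 < low quota: high quota clamps to 0, low capped at T
  kept3 <- round3_filter(masses, scores, T_budget = 20)
  expect_length(kept3, 20)
  expect_true(all(masses[kept3] < 1500))

  # exhaustive grid against quota arithmetic
  for (T_budget in c(0, 10, 24, 25, 26, 60, 300)) {
    kept <- round3_filter(masses, scores, T_budget)
    expect_length(kept, min(min(25, T_budget), 30) +
                    min(max(T_budget - 25, 0), 50))
  }
})

test_that("the Averagine budget follows T = 2(l - 1)", {
  b <- estimate_budget(11885.99)
  expect_equal(b$l, 107)
  expect_equal(b$T, 212)
  expect_equal(estimate_budget(10000), list(l = 90, T = 178))
  # degenerate clamp at l = 2
  expect_equal(estimate_budget(111.1254), list(l = 2, T = 2))
  expect_equal(estimate_budget(1), list(l = 2, T = 2))
  expect_error(estimate_budget(-5), "positive")
})

test_that("greedy generation assigns co-apex fragments and consumes them", {
  k <- 40
  model <- mk_model()
  cfg <- pipeline_config()
  # one SCPF, five co-apex fragments, no decoys: all five assigned
  s <- mk_scpf("P1", apex = 20, c_cycles = 7, k = k, mass = 5000)
  pool <- lapply(1:5, function(i) mk_frag(sprintf("F%d", i), apex = 20,
                                          n_cycles = 5, k = k,
                                          mass = 500 * i))
  out <- generate_pseudo_spectra(window_bundle("W01", list(s), pool),
                                 model, cfg)
  expect_length(out, 1)
  expect_setequal(out[[1]]$fragments$frag_id, paste0("F", 1:5))
  expect_equal(out[[1]]$fragments$mass, sort(500 * 1:5)) # sorted by mass

  # two SCPFs sharing a co-eluting fragment: only the more intense one
  # gets it
  s1 <- mk_scpf("P1", apex = 20, c_cycles = 7, k = k, total = 5000,
                mass = 5000)
  s2 <- mk_scpf("P2", apex = 20, c_cycles = 7, k = k, total = 1000,
                mass = 5000)
  shared <- mk_frag("Fshared", apex = 20, n_cycles = 5, k = k, mass = 900)
  out2 <- generate_pseudo_spectra(
    window_bundle("W01", list(s2, s1), list(shared)), model, cfg)
  expect_equal(out2[[1]]$scpf_id, "P1") # processed in intensity order
  expect_equal(out2[[1]]$fragments$frag_id, "Fshared")
  expect_equal(nrow(out2[[2]]$fragments), 0) # emitted but empty
})

test_that("greedy generation equals the independent cascade oracle", {
  model <- mk_model()
  for (seed in 1:60) {
    inst <- random_instance(seed)
    got <- assigned_ids(generate_pseudo_spectra(inst$bundle, model,
                                                inst$cfg))
    want <- oracle_demux(inst$bundle$scpfs, inst$bundle$fragments, model,
                         inst$cfg)
    expect_identical(got[names(want)], want, info = paste("seed", seed))
  }
})

test_that("run-level demultiplexing is window-disjoint and order-invariant", {
  model <- trained_model()
  sim <- simulate_run(sim_config(seed = 51, n_proteoforms = 20))
  bundles <- make_bundles(sim$scpfs, sim$fragments)
  out <- run_demux(bundles, model)

  # empty run
  expect_length(run_demux(list(), model), 0)

  # fragment disjointness within every window
  by_window <- split(out, sapply(out, `[[`, "window_id"))
  for (grp in by_window) {
    ids <- unlist(lapply(grp, function(sp) sp$fragments$frag_id))
    expect_false(anyDuplicated(ids) > 0)
  }
  # spectrum ids unique across the run
  expect_false(anyDuplicated(sapply(out, `[[`, "spectrum_id")) > 0)

  # every assigned fragment satisfies its SCPF's round-1 distance bound
  scpf_by_id <- setNames(sim$scpfs, sapply(sim$scpfs, `[[`, "scpf_id"))
  frag_by_id <- setNames(sim$fragments,
                         sapply(sim$fragments, `[[`, "frag_id"))
  for (sp in out) {
    s <- scpf_by_id[[sp$scpf_id]]
    thr <- min(3, floor(s$cycle_count / 2))
    for (fid in sp$fragments$frag_id)
      expect_lte(apex_cycle_distance(s$xic, frag_by_id[[fid]]$xic), thr)
    # budget bound on spectrum size
    Tb <- estimate_budget(s$neutral_mass)$T
    expect_lte(nrow(sp$fragments), max(Tb, 25))
  }

  # permuting window processing order leaves the output invariant
  out_perm <- run_demux(rev(bundles), model)
  expect_equal(assigned_ids(out), assigned_ids(out_perm))

  # unsorted SCPF lists are rejected
  b <- bundles[[which(sapply(bundles, function(b) length(b$scpfs)) > 1)[1]]]
  b$scpfs <- rev(b$scpfs)
  expect_error(generate_pseudo_spectra(b, model), "sorted")
})
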