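test_that("normalized intensity rank matches a full-sort oracle", {
  set.seed(31)
  pool <- lapply(1:50, function(i)
    mk_frag(sprintf("F%02d", i), apex = 10,
            total = sample(c(10, 50, 100, 500), 1))) # deliberate ties
  int <- sapply(pool, function(f) f$total_intensity)
  ids <- sapply(pool, function(f) f$frag_id)
  for (i in seq_along(pool)) {
    # oracle: position of i in the list sorted by (-intensity, id)
    ord <- order(-int, ids)
    expect_equal(norm_intensity_rank(pool[[i]], pool),
                 which(ord == i) / 50)
  }
  expect_equal(norm_intensity_rank(pool[[1]], pool[1]), 1.0)
  expect_error(norm_intensity_rank(mk_frag("zz", 5), pool), "not a member")
})

test_that("most intense of 10 has normalized rank 0.1", {
  pool <- lapply(1:10, function(i) mk_frag(sprintf("F%02d", i), 10,
                                           total = 100 + i))
  expect_equal(norm_intensity_rank(pool[[10]], pool), 0.1)
})

test_that("normalized cycle number is the uncapped support ratio", {
  s <- mk_scpf("P1", apex = 15, c_cycles = 8)
  expect_equal(norm_cycle_number(mk_frag("F1", 15, n_cycles = 4), s), 0.5)
  expect_equal(norm_cycle_number(mk_frag("F1", 15, n_cycles = 8), s), 1.0)
  s4 <- mk_scpf("P1", apex = 15, c_cycles = 4)
  expect_equal(norm_cycle_number(mk_frag("F1", 15, n_cycles = 6), s4), 1.5)
})

test_that("shared XIC behaves as a normalized overlap area", {
  x1 <- build_xic(5:9, c(1, 4, 8, 4, 1), 20)
  expect_equal(shared_xic(x1, x1), 1.0, tolerance = 1e-9)

  # scale invariance in each argument and symmetry
  x2 <- build_xic(6:10, c(2, 5, 9, 5, 2), 20)
  expect_equal(shared_xic(x1, x2),
               shared_xic(x1, build_xic(6:10, 7 * c(2, 5, 9, 5, 2), 20)))
  expect_equal(shared_xic(x1, x2), shared_xic(x2, x1))
  expect_gte(shared_xic(x1, x2), 0)
  expect_lte(shared_xic(x1, x2), 1)

  # supports separated by an empty cycle share nothing
  expect_equal(shared_xic(build_xic(2, 5, 10), build_xic(5:6, c(1, 1), 10)),
               0.0)
})

test_that("shared XIC matches a 10x-finer integration oracle", {
  # reference: trapezoid integration of the pointwise minimum of the two
  # area-normalized linear interpolants on a 100-points-per-cycle grid
  fine_oracle <- function(v1, v2) {
    sup <- c(which(v1 > 0), which(v2 > 0))
    g <- seq(min(sup), max(sup), by = 0.01)
    f1 <- approx(seq_along(v1), v1, g)$y
    f2 <- approx(seq_along(v2), v2, g)$y
    tz <- function(y) sum(diff(g) * (y[-1] + y[-length(y)]) / 2)
    tz(pmin(f1 / tz(f1), f2 / tz(f2)))
  }
  v1 <- c(0, 4, 8, 4, 0)
  v2 <- c(0, 0, 8, 8, 0)
  expect_lt(abs(shared_xic(xic(v1), xic(v2)) - fine_oracle(v1, v2)), 1e-3)

  set.seed(33)
  for (i in 1:30) {
    a <- numeric(12); b <- numeric(12)
    ia <- sample(12, sample(2:6, 1)); a[ia] <- runif(length(ia), 0.1, 5)
    ib <- sample(12, sample(2:6, 1)); b[ib] <- runif(length(ib), 0.1, 5)
    expect_lt(abs(shared_xic(xic(a), xic(b)) - fine_oracle(a, b)), 5e-3)
  }
})

test_that("pair scores evaluate the logistic closed form", {
  m0 <- mk_model(w = c(0, 0, 0), b = 0)
  expect_equal(score_pair(c(0.3, 2, 0.9), m0), 0.5)

  m <- mk_model(w = c(-1, 1, 2), b = 0)
  expect_equal(score_pair(c(0.5, 1, 0.75), m), 1 / (1 + exp(-2)),
               tolerance = 1e-9)

  # monotone in shared_xic under a positive weight
  xs <- data.frame(norm_intensity_rank = 0.5, norm_cycle_number = 1,
                   shared_xic = seq(0, 1, by = 0.1))
  expect_true(all(diff(score_pair(xs, m)) > 0))
})

test_that("theoretical b/y masses follow the residue-sum definition", {
  ag <- theoretical_by_masses("AG")
  expect_equal(sort(ag), sort(c(71.03711, 75.032025)), tolerance = 1e-6)

  # complementarity: b_i + y_(n-i) equals the precursor neutral mass
  seqs <- c("PEPTIDE", "ACDEFGHIKLMNPQRSTVWY", "GGGG")
  for (sq in seqs) {
    res <- strsplit(sq, "")[[1]]
    n <- length(res)
    masses <- theoretical_by_masses(sq)
    expect_length(masses, 2 * (n - 1))
    # rebuild b and y series with an independent per-residue accumulation
    tab <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
             V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
             I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
             K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
             F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
    b <- y <- numeric(0)
    acc <- 0
    for (i in 1:(n - 1)) { acc <- acc + tab[[res[i]]]; b <- c(b, acc) }
    acc <- 18.010565
    for (i in n:2) { acc <- acc + tab[[res[i]]]; y <- c(y, acc) }
    expect_equal(masses, sort(c(b, y)), tolerance = 1e-5)
    prec <- sequence_mass(sq)
    for (i in 1:(n - 1)) expect_equal(b[i] + y[n - i], prec,
                                      tolerance = 1e-9)
  }
  expect_error(theoretical_by_masses("AXG"), "unknown residue")
  expect_error(theoretical_by_masses("A"), "at least two")
})

test_that("pair labeling matches b/y masses within ppm tolerance", {
  sq <- "MKVLAEDTRGFNQW"
  theo <- theoretical_by_masses(sq)
  pairs <- data.frame(
    scpf_id = "P1",
    frag_mass = c(theo[3], theo[5] * (1 + 100e-6), theo[8] * (1 + 5e-6)))
  out <- label_pairs(pairs, c(P1 = sq), tol_ppm = 10)
  expect_equal(out$label, c("positive", "negative", "positive"))
  expect_error(label_pairs(pairs, c(P1 = "")), "empty")
})

test_that("simulator labels agree with ground-truth provenance", {
  sim <- simulate_run(sim_config(seed = 35, n_proteoforms = 6,
                                 seq_len_range = c(40, 60)))
  pairs <- build_training_pairs(sim$scpfs, sim$fragments,
                                sim$truth$sequences)
  pv <- sim$truth$provenance
  own <- !is.na(pv[pairs$frag_id]) & pv[pairs$frag_id] == pairs$scpf_id
  # every fragment paired with its own precursor is labeled positive
  expect_true(all(pairs$label[own] == "positive"))
  # decoys are negative unless their random mass collides with a b/y mass
  decoy <- is.na(pv[pairs$frag_id])
  collided <- vapply(which(decoy), function(i) {
    theo <- sim$truth$by_masses[[pairs$scpf_id[i]]]
    any(abs(pairs$frag_mass[i] - theo) <= 10e-6 * theo)
  }, logical(1))
  expect_true(all(pairs$label[which(decoy)[!collided]] == "negative"))
})

test_that("training is reproducible and separates separable classes", {
  set.seed(36)
  n <- 600
  x <- c(runif(n / 2, 0.6, 1), runif(n / 2, 0, 0.4))
  pairs <- data.frame(x = x, label = rep(c("positive", "negative"),
                                         each = n / 2))
  # a perfectly separable fit triggers glm's saturation warning by design
  m1 <- suppressWarnings(train_pair_model(pairs, seed = 5, features = "x"))
  m2 <- suppressWarnings(train_pair_model(pairs, seed = 5, features = "x"))
  expect_identical(coef(m1), coef(m2))
  expect_gte(m1$metrics$balanced_accuracy, 0.95)
  expect_gte(m1$metrics$auc, 0.99)

  expect_error(train_pair_model(transform(pairs, label = "positive"),
                                features = "x"), "both")
})
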