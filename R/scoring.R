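# Pair scoring: the three chromatographic attributes of an SCPF-fragment
# candidate pair, the logistic model over them, and the training harness
# with b/y-ion labeling.

#' Normalized intensity rank of a fragment feature
#'
#' Rank of the fragment when the candidate list is sorted by decreasing
#' total intensity (1 = most intense; ties broken by ascending frag_id),
#' divided by the list size. Lies in (0, 1].
#'
#' @param frag A \code{\link{fragment_feature}} that is a member of
#'   \code{pool}.
#' @param pool List of \code{\link{fragment_feature}} objects (the round-1
#'   survivor list \code{L}).
#' @return The normalized rank.
#' @export
norm_intensity_rank <- function(frag, pool) {
  ranks <- .intensity_ranks(pool)
  i <- match(frag$frag_id, vapply(pool, `[[`, character(1), "frag_id"))
  if (is.na(i)) stop("fragment is not a member of the candidate list")
  ranks[i] / length(pool)
}

# rank positions for a fragment pool, decreasing intensity, frag_id ties
.intensity_ranks <- function(pool) {
  int <- vapply(pool, `[[`, numeric(1), "total_intensity")
  ids <- vapply(pool, `[[`, character(1), "frag_id")
  ord <- order(-int, ids)
  ranks <- integer(length(pool))
  ranks[ord] <- seq_along(pool)
  ranks
}

#' Normalized cycle number of a fragment feature
#'
#' Number of cycles in which the fragment is observed divided by the number
#' of cycles in which the SCPF is observed. Deliberately uncapped, so
#' values above 1 are possible for long-eluting fragments.
#'
#' @param frag A \code{\link{fragment_feature}}.
#' @param scpf An \code{\link{scpf}} with \code{cycle_count >= 1}.
#' @return The ratio.
#' @export
norm_cycle_number <- function(frag, scpf) {
  if (scpf$cycle_count < 1L) stop("SCPF observed in no cycle")
  length(frag$xic$support) / scpf$cycle_count
}

#' Shared area under two normalized XICs
#'
#' Both chromatograms are linearly interpolated onto a uniform grid
#' spanning the union of their supports (\code{points_per_cycle}
#' subdivisions per cycle), each curve is normalized to unit area
#' (trapezoid rule), and the trapezoid integral of the pointwise minimum is
#' returned. The result lies in [0, 1]: 1 for identical elution shapes,
#' 0 for supports separated by at least one empty cycle.
#'
#' @param x1,x2 \code{\link{xic}} objects with non-empty support.
#' @param points_per_cycle Grid density (subdivisions per cycle index).
#' @return Shared area in [0, 1].
#' @export
shared_xic <- function(x1, x2, points_per_cycle = 10) {
  stopifnot(inherits(x1, "xic"), inherits(x2, "xic"))
  if (!length(x1$support) || !length(x2$support))
    stop("shared XIC undefined for an XIC with empty support")
  lo <- min(x1$support[1L], x2$support[1L])
  hi <- max(x1$support[length(x1$support)], x2$support[length(x2$support)])
  if (lo == hi) return(1)
  grid <- seq(lo, hi, by = 1 / points_per_cycle)
  y1 <- stats::approx(seq_len(x1$k), x1$values, xout = grid)$y
  y2 <- stats::approx(seq_len(x2$k), x2$values, xout = grid)$y
  a1 <- .trapz(grid, y1)
  a2 <- .trapz(grid, y2)
  if (a1 <= 0 || a2 <= 0)
    stop("shared XIC undefined for a zero-area XIC on the common grid")
  .trapz(grid, pmin(y1 / a1, y2 / a2))
}

.trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

#' Feature triples for all SCPF-fragment candidate pairs
#'
#' Computes the three model attributes (normalized intensity rank,
#' normalized cycle number, shared XIC) of every fragment in a candidate
#' list against one SCPF.
#'
#' @param scpf An \code{\link{scpf}}.
#' @param pool List of \code{\link{fragment_feature}} objects.
#' @param points_per_cycle Grid density for \code{\link{shared_xic}}.
#' @return Data frame with one row per fragment: \code{scpf_id},
#'   \code{frag_id}, \code{frag_mass}, \code{norm_intensity_rank},
#'   \code{norm_cycle_number}, \code{shared_xic}.
#' @export
pair_features <- function(scpf, pool, points_per_cycle = 10) {
  n <- length(pool)
  if (n == 0L)
    return(data.frame(scpf_id = character(), frag_id = character(),
                      frag_mass = numeric(), norm_intensity_rank = numeric(),
                      norm_cycle_number = numeric(), shared_xic = numeric(),
                      stringsAsFactors = FALSE))
  ranks <- .intensity_ranks(pool)
  data.frame(
    scpf_id = scpf$scpf_id,
    frag_id = vapply(pool, `[[`, character(1), "frag_id"),
    frag_mass = vapply(pool, `[[`, numeric(1), "neutral_mass"),
    norm_intensity_rank = ranks / n,
    norm_cycle_number = vapply(pool, norm_cycle_number, numeric(1),
                               scpf = scpf),
    shared_xic = vapply(pool, function(f)
      shared_xic(scpf$xic, f$xic, points_per_cycle), numeric(1)),
    stringsAsFactors = FALSE)
}

#' Score feature triples with a logistic model
#'
#' Evaluates \code{1 / (1 + exp(-(w . x + b)))} for each row of feature
#' values.
#'
#' @param x Numeric vector of length 3, or a matrix / data frame whose
#'   columns include the model's feature names.
#' @param model A \code{"pair_model"} (from \code{\link{train_pair_model}}
#'   or \code{\link{read_pair_model}}).
#' @return Scores in (0, 1).
#' @export
score_pair <- function(x, model) {
  stopifnot(inherits(model, "pair_model"))
  if (is.null(dim(x))) {
    if (length(x) != length(model$weights))
      stop("feature vector length does not match the model")
    x <- matrix(x, nrow = 1L, dimnames = list(NULL, model$features))
  }
  x <- as.matrix(as.data.frame(x)[, model$features, drop = FALSE])
  as.numeric(stats::plogis(model$bias + x %*% model$weights))
}

# Monoisotopic masses of the 20 standard amino-acid residues (Da).
.residue_masses <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)

.water_mass <- 18.010565

#' Theoretical b/y fragment neutral masses of a residue sequence
#'
#' For an unmodified sequence of length n: b_i is the sum of the first i
#' residue monoisotopic masses (1 <= i <= n-1) and y_i is the sum of the
#' last i residue masses plus one water.
#'
#' @param sequence Character string over the 20 standard one-letter residue
#'   codes, length >= 2.
#' @return Sorted numeric vector of the 2(n-1) neutral fragment masses.
#' @export
theoretical_by_masses <- function(sequence) {
  res <- strsplit(toupper(sequence), "")[[1]]
  if (length(res) < 2L) stop("sequence must have at least two residues")
  m <- .residue_masses[res]
  if (any(is.na(m)))
    stop(sprintf("unknown residue '%s'", res[which(is.na(m))[1]]))
  cum <- cumsum(m)
  n <- length(m)
  b <- cum[seq_len(n - 1L)]
  y <- cum[n] - cum[seq_len(n - 1L)] + .water_mass
  sort(unname(c(b, y)))
}

#' Neutral precursor mass of a residue sequence
#'
#' Sum of residue monoisotopic masses plus one water.
#'
#' @inheritParams theoretical_by_masses
#' @return Neutral monoisotopic mass (Da).
#' @export
sequence_mass <- function(sequence) {
  res <- strsplit(toupper(sequence), "")[[1]]
  m <- .residue_masses[res]
  if (any(is.na(m)))
    stop(sprintf("unknown residue '%s'", res[which(is.na(m))[1]]))
  sum(m) + .water_mass
}

#' Label candidate pairs against identified proteoform sequences
#'
#' A pair is labeled positive when the fragment's neutral mass matches any
#' theoretical b- or y-ion mass of its SCPF's identified (unmodified)
#' sequence within \code{tol_ppm} parts per million (relative to the
#' theoretical mass), and negative otherwise.
#'
#' @param pairs Data frame with columns \code{scpf_id} and
#'   \code{frag_mass}, e.g. from \code{\link{pair_features}}.
#' @param sequences Named character vector mapping \code{scpf_id} to its
#'   proteoform residue sequence.
#' @param tol_ppm Mass tolerance in ppm.
#' @return \code{pairs} with a \code{label} column
#'   (\code{"positive"} / \code{"negative"}).
#' @export
label_pairs <- function(pairs, sequences, tol_ppm = 10) {
  if (any(!nzchar(sequences))) stop("empty proteoform sequence")
  by_masses <- lapply(sequences, theoretical_by_masses)
  lab <- vapply(seq_len(nrow(pairs)), function(i) {
    theo <- by_masses[[pairs$scpf_id[i]]]
    if (is.null(theo))
      stop(sprintf("no sequence for scpf_id %s", pairs$scpf_id[i]))
    any(abs(pairs$frag_mass[i] - theo) <= tol_ppm * 1e-6 * theo)
  }, logical(1))
  pairs$label <- ifelse(lab, "positive", "negative")
  pairs
}

#' Train the logistic pair-scoring model
#'
#' Fits an unregularized logistic regression (maximum likelihood via
#' \code{\link[stats]{glm}}) of the pair label on the three attributes,
#' using a random 70:30 train/test split, and reports balanced accuracy
#' (at probability 0.5) and ROC AUC on the held-out 30\%.
#'
#' @param pairs Data frame with the feature columns and a \code{label}
#'   column coded \code{"positive"} / \code{"negative"} (both classes must
#'   be present in the training split).
#' @param split Fraction of rows used for training.
#' @param seed Integer seed fixing the split.
#' @param features Feature column names, in model order.
#' @return An object of class \code{"pair_model"} with elements
#'   \code{weights}, \code{bias}, \code{features}, \code{fit} (the glm),
#'   and \code{metrics} (balanced accuracy, AUC, split sizes).
#' @export
train_pair_model <- function(pairs, split = 0.7, seed = 1,
                             features = c("norm_intensity_rank",
                                          "norm_cycle_number",
                                          "shared_xic")) {
  if (!"label" %in% names(pairs)) stop("pairs must carry a label column")
  miss <- setdiff(features, names(pairs))
  if (length(miss))
    stop(sprintf("missing feature column(s): %s",
                 paste(miss, collapse = ", ")))
  y <- pairs$label == "positive"
  if (length(unique(y)) < 2L)
    stop("training requires both positive and negative pairs")
  n <- nrow(pairs)
  set.seed(seed)
  idx <- sample.int(n, size = floor(split * n))
  train <- pairs[idx, , drop = FALSE]
  test <- pairs[-idx, , drop = FALSE]
  if (length(unique(train$label)) < 2L)
    stop("training split contains a single class")
  dat <- cbind(train[, features, drop = FALSE],
               .y = as.integer(train$label == "positive"))
  fit <- stats::glm(stats::reformulate(features, ".y"),
                    family = stats::binomial(), data = dat)
  w <- stats::coef(fit)
  model <- structure(
    list(weights = w[features], bias = unname(w["(Intercept)"]),
         features = features, fit = fit, metrics = NULL,
         seed = seed, split = split),
    class = "pair_model")
  if (nrow(test)) {
    p <- score_pair(test, model)
    truth <- test$label == "positive"
    model$metrics <- list(
      balanced_accuracy = balanced_accuracy(truth, p >= 0.5),
      auc = if (length(unique(truth)) == 2L) roc_auc(truth, p) else NA_real_,
      n_train = nrow(train), n_test = nrow(test))
  }
  model
}

#' Balanced accuracy
#'
#' Mean of sensitivity and specificity.
#'
#' @param truth Logical vector of true class memberships.
#' @param predicted Logical vector of predicted memberships.
#' @return Balanced accuracy in [0, 1].
#' @export
balanced_accuracy <- function(truth, predicted) {
  sens <- mean(predicted[truth])
  spec <- mean(!predicted[!truth])
  (sens + spec) / 2
}

#' Area under the ROC curve
#'
#' Thin wrapper over \code{\link[pROC]{roc}} with a fixed direction so that
#' higher scores indicate the positive class.
#'
#' @param truth Logical vector of true class memberships.
#' @param score Numeric scores.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(truth, score) {
  as.numeric(pROC::auc(pROC::roc(response = truth, predictor = score,
                                 levels = c(FALSE, TRUE), direction = "<",
                                 quiet = TRUE)))
}

#' @export
print.pair_model <- function(x, ...) {
  cat("Logistic SCPF-fragment pair model\n")
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  cat("  weights: ", paste(sprintf("%.4f", x$weights), collapse = ", "),
      "  bias:", sprintf("%.4f", x$bias), "\n")
  if (!is.null(x$metrics))
    cat(sprintf("  held-out balanced accuracy %.4f, AUC %.4f (n=%d)\n",
                x$metrics$balanced_accuracy, x$metrics$auc,
                x$metrics$n_test))
  invisible(x)
}

#' @export
coef.pair_model <- function(object, ...) {
  c("(Intercept)" = object$bias, object$weights)
}

#' @export
predict.pair_model <- function(object, newdata, ...) {
  score_pair(newdata, object)
}

#' @export
summary.pair_model <- function(object, ...) {
  print(object)
  if (!is.null(object$fit)) {
    cat("\nGLM coefficient table:\n")
    stats::printCoefmat(summary(object$fit)$coefficients)
  }
  invisible(object)
}
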