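#' Configuration of regularized common spatial pattern extraction
#'
#' Two shrinkage parameters stabilize the per-class covariance estimate:
#' `beta` shrinks the subject's own covariance sum toward a generic sum
#' pooled from other subjects (generic learning), and `gamma` shrinks the
#' resulting matrix toward a scaled identity. `beta = gamma = 0` recovers
#' classical CSP on the subject's own trials.
#'
#' @param beta generic-learning shrinkage weight in `[0, 1]`.
#' @param gamma identity shrinkage weight in `[0, 1]`.
#' @param alpha number of filter columns retained per end of the
#'   eigenvalue spectrum; each pairwise filter has `Q = 2 * alpha`
#'   columns.
#' @return Object of class `rcsp_config`.
#' @export
rcsp_config <- function(beta = 0, gamma = 0, alpha = 2) {
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]")
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  if (alpha < 1) stop("alpha must be >= 1")
  structure(list(beta = beta, gamma = gamma, alpha = as.integer(alpha)),
            class = "rcsp_config")
}

#' Trace-normalized sample covariance of a trial
#'
#' `S = E %*% t(E) / trace(E %*% t(E))`, so every trial contributes unit
#' trace regardless of its amplitude.
#'
#' @param e numeric trial matrix, channels x samples.
#' @return Symmetric positive semidefinite matrix with unit trace.
#' @export
normalized_covariance <- function(e) {
  e <- as.matrix(e)
  if (ncol(e) < 2) stop("trial must have at least 2 samples")
  s <- tcrossprod(e)
  tr <- sum(diag(s))
  if (tr <= 0) stop("zero-energy trial")
  s / tr
}

#' Per-class covariance summary with a generic pool
#'
#' Sums the trace-normalized trial covariances of the subject's own
#' training trials (`S_sum`, `m` trials) and of the pooled generic trials
#' from other subjects (`S_hat_sum`, `m_hat` trials) for one class.
#'
#' @param own_trials list of trial matrices (or `eeg_trial` objects) of
#'   the class for the subject of interest.
#' @param generic_trials list of trial matrices pooled from the other
#'   subjects (may be empty).
#' @param label the class label.
#' @return Object of class `class_cov_summary`.
#' @export
class_cov_summary <- function(own_trials, generic_trials = list(),
                              label = NULL) {
  as_mat <- function(t) if (inherits(t, "eeg_trial")) t$data else t
  sum_cov <- function(trials) {
    if (length(trials) == 0) return(NULL)
    Reduce(`+`, lapply(trials, function(t) normalized_covariance(as_mat(t))))
  }
  if (length(own_trials) == 0) stop("incomplete training set: no own trials")
  structure(list(S_sum = sum_cov(own_trials),
                 S_hat_sum = sum_cov(generic_trials),
                 m = length(own_trials),
                 m_hat = length(generic_trials),
                 label = label),
            class = "class_cov_summary")
}

#' Regularized average spatial covariance of one class
#'
#' First-stage shrinkage blends own and generic covariance sums:
#' `Sigma(beta) = ((1-beta) S_sum + beta S_hat_sum) /
#' ((1-beta) m + beta m_hat)`. Second-stage shrinkage blends toward a
#' scaled identity with the trace preserved:
#' `Sigma(beta, gamma) = (1-gamma) Sigma(beta) +
#' (gamma / N) trace(Sigma(beta)) I`.
#'
#' @param summary a [class_cov_summary()].
#' @param config an [rcsp_config()].
#' @return Symmetric positive semidefinite N x N matrix.
#' @export
regularized_covariance <- function(summary, config) {
  beta <- config$beta; gamma <- config$gamma
  if (beta > 0 && is.null(summary$S_hat_sum))
    stop("beta > 0 requires a generic covariance pool")
  denom <- (1 - beta) * summary$m + beta * summary$m_hat
  if (denom <= 0) stop("degenerate shrinkage denominator")
  num <- (1 - beta) * summary$S_sum
  if (!is.null(summary$S_hat_sum))
    num <- num + beta * summary$S_hat_sum
  sigma_beta <- num / denom
  n <- nrow(sigma_beta)
  (1 - gamma) * sigma_beta +
    (gamma / n) * sum(diag(sigma_beta)) * diag(n)
}

# Deterministic eigenvector orientation: largest-magnitude entry positive.
orient_columns <- function(v) {
  flip <- apply(v, 2, function(col) {
    j <- which.max(abs(col))
    if (col[j] < 0) -1 else 1
  })
  sweep(v, 2, flip, "*")
}

#' Pairwise CSP spatial filters from two class covariances
#'
#' Eigendecomposes the composite covariance (eigenvalues descending),
#' whitens with `P = Lambda^(-1/2) t(U)`, eigendecomposes the whitened
#' first-class covariance (descending) to get `B`, forms the full
#' projection `W0 = t(B) %*% P` and retains the first and last `alpha`
#' filters: the ends of the whitened eigenvalue spectrum, where the
#' variance ratio between the two classes is most extreme. The returned
#' matrix `W` is N x Q, oriented so that `Z = t(W) %*% E` has Q rows.
#'
#' @param sigma1,sigma2 class covariance matrices (N x N).
#' @param alpha filters retained per spectrum end.
#' @return N x Q filter matrix (Q = 2 alpha) with attributes
#'   `whitened_eigenvalues` (of class 1) carried for diagnostics.
#' @export
csp_pair_filters <- function(sigma1, sigma2, alpha = 2) {
  n <- nrow(sigma1)
  if (2 * alpha > n) stop("2 * alpha cannot exceed the channel count")
  comp <- sigma1 + sigma2
  ec <- eigen((comp + t(comp)) / 2, symmetric = TRUE)
  if (min(ec$values) <= 1e-12 * max(ec$values))
    stop("degenerate covariance: composite matrix is not positive definite")
  u <- orient_columns(ec$vectors)          # eigenvalues already descending
  p <- t(u) / sqrt(ec$values)              # Lambda^(-1/2) t(U)
  s1t <- p %*% sigma1 %*% t(p)
  e1 <- eigen((s1t + t(s1t)) / 2, symmetric = TRUE)
  b <- orient_columns(e1$vectors)
  w0 <- crossprod(b, p)                    # rows are spatial filters
  keep <- c(seq_len(alpha), seq.int(n - alpha + 1, n))
  w <- t(w0[keep, , drop = FALSE])
  attr(w, "whitened_eigenvalues") <- e1$values
  w
}

#' Build the six-filter one-vs-one spatial filter bank
#'
#' For each of the six unordered class pairs (canonical order, see
#' [class_pairs()]), regularizes both class covariances and computes the
#' pairwise CSP filters. The generic pool for each class is the union of
#' the other subjects' training trials of that class.
#'
#' @param own an [eeg_dataset()] for the subject of interest (training
#'   split used).
#' @param generic list of [eeg_dataset()] objects for the other subjects
#'   (training splits pooled); may be empty when `beta = 0`.
#' @param config an [rcsp_config()].
#' @return Object of class `spatial_filter_bank`: named list of N x Q
#'   filter matrices keyed `"A|B"`, plus the config and summaries.
#' @export
build_filter_bank <- function(own, generic = list(),
                              config = rcsp_config()) {
  summaries <- class_summaries(own, generic)
  bank_from_summaries(summaries, config)
}

# Per-class covariance summaries; computed once, reusable across the
# whole (beta, gamma) grid.
class_summaries <- function(own, generic = list()) {
  own_trials <- dataset_trials(own, "train")
  own_labels <- dataset_labels(own, "train")
  gen_trials <- unlist(lapply(generic, dataset_trials, split = "train"),
                       recursive = FALSE)
  gen_labels <- unlist(lapply(generic, dataset_labels, split = "train"))
  lapply(stats::setNames(nm = class_levels()), function(cl) {
    ow <- own_trials[own_labels == cl]
    if (length(ow) == 0)
      stop("incomplete training set: class ", cl, " has no trials")
    class_cov_summary(ow, gen_trials[gen_labels == cl], label = cl)
  })
}

bank_from_summaries <- function(summaries, config) {
  sigmas <- lapply(summaries, regularized_covariance, config = config)
  pairs <- class_pairs()
  filters <- list()
  for (i in seq_len(nrow(pairs))) {
    key <- paste(pairs[i, ], collapse = "|")
    filters[[key]] <- csp_pair_filters(sigmas[[pairs[i, 1]]],
                                       sigmas[[pairs[i, 2]]],
                                       config$alpha)
  }
  structure(list(filters = filters, pairs = pairs, config = config,
                 n_channels = nrow(sigmas[[1]])),
            class = "spatial_filter_bank")
}

#' @export
print.spatial_filter_bank <- function(x, ...) {
  cat("Spatial filter bank:", length(x$filters), "pairwise filters,",
      x$n_channels, "channels,", "Q =", 2 * x$config$alpha,
      sprintf("(beta = %.2f, gamma = %.2f)\n", x$config$beta,
              x$config$gamma))
  invisible(x)
}

#' Log-variance feature vector of one trial
#'
#' Projects the trial through every filter of the bank and takes, per
#' filter, the log of each projected row's variance normalized by the
#' summed variance across that filter's Q rows. Blocks are concatenated
#' in the fixed pair order, giving `6 * Q` values (24 with `alpha = 2`).
#'
#' @param e trial matrix (channels x samples) or an [eeg_trial()].
#' @param bank a `spatial_filter_bank`.
#' @return Numeric feature vector of length `6 * Q`.
#' @export
extract_features <- function(e, bank) {
  if (inherits(e, "eeg_trial")) e <- e$data
  if (nrow(e) != bank$n_channels)
    stop("trial has ", nrow(e), " channels but the bank expects ",
         bank$n_channels)
  unlist(lapply(bank$filters, function(w) {
    z <- crossprod(w, e)
    v <- apply(z, 1, stats::var)
    if (any(v <= 0)) stop("degenerate projection: zero-variance component")
    log(v / sum(v))
  }), use.names = FALSE)
}

# Identical features computed from a precomputed centred trial covariance
# ct = tcrossprod(E - rowMeans(E)) / (T - 1): var(w' E) = w' ct w.
features_from_cov <- function(ct, bank) {
  unlist(lapply(bank$filters, function(w) {
    v <- colSums(w * (ct %*% w))
    if (any(v <= 0)) stop("degenerate projection: zero-variance component")
    log(v / sum(v))
  }), use.names = FALSE)
}

centered_covariance <- function(e) {
  if (inherits(e, "eeg_trial")) e <- e$data
  ec <- e - rowMeans(e)
  tcrossprod(ec) / (ncol(e) - 1)
}

#' Feature matrix for a list of trials
#'
#' @param trials list of trials (or an [eeg_dataset()], optionally
#'   restricted by `split`).
#' @param bank a `spatial_filter_bank`.
#' @param split when `trials` is a dataset: "train", "test" or NULL.
#' @return Matrix with one row per trial and `6 * Q` columns, with a
#'   `labels` attribute when trials carry labels.
#' @export
feature_matrix <- function(trials, bank, split = NULL) {
  if (inherits(trials, "eeg_dataset")) {
    labels <- dataset_labels(trials, split)
    trials <- dataset_trials(trials, split)
  } else {
    labels <- vapply(trials, function(t)
      if (inherits(t, "eeg_trial")) t$label else NA_character_, character(1))
  }
  feats <- t(vapply(trials, extract_features, bank = bank,
                    numeric(length(bank$filters) * 2 * bank$config$alpha)))
  attr(feats, "labels") <- labels
  feats
}
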