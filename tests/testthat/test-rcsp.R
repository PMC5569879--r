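test_that("trace-normalized covariance has unit trace and is PSD", {
  expect_equal(normalized_covariance(diag(2)), diag(2) / 2)
  expect_equal(normalized_covariance(rbind(c(2, 0), c(0, 0))),
               rbind(c(1, 0), c(0, 0)))
  set.seed(71)
  s <- normalized_covariance(matrix(rnorm(6 * 512), 6))
  expect_equal(sum(diag(s)), 1, tolerance = 1e-10)
  expect_gte(min(eigen(s, symmetric = TRUE)$values), -1e-10)
  expect_matrix_equal(s, t(s), 1e-12)
  expect_error(normalized_covariance(matrix(0, 3, 10)), "zero-energy")
})

test_that("class covariance summaries sum unit-trace trial covariances", {
  set.seed(72)
  own <- lapply(1:5, function(i) matrix(rnorm(4 * 100), 4))
  gen <- lapply(1:8, function(i) matrix(rnorm(4 * 100), 4))
  sm <- class_cov_summary(own, gen, label = "LH")
  expect_equal(sm$m, 5)
  expect_equal(sm$m_hat, 8)
  expect_equal(sum(diag(sm$S_sum)), 5, tolerance = 1e-8)
  expect_equal(sum(diag(sm$S_hat_sum)), 8, tolerance = 1e-8)
  expect_error(class_cov_summary(list()), "incomplete training set")
})

test_that("regularized covariance interpolates between own, generic and identity", {
  set.seed(73)
  own <- lapply(1:6, function(i) matrix(rnorm(5 * 200), 5))
  gen <- lapply(1:12, function(i) matrix(rnorm(5 * 200), 5))
  sm <- class_cov_summary(own, gen)
  # beta = gamma = 0: the classical per-class average
  s00 <- regularized_covariance(sm, rcsp_config(0, 0))
  expect_matrix_equal(s00, sm$S_sum / sm$m, 1e-12)
  # beta = 1: generic-only average
  s10 <- regularized_covariance(sm, rcsp_config(1, 0))
  expect_matrix_equal(s10, sm$S_hat_sum / sm$m_hat, 1e-12)
  # gamma = 1: exactly the scaled identity
  s01 <- regularized_covariance(sm, rcsp_config(0, 1))
  expect_matrix_equal(s01, diag(5) * sum(diag(s00)) / 5, 1e-12)
  # trace is preserved across gamma
  for (g in c(0.2, 0.5, 0.9)) {
    sg <- regularized_covariance(sm, rcsp_config(0.3, g))
    s0 <- regularized_covariance(sm, rcsp_config(0.3, 0))
    expect_equal(sum(diag(sg)), sum(diag(s0)), tolerance = 1e-10)
  }
  # off-diagonal energy decays monotonically to zero with gamma
  off <- vapply(seq(0, 1, 0.1), function(g) {
    sg <- regularized_covariance(sm, rcsp_config(0.3, g))
    sum((sg - diag(diag(sg)))^2)
  }, numeric(1))
  expect_true(all(diff(off) < 1e-15))
  expect_lt(off[11], 1e-20)
  expect_error(rcsp_config(beta = 1.2), "beta")
  expect_error(rcsp_config(gamma = -0.1), "gamma")
})

test_that("pairwise filters isolate discriminative channels on diagonal input", {
  w <- csp_pair_filters(diag(c(0.9, 0.1)), diag(c(0.1, 0.9)), alpha = 1)
  # projections isolate channel 1 vs channel 2 up to sign/scale
  expect_equal(abs(w[, 1]) / max(abs(w[, 1])), c(1, 0), tolerance = 1e-10)
  expect_equal(abs(w[, 2]) / max(abs(w[, 2])), c(0, 1), tolerance = 1e-10)
  expect_equal(attr(w, "whitened_eigenvalues"), c(0.9, 0.1),
               tolerance = 1e-10)
})

test_that("whitening and eigenvalue complementarity hold for every pair", {
  set.seed(74)
  for (rep in 1:5) {
    s1 <- normalized_covariance(matrix(rnorm(6 * 300), 6))
    s2 <- normalized_covariance(matrix(rnorm(6 * 300), 6))
    comp <- s1 + s2
    ec <- eigen(comp, symmetric = TRUE)
    p <- t(ec$vectors) / sqrt(ec$values)
    expect_matrix_equal(p %*% comp %*% t(p), diag(6), 1e-8)
    s1t <- p %*% s1 %*% t(p)
    s2t <- p %*% s2 %*% t(p)
    b <- eigen(s1t, symmetric = TRUE)$vectors
    expect_matrix_equal(crossprod(b, s1t %*% b) + crossprod(b, s2t %*% b),
                        diag(6), 1e-8)
    lam1 <- eigen(s1t, symmetric = TRUE)$values
    lam2 <- rev(eigen(s2t, symmetric = TRUE)$values)
    expect_matrix_equal(lam1 + lam2, rep(1, 6), 1e-8)
  }
})

test_that("equal class covariances give all-0.5 whitened eigenvalues", {
  set.seed(75)
  s <- normalized_covariance(matrix(rnorm(5 * 200), 5))
  w <- csp_pair_filters(s, s, alpha = 2)
  expect_matrix_equal(attr(w, "whitened_eigenvalues"), rep(0.5, 5), 1e-8)
  expect_equal(dim(w), c(5, 4))
})

test_that("classical CSP filters match the generalized eigenproblem oracle", {
  set.seed(76)
  for (rep in 1:5) {
    tr1 <- lapply(1:10, function(i) matrix(rnorm(6 * 256), 6) *
                    sqrt(c(2, 1, 1, 1, 1, 0.5)))
    tr2 <- lapply(1:10, function(i) matrix(rnorm(6 * 256), 6) *
                    sqrt(c(0.5, 1, 1, 1, 1, 2)))
    s1 <- Reduce(`+`, lapply(tr1, normalized_covariance)) / 10
    s2 <- Reduce(`+`, lapply(tr2, normalized_covariance)) / 10
    w <- csp_pair_filters(s1, s2, alpha = 2)
    # oracle: solve S1 w = lambda (S1 + S2) w directly
    ge <- eigen(solve(s1 + s2, s1))
    ord <- order(-Re(ge$values))
    worc <- Re(ge$vectors[, ord])
    ratio <- function(wv, s) drop(crossprod(wv, s %*% wv) /
                                    crossprod(wv, (s1 + s2) %*% wv))
    impl <- vapply(1:4, function(q) ratio(w[, q], s1), numeric(1))
    orac <- vapply(c(1, 2, 5, 6), function(q) ratio(worc[, q], s1),
                   numeric(1))
    expect_matrix_equal(impl, orac, 1e-6)
  }
})

test_that("log-variance features are normalized and scale-invariant", {
  set.seed(77)
  bank <- structure(list(filters = list(`R|RF` = diag(2)),
                         pairs = rbind(c("R", "RF")),
                         config = rcsp_config(alpha = 1), n_channels = 2),
                    class = "spatial_filter_bank")
  # projected variances (3, 1) -> log 0.75, log 0.25
  e <- rbind(sqrt(3) * scale(rnorm(400))[, 1], scale(rnorm(400))[, 1])
  fv <- extract_features(e, bank)
  expect_equal(fv, c(log(0.75), log(0.25)), tolerance = 1e-8)
  expect_equal(sum(exp(fv)), 1, tolerance = 1e-8)
  expect_matrix_equal(extract_features(10 * e, bank), fv, 1e-8)
  expect_error(extract_features(matrix(1, 2, 10), bank),
               "degenerate projection")
})

test_that("feature extraction from trial covariances matches the direct path", {
  set.seed(78)
  cfg <- tiny_config(seed = 78)
  ds <- generate_dataset(cfg)[[1]]
  bank <- build_filter_bank(ds, list(), rcsp_config())
  for (tr in ds$trials[1:4]) {
    direct <- extract_features(tr, bank)
    via_cov <- mibci:::features_from_cov(mibci:::centered_covariance(tr),
                                         bank)
    expect_matrix_equal(direct, via_cov, 1e-10)
  }
})

test_that("the filter bank has one filter per class pair with Q columns", {
  cfg <- tiny_config(seed = 79)
  datasets <- generate_dataset(synthetic_config(n_subjects = 2,
                                                trials_per_state = 6,
                                                train_per_state = 4,
                                                seed = 79))
  bank <- build_filter_bank(datasets[[1]], datasets[-1],
                            rcsp_config(beta = 0.5, gamma = 0.1))
  expect_length(bank$filters, 6)
  expect_identical(names(bank$filters),
                   c("R|RF", "R|LH", "R|RS", "RF|LH", "RF|RS", "LH|RS"))
  for (w in bank$filters) expect_equal(dim(w), c(14, 4))
  fv <- extract_features(datasets[[1]]$trials[[1]], bank)
  expect_length(fv, 24)
  # generic pool counts: M from own, M_hat = M * (L - 1) when balanced
  sm <- mibci:::class_summaries(datasets[[1]], datasets[-1])
  expect_equal(sm$R$m, 4)
  expect_equal(sm$R$m_hat, 4 * (2 - 1))
})

test_that("beta = 0 ignores the generic pool entirely", {
  datasets <- generate_dataset(synthetic_config(n_subjects = 2,
                                                trials_per_state = 6,
                                                train_per_state = 4,
                                                seed = 80))
  b_alone <- build_filter_bank(datasets[[1]], list(), rcsp_config(0, 0))
  b_pooled <- build_filter_bank(datasets[[1]], datasets[-1],
                                rcsp_config(0, 0))
  for (key in names(b_alone$filters))
    expect_matrix_equal(b_alone$filters[[key]], b_pooled$filters[[key]],
                        1e-10)
})

test_that("filters recover the class-specific channels on synthetic data", {
  hits <- 0
  for (s in 1:10) {
    cfg <- synthetic_config(n_subjects = 1, trials_per_state = 12,
                            train_per_state = 10, blink_amplitude = 0,
                            seed = 100 + s)
    ds <- generate_dataset(cfg)
    ds[[1]]$trials <- lapply(ds[[1]]$trials, function(t)
      crop_trial(filter_trial(t, notch = FALSE)))
    bank <- build_filter_bank(ds[[1]], list(), rcsp_config())
    # LH activates C4/FC4/CP4, RS activates C3/FC3/CP3: the extreme
    # columns of the LH|RS filter should load maximally on those sets
    w <- bank$filters[["LH|RS"]]
    m <- default_montage()
    lh_set <- match(c("C4", "FC4", "CP4"), m$eeg_channels)
    rs_set <- match(c("C3", "FC3", "CP3"), m$eeg_channels)
    top1 <- which.max(abs(w[, 1]))
    top4 <- which.max(abs(w[, 4]))
    if ((top1 %in% lh_set && top4 %in% rs_set) ||
        (top1 %in% rs_set && top4 %in% lh_set)) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("grid search enumerates the full parameter lattice", {
  datasets <- generate_dataset(synthetic_config(n_subjects = 2,
                                                trials_per_state = 8,
                                                train_per_state = 6,
                                                seed = 81))
  datasets <- lapply(datasets, function(d) {
    d$trials <- lapply(d$trials, function(t) crop_trial(t, c(2, 4)))
    d
  })
  gs <- grid_search(datasets[[1]], datasets[-1], grid_step = 0.5,
                    folds = 3, seed = 2)
  expect_equal(dim(gs$accuracy), c(3, 3))       # 3 x 3 = 9 cells
  expect_true(all(!is.na(gs$accuracy)))
  expect_s3_class(gs$best, "rcsp_config")
  expect_true(gs$accuracy[as.character(gs$best$beta),
                          as.character(gs$best$gamma)] ==
                max(gs$accuracy))
})
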