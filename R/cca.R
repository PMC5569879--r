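#' Remove the mean of each row
#'
#' Centring step preceding canonical correlation analysis; the means are
#' returned so the denoised signals can be reconstructed on the original
#' baseline.
#'
#' @param m numeric matrix (channels x samples), at least 2 samples.
#' @return List with `centered` (matrix) and `means` (per-row means).
#' @export
center_rows <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("need at least 2 samples to centre")
  mu <- rowMeans(m)
  list(centered = m - mu, means = mu)
}

#' Canonical correlation analysis of two centred signal blocks
#'
#' Finds direction matrices `A` and `B` such that the canonical variates
#' `U = t(A) %*% Xc` and `V = t(B) %*% Yc` are, pair by pair, maximally
#' correlated, each variate having unit variance
#' (`t(a) %*% Cxx %*% a = 1`). Solved by whitening each block with the
#' symmetric inverse square root of its covariance and taking the SVD of
#' the whitened cross-covariance. Sign indeterminacy is resolved by
#' making each left variate's covariance with its block's first channel
#' non-negative (the paired right direction is flipped with it so the
#' canonical correlations stay non-negative).
#'
#' @param xc,yc centred blocks (rows = channels, columns = samples; equal
#'   column counts). Covariances use the 1/(T-1) convention.
#' @param tol relative eigenvalue tolerance below which a block is
#'   declared rank-deficient.
#' @return Object of class `cca_model` with direction matrices `A`, `B`
#'   and canonical correlations `rho` (descending).
#' @export
cca_fit <- function(xc, yc, tol = 1e-10) {
  xc <- as.matrix(xc); yc <- as.matrix(yc)
  if (ncol(xc) != ncol(yc)) stop("blocks must share the sample count")
  tt <- ncol(xc)
  if (tt <= max(nrow(xc), nrow(yc)))
    stop("need more samples than channels per block")
  cxx <- tcrossprod(xc) / (tt - 1)
  cyy <- tcrossprod(yc) / (tt - 1)
  cxy <- tcrossprod(xc, yc) / (tt - 1)
  wx <- inv_sqrt_sym(cxx, tol, "left block")
  wy <- inv_sqrt_sym(cyy, tol, "right block")
  sv <- svd(wx %*% cxy %*% wy)
  k <- min(nrow(xc), nrow(yc))
  a <- wx %*% sv$u[, seq_len(k), drop = FALSE]
  b <- wy %*% sv$v[, seq_len(k), drop = FALSE]
  # anchor sign: cov(u_i, first left channel) = (Cxx a_i)[1] >= 0
  anchor <- drop(cxx[1, , drop = FALSE] %*% a)
  flip <- ifelse(anchor < 0, -1, 1)
  a <- sweep(a, 2, flip, "*")
  b <- sweep(b, 2, flip, "*")
  structure(list(A = a, B = b, rho = sv$d[seq_len(k)],
                 means = NULL),
            class = "cca_model")
}

inv_sqrt_sym <- function(s, tol, what) {
  e <- eigen(s, symmetric = TRUE)
  if (min(e$values) < tol * max(e$values))
    stop("degenerate covariance in ", what)
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' @export
print.cca_model <- function(x, ...) {
  cat("CCA model:", nrow(x$A), "x", ncol(x$A),
      "directions; canonical correlations:\n ",
      paste(sprintf("%.4f", x$rho), collapse = " "), "\n")
  invisible(x)
}
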