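# Eigenmode analysis of the coarse-grained surface: mass-weighted mode
# decomposition with rigid-body-mode exclusion, mode-weighted motion
# correlations (including unstable modes via |lambda| weighting), and the
# exponential decay-ratio fit of correlation-distance curves.

#' Mass-weighted mode decomposition of a coarse-grained Hessian
#'
#' Diagonalizes `M^-1/2 Hp M^-1/2` and flags the `zero_count` modes of
#' smallest magnitude (the rigid-body modes of a free system) as excluded
#' from correlation averages.  Solvent-particle masses should be full water
#' masses (see [unit_table()]).
#'
#' @param Hp symmetric 3N x 3N coarse-grained Hessian (kcal/mol/A^2).
#' @param masses per-unit masses, length N (amu).
#' @param zero_count number of smallest-|lambda| modes to exclude.
#' @return list of class `mode_set` with `values` (sorted by |lambda|,
#'   ascending), `vectors` (orthonormal in mass-weighted coordinates),
#'   `zeroed` and `masses`.
#' @export
mode_decompose <- function(Hp, masses, zero_count = 6L) {
  n3 <- nrow(Hp)
  stopifnot(length(masses) * 3L == n3, all(masses > 0))
  if (max(abs(Hp - t(Hp))) > 1e-9 * max(1, max(abs(Hp))))
    stop("Hp must be symmetric")
  m3 <- rep(masses, each = 3L)
  s <- 1 / sqrt(m3)
  Hmw <- Hp * (s %o% s)
  Hmw <- (Hmw + t(Hmw)) / 2
  ee <- eigen(Hmw, symmetric = TRUE)
  ord <- order(abs(ee$values))
  structure(list(values = ee$values[ord],
                 vectors = ee$vectors[, ord, drop = FALSE],
                 zeroed = as.integer(zero_count),
                 masses = masses),
            class = "mode_set")
}

# Cartesian displacement patterns of the included modes, columns scaled by
# sqrt(1/|lambda|) so the Gram matrix is the weighted covariance.
.weighted_modes <- function(modes) {
  n <- length(modes$values)
  if (modes$zeroed >= n) stop("undefined correlation: all modes excluded")
  inc <- (modes$zeroed + 1L):n
  lam <- abs(modes$values[inc])
  if (any(lam == 0)) stop("zero eigenvalue among included modes")
  s <- 1 / sqrt(rep(modes$masses, each = 3L))
  (modes$vectors[, inc, drop = FALSE] * s) *
    rep(1 / sqrt(lam), each = nrow(modes$vectors))
}

#' Motion correlation between two units
#'
#' Normalized mode-weighted covariance of the two units' displacement
#' vectors, `c_ij = <a.b> / sqrt(<a.a><b.b>)`, where `<x.y>` sums
#' `x_k . y_k / |lambda_k|` over the included modes.  Unstable
#' (negative-eigenvalue) modes contribute through the magnitude of their
#' eigenvalue, which keeps the self-covariance positive and `|c| <= 1`.
#'
#' @param modes a [mode_decompose()] result.
#' @param i,j unit indices.
#' @return correlation in [-1, 1]; `c_ii = 1`.
#' @export
motion_correlation <- function(modes, i, j) {
  U <- .weighted_modes(modes)
  bi <- (3L * (i - 1L) + 1L):(3L * i)
  bj <- (3L * (j - 1L) + 1L):(3L * j)
  ab <- sum(U[bi, , drop = FALSE] * U[bj, , drop = FALSE])
  aa <- sum(U[bi, , drop = FALSE]^2)
  bb <- sum(U[bj, , drop = FALSE]^2)
  ab / sqrt(aa * bb)
}

#' Full unit-by-unit motion-correlation matrix
#'
#' @param modes a [mode_decompose()] result.
#' @return N x N matrix of correlations (a normalized Gram matrix, hence
#'   positive semidefinite with unit diagonal).
#' @export
correlation_matrix <- function(modes) {
  U <- .weighted_modes(modes)
  N <- length(modes$masses)
  G <- tcrossprod(U)                 # 3N x 3N weighted covariance
  arr <- array(G, c(3L, N, 3L, N))
  C <- arr[1L, , 1L, ] + arr[2L, , 2L, ] + arr[3L, , 3L, ]
  d <- sqrt(diag(C))
  C / (d %o% d)
}

#' Exponential decay ratio of a correlation-distance curve
#'
#' Fits a least-squares line to `ln(y - baseline)` versus `x` over the
#' window and returns `exp(slope)`, the per-A decay ratio of
#' `y = a * ratio^x + b`.  The default baseline is zero; finite systems
#' whose correlations plateau at a nonzero offset can subtract an estimated
#' baseline instead.
#'
#' @param curve data.frame with columns `x` and `mean` (or `y`).
#' @param window numeric length-2 fitting window in A.
#' @param baseline constant offset subtracted from `y` before the log fit.
#' @return the fitted ratio.
#' @export
decay_ratio <- function(curve, window = c(5, 10), baseline = 0) {
  y <- (if ("mean" %in% names(curve)) curve$mean else curve$y) - baseline
  x <- curve$x
  sel <- !is.na(y) & x >= window[1L] & x <= window[2L]
  if (sum(sel) < 2L) stop("fewer than two points in the fitting window")
  if (any(y[sel] <= 0)) stop("log-domain error: nonpositive values in window")
  fit <- stats::lm(log(y[sel]) ~ x[sel])
  exp(unname(stats::coef(fit)[2L]))
}
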