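## Unidimensionality and local-independence checks on the polychoric
## correlation matrix: two-step polychoric estimation, a one-factor model
## fitted by unweighted least squares with the usual fit indices, the
## exploratory eigenvalue ratio, and residual-correlation screening.

# Standard bivariate-normal rectangle probabilities via the 1-D reduction
# Phi2(h, k, rho) = int_{-inf}^h phi(x) Phi((k - rho x)/sqrt(1-rho^2)) dx,
# evaluated with fixed Gauss-Legendre nodes. Accurate to ~1e-10 for
# |rho| <= 0.999, which is all the pair likelihood ever requests.
gauss_legendre <- function(n) {
  # Golub-Welsch on [-1, 1]
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
}

.gl64 <- gauss_legendre(64)

binorm_cdf_grid <- function(h, k, rho) {
  # matrix of Phi2(h_i, k_j, rho) for finite cut vectors h, k
  s <- sqrt(max(1 - rho^2, 1e-12))
  out <- matrix(0, length(h), length(k))
  for (i in seq_along(h)) {
    lo <- -8.5
    hi <- h[i]
    if (hi <= lo) { out[i, ] <- 0; next }
    x <- (lo + hi) / 2 + (hi - lo) / 2 * .gl64$nodes
    w <- (hi - lo) / 2 * .gl64$weights * stats::dnorm(x)
    for (j in seq_along(k)) {
      out[i, j] <- sum(w * stats::pnorm((k[j] - rho * x) / s))
    }
  }
  out
}

polychoric_cell_probs <- function(cuts1, cuts2, rho) {
  # cell probabilities of the discretized bivariate normal
  m1 <- length(cuts1) + 1L
  m2 <- length(cuts2) + 1L
  # cumulative grid including the +/- infinity borders
  G <- matrix(0, m1 + 1L, m2 + 1L)
  G[2:m1, 2:m2] <- binorm_cdf_grid(cuts1, cuts2, rho)
  G[m1 + 1L, 2:m2] <- stats::pnorm(cuts2)
  G[2:m1, m2 + 1L] <- stats::pnorm(cuts1)
  G[m1 + 1L, m2 + 1L] <- 1
  P <- G[-1, -1, drop = FALSE] - G[-(m1 + 1L), -1, drop = FALSE] -
    G[-1, -(m2 + 1L), drop = FALSE] + G[-(m1 + 1L), -(m2 + 1L), drop = FALSE]
  pmax(P, 1e-12)
}

#' Estimate a single polychoric correlation
#'
#' Two-step estimator: item thresholds are fixed at the inverse-normal of
#' the cumulative marginal proportions, then the correlation of the latent
#' bivariate normal is found by maximizing the contingency-table likelihood
#' over \code{[-0.999, 0.999]}.
#'
#' @param x,y integer category vectors of equal length (complete cases).
#' @return list with `rho`, `cuts_x`, `cuts_y`, `converged` (FALSE when the
#'   maximum sits on the correlation bound).
#' @export
polychoric_pair <- function(x, y) {
  tab <- table(factor(x, levels = sort(unique(x))),
               factor(y, levels = sort(unique(y))))
  cuts1 <- marginal_cuts(rowSums(tab))
  cuts2 <- marginal_cuts(colSums(tab))
  negll <- function(rho) {
    -sum(tab * log(polychoric_cell_probs(cuts1, cuts2, rho)))
  }
  opt <- stats::optimize(negll, interval = c(-0.999, 0.999), tol = 1e-6)
  rho <- opt$minimum
  converged <- TRUE
  for (edge in c(-0.999, 0.999)) {          # boundary maxima
    if (negll(edge) <= opt$objective) {
      rho <- edge
      converged <- FALSE
    }
  }
  list(rho = rho, cuts_x = cuts1, cuts_y = cuts2, converged = converged)
}

marginal_cuts <- function(counts) {
  n <- sum(counts)
  cum <- cumsum(counts)[-length(counts)] / n
  stats::qnorm(pmin(pmax(cum, 1 / (2 * n)), 1 - 1 / (2 * n)))
}

#' Polychoric correlation matrix of a response matrix
#'
#' @param rm a `response_matrix` with complete cases; every item must show
#'   at least two observed categories.
#' @return list of class `polychoric_result` with `rho` (symmetric,
#'   unit-diagonal matrix), `thresholds` (per-item normal-metric cuts from
#'   the observed marginals) and `converged` (logical matrix; `FALSE`
#'   marks pairs whose estimate sits on the correlation bound).
#' @export
polychoric_matrix <- function(rm) {
  stopifnot(inherits(rm, "response_matrix"))
  require_complete(rm, "polychoric_matrix")
  X <- rm$responses
  p <- ncol(X)
  if (p < 2) stop("need >= 2 items")
  for (j in seq_len(p)) {
    if (length(unique(X[, j])) < 2) {
      stop(sprintf("item '%s' has a single observed category", rm$item_ids[j]))
    }
  }
  rho <- diag(1, p)
  conv <- matrix(TRUE, p, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      est <- polychoric_pair(X[, i], X[, j])
      rho[i, j] <- rho[j, i] <- est$rho
      conv[i, j] <- conv[j, i] <- est$converged
    }
  }
  dimnames(rho) <- list(rm$item_ids, rm$item_ids)
  thresholds <- lapply(seq_len(p), function(j) {
    marginal_cuts(tabulate(factor(X[, j], levels = sort(unique(X[, j])))))
  })
  names(thresholds) <- rm$item_ids
  structure(
    list(rho = rho, thresholds = thresholds, converged = conv),
    class = "polychoric_result"
  )
}

# raise negative eigenvalues to a floor and rescale to unit diagonal
smooth_to_psd <- function(R, floor = 1e-6) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= 0) return(R)
  v <- pmax(e$values, floor)
  S <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(S))
  S <- S / tcrossprod(d)
  diag(S) <- 1
  dimnames(S) <- dimnames(R)
  S
}

#' One-factor fit of a polychoric correlation matrix
#'
#' Fits the single-factor model `R = lambda lambda' + diag(1 - lambda^2)`
#' by unweighted least squares on the (smoothed) polychoric matrix and
#' reports the usual global fit indices: `chi2 = (n - 1) F_min` with
#' `F_min = sum of squared off-diagonal residuals`, CFI and TLI against the
#' independence baseline, `RMSEA = sqrt(max(chi2 - df, 0) / (df (n - 1)))`
#' and SRMR (root mean squared off-diagonal residual). Loadings above 1 in
#' magnitude (Heywood cases) are clamped to 0.999 with a flag.
#'
#' @param pc a `polychoric_result` (or a bare correlation matrix).
#' @param n listwise-complete sample size the matrix was computed from.
#' @return list of class `one_factor_fit` with `fit_indices` (chi_square,
#'   df, cfi, tli, rmsea, srmr, plus the baseline statistic), `loadings`,
#'   `residuals` (observed minus model-implied, zero diagonal), and flags
#'   `heywood`, `degenerate_baseline`.
#' @export
one_factor_fit <- function(pc, n) {
  R <- if (inherits(pc, "polychoric_result")) pc$rho else as.matrix(pc)
  p <- ncol(R)
  if (p < 3) stop("one-factor fit needs >= 3 items")
  R <- smooth_to_psd(R)

  e <- eigen(R, symmetric = TRUE)
  lam <- e$vectors[, 1] * sqrt(max(e$values[1], 0))
  lam <- sign(sum(lam)) * lam               # orient positively
  lam <- pmin(pmax(lam, -0.995), 0.995)

  off <- upper.tri(R)
  obj <- function(l) sum((R[off] - tcrossprod(l)[off])^2)
  grad <- function(l) {
    res <- R - tcrossprod(l)
    diag(res) <- 0
    -2 * res %*% l
  }
  opt <- stats::optim(lam, obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  lam <- opt$par
  heywood <- any(abs(lam) > 1)
  if (heywood) {
    warning("Heywood case: loading(s) clamped at 0.999")
    lam <- pmin(pmax(lam, -0.999), 0.999)
  }

  implied <- tcrossprod(lam)
  diag(implied) <- 1
  residuals <- R - implied
  dimnames(residuals) <- dimnames(R)

  f_min <- sum(residuals[off]^2)
  chi2 <- (n - 1) * f_min
  df <- p * (p - 1) / 2 - p
  f_base <- sum(R[off]^2)
  chi2_b <- (n - 1) * f_base
  df_b <- p * (p - 1) / 2

  degenerate <- (chi2_b - df_b) <= 0
  cfi <- if (degenerate) 1 else {
    1 - max(chi2 - df, 0) / max(chi2_b - df_b, 0)
  }
  tli <- if (degenerate || df == 0) 1 else {
    ((chi2_b / df_b) - (chi2 / df)) / ((chi2_b / df_b) - 1)
  }
  fit <- list(
    chi_square = chi2, df = df,
    baseline_chi_square = chi2_b, baseline_df = df_b,
    cfi = min(max(cfi, 0), 1),
    tli = min(max(tli, 0), 1),
    rmsea = sqrt(max(chi2 - df, 0) / (df * (n - 1))),
    srmr = sqrt(mean(residuals[off]^2)),
    n = n
  )
  structure(
    list(fit_indices = fit, loadings = stats::setNames(lam, colnames(R)),
         residuals = residuals, heywood = heywood,
         degenerate_baseline = degenerate),
    class = "one_factor_fit"
  )
}

#' @export
print.one_factor_fit <- function(x, ...) {
  f <- x$fit_indices
  cat(sprintf(
    "<one_factor_fit> chi2(%d) = %.2f, CFI %.3f, TLI %.3f, RMSEA %.3f, SRMR %.3f\n",
    f$df, f$chi_square, f$cfi, f$tli, f$rmsea, f$srmr
  ))
  invisible(x)
}

#' Exploratory eigenvalue ratio of the polychoric matrix
#'
#' The unidimensionality screen: descending eigenvalues of the polychoric
#' correlation matrix, the first-to-second ratio, and the proportion of
#' total variance carried by the first eigenvalue. Conventional criteria:
#' ratio greater than 4 and first factor at least 20% of the variance.
#'
#' @param pc a `polychoric_result` or a correlation matrix.
#' @return list with `eigenvalues` (descending), `ratio`, `pct_first`.
#' @export
efa_eigen_ratio <- function(pc) {
  R <- if (inherits(pc, "polychoric_result")) pc$rho else as.matrix(pc)
  ev <- sort(eigen(R, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  list(eigenvalues = ev, ratio = ev[1] / ev[2], pct_first = ev[1] / ncol(R))
}

#' Screen residual correlations for local dependence
#'
#' After removing the dominant factor, item pairs whose absolute residual
#' correlation exceeds the threshold (default 0.20) are flagged as possibly
#' locally dependent, sorted by magnitude.
#'
#' @param residuals residual matrix from [one_factor_fit()] (or the fit
#'   object itself).
#' @param threshold flagging threshold on `|residual|`, default 0.20.
#' @return list of class `local_dependence_result` with `residuals`,
#'   `threshold`, and `flagged_pairs` (data.frame: item_i, item_j,
#'   residual).
#' @export
local_dependence <- function(residuals, threshold = 0.20) {
  if (inherits(residuals, "one_factor_fit")) residuals <- residuals$residuals
  R <- as.matrix(residuals)
  ids <- colnames(R)
  if (is.null(ids)) ids <- paste0("item", seq_len(ncol(R)))
  idx <- which(upper.tri(R) & abs(R) > threshold, arr.ind = TRUE)
  flagged <- data.frame(
    item_i = ids[idx[, 1]],
    item_j = ids[idx[, 2]],
    residual = R[idx],
    stringsAsFactors = FALSE
  )
  flagged <- flagged[order(-abs(flagged$residual)), , drop = FALSE]
  rownames(flagged) <- NULL
  structure(
    list(residuals = R, threshold = threshold, flagged_pairs = flagged),
    class = "local_dependence_result"
  )
}
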