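#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix differs from identity:
#' \eqn{\chi^2 = -(n - 1 - (2p + 5)/6)\,\ln|R|} on \eqn{p(p-1)/2} df.
#'
#' @param R Correlation matrix.
#' @param n Sample size the matrix was computed from.
#' @return List `chisq`, `df`, `p`.
#' @export
bartlett_sphericity <- function(R, n) {
  p <- ncol(R)
  detR <- det(R)
  if (detR <= 0) stop("singular correlation matrix")
  chisq <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Overall KMO: the ratio of summed squared correlations to summed squared
#' correlations plus summed squared partial (anti-image) correlations.
#'
#' @param R Correlation matrix.
#' @return Scalar KMO in \[0, 1\].
#' @export
kmo_index <- function(R) {
  Ri <- tryCatch(solve(R), error = function(e) stop("singular correlation matrix"))
  P <- -stats::cov2cor(Ri)          # partial correlations (off-diagonal)
  off <- upper.tri(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(P[off]^2))
}

minres_objective <- function(psi, R, m) {
  Rr <- R
  diag(Rr) <- 1 - psi
  e <- eigen(Rr, symmetric = TRUE)
  lam <- e$vectors[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(m)], 0)), m)
  resid <- R - tcrossprod(lam)
  diag(resid) <- 0
  sum(resid^2) / 2
}

minres_loadings <- function(psi, R, m) {
  Rr <- R
  diag(Rr) <- 1 - psi
  e <- eigen(Rr, symmetric = TRUE)
  e$vectors[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(m)], 0)), m)
}

#' Exploratory factor analysis: minres extraction with varimax rotation
#'
#' Minimum-residual extraction (uniquenesses optimised to minimise the sum of
#' squared off-diagonal residuals of the correlation matrix), followed by
#' variance-maximising orthogonal (varimax) rotation. Factors are ordered by
#' explained variance and sign-anchored so each column's loading sum is
#' positive. Sampling adequacy is gated: the fit refuses (with a diagnostic
#' error) when Bartlett's sphericity p >= 0.05 or KMO < 0.6. Model fit is
#' summarised by the empirical chi-square (n times the sum of squared
#' off-diagonal residual correlations), RMSEA and CFI (against the
#' independence model).
#'
#' @param test_scores Numeric matrix/data.frame, subjects x tests (n >= 50);
#'   columns are standardized internally.
#' @param n_factors Number of factors (default 2).
#' @return A `factor_model` list: `loadings` (rotated, p x m), `rotmat`,
#'   `uniquenesses`, `communalities`, `ss_loadings`, `eigenvalues` (of R),
#'   `prop_var`, `var_explained` (total, percent), `fit` (chisq, df, p,
#'   rmsea, cfi), `adequacy` (bartlett, kmo), `R`, `center`, `scale`, `n`.
#' @export
factor_analysis <- function(test_scores, n_factors = 2) {
  X <- as.matrix(test_scores)
  if (anyNA(X)) {
    keep <- stats::complete.cases(X)
    X <- X[keep, , drop = FALSE]
  }
  n <- nrow(X); p <- ncol(X)
  if (n < 50) stop("factor analysis requires n >= 50")
  if (n_factors >= p) stop("n_factors must be below the number of tests")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) stop("constant test column: ",
                          paste(colnames(X)[scl == 0], collapse = ", "))
  Z <- scale(X, center = ctr, scale = scl)
  R <- stats::cor(X)

  bart <- bartlett_sphericity(R, n)
  kmo <- kmo_index(R)
  if (bart$p >= 0.05 || kmo < 0.6) {
    stop(sprintf(paste0("data unsuitable for factor analysis: Bartlett p = ",
                        "%.3g (need < 0.05), KMO = %.3f (need >= 0.6)"),
                 bart$p, kmo))
  }

  smc <- 1 - 1 / diag(solve(R))
  start <- pmin(pmax(1 - smc, 0.05), 0.95)
  opt <- stats::optim(start, minres_objective, R = R, m = n_factors,
                      method = "L-BFGS-B", lower = 0.005, upper = 1,
                      control = list(maxit = 1000))
  lam <- minres_loadings(opt$par, R, n_factors)

  rot <- stats::varimax(lam, normalize = TRUE)
  L <- unclass(rot$loadings)
  ssl <- colSums(L^2)
  ord <- order(ssl, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  rotmat <- rot$rotmat[, ord, drop = FALSE]
  flip <- ifelse(colSums(L) < 0, -1, 1)
  L <- sweep(L, 2, flip, `*`)
  rotmat <- sweep(rotmat, 2, flip, `*`)
  ssl <- colSums(L^2)
  dimnames(L) <- list(colnames(X), paste0("F", seq_len(n_factors)))

  resid <- R - tcrossprod(L)
  off <- upper.tri(R)
  chisq <- n * sum(resid[off]^2)   # n * sum of squared off-diag residuals
  df <- ((p - n_factors)^2 - (p + n_factors)) / 2
  p_chi <- stats::pchisq(chisq, df, lower.tail = FALSE)
  rmsea <- sqrt(max(chisq / df - 1, 0) / (n - 1))
  null_chi <- bart$chisq
  null_df <- bart$df
  cfi <- 1 - max(chisq - df, 0) / max(chisq - df, null_chi - null_df, 1e-12)

  structure(list(
    loadings = L, rotmat = rotmat,
    uniquenesses = stats::setNames(opt$par, colnames(X)),
    communalities = stats::setNames(rowSums(L^2), colnames(X)),
    ss_loadings = ssl,
    eigenvalues = eigen(R, symmetric = TRUE, only.values = TRUE)$values,
    prop_var = ssl / p,
    var_explained = 100 * sum(ssl) / p,
    fit = list(chisq = chisq, df = df, p = p_chi, rmsea = rmsea, cfi = cfi),
    adequacy = list(bartlett = bart, kmo = kmo),
    R = R, center = ctr, scale = scl, n = n),
    class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model> %d factors on %d tests (n = %d); %.1f%% variance explained\n",
              ncol(x$loadings), nrow(x$loadings), x$n, x$var_explained))
  cat(sprintf("  KMO %.2f | Bartlett p %.2g | CFI %.3f | RMSEA %.3f\n",
              x$adequacy$kmo, x$adequacy$bartlett$p, x$fit$cfi, x$fit$rmsea))
  invisible(x)
}

#' Thurstone regression factor scores
#'
#' Factor-score weights are \eqn{W = R^{-1} \Lambda} (inverse observed
#' correlation matrix times the rotated loadings) and per-subject scores are
#' the standardized test scores times the weights. A near-singular R is
#' ridge-regularised (`R + eps I`) with the epsilon reported in a warning.
#'
#' @param model A fitted `factor_model`.
#' @param test_scores Subjects x tests matrix with the same columns the model
#'   was fitted on.
#' @return Numeric matrix, subjects x factors.
#' @export
thurstone_scores <- function(model, test_scores) {
  stopifnot(inherits(model, "factor_model"))
  X <- as.matrix(test_scores)
  if (ncol(X) != nrow(model$loadings)) {
    stop("test_scores must have the model's ", nrow(model$loadings), " columns")
  }
  Z <- scale(X, center = model$center, scale = model$scale)
  R <- model$R
  W <- tryCatch(solve(R, model$loadings), error = function(e) NULL)
  if (is.null(W) || kappa(R) > 1e10) {
    eps <- 1e-6 * mean(diag(R))
    warning(sprintf("near-singular correlation matrix; ridge eps = %.2g", eps))
    W <- solve(R + diag(eps, ncol(R)), model$loadings)
  }
  S <- Z %*% W
  colnames(S) <- colnames(model$loadings)
  S
}
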