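#' Latent-factor GEA regression (LFMM-style ridge estimator)
#'
#' Two-stage least-squares estimator of the SNP x covariable coefficient
#' matrix B while absorbing neutral population structure into K latent
#' factors: (1) frequencies are centred per SNP and covariables per column;
#' (2) K latent factors are taken as the leading left singular vectors of the
#' frequency matrix after down-weighting the covariable subspace (the ridge
#' parameter `lambda` controls how strongly directions spanned by the
#' covariables are suppressed); (3) B solves the least-squares regression of
#' the frequencies on the centred covariables with the latent factors as
#' additional regressors -- jointly over all covariables by default, or one
#' covariable at a time when `univariate = TRUE`.
#'
#' Coefficients are in frequency units per covariable unit, so the geometric
#' offset computed from them carries the f2 interpretation.
#'
#' @param table a [freq_table()].
#' @param env populations x covariables matrix (or data.frame).
#' @param K number of latent factors (0 gives ordinary least squares).
#' @param lambda ridge parameter of the covariable-subspace projection.
#' @param univariate refit each covariable separately (with the same factors).
#' @return an object of class `gea_fit`: list with `B` (SNPs x covariables),
#'   `method`, `K`, `factors`, `env_names`, `env_center`, `env_scale`, `nsnp`.
#' @export
fit_latent_factor_regression <- function(table, env, K = 2L, lambda = 1e-5,
                                         univariate = FALSE) {
  env <- as.matrix(env)
  Y <- table$freq
  npop <- nrow(Y)
  m <- ncol(env)
  stopifnot(nrow(env) == npop)
  if (K >= npop) stop("K must be smaller than the number of populations")
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- scale(env, center = TRUE, scale = FALSE)
  if (!univariate && qr(Xc)$rank < m)
    stop("covariables are collinear after centering; use univariate = TRUE or PCs")

  factors <- NULL
  if (K > 0) {
    sv <- svd(Xc)
    pos <- sv$d > max(sv$d[1], 1) * 1e-12
    U <- sv$u[, pos, drop = FALSE]
    d2 <- sv$d[pos]^2
    # down-weight the covariable subspace, then extract leading structure
    Yproj <- Yc - U %*% ((d2 / (d2 + lambda)) * crossprod(U, Yc))
    sy <- svd(Yproj, nu = K, nv = 0)
    factors <- sy$u[, seq_len(K), drop = FALSE]
  }

  if (univariate) {
    B <- matrix(NA_real_, nrow = ncol(Y), ncol = m)
    for (k in seq_len(m)) {
      Z <- cbind(Xc[, k], factors)
      cf <- qr.coef(qr(Z), Yc)
      B[, k] <- cf[1, ]
    }
  } else {
    Z <- cbind(Xc, factors)
    cf <- qr.coef(qr(Z), Yc)
    B <- t(cf[seq_len(m), , drop = FALSE])
  }
  B[is.na(B)] <- 0
  new_gea_fit(B, method = "lfmm", K = K, factors = factors, env = env,
              univariate = univariate)
}

new_gea_fit <- function(B, method, K = 0L, factors = NULL, omega = NULL,
                        env, env_center = NULL, env_scale = NULL,
                        univariate = FALSE) {
  env_names <- colnames(env)
  if (is.null(env_names)) env_names <- paste0("env", seq_len(ncol(env)))
  colnames(B) <- env_names
  structure(list(B = B, method = method, K = as.integer(K), factors = factors,
                 omega = omega, env_names = env_names,
                 env_center = env_center %||% colMeans(env),
                 env_scale = env_scale %||% rep(1, ncol(env)),
                 univariate = univariate, nsnp = nrow(B)),
            class = "gea_fit")
}

#' @export
print.gea_fit <- function(x, ...) {
  cat(sprintf("gea_fit (%s%s): %d SNPs x %d covariables, K = %d\n", x$method,
              if (x$univariate) ", univariate" else "", x$nsnp,
              ncol(x$B), x$K))
  invisible(x)
}

#' Estimate the population covariance matrix Omega
#'
#' Shrunk sample covariance across SNPs of standardized allele frequencies:
#' each SNP is centred by its across-population mean `pi` and scaled either by
#' `sqrt(pi (1 - pi))` (the binomial convention used by Bayesian GEA models)
#' or by its sample standard deviation. Linear shrinkage towards a scaled
#' identity guarantees positive-definiteness. The overall scale of Omega is
#' irrelevant to the whitened GLS fit and the XtX statistic.
#'
#' @param table a [freq_table()] (or a residual table for `scale = "sd"`).
#' @param shrinkage shrinkage weight in \[0, 1\] towards `(tr/npop) I`.
#' @param scale per-SNP scaling convention.
#' @return a symmetric positive-definite npop x npop matrix.
#' @export
estimate_omega <- function(table, shrinkage = 0.05, scale = c("binomial", "sd")) {
  scale <- match.arg(scale)
  Y <- table$freq
  if (ncol(Y) < 2) stop("Omega estimation needs at least 2 SNPs")
  pbar <- colMeans(Y)
  s <- switch(scale,
              binomial = sqrt(pbar * (1 - pbar)),
              sd = apply(Y, 2, stats::sd))
  keep <- s > 0
  Z <- sweep(Y[, keep, drop = FALSE], 2, pbar[keep], "-")
  Z <- sweep(Z, 2, s[keep], "/")
  omega <- tcrossprod(Z) / ncol(Z)
  target <- diag(mean(diag(omega)), nrow(omega))
  omega <- (1 - shrinkage) * omega + shrinkage * target
  dimnames(omega) <- list(table$pop_ids, table$pop_ids)
  omega
}

#' Covariance-whitened GLS GEA regression
#'
#' Analogue of the Bayesian hierarchical GEA estimators: the population
#' dimension is whitened by the Cholesky factor of Omega, then coefficients
#' are obtained by least squares of the whitened frequencies on the whitened
#' covariables (plus intercept) -- per covariable separately
#' (`mode = "univariate"`, mirroring importance-sampling estimation that
#' treats covariates independently) or jointly (`mode = "multivariate"`,
#' mirroring MCMC joint estimation). With `omega = I` the multivariate mode
#' coincides with [fit_latent_factor_regression()] at `K = 0`.
#'
#' @param table a [freq_table()].
#' @param env populations x covariables matrix.
#' @param omega positive-definite population covariance (see
#'   [estimate_omega()]).
#' @param mode "multivariate" or "univariate".
#' @return a `gea_fit` with method `gls_multi` or `gls_uni`.
#' @export
fit_gls_regression <- function(table, env, omega,
                               mode = c("multivariate", "univariate")) {
  mode <- match.arg(mode)
  env <- as.matrix(env)
  Y <- table$freq
  npop <- nrow(Y)
  m <- ncol(env)
  stopifnot(nrow(env) == npop, nrow(omega) == npop, ncol(omega) == npop)
  L <- tryCatch(t(chol(omega)), error = function(e) stop("omega is not positive-definite"))
  Yw <- forwardsolve(L, Y)
  if (mode == "multivariate") {
    Z <- cbind(1, env)
    if (qr(Z)$rank < m + 1) stop("covariables are collinear; use univariate mode or PCs")
    cf <- qr.coef(qr(forwardsolve(L, Z)), Yw)
    B <- t(cf[-1, , drop = FALSE])
  } else {
    B <- matrix(NA_real_, nrow = ncol(Y), ncol = m)
    for (k in seq_len(m)) {
      Zw <- forwardsolve(L, cbind(1, env[, k]))
      cf <- qr.coef(qr(Zw), Yw)
      B[, k] <- cf[2, ]
    }
  }
  B[is.na(B)] <- 0
  new_gea_fit(B, method = if (mode == "multivariate") "gls_multi" else "gls_uni",
              omega = omega, env = env, univariate = mode == "univariate")
}

#' Remove rank-K latent structure from a frequency table
#'
#' Centres frequencies per SNP and subtracts the best rank-K reconstruction
#' (truncated SVD), leaving the residuals used as gradient-forest responses.
#'
#' @param table a [freq_table()].
#' @param K latent rank (0 returns the centred table).
#' @return a residual [freq_table()].
#' @export
residualize_frequencies <- function(table, K) {
  npop <- n_pops(table)
  if (K >= npop) stop("K must be smaller than the number of populations")
  Yc <- scale(table$freq, center = TRUE, scale = FALSE)
  if (K > 0) {
    sv <- svd(Yc, nu = K, nv = K)
    Yc <- Yc - sv$u %*% (sv$d[seq_len(K)] * t(sv$v))
  }
  freq_table(unclass(Yc), sample_size = table$sample_size, snp = table$snp,
             pop_ids = table$pop_ids, residual = TRUE)
}

#' Structure-corrected SNP differentiation scores (XtX-style)
#'
#' For SNP j with centred, `sqrt(pi(1-pi))`-scaled frequency vector `z_j`,
#' the score is `z_j' Omega^{-1} z_j`. This is a moment analogue of the
#' calibrated Bayesian XtX* statistic, suitable for ranking SNPs by
#' structure-corrected differentiation.
#'
#' @param table a [freq_table()].
#' @param omega positive-definite population covariance.
#' @return an object of class `snp_scores`: list with `score` and `ranking`
#'   (SNP indices, most differentiated first, ties broken by index).
#' @export
xtx_statistic <- function(table, omega) {
  Y <- table$freq
  pbar <- colMeans(Y)
  s <- sqrt(pbar * (1 - pbar))
  Z <- sweep(Y, 2, pbar, "-")
  const <- s == 0
  s[const] <- 1
  Z <- sweep(Z, 2, s, "/")
  Oi <- tryCatch(solve(omega), error = function(e) stop("omega is singular"))
  score <- colSums(Z * (Oi %*% Z))
  score[const] <- 0
  score <- pmax(score, 0)
  structure(list(score = score,
                 ranking = order(-score, seq_along(score))),
            class = "snp_scores")
}

#' Keep the most differentiated SNPs
#'
#' Retains `ceiling(fraction * nsnp)` top-ranked SNPs (ties broken by SNP
#' index), preserving the original column order.
#'
#' @param table a [freq_table()].
#' @param scores an [xtx_statistic()] result (or any `snp_scores`).
#' @param fraction fraction of SNPs to keep, in (0, 1].
#' @return the filtered [freq_table()].
#' @export
preselect_snps <- function(table, scores, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  ns <- n_snps(table)
  if (!ns) stop("empty table")
  stopifnot(length(scores$score) == ns)
  keep <- sort(scores$ranking[seq_len(ceiling(fraction * ns))])
  subset_snps(table, keep)
}

#' PCA of environmental covariables
#'
#' PCA on column-standardized covariables with a deterministic sign
#' convention (the largest-magnitude loading of each component is positive).
#' New sites are projected with the same centring, scaling and loadings via
#' [project_covariables()].
#'
#' @param env_matrix populations x covariables matrix.
#' @param n_pcs number of components to retain.
#' @return an object of class `cov_pca`: list with `scores`, `loadings`,
#'   `center`, `scale`, `explained_variance`, `n_pcs`.
#' @export
pca_covariables <- function(env_matrix, n_pcs) {
  X <- as.matrix(env_matrix)
  stopifnot(n_pcs >= 1, n_pcs <= min(dim(X)))
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) stop("zero-variance covariable column")
  Xs <- scale(X, center = ctr, scale = scl)
  sv <- svd(Xs)
  W <- sv$v[, seq_len(n_pcs), drop = FALSE]
  for (k in seq_len(n_pcs)) {
    j <- which.max(abs(W[, k]))
    if (W[j, k] < 0) W[, k] <- -W[, k]
  }
  rownames(W) <- colnames(X)
  colnames(W) <- paste0("PC", seq_len(n_pcs))
  scores <- Xs %*% W
  ev <- sv$d^2 / sum(sv$d^2)
  structure(list(scores = scores, loadings = W, center = ctr, scale = scl,
                 explained_variance = ev[seq_len(min(length(ev), ncol(X)))],
                 n_pcs = n_pcs),
            class = "cov_pca")
}

#' Project covariable rows onto fitted principal components
#'
#' @param pca a [pca_covariables()] result.
#' @param new_env rows of covariables in the original units.
#' @return matrix of PC scores.
#' @export
project_covariables <- function(pca, new_env) {
  X <- if (is.null(dim(new_env))) matrix(as.numeric(new_env), nrow = 1)
       else as.matrix(new_env)
  stopifnot(ncol(X) == length(pca$center))
  scale(X, center = pca$center, scale = pca$scale) %*% pca$loadings
}

#' Back-transform PC-space coefficients to the original covariables
#'
#' For a linear GEA fit trained on PC scores (`scores = X_std W`), the
#' coefficients on the original standardized covariables are
#' `B_orig = B_pc W'`, which leaves every geometric offset unchanged while
#' making per-variable importance (column norms of `B_orig`) interpretable.
#'
#' @param fit a `gea_fit` trained on the `scores` of `pca`.
#' @param pca the [pca_covariables()] object that produced the scores.
#' @return a `gea_fit` on the original (standardized) covariables with an
#'   `importance` element (named column norms).
#' @export
back_transform_importance <- function(fit, pca) {
  stopifnot(inherits(fit, "gea_fit"), inherits(pca, "cov_pca"))
  if (ncol(fit$B) != pca$n_pcs)
    stop("fit was not trained on the scores of this PCA")
  B_orig <- fit$B %*% t(pca$loadings)
  out <- new_gea_fit(B_orig, method = fit$method, K = fit$K,
                     factors = fit$factors, omega = fit$omega,
                     env = matrix(0, 1, ncol(B_orig),
                                  dimnames = list(NULL, colnames(B_orig))),
                     env_center = pca$center, env_scale = pca$scale,
                     univariate = fit$univariate)
  out$importance <- sqrt(colSums(B_orig^2))
  names(out$importance) <- colnames(B_orig)
  out
}
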