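test_that("latent-factor regression reduces to OLS at K = 0", {
  fx <- make_linear_fixture(npop = 20, nsnp = 300, m = 3, K = 0,
                            noise_sd = 0.02, seed = 1)
  fit <- fit_latent_factor_regression(fx$table, fx$env, K = 0)
  # independent normal-equations oracle
  Xc <- scale(fx$env, scale = FALSE)
  Yc <- scale(fx$table$freq, scale = FALSE)
  B_ols <- t(solve(crossprod(Xc), crossprod(Xc, Yc)))
  expect_lt(max(abs(fit$B - B_ols)), 1e-8)
})

test_that("a covariable orthogonal to all SNPs gets zero coefficients", {
  set.seed(2)
  npop <- 24
  y <- matrix(runif(npop * 50, 0.3, 0.7), npop, 50)
  x1 <- rnorm(npop)
  # orthogonalize x2 against every (centred) SNP column jointly is only
  # possible for nsnp < npop; use 10 SNPs and build x2 in their null space
  y10 <- y[, 1:10]
  Q <- qr.Q(qr(cbind(1, y10)))
  x2 <- rnorm(npop)
  x2 <- x2 - Q %*% crossprod(Q, x2)
  tab <- freq_table(y10, 100)
  fit <- fit_latent_factor_regression(tab, cbind(a = x1, b = as.numeric(x2)),
                                      K = 0, univariate = TRUE)
  expect_lt(max(abs(fit$B[, 2])), 1e-8)
})

test_that("coefficients are recovered on fixtures with latent structure", {
  fx <- make_linear_fixture(npop = 25, nsnp = 500, m = 2, K = 2,
                            noise_sd = 0.05, seed = 3)
  fit <- fit_latent_factor_regression(fx$table, fx$env, K = 2)
  rel <- norm(fit$B - fx$truth$B0, "F") / norm(fx$truth$B0, "F")
  expect_lt(rel, 0.2)
  expect_error(fit_latent_factor_regression(fx$table, fx$env, K = 25), "K must")
  # collinear covariables rejected in multivariate mode
  env_bad <- cbind(fx$env, fx$env[, 1] * 2)
  expect_error(fit_latent_factor_regression(fx$table, env_bad, K = 0),
               "collinear")
})

test_that("omega estimation recovers identity, duplication and blocks", {
  set.seed(4)
  # iid pseudo-frequencies: near-identity under sd scaling
  Y <- matrix(rnorm(30 * 4000), 30, 4000)
  tab <- freq_table(Y, 100, residual = TRUE)
  om <- estimate_omega(tab, shrinkage = 0, scale = "sd")
  expect_lt(max(abs(om - diag(30))), 0.15)
  # duplicated population rows: off-diagonal ~ diagonal
  Y2 <- rbind(Y[1, ], Y[1, ], Y[2:10, ])
  om2 <- estimate_omega(freq_table(Y2, 100, residual = TRUE), shrinkage = 0,
                        scale = "sd")
  expect_gt(om2[1, 2] / sqrt(om2[1, 1] * om2[2, 2]), 0.95)
  # planted block covariance
  blk <- kronecker(diag(5), matrix(0.8, 5, 5)) + diag(25) * 0.2
  fx <- make_linear_fixture(npop = 25, nsnp = 5000, m = 2,
                            B0 = matrix(0, 5000, 2), noise_sd = 0.1,
                            omega_spec = blk, seed = 5)
  omh <- estimate_omega(fx$table, scale = "sd")
  expect_gt(cor(as.vector(omh), as.vector(blk)), 0.9)
  # shrinkage keeps the estimate positive-definite even when nsnp < npop
  small <- freq_table(matrix(runif(25 * 10), 25, 10), 100)
  expect_no_error(chol(estimate_omega(small, shrinkage = 0.2)))
})

test_that("whitened GLS equals the latent-factor fit when omega is identity", {
  fx <- make_linear_fixture(npop = 20, nsnp = 200, m = 2, seed = 6)
  f_gls <- fit_gls_regression(fx$table, fx$env, diag(20), "multivariate")
  f_lf <- fit_latent_factor_regression(fx$table, fx$env, K = 0)
  expect_lt(max(abs(f_gls$B - f_lf$B)), 1e-10)
})

test_that("multivariate GLS matches the normal-equations oracle", {
  fx <- make_linear_fixture(npop = 20, nsnp = 150, m = 3, seed = 7)
  A <- matrix(rnorm(400), 20)
  om <- crossprod(A) / 20 + diag(20) * 0.5
  fit <- fit_gls_regression(fx$table, fx$env, om, "multivariate")
  Z <- cbind(1, fx$env)
  Oi <- solve(om)
  B_oracle <- t(solve(t(Z) %*% Oi %*% Z, t(Z) %*% Oi %*% fx$table$freq))[, -1]
  expect_lt(max(abs(fit$B - B_oracle)), 1e-8)
  expect_error(fit_gls_regression(fx$table, fx$env, matrix(0, 20, 20)),
               "positive-definite")
})

test_that("univariate and multivariate GLS differ under correlated covariables", {
  set.seed(8)
  npop <- 25
  x1 <- rnorm(npop)
  x2 <- 0.8 * x1 + sqrt(1 - 0.64) * rnorm(npop)
  fx <- make_linear_fixture(npop = npop, nsnp = 300, m = 2,
                            X = cbind(x1, x2), noise_sd = 0.05, seed = 8)
  om <- diag(npop)
  fu <- fit_gls_regression(fx$table, fx$env, om, "univariate")
  fm <- fit_gls_regression(fx$table, fx$env, om, "multivariate")
  expect_gt(max(abs(fu$B - fm$B)), 0.01)
})

test_that("using the true omega improves recovery over identity whitening", {
  blk <- kronecker(diag(4), matrix(0.9, 5, 5)) + diag(20) * 0.6
  wins <- 0
  for (s in 1:20) {
    fx <- make_linear_fixture(npop = 20, nsnp = 400, m = 2, noise_sd = 0.15,
                              omega_spec = blk, b_sd = 0.02, seed = 100 + s)
    e_true <- norm(fit_gls_regression(fx$table, fx$env, blk,
                                      "multivariate")$B - fx$truth$B0, "F")
    e_id <- norm(fit_gls_regression(fx$table, fx$env, diag(20),
                                    "multivariate")$B - fx$truth$B0, "F")
    wins <- wins + (e_true < e_id)
  }
  expect_gte(wins, 15)
})

test_that("residualization removes exactly the requested latent rank", {
  set.seed(9)
  tab <- freq_table(matrix(runif(20 * 60, 0.2, 0.8), 20, 60), 100)
  r0 <- residualize_frequencies(tab, 0)
  expect_equal(r0$freq, scale(tab$freq, scale = FALSE), ignore_attr = TRUE)
  r_full <- residualize_frequencies(tab, 19)
  expect_lt(max(abs(r_full$freq)), 1e-10)
  # rank-2 matrix plus noise: residual variance ~ noise variance
  U <- matrix(rnorm(20 * 2), 20, 2)
  V <- matrix(rnorm(60 * 2), 60, 2)
  noise <- matrix(rnorm(20 * 60, sd = 0.05), 20, 60)
  tab2 <- freq_table(U %*% t(V) * 0.1 + 0.5 + noise, 100, residual = TRUE)
  r2 <- residualize_frequencies(tab2, 2)
  expect_lt(abs(sd(as.vector(r2$freq)) - 0.05), 0.01)
  expect_error(residualize_frequencies(tab, 20), "K must")
})

test_that("XtX scores rank structure-corrected differentiation", {
  # constant SNP scores zero
  Y <- cbind(rep(0.4, 3), c(0.1, 0.5, 0.9), c(0.45, 0.5, 0.55))
  tab <- freq_table(Y, 100)
  sc <- xtx_statistic(tab, diag(3))
  expect_equal(sc$score[1], 0)
  # identity omega: score equals npop x standardized variance (hand check)
  p <- c(0.1, 0.5, 0.9)
  pbar <- mean(p)
  hand <- sum((p - pbar)^2) / (pbar * (1 - pbar))
  expect_equal(sc$score[2], hand, tolerance = 1e-12)
  expect_gt(sc$score[2], sc$score[3])
  expect_equal(sc$ranking[1], 2)
})

test_that("QTNs are enriched among top-decile XtX scores on simulated data", {
  sim <- desk_sim(seed = 1)
  tab <- sample_population_frequencies(sim, seed = 2)
  sc <- xtx_statistic(tab, estimate_omega(tab))
  top <- sc$ranking[seq_len(ceiling(0.1 * ncol(tab$freq)))]
  n_qtn <- sum(tab$snp$is_qtn)
  hits <- sum(tab$snp$is_qtn[top])
  # one-sided binomial test against the 10% baseline
  expect_lt(binom.test(hits, n_qtn, 0.1, alternative = "greater")$p.value, 0.01)
})

test_that("SNP pre-selection keeps the top-ranked fraction", {
  Y <- matrix(runif(5 * 10, 0.2, 0.8), 5, 10)
  tab <- freq_table(Y, 100, snp = data.frame(chrom = 1L, site = 0:9,
                                             is_qtn = FALSE))
  sc <- xtx_statistic(tab, diag(5))
  expect_equal(ncol(preselect_snps(tab, sc, 1)$freq), 10)
  one <- preselect_snps(tab, sc, 0.1)
  expect_equal(ncol(one$freq), 1)
  kept <- preselect_snps(tab, sc, 0.3)
  kept_scores <- sc$score[match(kept$snp$site, tab$snp$site)]
  expect_gte(min(kept_scores), max(sc$score[!(tab$snp$site %in% kept$snp$site)]))
})

test_that("covariable PCA is deterministic, invertible and projectable", {
  set.seed(10)
  X <- matrix(rnorm(30 * 5), 30, 5)
  colnames(X) <- paste0("v", 1:5)
  pca <- pca_covariables(X, 5)
  # exact reconstruction with all PCs
  Xs <- scale(X)
  expect_lt(max(abs(pca$scores %*% t(pca$loadings) - Xs)), 1e-10)
  # training rows project onto their own scores
  expect_lt(max(abs(project_covariables(pca, X) - pca$scores)), 1e-10)
  # sign convention: largest-magnitude loading positive
  for (k in 1:5) expect_gt(pca$loadings[which.max(abs(pca$loadings[, k])), k], 0)
  # duplicated column: shared variance on PC1
  X2 <- cbind(X[, 1], X[, 1], rnorm(30))
  p2 <- pca_covariables(X2, 3)
  expect_gt(p2$explained_variance[1], 0.6)
  expect_error(pca_covariables(cbind(X, 0), 2), "zero-variance")
})

test_that("orthogonal equal-variance covariables share explained variance", {
  # orthonormal columns that are also orthogonal to the intercept, so
  # centring and scaling preserve their orthogonality exactly
  set.seed(13)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(40 * 4), 40, 4))))[, -1]
  pca <- pca_covariables(Q, 4)
  expect_lt(diff(range(pca$explained_variance[1:4])), 1e-10)
})

test_that("PC-space fits back-transform without changing the offset", {
  fx <- make_linear_fixture(npop = 25, nsnp = 200, m = 5, noise_sd = 0.03,
                            seed = 11)
  pca <- pca_covariables(fx$env, 5)
  fit_pc <- fit_latent_factor_regression(
    freq_table(fx$table$freq, 100), pca$scores, K = 0)
  bt <- back_transform_importance(fit_pc, pca)
  for (i in 1:5) {
    e <- fx$env[i, ]
    es <- fx$env[i + 10, ]
    go_pc <- geometric_offset(fit_pc, project_covariables(pca, e),
                              project_covariables(pca, es))
    go_orig <- geometric_offset(bt, e, es)
    expect_lt(abs(go_pc - go_orig), 1e-8)
  }
  # identity loadings leave coefficients unchanged
  pca_id <- pca
  pca_id$loadings <- diag(5)
  bt_id <- back_transform_importance(fit_pc, pca_id)
  expect_equal(unname(bt_id$B), unname(fit_pc$B))
  expect_length(bt$importance, 5)
})

test_that("a covariable with zero loadings gets zero back-transformed importance", {
  fx <- make_linear_fixture(npop = 20, nsnp = 100, m = 3, seed = 12)
  pca <- pca_covariables(fx$env, 2)
  pca$loadings[3, ] <- 0        # third covariable absent from retained PCs
  scores <- scale(fx$env, pca$center, pca$scale) %*% pca$loadings
  fit_pc <- fit_latent_factor_regression(fx$table, scores, K = 0)
  bt <- back_transform_importance(fit_pc, pca)
  expect_equal(unname(bt$importance[3]), 0)
})
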