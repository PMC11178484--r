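#' Linear-model allele-frequency fixture with known truth
#'
#' Generates a population x SNP table with the statistical structure the GEA
#' stage assumes: `freq = clip01(0.5 + X B0' + U V' + E)` with known
#' coefficients `B0`, a rank-K latent term and noise whose across-population
#' covariance follows `omega_spec`. Used to test estimator recovery without
#' running the forward simulator.
#'
#' @param npop populations.
#' @param nsnp SNPs.
#' @param m covariables (drawn iid standard normal unless `X` is given).
#' @param K latent rank.
#' @param B0 true coefficient matrix (nsnp x m); default iid Normal(0, b_sd).
#' @param noise_sd elementwise noise standard deviation.
#' @param omega_spec "identity", or a positive-definite npop x npop matrix
#'   for correlated noise across populations.
#' @param latent_sd scale of the latent term.
#' @param b_sd scale of the default `B0` entries.
#' @param X optional explicit covariable matrix.
#' @param seed RNG seed.
#' @return list with `table` (a [freq_table()]), `env` (the covariables) and
#'   `truth` (list: `B0`, `factors`, `loadings`, `omega`).
#' @export
make_linear_fixture <- function(npop = 25L, nsnp = 2000L, m = 2L, K = 0L,
                                B0 = NULL, noise_sd = 0.05,
                                omega_spec = "identity", latent_sd = 0.05,
                                b_sd = 0.1, X = NULL, seed = NULL) {
  stopifnot(npop >= 2, nsnp >= 1, m >= 1, K >= 0, K < npop)
  with_seed_maybe(seed, {
    if (is.null(X)) X <- matrix(rnorm(npop * m), npop, m)
    X <- as.matrix(X)
    stopifnot(nrow(X) == npop, ncol(X) == m)
    colnames(X) <- colnames(X) %||% paste0("env", seq_len(m))
    if (is.null(B0)) B0 <- matrix(rnorm(nsnp * m, sd = b_sd), nsnp, m)
    stopifnot(nrow(B0) == nsnp, ncol(B0) == m)
    mu <- 0.5 + X %*% t(B0)
    factors <- NULL; loadings <- NULL
    if (K > 0) {
      # plant latent structure orthogonal to the covariables: with few
      # populations a raw random factor is confounded with X by chance,
      # which would make part of B0 unidentifiable for any estimator
      factors <- matrix(rnorm(npop * K), npop, K)
      factors <- qr.resid(qr(cbind(1, X)), factors)
      factors <- scale(factors, center = FALSE,
                       scale = apply(factors, 2, stats::sd))
      loadings <- matrix(rnorm(nsnp * K, sd = latent_sd), nsnp, K)
      mu <- mu + factors %*% t(loadings)
    }
    omega <- if (identical(omega_spec, "identity")) diag(npop)
             else as.matrix(omega_spec)
    stopifnot(nrow(omega) == npop, ncol(omega) == npop)
    E <- if (noise_sd > 0) {
      t(chol(omega)) %*% matrix(rnorm(npop * nsnp, sd = noise_sd), npop, nsnp)
    } else matrix(0, npop, nsnp)
    fr <- pmin(pmax(mu + E, 0), 1)
    tab <- freq_table(fr, sample_size = rep(1e6, npop),
                      snp = data.frame(chrom = rep(1L, nsnp),
                                       site = seq_len(nsnp) - 1L,
                                       is_qtn = rep(TRUE, nsnp)))
    list(table = tab, env = X,
         truth = list(B0 = B0, factors = factors, loadings = loadings,
                      omega = omega))
  })
}
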