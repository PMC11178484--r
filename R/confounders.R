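#' Extend causal covariables with confounding and fake variables
#'
#' Builds the eight-covariable set used in the confounded evaluation design:
#' the two causal variables, two "fake" Gaussian variables resampled until
#' their sample correlation with both causal variables lies in
#' `[-tol, tol]`, and four confounders correlated with a causal variable
#' (targets r = 0.4 and r = 0.8 for each of e1 and e2), built as
#' `r * standardized(causal) + sqrt(1 - r^2) * noise` and redrawn until the
#' realized correlation is within `tol` of the target. The draw is performed
#' jointly over all supplied environments (native demes plus candidate
#' invasion targets) so native and target rows share one covariable
#' definition.
#'
#' @param causal_env matrix with columns `e1`, `e2`, one row per environment
#'   (native demes first, then invadable environments).
#' @param seed RNG seed.
#' @param r_targets correlation targets for the confounders.
#' @param tol acceptance window around the targets (and around 0 for fakes).
#' @param max_tries bounded resampling attempts per column.
#' @return matrix with columns `e1, e2, fake1, fake2, corr1_0.4, corr1_0.8,
#'   corr2_0.4, corr2_0.8`.
#' @export
generate_confounders <- function(causal_env, seed = NULL,
                                 r_targets = c(0.4, 0.8), tol = 0.1,
                                 max_tries = 2000L) {
  causal_env <- as.matrix(causal_env)
  stopifnot(ncol(causal_env) == 2, nrow(causal_env) >= 4)
  n <- nrow(causal_env)
  e1 <- causal_env[, 1]; e2 <- causal_env[, 2]
  s1 <- as.numeric(scale(e1)); s2 <- as.numeric(scale(e2))
  with_seed_maybe(seed, {
    draw_fake <- function() {
      for (i in seq_len(max_tries)) {
        cand <- rnorm(n)
        if (abs(cor(cand, e1)) <= tol && abs(cor(cand, e2)) <= tol)
          return(cand)
      }
      stop("could not satisfy the fake-variable correlation window")
    }
    draw_corr <- function(s, r) {
      for (i in seq_len(max_tries)) {
        cand <- r * s + sqrt(1 - r^2) * rnorm(n)
        if (abs(cor(cand, s) - r) <= tol) return(cand)
      }
      stop("could not satisfy the confounder correlation window")
    }
    out <- cbind(e1 = e1, e2 = e2, fake1 = draw_fake(), fake2 = draw_fake(),
                 corr1_0.4 = draw_corr(s1, r_targets[1]),
                 corr1_0.8 = draw_corr(s1, r_targets[2]),
                 corr2_0.4 = draw_corr(s2, r_targets[1]),
                 corr2_0.8 = draw_corr(s2, r_targets[2]))
    rownames(out) <- rownames(causal_env)
    out
  })
}
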