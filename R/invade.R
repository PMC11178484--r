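#' Invasion configuration
#'
#' Parameters of the non-Wright-Fisher invasion model: a founder cohort drawn
#' from a source deme reproduces and dies in discrete time steps in a new
#' environment; repeated runs estimate the establishment probability.
#'
#' @param n_founders founder individuals (>= 2).
#' @param target_optima `(e1, e2)` of the invaded environment.
#' @param n_repetitions independent invasion repetitions.
#' @param size_threshold population size above which the invasion is deemed
#'   established.
#' @param time_threshold number of time steps after which a surviving
#'   population is deemed established (the founding cohort counts as step 1).
#' @param max_age individuals are removed once their age exceeds this many
#'   steps.
#' @param fecundity mean offspring per living individual per step; the
#'   offspring pool is Poisson(`fecundity` x current size) with uniformly
#'   drawn parent pairs.
#' @param survival `"all"` applies the fitness-based survival draw to every
#'   living individual including same-step newborns (viability selection, the
#'   default); `"pre_existing"` exempts newborns for one step.
#' @param hard_cap optional memory guard; reaching it ends the run with cause
#'   `"cap"` (not established).
#' @param seed root seed for the repetition ensemble.
#' @return an object of class `invasion_config`.
#' @export
invasion_config <- function(n_founders = 10L, target_optima = c(0, 0),
                            n_repetitions = 100L, size_threshold = 2000L,
                            time_threshold = 50L, max_age = 3L,
                            fecundity = 2.0, survival = c("all", "pre_existing"),
                            hard_cap = NULL, seed = NULL) {
  survival <- match.arg(survival)
  cfg <- list(n_founders = as.integer(n_founders),
              target_optima = as.numeric(target_optima),
              n_repetitions = as.integer(n_repetitions),
              size_threshold = as.integer(size_threshold),
              time_threshold = as.integer(time_threshold),
              max_age = as.integer(max_age), fecundity = fecundity,
              survival = survival,
              hard_cap = if (is.null(hard_cap)) NULL else as.integer(hard_cap),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  stopifnot(cfg$n_founders >= 2, cfg$n_repetitions >= 1,
            cfg$size_threshold >= 1, cfg$time_threshold >= 1,
            cfg$max_age >= 1, cfg$fecundity >= 0,
            length(cfg$target_optima) == 2)
  class(cfg) <- "invasion_config"
  cfg
}

#' Draw a founder cohort from a source deme
#'
#' Samples `n_founders` individuals without replacement from the source deme
#' of the native metapopulation; ages are initialized to 0.
#'
#' @param metapop a `metapop` (or `native_sim`).
#' @param source_deme deme index.
#' @param n_founders cohort size (<= deme size).
#' @param seed optional sampling seed.
#' @param qtn_only keep only QTN loci (neutral loci do not affect invasion
#'   dynamics; dropping them speeds simulation up).
#' @return an object of class `invasion_cohort`: list with `haplotypes`,
#'   `loci`, `fixed_effect`, `ages`, `sim_params` (inherited genome
#'   parameters).
#' @export
found_invasion <- function(metapop, source_deme, n_founders, seed = NULL,
                           qtn_only = FALSE) {
  mp <- if (inherits(metapop, "native_sim")) metapop$metapop else metapop
  stopifnot(inherits(mp, "metapop"))
  cfg <- mp$config
  N <- cfg$deme_size
  if (n_founders > N) stop("n_founders exceeds deme_size")
  D <- nrow(mp$layout$optima)
  stopifnot(source_deme >= 1, source_deme <= D)
  ind <- with_seed_maybe(seed, {
    if (n_founders == N) seq_len(N) else sample.int(N, n_founders)
  })
  cols <- as.vector(rbind(2L * ((source_deme - 1L) * N + ind - 1L) + 1L,
                          2L * ((source_deme - 1L) * N + ind - 1L) + 2L))
  keep <- if (qtn_only) mp$loci$is_qtn else rep(TRUE, nrow(mp$loci))
  structure(list(haplotypes = mp$haplotypes[keep, cols, drop = FALSE],
                 loci = mp$loci[keep, , drop = FALSE],
                 fixed_effect = mp$fixed_effect,
                 ages = rep(0L, n_founders),
                 sim_params = cfg, source_deme = source_deme),
            class = "invasion_cohort")
}

cohort_size <- function(cohort) length(cohort$ages)

# Phenotypes of every cohort member (n x 2).
cohort_phenotypes <- function(cohort) {
  cpp_phenotypes(cohort$haplotypes, cohort$loci$effect1, cohort$loci$effect2,
                 cohort$loci$is_qtn, cohort$fixed_effect[1], cohort$fixed_effect[2])
}

#' Advance an invasion cohort one time step
#'
#' Events within a step: (1) reproduction -- a Poisson(`fecundity` x size)
#' offspring pool with both parents drawn uniformly among all living
#' individuals, gametes produced by the same recombination/mutation machinery
#' as the native simulator; (2) survival -- each individual survives with
#' probability equal to its Gaussian fitness in the target environment
#' (applied to newborns as well under the default `survival = "all"`);
#' (3) ageing -- surviving pre-existing individuals age by one step and are
#' removed once their age exceeds `max_age`.
#'
#' @param cohort an `invasion_cohort`.
#' @param target_optima `(e1, e2)` of the invaded environment.
#' @param config an [invasion_config()].
#' @return the advanced cohort (possibly of size 0, signalling extinction);
#'   `attr(, "mean_fitness")` carries the pre-step cohort mean fitness.
#' @export
invasion_time_step <- function(cohort, target_optima, config) {
  stopifnot(inherits(cohort, "invasion_cohort"))
  if (!cohort_size(cohort)) stop("empty cohort")
  sp <- cohort$sim_params
  # neutral mutation is disabled when neutral loci were dropped from the cohort
  neutral_rate <- if (any(!cohort$loci$is_qtn)) sp$neutral_mut_rate else 0
  res <- cpp_invasion_step(cohort$haplotypes, cohort$ages, cohort$loci$chrom,
                           cohort$loci$site, cohort$loci$effect1,
                           cohort$loci$effect2, cohort$loci$is_qtn,
                           cohort$fixed_effect[1], cohort$fixed_effect[2],
                           target_optima[1], target_optima[2], sp$fitness_width,
                           config$fecundity, config$max_age,
                           sp$per_site_recomb_rate, sp$chromosome_length,
                           sp$n_chromosomes, n_qtn_chromosomes(sp),
                           sp$qtn_mut_rate, neutral_rate, sp$effect_sd,
                           config$survival == "all")
  n_new <- length(res$new_chrom)
  loci <- cohort$loci
  if (n_new > 0) {
    loci <- rbind(loci, data.frame(id = max(loci$id, 0L) + seq_len(n_new),
                                   chrom = res$new_chrom, site = res$new_pos,
                                   is_qtn = res$new_is_qtn,
                                   effect1 = res$new_eff1, effect2 = res$new_eff2,
                                   origin_generation = NA_integer_))
  }
  out <- cohort
  out$haplotypes <- res$H
  out$ages <- res$ages
  out$loci <- loci
  attr(out, "mean_fitness") <- res$mean_fitness
  out
}

#' Run one invasion to establishment or extinction
#'
#' The trajectory records the population size at each time step, the founding
#' cohort counting as step 1. The run ends when the size reaches
#' `size_threshold` (established), the step count reaches `time_threshold`
#' with a surviving population (established), the population goes extinct, or
#' the optional `hard_cap` is hit.
#'
#' @param cohort an `invasion_cohort`.
#' @param config an [invasion_config()].
#' @return an object of class `invasion_outcome`: list with `established`,
#'   `end_step`, `size_trajectory`, `cause`, and `founder_mean_fitness`.
#' @export
run_invasion <- function(cohort, config) {
  stopifnot(inherits(cohort, "invasion_cohort"))
  target <- config$target_optima
  z <- cohort_phenotypes(cohort)
  founder_fit <- mean(fitness_of(z, target, cohort$sim_params$fitness_width))
  traj <- cohort_size(cohort)
  step <- 1L
  cause <- NULL
  repeat {
    size <- traj[length(traj)]
    if (size >= config$size_threshold) { cause <- "size_threshold"; break }
    if (size == 0L) { cause <- "extinction"; break }
    if (step >= config$time_threshold) { cause <- "time_threshold"; break }
    if (!is.null(config$hard_cap) && size >= config$hard_cap) { cause <- "cap"; break }
    cohort <- invasion_time_step(cohort, target, config)
    step <- step + 1L
    traj <- c(traj, cohort_size(cohort))
  }
  structure(list(established = cause %in% c("size_threshold", "time_threshold"),
                 end_step = step, size_trajectory = traj, cause = cause,
                 founder_mean_fitness = founder_fit),
            class = "invasion_outcome")
}

#' Early log-linear growth rate of an invasion trajectory
#'
#' Least-squares slope of `log(size + 1)` on the step index over the first
#' `window` trajectory entries.
#'
#' @param outcome an `invasion_outcome` (or a bare numeric trajectory).
#' @param window steps used for the fit.
#' @return per-step growth rate.
#' @export
growth_rate <- function(outcome, window = 10L) {
  traj <- if (inherits(outcome, "invasion_outcome")) outcome$size_trajectory
          else as.numeric(outcome)
  if (length(traj) < 2) stop("trajectory too short for a growth rate")
  k <- min(window, length(traj))
  if (k < 2) stop("degenerate window")
  y <- log(traj[seq_len(k)] + 1)
  x <- seq_len(k) - 1
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Establishment probability from repeated invasions
#'
#' Repeats founder sampling and invasion `n_repetitions` times with seeds
#' derived from the root seed, and tallies established runs. `log_ep` applies
#' the continuity correction `ep = 1/(2 n_repetitions)` before taking the log
#' when no repetition establishes.
#'
#' @param metapop a `metapop` or `native_sim`.
#' @param source_deme source deme index.
#' @param config an [invasion_config()].
#' @return an object of class `establishment_result`: list with `ep`,
#'   `log_ep`, `outcomes`, `mean_founder_fitness`, `mean_growth_rate`,
#'   `config`.
#' @export
establishment_probability <- function(metapop, source_deme, config) {
  mp <- if (inherits(metapop, "native_sim")) metapop$metapop else metapop
  stopifnot(inherits(mp, "metapop"), inherits(config, "invasion_config"))
  seeds <- derive_seeds(config$seed, config$n_repetitions)
  outcomes <- vector("list", config$n_repetitions)
  for (r in seq_len(config$n_repetitions)) {
    outcomes[[r]] <- withr::with_seed(seeds[r], {
      cohort <- found_invasion(mp, source_deme, config$n_founders,
                               qtn_only = TRUE)
      run_invasion(cohort, config)
    })
  }
  n_est <- sum(vapply(outcomes, function(o) o$established, logical(1)))
  ep <- n_est / config$n_repetitions
  ep_for_log <- if (ep == 0) 1 / (2 * config$n_repetitions) else ep
  growth <- vapply(outcomes, function(o) {
    if (length(o$size_trajectory) >= 2) growth_rate(o) else NA_real_
  }, numeric(1))
  structure(list(ep = ep, log_ep = log(ep_for_log), outcomes = outcomes,
                 mean_founder_fitness = mean(vapply(outcomes, function(o)
                   o$founder_mean_fitness, numeric(1))),
                 mean_growth_rate = mean(growth, na.rm = TRUE),
                 config = config, source_deme = source_deme),
            class = "establishment_result")
}

#' @export
print.establishment_result <- function(x, ...) {
  cat(sprintf("establishment_result: ep = %.3f (log_ep = %.3f) over %d repetitions\n",
              x$ep, x$log_ep, x$config$n_repetitions))
  cat(sprintf("  mean founder fitness %.3f, mean growth rate %.3f\n",
              x$mean_founder_fitness, x$mean_growth_rate))
  invisible(x)
}
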