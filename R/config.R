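#' Simulation configuration for the native-range grid model
#'
#' Bundles and validates the parameters of the Wright-Fisher stepping-stone
#' simulator. Defaults are desk-scale (small demes, short genome, short
#' phases) so a full grid history runs in seconds; the original study scale
#' (1000 individuals per deme, 5e5-site chromosomes, 1000-generation phases)
#' is reachable by overriding the corresponding fields.
#'
#' @param grid_side side of the square grid of demes (default 5, i.e. 25 demes).
#' @param deme_size diploid individuals per deme (constant over WF phases).
#' @param migration_rate per-offspring probability that both parents come from
#'   one uniformly chosen von Neumann neighbour deme (total immigration rate).
#' @param n_chromosomes number of chromosomes; QTNs arise on the first
#'   `n_chromosomes - 1` of them, neutral mutations anywhere.
#' @param chromosome_length sites per chromosome.
#' @param per_site_recomb_rate per-site, per-generation crossover probability;
#'   chromosomes assort freely.
#' @param qtn_mut_rate per-site, per-generation QTN mutation rate on QTN
#'   chromosomes.
#' @param neutral_mut_rate per-site, per-generation neutral mutation rate.
#' @param effect_sd standard deviation of QTN effect sizes (per trait,
#'   phenotypic-SD units).
#' @param fitness_width width (sigma_w) of the bivariate Gaussian stabilizing
#'   fitness kernel, in trait units.
#' @param phase_lengths generations for the three phases: burn-in at optima 0,
#'   linear ramp towards the layout optima, hold at the layout optima.
#' @param maf_threshold minor-allele-frequency cutoff applied when sampling
#'   population frequencies.
#' @param sample_size individuals sampled per deme for GEA training tables
#'   (default: 50, capped at `deme_size`).
#' @param n_neutral_init number of standing neutral polymorphisms seeded at
#'   burn-in start from a truncated 1/x site-frequency spectrum.
#' @param seed integer root seed; `NULL` uses the current RNG stream.
#' @return an object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(grid_side = 5L, deme_size = 100L, migration_rate = 0.005,
                       n_chromosomes = 5L, chromosome_length = 50000L,
                       per_site_recomb_rate = 1e-5, qtn_mut_rate = 2.5e-8,
                       neutral_mut_rate = 1e-7, effect_sd = 0.1,
                       fitness_width = 0.5, phase_lengths = c(200L, 200L, 200L),
                       maf_threshold = 0.01, sample_size = NULL,
                       n_neutral_init = 3000L, seed = NULL) {
  if (is.null(sample_size)) sample_size <- min(50L, as.integer(deme_size))
  cfg <- list(grid_side = as.integer(grid_side), deme_size = as.integer(deme_size),
              migration_rate = migration_rate, n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = as.integer(chromosome_length),
              per_site_recomb_rate = per_site_recomb_rate, qtn_mut_rate = qtn_mut_rate,
              neutral_mut_rate = neutral_mut_rate, effect_sd = effect_sd,
              fitness_width = fitness_width, phase_lengths = as.integer(phase_lengths),
              maf_threshold = maf_threshold, sample_size = as.integer(sample_size),
              n_neutral_init = as.integer(n_neutral_init),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  rates <- c(migration_rate = cfg$migration_rate,
             per_site_recomb_rate = cfg$per_site_recomb_rate,
             qtn_mut_rate = cfg$qtn_mut_rate, neutral_mut_rate = cfg$neutral_mut_rate,
             maf_threshold = cfg$maf_threshold)
  if (any(rates < 0 | rates > 1)) stop("all rates and fractions must lie in [0, 1]")
  counts <- c(cfg$grid_side, cfg$deme_size, cfg$n_chromosomes, cfg$chromosome_length)
  if (any(counts < 1)) stop("all lengths/counts must be >= 1")
  if (length(cfg$phase_lengths) != 3 || any(cfg$phase_lengths < 0))
    stop("phase_lengths must be three non-negative generation counts")
  if (cfg$fitness_width <= 0) stop("fitness_width must be > 0")
  if (cfg$effect_sd < 0) stop("effect_sd must be >= 0")
  if (cfg$sample_size < 1 || cfg$sample_size > cfg$deme_size)
    stop("sample_size must be in 1..deme_size")
  if (cfg$n_neutral_init < 0) stop("n_neutral_init must be >= 0")
  invisible(cfg)
}

#' Read a simulation configuration from YAML or JSON
#'
#' Unknown keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return a [sim_config()] object.
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(sim_config, raw)
}

# Number of chromosomes carrying QTNs: the last chromosome is neutral-only,
# matching a five-chromosome genome with QTNs on the first four.
n_qtn_chromosomes <- function(cfg) max(1L, cfg$n_chromosomes - 1L)
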