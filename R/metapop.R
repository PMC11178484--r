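#' @section Metapopulation representation:
#' A `metapop` object stores the whole grid as one dense 0/1 haplotype matrix
#' (`haplotypes`: loci x 2 * deme_size * n_demes, two adjacent columns per
#' diploid individual, demes in index order) plus a locus registry `loci`
#' (data.frame: id, chrom, site, is_qtn, effect1, effect2, origin_generation).
#' Sites are 0-based internally and written 1-based on disk. QTNs that reach
#' fixation are compacted away and their effects accumulated into
#' `fixed_effect` so phenotypes are unchanged.
#' @name metapop-internals
#' @keywords internal
NULL

new_metapop <- function(haplotypes, loci, fixed_effect, layout, config,
                        generation = 0L, next_id = NULL) {
  if (is.null(next_id)) next_id <- if (nrow(loci)) max(loci$id) + 1L else 1L
  structure(list(generation = as.integer(generation), haplotypes = haplotypes,
                 loci = loci, fixed_effect = fixed_effect, layout = layout,
                 config = config, next_id = as.integer(next_id)),
            class = "metapop")
}

empty_loci <- function() {
  data.frame(id = integer(0), chrom = integer(0), site = integer(0),
             is_qtn = logical(0), effect1 = numeric(0), effect2 = numeric(0),
             origin_generation = integer(0))
}

#' Initialize a metapopulation with standing neutral variation
#'
#' Seeds `n_neutral_init` neutral polymorphisms at unique sites. Initial
#' frequencies are drawn from a 1/x site-frequency spectrum truncated to
#' `[1/(2N), 1 - 1/(2N)]` and alleles are assigned binomially and
#' independently across all haplotypes (a panmictic ancestral population).
#' QTNs are absent at initialization; they arise by mutation during burn-in.
#'
#' @param config a [sim_config()].
#' @param layout an [build_environment_layout()] result.
#' @return a `metapop` object at generation 0.
#' @export
init_metapopulation <- function(config, layout) {
  validate_sim_config(config)
  D <- config$grid_side^2
  stopifnot(nrow(layout$optima) == D)
  n_hap <- 2L * config$deme_size * D
  L <- config$n_neutral_init
  if (L > 0) {
    a <- 1 / (2 * config$deme_size)
    b <- 1 - a
    u <- runif(L)
    freqs <- a * (b / a)^u                       # inverse CDF of 1/x on [a, b]
    sites <- sample_unique_sites(L, config$n_chromosomes, config$chromosome_length)
    H <- matrix(0L, nrow = L, ncol = n_hap)
    for (r in seq_len(L)) H[r, ] <- rbinom(n_hap, 1L, freqs[r])
    loci <- data.frame(id = seq_len(L), chrom = sites$chrom, site = sites$site,
                       is_qtn = FALSE, effect1 = 0, effect2 = 0,
                       origin_generation = 0L)
  } else {
    H <- matrix(0L, nrow = 0, ncol = n_hap)
    loci <- empty_loci()
  }
  new_metapop(H, loci, c(0, 0), layout, config)
}

# Unique (chrom, site) pairs, site 0-based.
sample_unique_sites <- function(n, n_chrom, chrom_len) {
  keys <- integer(0)
  while (length(keys) < n) {
    cand <- (sample.int(n_chrom, n, replace = TRUE) - 1L) * chrom_len +
      (sample.int(chrom_len, n, replace = TRUE) - 1L)
    keys <- unique(c(keys, cand))
  }
  keys <- keys[seq_len(n)]
  list(chrom = keys %/% chrom_len + 1L, site = keys %% chrom_len)
}

#' Additive phenotypes of one individual
#'
#' Sums, over both haplotypes, the per-trait effect sizes of all QTNs carried
#' by the individual (strictly additive, dosage-weighted), plus any effect
#' accumulated from fixed QTNs.
#'
#' @param individual a list with integer vectors `hap1` and `hap2` of locus
#'   ids (see [get_individual()]).
#' @param qtn_registry the `loci` data.frame of a `metapop` (only rows with
#'   `is_qtn` contribute).
#' @param fixed_effect length-2 offset from fixed QTNs (default none).
#' @return numeric `(z1, z2)`.
#' @export
phenotype_of <- function(individual, qtn_registry, fixed_effect = c(0, 0)) {
  ids <- c(individual$hap1, individual$hap2)
  if (length(ids)) {
    pos <- match(ids, qtn_registry$id)
    if (anyNA(pos)) stop("unresolvable mutation id: ",
                         paste(ids[is.na(pos)], collapse = ", "))
    keep <- qtn_registry$is_qtn[pos]
    z <- c(sum(qtn_registry$effect1[pos][keep]), sum(qtn_registry$effect2[pos][keep]))
  } else {
    z <- c(0, 0)
  }
  z + fixed_effect
}

#' Extract one individual as sparse haplotype id sets
#'
#' @param metapop a `metapop`.
#' @param deme deme index (1-based).
#' @param i individual index within the deme.
#' @return list with `hap1`, `hap2` (locus ids carried).
#' @export
get_individual <- function(metapop, deme, i) {
  N <- metapop$config$deme_size
  stopifnot(deme >= 1, deme <= nrow(metapop$layout$optima), i >= 1, i <= N)
  base <- 2L * ((deme - 1L) * N + (i - 1L))
  h1 <- metapop$haplotypes[, base + 1L]
  h2 <- metapop$haplotypes[, base + 2L]
  list(hap1 = metapop$loci$id[h1 == 1L], hap2 = metapop$loci$id[h2 == 1L])
}

#' Gaussian stabilizing fitness
#'
#' `w = exp(-((z1-e1)^2 + (z2-e2)^2) / (2 sigma_w^2))`: maximal (1) when the
#' phenotypes match the optima, strictly decreasing in the Euclidean
#' phenotype-optimum distance, symmetric in the sign of the deviation.
#'
#' @param phenotypes numeric length-2 `(z1, z2)` or an n x 2 matrix.
#' @param optima numeric length-2 `(e1, e2)`.
#' @param fitness_width kernel width sigma_w (> 0).
#' @return fitness in (0, 1] (vectorized over matrix rows).
#' @export
fitness_of <- function(phenotypes, optima, fitness_width) {
  stopifnot(fitness_width > 0)
  if (is.matrix(phenotypes)) {
    d2 <- (phenotypes[, 1] - optima[1])^2 + (phenotypes[, 2] - optima[2])^2
  } else {
    d2 <- (phenotypes[1] - optima[1])^2 + (phenotypes[2] - optima[2])^2
  }
  exp(-d2 / (2 * fitness_width^2))
}

# Phenotypes of every individual in the grid (n_ind x 2 matrix).
metapop_phenotypes <- function(mp) {
  cpp_phenotypes(mp$haplotypes, mp$loci$effect1, mp$loci$effect2,
                 mp$loci$is_qtn, mp$fixed_effect[1], mp$fixed_effect[2])
}

#' Advance the metapopulation one Wright-Fisher generation
#'
#' For each offspring slot, with probability `migration_rate` both parents are
#' drawn from one uniformly chosen von Neumann neighbour deme, otherwise from
#' the home deme; parents are drawn with probability proportional to their
#' Gaussian fitness under the deme's current optima; each transmitted gamete
#' is produced by free chromosome assortment with Poisson crossovers, and new
#' QTN/neutral mutations are added at the configured rates with QTN effects
#' drawn iid Normal(0, effect_sd) per trait.
#'
#' @param metapop a `metapop`.
#' @param current_optima `n_demes x 2` matrix of this generation's optima.
#' @param config a [sim_config()] (defaults to the one stored in `metapop`).
#' @return the advanced `metapop`; the parental mean fitness per deme is
#'   available as `attr(, "mean_fitness")`.
#' @export
wf_generation <- function(metapop, current_optima, config = metapop$config) {
  stopifnot(inherits(metapop, "metapop"))
  current_optima <- as.matrix(current_optima)
  res <- cpp_wf_generation(metapop$haplotypes, metapop$loci$chrom, metapop$loci$site,
                           metapop$loci$effect1, metapop$loci$effect2,
                           metapop$loci$is_qtn, metapop$fixed_effect[1],
                           metapop$fixed_effect[2], current_optima,
                           grid_neighbors(config$grid_side), config$deme_size,
                           config$migration_rate, config$fitness_width,
                           config$per_site_recomb_rate, config$chromosome_length,
                           config$n_chromosomes, n_qtn_chromosomes(config),
                           config$qtn_mut_rate, config$neutral_mut_rate,
                           config$effect_sd)
  n_new <- length(res$new_chrom)
  loci <- metapop$loci
  next_id <- metapop$next_id
  if (n_new > 0) {
    gen <- metapop$generation + 1L
    loci <- rbind(loci, data.frame(id = next_id + seq_len(n_new) - 1L,
                                   chrom = res$new_chrom, site = res$new_pos,
                                   is_qtn = res$new_is_qtn,
                                   effect1 = res$new_eff1, effect2 = res$new_eff2,
                                   origin_generation = gen))
    next_id <- next_id + n_new
  }
  out <- new_metapop(res$H, loci, metapop$fixed_effect, metapop$layout,
                     metapop$config, metapop$generation + 1L, next_id)
  attr(out, "mean_fitness") <- res$mean_fitness
  out
}

# Drop loci lost everywhere; fold fixed QTNs into the fixed-effect offset.
compact_metapop <- function(mp) {
  if (!nrow(mp$loci)) return(mp)
  counts <- rowSums(mp$haplotypes)
  n_hap <- ncol(mp$haplotypes)
  lost <- counts == 0L
  fixed <- counts == n_hap
  if (!any(lost | fixed)) return(mp)
  add <- which(fixed & mp$loci$is_qtn)
  if (length(add)) {
    mp$fixed_effect <- mp$fixed_effect +
      c(2 * sum(mp$loci$effect1[add]), 2 * sum(mp$loci$effect2[add]))
  }
  keep <- !(lost | fixed)
  mp$haplotypes <- mp$haplotypes[keep, , drop = FALSE]
  mp$loci <- mp$loci[keep, , drop = FALSE]
  rownames(mp$loci) <- NULL
  mp
}

#' Run the full native-range simulation
#'
#' Three phases: (i) burn-in with every optimum at 0, (ii) a per-generation
#' linear ramp of each deme's optima from 0 to the layout values, (iii) hold
#' at the layout values. Standing neutral variation is seeded at burn-in start
#' and mutated forward throughout.
#'
#' @param config a [sim_config()]; its `seed` (if non-NULL) makes the run
#'   fully reproducible.
#' @param layout an `env_layout` matching `config$grid_side`.
#' @return an object of class `native_sim`: list with `metapop` (final state),
#'   `fitness_history` (generations x demes matrix of parental mean fitness),
#'   `config`, `layout` and `seed`.
#' @details The full generation loop runs in compiled code with loci kept
#'   sorted and compacted every generation; [wf_generation()] exposes the
#'   same single-generation transition for inspection and testing.
#' @export
run_native_simulation <- function(config, layout) {
  validate_sim_config(config)
  with_seed_maybe(config$seed, {
    mp <- init_metapopulation(config, layout)
    res <- cpp_run_native(mp$haplotypes, mp$loci$id, mp$loci$chrom, mp$loci$site,
                          mp$loci$is_qtn, mp$loci$effect1, mp$loci$effect2,
                          mp$loci$origin_generation, mp$fixed_effect[1],
                          mp$fixed_effect[2], layout$optima,
                          grid_neighbors(config$grid_side), config$deme_size,
                          config$migration_rate, config$fitness_width,
                          config$per_site_recomb_rate, config$chromosome_length,
                          config$n_chromosomes, n_qtn_chromosomes(config),
                          config$qtn_mut_rate, config$neutral_mut_rate,
                          config$effect_sd, config$phase_lengths, mp$next_id)
    loci <- data.frame(id = res$id, chrom = res$chrom, site = res$site,
                       is_qtn = res$is_qtn, effect1 = res$eff1,
                       effect2 = res$eff2, origin_generation = res$origin)
    mp <- new_metapop(res$H, loci, c(res$fixed1, res$fixed2), layout, config,
                      generation = res$generation, next_id = res$next_id)
    structure(list(metapop = mp, fitness_history = res$fitness_history,
                   config = config, layout = layout, seed = config$seed),
              class = "native_sim")
  })
}

#' Population allele-frequency table from sampled individuals
#'
#' Samples `sample_size` individuals per deme without replacement (frequencies
#' are computed over `2 * sample_size` alleles), restricts to the requested
#' SNP class, and removes SNPs whose pooled minor-allele frequency falls below
#' `maf_threshold`.
#'
#' @param x a `metapop` or `native_sim`.
#' @param sample_size individuals per deme (defaults to the config value;
#'   `deme_size` yields full-population frequencies).
#' @param maf_threshold pooled-MAF cutoff (0 keeps all segregating SNPs).
#' @param seed optional sampling seed.
#' @param snp_set one of "all", "qtn_only", "neutral_only".
#' @return a [freq_table()] (populations x SNPs).
#' @export
sample_population_frequencies <- function(x, sample_size = NULL, maf_threshold = NULL,
                                          seed = NULL,
                                          snp_set = c("all", "qtn_only", "neutral_only")) {
  mp <- if (inherits(x, "native_sim")) x$metapop else x
  stopifnot(inherits(mp, "metapop"))
  snp_set <- match.arg(snp_set)
  cfg <- mp$config
  if (is.null(sample_size)) sample_size <- cfg$sample_size
  if (is.null(maf_threshold)) maf_threshold <- cfg$maf_threshold
  if (sample_size > cfg$deme_size) stop("sample_size exceeds deme_size")
  D <- nrow(mp$layout$optima)
  N <- cfg$deme_size
  keep_snp <- switch(snp_set,
                     all = rep(TRUE, nrow(mp$loci)),
                     qtn_only = mp$loci$is_qtn,
                     neutral_only = !mp$loci$is_qtn)
  H <- mp$haplotypes[keep_snp, , drop = FALSE]
  loci <- mp$loci[keep_snp, , drop = FALSE]
  freq <- with_seed_maybe(seed, {
    f <- matrix(NA_real_, nrow = D, ncol = nrow(H))
    for (d in seq_len(D)) {
      ind <- if (sample_size == N) seq_len(N) else sample.int(N, sample_size)
      cols <- as.vector(rbind(2L * ((d - 1L) * N + ind - 1L) + 1L,
                              2L * ((d - 1L) * N + ind - 1L) + 2L))
      f[d, ] <- rowMeans(H[, cols, drop = FALSE])
    }
    f
  })
  tab <- freq_table(freq, sample_size = rep(2L * sample_size, D),
                    snp = data.frame(chrom = loci$chrom, site = loci$site,
                                     is_qtn = loci$is_qtn),
                    pop_ids = paste0("pop", seq_len(D)))
  maf_filter(tab, maf_threshold)
}
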