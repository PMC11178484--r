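# Shared simulation fixtures, built lazily and cached for the whole test run.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, expr, envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# Small grid history for unit tests: runs in well under a second.
tiny_config <- function(seed = 1, migration_rate = 0.005, ...) {
  sim_config(deme_size = 30L, chromosome_length = 10000L,
             n_neutral_init = 400L, phase_lengths = c(60L, 60L, 60L),
             sample_size = 20L, migration_rate = migration_rate,
             seed = seed, ...)
}

tiny_sim <- function(seed = 1, migration_rate = 0.005, layout_type = "L") {
  key <- paste("tiny", seed, migration_rate, layout_type)
  cached(key, run_native_simulation(tiny_config(seed, migration_rate),
                                    build_environment_layout(layout_type)))
}

# Desk-scale history (spec-default config): ~10 s, shared across tests that
# need realistic levels of polymorphism and structure.
desk_sim <- function(seed = 1, migration_rate = 0.005) {
  key <- paste("desk", seed, migration_rate)
  cached(key, run_native_simulation(
    sim_config(migration_rate = migration_rate, seed = seed),
    build_environment_layout("L")))
}

# Build a metapop by hand from explicit haplotypes (loci x 2N matrix per deme).
manual_metapop <- function(haplo_list, loci, config, layout,
                           fixed_effect = c(0, 0)) {
  H <- do.call(cbind, haplo_list)
  invadeGO:::new_metapop(H, loci, fixed_effect, layout, config)
}

make_loci <- function(n, chrom = 1L, is_qtn = FALSE, effect1 = 0, effect2 = 0) {
  data.frame(id = seq_len(n), chrom = chrom, site = seq_len(n) - 1L,
             is_qtn = is_qtn, effect1 = effect1, effect2 = effect2,
             origin_generation = 0L)
}
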