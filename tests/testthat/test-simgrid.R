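fake_layout <- function(optima) {
  structure(list(layout_type = "custom", grid_side = as.integer(sqrt(nrow(optima))),
                 optima = optima), class = "env_layout")
}

test_that("phenotypes are additive, dosage-weighted sums of QTN effects", {
  reg <- make_loci(3, is_qtn = c(TRUE, TRUE, FALSE),
                   effect1 = c(0.1, -0.3, 99), effect2 = c(-0.2, 0.5, 99))
  expect_equal(phenotype_of(list(hap1 = integer(0), hap2 = integer(0)), reg),
               c(0, 0))
  # heterozygous then homozygous for QTN 1
  expect_equal(phenotype_of(list(hap1 = 1L, hap2 = integer(0)), reg),
               c(0.1, -0.2))
  expect_equal(phenotype_of(list(hap1 = 1L, hap2 = 1L), reg), c(0.2, -0.4))
  # neutral loci never contribute
  expect_equal(phenotype_of(list(hap1 = 3L, hap2 = 3L), reg), c(0, 0))
  expect_error(phenotype_of(list(hap1 = 77L, hap2 = integer(0)), reg),
               "unresolvable")
})

test_that("compiled phenotypes match a brute-force loop over haplotypes", {
  sim <- tiny_sim()
  mp <- sim$metapop
  Z <- invadeGO:::metapop_phenotypes(mp)
  for (pick in list(c(1, 1), c(3, 7), c(25, 30))) {
    ind <- get_individual(mp, pick[1], pick[2])
    # independent brute force: look up each carried id in the registry
    brute <- c(0, 0)
    for (id in c(ind$hap1, ind$hap2)) {
      r <- which(mp$loci$id == id)
      if (mp$loci$is_qtn[r])
        brute <- brute + c(mp$loci$effect1[r], mp$loci$effect2[r])
    }
    brute <- brute + mp$fixed_effect
    i <- (pick[1] - 1) * mp$config$deme_size + pick[2]
    expect_equal(unname(Z[i, ]), brute, tolerance = 1e-12)
  }
})

test_that("Gaussian fitness kernel is maximal at the optimum and symmetric", {
  expect_equal(fitness_of(c(0.3, -0.7), c(0.3, -0.7), 0.5), 1)
  d <- c(0.2, -0.4)
  e <- c(0.1, 0.6)
  expect_equal(fitness_of(e + d, e, 0.5), fitness_of(e - d, e, 0.5))
  # closed form of the kernel
  expect_equal(fitness_of(c(0.5, 0), c(0, 0), 0.5), exp(-0.5))
  # strictly decreasing in distance
  ds <- seq(0, 2, 0.25)
  w <- vapply(ds, function(x) fitness_of(c(x, 0), c(0, 0), 0.5), numeric(1))
  expect_true(all(diff(w) < 0))
  expect_true(all(w > 0 & w <= 1))
  expect_error(fitness_of(c(0, 0), c(0, 0), 0))
})

test_that("wf_generation preserves deme sizes and is seeded-deterministic", {
  cfg <- tiny_config(seed = NULL)
  lay <- build_environment_layout("L")
  set.seed(5)
  mp <- init_metapopulation(cfg, lay)
  a <- withr::with_seed(9, wf_generation(mp, lay$optima, cfg))
  b <- withr::with_seed(9, wf_generation(mp, lay$optima, cfg))
  expect_identical(a$haplotypes, b$haplotypes)
  expect_identical(a$loci, b$loci)
  expect_equal(ncol(a$haplotypes), 2 * cfg$deme_size * 25)
  expect_equal(a$generation, 1L)
  expect_true(all(attr(a, "mean_fitness") > 0 & attr(a, "mean_fitness") <= 1))
})

test_that("QTN effect sizes are drawn with the configured standard deviation", {
  cfg <- sim_config(grid_side = 1, deme_size = 30, chromosome_length = 10000,
                    n_neutral_init = 0, qtn_mut_rate = 6.25e-5,
                    neutral_mut_rate = 0, sample_size = 30,
                    phase_lengths = c(1, 1, 1))
  lay <- fake_layout(matrix(0, 1, 2))
  mp <- withr::with_seed(3, init_metapopulation(cfg, lay))
  withr::with_seed(4, {
    for (g in 1:12) mp <- wf_generation(mp, lay$optima, cfg)
  })
  eff <- c(mp$loci$effect1[mp$loci$is_qtn], mp$loci$effect2[mp$loci$is_qtn])
  expect_gt(length(eff), 1000)
  expect_lt(abs(sd(eff) - 0.1), 0.01)
  expect_lt(abs(mean(eff)), 0.01)
})

test_that("a strongly beneficial QTN rises in frequency under selection", {
  cfg <- sim_config(grid_side = 1, deme_size = 40, chromosome_length = 1000,
                    n_neutral_init = 0, qtn_mut_rate = 0, neutral_mut_rate = 0,
                    sample_size = 40, phase_lengths = c(1, 1, 1))
  lay <- fake_layout(matrix(c(1, 1), 1, 2))
  loci <- make_loci(1, is_qtn = TRUE, effect1 = 0.5, effect2 = 0.5)
  deltas <- vapply(1:50, function(s) {
    withr::with_seed(s, {
      H <- matrix(rbinom(80, 1, 0.25), nrow = 1)
      mp <- manual_metapop(list(H), loci, cfg, lay)
      p0 <- mean(H)
      mp2 <- wf_generation(mp, lay$optima, cfg)
      mean(mp2$haplotypes[1, ]) - p0
    })
  }, numeric(1))
  expect_gt(mean(deltas), 0.1)
  expect_lt(t.test(deltas, alternative = "greater")$p.value, 1e-6)
})

test_that("neutral heterozygosity decays at rate (1 - 1/(2N)) without selection", {
  N <- 20L
  gens <- 15L
  cfg <- sim_config(grid_side = 1, deme_size = N, chromosome_length = 500,
                    n_chromosomes = 5, n_neutral_init = 0, qtn_mut_rate = 0,
                    neutral_mut_rate = 0, fitness_width = 1e6, sample_size = N,
                    phase_lengths = c(1, 1, 1))
  lay <- fake_layout(matrix(0, 1, 2))
  loci <- make_loci(20, chrom = rep(1:5, each = 4))
  ratios <- vapply(1:30, function(s) {
    withr::with_seed(100 + s, {
      H <- matrix(rbinom(20 * 2 * N, 1, 0.5), nrow = 20)
      mp <- manual_metapop(list(H), loci, cfg, lay)
      het0 <- mean(2 * rowMeans(H) * (1 - rowMeans(H)))
      for (g in seq_len(gens)) mp <- wf_generation(mp, lay$optima, cfg)
      p <- rowMeans(mp$haplotypes)
      mean(2 * p * (1 - p)) / het0
    })
  }, numeric(1))
  expected <- (1 - 1 / (2 * N))^gens
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - expected), 3 * se + 1e-8)
})

test_that("phase structure controls when the environmental optima apply", {
  lay <- build_environment_layout("L")
  # degenerate phases: optima at layout values from generation 1
  cfg_a <- tiny_config(seed = 21)
  cfg_a$phase_lengths <- c(0L, 0L, 10L)
  sim_a <- run_native_simulation(cfg_a, lay)
  expect_lt(sim_a$fitness_history[1, 1], 0.1)   # corner deme mismatched at once
  # burn-in only: optima all zero, unadapted populations are near-optimal
  cfg_b <- tiny_config(seed = 21)
  cfg_b$phase_lengths <- c(10L, 0L, 0L)
  sim_b <- run_native_simulation(cfg_b, lay)
  expect_gt(sim_b$fitness_history[1, 1], 0.9)
})

test_that("native simulation is bit-reproducible under the same seed", {
  cfg <- tiny_config(seed = 77)
  lay <- build_environment_layout("L")
  a <- run_native_simulation(cfg, lay)
  b <- run_native_simulation(cfg, lay)
  expect_identical(a$metapop$haplotypes, b$metapop$haplotypes)
  expect_identical(a$metapop$loci, b$metapop$loci)
  expect_identical(a$fitness_history, b$fitness_history)
})

test_that("adaptation happens: mean fitness recovers during phase 3", {
  sim <- tiny_sim()
  fh <- rowMeans(sim$fitness_history)
  ph <- sim$config$phase_lengths
  # fitness dips as optima ramp away, then recovers by the end of phase 3
  expect_gt(fh[sum(ph)], fh[ph[1] + ph[2]])
  expect_true(all(fh > 0 & fh <= 1))
})

test_that("sampled frequency tables match hand counts and apply filters", {
  cfg <- sim_config(grid_side = 1, deme_size = 4, chromosome_length = 100,
                    n_neutral_init = 0, sample_size = 4,
                    phase_lengths = c(1, 1, 1))
  lay <- fake_layout(matrix(0, 1, 2))
  loci <- make_loci(3, is_qtn = c(TRUE, FALSE, FALSE))
  H <- rbind(c(1, 0, 0, 0, 1, 1, 0, 1),   # 4/8
             c(1, 1, 1, 1, 1, 1, 1, 0),   # 7/8
             c(0, 0, 0, 0, 0, 0, 0, 1))   # 1/8
  mp <- manual_metapop(list(H), loci, cfg, lay)
  tab <- sample_population_frequencies(mp, sample_size = 4, maf_threshold = 0)
  expect_equal(as.numeric(tab$freq), c(4, 7, 1) / 8)
  expect_equal(tab$sample_size, 8)
  # MAF filter on the pooled frequency
  tab2 <- sample_population_frequencies(mp, sample_size = 4, maf_threshold = 0.2)
  expect_equal(ncol(tab2$freq), 1)      # only the 4/8 SNP survives
  # SNP class restriction
  tabq <- sample_population_frequencies(mp, sample_size = 4, maf_threshold = 0,
                                        snp_set = "qtn_only")
  expect_equal(as.numeric(tabq$freq), 0.5)
  expect_error(sample_population_frequencies(mp, sample_size = 10),
               "exceeds deme_size")
})

test_that("full-sample frequencies equal whole-population frequencies", {
  sim <- tiny_sim()
  tab <- sample_population_frequencies(sim, sample_size = 30, maf_threshold = 0)
  H <- sim$metapop$haplotypes
  d <- 7
  cols <- (2 * (d - 1) * 30 + 1):(2 * d * 30)
  expect_equal(unname(tab$freq[d, ]), unname(rowMeans(H[, cols])))
  expect_true(all(tab$freq >= 0 & tab$freq <= 1))
})
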