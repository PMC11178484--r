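#' Pairwise f2 statistic
#'
#' Mean squared allele-frequency difference between two populations; when
#' `unbiased = TRUE` the Patterson-style finite-sample correction
#' `h_x = p_x (1 - p_x) / (n_x - 1)` (n_x = allele count) is subtracted for
#' each population so the estimator targets the true squared difference of
#' population frequencies.
#'
#' @param table a [freq_table()].
#' @param pop_a,pop_b population index or id.
#' @param unbiased apply the finite-sample correction (requires sample sizes).
#' @return object of class `pairwise_stat`: list with `pop_a`, `pop_b`, `f2`,
#'   `n_snps`, `unbiased`.
#' @export
f2_statistic <- function(table, pop_a, pop_b, unbiased = TRUE) {
  ia <- pop_index(table, pop_a); ib <- pop_index(table, pop_b)
  pa <- table$freq[ia, ]; pb <- table$freq[ib, ]
  val <- (pa - pb)^2
  if (unbiased) {
    na <- table$sample_size[ia]; nb <- table$sample_size[ib]
    if (is.na(na) || is.na(nb) || na < 2 || nb < 2)
      stop("unbiased f2 requires allele counts >= 2 for both populations")
    val <- val - pa * (1 - pa) / (na - 1) - pb * (1 - pb) / (nb - 1)
  }
  structure(list(pop_a = table$pop_ids[ia], pop_b = table$pop_ids[ib],
                 f2 = mean(val), n_snps = length(val), unbiased = unbiased),
            class = "pairwise_stat")
}

#' Genome-wide multi-population FST
#'
#' Moment (one-way ANOVA on alleles) estimator combined across SNPs as a
#' ratio of averages: per SNP, the among-population variance component
#' `(MSP - MSG)/n_c` over the total `(MSP + (n_c - 1) MSG)/n_c`, summed over
#' SNPs before taking the ratio. This is a Weir-Cockerham-type estimator for
#' frequency data with known allele counts.
#'
#' @param table a [freq_table()] with known sample sizes.
#' @return a single FST value.
#' @export
fst_genomewide <- function(table) {
  r <- n_pops(table)
  if (r < 2) stop("FST needs at least two populations")
  n <- table$sample_size
  if (anyNA(n)) stop("FST needs known sample sizes")
  P <- table$freq
  Ntot <- sum(n)
  nc <- (Ntot - sum(n^2) / Ntot) / (r - 1)
  pbar <- as.vector(crossprod(n, P)) / Ntot        # weighted mean per SNP
  ssb <- colSums(n * sweep(P, 2, pbar, "-")^2)
  msp <- ssb / (r - 1)
  msg <- colSums(n * P * (1 - P)) / (Ntot - r)
  num <- msp - msg
  den <- msp + (nc - 1) * msg
  if (sum(den) <= 0) stop("monomorphic table: FST undefined")
  sum(num) / sum(den)
}

#' Filter SNPs on pooled minor-allele frequency
#'
#' The pooled frequency is the allele-count-weighted mean across populations
#' (plain mean when counts are unknown); SNPs with
#' `min(p, 1 - p) < threshold` are dropped.
#'
#' @param table a [freq_table()].
#' @param threshold MAF cutoff in \[0, 0.5\].
#' @return the filtered [freq_table()].
#' @export
maf_filter <- function(table, threshold) {
  stopifnot(threshold >= 0, threshold <= 0.5)
  if (threshold == 0 || !n_snps(table)) return(table)
  n <- table$sample_size
  pooled <- if (anyNA(n)) colMeans(table$freq)
            else as.vector(crossprod(n, table$freq)) / sum(n)
  maf <- pmin(pooled, 1 - pooled)
  subset_snps(table, maf >= threshold)
}

#' Expected heterozygosity of one population
#'
#' Mean over SNPs of `2 p (1 - p)`, optionally with the small-sample
#' correction factor `n / (n - 1)`.
#'
#' @param table a [freq_table()].
#' @param pop population index or id.
#' @param corrected apply `n/(n-1)` (requires the allele count).
#' @return expected heterozygosity.
#' @export
heterozygosity <- function(table, pop, corrected = FALSE) {
  i <- pop_index(table, pop)
  p <- table$freq[i, ]
  h <- mean(2 * p * (1 - p))
  if (corrected) {
    n <- table$sample_size[i]
    if (is.na(n) || n < 2) stop("correction requires an allele count >= 2")
    h <- h * n / (n - 1)
  }
  h
}
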