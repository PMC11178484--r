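#' Population x SNP allele-frequency table
#'
#' The shared container for all GEA and population-statistics operations:
#' a populations x SNPs matrix of reference-allele frequencies, per-population
#' allele counts (2 x sampled individuals), and per-SNP metadata.
#'
#' @param freq numeric matrix, populations in rows, SNPs in columns.
#' @param sample_size per-population allele counts (length = populations).
#' @param snp optional data.frame with one row per SNP (typically `chrom`,
#'   `site`, `is_qtn`).
#' @param pop_ids population identifiers.
#' @param residual set TRUE for residualized tables whose entries may leave
#'   \[0, 1\].
#' @return an object of class `freq_table`.
#' @export
freq_table <- function(freq, sample_size, snp = NULL, pop_ids = NULL,
                       residual = FALSE) {
  freq <- as.matrix(freq)
  if (is.null(pop_ids)) pop_ids <- rownames(freq)
  if (is.null(pop_ids)) pop_ids <- paste0("pop", seq_len(nrow(freq)))
  if (length(sample_size) == 1L) sample_size <- rep(sample_size, nrow(freq))
  stopifnot(length(sample_size) == nrow(freq), length(pop_ids) == nrow(freq))
  if (!residual && nrow(freq) && ncol(freq) &&
      (min(freq, na.rm = TRUE) < 0 || max(freq, na.rm = TRUE) > 1))
    stop("allele frequencies must lie in [0, 1]")
  if (is.null(snp)) {
    snp <- data.frame(chrom = rep(NA_integer_, ncol(freq)),
                      site = rep(NA_integer_, ncol(freq)),
                      is_qtn = rep(NA, ncol(freq)))
  }
  stopifnot(nrow(snp) == ncol(freq))
  rownames(freq) <- pop_ids
  structure(list(freq = freq, sample_size = as.numeric(sample_size), snp = snp,
                 pop_ids = pop_ids, residual = isTRUE(residual)),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("freq_table: %d populations x %d SNPs%s\n", nrow(x$freq),
              ncol(x$freq), if (x$residual) " (residualized)" else ""))
  if (!all(is.na(x$snp$is_qtn)))
    cat(sprintf("  QTN SNPs: %d, neutral: %d\n", sum(x$snp$is_qtn),
                sum(!x$snp$is_qtn)))
  invisible(x)
}

n_snps <- function(table) ncol(table$freq)
n_pops <- function(table) nrow(table$freq)

subset_snps <- function(table, keep) {
  table$freq <- table$freq[, keep, drop = FALSE]
  table$snp <- table$snp[keep, , drop = FALSE]
  rownames(table$snp) <- NULL
  table
}

pop_index <- function(table, pop) {
  if (is.character(pop)) {
    i <- match(pop, table$pop_ids)
    if (is.na(i)) stop("unknown population: ", pop)
    i
  } else {
    stopifnot(pop >= 1, pop <= n_pops(table))
    as.integer(pop)
  }
}

#' Write an allele-frequency table as TSV
#'
#' One row per SNP: `chrom`, `site` (1-based on disk), `is_qtn`, then one
#' frequency column per population.
#'
#' @param table a [freq_table()].
#' @param path output file.
#' @export
write_frequency_table <- function(table, path) {
  out <- data.frame(chrom = table$snp$chrom, site = table$snp$site + 1L,
                    is_qtn = table$snp$is_qtn)
  fr <- t(table$freq)
  colnames(fr) <- table$pop_ids
  write.table(cbind(out, fr), path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read an allele-frequency table
#'
#' Accepts the frequency TSV written by [write_frequency_table()] and a
#' paired-column allele-count dialect (two integer columns per population
#' named `<pop>_ref` and `<pop>_alt`), from which frequencies and per-SNP
#' sample sizes are derived. Missing frequency cells are imputed by the
#' across-population mean frequency of the SNP (count reported via a message).
#'
#' @param path TSV path.
#' @param sample_sizes optional per-population allele counts for the
#'   frequency dialect (unknown otherwise: recorded as NA).
#' @return a [freq_table()].
#' @export
read_frequency_table <- function(path, sample_sizes = NULL) {
  df <- read.delim(path, check.names = FALSE)
  meta_cols <- intersect(c("chrom", "site", "is_qtn"), names(df))
  dat <- df[, setdiff(names(df), meta_cols), drop = FALSE]
  if (!ncol(dat)) stop("no population columns found")
  is_count <- all(grepl("_(ref|alt)$", names(dat)))
  if (is_count) {
    pops <- unique(sub("_(ref|alt)$", "", names(dat)))
    ref <- as.matrix(dat[, paste0(pops, "_ref"), drop = FALSE])
    alt <- as.matrix(dat[, paste0(pops, "_alt"), drop = FALSE])
    if (any(ref < 0 | alt < 0)) stop("negative allele counts")
    tot <- ref + alt
    freq <- ifelse(tot > 0, ref / tot, NA_real_)
    sample_sizes <- apply(tot, 2, stats::median)
    fr <- t(freq)
    pop_ids <- pops
  } else {
    fr <- t(as.matrix(dat))
    pop_ids <- names(dat)
    if (is.null(sample_sizes)) sample_sizes <- rep(NA_real_, length(pop_ids))
  }
  # impute missing cells by the SNP's across-population mean
  nas <- which(is.na(fr), arr.ind = TRUE)
  if (nrow(nas)) {
    col_means <- colMeans(fr, na.rm = TRUE)
    if (anyNA(col_means)) stop("SNP with all values missing")
    fr[nas] <- col_means[nas[, 2]]
    message(nrow(nas), " missing cells imputed by across-population means")
  }
  if (min(fr) < 0 || max(fr) > 1) stop("allele frequencies must lie in [0, 1]")
  snp <- if (length(meta_cols)) {
    data.frame(chrom = df[["chrom"]] %||% NA_integer_,
               site = (df[["site"]] %||% NA_integer_) - 1L,
               is_qtn = df[["is_qtn"]] %||% NA)
  } else NULL
  freq_table(fr, sample_size = sample_sizes, snp = snp, pop_ids = pop_ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a population x covariable environment table
#'
#' The file must contain a `pop` key column; rows are re-aligned to `pop_ids`
#' by that key (silent positional joins are refused).
#'
#' @param path TSV path with header.
#' @param pop_ids population ids to align to.
#' @return numeric matrix (populations x covariables) in `pop_ids` order.
#' @export
read_environment_table <- function(path, pop_ids) {
  df <- read.delim(path, check.names = FALSE)
  if (!"pop" %in% names(df))
    stop("environment table must contain a 'pop' key column")
  idx <- match(pop_ids, df$pop)
  if (anyNA(idx))
    stop("environment table is missing populations: ",
         paste(pop_ids[is.na(idx)], collapse = ", "))
  mat <- as.matrix(df[idx, setdiff(names(df), "pop"), drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric covariable cells")
  rownames(mat) <- pop_ids
  mat
}

#' Export diploid genotypes as VCF
#'
#' Writes a minimal VCF 4.2 with GT fields, chromosome names `chr1..chrK` and
#' 1-based positions, one sample per individual (`d<deme>_i<ind>`).
#'
#' @param metapop a `metapop`.
#' @param path output path.
#' @export
write_metapop_vcf <- function(metapop, path) {
  mp <- metapop
  N <- mp$config$deme_size
  D <- nrow(mp$layout$optima)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=invadeGO",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'), con)
  ids <- paste0("d", rep(seq_len(D), each = N), "_i", rep(seq_len(N), D))
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"), con)
  ord <- order(mp$loci$chrom, mp$loci$site)
  H <- mp$haplotypes
  for (r in ord) {
    gt <- paste0(H[r, seq(1, ncol(H), 2)], "|", H[r, seq(2, ncol(H), 2)])
    writeLines(paste(c(paste0("chr", mp$loci$chrom[r]), mp$loci$site[r] + 1L,
                       paste0("snp", mp$loci$id[r]), "A", "T", ".", "PASS",
                       if (mp$loci$is_qtn[r]) "QTN" else "NEUTRAL", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}
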