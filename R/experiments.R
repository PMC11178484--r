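#' Evaluation design
#'
#' Bundles everything needed to replicate the two evaluation pipelines:
#' offset versus log establishment probability, and geometric offset versus
#' the f2 statistic. Defaults are desk-scale; study-scale values are
#' reachable through `sim_config`/`invasion` overrides.
#'
#' @param layout_type native environment layout ("L", "M" or "R").
#' @param migration_rate native-grid migration rate.
#' @param n_replicates independent native histories.
#' @param source_optima list of source environments (demes are matched by
#'   optima; the lowest-index matching deme is used).
#' @param target_optima matrix of invadable environments (default: the nine
#'   combinations of \{-1, 0, 1\}^2).
#' @param n_founders founder individuals per invasion.
#' @param covariable_mode "causal" (the two causal variables),
#'   "causal_plus_confounders" (eight covariables) or "pcs" (leading PCs of
#'   those eight).
#' @param n_confounder_draws independent confounder draws to average over.
#' @param snp_mode "all" or "top_decile_xtx" (pre-select the top 10 percent
#'   most differentiated SNPs).
#' @param methods offset estimators to evaluate (subset of `"lfmm"`,
#'   `"gls_multi"`, `"gls_uni"`, `"gf"`, `"euclidean"`).
#' @param response response variable paired with the offsets.
#' @param correlation correlation flavour for R-squared.
#' @param n_pcs PCs retained in "pcs" mode.
#' @param K latent factors for the LFMM-style fit and residualization.
#' @param gf_trees,gf_min_leaf gradient-forest parameters.
#' @param sim_config a [sim_config()] template (its `migration_rate` and
#'   `seed` are overridden per replicate).
#' @param invasion an [invasion_config()] template (its `target_optima` and
#'   `seed` are overridden per invasion).
#' @param seed root seed of the whole experiment.
#' @return an object of class `experiment_design`.
#' @export
experiment_design <- function(layout_type = "L", migration_rate = 0.005,
                              n_replicates = 5L,
                              source_optima = list(c(-1, -1), c(0, 0), c(1, 1)),
                              target_optima = NULL, n_founders = 10L,
                              covariable_mode = c("causal", "causal_plus_confounders", "pcs"),
                              n_confounder_draws = 3L,
                              snp_mode = c("all", "top_decile_xtx"),
                              methods = c("lfmm", "gls_multi", "gls_uni", "euclidean"),
                              response = c("log_ep", "mean_fitness", "growth_rate"),
                              correlation = c("spearman", "pearson"),
                              n_pcs = 4L, K = 2L, gf_trees = 50L, gf_min_leaf = 2L,
                              sim_config = invadeGO::sim_config(),
                              invasion = invasion_config(), seed = NULL) {
  covariable_mode <- match.arg(covariable_mode)
  snp_mode <- match.arg(snp_mode)
  response <- match.arg(response)
  correlation <- match.arg(correlation)
  methods <- match.arg(methods, c("lfmm", "gls_multi", "gls_uni", "gf", "euclidean"),
                       several.ok = TRUE)
  if (is.null(target_optima))
    target_optima <- as.matrix(expand.grid(e1 = c(-1, 0, 1), e2 = c(-1, 0, 1)))
  target_optima <- as.matrix(target_optima)
  stopifnot(nrow(target_optima) >= 1, ncol(target_optima) == 2,
            length(source_optima) >= 1, n_replicates >= 1)
  structure(list(layout_type = layout_type, migration_rate = migration_rate,
                 n_replicates = as.integer(n_replicates),
                 source_optima = source_optima, target_optima = target_optima,
                 n_founders = as.integer(n_founders),
                 covariable_mode = covariable_mode,
                 n_confounder_draws = as.integer(n_confounder_draws),
                 snp_mode = snp_mode, methods = methods, response = response,
                 correlation = correlation, n_pcs = as.integer(n_pcs),
                 K = as.integer(K), gf_trees = as.integer(gf_trees),
                 gf_min_leaf = as.integer(gf_min_leaf),
                 sim_config = sim_config, invasion = invasion,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "experiment_design")
}

source_label <- function(opt) paste0(opt[1], "/", opt[2])

# Per-replicate native history + GEA training table, shared by both
# experiment pipelines.
replicate_native <- function(design, rep_seed) {
  sub <- withr::with_seed(rep_seed, sample.int(.Machine$integer.max - 1L, 4L))
  cfg <- design$sim_config
  cfg$migration_rate <- design$migration_rate
  cfg$seed <- sub[1]
  layout <- build_environment_layout(design$layout_type, cfg$grid_side,
                                     seed = sub[2])
  sim <- run_native_simulation(cfg, layout)
  list(sim = sim, cfg = cfg, layout = layout, sample_seed = sub[3],
       aux_seed = sub[4])
}

# Covariable sets for one replicate and one confounder draw:
# native rows (demes) and target rows (invadable environments) expressed in
# the same covariable system.
build_covariables <- function(design, layout, draw_seed) {
  native <- layout$optima
  targets <- design$target_optima
  colnames(targets) <- c("e1", "e2")
  if (design$covariable_mode == "causal")
    return(list(native = native, targets = targets))
  joint <- generate_confounders(rbind(native, targets), seed = draw_seed)
  nn <- nrow(native)
  native8 <- joint[seq_len(nn), , drop = FALSE]
  target8 <- joint[nn + seq_len(nrow(targets)), , drop = FALSE]
  if (design$covariable_mode == "causal_plus_confounders")
    return(list(native = native8, targets = target8))
  pca <- pca_covariables(native8, design$n_pcs)
  list(native = pca$scores, targets = project_covariables(pca, target8),
       pca = pca)
}

fit_offsets_one_method <- function(method, table, covs, design, omega, gf_seed) {
  nn <- nrow(covs$native)
  fit <- switch(method,
    lfmm = fit_latent_factor_regression(table, covs$native, K = design$K),
    gls_multi = fit_gls_regression(table, covs$native, omega, "multivariate"),
    gls_uni = fit_gls_regression(table, covs$native, omega, "univariate"),
    gf = fit_gradient_forest(residualize_frequencies(table, design$K),
                             covs$native, n_trees = design$gf_trees,
                             min_leaf = design$gf_min_leaf, seed = gf_seed),
    euclidean = "euclidean")
  fit
}

offsets_to_targets <- function(fit, source_env, targets) {
  as.numeric(offset_map(fit, source_env, targets))
}

#' Offset-versus-establishment evaluation
#'
#' For each replicate: simulate a native history, build the GEA training
#' table (sampled individuals, MAF filter, optional XtX pre-selection), build
#' the covariable set for the requested mode, fit every requested method,
#' compute offsets from each source environment to every invadable
#' environment, estimate establishment probabilities by repeated invasion,
#' and pool `|targets| x n_replicates` observations per (method, source).
#' R-squared is computed per confounder draw and averaged across draws.
#'
#' @param design an [experiment_design()].
#' @param verbose print progress.
#' @return an object of class `evaluation_report`: list with `observations`
#'   (one row per method x source x draw x target x replicate), `r2`
#'   (summary per method x source), `design` and `seeds`.
#' @export
run_prediction_experiment <- function(design, verbose = FALSE) {
  stopifnot(inherits(design, "experiment_design"))
  rep_seeds <- derive_seeds(design$seed, design$n_replicates)
  n_draws <- if (design$covariable_mode == "causal") 1L else design$n_confounder_draws
  obs <- list()
  for (rep in seq_len(design$n_replicates)) {
    if (verbose) message("replicate ", rep, "/", design$n_replicates)
    ctx <- replicate_native(design, rep_seeds[rep])
    table <- sample_population_frequencies(ctx$sim, seed = ctx$sample_seed)
    omega <- if (any(c("gls_multi", "gls_uni") %in% design$methods) ||
                 design$snp_mode == "top_decile_xtx")
      estimate_omega(table) else NULL
    if (design$snp_mode == "top_decile_xtx") {
      table <- preselect_snps(table, xtx_statistic(table, omega), 0.1)
      omega <- if (!is.null(omega)) estimate_omega(table) else NULL
    }
    aux <- withr::with_seed(ctx$aux_seed,
                            sample.int(.Machine$integer.max - 1L,
                                       2L + n_draws))
    # establishment responses are shared across methods and draws
    inv_seeds <- withr::with_seed(aux[1],
                                  sample.int(.Machine$integer.max - 1L,
                                             length(design$source_optima) *
                                               nrow(design$target_optima)))
    resp <- list()
    k <- 0L
    for (si in seq_along(design$source_optima)) {
      src <- design$source_optima[[si]]
      sd_deme <- deme_with_optima(ctx$layout, src)
      for (ti in seq_len(nrow(design$target_optima))) {
        k <- k + 1L
        icfg <- design$invasion
        icfg$target_optima <- as.numeric(design$target_optima[ti, ])
        icfg$n_founders <- design$n_founders
        icfg$seed <- inv_seeds[k]
        er <- establishment_probability(ctx$sim, sd_deme, icfg)
        resp[[paste(si, ti)]] <- er
      }
    }
    for (draw in seq_len(n_draws)) {
      covs <- build_covariables(design, ctx$layout, aux[2L + draw])
      fits <- lapply(design$methods, fit_offsets_one_method, table = table,
                     covs = covs, design = design, omega = omega,
                     gf_seed = aux[2])
      names(fits) <- design$methods
      for (si in seq_along(design$source_optima)) {
        src <- design$source_optima[[si]]
        sd_deme <- deme_with_optima(ctx$layout, src)
        src_env <- covs$native[sd_deme, ]
        for (mi in seq_along(design$methods)) {
          go <- offsets_to_targets(fits[[mi]], src_env, covs$targets)
          for (ti in seq_len(nrow(design$target_optima))) {
            er <- resp[[paste(si, ti)]]
            obs[[length(obs) + 1L]] <- data.frame(
              replicate = rep, method = design$methods[mi],
              mode = design$covariable_mode, draw = draw,
              source = source_label(src),
              target = source_label(design$target_optima[ti, ]),
              go = go[ti], ep = er$ep, log_ep = er$log_ep,
              mean_fitness = er$mean_founder_fitness,
              growth_rate = er$mean_growth_rate)
          }
        }
      }
    }
  }
  observations <- do.call(rbind, obs)
  r2 <- summarize_r2(observations, design)
  structure(list(observations = observations, r2 = r2, design = design,
                 seeds = rep_seeds),
            class = "evaluation_report")
}

summarize_r2 <- function(observations, design) {
  respcol <- design$response
  out <- list()
  for (method in unique(observations$method)) {
    for (src in unique(observations$source)) {
      draws <- sort(unique(observations$draw))
      r2d <- vapply(draws, function(d) {
        sub <- observations[observations$method == method &
                              observations$source == src &
                              observations$draw == d, ]
        rank_correlation_r2(sub$go, sub[[respcol]],
                            method = design$correlation)$r2
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        method = method, source = src, response = respcol,
        r2 = mean(r2d), r2_min = min(r2d), r2_max = max(r2d),
        n_obs = sum(observations$method == method &
                      observations$source == src &
                      observations$draw == draws[1]))
    }
  }
  do.call(rbind, out)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report:", nrow(x$observations), "observations\n")
  print(x$r2, row.names = FALSE)
  invisible(x)
}

#' Geometric-offset-versus-f2 evaluation
#'
#' Compares geometric offsets with the f2 statistic between each source
#' population and the native demes carrying the nine target optima
#' combinations. Two settings: `"ideal"` fits the GEA on QTN-only
#' full-population frequencies with the two causal covariables;
#' `"realistic"` fits on MAF-filtered QTN+neutral frequencies from sampled
#' individuals and reports both the QTN-only f2 (the theoretical target) and
#' the QTN+neutral f2 (the upper bound). Pairs with zero environmental
#' distance (offset and f2 both exactly 0) and pairs whose bias-corrected f2
#' is non-positive are excluded from MAPE, with the count recorded.
#'
#' @param design an [experiment_design()] (its `methods` are ignored; the
#'   two joint-modelling estimators `lfmm` and `gls_multi` are compared).
#' @param setting "ideal" or "realistic".
#' @param verbose print progress.
#' @return an object of class `f2_report`: list with `observations`, `mape`
#'   (per method), `n_dropped`, `setting`, `design`, `seeds`.
#' @export
run_f2_experiment <- function(design, setting = c("ideal", "realistic"),
                              verbose = FALSE) {
  stopifnot(inherits(design, "experiment_design"))
  setting <- match.arg(setting)
  rep_seeds <- derive_seeds(design$seed, design$n_replicates)
  obs <- list()
  for (rep in seq_len(design$n_replicates)) {
    if (verbose) message("replicate ", rep, "/", design$n_replicates)
    ctx <- replicate_native(design, rep_seeds[rep])
    cfg <- ctx$cfg
    if (setting == "ideal") {
      # the study dataset is MAF-filtered upstream of any analysis, so the
      # "all QTNs" setting means all QTNs passing the MAF threshold
      full_qtn <- sample_population_frequencies(ctx$sim, sample_size = cfg$deme_size,
                                                maf_threshold = cfg$maf_threshold,
                                                snp_set = "qtn_only")
      est_table <- full_qtn
      full_all <- NULL
    } else {
      full_qtn <- sample_population_frequencies(ctx$sim, sample_size = cfg$deme_size,
                                                maf_threshold = cfg$maf_threshold,
                                                snp_set = "qtn_only")
      full_all <- sample_population_frequencies(ctx$sim, sample_size = cfg$deme_size,
                                                maf_threshold = cfg$maf_threshold,
                                                snp_set = "all")
      est_table <- sample_population_frequencies(ctx$sim, seed = ctx$sample_seed)
    }
    env <- ctx$layout$optima
    fits <- list(lfmm = fit_latent_factor_regression(est_table, env, K = design$K),
                 gls_multi = fit_gls_regression(est_table, env,
                                                estimate_omega(est_table),
                                                "multivariate"))
    for (si in seq_along(design$source_optima)) {
      src <- design$source_optima[[si]]
      sd_deme <- deme_with_optima(ctx$layout, src)
      for (ti in seq_len(nrow(design$target_optima))) {
        tgt <- as.numeric(design$target_optima[ti, ])
        td_deme <- deme_with_optima(ctx$layout, tgt)
        if (td_deme == sd_deme) next
        f2q <- f2_statistic(full_qtn, sd_deme, td_deme, unbiased = TRUE)$f2
        f2a <- if (!is.null(full_all))
          f2_statistic(full_all, sd_deme, td_deme, unbiased = TRUE)$f2 else NA_real_
        for (method in names(fits)) {
          obs[[length(obs) + 1L]] <- data.frame(
            replicate = rep, method = method, source = source_label(src),
            target = source_label(tgt),
            ggo = geometric_offset(fits[[method]], env[sd_deme, ], tgt),
            f2_qtn = f2q, f2_all = f2a)
        }
      }
    }
  }
  observations <- do.call(rbind, obs)
  usable <- observations$f2_qtn > 0
  mape_tab <- do.call(rbind, lapply(unique(observations$method), function(method) {
    sub <- observations[observations$method == method & usable, ]
    data.frame(method = method, setting = setting,
               mape = mape(sub$ggo, sub$f2_qtn), n_pairs = nrow(sub))
  }))
  structure(list(observations = observations, mape = mape_tab,
                 n_dropped = sum(!usable), setting = setting, design = design,
                 seeds = rep_seeds),
            class = "f2_report")
}

#' @export
print.f2_report <- function(x, ...) {
  cat("f2_report (", x$setting, " setting): ", nrow(x$observations),
      " pairs, ", x$n_dropped, " dropped\n", sep = "")
  print(x$mape, row.names = FALSE)
  invisible(x)
}
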