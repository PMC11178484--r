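#' Serialize a GEA fit
#'
#' Writes the coefficient matrix as TSV (`<stem>_B.tsv`), Omega (if any) as
#' TSV (`<stem>_omega.tsv`) and the remaining metadata as a JSON sidecar
#' (`<stem>.json`).
#'
#' @param fit a `gea_fit`.
#' @param stem output path stem.
#' @return the JSON sidecar path, invisibly.
#' @export
write_gea_fit <- function(fit, stem) {
  stopifnot(inherits(fit, "gea_fit"))
  write.table(fit$B, paste0(stem, "_B.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(fit$omega))
    write.table(fit$omega, paste0(stem, "_omega.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  meta <- list(method = fit$method, K = fit$K, env_names = fit$env_names,
               env_center = fit$env_center, env_scale = fit$env_scale,
               univariate = fit$univariate, nsnp = fit$nsnp,
               has_omega = !is.null(fit$omega))
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(stem, ".json"))
}

#' Read back a serialized GEA fit
#'
#' @param stem the stem used in [write_gea_fit()].
#' @return a `gea_fit`.
#' @export
read_gea_fit <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  B <- as.matrix(read.delim(paste0(stem, "_B.tsv"), check.names = FALSE))
  omega <- if (isTRUE(meta$has_omega))
    as.matrix(read.delim(paste0(stem, "_omega.tsv"), check.names = FALSE)) else NULL
  env <- matrix(0, 1, ncol(B), dimnames = list(NULL, meta$env_names))
  fit <- new_gea_fit(B, method = meta$method, K = meta$K, omega = omega,
                     env = env, env_center = meta$env_center,
                     env_scale = meta$env_scale,
                     univariate = isTRUE(meta$univariate))
  fit
}

#' Serialize a turnover model as per-covariable breakpoint TSV
#'
#' @param model a `turnover_model`.
#' @param path output TSV (columns: covariable, breakpoint, cumulative
#'   importance, interpolation).
#' @export
write_turnover_model <- function(model, path) {
  stopifnot(inherits(model, "turnover_model"))
  rows <- do.call(rbind, lapply(names(model$curves), function(nm) {
    cv <- model$curves[[nm]]
    if (!length(cv$breaks)) return(NULL)
    data.frame(covariable = nm, breakpoint = cv$breaks, cumimp = cv$cumimp,
               interpolation = cv$interpolation)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a serialized turnover model
#'
#' @param path TSV written by [write_turnover_model()].
#' @return a `turnover_model`.
#' @export
read_turnover_model <- function(path) {
  df <- read.delim(path)
  curves <- lapply(split(df, df$covariable), function(d) {
    ord <- order(d$breakpoint)
    list(breaks = d$breakpoint[ord], cumimp = d$cumimp[ord],
         interpolation = d$interpolation[1])
  })
  turnover_model(curves)
}

#' Write a run manifest
#'
#' Records the package version, a configuration echo, the root seed and any
#' derived seeds, so a stage can be replayed exactly.
#'
#' @param path output JSON path.
#' @param config any configuration list (classes are dropped).
#' @param seed root seed.
#' @param derived_seeds optional derived seed vector.
#' @param extra optional named list of extra fields.
#' @export
write_run_manifest <- function(path, config, seed, derived_seeds = NULL,
                               extra = NULL) {
  manifest <- c(list(tool = "invadeGO",
                     version = as.character(utils::packageVersion("invadeGO")),
                     timestamp = format(Sys.time(), tz = "UTC"),
                     config = unclass(config), seed = seed,
                     derived_seeds = derived_seeds), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
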