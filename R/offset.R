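#' Geometric genomic offset
#'
#' `gGO = (1/nsnp) (e - e*)' B' B (e - e*)`: the squared genetics-weighted
#' environmental distance between two environments, computed from a linear
#' GEA coefficient matrix. Symmetric in `(e, e*)`, non-negative, and zero at
#' identical environments. Between locally adapted populations at equilibrium
#' it estimates the f2 statistic at causal loci.
#'
#' @param fit a `gea_fit`.
#' @param e,e_star covariable vectors (same length and order as the fit's
#'   covariables, original units).
#' @return a single non-negative offset value.
#' @export
geometric_offset <- function(fit, e, e_star) {
  stopifnot(inherits(fit, "gea_fit"))
  m <- ncol(fit$B)
  if (length(e) != m || length(e_star) != m)
    stop("environment vectors must have length ", m)
  d <- (as.numeric(e) - as.numeric(e_star)) / fit$env_scale
  v <- fit$B %*% d
  sum(v^2) / fit$nsnp
}

#' Squared Euclidean environmental distance (baseline offset)
#'
#' `delta_e = (1/ne) sum_k (e_k - e*_k)^2`, reported squared
#' (`delta_e_squared`) to match the scaling convention of the genomic
#' offsets; both values are returned.
#'
#' @param e,e_star covariable vectors of equal length.
#' @return list with `delta_e` and `delta_e_squared`.
#' @export
euclidean_offset <- function(e, e_star) {
  if (length(e) != length(e_star)) stop("environment vectors differ in length")
  de <- mean((as.numeric(e) - as.numeric(e_star))^2)
  list(delta_e = de, delta_e_squared = de^2)
}

#' Offsets from one source environment to many targets
#'
#' Vectorized offsets for every row of a target table, streamed in chunks so
#' memory stays bounded regardless of the number of targets. Dispatches on
#' the model type: `gea_fit` (geometric offset), `turnover_model`
#' (gradient-forest offset) or the string `"euclidean"`.
#'
#' @param object a `gea_fit`, a `turnover_model`, or `"euclidean"`.
#' @param source_env covariable vector of the source environment.
#' @param target_env_table matrix/data.frame of target environments (one row
#'   per site, columns matching the model's covariables).
#' @param chunk_size rows processed per chunk.
#' @param ... unused.
#' @return numeric vector of offsets, one per target row.
#' @export
offset_map <- function(object, source_env, target_env_table,
                       chunk_size = 10000L, ...) {
  UseMethod("offset_map")
}

check_target_cols <- function(target, expected) {
  target <- as.matrix(target)
  if (ncol(target) != length(expected) &&
      !is.null(colnames(target)) && all(expected %in% colnames(target)))
    target <- target[, expected, drop = FALSE]
  if (ncol(target) != length(expected))
    stop("target table columns do not match the model covariables")
  target
}

map_in_chunks <- function(n, chunk_size, f) {
  out <- numeric(n)
  at <- 1L
  while (at <= n) {
    hi <- min(at + chunk_size - 1L, n)
    out[at:hi] <- f(at:hi)
    at <- hi + 1L
  }
  out
}

#' @rdname offset_map
#' @export
offset_map.gea_fit <- function(object, source_env, target_env_table,
                               chunk_size = 10000L, ...) {
  tg <- check_target_cols(target_env_table, object$env_names)
  M <- crossprod(object$B) / object$nsnp
  src <- as.numeric(source_env) / object$env_scale
  map_in_chunks(nrow(tg), chunk_size, function(ix) {
    D <- sweep(sweep(tg[ix, , drop = FALSE], 2, object$env_scale, "/"), 2, src, "-")
    rowSums((D %*% M) * D)
  })
}

#' @rdname offset_map
#' @export
offset_map.turnover_model <- function(object, source_env, target_env_table,
                                      chunk_size = 10000L, ...) {
  tg <- check_target_cols(target_env_table, names(object$curves))
  fs <- vapply(seq_along(object$curves),
               function(k) turnover_eval(object$curves[[k]], source_env[k]),
               numeric(1))
  map_in_chunks(nrow(tg), chunk_size, function(ix) {
    acc <- numeric(length(ix))
    for (k in seq_along(object$curves)) {
      ft <- turnover_eval(object$curves[[k]], tg[ix, k])
      acc <- acc + (ft - fs[k])^2
    }
    acc
  })
}

#' @rdname offset_map
#' @export
offset_map.character <- function(object, source_env, target_env_table,
                                 chunk_size = 10000L, ...) {
  if (!identical(object, "euclidean")) stop("unknown offset method: ", object)
  tg <- as.matrix(target_env_table)
  src <- as.numeric(source_env)
  if (ncol(tg) != length(src)) stop("target table columns do not match source_env")
  map_in_chunks(nrow(tg), chunk_size, function(ix) {
    D <- sweep(tg[ix, , drop = FALSE], 2, src, "-")
    rowMeans(D^2)^2
  })
}
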