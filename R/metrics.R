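#' Squared rank correlation between offsets and a response
#'
#' Squared Spearman correlation (average ranks for ties) by default; a flag
#' switches to Pearson. The signed coefficient is reported alongside the
#' square.
#'
#' @param go_values numeric offsets.
#' @param responses numeric responses (e.g. log establishment probability).
#' @param method "spearman" or "pearson".
#' @return list with `r2`, `coefficient`, `method`.
#' @export
rank_correlation_r2 <- function(go_values, responses,
                                method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(go_values) != length(responses)) stop("input lengths differ")
  if (length(go_values) < 3) stop("need at least 3 observations")
  if (length(unique(go_values)) == 1L || length(unique(responses)) == 1L)
    stop("correlation undefined for a constant input vector")
  rho <- stats::cor(go_values, responses, method = method)
  list(r2 = rho^2, coefficient = rho, method = method)
}

#' Mean absolute percentage error
#'
#' `100 * mean(|estimate - truth| / truth)`; truths must be strictly
#' positive.
#'
#' @param estimates numeric estimates.
#' @param truths strictly positive truths of the same length.
#' @return MAPE in percent.
#' @export
mape <- function(estimates, truths) {
  if (length(estimates) != length(truths)) stop("input lengths differ")
  if (any(truths <= 0)) stop("MAPE requires strictly positive truths")
  100 * mean(abs(estimates - truths) / truths)
}
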