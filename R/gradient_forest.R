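#' Gradient-forest turnover model
#'
#' Fits, for every SNP, a bootstrap ensemble of regression trees of (residual)
#' allele frequency on the covariables. Every split on covariable k at
#' threshold t contributes its raw impurity (sum-of-squares) reduction to the
#' pair (k, t); contributions are aggregated across SNPs weighted by each
#' SNP's ensemble out-of-bag R-squared (negative values truncated to zero),
#' and per covariable the accrued importance is sorted by threshold and
#' cumulated into a monotone non-decreasing turnover function F_k.
#'
#' @param residual_table a [freq_table()], typically the output of
#'   [residualize_frequencies()].
#' @param env populations x covariables matrix (>= 2 covariables recommended).
#' @param n_trees trees per SNP.
#' @param min_leaf minimum observations per leaf.
#' @param seed RNG seed for bootstrap draws.
#' @param max_depth maximum tree depth.
#' @return an object of class `turnover_model`: per-covariable turnover
#'   curves, total `importance` per covariable, per-SNP out-of-bag `r2`,
#'   and `n_trees`.
#' @export
fit_gradient_forest <- function(residual_table, env, n_trees = 100L,
                                min_leaf = 2L, seed = NULL, max_depth = 6L) {
  X <- as.matrix(env)
  Y <- residual_table$freq
  npop <- nrow(Y)
  m <- ncol(X)
  stopifnot(nrow(X) == npop, npop >= 5)
  env_names <- colnames(X)
  if (is.null(env_names)) env_names <- paste0("env", seq_len(m))

  vary <- apply(Y, 2, stats::var)
  active <- which(vary > 0)
  if (!length(active))
    stop("all SNP responses are constant: gradient forest undefined")

  with_seed_maybe(seed, {
    split_thr <- vector("list", m)   # accrued (threshold, weighted importance)
    split_imp <- vector("list", m)
    for (k in seq_len(m)) { split_thr[[k]] <- list(); split_imp[[k]] <- list() }
    r2 <- rep(NA_real_, ncol(Y))

    for (j in active) {
      y <- Y[, j]
      oob_sum <- numeric(npop)
      oob_n <- integer(npop)
      snp_thr <- vector("list", m)
      snp_imp <- vector("list", m)
      for (t in seq_len(n_trees)) {
        boot <- sample.int(npop, npop, replace = TRUE)
        oob <- setdiff(seq_len(npop), unique(boot))
        tree <- grow_tree(X[boot, , drop = FALSE], y[boot], min_leaf, max_depth)
        for (sp in tree$splits) {
          snp_thr[[sp$var]] <- c(snp_thr[[sp$var]], sp$threshold)
          snp_imp[[sp$var]] <- c(snp_imp[[sp$var]], sp$improve)
        }
        if (length(oob)) {
          pred <- predict_tree(tree$root, X[oob, , drop = FALSE])
          oob_sum[oob] <- oob_sum[oob] + pred
          oob_n[oob] <- oob_n[oob] + 1L
        }
      }
      seen <- oob_n > 0
      r2[j] <- if (any(seen)) {
        mse <- mean((y[seen] - oob_sum[seen] / oob_n[seen])^2)
        1 - mse / vary[j]
      } else NA_real_
      w <- max(r2[j], 0, na.rm = TRUE)
      if (w > 0) {
        for (k in seq_len(m)) {
          if (length(snp_thr[[k]])) {
            split_thr[[k]] <- c(split_thr[[k]], snp_thr[[k]])
            split_imp[[k]] <- c(split_imp[[k]],
                                lapply(snp_imp[[k]], function(v) v * w))
          }
        }
      }
    }

    curves <- vector("list", m)
    names(curves) <- env_names
    importance <- setNames(numeric(m), env_names)
    for (k in seq_len(m)) {
      thr <- unlist(split_thr[[k]])
      imp <- unlist(split_imp[[k]])
      if (is.null(thr) || !length(thr)) {
        curves[[k]] <- list(breaks = numeric(0), cumimp = numeric(0),
                            interpolation = "step")
        next
      }
      agg <- tapply(imp, thr, sum)
      brk <- as.numeric(names(agg))
      ord <- order(brk)
      curves[[k]] <- list(breaks = brk[ord],
                          cumimp = cumsum(as.numeric(agg)[ord]),
                          interpolation = "step")
      importance[k] <- sum(imp)
    }
    structure(list(curves = curves, importance = importance, r2 = r2,
                   n_trees = n_trees, env_names = env_names),
              class = "turnover_model")
  })
}

#' Construct a turnover model from explicit curves
#'
#' Mostly useful for tests and for evaluating hand-specified turnover
#' functions; each curve is a list with `breaks` (increasing) and `cumimp`
#' (non-decreasing, starting from an implicit 0 before the first break) and
#' an `interpolation` mode ("step" or "linear").
#'
#' @param curves named list of curves (one per covariable).
#' @param interpolation default interpolation for curves not specifying one.
#' @return a `turnover_model`.
#' @export
turnover_model <- function(curves, interpolation = "step") {
  for (k in seq_along(curves)) {
    cv <- curves[[k]]
    stopifnot(length(cv$breaks) == length(cv$cumimp),
              !is.unsorted(cv$breaks), !is.unsorted(cv$cumimp))
    if (is.null(cv$interpolation)) curves[[k]]$interpolation <- interpolation
  }
  structure(list(curves = curves,
                 importance = vapply(curves, function(cv)
                   if (length(cv$cumimp)) max(cv$cumimp) else 0, numeric(1)),
                 r2 = NULL, n_trees = 0L, env_names = names(curves)),
            class = "turnover_model")
}

# Evaluate a turnover curve at x (vectorized): monotone non-decreasing,
# 0 before the first break, clamped to the final value beyond the last.
turnover_eval <- function(curve, x) {
  if (!length(curve$breaks)) return(rep(0, length(x)))
  if (identical(curve$interpolation, "linear")) {
    if (length(curve$breaks) == 1L)
      return(ifelse(x < curve$breaks, 0, curve$cumimp))
    stats::approx(curve$breaks, curve$cumimp, xout = x, rule = 2)$y
  } else {
    idx <- findInterval(x, curve$breaks)
    c(0, curve$cumimp)[idx + 1L]
  }
}

#' Gradient-forest genomic offset
#'
#' `GOgf = sum_k (F_k(e_k) - F_k(e*_k))^2`: the squared Euclidean distance in
#' turnover-transformed covariable space. Values outside a curve's support
#' are clamped to the curve ends.
#'
#' @param model a `turnover_model`.
#' @param e,e_star covariable vectors named or ordered as in the model.
#' @return a single non-negative offset value.
#' @export
gradient_forest_offset <- function(model, e, e_star) {
  stopifnot(inherits(model, "turnover_model"))
  nm <- names(model$curves)
  if (!is.null(names(e))) {
    if (!all(nm %in% names(e))) stop("unknown covariable name in e")
    e <- e[nm]; e_star <- e_star[nm]
  }
  if (length(e) != length(nm) || length(e_star) != length(nm))
    stop("environment vectors must match the model covariables")
  acc <- 0
  for (k in seq_along(nm)) {
    fk <- turnover_eval(model$curves[[k]], c(e[k], e_star[k]))
    acc <- acc + (fk[1] - fk[2])^2
  }
  acc
}

# --- Minimal CART regression tree -----------------------------------------
# Best-split search over all covariables; split quality is the raw reduction
# in sum of squares. Returns the tree and the list of (var, threshold,
# improve) split records.

grow_tree <- function(X, y, min_leaf, max_depth) {
  splits <- list()
  build <- function(rows, depth) {
    n <- length(rows)
    yv <- y[rows]
    if (n < 2 * min_leaf || depth >= max_depth || stats::var(yv) == 0)
      return(list(leaf = TRUE, pred = mean(yv)))
    best <- find_best_split(X[rows, , drop = FALSE], yv, min_leaf)
    if (is.null(best)) return(list(leaf = TRUE, pred = mean(yv)))
    splits[[length(splits) + 1L]] <<- list(var = best$var,
                                           threshold = best$threshold,
                                           improve = best$improve)
    left <- rows[X[rows, best$var] <= best$threshold]
    right <- rows[X[rows, best$var] > best$threshold]
    list(leaf = FALSE, var = best$var, threshold = best$threshold,
         left = build(left, depth + 1L), right = build(right, depth + 1L))
  }
  root <- build(seq_along(y), 0L)
  list(root = root, splits = splits)
}

find_best_split <- function(X, y, min_leaf) {
  n <- length(y)
  ss_parent <- sum(y^2) - sum(y)^2 / n
  best <- NULL
  best_imp <- 1e-12
  for (k in seq_len(ncol(X))) {
    x <- X[, k]
    ord <- order(x)
    xs <- x[ord]; ys <- y[ord]
    cs <- cumsum(ys); cs2 <- cumsum(ys^2)
    tot <- cs[n]; tot2 <- cs2[n]
    # candidate cuts between distinct consecutive values
    i <- seq_len(n - 1)
    valid <- i >= min_leaf & (n - i) >= min_leaf & xs[i] < xs[i + 1]
    if (!any(valid)) next
    i <- i[valid]
    ss_l <- cs2[i] - cs[i]^2 / i
    ss_r <- (tot2 - cs2[i]) - (tot - cs[i])^2 / (n - i)
    imp <- ss_parent - (ss_l + ss_r)
    bi <- which.max(imp)
    if (imp[bi] > best_imp) {
      best_imp <- imp[bi]
      best <- list(var = k, threshold = (xs[i[bi]] + xs[i[bi] + 1]) / 2,
                   improve = imp[bi])
    }
  }
  best
}

predict_tree <- function(node, X) {
  n <- nrow(X)
  out <- numeric(n)
  rec <- function(node, rows) {
    if (!length(rows)) return()
    if (node$leaf) { out[rows] <<- node$pred; return() }
    go_left <- X[rows, node$var] <= node$threshold
    rec(node$left, rows[go_left])
    rec(node$right, rows[!go_left])
  }
  rec(node, seq_len(n))
  out
}
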