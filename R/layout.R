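#' Environmental layouts for the native grid
#'
#' Assigns a pair of environmental optima (e1, e2), each in \[-1, 1\], to every
#' deme of the square grid. Three layouts are supported:
#' \describe{
#'   \item{L (linear)}{e1 is a linear row gradient from -1 (top) to 1 (bottom),
#'     e2 a linear column gradient from -1 (left) to 1 (right); on a 5x5 grid
#'     deme 1 is (-1,-1), deme 13 is (0,0) and deme 25 is (1,1).}
#'   \item{M (mountain)}{optima depend on the Chebyshev ring distance from the
#'     centre deme: centre (1,1), first ring (0,0), outer rings including the
#'     corners (-1,-1).}
#'   \item{R (random)}{a seeded random assignment of pairs from \{-1,0,1\}^2,
#'     redrawn until the three invasion-source optima (-1,-1), (0,0) and (1,1)
#'     are all present.}
#' }
#' Deme indices are row-major from the top-left corner.
#'
#' @param layout_type one of "L", "M", "R".
#' @param grid_side side of the square grid (odd for "M").
#' @param seed seed for the "R" layout draw.
#' @param optima optional explicit `grid_side^2 x 2` matrix of optima that
#'   overrides the built-in layout (still validated).
#' @return an object of class `env_layout`: list with `layout_type`,
#'   `grid_side` and the `optima` matrix (columns `e1`, `e2`).
#' @export
build_environment_layout <- function(layout_type = c("L", "M", "R"), grid_side = 5L,
                                     seed = NULL, optima = NULL) {
  layout_type <- match.arg(layout_type)
  grid_side <- as.integer(grid_side)
  D <- grid_side^2
  row <- rep(seq_len(grid_side), each = grid_side)
  col <- rep(seq_len(grid_side), times = grid_side)

  if (is.null(optima)) {
    if (layout_type == "L") {
      vals <- seq(-1, 1, length.out = grid_side)
      optima <- cbind(e1 = vals[row], e2 = vals[col])
    } else if (layout_type == "M") {
      if (grid_side %% 2 == 0)
        stop("the mountain layout needs an odd grid_side (no centre deme)")
      ctr <- (grid_side + 1L) / 2L
      ring <- pmax(abs(row - ctr), abs(col - ctr))
      v <- ifelse(ring == 0, 1, ifelse(ring == 1, 0, -1))
      optima <- cbind(e1 = v, e2 = v)
    } else {
      combos <- as.matrix(expand.grid(e1 = c(-1, 0, 1), e2 = c(-1, 0, 1)))
      optima <- with_seed_maybe(seed, {
        for (try in 1:1000) {
          pick <- combos[sample.int(nrow(combos), D, replace = TRUE), , drop = FALSE]
          if (all(c(has_optima(pick, c(-1, -1)), has_optima(pick, c(0, 0)),
                    has_optima(pick, c(1, 1)))))
            break
        }
        pick
      })
    }
  } else {
    optima <- as.matrix(optima)
    if (nrow(optima) != D || ncol(optima) != 2)
      stop("explicit optima must be a grid_side^2 x 2 matrix")
    colnames(optima) <- c("e1", "e2")
  }

  if (any(optima < -1 | optima > 1)) stop("optima must lie in [-1, 1]")
  for (src in list(c(-1, -1), c(0, 0), c(1, 1)))
    if (!has_optima(optima, src))
      stop("layout must contain at least one deme at (", src[1], ",", src[2], ")")
  rownames(optima) <- NULL
  structure(list(layout_type = layout_type, grid_side = grid_side,
                 optima = optima),
            class = "env_layout")
}

has_optima <- function(optima, target) {
  any(optima[, 1] == target[1] & optima[, 2] == target[2])
}

#' Find the deme matching a pair of optima
#'
#' Returns the lowest-index deme whose optima equal `target` (the documented
#' tie-break when several demes share the optima of an invasion source).
#'
#' @param layout an `env_layout`.
#' @param target length-2 numeric `(e1, e2)`.
#' @return a deme index, or an error if no deme matches.
#' @export
deme_with_optima <- function(layout, target) {
  hit <- which(layout$optima[, 1] == target[1] & layout$optima[, 2] == target[2])
  if (!length(hit))
    stop("no deme carries optima (", target[1], ",", target[2], ")")
  hit[1]
}

# Von Neumann neighbours (4-neighbourhood, no wrap-around), 1-based deme ids.
grid_neighbors <- function(grid_side) {
  D <- grid_side^2
  row <- rep(seq_len(grid_side), each = grid_side)
  col <- rep(seq_len(grid_side), times = grid_side)
  lapply(seq_len(D), function(d) {
    r <- row[d]; cc <- col[d]
    nb <- integer(0)
    if (r > 1) nb <- c(nb, d - grid_side)
    if (r < grid_side) nb <- c(nb, d + grid_side)
    if (cc > 1) nb <- c(nb, d - 1L)
    if (cc < grid_side) nb <- c(nb, d + 1L)
    as.integer(nb)
  })
}
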