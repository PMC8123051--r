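# Clustering formation score (CFS) of a binarized response surface, with a
# random-permutation baseline.  CFS is 1 minus the normalized count of
# class-discordant horizontally/vertically adjacent neuron pairs on the
# non-toroidal grid: 1 for a uniform surface, 0 for a checkerboard.

#' Binarize the response surface of a model
#'
#' @param model A fitted `som_model`.
#' @return An `nx` x `ny` integer matrix (rows indexed by `i`, columns by
#'   `j`) with entry 1 where the neuron's output weight exceeds 0.5 and 0
#'   elsewhere (exactly 0.5 maps to 0).
#' @export
binarize_responses <- function(model) {
  stopifnot(inherits(model, "som_model"))
  m <- model$grid$nx * model$grid$ny
  if (length(model$output) != m) abort("Malformed model: output layer size mismatch.")
  # output is stored in row-major neuron order: neuron = (i-1)*ny + j
  matrix(as.integer(model$output > 0.5),
         nrow = model$grid$nx, ncol = model$grid$ny, byrow = TRUE)
}

check_response_grid <- function(grid) {
  if (!is.matrix(grid) || !all(grid %in% c(0L, 1L))) {
    abort("`grid` must be a binary (0/1) matrix.")
  }
  if (nrow(grid) < 2 && ncol(grid) < 2) {
    abort("CFS is undefined on a 1 x 1 grid (zero adjacent pairs).")
  }
  invisible(grid)
}

#' Clustering formation score
#'
#' `CFS = 1 - D / (2 * Nx * Ny - Nx - Ny)` where `D` is the sum of absolute
#' differences over all horizontally and vertically adjacent neuron pairs of
#' the binarized response grid and the denominator is the total number of
#' such pairs on a non-toroidal `Nx` x `Ny` grid.  A response surface where
#' all neurons agree scores 1; a checkerboard scores 0.
#'
#' @param grid Binary (0/1) matrix, at least 1 x 2.
#' @return Score in \[0, 1\].
#' @examples
#' cfs(matrix(1, 4, 4))                             # 1
#' cfs(outer(1:4, 1:4, function(i, j) (i + j) %% 2)) # checkerboard: 0
#' @export
cfs <- function(grid) {
  check_response_grid(grid)
  nx <- nrow(grid); ny <- ncol(grid)
  d <- 0L
  if (nx > 1) d <- d + sum(abs(grid[-1, , drop = FALSE] - grid[-nx, , drop = FALSE]))
  if (ny > 1) d <- d + sum(abs(grid[, -1, drop = FALSE] - grid[, -ny, drop = FALSE]))
  1 - d / (2 * nx * ny - nx - ny)
}

#' Permutation baseline for the clustering formation score
#'
#' The expected CFS of the same responses placed at random on the same grid:
#' the mean CFS over random permutations of the grid entries (class counts
#' preserved).  With `exhaustive = TRUE` all distinct arrangements are
#' enumerated instead, giving the exact permutation mean (small grids only).
#'
#' @param grid Binary (0/1) matrix.
#' @param n_permutations Number of Monte-Carlo permutations (default 100).
#' @param seed Optional integer seed.
#' @param exhaustive Enumerate all distinct arrangements (requires
#'   `choose(cells, ones) <= 1e5`).
#' @return The mean CFS; the per-permutation scores are attached as
#'   attribute `"scores"` (Monte-Carlo mode).
#' @export
cfs_random_baseline <- function(grid, n_permutations = 100, seed = NULL,
                                exhaustive = FALSE) {
  check_response_grid(grid)
  m <- length(grid)
  ones <- sum(grid)
  if (exhaustive) {
    n_arr <- choose(m, ones)
    if (n_arr > 1e5) abort("Too many arrangements for exhaustive enumeration.")
    if (ones == 0 || ones == m) return(1)
    sets <- combn(m, ones)
    scores <- apply(sets, 2, function(pos) {
      g <- matrix(0L, nrow(grid), ncol(grid))
      g[pos] <- 1L
      cfs(g)
    })
    return(mean(scores))
  }
  check_scalar_number(n_permutations, "n_permutations", lower = 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  scores <- vapply(seq_len(n_permutations), function(r) {
    g <- matrix(grid[sample.int(m)], nrow(grid), ncol(grid))
    cfs(g)
  }, numeric(1))
  structure(mean(scores), scores = scores)
}

#' CFS difference between a model and its permutation baseline
#'
#' Binarizes the model's response surface, scores it, and subtracts the mean
#' CFS of random rearrangements of the same responses.  Larger values mean
#' the algorithm formed more contiguous class clusters than chance placement
#' of the same per-class neuron counts.
#'
#' @param model A fitted `som_model`.
#' @inheritParams cfs_random_baseline
#' @return A one-row tibble with `cfs_model`, `cfs_random` and `delta`.
#' @export
cfs_delta <- function(model, n_permutations = 100, seed = NULL,
                      exhaustive = FALSE) {
  g <- binarize_responses(model)
  cm <- cfs(g)
  cr <- as.numeric(cfs_random_baseline(g, n_permutations, seed, exhaustive))
  tibble(cfs_model = cm, cfs_random = cr, delta = cm - cr)
}

#' Density summary of CFS differences
#'
#' Gaussian kernel-density estimate (rule-of-thumb bandwidth) of a set of
#' `CFS(model) - CFS(random)` differences, as a tidy tibble suitable for
#' plotting algorithm comparisons.
#'
#' @param deltas Numeric vector of CFS differences.
#' @param n Number of evaluation points.
#' @return A tibble with columns `delta` and `density`.
#' @export
cfs_delta_density <- function(deltas, n = 256) {
  if (!is.numeric(deltas) || length(deltas) < 2) {
    abort("`deltas` must be a numeric vector of length >= 2.")
  }
  d <- stats::density(deltas, n = n)
  tibble(delta = d$x, density = d$y)
}
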