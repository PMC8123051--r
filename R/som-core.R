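# Rectangular non-toroidal SOM grid and the elementary Kohonen operations:
# winner search, triangular neighborhood, linear learning-rate schedule and
# the basic weight update.  Neuron positions are 1-based integer pairs (i, j)
# with 1 <= i <= nx, 1 <= j <= ny; the linear (row-major) index of neuron
# (i, j) is (i - 1) * ny + j, which is also the tie-break order everywhere.

#' Define a rectangular SOM grid
#'
#' Creates a rectangular, non-toroidal grid of `nx * ny` neurons.  Grid
#' coordinates are 1-based integer pairs; the neighborhood metric between
#' neurons is the Chebyshev distance `max(|i1 - i2|, |j1 - j2|)`, giving the
#' conventional square SOM neighborhoods.
#'
#' @param nx,ny Number of neurons in the x and y directions (each >= 1).
#' @return A `som_grid` object (list with `nx`, `ny`).
#' @examples
#' g <- som_grid(8, 8)
#' grid_positions(g)
#' @export
som_grid <- function(nx, ny = nx) {
  check_scalar_number(nx, "nx", lower = 1)
  check_scalar_number(ny, "ny", lower = 1)
  structure(list(nx = as.integer(nx), ny = as.integer(ny), toroidal = FALSE),
            class = "som_grid")
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("<som_grid> %d x %d rectangular, non-toroidal\n", x$nx, x$ny))
  invisible(x)
}

#' Neuron positions of a grid
#'
#' @param grid A [som_grid()].
#' @return A tibble with columns `neuron` (row-major linear index), `i`, `j`.
#' @export
grid_positions <- function(grid) {
  stopifnot(inherits(grid, "som_grid"))
  i <- rep(seq_len(grid$nx), each = grid$ny)
  j <- rep(seq_len(grid$ny), times = grid$nx)
  tibble(neuron = seq_along(i), i = i, j = j)
}

#' Chebyshev distance between grid positions
#'
#' @param i1,j1,i2,j2 Grid coordinates (vectorized).
#' @return Non-negative integer distances.
#' @export
grid_distance <- function(i1, j1, i2, j2) {
  pmax(abs(i1 - i2), abs(j1 - j2))
}

#' Triangular neighborhood kernel
#'
#' The correction factor applied to a neuron at grid distance `d` from the
#' winner when the current neighborhood radius is `radius`.  The kernel is
#' triangular: 1 at the winner, decreasing linearly as
#' `max(0, 1 - d / (radius + 1))`, and 0 for every neuron farther than the
#' radius.  At radius 0 only the winner receives a nonzero factor.
#'
#' @param d Grid distance(s) from the winning neuron, >= 0.
#' @param radius Current neighborhood radius, >= 0.
#' @return Factor(s) in \[0, 1\].
#' @examples
#' neighborhood_factor(0, 3)   # winner: 1
#' neighborhood_factor(2, 4)   # 1 - 2/5 = 0.6
#' neighborhood_factor(5, 4)   # outside: 0
#' @export
neighborhood_factor <- function(d, radius) {
  if (any(!is.finite(d)) || any(d < 0)) abort("`d` must be finite and >= 0.")
  if (any(!is.finite(radius)) || any(radius < 0)) abort("`radius` must be finite and >= 0.")
  h <- 1 - d / (radius + 1)
  h[d > radius] <- 0
  pmax(h, 0)
}

#' Training schedules
#'
#' Bundles the learning-rate range, the total iteration count and the initial
#' neighborhood radius.  The learning rate decreases linearly from `eta_max`
#' at the first iteration to `eta_min` at the last; the radius decreases
#' linearly from `initial_radius` to 0 at the last iteration (winner-only
#' update), stepped once per presented object.
#'
#' @param eta_min,eta_max Learning-rate bounds, `0 < eta_min <= eta_max`.
#' @param total_iterations Number of object presentations (>= 1).
#' @param initial_radius Starting neighborhood radius (>= 0); by default the
#'   largest possible neighborhood, `max(nx, ny) - 1`, is set by the trainer.
#' @return A `som_schedules` object.
#' @export
som_schedules <- function(eta_min, eta_max, total_iterations, initial_radius) {
  check_scalar_number(eta_min, "eta_min", lower = .Machine$double.eps)
  check_scalar_number(eta_max, "eta_max", lower = eta_min)
  check_scalar_number(total_iterations, "total_iterations", lower = 1)
  check_scalar_number(initial_radius, "initial_radius", lower = 0)
  structure(list(eta_min = eta_min, eta_max = eta_max,
                 total_iterations = as.integer(total_iterations),
                 initial_radius = initial_radius),
            class = "som_schedules")
}

#' Learning rate at an iteration
#'
#' Linear interpolation from `eta_max` (first iteration) down to `eta_min`
#' (last iteration).
#'
#' @param t Iteration number, `1 <= t <= total_iterations`.
#' @param schedules A [som_schedules()].
#' @return Learning rate in `[eta_min, eta_max]`.
#' @export
learning_rate <- function(t, schedules) {
  stopifnot(inherits(schedules, "som_schedules"))
  Tn <- schedules$total_iterations
  if (any(t < 1) || any(t > Tn)) abort("`t` out of range 1..total_iterations.")
  if (Tn == 1L) return(rep(schedules$eta_max, length(t)))
  schedules$eta_max + (schedules$eta_min - schedules$eta_max) * (t - 1) / (Tn - 1)
}

#' Neighborhood radius at an iteration
#'
#' Linear decrease from `initial_radius` at the first iteration to exactly 0
#' at the last.
#'
#' @inheritParams learning_rate
#' @return Radius value(s) >= 0.
#' @export
neighborhood_radius <- function(t, schedules) {
  stopifnot(inherits(schedules, "som_schedules"))
  Tn <- schedules$total_iterations
  if (any(t < 1) || any(t > Tn)) abort("`t` out of range 1..total_iterations.")
  if (Tn == 1L) return(rep(0, length(t)))
  schedules$initial_radius * (Tn - t) / (Tn - 1)
}

#' Basic Kohonen weight update
#'
#' Moves a weight toward the presented object value:
#' `w_new = w + eta * h * (o - w)`.  With `eta * h` in \[0, 1\] the new weight
#' always lies between the old weight and the object value.
#'
#' @param w Current weight value(s).
#' @param o Object value(s) (same length as `w` or scalar).
#' @param eta Learning rate.
#' @param h Neighborhood factor.
#' @return Updated weight value(s).
#' @examples
#' kohonen_update(0.2, 0.6, eta = 0.5, h = 1) # 0.4
#' @export
kohonen_update <- function(w, o, eta, h) {
  step <- eta * h
  if (any(!is.finite(step)) || any(step < 0) || any(step > 1)) {
    abort("`eta * h` must lie in [0, 1] (larger values would overshoot).")
  }
  w + step * (o - w)
}

#' Initialize a SOM model with random weights
#'
#' All descriptor-layer and output-layer weights are drawn uniformly from
#' (0, 1), reproducibly for a given seed.
#'
#' @param grid A [som_grid()].
#' @param k Number of descriptors (>= 1).
#' @param seed Integer seed.
#' @param descriptor_names Optional character vector of length `k`.
#' @return An (untrained) `som_model`; see [som_train()] for the fitted form.
#' @export
som_initialize <- function(grid, k, seed, descriptor_names = NULL) {
  stopifnot(inherits(grid, "som_grid"))
  check_scalar_number(k, "k", lower = 1)
  k <- as.integer(k)
  m <- grid$nx * grid$ny
  set.seed(as.integer(seed))
  W <- matrix(runif(m * k), nrow = m, ncol = k)
  O <- runif(m)
  if (is.null(descriptor_names)) descriptor_names <- paste0("D", seq_len(k))
  stopifnot(length(descriptor_names) == k)
  colnames(W) <- descriptor_names
  new_som_model(grid, W, O, descriptor_names,
                algorithm = "untrained", config = NULL, seed = as.integer(seed))
}

new_som_model <- function(grid, W, O, descriptor_names, algorithm, config, seed,
                          ranges = NULL) {
  structure(list(grid = grid, weights = W, output = O,
                 descriptor_names = descriptor_names,
                 algorithm = algorithm, config = config, seed = seed,
                 ranges = ranges),
            class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("<som_model> %s, %d x %d grid, %d descriptors\n",
              x$algorithm, x$grid$nx, x$grid$ny, length(x$descriptor_names)))
  invisible(x)
}

#' Find the winning neuron for an object
#'
#' The winner is the neuron with the shortest Euclidean distance between the
#' object's descriptors and the neuron's descriptor-layer weights.  The output
#' layer is never consulted.  Ties are broken toward the lowest row-major
#' linear index.
#'
#' @param x Numeric descriptor vector of length equal to the model's
#'   descriptor count (no missing values).
#' @param model A `som_model`.
#' @return A named list with `neuron` (linear index), `i`, `j` and `distance`.
#' @export
find_winner <- function(x, model) {
  stopifnot(inherits(model, "som_model"))
  if (!is.numeric(x) || anyNA(x)) abort("`x` must be numeric with no missing values.")
  k <- ncol(model$weights)
  if (length(x) != k) {
    abort(sprintf("Object has %d descriptors but the model expects %d.", length(x), k))
  }
  if (nrow(model$weights) == 0L) abort("Model has an empty grid.")
  d2 <- colSums((t(model$weights) - x)^2)
  w <- which.min(d2)  # which.min returns the first (lowest index) minimum
  ny <- model$grid$ny
  list(neuron = as.integer(w),
       i = as.integer((w - 1L) %/% ny + 1L),
       j = as.integer((w - 1L) %% ny + 1L),
       distance = sqrt(d2[[w]]))
}
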