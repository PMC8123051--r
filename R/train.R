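# Supervised training of the four network variants on a descriptor table,
# with class-balanced random subsampling each epoch, plus prediction and
# portable (JSON) model serialization.

#' Training configuration
#'
#' @param algorithm One of `"cpann"` (standard counter-propagation),
#'   `"xyf"` (X-Y fused network with adaptive learning),
#'   `"cpann_v1"`, `"cpann_v2"` (damped-update variants).
#' @param epochs Number of training epochs (>= 1).  One epoch presents every
#'   object of that epoch's balanced random subsample exactly once.
#' @param nx,ny Grid dimensions.
#' @param eta_min,eta_max Learning-rate bounds (`0 < eta_min <= eta_max`).
#'   For `"xyf"` keep `eta_max <= 0.5` so the doubled correction of a
#'   perfectly matched object cannot overshoot.
#' @param subsample_majority,subsample_minority Per-class subsampling
#'   fractions in (0, 1].  The defaults (0.33 for the majority class, 0.66
#'   for the minority class) equalize the class counts in each subsample for
#'   a dataset with a 2:1 imbalance.
#' @param seed Integer seed controlling weight initialization and subsampling.
#' @param p_fixed Optional override pinning the annealing parameter `p` of
#'   the damped variants to a constant (mainly for algorithm diagnostics:
#'   `p_fixed = 1` makes `cpann_v1`/`cpann_v2` coincide with `cpann`).
#'   `NULL` (default) uses the linear 1 -> 0 schedule across epochs.
#' @param alpha_start Starting value of the fused-network mixing weight
#'   `alpha`; it decreases linearly to 0.5 at the final epoch.
#' @return A `som_config` list.
#' @export
som_config <- function(algorithm = c("cpann", "xyf", "cpann_v1", "cpann_v2"),
                       epochs = 50, nx = 8, ny = nx,
                       eta_min = 0.01, eta_max = 0.5,
                       subsample_majority = 0.33, subsample_minority = 0.66,
                       seed = 1L, p_fixed = NULL, alpha_start = 1.0) {
  algorithm <- match.arg(algorithm)
  check_scalar_number(epochs, "epochs", lower = 1)
  check_scalar_number(eta_min, "eta_min", lower = .Machine$double.eps)
  check_scalar_number(eta_max, "eta_max", lower = eta_min)
  check_scalar_number(subsample_majority, "subsample_majority",
                      lower = .Machine$double.eps, upper = 1)
  check_scalar_number(subsample_minority, "subsample_minority",
                      lower = .Machine$double.eps, upper = 1)
  if (!is.null(p_fixed)) check_scalar_number(p_fixed, "p_fixed", 0, 1)
  check_scalar_number(alpha_start, "alpha_start", 0.5, 1)
  structure(list(algorithm = algorithm, epochs = as.integer(epochs),
                 nx = as.integer(nx), ny = as.integer(ny),
                 eta_min = eta_min, eta_max = eta_max,
                 subsample_majority = subsample_majority,
                 subsample_minority = subsample_minority,
                 seed = as.integer(seed), p_fixed = p_fixed,
                 alpha_start = alpha_start),
            class = "som_config")
}

#' Class-balanced random subsample
#'
#' Draws `round(fraction * class size)` indices (half-up rounding) without
#' replacement from each class and returns them in permuted order.  Training
#' redraws the subsample every epoch so that, over an optimization run, the
#' minority class is not swamped by the majority class.
#'
#' @param labels Binary (0/1) label vector; both classes must be present.
#' @param fraction_majority,fraction_minority Fractions in (0, 1] of the
#'   majority and minority class to draw.  The majority class is the more
#'   frequent label (ties: label 0).
#' @param seed Optional integer seed; `NULL` draws from the current RNG
#'   stream (as the trainer does between epochs).
#' @return Integer vector of row indices.
#' @examples
#' labels <- rep(c(0, 1), c(100, 50))
#' idx <- balanced_subsample(labels, 0.33, 0.66, seed = 1)
#' table(labels[idx]) # 33 of each class
#' @export
balanced_subsample <- function(labels, fraction_majority = 0.33,
                               fraction_minority = 0.66, seed = NULL) {
  if (!is_binary(labels)) abort("`labels` must be binary 0/1 with no missing values.")
  n0 <- sum(labels == 0); n1 <- sum(labels == 1)
  if (n0 == 0L || n1 == 0L) abort("Both classes must be present.")
  if (!is.null(seed)) set.seed(as.integer(seed))
  maj <- if (n1 > n0) 1 else 0
  frac <- c(fraction_majority, fraction_minority)
  classes <- c(maj, 1 - maj)
  idx <- unlist(lapply(seq_along(classes), function(c_i) {
    rows <- which(labels == classes[c_i])
    n_draw <- round_half_up(frac[c_i] * length(rows))
    n_draw <- max(1L, min(as.integer(n_draw), length(rows)))
    rows[sample.int(length(rows), n_draw)]
  }), use.names = FALSE)
  idx[sample.int(length(idx))]
}

#' Train a supervised self-organizing map
#'
#' Fits one of the four supervised SOM variants to a descriptor table whose
#' descriptor columns are normalized to \[0, 1\] and whose label column is
#' binary.  Each epoch draws a fresh class-balanced subsample and presents
#' its objects once; the global learning-rate and neighborhood-radius
#' schedules advance once per presented object, the annealing parameters once
#' per epoch.  The winner is found from descriptors only, except during X-Y
#' fused training where the fused dissimilarity (descriptors and target) is
#' minimized.  The output layer is trained toward the binary label.
#'
#' @param data A data frame with an id column, numeric descriptor columns in
#'   \[0, 1\] and a binary label column.
#' @param config A [som_config()].
#' @param id_col,label_col Names of the identifier and label columns.
#' @param ranges Optional normalization-range tibble (see
#'   [descriptor_ranges()]) stored in the model for later use on new data.
#' @return A fitted `som_model`: grid, descriptor-layer weight matrix
#'   (neurons x descriptors, row-major neuron order), output-layer weights,
#'   algorithm tag, config and seed.
#' @seealso [predict.som_model()], [write_som_model()]
#' @export
som_train <- function(data, config = som_config(), id_col = "compound_id",
                      label_col = "class", ranges = NULL) {
  stopifnot(inherits(config, "som_config"))
  X <- descriptor_matrix(data, id_col, label_col)
  if (!label_col %in% names(data)) abort(sprintf("No label column `%s`.", label_col))
  y <- as.numeric(data[[label_col]])
  if (!is_binary(y)) abort("Labels must be binary 0/1.")
  if (min(X) < -1e-8 || max(X) > 1 + 1e-8) {
    abort("Descriptors must be normalized to [0, 1] (see `normalize_descriptors()`).")
  }
  X <- pmin(pmax(X, 0), 1)
  k <- ncol(X)
  grid <- som_grid(config$nx, config$ny)
  m <- grid$nx * grid$ny

  # range-scaled views used by the damping factors: per-variable ranges over
  # the full training set, and the target scaled over the observed labels
  SX <- apply(X, 2, function(col) range_scale(col, min(col), max(col)))
  SX <- matrix(SX, nrow = nrow(X))
  sy <- range_scale(y, min(y), max(y))

  set.seed(config$seed)
  W0 <- matrix(runif(m * k), nrow = m, ncol = k)
  O0 <- runif(m)
  ord <- unlist(lapply(seq_len(config$epochs), function(e) {
    balanced_subsample(y, config$subsample_majority, config$subsample_minority)
  }), use.names = FALSE)
  epoch_len <- length(ord) %/% config$epochs

  alg_code <- match(config$algorithm, c("cpann", "xyf", "cpann_v1", "cpann_v2")) - 1L
  fit <- som_train_cpp(X, SX, y, sy, W0, O0, grid$nx, grid$ny,
                       as.integer(ord) - 1L, epoch_len,
                       config$eta_min, config$eta_max,
                       max(grid$nx, grid$ny) - 1,
                       alg_code, config$p_fixed %||% -1, config$alpha_start)
  W <- fit$weights
  colnames(W) <- colnames(X)
  new_som_model(grid, W, fit$output, colnames(X),
                algorithm = config$algorithm, config = config,
                seed = config$seed, ranges = ranges)
}

#' Predict classes with a fitted model
#'
#' For every object the winning neuron is found by descriptor-only Euclidean
#' distance (all four algorithms, including the X-Y fused network at
#' prediction time) and the winner's position is projected onto the output
#' layer: class 1 if the output weight exceeds 0.5, class 0 otherwise
#' (a response of exactly 0.5 maps to 0).
#'
#' @param object A fitted `som_model`.
#' @param data Data frame with the model's descriptor columns, normalized
#'   with the training ranges.
#' @param id_col,label_col Column names ignored when extracting descriptors.
#' @param ... Unused.
#' @return A tibble with one row per object: `neuron`, `i`, `j`, `distance`
#'   (to the winner), `response` (output weight) and `pred` (0/1).
#' @export
predict.som_model <- function(object, data, id_col = "compound_id",
                              label_col = "class", ...) {
  if (is.matrix(data)) {
    X <- data
  } else {
    X <- descriptor_matrix(data, id_col, label_col)
  }
  if (ncol(X) != ncol(object$weights)) {
    abort(sprintf("Data has %d descriptors but the model expects %d.",
                  ncol(X), ncol(object$weights)))
  }
  res <- find_winners_cpp(X, object$weights)
  ny <- object$grid$ny
  neuron <- res$neuron
  response <- object$output[neuron]
  tibble(neuron = neuron,
         i = (neuron - 1L) %/% ny + 1L,
         j = (neuron - 1L) %% ny + 1L,
         distance = res$distance,
         response = response,
         pred = as.integer(response > 0.5))
}

#' Save a fitted model as portable JSON
#'
#' Stores grid shape, both weight layers, normalization ranges, algorithm tag,
#' configuration and seed at full floating-point precision; [read_som_model()]
#' restores an equivalent model.
#'
#' @param model A `som_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_som_model <- function(model, path) {
  stopifnot(inherits(model, "som_model"))
  payload <- list(
    format = "cpann_som_model", version = 1L,
    nx = model$grid$nx, ny = model$grid$ny,
    algorithm = model$algorithm,
    descriptor_names = model$descriptor_names,
    weights = model$weights, output = model$output,
    seed = model$seed,
    config = if (!is.null(model$config)) unclass(model$config),
    ranges = if (!is.null(model$ranges)) as.list(model$ranges)
  )
  # 17 significant digits: exact IEEE double round trip
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' Load a model saved by [write_som_model()]
#'
#' @param path File path.
#' @return A `som_model`.
#' @export
read_som_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "cpann_som_model")) abort("Not a cpann model file.")
  W <- p$weights  # jsonlite restores the rowmajor matrix orientation
  colnames(W) <- p$descriptor_names
  config <- if (!is.null(p$config)) {
    cfg <- p$config
    if (length(cfg$p_fixed) == 0) cfg["p_fixed"] <- list(NULL)
    structure(cfg, class = "som_config")
  }
  ranges <- if (!is.null(p$ranges)) as_tibble(p$ranges)
  new_som_model(som_grid(p$nx, p$ny), W, as.numeric(p$output),
                p$descriptor_names, p$algorithm, config,
                as.integer(p$seed), ranges = ranges)
}

#' @describeIn som_train Per-neuron tidy summary of a fitted model: one row
#'   per neuron with position, output weight and predicted class.
#' @param x A `som_model`.
#' @param ... Unused.
#' @export
tidy.som_model <- function(x, ...) {
  pos <- grid_positions(x$grid)
  dplyr::mutate(pos, response = x$output[.data$neuron],
                pred = as.integer(.data$response > 0.5))
}

#' @describeIn som_train One-row model summary: algorithm, grid, descriptor
#'   count, clustering formation score of the binarized response surface.
#' @export
glance.som_model <- function(x, ...) {
  grid_ok <- x$grid$nx >= 2 || x$grid$ny >= 2
  tibble(algorithm = x$algorithm, nx = x$grid$nx, ny = x$grid$ny,
         n_descriptors = length(x$descriptor_names),
         epochs = if (!is.null(x$config)) x$config$epochs else NA_integer_,
         cfs = if (grid_ok) cfs(binarize_responses(x)) else NA_real_)
}

#' Response-surface plot of a fitted model
#'
#' Tile map of the output layer; tiles are colored by the predicted class
#' (output weight > 0.5).
#'
#' @param object A `som_model`.
#' @param binarize Plot the 0/1 predicted class (default) instead of the raw
#'   output weight.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.som_model <- function(object, binarize = TRUE, ...) {
  d <- tidy(object)
  fill <- if (binarize) factor(d$pred) else d$response
  ggplot2::ggplot(d, ggplot2::aes(x = .data$i, y = .data$j)) +
    ggplot2::geom_tile(ggplot2::aes(fill = fill), color = "grey30") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "i", y = "j",
                  fill = if (binarize) "class" else "response",
                  title = sprintf("%s response surface (%d x %d)",
                                  object$algorithm, object$grid$nx, object$grid$ny)) +
    ggplot2::theme_minimal()
}
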