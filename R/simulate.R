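# Seeded generator of synthetic descriptor-table classification datasets
# with planted cluster structure: class-separating (informative)
# descriptors, class-independent noise descriptors, and redundant
# near-duplicates of informative descriptors for correlation-pruning tests.
# The generator is the test substrate for every other module.

#' Specification of a synthetic descriptor dataset
#'
#' The defaults emulate the shape of a curated QSAR hepatotoxicity table: a
#' few hundred compounds with a 2:1 class imbalance (the majority class is
#' the negative/non-toxic one), tens of continuous descriptors scaled to
#' \[0, 1\], a handful of class-separating descriptors, and redundant
#' near-duplicates (`|r| > 0.9` with their parent) mimicking the strong
#' pairwise correlations of real descriptor pools.
#'
#' @param n_per_class Rows per class as `c(negative, positive)`.
#' @param n_informative Number of class-separating descriptors.
#' @param n_noise Number of class-independent descriptors.
#' @param n_redundant Number of near-duplicates of informative descriptors.
#' @param separation Distance between the class means of each informative
#'   descriptor, in units of the within-class standard deviation; 0 plants
#'   no signal.
#' @param seed Integer seed.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_per_class = c(160, 80), n_informative = 4,
                       n_noise = 12, n_redundant = 4, separation = 2,
                       seed = 1L) {
  stopifnot(length(n_per_class) == 2, all(n_per_class >= 1))
  check_scalar_number(n_informative, "n_informative", lower = 0)
  check_scalar_number(n_noise, "n_noise", lower = 0)
  check_scalar_number(n_redundant, "n_redundant", lower = 0)
  if (n_informative + n_noise + n_redundant < 1) {
    abort("At least one descriptor is required.")
  }
  if (n_redundant > 0 && n_informative == 0) {
    abort("Redundant descriptors need informative parents.")
  }
  check_scalar_number(separation, "separation", lower = 0)
  structure(list(n_per_class = as.integer(n_per_class),
                 n_informative = as.integer(n_informative),
                 n_noise = as.integer(n_noise),
                 n_redundant = as.integer(n_redundant),
                 separation = separation, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a synthetic descriptor dataset
#'
#' Informative descriptors are drawn from class-conditional Gaussians with
#' unit within-class spread and a mean gap of `separation`; noise
#' descriptors are standard Gaussians independent of class; redundant
#' descriptors are their parent informative descriptor plus a small Gaussian
#' perturbation (sd 0.3, giving `|r| > 0.9`).  Every column is then
#' range-scaled to \[0, 1\], so the output is training-ready.  Fully
#' reproducible for a given spec.
#'
#' @param spec A [synth_spec()].
#' @return A list with `$data` (tibble: `compound_id`, descriptor columns,
#'   `class` with 1 = positive/minority) and `$manifest` (tibble:
#'   `descriptor`, `role` in informative/redundant/noise, `parent`).
#' @examples
#' d <- generate_dataset(synth_spec(n_per_class = c(30, 15), seed = 7))
#' dplyr::count(d$data, class)
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  n0 <- spec$n_per_class[1]; n1 <- spec$n_per_class[2]
  n <- n0 + n1
  y <- rep(c(0L, 1L), c(n0, n1))

  k_inf <- spec$n_informative; k_red <- spec$n_redundant; k_noi <- spec$n_noise
  cols <- list()
  roles <- character(); parents <- character()
  for (k in seq_len(k_inf)) {
    cols[[length(cols) + 1L]] <- stats::rnorm(n, mean = y * spec$separation, sd = 1)
    roles <- c(roles, "informative"); parents <- c(parents, NA_character_)
  }
  red_parent <- if (k_red > 0) ((seq_len(k_red) - 1L) %% k_inf) + 1L else integer()
  for (k in seq_len(k_red)) {
    cols[[length(cols) + 1L]] <- cols[[red_parent[k]]] + stats::rnorm(n, sd = 0.3)
    roles <- c(roles, "redundant")
    parents <- c(parents, paste0("D", sprintf("%02d", red_parent[k])))
  }
  for (k in seq_len(k_noi)) {
    cols[[length(cols) + 1L]] <- stats::rnorm(n, mean = 0, sd = 1)
    roles <- c(roles, "noise"); parents <- c(parents, NA_character_)
  }
  names(cols) <- paste0("D", sprintf("%02d", seq_along(cols)))
  X <- vapply(cols, function(x) range_scale(x, min(x), max(x)), numeric(n))

  data <- dplyr::bind_cols(
    tibble(compound_id = sprintf("C%04d", seq_len(n))),
    as_tibble(X),
    tibble(class = y))
  manifest <- tibble(descriptor = names(cols), role = roles, parent = parents)
  list(data = data, manifest = manifest)
}

#' Generate a batch of synthetic datasets
#'
#' Crosses a list of seeds with a list of specs, producing one dataset per
#' combination (the spec's own seed is replaced by the batch seed) — the
#' substrate for algorithm-comparison experiments across many replicates.
#'
#' @param seeds Integer vector of seeds.
#' @param specs A list of [synth_spec()] objects.
#' @return A tibble with columns `seed`, `spec_id`, `data` and `manifest`
#'   (list columns).
#' @export
benchmark_suite <- function(seeds, specs) {
  if (length(seeds) == 0 || length(specs) == 0) {
    abort("`seeds` and `specs` must be non-empty.")
  }
  if (inherits(specs, "synth_spec")) specs <- list(specs)
  purrr::map_dfr(seq_along(specs), function(s_i) {
    purrr::map_dfr(seeds, function(sd) {
      sp <- specs[[s_i]]
      sp$seed <- as.integer(sd)
      g <- generate_dataset(sp)
      tibble(seed = as.integer(sd), spec_id = s_i,
             data = list(g$data), manifest = list(g$manifest))
    })
  })
}
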