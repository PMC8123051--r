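# Post-GA model screening: threshold checks over the final generations,
# stability evaluation by repeated retraining, external validation, and
# frequent-descriptor analysis across groups of selected models.

set_mean <- function(sens, spec, strict) {
  if (strict) pmin(sens, spec) else (sens + spec) / 2
}

#' Screen a GA run for candidate chromosomes
#'
#' A run passes when, within the final `window` generations, at least one
#' best-5 chromosome has average sensitivity/specificity of at least
#' `threshold` on the train, internal test and (when recorded) internal
#' validation sets.  The per-set quantity thresholded is the mean of
#' sensitivity and specificity; `strict = TRUE` instead requires each metric
#' individually to reach the threshold.  When the run passes, the best five
#' chromosomes of the final population are returned as candidates.
#'
#' @param history A `ga_history` from [ga_run()].
#' @param threshold Screening threshold (default 0.7, boundary inclusive).
#' @param window Number of final generations searched (default 20).
#' @param strict Require each metric >= threshold instead of the per-set mean.
#' @return The candidate rows (final-population best 5) when the run passes,
#'   otherwise an empty tibble; the pass flag is attached as attribute
#'   `"passed"`.
#' @export
screen_run <- function(history, threshold = 0.7, window = 20, strict = FALSE) {
  if (!all(c("generation", "rank", "sens_train") %in% names(history))) {
    abort("`history` must be a ga_run() history.")
  }
  n_gen <- max(history$generation)
  if (n_gen < window) {
    abort(sprintf("History covers %d generations; `window` needs >= %d.", n_gen, window))
  }
  tail_gen <- history[history$generation > n_gen - window, , drop = FALSE]
  ok <- set_mean(tail_gen$sens_train, tail_gen$spec_train, strict) >= threshold &
        set_mean(tail_gen$sens_test, tail_gen$spec_test, strict) >= threshold
  if ("sens_val" %in% names(tail_gen)) {
    ok <- ok & set_mean(tail_gen$sens_val, tail_gen$spec_val, strict) >= threshold
  }
  passed <- any(ok)
  out <- if (passed) {
    history[history$generation == n_gen & history$rank <= 5, , drop = FALSE]
  } else {
    history[0, , drop = FALSE]
  }
  structure(out, passed = passed)
}

#' Stability evaluation of a candidate chromosome
#'
#' Rebuilds `n_models` models that differ only in the training permutation
#' seed (weight initialization and per-epoch subsample draws) and averages
#' sensitivity and specificity per set.  The stage passes when every per-set
#' average reaches `threshold`; the external validation set, when given, is
#' checked last with the same threshold.
#'
#' @param candidate A one-row chromosome record (e.g. a [screen_run()] row):
#'   needs `descriptors` (list column or character vector), `epochs`, `grid`,
#'   `eta_min`, `eta_max`.
#' @param train,test Normalized descriptor data frames.
#' @param validation,external Optional internal-validation and external
#'   validation sets.
#' @param n_models Number of retrained models (default 100).
#' @param threshold Pass threshold (default 0.7).
#' @param seed Integer seed; model `r` trains with a seed derived from
#'   `(seed, r)`.
#' @param training A [som_config()] supplying algorithm and subsampling
#'   fractions.
#' @param strict Threshold each metric individually instead of the per-set
#'   mean of sensitivity and specificity.
#' @param id_col,label_col Column names.
#' @return A `selection_report` list: `$summary` (per-set averaged metrics
#'   and pass flags), `$models` (per-model per-set metrics), `$selected`
#'   (overall pass).
#' @export
stability_evaluation <- function(candidate, train, test, validation = NULL,
                                 external = NULL, n_models = 100,
                                 threshold = 0.7, seed = 1L,
                                 training = som_config(), strict = FALSE,
                                 id_col = "compound_id", label_col = "class") {
  check_scalar_number(n_models, "n_models", lower = 1)
  desc <- candidate$descriptors
  if (is.list(desc)) desc <- desc[[1]]
  if (!is.character(desc) || length(desc) == 0) {
    abort("`candidate` must carry a non-empty descriptor name set.")
  }
  cols <- c(intersect(id_col, names(train)), desc, label_col)
  sets <- list(train = train, test = test,
               validation = validation, external = external)
  sets <- sets[!vapply(sets, is.null, logical(1))]

  per_model <- purrr::map_dfr(seq_len(n_models), function(r) {
    cfg <- som_config(algorithm = training$algorithm,
                      epochs = candidate$epochs,
                      nx = candidate$grid, ny = candidate$grid,
                      eta_min = candidate$eta_min, eta_max = candidate$eta_max,
                      subsample_majority = training$subsample_majority,
                      subsample_minority = training$subsample_minority,
                      seed = derive_seed(seed, r),
                      p_fixed = training$p_fixed,
                      alpha_start = training$alpha_start)
    model <- som_train(train[cols], cfg, id_col = id_col, label_col = label_col)
    purrr::map_dfr(names(sets), function(s) {
      pr <- predict(model, sets[[s]][cols], id_col = id_col, label_col = label_col)
      dplyr::mutate(confusion_metrics(sets[[s]][[label_col]], pr$pred),
                    model = r, set = s, .before = 1)
    })
  })

  summary <- per_model |>
    dplyr::group_by(.data$set) |>
    dplyr::summarise(sensitivity = mean(.data$sensitivity),
                     specificity = mean(.data$specificity), .groups = "drop") |>
    dplyr::mutate(
      combined = set_mean(.data$sensitivity, .data$specificity, strict),
      passed = .data$combined >= threshold)

  internal <- summary[summary$set != "external", , drop = FALSE]
  internal_pass <- all(internal$passed)
  external_pass <- if ("external" %in% summary$set) {
    internal_pass && all(summary$passed[summary$set == "external"])
  } else {
    internal_pass
  }
  structure(list(summary = summary, models = per_model,
                 threshold = threshold, n_models = n_models,
                 selected = external_pass),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %d retrained models, threshold %.2f, %s\n",
              x$n_models, x$threshold,
              if (x$selected) "SELECTED" else "not selected"))
  print(x$summary)
  invisible(x)
}

#' Most frequently selected descriptors and their common core
#'
#' For each group of selected models (typically one group per training
#' algorithm), ranks descriptors by how many models selected them and takes
#' the `top_k` most frequent (ties at the k-th frequency are all included;
#' equal frequencies are ordered alphabetically).  The descriptors common to
#' every group's top list are returned as the intersection — the candidates
#' for the most informative descriptors overall.
#'
#' @param models A data frame with columns `group`, `model` (model id within
#'   group) and `descriptor` (one row per descriptor selected by a model).
#' @param top_k Size of each group's top list (default 10).
#' @return A list: `$top` (tibble `group`, `descriptor`, `freq`, `rank`) and
#'   `$common` (character vector of descriptors present in all top lists).
#' @export
frequent_descriptors <- function(models, top_k = 10) {
  if (!is.data.frame(models) || nrow(models) == 0 ||
      !all(c("group", "descriptor") %in% names(models))) {
    abort("`models` must be a non-empty data frame with `group` and `descriptor`.")
  }
  top <- models |>
    dplyr::count(.data$group, .data$descriptor, name = "freq") |>
    dplyr::arrange(.data$group, dplyr::desc(.data$freq), .data$descriptor) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(rank = dplyr::min_rank(dplyr::desc(.data$freq))) |>
    dplyr::filter(.data$rank <= top_k) |>
    dplyr::ungroup()
  lists <- split(top$descriptor, top$group)
  common <- Reduce(intersect, lists)
  list(top = top, common = sort(common))
}
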