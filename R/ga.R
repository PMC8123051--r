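# Genetic-algorithm selection of descriptor subsets and training
# hyperparameters.  Chromosomes hold a binary descriptor mask plus four
# hyperparameter genes (epochs, square grid size, eta_min, eta_max); fitness
# is one of the four optimization criteria evaluated by training a model on
# the masked training set and scoring it on the train and internal test sets.

#' GA configuration
#'
#' @param criterion Fitness criterion, see [optimization_criterion()].
#' @param population_size Chromosomes per population (default 95).
#' @param elites Number of best chromosomes passed unchanged to the next
#'   population (default 5).
#' @param generations Number of populations (default 200).
#' @param a Penalty coefficient of [f_nsel()].
#' @param seed Integer seed for the whole run.
#' @param gene_ranges Ranges of the hyperparameter genes: a list with
#'   `epochs`, `grid` (square grid side), `eta_min`, `eta_max`, each a
#'   length-2 numeric range.
#' @param init_density Probability that a descriptor bit is on in the initial
#'   population (and in mask-repair redraws).
#' @param tournament_size Tournament size for parent selection.
#' @param single_f Passed to [optimization_criterion()] (OC4 variant).
#' @return A `ga_config` list.
#' @export
ga_config <- function(criterion = c("oc1", "oc2", "oc3", "oc4"),
                      population_size = 95, elites = 5, generations = 200,
                      a = 1, seed = 1L,
                      gene_ranges = list(epochs = c(20, 200), grid = c(6, 12),
                                         eta_min = c(0.01, 0.1),
                                         eta_max = c(0.1, 0.5)),
                      init_density = 0.5, tournament_size = 3,
                      single_f = FALSE) {
  criterion <- match.arg(criterion)
  check_scalar_number(population_size, "population_size", lower = 2)
  check_scalar_number(elites, "elites", lower = 0, upper = population_size - 1)
  check_scalar_number(generations, "generations", lower = 1)
  stopifnot(all(c("epochs", "grid", "eta_min", "eta_max") %in% names(gene_ranges)))
  structure(list(criterion = criterion,
                 population_size = as.integer(population_size),
                 elites = as.integer(elites),
                 generations = as.integer(generations),
                 a = a, seed = as.integer(seed), gene_ranges = gene_ranges,
                 init_density = init_density,
                 tournament_size = as.integer(tournament_size),
                 single_f = single_f),
            class = "ga_config")
}

random_genes <- function(gr) {
  list(epochs = sample(seq(gr$epochs[1], gr$epochs[2]), 1L),
       grid = sample(seq(gr$grid[1], gr$grid[2]), 1L),
       eta_min = runif(1, gr$eta_min[1], gr$eta_min[2]),
       eta_max = runif(1, gr$eta_max[1], gr$eta_max[2]))
}

random_mask <- function(ndes, density) {
  repeat {
    mask <- runif(ndes) < density
    if (any(mask)) return(mask)
  }
}

fix_eta <- function(genes) {
  if (genes$eta_min > genes$eta_max) {
    tmp <- genes$eta_min; genes$eta_min <- genes$eta_max; genes$eta_max <- tmp
  }
  genes
}

chromosome_key <- function(chrom) {
  paste(paste(as.integer(chrom$mask), collapse = ""),
        chrom$genes$epochs, chrom$genes$grid,
        sprintf("%.10f", chrom$genes$eta_min),
        sprintf("%.10f", chrom$genes$eta_max), sep = "|")
}

# Deterministic per-chromosome training seed: fitness is a pure function of
# (chromosome, base seed) regardless of when the GA evaluates it.
chromosome_seed <- function(chrom, base_seed) {
  derive_seed(base_seed, which(chrom$mask), chrom$genes$epochs,
              chrom$genes$grid, chrom$genes$eta_min, chrom$genes$eta_max)
}

evaluate_chromosome <- function(chrom, sets, config, training, id_col, label_col) {
  desc <- attr(sets, "descriptors")[chrom$mask]
  cols_tr <- c(intersect(id_col, names(sets$train)), desc, label_col)
  cfg <- som_config(algorithm = training$algorithm,
                    epochs = chrom$genes$epochs,
                    nx = chrom$genes$grid, ny = chrom$genes$grid,
                    eta_min = chrom$genes$eta_min,
                    eta_max = chrom$genes$eta_max,
                    subsample_majority = training$subsample_majority,
                    subsample_minority = training$subsample_minority,
                    seed = chromosome_seed(chrom, config$seed),
                    p_fixed = training$p_fixed,
                    alpha_start = training$alpha_start)
  model <- som_train(sets$train[cols_tr], cfg, id_col = id_col, label_col = label_col)
  score_set <- function(d) {
    if (is.null(d)) return(NULL)
    pr <- predict(model, d[cols_tr], id_col = id_col, label_col = label_col)
    confusion_metrics(d[[label_col]], pr$pred)
  }
  mtr <- score_set(sets$train)
  mte <- score_set(sets$test)
  mva <- score_set(sets$validation)
  fitness <- optimization_criterion(config$criterion, mtr, mte,
                                    nsel = sum(chrom$mask),
                                    ndes = length(chrom$mask),
                                    a = config$a, single_f = config$single_f)
  list(fitness = fitness, train = mtr, test = mte, validation = mva)
}

crossover <- function(a, b) {
  nd <- length(a$mask)
  pick_a <- runif(nd) < 0.5
  mask <- ifelse(pick_a, a$mask, b$mask)
  cut <- sample(1:3, 1L)  # one-point crossover on the 4 hyperparameter genes
  ga <- unclass(a$genes); gb <- unclass(b$genes)
  genes <- c(ga[seq_len(cut)], gb[setdiff(seq_len(4), seq_len(cut))])
  genes <- genes[c("epochs", "grid", "eta_min", "eta_max")]
  list(mask = mask, genes = fix_eta(genes))
}

mutate_chromosome <- function(chrom, gr, pm, init_density) {
  nd <- length(chrom$mask)
  flip <- runif(nd) < pm
  chrom$mask <- xor(chrom$mask, flip)
  g <- chrom$genes
  if (runif(1) < pm) g$epochs <- sample(seq(gr$epochs[1], gr$epochs[2]), 1L)
  if (runif(1) < pm) g$grid <- sample(seq(gr$grid[1], gr$grid[2]), 1L)
  if (runif(1) < pm) g$eta_min <- runif(1, gr$eta_min[1], gr$eta_min[2])
  if (runif(1) < pm) g$eta_max <- runif(1, gr$eta_max[1], gr$eta_max[2])
  chrom$genes <- fix_eta(g)
  if (!any(chrom$mask)) chrom$mask <- random_mask(nd, init_density)
  chrom
}

#' Run a GA optimization
#'
#' Evolves a population of chromosomes for the configured number of
#' generations.  Each fitness evaluation trains one supervised SOM on the
#' chromosome's descriptor subset with its hyperparameter genes and scores
#' the configured optimization criterion on the train and internal test
#' sets; internal-validation metrics are recorded for later screening.
#' Parents are chosen by tournament selection, the descriptor mask undergoes
#' uniform crossover and the hyperparameter genes one-point crossover, every
#' gene mutates with probability `1 / (n_descriptors + 4)`, and the best
#' `elites` chromosomes pass unchanged to the next population, so the best
#' fitness is non-decreasing across generations.  The whole run is
#' deterministic for a given seed.
#'
#' @param train,test Normalized descriptor data frames (shared descriptor
#'   columns) used for fitness; `validation` (optional) is only recorded.
#' @param validation Optional internal validation set.
#' @param config A [ga_config()].
#' @param training A [som_config()] providing the algorithm, subsampling
#'   fractions and annealing options; its epochs/grid/learning rates are
#'   overridden by the chromosome genes.
#' @param id_col,label_col Column names.
#' @return A `ga_history` tibble: one row per generation per best-5 rank
#'   with fitness, genes, the selected descriptor names (list column) and
#'   per-set sensitivity/specificity/MCC.
#' @export
ga_run <- function(train, test, validation = NULL, config = ga_config(),
                   training = som_config(), id_col = "compound_id",
                   label_col = "class") {
  stopifnot(inherits(config, "ga_config"), inherits(training, "som_config"))
  desc <- descriptor_names(train, id_col, label_col)
  for (d in list(test, validation)) {
    if (!is.null(d) && !all(desc %in% names(d))) {
      abort("All sets must share the training set's descriptor columns.")
    }
  }
  for (d in list(train, test)) {
    if (length(unique(d[[label_col]])) < 2) {
      abort("Train and test sets must contain both classes.")
    }
  }
  sets <- structure(list(train = train, test = test, validation = validation),
                    descriptors = desc)
  nd <- length(desc)
  pm <- 1 / (nd + 4)
  gr <- config$gene_ranges
  cache <- new.env(parent = emptyenv())

  eval_cached <- function(chrom) {
    key <- chromosome_key(chrom)
    if (!is.null(cache[[key]])) return(cache[[key]])
    res <- evaluate_chromosome(chrom, sets, config, training, id_col, label_col)
    cache[[key]] <- res
    res
  }

  set.seed(config$seed)
  pop <- lapply(seq_len(config$population_size), function(i) {
    list(mask = random_mask(nd, config$init_density),
         genes = fix_eta(random_genes(gr)))
  })

  history <- vector("list", config$generations)
  for (gen in seq_len(config$generations)) {
    evals <- lapply(pop, eval_cached)
    fit <- vapply(evals, function(e) e$fitness, numeric(1))
    ord <- order(fit, decreasing = TRUE)
    top <- head(ord, max(config$elites, 5L))

    history[[gen]] <- purrr::map_dfr(seq_along(top), function(r) {
      idx <- top[r]; ch <- pop[[idx]]; ev <- evals[[idx]]
      row <- tibble(generation = gen, rank = r, fitness = ev$fitness,
                    n_desc = sum(ch$mask),
                    descriptors = list(desc[ch$mask]),
                    epochs = ch$genes$epochs, grid = ch$genes$grid,
                    eta_min = ch$genes$eta_min, eta_max = ch$genes$eta_max,
                    sens_train = ev$train$sensitivity,
                    spec_train = ev$train$specificity,
                    mcc_train = ev$train$mcc,
                    sens_test = ev$test$sensitivity,
                    spec_test = ev$test$specificity,
                    mcc_test = ev$test$mcc)
      if (!is.null(ev$validation)) {
        row$sens_val <- ev$validation$sensitivity
        row$spec_val <- ev$validation$specificity
      }
      row
    })

    if (gen == config$generations) break
    elites <- pop[head(ord, config$elites)]
    children <- lapply(seq_len(config$population_size - config$elites), function(i) {
      pa <- pop[[tournament(fit, config$tournament_size)]]
      pb <- pop[[tournament(fit, config$tournament_size)]]
      mutate_chromosome(crossover(pa, pb), gr, pm, config$init_density)
    })
    pop <- c(elites, children)
  }

  out <- dplyr::bind_rows(history)
  structure(out, class = c("ga_history", class(out)), config = config,
            training = training, descriptors = desc)
}

tournament <- function(fit, size) {
  cand <- sample.int(length(fit), size)
  cand[which.max(fit[cand])]
}

#' @export
glance.ga_history <- function(x, ...) {
  best <- dplyr::filter(x, .data$rank == 1, .data$generation == max(.data$generation))
  tibble(generations = max(x$generation), best_fitness = best$fitness,
         best_n_desc = best$n_desc, best_epochs = best$epochs,
         best_grid = best$grid)
}

#' @export
autoplot.ga_history <- function(object, ...) {
  d <- dplyr::filter(object, .data$rank == 1)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$generation, y = .data$fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "generation", y = "best fitness") +
    ggplot2::theme_minimal()
}
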