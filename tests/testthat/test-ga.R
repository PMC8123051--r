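test_that("confusion metrics match hand-computed values", {
  perfect <- confusion_metrics(rep(c(1, 0), each = 5), rep(c(1, 0), each = 5))
  expect_equal(perfect[c("sensitivity", "specificity", "mcc")],
               tibble::tibble(sensitivity = 1, specificity = 1, mcc = 1))

  # TP = TN = FP = FN = 2: no association
  truth <- c(1, 1, 1, 1, 0, 0, 0, 0)
  pred  <- c(1, 1, 0, 0, 0, 0, 1, 1)
  expect_equal(confusion_metrics(truth, pred)$mcc, 0)

  # TP=4 TN=3 FP=1 FN=2 -> MCC = 10/sqrt(600)
  truth2 <- c(rep(1, 6), rep(0, 4))
  pred2  <- c(rep(1, 4), 0, 0, 1, 0, 0, 0)
  m <- confusion_metrics(truth2, pred2)
  expect_equal(c(m$tp, m$tn, m$fp, m$fn), c(4, 3, 1, 2))
  expect_equal(m$mcc, 10 / sqrt(600))

  # zero denominators yield 0, not NaN
  degen <- confusion_metrics(c(1, 1), c(1, 1))
  expect_equal(degen$specificity, 0)
  expect_equal(degen$mcc, 0)

  expect_error(confusion_metrics(c(1, 0), c(1, 0, 1)), "equal length")
  expect_error(confusion_metrics(c(1, 2), c(1, 0)), "binary")
})

test_that("descriptor-count penalty follows its formula, including negativity", {
  expect_equal(f_nsel(1, 49, a = 1), 1)
  expect_equal(f_nsel(1, 268, a = 4), 1)
  expect_equal(f_nsel(25, 49, a = 1), 25 / 49)
  expect_equal(f_nsel(268, 268, a = 4), 1 - 4 * 267 / 268)  # ~ -2.985
  expect_error(f_nsel(0, 10, 1), ">= 1")
})

metrics_of <- function(sens, spec, mcc) {
  tibble::tibble(sensitivity = sens, specificity = spec, mcc = mcc)
}

test_that("optimization criteria evaluate as defined", {
  tr <- metrics_of(1, 1, 1); te <- metrics_of(1, 1, 1)
  expect_equal(optimization_criterion("oc1", tr, te, nsel = 1, ndes = 49), 2)

  tr2 <- metrics_of(0.9, 0.9, 0.8); te2 <- metrics_of(0.9, 0.9, 0.8)
  expect_equal(optimization_criterion("oc2", tr2, te2, nsel = 1, ndes = 49), 0.64)

  tr3 <- metrics_of(0.9, 0.8, 0.7); te3 <- metrics_of(0.85, 0.75, 0.65)
  f <- f_nsel(5, 49, 1)
  expect_equal(optimization_criterion("oc3", tr3, te3, nsel = 5, ndes = 49),
               0.75 * f)
  # oc4 with Max_val = Min_val collapses to OC3 * f (the doubled factor)
  tr4 <- metrics_of(0.8, 0.8, 0.7); te4 <- metrics_of(0.8, 0.8, 0.7)
  expect_equal(optimization_criterion("oc4", tr4, te4, nsel = 5, ndes = 49),
               0.8 * f * f)
  expect_equal(optimization_criterion("oc4", tr4, te4, nsel = 5, ndes = 49,
                                      single_f = TRUE), 0.8 * f)
  # oc4 carries the spread penalty
  expect_equal(optimization_criterion("oc4", tr3, te3, nsel = 5, ndes = 49),
               0.75 * f * (1 - (0.9 - 0.75)) * f)
})

test_that("criteria are finite, reduce to pure metrics at a = 0, and OC3 >= OC4", {
  set.seed(41)
  for (r in 1:25) {
    tr <- metrics_of(runif(1), runif(1), runif(1, -1, 1))
    te <- metrics_of(runif(1), runif(1), runif(1, -1, 1))
    nsel <- sample(1:20, 1)
    for (kind in c("oc1", "oc2", "oc3", "oc4")) {
      v <- optimization_criterion(kind, tr, te, nsel, 20, a = 1)
      expect_true(is.finite(v))
      v0 <- optimization_criterion(kind, tr, te, nsel, 20, a = 0)
      expect_equal(v0, optimization_criterion(kind, tr, te, 1, 20, a = 1))
    }
    oc3 <- optimization_criterion("oc3", tr, te, nsel, 20, a = 1)
    oc4 <- optimization_criterion("oc4", tr, te, nsel, 20, a = 1)
    if (f_nsel(nsel, 20, 1) >= 0) expect_gte(oc3, oc4 - 1e-12)
  }
})

small_ga_setup <- function(seed) {
  tr <- separated_data(seed = seed, n = c(30, 30), separation = 4,
                       n_informative = 2, n_noise = 8)
  te <- separated_data(seed = seed + 500, n = c(20, 20), separation = 4,
                       n_informative = 2, n_noise = 8)
  list(train = tr, test = te)
}

test_that("the GA is elitist, seeded, and rejects degenerate inputs", {
  s <- small_ga_setup(51)
  cfg <- ga_config("oc1", population_size = 12, elites = 3, generations = 6,
                   seed = 9,
                   gene_ranges = list(epochs = c(5, 10), grid = c(4, 5),
                                      eta_min = c(0.01, 0.1), eta_max = c(0.1, 0.5)))
  trn <- som_config("cpann", subsample_majority = 1, subsample_minority = 1)
  h1 <- ga_run(s$train, s$test, config = cfg, training = trn)
  h2 <- ga_run(s$train, s$test, config = cfg, training = trn)
  expect_equal(as.data.frame(h1), as.data.frame(h2))

  best <- h1$fitness[h1$rank == 1]
  expect_true(all(diff(best) >= 0))  # elites carried unchanged
  expect_equal(max(h1$generation), 6L)
  expect_true(all(h1$n_desc >= 1))

  single <- s$train
  single$class <- 0L
  expect_error(ga_run(single, s$test, config = cfg, training = trn),
               "both classes")
})

test_that("fitness evaluation is a pure function of chromosome and seed", {
  s <- small_ga_setup(52)
  cfg <- ga_config("oc2", population_size = 8, elites = 2, generations = 2, seed = 3,
                   gene_ranges = list(epochs = c(5, 8), grid = c(4, 4),
                                      eta_min = c(0.01, 0.05), eta_max = c(0.2, 0.4)))
  trn <- som_config("cpann", subsample_majority = 1, subsample_minority = 1)
  h <- ga_run(s$train, s$test, config = cfg, training = trn)
  row <- h[h$generation == 2 & h$rank == 1, ]
  # rebuild the same chromosome's model directly and rescore it
  chrom <- list(mask = attr(h, "descriptors") %in% row$descriptors[[1]],
                genes = list(epochs = row$epochs, grid = row$grid,
                             eta_min = row$eta_min, eta_max = row$eta_max))
  sets <- structure(list(train = s$train, test = s$test, validation = NULL),
                    descriptors = attr(h, "descriptors"))
  ev <- cpann:::evaluate_chromosome(chrom, sets, cfg, trn,
                                    "compound_id", "class")
  expect_equal(ev$fitness, row$fitness)
})

test_that("GA history records validation metrics when a validation set is given", {
  s <- small_ga_setup(53)
  va <- separated_data(seed = 999, n = c(15, 15), separation = 4,
                       n_informative = 2, n_noise = 8)
  cfg <- ga_config("oc1", population_size = 8, elites = 2, generations = 2, seed = 4,
                   gene_ranges = list(epochs = c(5, 8), grid = c(4, 4),
                                      eta_min = c(0.01, 0.05), eta_max = c(0.2, 0.4)))
  trn <- som_config("cpann", subsample_majority = 1, subsample_minority = 1)
  h <- ga_run(s$train, s$test, va, config = cfg, training = trn)
  expect_true(all(c("sens_val", "spec_val") %in% names(h)))
  expect_true(all(h$sens_val >= 0 & h$sens_val <= 1))
})
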