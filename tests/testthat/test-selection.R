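test_that("screening passes clear histories and rejects weak ones", {
  pass <- screen_run(fake_history(25, sens = 1, spec = 1), 0.7, window = 20)
  expect_true(attr(pass, "passed"))
  expect_equal(nrow(pass), 5)
  expect_true(all(pass$generation == 25))

  fail <- screen_run(fake_history(25, sens = 0.5, spec = 0.5), 0.7, window = 20)
  expect_false(attr(fail, "passed"))
  expect_equal(nrow(fail), 0)

  # "at least 0.7" is boundary-inclusive
  edge <- screen_run(fake_history(25, sens = 0.7, spec = 0.7), 0.7, window = 20)
  expect_true(attr(edge, "passed"))

  # per-set mean of sensitivity and specificity is the default quantity
  mixed <- screen_run(fake_history(25, sens = 0.9, spec = 0.55), 0.7, window = 20)
  expect_true(attr(mixed, "passed"))
  strict <- screen_run(fake_history(25, sens = 0.9, spec = 0.55), 0.7,
                       window = 20, strict = TRUE)
  expect_false(attr(strict, "passed"))

  expect_error(screen_run(fake_history(10), window = 20), "generations")
})

test_that("raising the threshold never adds selected models", {
  sens_levels <- seq(0.5, 1, by = 0.05)
  histories <- lapply(sens_levels, function(s) fake_history(25, sens = s, spec = s))
  n_selected <- function(thr) {
    sum(vapply(histories, function(h) attr(screen_run(h, thr, 20), "passed"),
               logical(1)))
  }
  thresholds <- seq(0.5, 0.95, by = 0.05)
  counts <- vapply(thresholds, n_selected, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

candidate_row <- function(desc, epochs = 15, grid = 6) {
  tibble::tibble(descriptors = list(desc), epochs = epochs, grid = grid,
                 eta_min = 0.01, eta_max = 0.4)
}

test_that("stability evaluation passes separable data and fails label noise", {
  tr <- separated_data(seed = 61, n = c(30, 30), separation = 6)
  te <- separated_data(seed = 62, n = c(20, 20), separation = 6)
  ex <- separated_data(seed = 63, n = c(15, 15), separation = 6)
  cand <- candidate_row(c("D01", "D02"))
  trn <- som_config("cpann", subsample_majority = 1, subsample_minority = 1)

  rep1 <- stability_evaluation(cand, tr, te, external = ex, n_models = 10,
                               seed = 7, training = trn)
  expect_true(rep1$selected)
  expect_true(all(rep1$summary$sensitivity > 0.95))
  expect_equal(nrow(rep1$models), 10 * 3)

  # identical seeds give identical reports
  rep2 <- stability_evaluation(cand, tr, te, external = ex, n_models = 10,
                               seed = 7, training = trn)
  expect_equal(rep1$summary, rep2$summary)

  # randomized labels: performance collapses toward chance and fails the 0.7 bar
  set.seed(99)
  tr_null <- tr; tr_null$class <- sample(tr_null$class)
  te_null <- te; te_null$class <- sample(te_null$class)
  rep_null <- stability_evaluation(cand, tr_null, te_null, n_models = 10,
                                   seed = 7, training = trn)
  expect_false(rep_null$selected)
  # held-out performance collapses to chance (train can memorize the noise)
  test_combined <- rep_null$summary$combined[rep_null$summary$set == "test"]
  expect_lt(abs(test_combined - 0.5), 0.15)

  expect_error(stability_evaluation(cand, tr, te, n_models = 0, training = trn),
               "n_models")
})

test_that("stability averages stabilize as the model count grows", {
  tr <- separated_data(seed = 64, n = c(25, 25), separation = 3, n_noise = 10)
  te <- separated_data(seed = 65, n = c(20, 20), separation = 3, n_noise = 10)
  cand <- candidate_row(c("D01", "D02"), epochs = 10, grid = 5)
  trn <- som_config("cpann", subsample_majority = 1, subsample_minority = 1)
  r_small <- stability_evaluation(cand, tr, te, n_models = 15, seed = 11, training = trn)
  r_large <- stability_evaluation(cand, tr, te, n_models = 30, seed = 11, training = trn)
  per_set_sd <- r_large$models |>
    dplyr::group_by(set) |>
    dplyr::summarise(se = sd((sensitivity + specificity) / 2) / sqrt(30))
  diffs <- abs(r_large$summary$combined - r_small$summary$combined)
  expect_true(all(diffs <= 3 * per_set_sd$se + 0.02))
})

test_that("frequent descriptors are ranked, tie-inclusive, and intersected", {
  one <- tibble::tibble(group = "a", model = 1, descriptor = c("D1", "D3"))
  fd <- frequent_descriptors(one, top_k = 10)
  expect_setequal(fd$top$descriptor, c("D1", "D3"))
  expect_setequal(fd$common, c("D1", "D3"))

  # disjoint top lists give an empty intersection
  two <- dplyr::bind_rows(
    tibble::tibble(group = "a", model = 1, descriptor = c("D1", "D2")),
    tibble::tibble(group = "b", model = 1, descriptor = c("D3", "D4")))
  expect_length(frequent_descriptors(two)$common, 0)

  # three groups share exactly one planted descriptor
  mk <- function(g, extra) tibble::tibble(
    group = g, model = rep(1:3, each = 3),
    descriptor = rep(c("COMMON", extra), times = 3))
  three <- dplyr::bind_rows(mk("a", c("A1", "A2")), mk("b", c("B1", "B2")),
                            mk("c", c("C1", "C2")))
  expect_equal(frequent_descriptors(three, top_k = 3)$common, "COMMON")

  # ties at rank k are all included
  tied <- tibble::tibble(group = "g", model = 1,
                         descriptor = c("D1", "D2", "D3"))
  expect_equal(nrow(frequent_descriptors(tied, top_k = 2)$top), 3)

  expect_error(frequent_descriptors(tibble::tibble()), "non-empty")
})
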