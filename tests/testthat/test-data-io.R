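toy_table <- function() {
  tibble::tibble(compound_id = c("a", "b", "c"),
                 D1 = c(0.1, 0.2, 0.3), D2 = c(1.5, 2.5, 0.5),
                 class = c(0L, 1L, 0L))
}

test_that("descriptor tables round-trip through CSV and TSV", {
  d <- toy_table()
  for (ext in c(".csv", ".tsv")) {
    path <- tempfile(fileext = ext)
    write_descriptor_data(d, path)
    back <- read_descriptor_data(path)
    expect_equal(as.data.frame(back), as.data.frame(d))
    unlink(path)
  }
})

test_that("malformed files fail with informative errors", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("compound_id,D1,class", "a,0.1,0", "b,oops,1"), path)
  expect_error(read_descriptor_data(path), "D1.*row 2")
  writeLines(c("compound_id,D1,D1,class", "a,1,2,0"), path)
  expect_error(read_descriptor_data(path), "Duplicate")
  writeLines(c("compound_id,D1", "a,1"), path)
  expect_error(read_descriptor_data(path), "class")
  unlink(path)
})

test_that("low-variability filter applies the inclusive 70% rule", {
  d <- tibble::tibble(
    compound_id = sprintf("c%02d", 1:10),
    eighty = c(rep(1, 8), 2, 3),          # 80% equal: dropped
    seventy = c(rep(1, 7), 2, 3, 4),      # exactly 70%: kept
    distinct = 1:10,                      # kept
    class = rep(0:1, 5))
  out <- filter_low_variability(d)
  expect_setequal(cpann:::descriptor_names(out), c("seventy", "distinct"))
  expect_equal(attr(out, "dropped"), "eighty")
  all_const <- tibble::tibble(compound_id = "x", D1 = 1, class = 0)
  expect_error(filter_low_variability(all_const), "dropped")
})

test_that("correlation pruning removes the fewest, most connected descriptors", {
  set.seed(71)
  base <- rnorm(40)
  d <- tibble::tibble(
    compound_id = sprintf("c%02d", 1:40),
    A = base, B = base + rnorm(40, sd = 0.05), C = base + rnorm(40, sd = 0.05),
    indep = rnorm(40),
    class = rep(0:1, 20))
  out <- prune_correlated(d, max_abs_r = 0.5)
  kept <- cpann:::descriptor_names(out)
  # A ~ B ~ C pairwise correlated: two removals suffice, indep untouched
  expect_equal(length(attr(out, "dropped")), 2)
  expect_true("indep" %in% kept)
  expect_true(sum(c("A", "B", "C") %in% kept) == 1)

  # duplicated column: exactly one of the pair is removed
  d2 <- tibble::tibble(compound_id = as.character(1:20), P = rnorm(20),
                       class = rep(0:1, 10))
  d2$Q <- d2$P
  out2 <- prune_correlated(d2)
  expect_equal(sort(c(cpann:::descriptor_names(out2), attr(out2, "dropped"))),
               c("P", "Q"))

  # already-compliant data is unchanged, and the pipeline is idempotent
  out3 <- prune_correlated(out)
  expect_equal(out3, out, ignore_attr = TRUE)
  refiltered <- filter_low_variability(out, 0.7)
  expect_equal(refiltered, out, ignore_attr = TRUE)

  const <- tibble::tibble(compound_id = as.character(1:5), K = rep(1, 5),
                          L = rnorm(5), class = c(0, 0, 1, 1, 1))
  expect_error(prune_correlated(const), "Constant")
})

test_that("normalization uses training ranges, clamps, and inverts exactly", {
  train <- toy_table()
  ranges <- descriptor_ranges(train)
  norm <- normalize_descriptors(train, ranges)
  expect_equal(min(norm$D1), 0)
  expect_equal(max(norm$D1), 1)

  # constant training column maps everything to 1
  const <- tibble::tibble(compound_id = c("a", "b"), D1 = c(2, 2), class = 0:1)
  expect_equal(normalize_descriptors(const)$D1, c(1, 1))

  # external values outside the training range are clamped
  ext <- tibble::tibble(compound_id = "z", D1 = 9, D2 = -1, class = 1L)
  norm_ext <- normalize_descriptors(ext, ranges)
  expect_equal(norm_ext$D1, 1)
  expect_equal(norm_ext$D2, 0)

  # denormalize . normalize is the identity on training values
  back <- denormalize_descriptors(norm, ranges)
  expect_equal(back$D1, train$D1, tolerance = 1e-12)
  expect_equal(back$D2, train$D2, tolerance = 1e-12)

  bad_ranges <- ranges
  bad_ranges$min[1] <- bad_ranges$max[1] + 1
  expect_error(normalize_descriptors(train, bad_ranges), "min > max")
  expect_error(normalize_descriptors(train, ranges[1, ]), "No range")
})

test_that("SOM-stratified splitting is seeded, exhaustive, and structure-covering", {
  d <- separated_data(seed = 72, n = c(40, 20))
  sp <- som_split(d, som_grid(4, 4), seed = 5)
  expect_equal(sort(sp$row), 1:60)
  expect_equal(anyDuplicated(sp$row), 0L)
  expect_setequal(unique(sp$set), c("train", "test", "validation"))

  # per-neuron coverage: >= 3 compounds on a neuron reach every set
  per_neuron <- table(sp$neuron)
  for (nrn in names(per_neuron[per_neuron >= 3])) {
    expect_equal(sort(unique(sp$set[sp$neuron == as.integer(nrn)])),
                 c("test", "train", "validation"))
  }

  sp2 <- som_split(d, som_grid(4, 4), seed = 5)
  expect_equal(sp, sp2)

  all_train <- som_split(d, som_grid(4, 4), fractions = c(train = 1), seed = 5)
  expect_true(all(all_train$set == "train"))

  expect_error(som_split(d, fractions = c(train = 0.8, test = 0.4)), "at most 1")
})

test_that("median splitting uses the training median with a strict rule", {
  expect_equal(median_split(c(1, 2, 3, 4, 5)), c(0L, 0L, 0L, 1L, 1L))
  expect_equal(median_split(rep(2, 4)), rep(0L, 4))
  # test-set value above the training median is high-activity even if it is
  # below the test set's own median
  expect_equal(median_split(c(4, 9, 10), reference = c(1, 2, 3, 4, 5)),
               c(1L, 1L, 1L))
  expect_error(median_split(numeric(0)), "non-empty")
})

test_that("normalized Euclidean distance matches its definition", {
  expect_equal(normalized_distance(c(0.2, 0.4), c(0.2, 0.4)), 0)
  expect_equal(normalized_distance(rep(0, 7), rep(1, 7)), 1)
  expect_equal(normalized_distance(c(0, 0), c(0.6, 0.8)), 1 / sqrt(2))
  expect_error(normalized_distance(1:2, 1:3), "equal length")
})
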