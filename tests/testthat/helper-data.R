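# Shared fixture builders: everything is generated in code at test time.

# Well-separated two-cluster dataset (one cluster per class).
separated_data <- function(seed = 1, n = c(40, 20), separation = 6,
                           n_informative = 2, n_noise = 6) {
  generate_dataset(synth_spec(n_per_class = n, n_informative = n_informative,
                              n_noise = n_noise, n_redundant = 0,
                              separation = separation, seed = seed))$data
}

# A som_model with weights set by hand (for prediction/binarization tests).
manual_model <- function(W, output, nx, ny, algorithm = "cpann") {
  colnames(W) <- paste0("D", seq_len(ncol(W)))
  cpann:::new_som_model(som_grid(nx, ny), W, output,
                        colnames(W), algorithm, config = NULL, seed = 0L)
}

# Minimal ga_history-shaped tibble for screening tests: `sets` is a named
# list giving per-set (sensitivity, specificity) used for every row.
fake_history <- function(n_gen = 25, sens = 1, spec = 1, ranks = 1:5) {
  tidyr::expand_grid(generation = seq_len(n_gen), rank = ranks) |>
    dplyr::mutate(fitness = 1, n_desc = 2,
                  descriptors = list(c("D01", "D02")),
                  epochs = 10L, grid = 5L, eta_min = 0.01, eta_max = 0.3,
                  sens_train = sens, spec_train = spec, mcc_train = 1,
                  sens_test = sens, spec_test = spec, mcc_test = 1,
                  sens_val = sens, spec_val = spec)
}
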