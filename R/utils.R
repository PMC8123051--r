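# Internal helpers shared across modules.

# round-half-up (R's round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

is_binary <- function(x) {
  is.numeric(x) && !anyNA(x) && all(x %in% c(0, 1))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

# Deterministic 31-bit integer derived from a base seed and arbitrary values;
# used to give sub-computations independent but reproducible seeds.
derive_seed <- function(base, ...) {
  parts <- unlist(list(...), use.names = FALSE)
  h <- as.double(base) %% 2147483647
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(p)) else as.double(p)
    if (!is.finite(v)) v <- 0
    h <- (h * 69069 + abs(round(v * 1e4))) %% 2147483647
  }
  as.integer(h)
}

# Extract the numeric descriptor matrix from a descriptor data frame.
descriptor_matrix <- function(data, id_col = "compound_id", label_col = "class") {
  desc <- setdiff(names(data), c(id_col, label_col))
  if (length(desc) == 0L) abort("No descriptor columns found.")
  bad <- desc[!vapply(data[desc], is.numeric, logical(1))]
  if (length(bad)) {
    abort(sprintf("Descriptor columns must be numeric: %s", paste(bad, collapse = ", ")))
  }
  X <- as.matrix(data[desc])
  if (anyNA(X)) abort("Descriptor matrix contains missing values.")
  storage.mode(X) <- "double"
  X
}

descriptor_names <- function(data, id_col = "compound_id", label_col = "class") {
  setdiff(names(data), c(id_col, label_col))
}
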