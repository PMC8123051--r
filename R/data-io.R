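# Reading/writing descriptor tables, descriptor filtering, range
# normalization, SOM-stratified set splitting, median-split classing, and
# the normalized Euclidean distance utility.

#' Read a delimited descriptor table
#'
#' Reads a CSV/TSV file with a header row into a descriptor tibble: one row
#' per compound with an identifier column, numeric descriptor columns and a
#' binary label column.  Row order is preserved and the decimal mark is
#' always `"."`.
#'
#' @param path File path; the delimiter is `","` for `.csv` and `"\t"` for
#'   `.tsv`/`.txt` (override with `delim`).
#' @param id_col,label_col Names of the identifier and label columns.
#' @param delim Optional explicit field delimiter.
#' @return A tibble.
#' @export
read_descriptor_data <- function(path, id_col = "compound_id",
                                 label_col = "class", delim = NULL) {
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  header <- strsplit(readLines(path, n = 1L), delim, fixed = TRUE)[[1]]
  dup <- unique(header[duplicated(header)])
  if (length(dup)) {
    abort(sprintf("Duplicate column names in %s: %s", path, paste(dup, collapse = ", ")))
  }
  data <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE,
                            locale = readr::locale(decimal_mark = "."))
  for (col in c(id_col, label_col)) {
    if (!col %in% names(data)) abort(sprintf("Missing column `%s` in %s.", col, path))
  }
  desc <- setdiff(names(data), c(id_col, label_col))
  for (col in desc) {
    if (!is.numeric(data[[col]])) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(data[[col]]))))[1]
      abort(sprintf("Non-numeric descriptor value in column `%s`, row %d of %s.",
                    col, bad_row %||% 1L, path))
    }
    if (anyNA(data[[col]])) {
      abort(sprintf("Missing value in column `%s`, row %d of %s.",
                    col, which(is.na(data[[col]]))[1], path))
    }
  }
  data
}

#' Write a descriptor table
#'
#' @param data A descriptor tibble.
#' @param path Output path; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @return `path`, invisibly.
#' @export
write_descriptor_data <- function(data, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(data, path)
  } else {
    readr::write_tsv(data, path)
  }
  invisible(path)
}

#' Drop low-variability descriptors
#'
#' Removes every descriptor whose most frequent value accounts for more than
#' `max_equal_fraction` of the rows (the boundary is kept: a descriptor with
#' exactly that fraction of equal values stays).
#'
#' @param data Descriptor tibble.
#' @param max_equal_fraction Maximum tolerated fraction of equal values
#'   (default 0.70).
#' @param id_col,label_col Column names.
#' @return The reduced tibble; dropped names are attached as attribute
#'   `"dropped"`.
#' @export
filter_low_variability <- function(data, max_equal_fraction = 0.70,
                                   id_col = "compound_id", label_col = "class") {
  desc <- descriptor_names(data, id_col, label_col)
  n <- nrow(data)
  if (n == 0) abort("`data` is empty.")
  frac <- vapply(desc, function(d) max(table(data[[d]])) / n, numeric(1))
  keep <- desc[frac <= max_equal_fraction]
  if (length(keep) == 0) abort("All descriptors dropped by the variability filter.")
  out <- data[intersect(names(data), c(id_col, label_col, keep))]
  structure(out, dropped = setdiff(desc, keep))
}

#' Prune pairwise-correlated descriptors
#'
#' Iteratively removes descriptors one at a time until no pair has
#' `|Pearson r|` above `max_abs_r`.  At each step the descriptor involved in
#' the most offending pairs goes; ties are broken by the larger mean `|r|`
#' against the remaining descriptors, then by name order.  Constant
#' descriptors (undefined correlation) must be removed first with
#' [filter_low_variability()].
#'
#' @param data Descriptor tibble (>= 2 rows).
#' @param max_abs_r Correlation threshold (default 0.5).
#' @param id_col,label_col Column names.
#' @return The reduced tibble with attribute `"dropped"`.
#' @export
prune_correlated <- function(data, max_abs_r = 0.5,
                             id_col = "compound_id", label_col = "class") {
  desc <- descriptor_names(data, id_col, label_col)
  if (nrow(data) < 2) abort("Need at least 2 rows to compute correlations.")
  X <- descriptor_matrix(data, id_col, label_col)
  if (any(apply(X, 2, sd) == 0)) {
    abort("Constant descriptors present; run `filter_low_variability()` first.")
  }
  r <- abs(cor(X))
  diag(r) <- 0
  keep <- desc
  dropped <- character()
  while (length(keep) > 1 && max(r) > max_abs_r) {
    offending <- rowSums(r > max_abs_r)
    worst <- max(offending)
    cand <- names(offending)[offending == worst]
    if (length(cand) > 1) {
      mean_r <- rowMeans(r[cand, , drop = FALSE])
      cand <- cand[mean_r == max(mean_r)]
      cand <- sort(cand)[1]
    }
    dropped <- c(dropped, cand)
    keep <- setdiff(keep, cand)
    r <- r[keep, keep, drop = FALSE]
  }
  out <- data[intersect(names(data), c(id_col, label_col, keep))]
  structure(out, dropped = dropped)
}

#' Per-descriptor normalization ranges
#'
#' Computes the (min, max) of every descriptor on a training partition; these
#' ranges define the \[0, 1\] normalization applied to all sets.
#'
#' @param data Training-partition descriptor tibble.
#' @param id_col,label_col Column names.
#' @return A tibble with columns `descriptor`, `min`, `max`.
#' @export
descriptor_ranges <- function(data, id_col = "compound_id", label_col = "class") {
  X <- descriptor_matrix(data, id_col, label_col)
  tibble(descriptor = colnames(X),
         min = unname(apply(X, 2, min)), max = unname(apply(X, 2, max)))
}

#' Range-normalize descriptors to \[0, 1\]
#'
#' Applies `(x - min) / (max - min)` with training-partition ranges.  A
#' constant training descriptor maps everything to 1; values of new data
#' falling outside the training range are clamped to \[0, 1\] (the model's
#' weights live in the unit cube).
#'
#' @param data Descriptor tibble to normalize.
#' @param ranges Ranges from [descriptor_ranges()] (computed on the training
#'   partition); defaults to the ranges of `data` itself.
#' @param id_col,label_col Column names.
#' @return The normalized tibble.
#' @export
normalize_descriptors <- function(data, ranges = NULL,
                                  id_col = "compound_id", label_col = "class") {
  ranges <- ranges %||% descriptor_ranges(data, id_col, label_col)
  if (any(ranges$min > ranges$max)) abort("Invalid ranges: min > max.")
  desc <- descriptor_names(data, id_col, label_col)
  missing <- setdiff(desc, ranges$descriptor)
  if (length(missing)) {
    abort(sprintf("No range available for: %s", paste(missing, collapse = ", ")))
  }
  lut <- setNames(seq_len(nrow(ranges)), ranges$descriptor)
  for (d in desc) {
    i <- lut[[d]]
    data[[d]] <- range_scale(data[[d]], ranges$min[i], ranges$max[i])
  }
  data
}

#' Invert a \[0, 1\] normalization
#'
#' @inheritParams normalize_descriptors
#' @return The de-normalized tibble (identity composed with
#'   [normalize_descriptors()] on training-partition values).
#' @export
denormalize_descriptors <- function(data, ranges,
                                    id_col = "compound_id", label_col = "class") {
  desc <- descriptor_names(data, id_col, label_col)
  lut <- setNames(seq_len(nrow(ranges)), ranges$descriptor)
  for (d in desc) {
    i <- lut[[d]]
    data[[d]] <- ranges$min[i] + data[[d]] * (ranges$max[i] - ranges$min[i])
  }
  data
}

# Unsupervised Kohonen map fit (descriptor layer only), used for the
# SOM-stratified split.
kohonen_map <- function(X, grid, epochs = 20, eta_min = 0.01, eta_max = 0.5,
                        seed = 1L) {
  m <- grid$nx * grid$ny
  set.seed(as.integer(seed))
  W0 <- matrix(runif(m * ncol(X)), nrow = m)
  O0 <- runif(m)
  ord <- unlist(lapply(seq_len(epochs), function(e) sample.int(nrow(X))),
                use.names = FALSE)
  zeros <- rep(0, nrow(X))
  fit <- som_train_cpp(X, X, zeros, zeros, W0, O0, grid$nx, grid$ny,
                       as.integer(ord) - 1L, nrow(X),
                       eta_min, eta_max, max(grid$nx, grid$ny) - 1,
                       0L, -1, 1.0)
  fit$weights
}

#' SOM-stratified train/test/validation split
#'
#' Trains an unsupervised Kohonen map on the normalized descriptors, assigns
#' every compound to its winning neuron, and then draws the requested
#' fraction of each occupied neuron into each set, walking the compounds of
#' a neuron in order of distance to the neuron and assigning each to the set
#' currently furthest below its target share.  Every set therefore samples
#' the whole structure of the map (every occupied neuron with at least as
#' many compounds as there are non-empty sets contributes to each), which
#' automates the usual manual picking of structurally diverse validation
#' compounds from a drawn top-map.
#'
#' @param data Normalized descriptor tibble.
#' @param grid A [som_grid()] for the mapping (default 8 x 8).
#' @param fractions Named fractions per set, summing to at most 1
#'   (e.g. `c(train = 0.6, test = 0.2, validation = 0.2)`); any remainder is
#'   labelled `"unassigned"`.
#' @param seed Integer seed (map training is seeded too).
#' @param epochs Kohonen map training epochs.
#' @param id_col,label_col Column names.
#' @return A tibble with one row per compound: `row`, the id column when
#'   present, `neuron`, `distance` and `set`.
#' @export
som_split <- function(data, grid = som_grid(8, 8),
                      fractions = c(train = 0.6, test = 0.2, validation = 0.2),
                      seed = 1L, epochs = 20,
                      id_col = "compound_id", label_col = "class") {
  if (sum(fractions) > 1 + 1e-9) abort("`fractions` must sum to at most 1.")
  if (is.null(names(fractions)) || any(!nzchar(names(fractions)))) {
    abort("`fractions` must be named.")
  }
  X <- descriptor_matrix(data, id_col, label_col)
  W <- kohonen_map(X, grid, epochs = epochs, seed = seed)
  res <- find_winners_cpp(X, W)
  sets <- fractions[fractions > 0]
  assign <- tibble(row = seq_len(nrow(X)), neuron = res$neuron,
                   distance = res$distance)
  assign$set <- NA_character_
  sets <- sets[order(-sets, seq_along(sets))]  # largest fraction first
  for (nrn in unique(assign$neuron)) {
    rows <- assign$row[assign$neuron == nrn]
    rows <- rows[order(assign$distance[match(rows, assign$row)], rows)]
    counts <- setNames(numeric(length(sets)), names(sets))
    for (r in seq_along(rows)) {
      if (r <= length(sets)) {
        # first pass seeds one compound into every non-empty set, so each set
        # covers the whole structure of the map
        target <- names(sets)[r]
      } else {
        deficit <- sets * r - counts
        target <- names(sets)[which.max(deficit)]
        if (max(deficit) <= 0) target <- "unassigned"
      }
      counts[target] <- counts[target] + 1
      assign$set[assign$row == rows[r]] <- target
    }
  }
  assign$set[is.na(assign$set)] <- "unassigned"
  if (id_col %in% names(data)) {
    assign[[id_col]] <- data[[id_col]][assign$row]
    assign <- dplyr::relocate(assign, dplyr::all_of(id_col), .after = "row")
  }
  assign
}

#' Median-split binary classing of continuous activities
#'
#' Labels an activity 1 (high-activity class) when it lies strictly above
#' the median of the training activities, 0 otherwise (ties at the median go
#' to the low class).  The median is always computed from the training
#' partition, also when classing test-set activities.
#'
#' @param activities Numeric activity vector to class.
#' @param reference Training activities defining the median (defaults to
#'   `activities`).
#' @return Integer 0/1 labels.
#' @examples
#' median_split(c(1, 2, 3, 4, 5)) # 0 0 0 1 1
#' @export
median_split <- function(activities, reference = activities) {
  if (!is.numeric(activities) || length(activities) == 0 || anyNA(activities)) {
    abort("`activities` must be a non-empty numeric vector without NAs.")
  }
  if (length(reference) == 0 || anyNA(reference)) {
    abort("`reference` must be non-empty without NAs.")
  }
  as.integer(activities > median(reference))
}

#' Normalized Euclidean distance
#'
#' `ED / sqrt(n)` between two descriptor vectors of length `n`; lies in
#' \[0, 1\] when both vectors are in the unit cube.  Used to report how far a
#' compound sits from the nearest training compound exciting the same neuron.
#'
#' @param a,b Equal-length numeric vectors.
#' @return The normalized distance.
#' @examples
#' normalized_distance(c(0, 0), c(0.6, 0.8)) # 1/sqrt(2)
#' @export
normalized_distance <- function(a, b) {
  if (length(a) != length(b) || length(a) == 0) {
    abort("`a` and `b` must be non-empty vectors of equal length.")
  }
  sqrt(sum((a - b)^2)) / sqrt(length(a))
}
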