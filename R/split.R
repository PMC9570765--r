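#' Rational train/test split design
#'
#' Builds a test set that covers the multimember clusters of an ART-2a
#' clustering: clusters are visited in seeded random order, one randomly
#' drawn eligible member per cluster per pass, until the requested test size
#' is reached. The most potent and least potent siRNAs are never eligible
#' for the test set; everything not selected forms the training set.
#'
#' @param encoded Encoded dataset tibble (needs `potency`).
#' @param clustering A `sibcut_art2a` object for the same rows.
#' @param test_size Number of test samples, `0 <= test_size <= N - 2`.
#' @param seed Integer seed for the draw.
#' @return An object of class `sibcut_split`: integer vectors `train_idx`
#'   and `test_idx` (disjoint, covering all rows), plus `ids` if available.
#' @export
design_split <- function(encoded, clustering, test_size, seed = 1L) {
  parts <- encoded_parts(encoded)
  y <- parts$y
  n <- length(y)
  stopifnot(length(clustering$assignment) == n)
  if (test_size < 0 || test_size > n - 2L) {
    abort(sprintf("test_size must be in [0, N - 2] = [0, %d]", n - 2L),
          class = "sibcut_error_input")
  }
  extremes <- c(which.max(y), which.min(y))
  sizes <- clustering$cluster_sizes
  multi <- which(sizes >= 2L)
  eligible <- setdiff(which(clustering$assignment %in% multi), extremes)
  if (test_size > length(eligible)) {
    abort(sprintf(
      "test_size %d exceeds the %d eligible samples in multimember clusters",
      test_size, length(eligible)),
      class = "sibcut_error_input")
  }
  test_idx <- withr_seed(seed, {
    chosen <- integer(0)
    pool <- split(eligible, clustering$assignment[eligible])
    cluster_order <- sample(names(pool))
    while (length(chosen) < test_size) {
      drew <- FALSE
      for (cl in cluster_order) {
        if (length(chosen) >= test_size) break
        avail <- setdiff(pool[[cl]], chosen)
        if (length(avail)) {
          chosen <- c(chosen, if (length(avail) == 1L) avail else sample(avail, 1L))
          drew <- TRUE
        }
      }
      if (!drew) break
    }
    sort(chosen)
  })
  structure(list(
    train_idx = setdiff(seq_len(n), test_idx),
    test_idx = test_idx,
    ids = parts$ids,
    seed = seed
  ), class = "sibcut_split")
}

#' @export
print.sibcut_split <- function(x, ...) {
  cat(sprintf("<sibcut_split> train %d / test %d\n",
              length(x$train_idx), length(x$test_idx)))
  invisible(x)
}

#' Split membership as a tidy table
#'
#' @param x A `sibcut_split`.
#' @param ... Unused.
#' @return Tibble with columns `id` and `role` (`"train"`/`"test"`).
#' @method tidy sibcut_split
#' @export
tidy.sibcut_split <- function(x, ...) {
  n <- length(x$train_idx) + length(x$test_idx)
  role <- rep("train", n)
  role[x$test_idx] <- "test"
  ids <- if (!is.null(x$ids)) x$ids else as.character(seq_len(n))
  tibble(id = ids, role = role)
}

#' Generate a family of rational splits
#'
#' All splits share one clustering; each draw uses a seed derived from the
#' master seed, so the whole family is reproducible.
#'
#' @param encoded Encoded dataset tibble.
#' @param clustering A `sibcut_art2a` object.
#' @param n_splits Number of train/test pairs.
#' @param test_size Test-set size for every pair.
#' @param seed Master seed.
#' @return List of `sibcut_split` objects.
#' @export
generate_splits <- function(encoded, clustering, n_splits, test_size,
                            seed = 1L) {
  stopifnot(n_splits >= 1)
  map(seq_len(n_splits), function(k) {
    design_split(encoded, clustering, test_size,
                 seed = (seed + 7919L * k) %% .Machine$integer.max)
  })
}

# split whose test set covers clusters first and, when the eligible pool is
# exhausted, fills up with random non-extreme samples; used by the
# training-size scan where test sets are far larger than the covered pool
rational_subset <- function(encoded, clustering, test_size, seed = 1L) {
  parts <- encoded_parts(encoded)
  y <- parts$y; n <- length(y)
  extremes <- c(which.max(y), which.min(y))
  sizes <- clustering$cluster_sizes
  multi <- which(sizes >= 2L)
  eligible <- setdiff(which(clustering$assignment %in% multi), extremes)
  covered <- min(test_size, length(eligible))
  base <- if (covered > 0) {
    design_split(encoded, clustering, covered, seed = seed)$test_idx
  } else integer(0)
  extra_needed <- test_size - length(base)
  if (extra_needed > 0) {
    remaining <- setdiff(seq_len(n), c(base, extremes))
    if (extra_needed > length(remaining)) {
      abort("test_size leaves no room for the training extremes",
            class = "sibcut_error_input")
    }
    extra <- withr_seed(seed + 1L, sample(remaining, extra_needed))
    base <- sort(c(base, extra))
  }
  structure(list(
    train_idx = setdiff(seq_len(n), base),
    test_idx = base,
    ids = parts$ids,
    seed = seed
  ), class = "sibcut_split")
}
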