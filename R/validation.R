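#' Evaluate a PLS protocol over many rational splits
#'
#' Fits one model per split and reports training and test statistics per
#' split plus the aggregate mean, standard deviation, maximum and minimum
#' of each statistic.
#'
#' @param encoded Encoded dataset tibble.
#' @param splits List of `sibcut_split` objects.
#' @param n_components Components per model (integer or `"all"`).
#' @param scale Autoscale flag passed to [fit_pls()].
#' @param keep_models If `TRUE`, keep the fitted models (needed for
#'   [relative_importance()]).
#' @return An object of class `sibcut_split_stats`: tibbles `per_split` and
#'   `aggregate`, and optionally `models`.
#' @export
multi_split_evaluation <- function(encoded, splits, n_components = "all",
                                   scale = TRUE, keep_models = FALSE) {
  stopifnot(length(splits) >= 1)
  parts <- encoded_parts(encoded)
  n <- length(parts$y)
  rows <- list(); models <- list()
  for (k in seq_along(splits)) {
    sp <- splits[[k]]
    if (length(intersect(sp$train_idx, sp$test_idx)) ||
        length(union(sp$train_idx, sp$test_idx)) != n) {
      abort(sprintf("split %d does not partition the dataset", k),
            class = "sibcut_error_input")
    }
    fit <- suppressWarnings(fit_pls(
      parts$X[sp$train_idx, , drop = FALSE],
      y = parts$y[sp$train_idx],
      n_components = n_components, scale = scale
    ))
    tr <- evaluate_predictions(parts$y[sp$train_idx], fit$fitted)
    rows[[length(rows) + 1L]] <- bind_cols(tibble(split = k, set = "train"), tr)
    if (length(sp$test_idx)) {
      pred <- predict(fit, parts$X[sp$test_idx, , drop = FALSE])
      te <- evaluate_predictions(parts$y[sp$test_idx], pred)
      rows[[length(rows) + 1L]] <- bind_cols(tibble(split = k, set = "test"), te)
    }
    if (keep_models) models[[k]] <- fit
  }
  per_split <- bind_rows(rows)
  aggregate <- per_split |>
    tidyr::pivot_longer(c("r", "r2", "rmse"), names_to = "statistic") |>
    group_by(.data$set, .data$statistic) |>
    summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1L) stats::sd(.data$value) else 0,
      max = max(.data$value), min = min(.data$value),
      .groups = "drop"
    )
  structure(list(per_split = per_split, aggregate = aggregate,
                 models = if (keep_models) models else NULL,
                 n_components = n_components),
            class = "sibcut_split_stats")
}

#' @export
print.sibcut_split_stats <- function(x, ...) {
  n_splits <- max(x$per_split$split)
  cat(sprintf("<sibcut_split_stats> %d split(s), n_components = %s\n",
              n_splits, as.character(x$n_components)))
  r <- x$aggregate |> filter(.data$statistic == "r")
  for (k in seq_len(nrow(r))) {
    cat(sprintf("  %-5s r: mean %.3f sd %.3f max %.3f min %.3f\n",
                r$set[k], r$mean[k], r$sd[k], r$max[k], r$min[k]))
  }
  invisible(x)
}

#' @method tidy sibcut_split_stats
#' @export
tidy.sibcut_split_stats <- function(x, ...) x$per_split

#' @method glance sibcut_split_stats
#' @export
glance.sibcut_split_stats <- function(x, ...) {
  x$aggregate |>
    filter(.data$statistic == "r") |>
    tidyr::pivot_wider(names_from = "set",
                       values_from = c("mean", "sd", "max", "min"))
}

#' Scan the number of PLS components
#'
#' Fits a model per grid entry on a fixed split and reports training and
#' test statistics; the default grid is `"all"` followed by 1..14.
#'
#' @param encoded Encoded dataset tibble.
#' @param split A `sibcut_split`.
#' @param component_grid Vector mixing integers and the string `"all"`.
#' @param scale Autoscale flag.
#' @return Tibble of class `sibcut_pc_scan`: one row per grid entry and set.
#' @export
pc_scan <- function(encoded, split, component_grid = c("all", 1:14),
                    scale = TRUE) {
  stopifnot(length(component_grid) >= 1)
  parts <- encoded_parts(encoded)
  rows <- list()
  for (g in component_grid) {
    nc <- if (identical(g, "all") || identical(g, "\"all\"")) "all" else as.integer(g)
    fit <- suppressWarnings(fit_pls(
      parts$X[split$train_idx, , drop = FALSE],
      y = parts$y[split$train_idx],
      n_components = nc, scale = scale
    ))
    tr <- evaluate_predictions(parts$y[split$train_idx], fit$fitted)
    rows[[length(rows) + 1L]] <- bind_cols(
      tibble(n_components = as.character(g),
             components_used = fit$n_components_used, set = "train"), tr)
    if (length(split$test_idx)) {
      pred <- predict(fit, parts$X[split$test_idx, , drop = FALSE])
      te <- evaluate_predictions(parts$y[split$test_idx], pred)
      rows[[length(rows) + 1L]] <- bind_cols(
        tibble(n_components = as.character(g),
               components_used = fit$n_components_used, set = "test"), te)
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("sibcut_pc_scan", class(out))
  out
}

#' Scan the training-set size
#'
#' For each requested fraction, draws a rational split whose training set is
#' that fraction of the dataset (cluster coverage first, seeded random fill
#' when the covered pool is smaller than the test set), fits a model with
#' `n_components = "all"`, and evaluates both sets.
#'
#' @param encoded Encoded dataset tibble.
#' @param fractions Training fractions in (0, 1).
#' @param clustering Optional `sibcut_art2a`; computed at `vigilance` if
#'   missing.
#' @param vigilance Vigilance used when `clustering` is missing.
#' @param n_components Components per model (default `"all"`).
#' @param scale Autoscale flag.
#' @param seed Master seed.
#' @return Tibble: one row per fraction and set, with `n_train`, `n_test`
#'   and the evaluation statistics. Fractions leaving fewer than 2 training
#'   samples are skipped with a warning.
#' @export
training_size_scan <- function(encoded, fractions, clustering = NULL,
                               vigilance = 0.5, n_components = "all",
                               scale = TRUE, seed = 1L) {
  if (length(fractions) == 0) {
    return(tibble(fraction = numeric(), set = character(), r = numeric(),
                  r2 = numeric(), rmse = numeric(), n = integer(),
                  n_train = integer(), n_test = integer()))
  }
  stopifnot(all(fractions > 0 & fractions < 1))
  parts <- encoded_parts(encoded)
  n <- length(parts$y)
  if (is.null(clustering)) {
    clustering <- art2a_cluster(parts$X, vigilance = vigilance, seed = seed)
  }
  rows <- list()
  for (f in fractions) {
    n_train <- round(f * n)
    if (n_train < 2L) {
      warn(sprintf("fraction %.3f leaves %d training samples; skipped",
                   f, n_train))
      next
    }
    sp <- rational_subset(encoded, clustering, test_size = n - n_train,
                          seed = (seed + round(1e4 * f)) %% .Machine$integer.max)
    fit <- suppressWarnings(fit_pls(
      parts$X[sp$train_idx, , drop = FALSE], y = parts$y[sp$train_idx],
      n_components = n_components, scale = scale
    ))
    tr <- evaluate_predictions(parts$y[sp$train_idx], fit$fitted)
    rows[[length(rows) + 1L]] <- bind_cols(
      tibble(fraction = f, set = "train",
             n_train = length(sp$train_idx), n_test = length(sp$test_idx)), tr)
    if (length(sp$test_idx)) {
      pred <- predict(fit, parts$X[sp$test_idx, , drop = FALSE])
      te <- evaluate_predictions(parts$y[sp$test_idx], pred)
      rows[[length(rows) + 1L]] <- bind_cols(
        tibble(fraction = f, set = "test",
               n_train = length(sp$train_idx), n_test = length(sp$test_idx)), te)
    }
  }
  bind_rows(rows)
}

#' Y-scrambling validation
#'
#' Permutes the potencies across the whole dataset once (seeded), rebuilds
#' rational splits on the scrambled data (the potency extremes move), and
#' applies the same modeling protocol to the original and scrambled data.
#' A real structure-potency relationship should collapse: the paper-style
#' check is the percent reduction of the mean test correlation.
#'
#' @param encoded Encoded dataset tibble.
#' @param clustering A `sibcut_art2a` for the descriptor matrix (unchanged
#'   by scrambling).
#' @param n_splits,test_size Split-family parameters.
#' @param n_components Components per model.
#' @param scale Autoscale flag.
#' @param seed Master seed (drives the permutation and both split families).
#' @return List of class `sibcut_scramble`: `original` and `scrambled`
#'   `sibcut_split_stats`, `permutation`, and a `reduction` tibble with the
#'   percent drop of mean r for train and test (NA when the original mean r
#'   is <= 0, where a relative reduction is meaningless).
#' @export
y_scramble_test <- function(encoded, clustering, n_splits = 10L,
                            test_size, n_components = "all", scale = TRUE,
                            seed = 1L) {
  parts <- encoded_parts(encoded)
  n <- length(parts$y)
  perm <- withr_seed(seed * 2L + 1L, sample.int(n))
  scrambled <- encoded
  scrambled$potency <- parts$y[perm]
  splits_orig <- generate_splits(encoded, clustering, n_splits, test_size,
                                 seed = seed)
  splits_scr <- generate_splits(scrambled, clustering, n_splits, test_size,
                                seed = seed)
  orig <- multi_split_evaluation(encoded, splits_orig,
                                 n_components = n_components, scale = scale)
  scr <- multi_split_evaluation(scrambled, splits_scr,
                                n_components = n_components, scale = scale)
  mean_r <- function(stats, which_set) {
    stats$aggregate |>
      filter(.data$set == which_set, .data$statistic == "r") |>
      pull("mean")
  }
  reduction <- bind_rows(lapply(c("train", "test"), function(s) {
    ro <- mean_r(orig, s); rs <- mean_r(scr, s)
    tibble(set = s, original_mean_r = ro, scrambled_mean_r = rs,
           percent_reduction = if (ro > 0) 100 * (1 - rs / ro) else NA_real_)
  }))
  structure(list(original = orig, scrambled = scr, permutation = perm,
                 reduction = reduction),
            class = "sibcut_scramble")
}

#' @export
print.sibcut_scramble <- function(x, ...) {
  cat("<sibcut_scramble>\n")
  for (k in seq_len(nrow(x$reduction))) {
    with(x$reduction[k, ], cat(sprintf(
      "  %-5s mean r %.3f -> %.3f (reduction %s%%)\n",
      set, original_mean_r, scrambled_mean_r,
      ifelse(is.na(percent_reduction), "NA",
             sprintf("%.1f", percent_reduction)))))
  }
  invisible(x)
}

#' Relative importance of descriptors, positions and BCUT properties
#'
#' For each model the importance of descriptor column i is the normalized
#' absolute autoscaled regression coefficient `|b_i| / sum_j |b_j|`; these
#' are averaged over models. The per-position marginal averages a position's
#' 12 columns, and the per-BCUT marginal averages a descriptor's L position
#' columns; each marginal is renormalized to sum to one.
#'
#' @param models List of `sibcut_pls` models sharing column labels.
#' @param L Sequence length (positions); inferred from labels if missing.
#' @return Object of class `sibcut_importance`: tibbles `per_column`
#'   (`term`, `position`, `descriptor`, `importance`), `per_position`,
#'   `per_bcut`.
#' @export
relative_importance <- function(models, L = NULL) {
  stopifnot(length(models) >= 1)
  labels <- models[[1]]$labels
  for (m in models) {
    if (!identical(m$labels, labels)) {
      abort("models do not share column labels", class = "sibcut_error_input")
    }
  }
  imp_mat <- vapply(models, function(m) {
    b <- numeric(m$p); b[m$keep] <- abs(m$coef_scaled)
    s <- sum(b)
    if (s == 0) {
      abort("a model has an all-zero coefficient vector",
            class = "sibcut_error_degenerate")
    }
    b / s
  }, numeric(length(labels)))
  imp <- rowMeans(imp_mat)
  meta <- map(labels, parse_column_label)
  per_column <- tibble(
    term = labels,
    position = map_int(meta, "position"),
    descriptor = map_chr(meta, "descriptor"),
    importance = imp
  )
  if (is.null(L)) L <- max(per_column$position)
  per_position <- per_column |>
    group_by(.data$position) |>
    summarise(importance = mean(.data$importance), .groups = "drop") |>
    mutate(importance = .data$importance / sum(.data$importance)) |>
    arrange(.data$position)
  per_bcut <- per_column |>
    group_by(.data$descriptor) |>
    summarise(importance = mean(.data$importance), .groups = "drop") |>
    mutate(importance = .data$importance / sum(.data$importance))
  per_bcut <- per_bcut[match(BCUT_NAMES, per_bcut$descriptor), ]
  structure(list(per_column = per_column, per_position = per_position,
                 per_bcut = per_bcut, L = L),
            class = "sibcut_importance")
}

#' @export
print.sibcut_importance <- function(x, ...) {
  top <- x$per_position |> arrange(dplyr::desc(.data$importance)) |> head(5)
  cat(sprintf("<sibcut_importance> top positions: %s\n",
              paste0("nt", top$position, collapse = ", ")))
  invisible(x)
}

#' @method tidy sibcut_importance
#' @export
tidy.sibcut_importance <- function(x, ...) x$per_column
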