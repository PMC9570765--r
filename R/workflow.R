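#' Run the full modeling workflow
#'
#' Executes encode -> cluster -> split -> fit -> evaluate, with optional
#' component scan, training-size scan, y-scrambling and importance analyses,
#' and writes tidy CSV reports plus a JSON manifest (config, seed, package
#' version, train/test sizes) into an output directory. Rerunning with the
#' same config reproduces every number.
#'
#' @param config A named list or path to a YAML file with entries:
#'   `dataset` (siRNA CSV path), `descriptor_table` (TSV path or
#'   `"natural"`), `test_size`, `n_splits`, one of `vigilance` /
#'   `target_clusters`, `n_components` (integer or `"all"`), `seed`, and
#'   `analyses` (subset of `"pcscan"`, `"sizescan"`, `"scramble"`,
#'   `"importance"`).
#' @param output_dir Directory for reports (created if needed).
#' @return Invisibly, a list with the computed objects and report paths.
#' @export
run_workflow <- function(config, output_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(descriptor_table = "natural", test_size = NULL,
                   n_splits = 10L, vigilance = NULL, target_clusters = NULL,
                   n_components = "all", seed = 1L, analyses = character())
  config <- modifyList(defaults, config)
  if (is.null(config$dataset)) {
    abort("config$dataset is required", class = "sibcut_error_input")
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  records <- read_sirna_csv(config$dataset)
  table <- if (identical(config$descriptor_table, "natural")) {
    natural_descriptor_table()
  } else {
    load_descriptor_table(config$descriptor_table)
  }
  encoded <- encode_dataset(records, table)
  n <- nrow(encoded)
  if (is.null(config$test_size)) config$test_size <- max(1L, round(0.1 * n))

  if (!is.null(config$target_clusters)) {
    tuned <- tune_vigilance(encoded, config$target_clusters,
                            seed = config$seed)
    clustering <- tuned$clustering
  } else {
    v <- if (is.null(config$vigilance)) 0.5 else config$vigilance
    clustering <- art2a_cluster(encoded, vigilance = v, seed = config$seed)
  }

  splits <- generate_splits(encoded, clustering, config$n_splits,
                            config$test_size, seed = config$seed)
  stats <- multi_split_evaluation(encoded, splits,
                                  n_components = config$n_components,
                                  keep_models = TRUE)
  results <- list(clustering = clustering, splits = splits, stats = stats)

  paths <- list()
  wr <- function(df, name) {
    p <- file.path(output_dir, name)
    readr::write_csv(df, p)
    paths[[name]] <<- p
  }
  wr(stats$per_split, "split_stats.csv")
  wr(stats$aggregate, "split_stats_aggregate.csv")
  for (k in seq_along(splits)) {
    if (k == 1L) wr(tidy(splits[[k]]), "split_01_membership.csv")
  }

  if ("pcscan" %in% config$analyses) {
    scan <- pc_scan(encoded, splits[[1]])
    results$pc_scan <- scan
    wr(as_tibble(scan), "pc_scan.csv")
  }
  if ("sizescan" %in% config$analyses) {
    fr <- config$size_fractions
    if (is.null(fr)) fr <- c(0.01, 0.02, 0.03, 0.04, 0.05, 0.1,
                             seq(0.2, 0.9, by = 0.1))
    sizes <- training_size_scan(encoded, fr, clustering = clustering,
                                seed = config$seed)
    results$size_scan <- sizes
    wr(sizes, "size_scan.csv")
  }
  if ("scramble" %in% config$analyses) {
    scr <- y_scramble_test(encoded, clustering, n_splits = config$n_splits,
                           test_size = config$test_size,
                           n_components = config$n_components,
                           seed = config$seed)
    results$scramble <- scr
    wr(scr$reduction, "scramble_reduction.csv")
    wr(scr$scrambled$per_split, "scramble_split_stats.csv")
  }
  if ("importance" %in% config$analyses) {
    imp <- relative_importance(stats$models)
    results$importance <- imp
    wr(imp$per_column, "importance_columns.csv")
    wr(imp$per_position, "importance_positions.csv")
    wr(imp$per_bcut, "importance_bcut.csv")
  }

  manifest <- list(
    package = "sibcut",
    version = as.character(utils::packageVersion("sibcut")),
    config = config,
    n = n,
    n_train = length(splits[[1]]$train_idx),
    n_test = length(splits[[1]]$test_idx),
    vigilance = clustering$vigilance,
    n_multimember = clustering$n_multimember,
    reports = names(paths)
  )
  mpath <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  results$manifest <- manifest
  results$paths <- c(paths, manifest = mpath)
  invisible(results)
}
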