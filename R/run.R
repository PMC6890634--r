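#' Run the full modeling-and-optimization workflow
#'
#' End-to-end orchestration: expand the treatment table to replicate-level
#' records, split 75/25, fit one RBF surrogate per response on the training
#' partition, evaluate train/test metrics, optimize the four responses with
#' NSGA-II, select the ideal-point recipe and rank factor importance by
#' VSE/VSR over all records. All randomness derives from `seed`: replicates
#' use `seed`, the split `seed + 1`, CV folds `seed + 2` and NSGA-II
#' `seed + 3`.
#'
#' @param treatments Treatment tibble (default the built-in chrysanthemum
#'   experiment).
#' @param n_rep Simulated lines per treatment (default 9).
#' @param train_frac Training fraction (default 0.75).
#' @param seed Integer master seed.
#' @param fit_control [rbf_control()] for the surrogates (its `seed` is
#'   overridden by the derived seed).
#' @param nsga [nsga_control()] for the optimizer (its `seed` likewise).
#' @param out_dir Optional directory; when given, writes `replicates.csv`,
#'   `metrics.csv`, `front.csv`, `recipe.json`, `sensitivity.csv` and
#'   `provenance.json` there.
#' @return A list with `replicates`, `split`, `models`, `metrics` (tibble of
#'   train/test metrics per response), `opt` (a `medium_opt`), `sensitivity`
#'   and `seed`.
#' @export
run_pipeline <- function(treatments = chrysanthemum_treatments(), n_rep = 9,
                         train_frac = 0.75, seed = 1,
                         fit_control = rbf_control(),
                         nsga = nsga_control(), out_dir = NULL) {
  seed <- as.integer(seed)
  replicates <- simulate_replicates(treatments, n_rep = n_rep, seed = seed)
  split <- split_replicates(replicates, train_frac = train_frac, seed = seed + 1L)
  fit_control$seed <- seed + 2L
  nsga$seed <- seed + 3L

  resp <- growth_responses()
  models <- purrr::map(
    setNames(resp, resp),
    function(r) rbf_fit(split$train, r, control = fit_control)
  )

  metrics <- purrr::map_dfr(resp, function(r) {
    m <- models[[r]]
    train <- regression_metrics(split$train[[r]], predict(m, split$train))
    rows <- dplyr::bind_cols(tibble::tibble(response = r, set = "train"), train)
    if (nrow(split$test) > 0) {
      test <- regression_metrics(split$test[[r]], predict(m, split$test))
      rows <- dplyr::bind_rows(
        rows,
        dplyr::bind_cols(tibble::tibble(response = r, set = "test"), test)
      )
    }
    rows
  })

  # bounds and ideal come from the treatment-level experiment: the printed
  # means are the observed extremes, and simulated replicate noise must not
  # inflate the ideal point
  opt <- optimize_medium(models, treatments, control = nsga)
  sens <- sensitivity_vsr(models, replicates)

  result <- list(
    replicates = replicates, split = split, models = models,
    metrics = metrics, opt = opt, sensitivity = sens, seed = seed
  )
  if (!is.null(out_dir)) write_pipeline_bundle(result, out_dir)
  result
}

write_pipeline_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$replicates, file.path(out_dir, "replicates.csv"))
  readr::write_csv(result$metrics, file.path(out_dir, "metrics.csv"))
  readr::write_csv(result$opt$front, file.path(out_dir, "front.csv"))
  readr::write_csv(result$sensitivity, file.path(out_dir, "sensitivity.csv"))
  jsonlite::write_json(
    list(
      recipe = as.list(result$opt$recipe),
      predicted = as.list(result$opt$predicted),
      distance = result$opt$distance,
      ideal = as.list(result$opt$ideal)
    ),
    file.path(out_dir, "recipe.json"),
    digits = NA, auto_unbox = TRUE
  )
  jsonlite::write_json(
    list(
      seed = result$seed,
      n_replicates = nrow(result$replicates),
      n_train = nrow(result$split$train),
      n_test = nrow(result$split$test),
      nsga = unclass(result$opt$control),
      package_version = as.character(utils::packageVersion("mediumopt"))
    ),
    file.path(out_dir, "provenance.json"),
    digits = NA, auto_unbox = TRUE, null = "null"
  )
  invisible(out_dir)
}

#' Load a workflow configuration from YAML
#'
#' Reads a run configuration with optional keys `treatments_csv`, `n_rep`,
#' `train_frac`, `seed`, `fit` (fields of [rbf_control()]), `nsga` (fields of
#' [nsga_control()]) and `out_dir`, and returns the matched argument list
#' for [run_pipeline()].
#'
#' @param path YAML file path.
#' @return A named list of arguments for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(cfg$treatments_csv)) {
    args$treatments <- read_treatments(cfg$treatments_csv)
  }
  for (key in c("n_rep", "train_frac", "seed", "out_dir")) {
    if (!is.null(cfg[[key]])) args[[key]] <- cfg[[key]]
  }
  if (!is.null(cfg$fit)) args$fit_control <- do.call(rbf_control, cfg$fit)
  if (!is.null(cfg$nsga)) args$nsga <- do.call(nsga_control, cfg$nsga)
  args
}
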