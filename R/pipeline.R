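#' Pipeline configuration
#'
#' Bundles every choice of an end-to-end run: the input study (a CSV path
#' or a [generator_config()]), the pairwise construction, preprocessing,
#' and the model suite. Every random stage carries an explicit seed
#' derived from `seed`.
#'
#' @param input Path to a sample-table CSV, or a [generator_config()] to
#'   simulate one.
#' @param n_pairs Number of query/reference pairs (or `"all"`).
#' @param include_self Allow query == reference pairs. Defaults to `TRUE`
#'   here (unlike [build_pair_dataset()]): the published case count of
#'   123,872 exceeds the 352 x 351 non-self ordered pairs, so the
#'   paper-scale construction must draw from the full 352^2 grid.
#' @param scheme Perturbation anchoring, see [featurize_pair()].
#' @param feature_view `"grm"` (five features) or `"full"`.
#' @param normalization_fit `"full"` mirrors the published pipeline
#'   (parameters fitted on the whole dataset before splitting; a known
#'   leakage); `"train"` fits on the training set only.
#' @param train_fraction,split_mode Split specification, see
#'   [split_dataset()].
#' @param filter_threshold Residual cutoff for the outlier filter
#'   (`NULL` disables the filtered pass).
#' @param methods,grids Model suite, see [fit_suite()].
#' @param cv_folds,cv_repeats,collect_resamples Tuning design, see
#'   [fit_suite()].
#' @param seed Master seed.
#' @param outdir Optional directory: when set, [run_pipeline()] writes all
#'   report tables as CSV plus a provenance JSON there.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = generator_config(),
                            n_pairs = 123872, include_self = TRUE,
                            scheme = "reference-anchored",
                            feature_view = c("grm", "full"),
                            normalization_fit = c("full", "train"),
                            train_fraction = 0.75,
                            split_mode = c("case", "sample"),
                            filter_threshold = 0.4,
                            methods = suite_methods(),
                            grids = NULL,
                            cv_folds = 5, cv_repeats = 3,
                            collect_resamples = TRUE,
                            seed = 1, outdir = NULL) {
  feature_view <- match.arg(feature_view)
  normalization_fit <- match.arg(normalization_fit)
  split_mode <- match.arg(split_mode)
  if (!is.null(filter_threshold) && filter_threshold <= 0) {
    abort("filter_threshold must be positive (or NULL to disable)",
          class = "emma_config_error")
  }
  structure(list(
    input = input, n_pairs = n_pairs, include_self = include_self,
    scheme = scheme,
    feature_view = feature_view,
    normalization_fit = normalization_fit,
    train_fraction = train_fraction, split_mode = split_mode,
    filter_threshold = filter_threshold,
    methods = methods, grids = grids,
    cv_folds = cv_folds, cv_repeats = cv_repeats,
    collect_resamples = collect_resamples,
    seed = as.integer(seed), outdir = outdir
  ), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the whole chain: study input (read or simulate), stage
#' summaries, MA operators and the expected-value grid, pairwise
#' perturbation dataset, normalization and split, the model suite on the
#' unfiltered data, the residual outlier filter, and the suite again on
#' the filtered data -- mirroring the published two-pass design. The run
#' is idempotent: identical config and seeds give identical tables.
#'
#' @param config A [pipeline_config()].
#' @return A `emma_report` list: `samples`, `stage_summaries`, `ma`,
#'   `expected_grid`, `pairs` accounting, per-pass `results` tables,
#'   `importance`, `comparison` (when resamples were collected), and a
#'   `provenance` log with input/output row counts per stage.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  note <- function(stage, ...) {
    log[[stage]] <<- list(...)
  }

  if (inherits(config$input, "generator_config")) {
    study <- generate_study(config$input, seed = config$seed)
    samples <- study$samples
    note("input", source = "synthetic", n_samples = nrow(samples),
         n_animals = length(unique(samples$animal)), seed = config$seed)
  } else {
    samples <- add_carcass_yield(read_sample_table(config$input))
    note("input", source = as.character(config$input),
         n_samples = nrow(samples),
         n_animals = length(unique(samples$animal)))
  }

  stage_summaries <- dplyr::bind_rows(
    stage_summary(samples, "ghrelin"), stage_summary(samples, "ghr")
  )
  ma <- ma_tables(samples)
  expected_grid <- expected_value_grid(samples, "ghr")

  pairs <- build_pair_dataset(samples, n_pairs = config$n_pairs,
                              seed = config$seed, scheme = config$scheme,
                              include_self = config$include_self)
  note("pairs", n_cases = nrow(pairs), scheme = config$scheme,
       seed = config$seed)

  features <- pair_features(config$feature_view)
  grids <- config$grids %||% default_grids(length(features))

  run_pass <- function(cases, label) {
    if (config$normalization_fit == "full") {
      norm <- minmax_normalize(cases, cols = c(features, "target"))
      split <- split_dataset(norm$data, config$train_fraction,
                             seed = config$seed, mode = config$split_mode)
    } else {
      split_raw <- split_dataset(cases, config$train_fraction,
                                 seed = config$seed, mode = config$split_mode)
      norm <- minmax_normalize(split_raw$train, cols = c(features, "target"))
      split <- list(train = norm$data,
                    test = minmax_normalize(split_raw$test, norm$params)$data)
    }
    fits <- fit_suite(split$train, features, "target",
                      methods = config$methods, grids = grids,
                      seed = config$seed, cv_folds = config$cv_folds,
                      cv_repeats = config$cv_repeats,
                      collect_resamples = config$collect_resamples)
    evals <- purrr::map_dfr(fits, function(f) dplyr::bind_rows(
      evaluate(f, split$train, "train"), evaluate(f, split$test, "test")
    ))
    importance <- purrr::map_dfr(names(fits), function(m) {
      imp <- feature_importance(fits[[m]], seed = config$seed)
      imp$method <- m
      imp
    })
    comparison <- NULL
    cvs <- purrr::compact(purrr::map(fits, "cv"))
    if (length(cvs) >= 2) {
      comparison <- compare_models(purrr::map(cvs, "rmse"))
    }
    note(paste0("pass_", label), n_train = nrow(split$train),
         n_test = nrow(split$test))
    list(label = label, params = norm$params, split = split, fits = fits,
         evaluations = evals, results = render_results_table(evals, fits),
         importance = importance, comparison = comparison)
  }

  unfiltered <- run_pass(pairs, "unfiltered")
  filtered <- NULL
  filter_info <- NULL
  if (!is.null(config$filter_threshold)) {
    norm_all <- minmax_normalize(pairs, cols = c(features, "target"))
    grm <- fit_ols(norm_all$data, features, "target")
    flt <- pearson_residual_filter(norm_all$data, grm,
                                   threshold = config$filter_threshold)
    kept_raw <- minmax_denormalize(flt$kept, norm_all$params)
    filter_info <- list(
      threshold = config$filter_threshold,
      n_input = nrow(pairs), n_kept = nrow(flt$kept),
      n_removed = nrow(flt$removed),
      removed_fraction = flt$removed_fraction,
      grm = grm
    )
    note("filter", n_input = nrow(pairs), n_kept = nrow(flt$kept),
         n_removed = nrow(flt$removed),
         removed_fraction = round(flt$removed_fraction, 4))
    filtered <- run_pass(kept_raw, "filtered")
  }

  report <- structure(list(
    config = config,
    samples = samples,
    stage_summaries = stage_summaries,
    ma = ma,
    expected_grid = expected_grid,
    pairs_provenance = attr(pairs, "provenance"),
    unfiltered = unfiltered,
    filtered = filtered,
    filter = filter_info,
    provenance = log
  ), class = "emma_report")
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

#' Render the per-method results table
#'
#' One row per method in the published results-table layout: feature
#' count, model features, train/test RMSE and R^2, test R. The best model
#' maximizes test R^2, ties broken by lower test RMSE, then method name.
#'
#' @param evals Evaluation rows from [evaluate()] (train and test per
#'   method).
#' @param fits Optional named list of fits (to report selected features).
#' @return Tibble with one row per method and a logical `best` column.
#' @export
render_results_table <- function(evals, fits = NULL) {
  wide <- tidyr::pivot_wider(
    evals[, c("method", "subset", "rmse", "r_squared", "r")],
    names_from = "subset", values_from = c("rmse", "r_squared", "r")
  )
  out <- tibble::tibble(
    method = wide$method,
    n_features = NA_integer_,
    features = NA_character_,
    rmse_train = wide$rmse_train,
    r2_train = wide$r_squared_train,
    rmse_test = wide$rmse_test,
    r2_test = wide$r_squared_test,
    r_test = wide$r_test
  )
  if (!is.null(fits)) {
    sel <- purrr::map(fits, function(f) f$selected_features %||% f$features)
    out$n_features <- lengths(sel)[out$method]
    out$features <- vapply(sel, paste, character(1), collapse = "+")[out$method]
  }
  ranking <- order(-out$r2_test, out$rmse_test, out$method)
  out$best <- seq_len(nrow(out)) == ranking[1]
  out
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) readr::write_csv(x, file.path(outdir, name),
                                          progress = FALSE)
  write_sample_table(report$samples, file.path(outdir, "samples.csv"))
  w(report$stage_summaries, "stage_summaries.csv")
  w(report$expected_grid, "expected_value_grid.csv")
  ma_flat <- purrr::map_dfr(names(report$ma), function(g) {
    purrr::map_dfr(names(report$ma[[g]]), function(cc) {
      tab <- report$ma[[g]][[cc]]
      tibble::tibble(gene = g, condition_class = cc,
                     level = tab$level, mean = tab$mean, n = tab$n)
    })
  })
  w(ma_flat, "ma_tables.csv")
  for (pass in purrr::compact(list(report$unfiltered, report$filtered))) {
    w(pass$results, paste0("results_", pass$label, ".csv"))
    w(pass$importance, paste0("importance_", pass$label, ".csv"))
    if (!is.null(pass$comparison)) {
      w(pass$comparison$pairs, paste0("comparison_", pass$label, ".csv"))
    }
  }
  prov <- list(
    pairs = report$pairs_provenance,
    filter = report$provenance$filter,
    stages = report$provenance,
    package_version = as.character(utils::packageVersion("emmayield"))
  )
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' @method print emma_report
#' @export
print.emma_report <- function(x, ...) {
  cat("<emma_report>\n")
  cat("  samples:", nrow(x$samples), "from",
      length(unique(x$samples$animal)), "animals\n")
  cat("  pairs:", x$pairs_provenance$n_cases, "\n")
  if (!is.null(x$filter)) {
    cat(sprintf("  filter: kept %d / removed %d (%.1f%%)\n",
                x$filter$n_kept, x$filter$n_removed,
                100 * x$filter$removed_fraction))
  }
  for (pass in purrr::compact(list(x$unfiltered, x$filtered))) {
    cat("  --", pass$label, "pass --\n")
    print(pass$results[, c("method", "rmse_train", "r2_train",
                           "rmse_test", "r2_test", "best")])
  }
  invisible(x)
}
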