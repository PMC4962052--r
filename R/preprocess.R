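#' Min-max normalization
#'
#' Maps each feature (and the target) to `[0, 1]` by
#' `(x - min) / (max - min)`. Parameters may be fitted on the data at hand
#' or supplied (e.g. train-fitted parameters applied to a test set, where
#' values can legitimately fall outside `[0, 1]`). Constant columns are
#' rejected by name.
#'
#' @param data A data frame of cases.
#' @param params Optional parameter tibble from a previous call; when
#'   `NULL`, parameters are fitted on `data`'s `cols`.
#' @param cols Columns to normalize; default every numeric column except
#'   identifiers.
#' @return List with `data` (normalized tibble) and `params` (tibble with
#'   columns `feature`, `min`, `max`).
#' @export
minmax_normalize <- function(data, params = NULL, cols = NULL) {
  data <- tibble::as_tibble(data)
  if (is.null(cols)) {
    cols <- names(data)[vapply(data, is.numeric, logical(1))]
    cols <- setdiff(cols, c("query_id", "ref_id"))
  }
  if (is.null(params)) {
    mins <- vapply(data[cols], min, numeric(1))
    maxs <- vapply(data[cols], max, numeric(1))
    constant <- cols[maxs <= mins]
    if (length(constant) > 0) {
      abort(paste0("cannot min-max normalize constant column(s): ",
                   paste(constant, collapse = ", ")),
            class = "emma_normalization_error")
    }
    params <- tibble::tibble(feature = cols, min = mins, max = maxs)
  } else {
    missing_cols <- setdiff(params$feature, names(data))
    if (length(missing_cols) > 0) {
      abort(paste0("normalization params reference absent column(s): ",
                   paste(missing_cols, collapse = ", ")),
            class = "emma_schema_error")
    }
  }
  for (i in seq_len(nrow(params))) {
    f <- params$feature[i]
    data[[f]] <- (data[[f]] - params$min[i]) / (params$max[i] - params$min[i])
  }
  list(data = data, params = params)
}

#' @rdname minmax_normalize
#' @details `minmax_denormalize()` inverts the transform with the same
#'   parameters (identity to floating-point precision).
#' @export
minmax_denormalize <- function(data, params) {
  data <- tibble::as_tibble(data)
  for (i in seq_len(nrow(params))) {
    f <- params$feature[i]
    data[[f]] <- data[[f]] * (params$max[i] - params$min[i]) + params$min[i]
  }
  data
}

#' Train/test split of a pair dataset
#'
#' Deterministic 75/25 (by default) split. Cases are canonically ordered
#' by `(query_id, ref_id)` when those columns are present, so permuting
#' the input rows does not change membership under the same seed.
#' `mode = "sample"` holds out whole *samples*: a fraction of sample ids
#' is held out and every case whose query or reference touches a held-out
#' sample goes to test, so no held-out sample ever appears in a train
#' case (pairs sharing samples otherwise leak across a case-level split).
#'
#' @param data Tibble of cases.
#' @param train_fraction Fraction in (0, 1), default 0.75.
#' @param seed Integer seed.
#' @param mode `"case"` (default) or `"sample"`.
#' @return List with tibbles `train` and `test`.
#' @export
split_dataset <- function(data, train_fraction = 0.75, seed = 1,
                          mode = c("case", "sample")) {
  mode <- match.arg(mode)
  data <- tibble::as_tibble(data)
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must lie strictly between 0 and 1",
          class = "emma_config_error")
  }
  n <- nrow(data)
  if (n < 4) {
    abort("need at least 4 cases to split", class = "emma_config_error")
  }
  if (all(c("query_id", "ref_id") %in% names(data))) {
    data <- dplyr::arrange(data, .data$query_id, .data$ref_id)
  }
  if (mode == "case") {
    n_train <- round(train_fraction * n)
    train_idx <- withr::with_seed(as.integer(seed),
                                  sort(sample.int(n, n_train)))
    in_train <- logical(n)
    in_train[train_idx] <- TRUE
  } else {
    ids <- sort(unique(c(data$query_id, data$ref_id)))
    n_hold <- max(1L, round((1 - train_fraction) * length(ids)))
    held <- withr::with_seed(as.integer(seed),
                             sort(sample(ids, n_hold)))
    in_train <- !(data$query_id %in% held | data$ref_id %in% held)
  }
  list(train = data[in_train, ], test = data[!in_train, ])
}

#' Residual-based outlier filter
#'
#' Removes cases whose absolute residual against a fitted linear model
#' exceeds `threshold` on the (normalized) target scale -- by design twice
#' the maximum residual of the majority of the data (0.2), hence the 0.4
#' default. For a Gaussian linear model the Pearson residual is the raw
#' residual.
#'
#' @param data Tibble of cases including the model's features and target.
#' @param fit A fitted model from [fit_ols()] or [fit_suite()].
#' @param threshold Positive residual cutoff (default 0.4).
#' @return List with `kept`, `removed` (tibbles partitioning `data`) and
#'   `removed_fraction`.
#' @export
pearson_residual_filter <- function(data, fit, threshold = 0.4) {
  if (!is.numeric(threshold) || threshold <= 0) {
    abort("threshold must be a positive number", class = "emma_config_error")
  }
  data <- tibble::as_tibble(data)
  resid <- data[[fit$target]] - predict(fit, data)
  out <- abs(resid) > threshold
  list(
    kept = data[!out, ],
    removed = data[out, ],
    removed_fraction = mean(out)
  )
}
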