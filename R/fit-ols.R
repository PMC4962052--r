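new_emma_fit <- function(method, subclass, model, features, target,
                         coefficients = NULL, hyperparameters = list(),
                         inference = NULL, seed = NA_integer_,
                         train_data = NULL, cv = NULL) {
  structure(list(
    method = method,
    model = model,
    features = features,
    target = target,
    coefficients = coefficients,
    hyperparameters = hyperparameters,
    inference = inference,
    seed = seed,
    train_data = train_data,
    cv = cv
  ), class = c(subclass, "emma_fit"))
}

#' Ordinary least squares with full inference
#'
#' Closed-form multilinear regression of the target on the perturbation
#' features -- the surface of the published general multilinear model --
#' reporting the coefficient table and the global statistics: R, R^2,
#' residual sum of squares, regression degrees of freedom, and the overall
#' F test.
#'
#' @param data Tibble of cases (e.g. a normalized pair dataset).
#' @param features Feature column names; default [pair_features()]'s
#'   five-feature view.
#' @param target Target column name.
#' @return An `emma_ols` fit. `tidy()` gives the coefficient table,
#'   `glance()` the model statistics; `predict()` accepts new data.
#' @export
fit_ols <- function(data, features = pair_features("grm"), target = "target") {
  data <- tibble::as_tibble(data)
  check_feature_schema(data, features, target)
  n <- nrow(data)
  p <- length(features)
  if (n <= p + 1) {
    abort("need more cases than coefficients", class = "emma_design_error")
  }
  X <- stats::model.matrix(reformulate(features), data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("design is rank deficient; collinear feature(s): ",
                 paste(dropped, collapse = ", ")),
          class = "emma_rank_error")
  }
  model <- lm(reformulate(features, target), data = data)
  # exact (zero-residual) fits are legitimate degenerate inputs here
  sm <- suppressWarnings(summary(model))
  ss_res <- sum(stats::residuals(model)^2)
  r2 <- sm$r.squared
  fstat <- sm$fstatistic
  inference <- list(
    n = n,
    r = sqrt(max(r2, 0)),
    r_squared = r2,
    ss_residual = ss_res,
    df_model = unname(fstat[2]),
    df_residual = unname(fstat[3]),
    f_statistic = unname(fstat[1]),
    p_value = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  )
  new_emma_fit("lm", "emma_ols", model, features, target,
               coefficients = coef(model),
               inference = inference, train_data = data)
}

check_feature_schema <- function(data, features, target) {
  missing_cols <- setdiff(c(features, target), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("data is missing model column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "emma_schema_error")
  }
  invisible(TRUE)
}

#' Stepwise feature selection around OLS
#'
#' Greedy bidirectional (or forward/backward) search over the candidate
#' features by information criterion, starting from the intercept-only
#' model for forward/both and from the full model for backward; the
#' returned fit is [fit_ols()] on the selected set (intercept-only when
#' nothing survives).
#'
#' @param data Tibble of cases.
#' @param features Candidate feature columns.
#' @param target Target column.
#' @param direction `"both"`, `"forward"` or `"backward"`.
#' @param criterion `"AIC"` or `"BIC"`.
#' @return An `emma_ols` fit with `method = "glm"` and the selected
#'   features.
#' @export
stepwise_select <- function(data, features = pair_features("grm"),
                            target = "target",
                            direction = c("both", "forward", "backward"),
                            criterion = c("AIC", "BIC")) {
  direction <- match.arg(direction)
  criterion <- match.arg(criterion)
  data <- tibble::as_tibble(data)
  check_feature_schema(data, features, target)
  k <- if (criterion == "AIC") 2 else log(nrow(data))
  full <- reformulate(features, target)
  start <- if (direction == "backward") {
    lm(full, data = data)
  } else {
    lm(reformulate("1", target), data = data)
  }
  selected_model <- suppressWarnings(stats::step(
    start, scope = list(lower = reformulate("1", target), upper = full),
    direction = direction, k = k, trace = 0
  ))
  selected <- attr(stats::terms(selected_model), "term.labels")
  fit <- if (length(selected) == 0) {
    intercept_only_fit(data, target)
  } else {
    fit_ols(data, selected, target)
  }
  fit$method <- "glm"
  fit$hyperparameters <- list(direction = direction, criterion = criterion)
  fit
}

intercept_only_fit <- function(data, target) {
  model <- lm(reformulate("1", target), data = data)
  inference <- list(
    n = nrow(data), r = 0, r_squared = 0,
    ss_residual = sum(stats::residuals(model)^2),
    df_model = 0, df_residual = nrow(data) - 1,
    f_statistic = NA_real_, p_value = NA_real_
  )
  new_emma_fit("lm", "emma_ols", model, character(0), target,
               coefficients = coef(model), inference = inference,
               train_data = data)
}

#' @export
predict.emma_ols <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(unname(stats::fitted(object$model)))
  unname(predict(object$model, newdata = tibble::as_tibble(newdata)))
}

#' @method print emma_fit
#' @export
print.emma_fit <- function(x, ...) {
  cat("<emma_fit>", x$method, "\n")
  cat("  features:", if (length(x$features)) paste(x$features, collapse = ", ")
      else "(intercept only)", "\n")
  if (!is.null(x$inference)) {
    cat(sprintf("  N = %d, R = %.3f, R^2 = %.3f, SS residual = %.3f, df = %d, F = %.3f\n",
                x$inference$n, x$inference$r, x$inference$r_squared,
                x$inference$ss_residual, round(x$inference$df_model),
                x$inference$f_statistic))
  }
  invisible(x)
}

#' Tidy an OLS fit
#'
#' @param x An `emma_ols` fit.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
tidy.emma_ols <- function(x, ...) {
  sm <- suppressWarnings(summary(x$model))$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = unname(sm[, 1]), std.error = unname(sm[, 2]),
    statistic = unname(sm[, 3]), p.value = unname(sm[, 4])
  )
}

#' Model-level statistics of an OLS fit
#'
#' @param x An `emma_ols` fit.
#' @param ... Unused.
#' @return One-row tibble: `r`, `r.squared`, `ss.residual`, `df`,
#'   `statistic` (overall F), `p.value`, `nobs`.
#' @export
glance.emma_ols <- function(x, ...) {
  inf <- x$inference
  tibble::tibble(
    r = inf$r, r.squared = inf$r_squared, ss.residual = inf$ss_residual,
    df = inf$df_model, statistic = inf$f_statistic,
    p.value = unname(inf$p_value), nobs = inf$n
  )
}
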