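suite_methods <- function() c("lm", "glm", "pls", "lasso", "enet", "nn", "rf")

#' Default hyperparameter grids for the regression suite
#'
#' Grids follow the published sweeps: the neural network over
#' `size` in {1, 5, 10, 15, 20, 50} and `decay` in {0, 0.1, 0.001} (a
#' second published sweep used decays 0/0.0001/0.001/0.005 -- pass it via
#' `nn_decay` if wanted), and the random forest over `ntree` in {1, 5, 10}
#' with `mtry` 1..p.
#'
#' @param n_features Number of model features (bounds `mtry` and the PLS
#'   component count).
#' @param nn_decay Weight-decay values for the neural network grid.
#' @return Named list of grid tibbles, one per method.
#' @export
default_grids <- function(n_features = 5,
                          nn_decay = c(0, 0.1, 0.001)) {
  list(
    lm = tibble::tibble(.rows = 1),
    glm = tibble::tibble(direction = "both", criterion = "AIC"),
    pls = tibble::tibble(ncomp = seq_len(min(5, n_features))),
    lasso = tidyr::expand_grid(alpha = 1, lambda = 10^seq(-5, -1, length.out = 10)),
    enet = tidyr::expand_grid(alpha = c(0.25, 0.5, 0.75),
                              lambda = 10^seq(-5, -1, length.out = 5)),
    nn = tidyr::expand_grid(size = c(1, 5, 10, 15, 20, 50), decay = nn_decay),
    rf = tidyr::expand_grid(ntree = c(1, 5, 10), mtry = seq_len(min(5, n_features)))
  )
}

feature_matrix <- function(data, features) {
  m <- as.matrix(data[, features, drop = FALSE])
  rownames(m) <- seq_len(nrow(m))  # mixOmics insists on row identifiers
  m
}

fit_learner <- function(method, data, features, target, hyper, seed) {
  x <- feature_matrix(data, features)
  y <- data[[target]]
  withr::with_seed(seed, switch(
    method,
    lm = fit_ols(data, features, target),
    glm = stepwise_select(data, features, target,
                          direction = hyper$direction %||% "both",
                          criterion = hyper$criterion %||% "AIC"),
    pls = mixOmics::pls(x, y, ncomp = hyper$ncomp, mode = "regression"),
    lasso = glmnet::glmnet(x, y, alpha = 1),
    enet = glmnet::glmnet(x, y, alpha = hyper$alpha),
    nn = nnet::nnet(x, y, size = hyper$size, decay = hyper$decay,
                    linout = TRUE, maxit = 500, trace = FALSE,
                    MaxNWts = 5000),
    rf = randomForest::randomForest(x, y, ntree = hyper$ntree,
                                    mtry = hyper$mtry, importance = TRUE),
    abort(paste0("unknown regression method: ", method),
          class = "emma_config_error")
  ))
}

predict_learner <- function(method, model, data, features, hyper) {
  x <- feature_matrix(data, features)
  switch(
    method,
    lm = ,
    glm = predict(model, tibble::as_tibble(data)),
    pls = as.numeric(predict(model, x)$predict[, 1, hyper$ncomp]),
    lasso = ,
    enet = as.numeric(predict(model, newx = x, s = hyper$lambda)),
    nn = as.numeric(predict(model, x)),
    rf = unname(predict(model, x))
  )
}

#' Tune and fit the regression suite
#'
#' Fits any subset of the seven-method suite (multiple linear regression,
#' stepwise-selected linear model, partial least squares, Lasso, elastic
#' net, single-hidden-layer neural network, random forest). Methods with
#' more than one grid row are tuned by repeated k-fold cross-validation
#' minimizing RMSE over a fold assignment shared across methods and grid
#' rows; the winning configuration is refit on the full training set.
#' Every random step is seeded, so refitting is bit-reproducible.
#'
#' @param train Training cases (normalized pair dataset).
#' @param features Feature columns; default the five-feature view.
#' @param target Target column.
#' @param methods Methods to fit, a subset of
#'   `c("lm","glm","pls","lasso","enet","nn","rf")`.
#' @param grids Named list of grid tibbles, see [default_grids()].
#' @param seed Integer master seed.
#' @param cv_folds,cv_repeats Cross-validation design for tuning and for
#'   the resampled RMSEs consumed by [compare_models()].
#' @param collect_resamples Keep per-resample RMSEs for the chosen
#'   configuration even when the grid has a single row (needed for model
#'   comparison); set `FALSE` to skip cross-validation entirely for
#'   single-row grids.
#' @return Named list of `emma_fit` objects (class `emma_suite`), each
#'   carrying its hyperparameters and cross-validation resamples.
#' @export
fit_suite <- function(train, features = pair_features("grm"),
                      target = "target", methods = suite_methods(),
                      grids = default_grids(length(features)),
                      seed = 1, cv_folds = 5, cv_repeats = 3,
                      collect_resamples = TRUE) {
  train <- tibble::as_tibble(train)
  check_feature_schema(train, features, target)
  unknown <- setdiff(methods, suite_methods())
  if (length(unknown) > 0) {
    abort(paste0("unknown regression method(s): ",
                 paste(unknown, collapse = ", ")),
          class = "emma_config_error")
  }
  seed <- as.integer(seed)
  n <- nrow(train)
  folds <- withr::with_seed(seed, {
    purrr::map(seq_len(cv_repeats), function(r) {
      sample(rep_len(seq_len(cv_folds), n))
    })
  })

  fits <- purrr::map(setNames(methods, methods), function(method) {
    grid <- grids[[method]]
    if (is.null(grid) || nrow(grid) == 0) grid <- tibble::tibble(.rows = 1)
    method_seed <- seed + 1000L * match(method, suite_methods())
    needs_cv <- nrow(grid) > 1 || collect_resamples
    cv_tab <- NULL
    best_row <- 1L
    if (needs_cv) {
      # per-(repeat, fold) RMSE of every grid row; fold grain doubles as the
      # resample vector for compare_models()
      fold_scores <- purrr::map(seq_len(nrow(grid)), function(i) {
        hyper <- as.list(grid[i, , drop = FALSE])
        unlist(purrr::map(seq_along(folds), function(r) {
          f <- folds[[r]]
          purrr::map_dbl(seq_len(cv_folds), function(k) {
            hold <- f == k
            m <- fit_learner(method, train[!hold, ], features, target,
                             hyper, method_seed + 31L * r + k)
            pred <- predict_learner(method, m, train[hold, ], features, hyper)
            sqrt(mean((train[[target]][hold] - pred)^2))
          })
        }))
      })
      mean_rmse <- vapply(fold_scores, mean, numeric(1))
      best_row <- which.min(mean_rmse)
      cv_tab <- tibble::tibble(
        resample = paste0("rep", rep(seq_len(cv_repeats), each = cv_folds),
                          "_fold", rep(seq_len(cv_folds), cv_repeats)),
        rmse = fold_scores[[best_row]]
      )
    }
    hyper <- as.list(grid[best_row, , drop = FALSE])
    model <- fit_learner(method, train, features, target, hyper, method_seed)
    fit <- wrap_fit(method, model, train, features, target, hyper, method_seed)
    fit$cv <- cv_tab
    fit
  })
  class(fits) <- c("emma_suite", "list")
  fits
}

wrap_fit <- function(method, model, train, features, target, hyper, seed) {
  hyper <- hyper[setdiff(names(hyper), ".rows")]
  if (method %in% c("lm", "glm")) {
    fit <- model  # already an emma_fit
    fit$seed <- seed
    fit$hyperparameters <- utils::modifyList(fit$hyperparameters %||% list(), hyper)
    return(fit)
  }
  subclass <- paste0("emma_", method)
  selected <- features
  coefs <- NULL
  if (method %in% c("lasso", "enet")) {
    b <- as.matrix(coef(model, s = hyper$lambda))
    coefs <- setNames(b[, 1], rownames(b))
    selected <- names(coefs)[-1][coefs[-1] != 0]
  } else if (method == "pls") {
    coefs <- pls_coefficients(model, train, features, target, hyper)
  }
  fit <- new_emma_fit(method, subclass, model, features, target,
                      coefficients = coefs,
                      hyperparameters = hyper, seed = seed, train_data = train)
  fit$selected_features <- selected
  fit
}

# PLS prediction is linear in X: recover intercept + slopes by probing
pls_coefficients <- function(model, train, features, target, hyper) {
  x0 <- colMeans(feature_matrix(train, features))
  probe <- rbind(x0, sweep(diag(length(features)), 2, x0, "+"))
  colnames(probe) <- features
  rownames(probe) <- seq_len(nrow(probe))
  pred <- as.numeric(predict(model, probe)$predict[, 1, hyper$ncomp])
  slopes <- pred[-1] - pred[1]
  intercept <- pred[1] - sum(slopes * x0)
  setNames(c(intercept, slopes), c("(Intercept)", features))
}

#' @export
predict.emma_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$train_data
  predict_learner(object$method, object$model, tibble::as_tibble(newdata),
                  object$features, object$hyperparameters)
}

#' Evaluate a fitted model on a subset
#'
#' Root-mean-square error, coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot`, and the reporting companion
#' `R = sqrt(max(R^2, 0))`.
#'
#' @param fit An `emma_fit`.
#' @param data Cases to score.
#' @param subset Label for the output row (`"train"` / `"test"`).
#' @return One-row tibble: `method`, `subset`, `n`, `rmse`, `r_squared`,
#'   `r`.
#' @export
evaluate <- function(fit, data, subset = "test") {
  data <- tibble::as_tibble(data)
  check_feature_schema(data, fit$features, fit$target)
  obs <- data[[fit$target]]
  pred <- predict(fit, data)
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  r2 <- 1 - ss_res / ss_tot
  tibble::tibble(
    method = fit$method, subset = subset, n = nrow(data),
    rmse = sqrt(mean((obs - pred)^2)),
    r_squared = r2, r = sqrt(max(r2, 0))
  )
}

#' Feature importance on the varImp scale
#'
#' Linear fits score features by the absolute standardized coefficient;
#' random forests by permutation (out-of-bag increase in MSE, as fitted);
#' neural networks (and any other black box) by permutation increase in
#' RMSE on the training data. Scores are rescaled so the top feature is
#' 100.
#'
#' @param fit An `emma_fit`.
#' @param data Data for permutation scoring (default the training data).
#' @param seed Seed for the permutations.
#' @return Tibble `feature`, `importance`, sorted decreasing.
#' @export
feature_importance <- function(fit, data = NULL, seed = 1) {
  data <- tibble::as_tibble(data %||% fit$train_data)
  features <- fit$features
  if (!is.null(fit$coefficients)) {
    sds <- vapply(data[features], sd, numeric(1))
    b <- fit$coefficients[features]
    b[is.na(b)] <- 0
    score <- abs(b) * sds
  } else if (fit$method == "rf") {
    imp <- randomForest::importance(fit$model, type = 1, scale = FALSE)
    score <- setNames(pmax(imp[, 1], 0), rownames(imp))[features]
  } else {
    obs <- data[[fit$target]]
    base <- sqrt(mean((obs - predict(fit, data))^2))
    score <- withr::with_seed(as.integer(seed), vapply(features, function(f) {
      perm <- data
      perm[[f]] <- sample(perm[[f]])
      max(sqrt(mean((obs - predict(fit, perm))^2)) - base, 0)
    }, numeric(1)))
  }
  top <- max(score)
  importance <- if (top > 0) 100 * score / top else score * 0
  out <- tibble::tibble(feature = features, importance = unname(importance))
  dplyr::arrange(out, dplyr::desc(.data$importance))
}

#' Pairwise model comparison with Bonferroni correction
#'
#' Paired two-sided Student's t-tests on per-resample RMSE differences for
#' every model pair, with the p-values Bonferroni-multiplied by the number
#' of pairs, plus per-model mean performance with t-based confidence
#' limits at the Bonferroni-adjusted level. A pair with zero difference
#' variance is flagged degenerate: p = 0 when the means differ, p = 1 when
#' the vectors are identical.
#'
#' @param resamples Named list of equal-length numeric vectors (one per
#'   model, e.g. the `cv$rmse` of each [fit_suite()] fit), or a tibble
#'   with columns `method` and `rmse`.
#' @param conf_level Base confidence level (default 0.95).
#' @return List of class `emma_comparison` with tibbles `means`
#'   (`method`, `mean`, `lower`, `upper`, `n`) and `pairs` (`model_a`,
#'   `model_b`, `mean_difference`, `statistic`, `p.value`,
#'   `p.adjusted`, `degenerate`).
#' @export
compare_models <- function(resamples, conf_level = 0.95) {
  if (is.data.frame(resamples)) {
    resamples <- split(resamples$rmse, resamples$method)
  }
  if (length(resamples) < 2) {
    abort("need at least two models to compare", class = "emma_config_error")
  }
  len <- lengths(resamples)
  if (length(unique(len)) != 1) {
    abort("models must have equal numbers of paired resamples",
          class = "emma_config_error")
  }
  methods <- names(resamples)
  combs <- utils::combn(methods, 2)
  n_pairs <- ncol(combs)
  alpha <- (1 - conf_level) / n_pairs

  pairs <- purrr::map_dfr(seq_len(n_pairs), function(i) {
    a <- resamples[[combs[1, i]]]
    b <- resamples[[combs[2, i]]]
    d <- a - b
    if (sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
      tibble::tibble(model_a = combs[1, i], model_b = combs[2, i],
                     mean_difference = mean(d), statistic = NA_real_,
                     p.value = as.numeric(mean(d) == 0),
                     p.adjusted = as.numeric(mean(d) == 0),
                     degenerate = TRUE)
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
      tibble::tibble(model_a = combs[1, i], model_b = combs[2, i],
                     mean_difference = unname(tt$estimate),
                     statistic = unname(tt$statistic),
                     p.value = tt$p.value,
                     p.adjusted = min(1, tt$p.value * n_pairs),
                     degenerate = FALSE)
    }
  })
  means <- purrr::map_dfr(methods, function(m) {
    v <- resamples[[m]]
    se <- sd(v) / sqrt(length(v))
    q <- qt(1 - alpha / 2, df = length(v) - 1)
    tibble::tibble(method = m, mean = mean(v),
                   lower = mean(v) - q * se, upper = mean(v) + q * se,
                   n = length(v))
  })
  structure(list(means = means, pairs = pairs,
                 conf_level = conf_level, n_pairs = n_pairs),
            class = "emma_comparison")
}

#' @method print emma_comparison
#' @export
print.emma_comparison <- function(x, ...) {
  cat("<emma_comparison>", nrow(x$means), "models,", x$n_pairs, "pairs\n")
  print(x$means)
  invisible(x)
}
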