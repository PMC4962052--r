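random_regression_data <- function(n, p, seed, noise = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    beta <- rnorm(p + 1)
    y <- beta[1] + X %*% beta[-1] + rnorm(n, 0, noise)
    d <- tibble::as_tibble(as.data.frame(X))
    names(d) <- paste0("x", seq_len(p))
    d$target <- drop(y)
    d
  })
}

test_that("OLS matches the normal-equations oracle on random instances", {
  for (seed in 1:30) {
    n <- sample(20:200, 1)
    p <- sample(2:6, 1)
    d <- random_regression_data(n, p, seed = 400 + seed)
    feats <- paste0("x", seq_len(p))
    fit <- fit_ols(d, feats, "target")
    oracle <- bf_ols(as.matrix(d[feats]), d$target)
    expect_equal(unname(fit$coefficients), unname(oracle$coef),
                 tolerance = 1e-8)
    expect_equal(fit$inference$r_squared, oracle$r_squared, tolerance = 1e-8)
    expect_equal(fit$inference$ss_residual, oracle$ss_residual,
                 tolerance = 1e-8)
    expect_equal(fit$inference$f_statistic, oracle$f_statistic,
                 tolerance = 1e-8)
    expect_equal(tidy(fit)$std.error, unname(oracle$se), tolerance = 1e-8)
    expect_equal(unname(fit$inference$p_value), oracle$p_value,
                 tolerance = 1e-8)
  }
})

test_that("OLS handles exact fits and rejects rank deficiency", {
  d <- tibble::tibble(x = 1:10, target = 2 * (1:10))
  fit <- fit_ols(d, "x", "target")
  expect_equal(unname(fit$coefficients), c(0, 2), tolerance = 1e-10)
  expect_equal(fit$inference$r_squared, 1, tolerance = 1e-12)
  expect_lt(fit$inference$ss_residual, 1e-16)

  d$x2 <- 2 * d$x
  expect_error(fit_ols(d, c("x", "x2"), "target"), "x2",
               class = "emma_rank_error")
})

test_that("null-model slopes stay within three standard errors of zero", {
  hits <- vapply(1:40, function(s) {
    d <- random_regression_data(200, 1, seed = 900 + s)
    d$target <- withr::with_seed(1700 + s, rnorm(200))
    td <- tidy(fit_ols(d, "x1", "target"))
    abs(td$estimate[2]) <= 3 * td$std.error[2]
  }, logical(1))
  expect_gte(sum(hits), 38)
})

test_that("evaluation matches hand arithmetic and the fit's own R^2", {
  d <- tibble::tibble(x = c(1, 2, 3, 4), target = c(1, 3, 2, 6))
  fit <- fit_ols(d, "x", "target")
  ev_tr <- evaluate(fit, d, "train")
  expect_equal(ev_tr$r_squared, fit$inference$r_squared, tolerance = 1e-12)

  newd <- tibble::tibble(x = c(0, 10), target = c(1, 2))
  pred <- predict(fit, newd)
  ev <- evaluate(fit, newd)
  expect_equal(ev$rmse, sqrt(mean((newd$target - pred)^2)), tolerance = 1e-12)
  ss_res <- sum((newd$target - pred)^2)
  ss_tot <- sum((newd$target - mean(newd$target))^2)
  expect_equal(ev$r_squared, 1 - ss_res / ss_tot, tolerance = 1e-12)

  # perfect and mean-constant predictors
  exact <- fit_ols(tibble::tibble(x = 1:5, target = 2 + 3 * (1:5)), "x", "target")
  ev2 <- evaluate(exact, tibble::tibble(x = 6:8, target = 2 + 3 * (6:8)))
  expect_equal(ev2$rmse, 0, tolerance = 1e-9)
  expect_equal(ev2$r_squared, 1, tolerance = 1e-9)
})

test_that("stepwise selection finds planted signals and prunes noise", {
  # exact linear dependence on 2 of 5 features, no noise
  d <- random_regression_data(100, 5, seed = 77, noise = 1)
  d$target <- 1 + 2 * d$x2 - 3 * d$x4
  fit <- stepwise_select(d, paste0("x", 1:5), "target")
  expect_setequal(fit$features, c("x2", "x4"))

  # pure noise with a strong penalty collapses to the intercept
  d2 <- random_regression_data(60, 4, seed = 78)
  d2$target <- withr::with_seed(79, rnorm(60))
  fit2 <- stepwise_select(d2, paste0("x", 1:4), "target", criterion = "BIC")
  expect_length(fit2$features, 0)
  expect_equal(predict(fit2, d2), rep(mean(d2$target), 60), tolerance = 1e-9)

  # one predictive + noise features: signal kept, noise mostly dropped
  picked_noise <- vapply(1:10, function(s) {
    d3 <- random_regression_data(500, 5, seed = 200 + s)
    d3$target <- 2 * d3$x1 + withr::with_seed(300 + s, rnorm(500, 0, 0.5))
    f <- stepwise_select(d3, paste0("x", 1:5), "target", criterion = "BIC")
    expect_true("x1" %in% f$features)
    length(setdiff(f$features, "x1"))
  }, numeric(1))
  expect_lt(mean(picked_noise > 0), 0.5)
})

test_that("the suite recovers a noiseless linear truth (random forest aside)", {
  d <- random_regression_data(300, 3, seed = 55, noise = 0)
  # normalize to [0,1] so every learner sees its usual scale
  d <- minmax_normalize(d)$data
  grids <- default_grids(3)
  grids$nn <- tidyr::expand_grid(size = 5, decay = 0)
  grids$rf <- tidyr::expand_grid(ntree = 5, mtry = 2)
  fits <- fit_suite(d, paste0("x", 1:3), "target",
                    methods = c("lm", "glm", "pls", "lasso", "enet", "rf"),
                    grids = grids, seed = 2, cv_folds = 3, cv_repeats = 1,
                    collect_resamples = FALSE)
  for (m in c("lm", "glm", "pls")) {
    ev <- evaluate(fits[[m]], d, "train")
    expect_lt(ev$rmse, 1e-3)
  }
  for (m in c("lasso", "enet")) {
    # the penalty leaves a small bias even at the lightest grid value
    ev <- evaluate(fits[[m]], d, "train")
    expect_lt(ev$rmse, 1e-2)
  }
  # trees cannot extrapolate a continuous plane exactly
  expect_gt(evaluate(fits$rf, d, "train")$rmse, 1e-3)
})

test_that("suite fits are bit-reproducible under a fixed seed", {
  d <- random_regression_data(200, 4, seed = 60)
  d <- minmax_normalize(d)$data
  grids <- list(nn = tidyr::expand_grid(size = c(3, 5), decay = c(0, 0.01)),
                rf = tidyr::expand_grid(ntree = 5, mtry = c(1, 2)))
  run <- function() {
    fits <- fit_suite(d, paste0("x", 1:4), "target", methods = c("nn", "rf"),
                      grids = grids, seed = 9, cv_folds = 3, cv_repeats = 1)
    lapply(fits, function(f) predict(f, d))
  }
  expect_identical(run(), run())
})

test_that("heavy Lasso penalties collapse to the dominant feature", {
  withr::with_seed(123, {
    n <- 400
    d <- tibble::tibble(y_exp = runif(n))
    d$x2 <- rnorm(n, 0, 0.05)
    d$x3 <- rnorm(n, 0, 0.05)
    d$target <- d$y_exp + rnorm(n, 0, 0.05)
  })
  grids <- list(lasso = tidyr::expand_grid(alpha = 1, lambda = 0.05))
  fits <- fit_suite(d, c("y_exp", "x2", "x3"), "target", methods = "lasso",
                    grids = grids, seed = 4, collect_resamples = FALSE)
  expect_equal(fits$lasso$selected_features, "y_exp")
})

test_that("importance ranks planted signals and ignores irrelevant features", {
  withr::with_seed(321, {
    n <- 500
    d <- tibble::tibble(strong = runif(n), weak = runif(n), junk = runif(n))
    d$target <- 2 * d$strong + 0.2 * d$weak + rnorm(n, 0, 0.1)
  })
  fit <- fit_ols(d, c("strong", "weak", "junk"), "target")
  imp <- feature_importance(fit)
  expect_equal(imp$feature[1], "strong")
  expect_equal(imp$importance[1], 100)
  expect_lt(imp$importance[imp$feature == "junk"], 5)

  # permutation path (neural network) agrees on the ranking
  grids <- list(nn = tidyr::expand_grid(size = 4, decay = 0.001))
  nn <- fit_suite(d, c("strong", "weak", "junk"), "target", methods = "nn",
                  grids = grids, seed = 10, collect_resamples = FALSE)$nn
  imp_nn <- feature_importance(nn, seed = 2)
  expect_equal(imp_nn$feature[1], "strong")
  expect_lt(imp_nn$importance[imp_nn$feature == "junk"], 5)

  single <- fit_ols(d, "strong", "target")
  imp1 <- feature_importance(single)
  expect_equal(imp1$importance, 100)
})

test_that("model comparison applies paired t-tests with Bonferroni scaling", {
  a <- c(0.10, 0.11, 0.12, 0.10, 0.11)
  cmp_same <- compare_models(list(m1 = a, m2 = a))
  expect_equal(cmp_same$pairs$p.value, 1)
  expect_equal(cmp_same$pairs$mean_difference, 0)
  expect_true(cmp_same$pairs$degenerate)

  cmp_shift <- compare_models(list(m1 = a, m2 = a + 0.05))
  expect_equal(cmp_shift$pairs$p.value, 0)
  expect_true(cmp_shift$pairs$degenerate)

  b <- a + c(0.02, 0.01, 0.03, 0.015, 0.02)
  c3 <- list(m1 = a, m2 = b, m3 = a * 1.5)
  cmp <- compare_models(c3)
  expect_equal(nrow(cmp$pairs), 3)
  raw <- stats::t.test(a, b, paired = TRUE)$p.value
  got <- cmp$pairs[cmp$pairs$model_a == "m1" & cmp$pairs$model_b == "m2", ]
  expect_equal(got$p.adjusted, min(1, 3 * raw), tolerance = 1e-12)
  expect_equal(cmp$means$n, rep(5L, 3))

  expect_error(compare_models(list(m1 = a)), class = "emma_config_error")
  expect_error(compare_models(list(m1 = a, m2 = a[1:3])),
               class = "emma_config_error")
})
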