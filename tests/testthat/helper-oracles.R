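# Independent brute-force oracles used across tests. These deliberately
# avoid the package's vectorized code paths: plain loops and normal
# equations only.

# small random sample table over a subset of the design
toy_sample_table <- function(n, seed = 1, with_yield = TRUE) {
  withr::with_seed(seed, {
    cells <- rbind(
      expand.grid(day = c(0L, 7L, 14L), system = "L",
                  stringsAsFactors = FALSE),
      expand.grid(day = c(28L, 42L, 56L, 70L), system = c("S", "G"),
                  stringsAsFactors = FALSE)
    )
    pick <- cells[sample.int(nrow(cells), n, replace = TRUE), ]
    tibble::tibble(
      animal = sprintf("t%02d", seq_len(n)),
      segment = sample(git_segments(), n, replace = TRUE),
      day = pick$day,
      system = pick$system,
      ghrelin = round(runif(n, 0.01, 5), 4),
      ghr = round(runif(n, 0.01, 2), 4),
      yield = if (with_yield) round(runif(n, 0.35, 0.65), 4) else NA_real_
    )
  })
}

# loop-and-average MA operator
bf_ma_mean <- function(samples, gene, col, level) {
  v <- samples[[gene]][as.character(samples[[col]]) == as.character(level)]
  sum(v) / length(v)
}

# loop featurization of one (query, reference) row pair
bf_featurize <- function(samples, qi, ri, scheme = "reference-anchored") {
  q <- samples[qi, ]
  r <- samples[ri, ]
  a <- if (scheme == "reference-anchored") r else q
  same_triple <- as.character(samples$segment) == as.character(r$segment) &
    samples$day == r$day & as.character(samples$system) == as.character(r$system)
  y_exp <- mean(samples$yield[same_triple])
  out <- c(y_exp = y_exp, v1 = q$ghrelin, v2 = q$ghr)
  for (g in 1:2) {
    gene <- c("ghrelin", "ghr")[g]
    out[paste0("dv", g, "_s")] <-
      q[[gene]] - bf_ma_mean(samples, gene, "segment", a$segment)
    out[paste0("dv", g, "_t")] <-
      q[[gene]] - bf_ma_mean(samples, gene, "day", a$day)
    out[paste0("dv", g, "_m")] <-
      q[[gene]] - bf_ma_mean(samples, gene, "system", a$system)
  }
  out["target"] <- q$yield
  out
}

# closed-form OLS via normal equations, with the full inference block
bf_ols <- function(X, y) {
  Xd <- cbind(1, X)
  XtX <- t(Xd) %*% Xd
  beta <- solve(XtX, t(Xd) %*% y)
  fitted <- Xd %*% beta
  res <- y - fitted
  n <- length(y)
  p <- ncol(X)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  sigma2 <- ss_res / (n - p - 1)
  se <- sqrt(diag(sigma2 * solve(XtX)))
  f <- (ss_tot - ss_res) / p / sigma2
  list(coef = drop(beta), se = se, r_squared = r2, ss_residual = ss_res,
       f_statistic = f, df_model = p, df_residual = n - p - 1,
       p_value = stats::pf(f, p, n - p - 1, lower.tail = FALSE))
}

# stage means straight off the published matrices (independent of
# template_means() reshaping): unweighted mean of the printed cell means
bf_stage_means <- function(s_matrix, g_matrix, segment_index) {
  pre <- mean(s_matrix[segment_index, 1:3])
  trans <- mean(c(s_matrix[segment_index, 4:5], g_matrix[segment_index, 1:2]))
  rum <- mean(c(s_matrix[segment_index, 6:7], g_matrix[segment_index, 3:4]))
  c(pre, trans, rum)
}

table1_ghrelin_S <- matrix(c(
  0.004, 0.003, 0.002, 0.002, 0.004, 0.000, 0.002,
  1.80, 31.15, 49.92, 61.64, 252.26, 438.34, 567.67,
  1.00, 1.11, 1.33, 2.22, 0.74, 1.46, 0.99,
  0.13, 0.21, 0.36, 0.31, 0.16, 0.17, 0.18,
  0.03, 0.02, 0.001, 0.00, 0.01, 0.01, 0.02,
  0.01, 0.03, 0.05, 0.02, 0.01, 0.01, 0.01,
  0.02, 0.04, 0.03, 0.05, 0.05, 0.05, 0.05,
  0.02, 0.01, 0.02, 0.03, 0.06, 0.04, 0.02), nrow = 8, byrow = TRUE)

table1_ghrelin_G <- matrix(c(
  0.002, 0.004, 0.003, 0.004,
  85.12, 308.01, 564.58, 629.26,
  2.20, 2.98, 1.30, 1.57,
  0.43, 0.34, 0.33, 0.24,
  0.01, 0.01, 0.01, 0.01,
  0.03, 0.01, 0.03, 0.01,
  0.05, 0.04, 0.04, 0.06,
  0.05, 0.04, 0.15, 0.14), nrow = 8, byrow = TRUE)

table2_ghr_S <- matrix(c(
  0.26, 0.31, 0.46, 0.37, 0.15, 0.03, 0.11,
  0.85, 1.08, 1.16, 1.12, 0.64, 0.47, 0.46,
  1.00, 0.75, 1.02, 0.97, 0.47, 0.49, 0.45,
  1.21, 0.73, 0.77, 0.22, 0.36, 0.31, 0.27,
  0.89, 0.55, 0.25, 0.15, 0.15, 0.27, 0.12,
  0.43, 0.17, 0.33, 0.19, 0.11, 0.10, 0.12,
  0.49, 0.33, 0.44, 0.80, 0.52, 0.41, 0.33,
  0.39, 0.45, 0.31, 0.40, 0.57, 0.34, 0.33), nrow = 8, byrow = TRUE)

table2_ghr_G <- matrix(c(
  0.03, 0.03, 0.03, 0.05,
  0.52, 0.41, 0.33, 0.24,
  0.28, 0.15, 0.17, 0.11,
  0.11, 0.13, 0.16, 0.16,
  0.10, 0.10, 0.11, 0.09,
  0.08, 0.05, 0.06, 0.07,
  0.38, 0.36, 0.29, 0.16,
  0.29, 0.20, 0.22, 0.26), nrow = 8, byrow = TRUE)
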