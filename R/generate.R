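#' Configuration for the synthetic study generator
#'
#' Describes a study shaped like the real one: `n_animals` kids, each
#' slaughtered on one of the seven postnatal days and sampled at all eight
#' GIT segments (so `n_animals * 8` rows). Animals on d 0-14 are suckling
#' (system `"L"`); from d 28 they split evenly between Supplemental and
#' Grazing feeding. Expression is drawn lognormally around the published
#' per-cell template means; the growth yield is a logistic-squashed linear
#' form in condition-level GHR means and the animal's mean log2 Ghrelin,
#' plus an optional segment-gated step nonlinearity (an abomasum-GHR
#' threshold effect) that gives tree learners a genuine advantage.
#'
#' @param n_animals Number of animals; must spread evenly over the 11
#'   design cells (3 lactation days + 4 days x 2 systems), default 44.
#' @param noise_sd_log2 SD of expression noise on the log2 scale
#'   (lognormal multiplicative noise), default 0.25.
#' @param yield_coefs Named list of ground-truth coefficients on the logit
#'   yield scale: `intercept` (default chosen so the mean yield is
#'   `target_mean_yield`), `ghr_day` (weight on the day-level mean log2 GHR
#'   template), `ghr_system` (weight on the system-level mean), `ghrelin`
#'   (weight on the animal's mean log2 Ghrelin expression).
#' @param nonlinearity Strength of the planted segment-gated step (added to
#'   the logit when the animal's abomasum GHR expression exceeds
#'   `gate_threshold`); 0 disables it.
#' @param gate_threshold Abomasum GHR expression threshold for the gate;
#'   default the median of the abomasum GHR template cells.
#' @param yield_noise_sd SD of animal-level noise on the logit yield scale.
#' @param target_mean_yield Mean dressing ratio the intercept is calibrated
#'   to (default 0.47).
#' @param outlier_fraction Fraction of sample rows whose yield is replaced
#'   by an out-of-model value (default 0; used to exercise the residual
#'   filter).
#' @param outlier_shift Size of the outlier displacement as a multiple of
#'   the clean yield range (default 1).
#' @param expression_floor Positive floor applied to template means before
#'   lognormal sampling (two published cells are exactly 0).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_animals = 44,
                             noise_sd_log2 = 0.25,
                             yield_coefs = list(),
                             nonlinearity = 0.35,
                             gate_threshold = NULL,
                             yield_noise_sd = 0.05,
                             target_mean_yield = 0.47,
                             outlier_fraction = 0,
                             outlier_shift = 1,
                             expression_floor = 0.001) {
  cells <- design_cells()
  if (n_animals %% nrow(cells) != 0) {
    abort(sprintf("n_animals must be a multiple of %d design cells", nrow(cells)),
          class = "emma_config_error")
  }
  if (noise_sd_log2 < 0 || yield_noise_sd < 0) {
    abort("noise sds must be non-negative", class = "emma_config_error")
  }
  if (outlier_fraction < 0 || outlier_fraction >= 1) {
    abort("outlier_fraction must be in [0, 1)", class = "emma_config_error")
  }
  defaults <- list(intercept = NULL, ghr_day = 0.15,
                   ghr_system = 0.10, ghrelin = 0.10)
  coefs <- utils::modifyList(defaults, yield_coefs)
  if (is.null(gate_threshold)) {
    ab <- dplyr::filter(template_means(), .data$gene == "ghr",
                        .data$segment == "abomasum")
    gate_threshold <- median(ab$mean)
  }
  structure(list(
    n_animals = n_animals,
    noise_sd_log2 = noise_sd_log2,
    yield_coefs = coefs,
    nonlinearity = nonlinearity,
    gate_threshold = gate_threshold,
    yield_noise_sd = yield_noise_sd,
    target_mean_yield = target_mean_yield,
    outlier_fraction = outlier_fraction,
    outlier_shift = outlier_shift,
    expression_floor = expression_floor
  ), class = "generator_config")
}

# the 11 (day, system) design cells an animal can occupy
design_cells <- function() {
  dplyr::bind_rows(
    tibble::tibble(day = c(0L, 7L, 14L), system = "L"),
    tidyr::expand_grid(day = c(28L, 42L, 56L, 70L), system = c("S", "G"))
  )
}

# floored template grid for one gene as a (segment x cell) lookup
template_lookup <- function(gene, floor_at) {
  tm <- dplyr::filter(template_means(), .data$gene == !!gene)
  tm$mean <- pmax(tm$mean, floor_at)
  tm
}

# condition-level covariates of the planted yield model: day-level and
# system-level means of log2 GHR templates (over segments, and over the
# systems/days present at that level)
truth_condition_covariates <- function(floor_at) {
  ghr <- template_lookup("ghr", floor_at)
  ghr$system <- as.character(ghr$system)
  day_cov <- dplyr::summarise(dplyr::group_by(ghr, .data$day),
                              t2 = mean(log2(.data$mean)), .groups = "drop")
  sys_cov <- dplyr::summarise(dplyr::group_by(ghr, .data$system),
                              m2 = mean(log2(.data$mean)), .groups = "drop")
  list(day = day_cov, system = sys_cov)
}

# zero-noise animal-level covariate expectations per design cell
truth_cell_covariates <- function(floor_at) {
  cells <- design_cells()
  cov <- truth_condition_covariates(floor_at)
  gh <- template_lookup("ghrelin", floor_at)
  g_bar <- dplyr::summarise(dplyr::group_by(gh, .data$day, .data$system),
                            g = mean(log2(.data$mean)), .groups = "drop")
  g_bar$system <- as.character(g_bar$system)
  cells <- dplyr::left_join(cells, cov$day, by = "day")
  cells <- dplyr::left_join(cells, cov$system, by = "system")
  dplyr::left_join(cells, g_bar, by = c("day", "system"))
}

resolved_intercept <- function(config) {
  b <- config$yield_coefs
  if (!is.null(b$intercept)) return(b$intercept)
  cc <- truth_cell_covariates(config$expression_floor)
  ab <- template_lookup("ghr", config$expression_floor)
  ab <- ab[ab$segment == "abomasum", ]
  gate0 <- as.numeric(ab$mean[match(paste(cc$day, cc$system),
                                    paste(ab$day, ab$system))] >
                        config$gate_threshold)
  eta_wo <- b$ghr_day * cc$t2 + b$ghr_system * cc$m2 + b$ghrelin * cc$g +
    config$nonlinearity * gate0
  qlogis(config$target_mean_yield) - mean(eta_wo)
}

#' Generate a synthetic study with known ground truth
#'
#' Draws a full study table shaped like the deposited experimental dataset
#' (default: 44 animals x 8 segments = 352 rows) together with the planted
#' ground truth, byte-identically reproducible from `(config, seed)`.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed controlling every random draw.
#' @return A list with `samples` (a sample table, yields identical across
#'   each animal's 8 rows unless outliers were injected) and `truth` (the
#'   resolved coefficients, per-animal covariates and linear predictor,
#'   gate indicator, outlier row indices, and the seed).
#' @export
generate_study <- function(config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(as.integer(seed), generate_study_impl(config, as.integer(seed)))
}

generate_study_impl <- function(config, seed) {
  cells <- design_cells()
  per_cell <- config$n_animals / nrow(cells)
  animals <- tidyr::uncount(cells, per_cell)
  animals$animal <- sprintf("a%02d", seq_len(nrow(animals)))

  segs <- git_segments()
  grid <- tidyr::expand_grid(animal = animals$animal, segment = segs)
  grid <- dplyr::left_join(grid, animals, by = "animal")

  floor_at <- config$expression_floor
  tm1 <- template_lookup("ghrelin", floor_at)
  tm2 <- template_lookup("ghr", floor_at)
  key <- function(tm) setNames(tm$mean, paste(tm$segment, tm$day, tm$system))
  k1 <- key(tm1); k2 <- key(tm2)
  cell_key <- paste(grid$segment, grid$day, grid$system)
  mu1 <- unname(k1[cell_key])
  mu2 <- unname(k2[cell_key])
  n <- nrow(grid)
  grid$ghrelin <- mu1 * 2^rnorm(n, 0, config$noise_sd_log2)
  grid$ghr <- mu2 * 2^rnorm(n, 0, config$noise_sd_log2)

  # animal-level covariates of the planted yield model
  cov <- truth_condition_covariates(floor_at)
  per_animal <- dplyr::summarise(
    dplyr::group_by(grid, .data$animal, .data$day, .data$system),
    g_bar = mean(log2(.data$ghrelin)),
    v2_abomasum = .data$ghr[.data$segment == "abomasum"],
    .groups = "drop"
  )
  per_animal <- dplyr::left_join(per_animal, cov$day, by = "day")
  per_animal <- dplyr::left_join(per_animal, cov$system, by = "system")

  b <- config$yield_coefs
  b0 <- resolved_intercept(config)
  gate <- as.numeric(per_animal$v2_abomasum > config$gate_threshold)
  eta <- b0 + b$ghr_day * per_animal$t2 + b$ghr_system * per_animal$m2 +
    b$ghrelin * per_animal$g_bar + config$nonlinearity * gate +
    rnorm(nrow(per_animal), 0, config$yield_noise_sd)
  per_animal$gate <- gate
  per_animal$eta <- eta
  per_animal$yield <- plogis(eta)

  # body weights consistent with the yield: a simple kid growth line with
  # mild animal-level scatter, carcass weight derived from the yield
  lw <- (1.35 + 0.115 * per_animal$day) * exp(rnorm(nrow(per_animal), 0, 0.05))
  per_animal$live_weight <- lw
  per_animal$carcass_weight <- per_animal$yield * lw

  grid <- dplyr::left_join(
    grid,
    per_animal[, c("animal", "yield", "live_weight", "carcass_weight")],
    by = "animal"
  )

  outlier_rows <- integer(0)
  if (config$outlier_fraction > 0) {
    n_out <- round(config$outlier_fraction * n)
    if (n_out > 0) {
      outlier_rows <- sort(sample.int(n, n_out))
      rng <- range(per_animal$yield)
      # out-of-model replacement: a value sitting outlier_shift clean ranges
      # above the clean support, so it cannot be explained by any fit to the
      # majority of the data
      grid$yield[outlier_rows] <- min(rng[2] + config$outlier_shift * diff(rng),
                                      0.99)
    }
  }

  samples <- as_sample_table(grid[, sample_table_columns()])
  truth <- list(
    coefficients = c(intercept = b0, ghr_day = b$ghr_day,
                     ghr_system = b$ghr_system, ghrelin = b$ghrelin,
                     nonlinearity = config$nonlinearity),
    gate_threshold = config$gate_threshold,
    per_animal = per_animal,
    outlier_rows = outlier_rows,
    expression_floor = config$expression_floor,
    seed = seed
  )
  list(samples = samples, truth = truth)
}

#' Simulate qPCR Ct values that invert to given expressions
#'
#' For every sample row and both genes, draws a plausible beta-actin Ct in
#' the 15-25 cycle range and solves for the target Ct so that
#' [relative_expression_ddct()] reproduces the recorded relative expression
#' exactly (to floating point). The calibrator (duodenum d 0) Ct pair is
#' shared by all measurements of a gene.
#'
#' @param samples A sample table with positive expressions.
#' @param seed Integer seed.
#' @return Tibble with one row per sample x gene: the sample identity
#'   columns, `gene`, `ct_target`, `ct_actin`, `calibrator_ct_target`,
#'   `calibrator_ct_actin`.
#' @export
generate_qpcr <- function(samples, seed = 1) {
  samples <- as_sample_table(samples)
  if (any(samples$ghrelin == 0) || any(samples$ghr == 0)) {
    abort("relative expression must be strictly positive to invert 2^-ddCt",
          class = "emma_validation_error")
  }
  withr::with_seed(as.integer(seed), {
    long <- tidyr::pivot_longer(
      samples[, c("animal", "segment", "day", "system", "ghrelin", "ghr")],
      cols = c("ghrelin", "ghr"), names_to = "gene", values_to = "expression"
    )
    cal <- tibble::tibble(
      gene = study_genes(),
      calibrator_ct_actin = runif(2, 18, 22),
      dct_cal = runif(2, 1, 4)
    )
    cal$calibrator_ct_target <- cal$calibrator_ct_actin + cal$dct_cal
    long <- dplyr::left_join(long, cal, by = "gene")
    long$ct_actin <- runif(nrow(long), 15, 25)
    # ddCt = -log2(expression); dCt_sample = ddCt + dCt_cal
    long$ct_target <- long$ct_actin + long$dct_cal - log2(long$expression)
    long[, c("animal", "segment", "day", "system", "gene",
             "ct_target", "ct_actin",
             "calibrator_ct_target", "calibrator_ct_actin")]
  })
}
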