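#' Experimental design constants
#'
#' The study design samples the gastrointestinal tract (GIT) at eight
#' longitudinal segments, on seven postnatal days, under two feeding systems
#' applied from d 28 onward (Supplemental concentrate feeding `"S"` vs
#' Grazing `"G"`); before the split all kids are suckling and carry the
#' lactation label `"L"`.
#'
#' Segment order follows the anatomical ordering used throughout:
#' rumen (1), abomasum (2), duodenum (3), jejunum (4), ileum (5),
#' cecum (6), colon (7), rectum (8).
#'
#' @return Character (or integer) vector of the design levels.
#' @export
git_segments <- function() {
  c("rumen", "abomasum", "duodenum", "jejunum",
    "ileum", "cecum", "colon", "rectum")
}

#' @rdname git_segments
#' @export
study_days <- function() c(0L, 7L, 14L, 28L, 42L, 56L, 70L)

#' @rdname git_segments
#' @export
feeding_systems <- function() c("S", "G", "L")

#' @rdname git_segments
#' @export
study_genes <- function() c("ghrelin", "ghr")

sample_table_columns <- function() {
  c("animal", "segment", "day", "system", "ghrelin", "ghr",
    "live_weight", "carcass_weight", "yield")
}

#' Validate and canonicalize a sample table
#'
#' A sample table is a tibble with one row per mucosa sample and columns
#' `animal`, `segment`, `day`, `system`, `ghrelin`, `ghr` (relative mRNA
#' expression, fold change vs the duodenum d 0 calibrator) and optional
#' `live_weight`, `carcass_weight` (kg) and `yield` (carcass/live ratio,
#' in (0,1)). Segment and system labels are matched case-insensitively
#' against [git_segments()] and [feeding_systems()].
#'
#' @param data A data frame shaped as above.
#' @return A validated tibble with canonical factor levels and all nine
#'   columns present (optional columns filled with `NA` when absent).
#' @export
as_sample_table <- function(data) {
  data <- tibble::as_tibble(data)
  required <- c("animal", "segment", "day", "system", "ghrelin", "ghr")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("sample table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "emma_schema_error")
  }
  for (col in setdiff(sample_table_columns(), names(data))) {
    data[[col]] <- NA_real_
  }
  data <- data[, sample_table_columns()]

  seg <- match(tolower(trimws(as.character(data$segment))), git_segments())
  bad <- which(is.na(seg))
  if (length(bad) > 0) {
    abort(sprintf("unknown segment value '%s' in row %d",
                  as.character(data$segment)[bad[1]], bad[1]),
          class = "emma_validation_error")
  }
  sys <- match(toupper(trimws(as.character(data$system))), feeding_systems())
  bad <- which(is.na(sys))
  if (length(bad) > 0) {
    abort(sprintf("unknown system value '%s' in row %d",
                  as.character(data$system)[bad[1]], bad[1]),
          class = "emma_validation_error")
  }
  day <- suppressWarnings(as.integer(data$day))
  bad <- which(!day %in% study_days())
  if (length(bad) > 0) {
    abort(sprintf("day '%s' in row %d is not one of %s",
                  as.character(data$day)[bad[1]], bad[1],
                  paste(study_days(), collapse = ", ")),
          class = "emma_validation_error")
  }

  for (col in c("ghrelin", "ghr")) {
    v <- suppressWarnings(as.numeric(data[[col]]))
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad) > 0) {
      abort(sprintf("non-numeric or negative %s expression in row %d",
                    col, bad[1]),
            class = "emma_validation_error")
    }
    data[[col]] <- v
  }
  for (col in c("live_weight", "carcass_weight", "yield")) {
    data[[col]] <- suppressWarnings(as.numeric(data[[col]]))
  }
  both <- !is.na(data$live_weight) & !is.na(data$carcass_weight)
  if (any(both & (data$carcass_weight >= data$live_weight |
                  data$live_weight <= 0 | data$carcass_weight <= 0))) {
    abort("carcass_weight must be positive and strictly below live_weight",
          class = "emma_validation_error")
  }
  if (any(!is.na(data$yield) & (data$yield <= 0 | data$yield >= 1))) {
    abort("yield must lie strictly in (0, 1)", class = "emma_validation_error")
  }

  data$animal <- as.character(data$animal)
  data$segment <- factor(git_segments()[seg], levels = git_segments())
  data$day <- day
  data$system <- factor(feeding_systems()[sys], levels = feeding_systems())
  data
}

#' Read / write a sample table
#'
#' CSV I/O for the long-format sample table (RFC-4180, UTF-8, `.` decimal
#' separator). `read_sample_table()` validates every row on the way in;
#' `write_sample_table()` round-trips with it at full printed precision.
#'
#' @param source Path (or connection) to a CSV file with header columns
#'   `animal,segment,day,system,ghrelin,ghr` and optional
#'   `live_weight,carcass_weight,yield`.
#' @return `read_sample_table()`: a validated sample-table tibble.
#' @export
read_sample_table <- function(source) {
  raw <- readr::read_csv(source, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("animal", "segment", "day", "system", "ghrelin", "ghr")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("input file is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "emma_schema_error")
  }
  as_sample_table(raw)
}

#' @rdname read_sample_table
#' @param samples A validated sample table.
#' @param sink Path to write to.
#' @return `write_sample_table()`: the number of rows written, invisibly.
#' @export
write_sample_table <- function(samples, sink) {
  samples <- as_sample_table(samples)
  out <- samples
  out$segment <- as.character(out$segment)
  out$system <- as.character(out$system)
  readr::write_csv(out, sink, progress = FALSE)
  invisible(nrow(out))
}

#' Relative expression by the 2^-ddCt method
#'
#' Computes qPCR relative expression against the beta-actin housekeeping
#' gene and the duodenum d 0 calibrator sample:
#' `dCt = Ct_target - Ct_actin`, `ddCt = dCt_sample - dCt_calibrator`,
#' and the returned fold change is `2^-ddCt`. A sample whose Ct values
#' equal the calibrator's returns exactly 1.
#'
#' All arguments are vectorized and recycled.
#'
#' @param ct_target,ct_actin Cycle thresholds of the target gene and of
#'   beta-actin in the sample.
#' @param calibrator_ct_target,calibrator_ct_actin Cycle thresholds for the
#'   duodenum d 0 calibrator.
#' @return Numeric vector of fold changes (strictly positive).
#' @export
relative_expression_ddct <- function(ct_target, ct_actin,
                                     calibrator_ct_target,
                                     calibrator_ct_actin) {
  args <- vctrs_recycle(ct_target, ct_actin,
                        calibrator_ct_target, calibrator_ct_actin)
  if (!all(vapply(args, function(x) all(is.finite(x)), logical(1)))) {
    abort("all Ct values must be finite", class = "emma_validation_error")
  }
  ddct <- (args[[1]] - args[[2]]) - (args[[3]] - args[[4]])
  2^(-ddct)
}

# minimal common-length recycling (scalar-or-equal-length)
vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  lapply(args, function(x) {
    if (length(x) == n) x else if (length(x) == 1) rep(x, n) else
      abort("arguments must have length 1 or a common length",
            class = "emma_validation_error")
  })
}

#' Carcass yield (dressing ratio)
#'
#' The growth yield modelled downstream, defined as carcass weight over
#' live weight; dimensionless and strictly inside (0, 1).
#'
#' @param live_weight,carcass_weight Weights in kg; vectorized.
#' @return Numeric vector of yields.
#' @export
carcass_yield <- function(live_weight, carcass_weight) {
  args <- vctrs_recycle(live_weight, carcass_weight)
  lw <- args[[1]]; cw <- args[[2]]
  if (any(!is.finite(lw) | !is.finite(cw) | lw <= 0 | cw <= 0)) {
    abort("weights must be finite and positive", class = "emma_validation_error")
  }
  if (any(cw >= lw)) {
    abort("carcass_weight must be strictly below live_weight",
          class = "emma_validation_error")
  }
  cw / lw
}

#' Add the derived yield column to a sample table
#'
#' Fills `yield` with [carcass_yield()] wherever both weights are present
#' and `yield` is missing.
#'
#' @param samples A sample table.
#' @return The sample table with `yield` populated.
#' @export
add_carcass_yield <- function(samples) {
  samples <- as_sample_table(samples)
  fill <- is.na(samples$yield) &
    !is.na(samples$live_weight) & !is.na(samples$carcass_weight)
  samples$yield[fill] <- carcass_yield(samples$live_weight[fill],
                                       samples$carcass_weight[fill])
  samples
}

#' Round half away from zero
#'
#' Presentation rounding used for table entries (0.375 rounds to 0.38),
#' unlike base `round()`'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
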