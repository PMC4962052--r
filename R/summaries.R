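#' Developmental stages of the rumination transition
#'
#' Pre-rumination covers d 0-14 (suckling, before the feeding-system
#' split), transition d 28-42 and rumination d 56-70 (both with S and G
#' groups).
#'
#' @return Named list mapping stage name to the days it pools.
#' @export
rumination_stages <- function() {
  list(
    "pre-rumination" = c(0L, 7L, 14L),
    "transition" = c(28L, 42L),
    "rumination" = c(56L, 70L)
  )
}

#' Stage summary of relative expression
#'
#' For each segment and developmental stage, the stage mean is the
#' unweighted mean of the per-(day, system) cell means falling in that
#' stage: pre-rumination pools the three pre-split days (lactation cells),
#' transition and rumination each pool 2 days x 2 systems. The SEM is the
#' pooled within-cell residual standard error divided by sqrt(mean cell
#' size); it is `NA` when every cell holds a single animal (no residual
#' degrees of freedom). Empty stage cells mark the summary row as missing
#' rather than contributing zeros.
#'
#' @param samples A sample table.
#' @param gene `"ghrelin"` or `"ghr"`.
#' @return Tibble with columns `gene`, `segment`, `stage`, `mean`, `sem`,
#'   `n_cells`, `n_obs`, `missing`.
#' @export
stage_summary <- function(samples, gene = c("ghrelin", "ghr")) {
  gene <- match.arg(gene)
  samples <- as_sample_table(samples)
  stages <- rumination_stages()
  value <- samples[[gene]]

  out <- purrr::map_dfr(git_segments(), function(seg) {
    purrr::map_dfr(names(stages), function(st) {
      days <- stages[[st]]
      idx <- samples$segment == seg & samples$day %in% days
      sub <- samples[idx, ]
      v <- value[idx]
      expected_cells <- if (st == "pre-rumination") 3L else 4L
      if (nrow(sub) == 0) {
        return(tibble::tibble(gene = gene, segment = seg, stage = st,
                              mean = NA_real_, sem = NA_real_,
                              n_cells = 0L, n_obs = 0L, missing = TRUE))
      }
      cell <- interaction(sub$day, sub$system, drop = TRUE)
      cell_means <- tapply(v, cell, mean)
      n_per_cell <- tapply(v, cell, length)
      resid <- v - cell_means[as.character(cell)]
      df_res <- length(v) - length(cell_means)
      pooled_sd <- if (df_res > 0) sqrt(sum(resid^2) / df_res) else NA_real_
      sem <- pooled_sd / sqrt(mean(n_per_cell))
      tibble::tibble(gene = gene, segment = seg, stage = st,
                     mean = mean(cell_means), sem = sem,
                     n_cells = length(cell_means), n_obs = length(v),
                     missing = length(cell_means) < expected_cells)
    })
  })
  out$segment <- factor(out$segment, levels = git_segments())
  out$stage <- factor(out$stage, levels = names(stages))
  out
}

#' Orthogonal linear and quadratic age contrasts
#'
#' Tests linear and quadratic trends of expression over postnatal age for
#' one segment and feeding system, with contrast coefficients built by
#' `poly()` on the observation-level day vector, so they are orthogonal
#' under the actual unequal day spacing (0, 7, 14, 28, 42, 56, 70) and the
#' observed cell counts. Pre-split lactation samples (d 0-14) are shared by
#' both systems' trajectories.
#'
#' @param samples A sample table.
#' @param gene `"ghrelin"` or `"ghr"`.
#' @param segment One of [git_segments()].
#' @param system `"S"` or `"G"`: which post-split trajectory to follow.
#' @return Tibble with one row per term (`linear`, `quadratic`):
#'   `estimate`, `std.error`, `statistic`, `p.value`. The per-day contrast
#'   coefficient matrix and cell counts are attached as attributes
#'   `contrasts` and `counts`.
#' @export
age_trend_contrasts <- function(samples, gene = c("ghrelin", "ghr"),
                                segment, system = c("S", "G")) {
  gene <- match.arg(gene)
  system <- match.arg(system)
  samples <- as_sample_table(samples)
  segment <- match.arg(segment, git_segments())
  keep <- samples$segment == segment &
    (samples$system == "L" | samples$system == system)
  sub <- samples[keep, ]
  if (length(unique(sub$day)) < 3) {
    abort("age contrasts need at least 3 distinct days with data",
          class = "emma_design_error")
  }
  y <- sub[[gene]]
  p <- stats::poly(sub$day, degree = 2)
  fit <- lm(y ~ p)
  sm <- suppressWarnings(summary(fit))$coefficients
  terms <- c("linear", "quadratic")
  out <- tibble::tibble(
    gene = gene, segment = segment, system = system, term = terms,
    estimate = sm[2:3, 1], std.error = sm[2:3, 2],
    statistic = sm[2:3, 3], p.value = sm[2:3, 4]
  )
  lev <- sort(unique(sub$day))
  cmat <- cbind(day = lev, p[match(lev, sub$day), 1:2, drop = FALSE])
  colnames(cmat) <- c("day", "linear", "quadratic")
  attr(out, "contrasts") <- cmat
  attr(out, "counts") <- as.integer(table(factor(sub$day, levels = lev)))
  out
}

#' Two-way fixed-effects ANOVA for feeding system and age
#'
#' Analyses the post-split window (d 28-70, both systems present) with
#' fixed effects for feeding system, age and their interaction, the
#' individual animal as the experimental unit. Type-I sums of squares over
#' the balanced d 28-70 grid; the term and residual sums of squares
#' partition the total exactly.
#'
#' @param samples A sample table.
#' @param gene `"ghrelin"` or `"ghr"`.
#' @param segment One of [git_segments()].
#' @return Tibble with columns `term`, `df`, `sumsq`, `meansq`,
#'   `statistic`, `p.value` (rows: system, age, system:age, residuals).
#' @export
feeding_effect_anova <- function(samples, gene = c("ghrelin", "ghr"), segment) {
  gene <- match.arg(gene)
  samples <- as_sample_table(samples)
  segment <- match.arg(segment, git_segments())
  sub <- samples[samples$segment == segment & samples$day >= 28, ]
  sub <- sub[sub$system %in% c("S", "G"), ]
  if (length(unique(droplevels(sub$system))) < 2) {
    abort("both feeding systems must be present from d 28 onward",
          class = "emma_design_error")
  }
  counts <- table(sub$system[sub$system %in% c("S", "G")], sub$day)
  if (any(counts[c("S", "G"), ] < 2)) {
    abort("each system x day cell needs at least 2 animals",
          class = "emma_design_error")
  }
  y <- sub[[gene]]
  sys <- droplevels(sub$system)
  age <- factor(sub$day)
  fit <- lm(y ~ sys * age)
  tab <- suppressWarnings(anova(fit))
  stat <- tab$`F value`
  pval <- tab$`Pr(>F)`
  # degenerate designs: a term whose SS is (numerically) zero explains
  # nothing (F = 0), while a non-zero term over a zero residual is an
  # exact effect (F = Inf)
  ss <- tab$`Sum Sq`
  ss_total <- sum(ss)
  k <- nrow(tab)
  if (ss_total < 1e-20) {
    stat[seq_len(k - 1)] <- 0
    pval[seq_len(k - 1)] <- 1
  } else {
    tol <- 1e-10 * ss_total
    zero_term <- which(ss[-k] < tol)
    stat[zero_term] <- 0
    pval[zero_term] <- 1
    if (ss[k] < tol) {
      exact <- setdiff(seq_len(k - 1), zero_term)
      stat[exact] <- Inf
      pval[exact] <- 0
    }
  }
  tibble::tibble(
    gene = gene, segment = segment,
    term = c("system", "age", "system:age", "residuals"),
    df = tab$Df,
    sumsq = tab$`Sum Sq`,
    meansq = tab$`Mean Sq`,
    statistic = stat,
    p.value = pval
  )
}
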