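# Published per-cell mean relative expressions (fold change vs duodenum d0)
# for Ghrelin and GHR across 8 GIT segments. Rows: segments in anatomical
# order; columns: d0, d7, d14 (lactation), then d28..d70 under S and G.
.template_days <- c(0L, 7L, 14L, 28L, 42L, 56L, 70L)

.template_ghrelin_S <- matrix(c(
  0.004, 0.003, 0.002, 0.002, 0.004, 0.000, 0.002,
  1.80,  31.15, 49.92, 61.64, 252.26, 438.34, 567.67,
  1.00,  1.11,  1.33,  2.22,  0.74,  1.46,  0.99,
  0.13,  0.21,  0.36,  0.31,  0.16,  0.17,  0.18,
  0.03,  0.02,  0.001, 0.00,  0.01,  0.01,  0.02,
  0.01,  0.03,  0.05,  0.02,  0.01,  0.01,  0.01,
  0.02,  0.04,  0.03,  0.05,  0.05,  0.05,  0.05,
  0.02,  0.01,  0.02,  0.03,  0.06,  0.04,  0.02
), nrow = 8, byrow = TRUE)

.template_ghrelin_G <- matrix(c(
  0.002, 0.004, 0.003, 0.004,
  85.12, 308.01, 564.58, 629.26,
  2.20,  2.98,  1.30,  1.57,
  0.43,  0.34,  0.33,  0.24,
  0.01,  0.01,  0.01,  0.01,
  0.03,  0.01,  0.03,  0.01,
  0.05,  0.04,  0.04,  0.06,
  0.05,  0.04,  0.15,  0.14
), nrow = 8, byrow = TRUE)

.template_ghr_S <- matrix(c(
  0.26, 0.31, 0.46, 0.37, 0.15, 0.03, 0.11,
  0.85, 1.08, 1.16, 1.12, 0.64, 0.47, 0.46,
  1.00, 0.75, 1.02, 0.97, 0.47, 0.49, 0.45,
  1.21, 0.73, 0.77, 0.22, 0.36, 0.31, 0.27,
  0.89, 0.55, 0.25, 0.15, 0.15, 0.27, 0.12,
  0.43, 0.17, 0.33, 0.19, 0.11, 0.10, 0.12,
  0.49, 0.33, 0.44, 0.80, 0.52, 0.41, 0.33,
  0.39, 0.45, 0.31, 0.40, 0.57, 0.34, 0.33
), nrow = 8, byrow = TRUE)

.template_ghr_G <- matrix(c(
  0.03, 0.03, 0.03, 0.05,
  0.52, 0.41, 0.33, 0.24,
  0.28, 0.15, 0.17, 0.11,
  0.11, 0.13, 0.16, 0.16,
  0.10, 0.10, 0.11, 0.09,
  0.08, 0.05, 0.06, 0.07,
  0.38, 0.36, 0.29, 0.16,
  0.29, 0.20, 0.22, 0.26
), nrow = 8, byrow = TRUE)

#' Published per-condition template means
#'
#' Returns the embedded grid of mean relative expressions for Ghrelin and
#' GHR in every (segment, day, system) cell of the study design, exactly as
#' published. Days 0-14 precede the feeding-system split and carry the
#' lactation system `"L"`; days 28-70 carry both `"S"` and `"G"` cells.
#' The grid is the fixture behind the stage-summary worked examples and the
#' mean structure emulated by [generate_study()].
#'
#' @param complete If `TRUE`, additionally emit `"S"` and `"G"` rows for
#'   days 0-14 copied from the lactation values, so every
#'   (gene, segment, day, system in S/G) cell is populated.
#' @return Tibble with columns `gene`, `segment`, `day`, `system`, `mean`.
#' @export
template_means <- function(complete = FALSE) {
  seg <- factor(git_segments(), levels = git_segments())
  one_gene <- function(gene, m_s, m_g) {
    early <- tidyr::expand_grid(segment = seg, day = .template_days[1:3])
    early$system <- factor("L", levels = feeding_systems())
    early$mean <- m_s[cbind(as.integer(early$segment), match(early$day, .template_days))]
    late_s <- tidyr::expand_grid(segment = seg, day = .template_days[4:7])
    late_s$system <- factor("S", levels = feeding_systems())
    late_s$mean <- m_s[cbind(as.integer(late_s$segment), match(late_s$day, .template_days))]
    late_g <- tidyr::expand_grid(segment = seg, day = .template_days[4:7])
    late_g$system <- factor("G", levels = feeding_systems())
    late_g$mean <- m_g[cbind(as.integer(late_g$segment), match(late_g$day, .template_days) - 3L)]
    out <- dplyr::bind_rows(early, late_s, late_g)
    out$gene <- gene
    out[, c("gene", "segment", "day", "system", "mean")]
  }
  out <- dplyr::bind_rows(
    one_gene("ghrelin", .template_ghrelin_S, .template_ghrelin_G),
    one_gene("ghr", .template_ghr_S, .template_ghr_G)
  )
  if (complete) {
    early <- dplyr::filter(out, .data$system == "L")
    for (sys in c("S", "G")) {
      filled <- early
      filled$system <- factor(sys, levels = feeding_systems())
      out <- dplyr::bind_rows(out, filled)
    }
    out <- dplyr::filter(out, .data$system != "L")
  }
  dplyr::arrange(out, .data$gene, .data$segment, .data$day, .data$system)
}

#' Template fixture as a sample table
#'
#' Reshapes [template_means()] into a one-row-per-cell sample table (one
#' pseudo-animal per design cell), convenient for feeding the published
#' cell means through [stage_summary()] and the moving-average operators.
#'
#' @return A sample-table tibble with 88 rows (8 segments x 11 design cells)
#'   and both genes as columns.
#' @export
template_sample_table <- function() {
  wide <- tidyr::pivot_wider(template_means(), names_from = "gene",
                             values_from = "mean")
  wide$animal <- paste0("cell_", wide$day, "_", wide$system)
  as_sample_table(wide)
}
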