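test_that("stage summary reproduces every published stage mean", {
  fx <- template_sample_table()
  for (spec in list(list(gene = "ghrelin", s = table1_ghrelin_S, g = table1_ghrelin_G),
                    list(gene = "ghr", s = table2_ghr_S, g = table2_ghr_G))) {
    ss <- stage_summary(fx, spec$gene)
    for (k in 1:8) {
      expected <- bf_stage_means(spec$s, spec$g, k)
      got <- ss$mean[ss$segment == git_segments()[k]]
      expect_equal(got, expected, tolerance = 1e-12)
    }
  }
  # spot-check the published 2-dp table entries
  ab <- stage_summary(fx, "ghrelin")
  ab <- ab[ab$segment == "abomasum", ]
  expect_equal(round_half_away(ab$mean), c(27.62, 176.76, 549.96))
  ab2 <- stage_summary(fx, "ghr")
  ab2 <- ab2[ab2$segment == "abomasum", ]
  expect_equal(round_half_away(ab2$mean), c(1.03, 0.67, 0.38))
})

test_that("stage summary has zero SEM on constant replicates and flags gaps", {
  base <- tidyr::expand_grid(animal = c("x1", "x2"),
                             segment = "rumen",
                             day = c(28L, 42L), system = c("S", "G"))
  base$animal <- paste(base$animal, base$system, base$day)  # distinct animals
  base$ghrelin <- 2.5
  base$ghr <- 1
  ss <- stage_summary(base, "ghrelin")
  tr <- ss[ss$segment == "rumen" & ss$stage == "transition", ]
  expect_equal(tr$mean, 2.5)
  expect_equal(tr$sem, 0)
  expect_false(tr$missing)
  pre <- ss[ss$segment == "rumen" & ss$stage == "pre-rumination", ]
  expect_true(pre$missing)
  expect_true(is.na(pre$mean))
})

test_that("age contrasts are orthogonal under unequal spacing and counts", {
  st <- generate_study(generator_config(), seed = 5)$samples
  ct <- age_trend_contrasts(st, "ghr", "duodenum", "S")
  cm <- attr(ct, "contrasts")
  n <- attr(ct, "counts")
  lin <- cm[, 2]; quad <- cm[, 3]
  expect_lt(abs(sum(n * lin * quad)), 1e-10)
  expect_lt(abs(sum(n * lin)), 1e-10)
  expect_lt(abs(sum(n * quad)), 1e-10)

  # shifting all responses by a constant leaves the trend estimates alone
  shifted <- st
  shifted$ghr <- shifted$ghr + 5
  ct2 <- age_trend_contrasts(shifted, "ghr", "duodenum", "S")
  expect_equal(ct2$estimate, ct$estimate, tolerance = 1e-9)
})

test_that("pure linear/quadratic day trends isolate the matching contrast", {
  days <- study_days()
  make <- function(f) {
    tab <- tidyr::expand_grid(animal_i = 1:4, day = days)
    tab$animal <- sprintf("a%d_%d", tab$animal_i, tab$day)
    tab$segment <- "jejunum"
    tab$system <- ifelse(tab$day <= 14, "L", "S")
    tab$ghrelin <- f(tab$day)
    tab$ghr <- 1
    tab
  }
  lin_tab <- make(function(d) 0.5 + 0.01 * d)
  ct <- age_trend_contrasts(lin_tab, "ghrelin", "jejunum", "S")
  expect_lt(abs(ct$estimate[ct$term == "quadratic"]), 1e-9)
  expect_gt(abs(ct$estimate[ct$term == "linear"]), 1e-6)

  quad_tab <- make(function(d) 1 + 0.001 * (d - mean(days))^2)
  ct <- age_trend_contrasts(quad_tab, "ghrelin", "jejunum", "S")
  expect_gt(abs(ct$estimate[ct$term == "quadratic"]), 1e-6)
})

test_that("abomasum Ghrelin rises quadratically in synthetic studies", {
  ct <- age_trend_contrasts(generate_study(generator_config(), seed = 8)$samples,
                            "ghrelin", "abomasum", "S")
  expect_lt(ct$p.value[ct$term == "quadratic"], 0.05)
  expect_gt(ct$estimate[ct$term == "quadratic"], 0)
  expect_error(
    age_trend_contrasts(toy_sample_table(2, seed = 1), "ghr", "rumen", "S"),
    class = "emma_design_error"
  )
})

test_that("feeding ANOVA partitions sums of squares and handles degenerate cells", {
  st <- generate_study(generator_config(), seed = 9)$samples
  tab <- feeding_effect_anova(st, "ghr", "duodenum")
  expect_equal(sum(tab$sumsq[1:3]) + tab$sumsq[4],
               sum((st$ghr[st$segment == "duodenum" & st$day >= 28] -
                    mean(st$ghr[st$segment == "duodenum" & st$day >= 28]))^2),
               tolerance = 1e-8)

  flat <- st
  flat$ghr <- 1
  tab0 <- feeding_effect_anova(flat, "ghr", "duodenum")
  expect_equal(tab0$statistic[1:3], c(0, 0, 0))

  shift <- st
  shift$ghr <- ifelse(as.character(shift$system) == "S", 2, 1)
  tabs <- feeding_effect_anova(shift, "ghr", "duodenum")
  expect_true(is.infinite(tabs$statistic[tabs$term == "system"]))
  expect_equal(tabs$sumsq[tabs$term == "age"], 0)
})

test_that("the planted S over G GHR shift is detected in most seeds", {
  hits <- vapply(1:10, function(s) {
    st <- generate_study(generator_config(), seed = 100 + s)$samples
    tab <- feeding_effect_anova(st, "ghr", "duodenum")
    tab$p.value[tab$term == "system"] < 0.05
  }, logical(1))
  expect_gte(sum(hits), 9)
})
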