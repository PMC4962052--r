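test_that("MA operator matches the toy example and conserves the grand mean", {
  toy <- tibble::tibble(
    animal = c("a", "b", "c"),
    segment = c("rumen", "rumen", "abomasum"),
    day = c(0L, 0L, 0L), system = "L",
    ghrelin = c(1, 3, 10), ghr = c(1, 1, 1),
    yield = c(0.4, 0.5, 0.6)
  )
  mt <- ma_table(toy, "ghrelin", "segment")
  expect_equal(mt$mean[mt$level == "rumen"], 2)
  expect_equal(mt$mean[mt$level == "abomasum"], 10)
  expect_equal(mt$n, c(2L, 1L))

  for (cc in c("segment", "time", "system")) {
    st <- generate_study(generator_config(), seed = 12)$samples
    tab <- ma_table(st, "ghr", cc)
    expect_equal(sum(tab$mean * tab$n) / sum(tab$n), mean(st$ghr),
                 tolerance = 1e-9)
    expect_equal(sum(tab$n), nrow(st))
  }
})

test_that("template fixture ranks abomasum GHR above rumen", {
  fx <- template_sample_table()
  mt <- ma_table(fx, "ghr", "segment")
  expect_gt(mt$mean[mt$level == "abomasum"], mt$mean[mt$level == "rumen"])
})

test_that("expected yield table averages exact condition triples", {
  toy <- toy_sample_table(10, seed = 2)
  ey <- expected_yield_table(toy)
  # conservation: count-weighted mean over triples = global mean yield
  expect_equal(sum(ey$y_exp * ey$n) / sum(ey$n), mean(toy$yield),
               tolerance = 1e-12)
  # two samples sharing a triple average their yields
  two <- toy[c(1, 1), ]
  two$animal <- c("p", "q")
  two$yield <- c(0.4, 0.6)
  ey2 <- expected_yield_table(two)
  expect_equal(ey2$y_exp, 0.5)
  # one sample per triple: y_exp is that sample's yield
  one <- toy[!duplicated(paste(toy$segment, toy$day, toy$system)), ]
  ey1 <- expected_yield_table(one)
  expect_equal(sort(ey1$y_exp), sort(one$yield))
})

test_that("pair featurization equals the brute-force oracle on all pairs", {
  for (seed in 1:4) {
    n <- sample(4:10, 1)
    toy <- as_sample_table(toy_sample_table(n, seed = seed))
    for (scheme in c("reference-anchored", "query-anchored")) {
      pairs <- build_pair_dataset(toy, n_pairs = "all", seed = 1,
                                  scheme = scheme)
      expect_equal(nrow(pairs), n * (n - 1))
      toy_id <- paste(toy$animal, toy$segment, sep = "_")
      for (row in seq_len(nrow(pairs))) {
        qi <- match(pairs$query_id[row], toy_id)
        ri <- match(pairs$ref_id[row], toy_id)
        oracle <- bf_featurize(toy, qi, ri, scheme)
        got <- unlist(pairs[row, names(oracle)])
        expect_equal(unname(got), unname(oracle))
      }
    }
  }
})

test_that("single featurized pairs agree with the dataset construction", {
  toy <- as_sample_table(toy_sample_table(6, seed = 9))
  tabs <- ma_tables(toy)
  ey <- expected_yield_table(toy)
  one <- featurize_pair(toy[2, ], toy[5, ], tabs, ey)
  all_pairs <- build_pair_dataset(toy, "all", scheme = "reference-anchored")
  match_row <- all_pairs[all_pairs$query_id == one$query_id &
                           all_pairs$ref_id == one$ref_id, ]
  for (col in names(one)) {
    expect_equal(one[[col]], match_row[[col]])
  }

  # query-anchored self comparison: deviation from own level mean
  self <- featurize_pair(toy[2, ], toy[2, ], tabs, ey,
                         scheme = "query-anchored")
  seg <- as.character(toy$segment[2])
  expect_equal(self$dv1_s,
               toy$ghrelin[2] - bf_ma_mean(toy, "ghrelin", "segment", seg))
})

test_that("a single-level class makes its perturbation scheme-independent", {
  toy <- toy_sample_table(6, seed = 3)
  toy$system <- "L"
  toy$day <- 0L
  ra <- build_pair_dataset(toy, "all", scheme = "reference-anchored")
  qa <- build_pair_dataset(toy, "all", scheme = "query-anchored")
  expect_equal(ra$dv1_m, qa$dv1_m)
  expect_equal(ra$dv2_m, qa$dv2_m)
})

test_that("query-anchored perturbations average to zero within each level", {
  st <- generate_study(generator_config(), seed = 13)$samples
  # every sample appears as query; its dv is anchored at its own level
  all_q <- build_pair_dataset(st[1:40, ], "all", scheme = "query-anchored")
  seg_of_query <- sub("^.*_", "", all_q$query_id)
  one_per_query <- !duplicated(all_q$query_id)
  means <- tapply(all_q$dv1_s[one_per_query], seg_of_query[one_per_query], mean)
  expect_true(all(abs(means) < 1e-9))
})

test_that("pair capacity, duplicates, determinism and self-pair rules hold", {
  toy <- toy_sample_table(8, seed = 4)
  all_pairs <- build_pair_dataset(toy, "all")
  expect_equal(nrow(all_pairs), 8 * 7)
  expect_equal(anyDuplicated(paste(all_pairs$query_id, all_pairs$ref_id)), 0L)
  expect_true(all(all_pairs$query_id != all_pairs$ref_id))
  expect_true(all(table(all_pairs$query_id) == 7))

  with_self <- build_pair_dataset(toy, "all", include_self = TRUE)
  expect_equal(nrow(with_self), 64)

  s1 <- build_pair_dataset(toy, 20, seed = 7)
  s2 <- build_pair_dataset(toy, 20, seed = 7)
  s3 <- build_pair_dataset(toy, 20, seed = 8)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_false(identical(s1$query_id, s3$query_id))
  expect_equal(nrow(s3), 20)

  expect_error(build_pair_dataset(toy, 57), class = "emma_capacity_error")
  noy <- toy
  noy$yield <- NA_real_
  expect_error(build_pair_dataset(noy, 5), class = "emma_validation_error")
})

test_that("featurization is translation-equivariant", {
  toy <- toy_sample_table(7, seed = 6)
  base <- build_pair_dataset(toy, "all")
  shifted <- toy
  shifted$ghrelin <- shifted$ghrelin + 3
  moved <- build_pair_dataset(shifted, "all")
  expect_equal(moved$v1, base$v1 + 3)
  for (col in c("dv1_s", "dv1_t", "dv1_m", "dv2_s", "dv2_t", "dv2_m",
                "y_exp", "target")) {
    expect_equal(moved[[col]], base[[col]], tolerance = 1e-12)
  }
})

test_that("expected-value grid codes cells against the grand mean", {
  fx <- template_sample_table()
  grid <- expected_value_grid(fx, "ghr")
  expect_equal(nrow(grid), 8 * 3)
  expect_equal(grid$code[grid$segment == "abomasum" & grid$column == "L"], "+")
  expect_equal(grid$code[grid$segment == "rumen" & grid$column == "G"], "-")

  flat <- fx
  flat$ghr <- 0.5
  grid0 <- expected_value_grid(flat, "ghr")
  expect_true(all(grid0$code == "0"))
})
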