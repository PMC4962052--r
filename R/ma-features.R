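condition_classes <- function() c(segment = "segment", time = "day", system = "system")

class_column <- function(condition_class) {
  condition_class <- match.arg(condition_class, names(condition_classes()))
  unname(condition_classes()[condition_class])
}

#' Moving-average (Box-Jenkins) operator table
#'
#' The MA operator `<V_g(zeta_k)>` is the mean of a gene's relative
#' expression over all samples sharing one level of one experimental
#' condition class: GIT segment (8 levels), sampling time (7 days) or
#' feeding system. Perturbation features downstream are deviations from
#' these level means.
#'
#' The table satisfies conservation: the count-weighted mean of the level
#' means equals the grand mean of the input.
#'
#' @param samples A sample table.
#' @param gene `"ghrelin"` or `"ghr"`.
#' @param condition_class `"segment"`, `"time"` or `"system"`.
#' @return Tibble with columns `level`, `mean`, `n`; attributes `gene` and
#'   `condition_class`.
#' @export
ma_table <- function(samples, gene = c("ghrelin", "ghr"),
                     condition_class = c("segment", "time", "system")) {
  gene <- match.arg(gene)
  condition_class <- match.arg(condition_class)
  samples <- as_sample_table(samples)
  col <- class_column(condition_class)
  lev <- as.character(samples[[col]])
  v <- samples[[gene]]
  out <- tibble::tibble(level = lev, v = v)
  out <- dplyr::summarise(dplyr::group_by(out, .data$level),
                          mean = mean(.data$v), n = dplyr::n(),
                          .groups = "drop")
  out <- dplyr::arrange(out, match(.data$level, level_order(condition_class)))
  attr(out, "gene") <- gene
  attr(out, "condition_class") <- condition_class
  out
}

level_order <- function(condition_class) {
  switch(condition_class,
         segment = git_segments(),
         time = as.character(study_days()),
         system = feeding_systems())
}

#' All six MA tables of a study
#'
#' Convenience wrapper returning the MA operator tables for both genes and
#' all three condition classes, the form [featurize_pair()] consumes.
#'
#' @param samples A sample table.
#' @return Nested named list `tables[[gene]][[condition_class]]`.
#' @export
ma_tables <- function(samples) {
  samples <- as_sample_table(samples)
  purrr::map(setNames(study_genes(), study_genes()), function(g) {
    purrr::map(setNames(names(condition_classes()), names(condition_classes())),
               function(cc) ma_table(samples, g, cc))
  })
}

#' Expected yield per experimental-condition triple
#'
#' The expected yield `Y_exp` under a set of conditions is the mean
#' observed yield over all samples sharing the exact
#' (segment, day, system) triple.
#'
#' @param samples A sample table with yields.
#' @return Tibble with columns `segment`, `day`, `system`, `y_exp`, `n`.
#' @export
expected_yield_table <- function(samples) {
  samples <- as_sample_table(samples)
  if (any(is.na(samples$yield))) {
    abort("all samples need a yield to build the expected-yield table",
          class = "emma_validation_error")
  }
  dplyr::summarise(
    dplyr::group_by(samples, .data$segment, .data$day, .data$system),
    y_exp = mean(.data$yield), n = dplyr::n(), .groups = "drop"
  )
}

ma_lookup <- function(tables, gene, condition_class, levels) {
  tab <- tables[[gene]][[condition_class]]
  idx <- match(as.character(levels), tab$level)
  if (anyNA(idx)) {
    missing_lev <- unique(as.character(levels)[is.na(idx)])
    abort(sprintf("no MA level '%s' for gene %s, class %s",
                  missing_lev[1], gene, condition_class),
          class = "emma_featurization_error")
  }
  tab$mean[idx]
}

# vectorized core: query and reference are aligned sample tables
featurize_rows <- function(query, reference, tables, ey_table, scheme) {
  anchor <- if (scheme == "reference-anchored") reference else query
  ey_key <- paste(reference$segment, reference$day, reference$system)
  tab_key <- paste(ey_table$segment, ey_table$day, ey_table$system)
  idx <- match(ey_key, tab_key)
  if (anyNA(idx)) {
    abort(sprintf("no expected yield for condition triple (%s)",
                  ey_key[which(is.na(idx))[1]]),
          class = "emma_featurization_error")
  }
  feats <- tibble::tibble(
    query_id = query$sample_id,
    ref_id = reference$sample_id,
    y_exp = ey_table$y_exp[idx],
    v1 = query$ghrelin,
    v2 = query$ghr
  )
  for (g in c(1, 2)) {
    gene <- study_genes()[g]
    v <- query[[gene]]
    feats[[paste0("dv", g, "_s")]] <-
      v - ma_lookup(tables, gene, "segment", anchor$segment)
    feats[[paste0("dv", g, "_t")]] <-
      v - ma_lookup(tables, gene, "time", anchor$day)
    feats[[paste0("dv", g, "_m")]] <-
      v - ma_lookup(tables, gene, "system", anchor$system)
  }
  feats$target <- query$yield
  feats
}

#' Featurize one query/reference pair
#'
#' Builds one perturbation case from a query sample and a reference
#' sample: the expected yield `y_exp` at the reference's condition triple,
#' the query's expressions `v1` (Ghrelin) and `v2` (GHR), and the six
#' perturbation terms `dv{g}_{s,t,m}`. Under the default
#' `"reference-anchored"` scheme each perturbation is the query's
#' expression minus the MA operator at the *reference's* level of that
#' class; `"query-anchored"` substitutes the query's own level.
#' The target is the query's observed yield.
#'
#' @param query,reference One-row sample tables (with `sample_id` columns,
#'   see [build_pair_dataset()]; a missing `sample_id` is filled from
#'   animal and segment).
#' @param tables MA tables from [ma_tables()].
#' @param ey_table Expected-yield table from [expected_yield_table()].
#' @param scheme `"reference-anchored"` (default) or `"query-anchored"`.
#' @return One-row tibble with columns `query_id`, `ref_id`, `y_exp`,
#'   `v1`, `v2`, `dv1_s`, `dv1_t`, `dv1_m`, `dv2_s`, `dv2_t`, `dv2_m`,
#'   `target`.
#' @export
featurize_pair <- function(query, reference, tables, ey_table,
                           scheme = c("reference-anchored", "query-anchored")) {
  scheme <- match.arg(scheme)
  query <- ensure_sample_id(as_sample_table(query))
  reference <- ensure_sample_id(as_sample_table(reference))
  stopifnot(nrow(query) == 1, nrow(reference) == 1)
  featurize_rows(query, reference, tables, ey_table, scheme)
}

ensure_sample_id <- function(samples) {
  if (!"sample_id" %in% names(samples)) {
    samples$sample_id <- paste(samples$animal, samples$segment, sep = "_")
  }
  samples
}

#' Names of the perturbation-case feature columns
#'
#' The full view carries all ten input variables of the expanded linear
#' perturbation model; the `"grm"` view is the five-feature subset used by
#' the published general multilinear regression
#' (`y_exp`, `v1`, `dv2_s`, `dv2_t`, `dv2_m`).
#'
#' @param view `"grm"` or `"full"`.
#' @return Character vector of column names.
#' @export
pair_features <- function(view = c("grm", "full")) {
  view <- match.arg(view)
  if (view == "grm") {
    c("y_exp", "v1", "dv2_s", "dv2_t", "dv2_m")
  } else {
    c("y_exp", "v1", "v2", "dv1_s", "dv1_t", "dv1_m",
      "dv2_s", "dv2_t", "dv2_m")
  }
}

#' Build the two-block pairwise perturbation dataset
#'
#' Draws ordered (query, reference) pairs uniformly without replacement
#' from the `N (N - 1)` non-self pairs (self-pairs optionally included)
#' and featurizes each with [featurize_pair()]'s vectorized core. The MA
#' and expected-yield tables are computed from the full input table.
#'
#' @param samples A sample table with yields.
#' @param n_pairs Number of pairs, or `"all"` to enumerate every ordered
#'   pair.
#' @param seed Integer seed for the pair draw.
#' @param scheme Perturbation anchoring, see [featurize_pair()].
#' @param include_self Allow query == reference pairs (default `FALSE`).
#' @return Tibble of perturbation cases (class `emma_pairs`), one row per
#'   pair, with a `provenance` attribute recording the scheme, seed,
#'   requested size and source-table fingerprint.
#' @export
build_pair_dataset <- function(samples, n_pairs = "all", seed = 1,
                               scheme = c("reference-anchored", "query-anchored"),
                               include_self = FALSE) {
  scheme <- match.arg(scheme)
  samples <- ensure_sample_id(as_sample_table(samples))
  if (any(is.na(samples$yield))) {
    abort("all samples need a yield to build the pair dataset",
          class = "emma_validation_error")
  }
  n <- nrow(samples)
  capacity <- if (include_self) n * n else n * (n - 1)
  all_pairs <- identical(n_pairs, "all")
  if (!all_pairs) {
    n_pairs <- as.integer(n_pairs)
    if (n_pairs > capacity) {
      abort(sprintf("requested %d pairs but only %d ordered pairs exist",
                    n_pairs, capacity),
            class = "emma_capacity_error")
    }
  }
  idx <- if (all_pairs) seq_len(capacity) else {
    withr::with_seed(as.integer(seed), sort(sample.int(capacity, n_pairs)))
  }
  # decode linear index into (query, reference) without materializing the grid
  if (include_self) {
    q <- ((idx - 1L) %/% n) + 1L
    r <- ((idx - 1L) %% n) + 1L
  } else {
    q <- ((idx - 1L) %/% (n - 1L)) + 1L
    r <- ((idx - 1L) %% (n - 1L)) + 1L
    r <- r + (r >= q)  # skip the self slot
  }
  tables <- ma_tables(samples)
  ey <- expected_yield_table(samples)
  out <- featurize_rows(samples[q, ], samples[r, ], tables, ey, scheme)
  attr(out, "provenance") <- list(
    scheme = scheme,
    seed = if (all_pairs) NA_integer_ else as.integer(seed),
    n_requested = if (all_pairs) "all" else n_pairs,
    n_cases = nrow(out),
    n_samples = n,
    include_self = include_self,
    source_fingerprint = sum(samples$ghrelin) + sum(samples$ghr) +
      sum(samples$yield)
  )
  class(out) <- c("emma_pairs", class(out))
  out
}

#' Expected-value grid of GHR condition means
#'
#' Summarizes the MA expected values `<V_2>` per segment and
#' feeding-regime column (lactation, Supplemental, Grazing), coding each
#' cell as `"+"` / `"-"` / `"0"` according to whether it sits above,
#' below, or within `tolerance` of the grand mean -- the strong/poor
#' growth-yield effect coding of the published expected-value table.
#'
#' @param samples A sample table (or the template fixture).
#' @param gene Gene whose expectations are mapped (default `"ghr"`).
#' @param tolerance Half-width of the neutral band around the grand mean.
#' @return Tibble with one row per segment x column: `segment`, `column`,
#'   `mean`, `code`; the grand mean as attribute `grand_mean`.
#' @export
expected_value_grid <- function(samples, gene = c("ghr", "ghrelin"),
                                tolerance = 1e-12) {
  gene <- match.arg(gene)
  samples <- as_sample_table(samples)
  v <- samples[[gene]]
  grand <- mean(v)
  out <- tibble::tibble(segment = samples$segment,
                        column = as.character(samples$system), v = v)
  out <- dplyr::summarise(dplyr::group_by(out, .data$segment, .data$column),
                          mean = mean(.data$v), .groups = "drop")
  out$code <- dplyr::case_when(
    out$mean > grand + tolerance ~ "+",
    out$mean < grand - tolerance ~ "-",
    TRUE ~ "0"
  )
  out <- dplyr::arrange(out, .data$segment,
                        match(.data$column, c("L", "S", "G")))
  attr(out, "grand_mean") <- grand
  out
}
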