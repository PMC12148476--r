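rand_intervals <- function(seed, n, chrom_len = 200000L, max_len = 2000L,
                           ids = c("c1", "c2"), labels = NULL) {
  withr::with_seed(seed, {
    start <- sample.int(chrom_len - max_len, n)
    len <- sample.int(max_len, n)
    out <- tibble::tibble(
      seq_id = sample(ids, n, replace = TRUE),
      start = start, end = start + len
    ) |> dplyr::arrange(seq_id, start)
    if (!is.null(labels)) out$type_label <- sample(labels, n, replace = TRUE)
    out
  })
}

quadratic_pairs <- function(features, islands) {
  vapply(seq_len(nrow(features)), function(i) {
    sum(features$seq_id[i] == islands$seq_id &
          features$start[i] < islands$end &
          islands$start < features$end[i])
  }, numeric(1))
}

test_that("pair counting equals the quadratic all-pairs oracle", {
  for (seed in c(1, 2, 3)) {
    islands <- rand_intervals(seed, 400)
    islands$length <- islands$end - islands$start
    features <- rand_intervals(seed + 100, 600,
                               labels = c("roo", "opus", "INE-1", "gypsy"))
    rep <- overlap_report(islands, features)
    oracle <- tibble::tibble(type_label = features$type_label,
                             pairs = quadratic_pairs(features, islands)) |>
      dplyr::group_by(type_label) |>
      dplyr::summarise(total_count = dplyr::n(),
                       overlapping_pairs = sum(pairs))
    joined <- dplyr::left_join(rep, oracle, by = "type_label",
                               suffix = c("", "_oracle"))
    expect_equal(joined$total_count, joined$total_count_oracle)
    expect_equal(joined$overlapping_pairs, joined$overlapping_pairs_oracle)
  }
})

test_that("overlap percentages behave like the printed report arithmetic", {
  expect_equal(overlap_pct(388, 144), 269L)
  expect_equal(overlap_pct(68, 44), 155L)   # 154.5 rounds half away from zero
  expect_equal(overlap_pct(40, 44), 91L)

  # every shipped reference row satisfies pct == overlap_pct(pairs, total)
  te <- dm6_reference_te_overlap()
  expect_equal(overlap_pct(te$overlapping_pairs, te$total_count), te$pct)

  expect_equal(nrow(overlap_report(rand_intervals(1, 10), rand_intervals(2, 0,
    labels = character(0)))), 0L)

  # features strictly inside one island each: pct 100, pairs == total
  isl <- tibble::tibble(seq_id = "c1", start = c(0L, 5000L), end = c(2000L, 9000L),
                        length = c(2000L, 4000L))
  feats <- tibble::tibble(seq_id = "c1", start = c(100L, 5100L, 6000L),
                          end = c(200L, 5200L, 6400L), type_label = "te")
  rep <- overlap_report(isl, feats)
  expect_equal(rep$pct, 100L)
  expect_equal(rep$overlapping_pairs, rep$total_count)

  # touching intervals (half-open) do not overlap
  touch <- tibble::tibble(seq_id = "c1", start = 2000L, end = 2100L, type_label = "te")
  expect_equal(overlap_report(isl, touch)$overlapping_pairs, 0L)
})

test_that("percentages are invariant under joint renaming and translation", {
  islands <- rand_intervals(5, 200)
  islands$length <- islands$end - islands$start
  features <- rand_intervals(105, 300, labels = c("a", "b"))
  base <- overlap_report(islands, features)
  shift <- function(df) dplyr::mutate(df, seq_id = paste0("new_", seq_id),
                                      start = start + 777L, end = end + 777L)
  moved <- overlap_report(shift(islands), shift(features))
  expect_equal(base$pct, moved$pct)
  expect_equal(base$overlapping_pairs, moved$overlapping_pairs)
})

test_that("enrichment filtering applies both inclusive thresholds", {
  rep <- tibble::tibble(type_label = c("keep", "low_n", "low_pct"),
                        total_count = c(10L, 9L, 40L),
                        overlapping_pairs = c(8L, 9L, 20L),
                        pct = c(75L, 100L, 50L))
  kept <- filter_enriched(rep)
  expect_equal(kept$type_label, "keep")
  te <- dm6_reference_te_overlap()
  expect_equal(nrow(filter_enriched(te)), nrow(te))  # all top rows pass
})

test_that("permutation enrichment is seed-reproducible with sane limits", {
  cs <- tibble::tibble(seq_id = "c1", length = 10000L)
  isl <- tibble::tibble(seq_id = "c1", start = 0L, end = 10000L, length = 10000L)
  feats <- tibble::tibble(seq_id = "c1", start = c(100L, 4000L),
                          end = c(600L, 4400L), type_label = "te")
  full <- permutation_enrichment(isl, feats, cs, n_perm = 20, rng_seed = 3)
  expect_equal(full$fold, 1.0)  # island covers the chromosome: every shuffle identical

  none <- permutation_enrichment(
    dplyr::mutate(isl, end = 2000L, length = 2000L),
    feats[0, ], cs, n_perm = 20, rng_seed = 3)
  expect_equal(none$observed_bp, 0L)
  expect_equal(none$fold, 0)
  expect_equal(none$p_emp, 1.0)

  a <- permutation_enrichment(dplyr::mutate(isl, end = 2000L, length = 2000L),
                              feats, cs, n_perm = 50, rng_seed = 11)
  b <- permutation_enrichment(dplyr::mutate(isl, end = 2000L, length = 2000L),
                              feats, cs, n_perm = 50, rng_seed = 11)
  expect_identical(a$perm_bp, b$perm_bp)
  expect_identical(glance(a), glance(b))
  expect_gt(a$p_emp, 0)
  expect_lte(a$p_emp, 1)

  # islands shuffled onto themselves as features: observed is total island bp
  self <- permutation_enrichment(
    dplyr::mutate(isl, end = 3000L, length = 3000L),
    dplyr::mutate(isl, end = 3000L, length = 3000L, type_label = "self"),
    cs, n_perm = 5, rng_seed = 1)
  expect_equal(self$observed_bp, 3000L)

  too_big <- dplyr::mutate(isl, end = 20000L, length = 20000L)
  expect_error(permutation_enrichment(too_big, feats, cs), "longer")
})

test_that("a null configuration gives fold enrichment near one", {
  cs <- tibble::tibble(seq_id = "c1", length = 1000000L)
  isl <- tibble::tibble(seq_id = "c1",
                        start = seq(0L, 999000L, by = 2000L),
                        end = seq(0L, 999000L, by = 2000L) + 1000L)
  isl$length <- isl$end - isl$start          # 50% coverage
  feats <- withr::with_seed(21, {
    s <- sort(sample.int(990000L, 100L))
    tibble::tibble(seq_id = "c1", start = s, end = s + 1000L, type_label = "te")
  })                                          # ~10% coverage, independent
  e <- permutation_enrichment(isl, feats, cs, n_perm = 200, rng_seed = 9)
  expect_gte(e$fold, 0.8)
  expect_lte(e$fold, 1.25)
})

test_that("tidy and autoplot expose the permutation null", {
  cs <- tibble::tibble(seq_id = "c1", length = 50000L)
  isl <- tibble::tibble(seq_id = "c1", start = 1000L, end = 3000L, length = 2000L)
  feats <- tibble::tibble(seq_id = "c1", start = 1500L, end = 2500L, type_label = "te")
  e <- permutation_enrichment(isl, feats, cs, n_perm = 30, rng_seed = 2)
  td <- tidy(e)
  expect_equal(nrow(td), 30L)
  expect_equal(td$intersection_bp, e$perm_bp)
  expect_s3_class(autoplot(e), "ggplot")
})
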