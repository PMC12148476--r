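# Fixture builders shared across the suite. Everything is generated in code
# under fixed seeds; no files ship with the tests.

record_of <- function(seq, id = "fix") {
  tibble::tibble(seq_id = id, length = nchar(seq), seq = seq)
}

# A random row-stochastic 4x4 model; composition varies wildly from fixture
# to fixture so both CpX-rich and CpX-poor windows occur.
random_model <- function(seed) {
  withr::with_seed(seed, {
    tr <- matrix(stats::runif(16), 4, 4)
    tr <- tr / rowSums(tr)
    init <- stats::runif(4)
    markov_model(init / sum(init), tr)
  })
}

random_fixture <- function(seed, min_len = 2000L, max_len = 20000L) {
  len <- if (min_len == max_len) min_len else
    withr::with_seed(seed * 7L + 1L, sample(seq(min_len, max_len), 1L))
  generate_markov(random_model(seed), len, rng_seed = seed, seq_id = paste0("fix", seed))
}

revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), NULL)[[1L]]), collapse = "")
}

jaccard <- function(a_start, a_end, b_start, b_end) {
  inter <- max(0L, min(a_end, b_end) - max(a_start, b_start))
  inter / ((a_end - a_start) + (b_end - b_start) - inter)
}

# Covered-bp total of an island tibble.
covered_bp <- function(islands) sum(islands$length)

# Structural invariants every detection result must satisfy.
expect_island_invariants <- function(islands, params) {
  for (sid in unique(islands$seq_id)) {
    isl <- islands[islands$seq_id == sid, ]
    expect_false(is.unsorted(isl$start, strictly = TRUE))
    expect_true(all(isl$length >= params$window_size))
    expect_equal(isl$length, isl$end - isl$start)
    if (nrow(isl) > 1L) {
      gaps <- isl$start[-1L] - isl$end[-nrow(isl)]
      expect_true(all(gaps > params$max_merge_gap))
    }
  }
  invisible(islands)
}
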