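# Island / annotation-feature overlap reporting and a permutation-based
# enrichment control. The overlap predicate is >= 1 bp intersection in
# 0-based half-open coordinates (touching intervals do not overlap).

round_half_up <- function(x) floor(x + 0.5)

#' Percent of features overlapped, feature-island pairs over feature total
#'
#' The percentage printed in overlap reports:
#' `round(pairs / total * 100)`, rounding halves away from zero. Because one
#' feature locus can overlap several islands, values above 100 are possible.
#'
#' @param overlapping_pairs Number of (feature, island) pairs with >= 1 bp
#'   intersection.
#' @param total_count Number of features of the type.
#' @return Integer percentage.
#' @examples
#' overlap_pct(388, 144)  # 269
#' @export
overlap_pct <- function(overlapping_pairs, total_count) {
  as.integer(round_half_up(overlapping_pairs / total_count * 100))
}

#' Per-type overlap report between islands and annotation features
#'
#' For every feature type: the number of features, the number of
#' (feature, island) pairs sharing at least 1 bp, and the pair percentage
#' (see [overlap_pct()]).
#'
#' @param islands Island tibble, sorted per chromosome.
#' @param features Feature tibble (`seq_id`, `start`, `end`, `type_label`),
#'   sorted per chromosome (see [read_features()]).
#' @return Tibble with columns `type_label`, `total_count`,
#'   `overlapping_pairs`, `pct`, one row per type in first-appearance order;
#'   empty when there are no features.
#' @export
overlap_report <- function(islands, features) {
  if (nrow(features) == 0L) {
    return(tibble(type_label = character(0), total_count = integer(0),
                  overlapping_pairs = integer(0), pct = integer(0)))
  }
  levels <- unique(c(features$seq_id, islands$seq_id))
  feat_gr <- GenomicRanges::GRanges(
    seqnames = factor(features$seq_id, levels = levels),
    ranges = IRanges::IRanges(features$start + 1L, features$end))
  isl_gr <- GenomicRanges::GRanges(
    seqnames = factor(islands$seq_id, levels = levels),
    ranges = IRanges::IRanges(islands$start + 1L, islands$end))
  hits <- GenomicRanges::countOverlaps(feat_gr, isl_gr)
  tibble(type_label = features$type_label, pairs = hits) |>
    group_by(.data$type_label) |>
    summarise(total_count = dplyr::n(),
              overlapping_pairs = as.integer(sum(.data$pairs))) |>
    dplyr::slice(match(unique(features$type_label), .data$type_label)) |>
    mutate(pct = overlap_pct(.data$overlapping_pairs, .data$total_count))
}

#' Filter an overlap report for enriched feature types
#'
#' Keeps rows whose percentage and feature total meet both (inclusive)
#' thresholds; the defaults (75% and 10 features) are the conventional cut
#' for calling a type enriched while avoiding chance overlaps of rare types.
#'
#' @param report Tibble from [overlap_report()].
#' @param min_pct Minimum percentage (default 75).
#' @param min_total Minimum feature count (default 10).
#' @return The qualifying subset.
#' @export
filter_enriched <- function(report, min_pct = 75, min_total = 10) {
  filter(report, .data$pct >= min_pct, .data$total_count >= min_total)
}

union_bp <- function(df, levels) {
  if (nrow(df) == 0L) return(GenomicRanges::GRanges(seqnames = factor(character(0), levels = levels), ranges = IRanges::IRanges()))
  GenomicRanges::reduce(GenomicRanges::GRanges(
    seqnames = factor(df$seq_id, levels = levels),
    ranges = IRanges::IRanges(df$start + 1L, df$end)))
}

intersection_bp <- function(a, b, levels) {
  ga <- union_bp(a, levels); gb <- union_bp(b, levels)
  sum(IRanges::width(GenomicRanges::intersect(ga, gb)))
}

#' Permutation-based overlap enrichment
#'
#' Compares the observed intersection (in bp, between the union of islands
#' and the union of features) with a null distribution obtained by
#' relocating every island uniformly at random on its own chromosome
#' (lengths preserved; shuffled islands may overlap each other). The fold
#' enrichment is observed over mean permuted intersection, and the
#' empirical p-value is `(1 + #{permutations >= observed}) / (n_perm + 1)`.
#'
#' @param islands Island tibble.
#' @param features Feature tibble (`seq_id`, `start`, `end`, ...).
#' @param chrom_sizes Tibble with `seq_id`, `length` covering every island
#'   chromosome.
#' @param n_perm Number of permutations (default 100).
#' @param rng_seed Integer seed; the result is reproducible given the seed.
#' @return An object of class `cpx_enrichment`: a list with `observed_bp`,
#'   `perm_bp` (length `n_perm`), `mean_permuted_bp`, `fold` (0 when the
#'   observed intersection is 0; `Inf` when only the permuted mean is 0),
#'   `p_emp`, `n_perm`, `rng_seed`. Use [tidy()] / [glance()] /
#'   [autoplot()] on it.
#' @export
permutation_enrichment <- function(islands, features, chrom_sizes,
                                   n_perm = 100L, rng_seed = 1L) {
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L) abort("`n_perm` must be >= 1")
  len_of <- stats::setNames(chrom_sizes$length, chrom_sizes$seq_id)
  unknown <- setdiff(islands$seq_id, names(len_of))
  if (length(unknown)) abort(sprintf("island on unknown chromosome: %s", unknown[1L]))
  space <- unname(len_of[islands$seq_id]) - islands$length
  if (any(space < 0L)) abort("island longer than its chromosome")
  levels <- unique(c(chrom_sizes$seq_id, features$seq_id))
  observed <- intersection_bp(islands, features, levels)
  perm_bp <- withr::with_seed(rng_seed, {
    vapply(seq_len(n_perm), function(i) {
      new_start <- floor(stats::runif(nrow(islands)) * (space + 1L))
      shuf <- tibble(seq_id = islands$seq_id,
                     start = as.integer(pmin(new_start, space)),
                     end = as.integer(pmin(new_start, space)) + islands$length)
      intersection_bp(shuf, features, levels)
    }, numeric(1))
  })
  mean_perm <- mean(perm_bp)
  fold <- if (observed == 0) 0 else if (mean_perm == 0) Inf else observed / mean_perm
  structure(
    list(observed_bp = observed, perm_bp = perm_bp,
         mean_permuted_bp = mean_perm, fold = fold,
         p_emp = (1 + sum(perm_bp >= observed)) / (n_perm + 1),
         n_perm = n_perm, rng_seed = rng_seed),
    class = "cpx_enrichment"
  )
}

#' @export
print.cpx_enrichment <- function(x, ...) {
  cat("Permutation overlap enrichment\n")
  cat(sprintf("  observed intersection : %s bp\n", format(x$observed_bp, big.mark = ",")))
  cat(sprintf("  mean permuted         : %s bp (%d permutations, seed %d)\n",
              format(round(x$mean_permuted_bp, 1), big.mark = ","), x$n_perm, x$rng_seed))
  cat(sprintf("  fold enrichment       : %s\n", format(x$fold, digits = 4)))
  cat(sprintf("  empirical p           : %.4g\n", x$p_emp))
  invisible(x)
}

#' @rdname permutation_enrichment
#' @param x A `cpx_enrichment` object.
#' @param ... Unused.
#' @export
tidy.cpx_enrichment <- function(x, ...) {
  tibble(permutation = seq_len(x$n_perm), intersection_bp = x$perm_bp)
}

#' @rdname permutation_enrichment
#' @export
glance.cpx_enrichment <- function(x, ...) {
  tibble(observed_bp = x$observed_bp, mean_permuted_bp = x$mean_permuted_bp,
         fold = x$fold, p_emp = x$p_emp, n_perm = x$n_perm,
         rng_seed = x$rng_seed)
}

#' @rdname permutation_enrichment
#' @param object A `cpx_enrichment` object.
#' @export
autoplot.cpx_enrichment <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$intersection_bp)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed_bp,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(
      x = "island/feature intersection (bp)", y = "permutations",
      title = "Observed overlap vs permutation null",
      subtitle = sprintf("fold = %s, empirical p = %.3g",
                         format(object$fold, digits = 3), object$p_emp)
    ) +
    ggplot2::theme_minimal()
}
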