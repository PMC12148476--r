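# Per-chromosome and genome-wide island statistics, long-island subsets,
# and island shores.

#' Frequency and coverage rates from island counts
#'
#' Pure arithmetic shared by [summarize_islands()] and usable directly on a
#' published count table: islands per 1000 bp and percent of the chromosome
#' covered.
#'
#' @param df Tibble with columns `count` (islands), `total_bp` (bp covered
#'   by islands) and `chrom_length` (bp).
#' @return `df` with `freq_per_kb` and `coverage_pct` columns added.
#' @examples
#' island_rates(tibble::tibble(count = 3066, total_bp = 3407151,
#'                             chrom_length = 23542271))
#' @export
island_rates <- function(df) {
  dplyr::mutate(df,
    freq_per_kb = .data$count / .data$chrom_length * 1000,
    coverage_pct = .data$total_bp / .data$chrom_length * 100
  )
}

pooled_median <- function(x) if (length(x)) stats::median(x) else NA_real_

#' Summarize islands per chromosome and genome-wide
#'
#' One row per chromosome (in `chrom_sizes` order) plus a `total` row. The
#' count is summed over chromosomes for the total row; its median is taken
#' over all islands pooled. The median of an even number of lengths is the
#' mean of the two middle values. Chromosomes without islands get count 0,
#' frequency 0, coverage 0 and an undefined (`NA`) median.
#'
#' @param islands Island tibble (sorted, non-overlapping per sequence).
#' @param chrom_sizes Tibble with `seq_id`, `length` (see
#'   [read_chrom_sizes()] / [chrom_sizes()]).
#' @return Tibble with columns `seq_id`, `chrom_length`, `count`,
#'   `total_bp`, `median_length`, `freq_per_kb`, `coverage_pct`.
#' @export
summarize_islands <- function(islands, chrom_sizes) {
  unknown <- setdiff(islands$seq_id, chrom_sizes$seq_id)
  if (length(unknown)) {
    abort(sprintf("island on unknown chromosome: %s", unknown[1L]))
  }
  per <- islands |>
    group_by(.data$seq_id) |>
    summarise(count = dplyr::n(),
              total_bp = sum(.data$length),
              median_length = pooled_median(.data$length))
  out <- chrom_sizes |>
    dplyr::rename(chrom_length = "length") |>
    left_join(per, by = "seq_id") |>
    mutate(count = dplyr::coalesce(.data$count, 0L),
           total_bp = dplyr::coalesce(.data$total_bp, 0L)) |>
    island_rates()
  total <- tibble(
    seq_id = "total",
    chrom_length = sum(out$chrom_length),
    count = sum(out$count),
    total_bp = sum(out$total_bp),
    median_length = pooled_median(islands$length)
  ) |> island_rates()
  bind_rows(out, total)
}

#' Write a summary table as TSV
#'
#' Rounds for presentation the way summary tables are usually printed:
#' frequency to 3 decimals, coverage to 1 decimal, medians to integer bp.
#'
#' @param summary Tibble from [summarize_islands()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(summary, path) {
  out <- summary |>
    mutate(median_length = round(.data$median_length),
           freq_per_kb = round(.data$freq_per_kb, 3),
           coverage_pct = round(.data$coverage_pct, 1))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Keep only islands at least `min_len` bp long
#'
#' @param islands Island tibble.
#' @param min_len Inclusive length threshold in bp (the long-island subsets
#'   use 3000).
#' @return The qualifying subset, input order preserved.
#' @export
filter_min_length <- function(islands, min_len = 3000L) {
  if (min_len < 0L) abort("`min_len` must be >= 0")
  filter(islands, .data$length >= min_len)
}

#' Median island length of a chromosome group versus the rest
#'
#' Splits islands into those on the given chromosomes and all others and
#' returns the median length of each group (e.g. chromosome Y CpA islands
#' versus the remaining chromosomes).
#'
#' @param islands Island tibble.
#' @param group_ids Character vector of `seq_id`s forming the first group.
#' @return A tibble with one row: `median_group`, `median_rest`, `n_group`,
#'   `n_rest`.
#' @export
group_median_lengths <- function(islands, group_ids) {
  in_group <- islands$seq_id %in% group_ids
  if (!any(in_group) || all(in_group)) {
    abort("both chromosome groups must contain at least one island")
  }
  tibble(
    median_group = stats::median(islands$length[in_group]),
    median_rest = stats::median(islands$length[!in_group]),
    n_group = sum(in_group),
    n_rest = sum(!in_group)
  )
}

granges_from_intervals <- function(df, chrom_sizes = NULL) {
  seqlengths <- NULL
  seqnames_levels <- unique(df$seq_id)
  if (!is.null(chrom_sizes)) {
    seqnames_levels <- chrom_sizes$seq_id
    seqlengths <- stats::setNames(chrom_sizes$length, chrom_sizes$seq_id)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = factor(df$seq_id, levels = seqnames_levels),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
  if (!is.null(seqlengths)) GenomeInfoDb_safe_seqlengths(gr, seqlengths) else gr
}

GenomeInfoDb_safe_seqlengths <- function(gr, seqlengths) {
  GenomeInfoDb::seqinfo(gr) <- GenomeInfoDb::Seqinfo(
    seqnames = names(seqlengths), seqlengths = unname(seqlengths))
  gr
}

intervals_from_granges <- function(gr) {
  tibble(
    seq_id = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr)
  )
}

#' Compute island shores
#'
#' Shores are the flanking regions `flank` bp upstream and downstream of
#' each island (2 kb by convention), clipped to the chromosome, with all
#' island bodies subtracted and overlapping shore fragments merged. Usually
#' applied to a long-island subset but generic over any island list.
#'
#' @param islands Island tibble (sorted, non-overlapping per sequence).
#' @param chrom_sizes Tibble with `seq_id`, `length`.
#' @param flank Flank width in bp (default 2000).
#' @return Tibble of shore intervals (`seq_id`, `start`, `end`), 0-based
#'   half-open, disjoint from every island body.
#' @export
compute_shores <- function(islands, chrom_sizes, flank = 2000L) {
  if (nrow(islands) == 0L) {
    return(tibble(seq_id = character(0), start = integer(0), end = integer(0)))
  }
  unknown <- setdiff(islands$seq_id, chrom_sizes$seq_id)
  if (length(unknown)) abort(sprintf("island on unknown chromosome: %s", unknown[1L]))
  bodies <- granges_from_intervals(islands, chrom_sizes)
  up <- tibble(seq_id = islands$seq_id,
               start = pmax(0L, islands$start - as.integer(flank)),
               end = islands$start)
  down_len <- stats::setNames(chrom_sizes$length, chrom_sizes$seq_id)[islands$seq_id]
  down <- tibble(seq_id = islands$seq_id,
                 start = islands$end,
                 end = pmin(unname(down_len), islands$end + as.integer(flank)))
  flanks <- bind_rows(up, down) |> filter(.data$start < .data$end)
  if (nrow(flanks) == 0L) {
    return(tibble(seq_id = character(0), start = integer(0), end = integer(0)))
  }
  shore_gr <- GenomicRanges::setdiff(
    GenomicRanges::reduce(granges_from_intervals(flanks, chrom_sizes)),
    GenomicRanges::reduce(bodies)
  )
  out <- intervals_from_granges(shore_gr)
  out[out$seq_id %in% islands$seq_id, , drop = FALSE] |>
    arrange(factor(.data$seq_id, levels = unique(islands$seq_id)), .data$start)
}
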