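# Previously reported whole-genome island statistics for the D. melanogaster
# dm6 assembly (Release 6 plus ISO1 MT, GCF_000001215.4) under the default
# detection parameters. Shipped as plain-text tables for worked examples and
# arithmetic consistency checks; the genome itself is not distributed.

#' Reported per-chromosome dm6 island statistics
#'
#' Count, covered bp and (where available) median length of CpG, CpA and
#' CpT islands per dm6 chromosome, with chromosome lengths, from a
#' whole-genome run with the default parameters. Frequencies and coverages
#' are *not* stored: derive them with [island_rates()].
#'
#' @return Tibble with columns `island_type`, `seq_id`, `chrom_length`,
#'   `count`, `total_bp`, `median_length` (NA where not available).
#' @examples
#' dm6_reference_summary() |>
#'   dplyr::filter(island_type == "CpG", seq_id == "X") |>
#'   island_rates()
#' @export
dm6_reference_summary <- function() {
  path <- system.file("extdata", "dm6_reference_summary.tsv",
                      package = "cpxscan", mustWork = TRUE)
  readr::read_tsv(path, col_types = "ccdiii", progress = FALSE)
}

#' Reported genome-wide dm6 island statistics
#'
#' Genome totals per island type: island count, median length, and the
#' count of long (>= 3000 bp) islands.
#'
#' @return Tibble with columns `island_type`, `count`, `median_length`,
#'   `long_count`.
#' @export
dm6_reference_genome <- function() {
  path <- system.file("extdata", "dm6_reference_genome.tsv",
                      package = "cpxscan", mustWork = TRUE)
  readr::read_tsv(path, col_types = "ciii", progress = FALSE)
}

#' Reported top enriched transposable-element overlaps in dm6
#'
#' The most enriched TE families per island type: family label, total
#' feature count, overlapping (feature, island) pair count, and the
#' reported integer percentage.
#'
#' @return Tibble with columns `island_type`, `type_label`, `total_count`,
#'   `overlapping_pairs`, `pct`.
#' @export
dm6_reference_te_overlap <- function() {
  path <- system.file("extdata", "dm6_reference_te_overlap.tsv",
                      package = "cpxscan", mustWork = TRUE)
  readr::read_tsv(path, col_types = "cciii", progress = FALSE)
}
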