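# FASTA input and BED/BedGraph/CSV output. Internal and BED/BedGraph
# coordinates are 0-based half-open; the CSV export is 1-based inclusive
# (genome-browser style).

normalize_seq <- function(s) {
  s <- toupper(s)
  gsub("[^ACGTN]", "N", s)
}

#' Read genome sequences from a FASTA file
#'
#' Reads a (multi-record) FASTA file into a sequence tibble. Sequences are
#' uppercased, whitespace is dropped, and any character outside
#' `{A, C, G, T, N}` (IUPAC ambiguity codes, gaps, ...) is mapped to `N`.
#' The record id is the first whitespace-delimited token of the header.
#'
#' @param path Path to a FASTA (or headerless plain-text) file.
#' @return A tibble with columns `seq_id`, `length` (bp) and `seq`, in file
#'   order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(sprintf("no FASTA records in %s", path))
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) abort("FASTA record with empty header")
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate sequence id: %s", ids[duplicated(ids)][1L]))
  }
  seqs <- unname(normalize_seq(gsub("\\s", "", as.character(set))))
  if (any(!nzchar(seqs))) {
    abort(sprintf("record '%s' has no sequence", ids[!nzchar(seqs)][1L]))
  }
  tibble(seq_id = unname(ids), length = nchar(seqs), seq = unname(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Sequence tibble (`seq_id`, `seq`).
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    writeLines(paste0(">", seqs$seq_id[i]), con)
    s <- seqs$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a chromosome-sizes table
#'
#' Two-column tab-separated file: sequence id, length in bp.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `seq_id`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  tab <- readr::read_tsv(path, col_names = c("seq_id", "length"),
                         col_types = "ci", progress = FALSE)
  if (any(tab$length <= 0L)) abort("chromosome lengths must be positive")
  if (anyDuplicated(tab$seq_id)) abort("duplicate ids in chromosome-sizes table")
  tab
}

#' Derive a chromosome-sizes table from loaded sequences
#'
#' @param seqs Sequence tibble from [read_fasta()].
#' @return A tibble with columns `seq_id`, `length`.
#' @export
chrom_sizes <- function(seqs) {
  tibble(seq_id = seqs$seq_id, length = seqs$length)
}

check_sorted_islands <- function(islands) {
  if (nrow(islands) < 2L) return(invisible(TRUE))
  blocks <- rle(islands$seq_id)$values
  if (anyDuplicated(blocks)) abort("islands must be grouped by seq_id")
  by_chrom <- split(islands$start, factor(islands$seq_id, levels = blocks))
  if (any(vapply(by_chrom, is.unsorted, logical(1)))) {
    abort("islands must be sorted by start within each seq_id")
  }
  invisible(TRUE)
}

#' Write islands as BED4+3
#'
#' Tab-separated, no header: chrom, start (0-based), end (half-open), name
#' (`Cp<X>_<n>`), CX fraction, O/E ratio, length. Input must already be
#' sorted by (`seq_id`, `start`); sorting is the caller's job.
#'
#' @param islands Island tibble from [detect_islands()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(islands, path) {
  check_sorted_islands(islands)
  nt <- if (nrow(islands)) islands$second_nt else character(0)
  lines <- sprintf("%s\t%d\t%d\tCp%s_%d\t%.4f\t%.4f\t%d",
                   islands$seq_id, islands$start, islands$end,
                   nt, seq_len(nrow(islands)),
                   islands$cx_percent, islands$oe_ratio, islands$length)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED4+3 island file back into a tibble
#'
#' @param path Path written by [write_bed()].
#' @return Tibble with columns `seq_id`, `start`, `end`, `name`,
#'   `cx_percent`, `oe_ratio`, `length`.
#' @export
read_bed <- function(path) {
  readr::read_tsv(path,
                  col_names = c("seq_id", "start", "end", "name",
                                "cx_percent", "oe_ratio", "length"),
                  col_types = "ciicddi", progress = FALSE)
}

#' Write islands in strict BedGraph format
#'
#' Four tab-separated columns: chrom, start, end (0-based half-open) and one
#' selectable value column, formatted to 4 decimals.
#'
#' @inheritParams write_bed
#' @param value_field Which statistic to emit: `"cx_percent"` or
#'   `"oe_ratio"`.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(islands, path, value_field = c("cx_percent", "oe_ratio")) {
  value_field <- match.arg(value_field)
  check_sorted_islands(islands)
  lines <- sprintf("%s\t%d\t%d\t%.4f",
                   islands$seq_id, islands$start, islands$end,
                   islands[[value_field]])
  writeLines(lines, path)
  invisible(path)
}

#' Write islands as CSV with 1-based inclusive coordinates
#'
#' Header row then one row per island: `seq_id`, `start_1based`,
#' `end_1based` (inclusive), `sequence_preview` (the first
#' `seq_preview_len` bases, suffixed with an ellipsis when truncated),
#' `cx_percent`, `oe_ratio`, `length_bp`.
#'
#' @inheritParams write_bed
#' @param seqs Sequence tibble from [read_fasta()] supplying the island
#'   sequence text.
#' @param seq_preview_len Preview length in bases (default 40).
#' @return `path`, invisibly.
#' @export
write_islands_csv <- function(islands, path, seqs, seq_preview_len = 40L) {
  check_sorted_islands(islands)
  seq_of <- stats::setNames(seqs$seq, seqs$seq_id)
  missing <- setdiff(islands$seq_id, names(seq_of))
  if (length(missing)) abort(sprintf("no sequence available for %s", missing[1L]))
  full <- substr(seq_of[islands$seq_id], islands$start + 1L, islands$end)
  preview <- ifelse(nchar(full) > seq_preview_len,
                    paste0(substr(full, 1L, seq_preview_len), "…"),
                    full)
  out <- tibble(
    seq_id = islands$seq_id,
    start_1based = islands$start + 1L,
    end_1based = islands$end,
    sequence_preview = unname(preview),
    cx_percent = islands$cx_percent,
    oe_ratio = islands$oe_ratio,
    length_bp = islands$length
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read annotation features from a BED file
#'
#' Expects at least 4 columns: chrom, start, end (0-based half-open) and a
#' feature type label (for example a transposable-element family name).
#'
#' @param path BED file path.
#' @return Tibble with columns `seq_id`, `start`, `end`, `type_label`.
#' @export
read_features <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("seq_id", "start", "end", "type_label"),
                           colClasses = c("character", "integer", "integer", "character"),
                           fill = FALSE)
  out <- as_tibble(tab)
  if (any(out$start >= out$end)) abort("feature with start >= end")
  if (any(!nzchar(out$type_label))) abort("feature with empty type label")
  out
}
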