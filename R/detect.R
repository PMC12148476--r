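# Core sliding-window island detector. Coordinates are 0-based half-open
# throughout; a window of width W starting at s covers bases [s, s + W).

# Pull the sequence string out of a record (one-row tibble from read_fasta()
# or any list with a `seq` element).
record_seq <- function(record) {
  if (is.character(record) && length(record) == 1L) return(record)
  if (is.null(record$seq)) abort("`record` must carry a `seq` field.")
  if (length(record$seq) != 1L) abort("`record` must be a single sequence record.")
  record$seq
}

record_id <- function(record) {
  if (!is.null(record$seq_id) && length(record$seq_id) == 1L) record$seq_id else "seq"
}

# Prefix-sum index over one sequence: O(1) counts for any span.
cpx_index <- function(seq, x) {
  b <- strsplit(seq, NULL)[[1L]]
  n <- length(b)
  is_c <- b == "C"
  is_x <- b == x
  pair <- if (n >= 2L) is_c[-n] & is_x[-1L] else logical(0)
  list(n = n, x = x,
       cum_c = c(0L, cumsum(is_c)),
       cum_x = c(0L, cumsum(is_x)),
       cum_p = c(0L, cumsum(pair)))
}

# Raw counts over [start, end), 0-based half-open.
span_counts <- function(idx, start, end) {
  list(
    c = idx$cum_c[end + 1L] - idx$cum_c[start + 1L],
    x = idx$cum_x[end + 1L] - idx$cum_x[start + 1L],
    p = if (end - start >= 2L) idx$cum_p[end] - idx$cum_p[start + 1L] else 0L
  )
}

stats_row <- function(c_count, x_count, cpx_count, span_len, x) {
  x_eff <- if (x == "C") c_count else x_count
  cx <- if (x == "C") c_count / span_len else (c_count + x_count) / span_len
  oe <- if (c_count > 0L && x_eff > 0L) cpx_count * span_len / (c_count * x_eff) else 0
  tibble(
    c_count = as.integer(c_count), x_count = as.integer(x_count),
    cpx_count = as.integer(cpx_count), span_len = as.integer(span_len),
    cx_percent = cx, oe_ratio = oe
  )
}

span_qualifies <- function(idx, start, end, params) {
  cnt <- span_counts(idx, start, end)
  x_eff <- if (idx$x == "C") cnt$c else cnt$x
  cx <- if (idx$x == "C") cnt$c / (end - start) else (cnt$c + cnt$x) / (end - start)
  oe <- if (cnt$c > 0L && x_eff > 0L) cnt$p * (end - start) / (cnt$c * x_eff) else 0
  cx >= params$min_cx && oe >= params$min_oe
}

#' Base and dinucleotide statistics over a sequence span
#'
#' Counts cytosines, the chosen second nucleotide X, and overlapping CpX
#' dinucleotide occurrences fully inside `[start, end)` (0-based half-open),
#' and derives the CX fraction and the observed/expected CpX ratio. `N` bases
#' count as neither C nor X and dinucleotides containing `N` never count.
#' When both counts in the expected-value denominator are zero the O/E ratio
#' is defined as 0. For `x = "C"`, overlapping CpC pairs are counted (so
#' `"CCC"` contains two) and the expected count uses `count(C)^2 / N`.
#'
#' @param record A one-row tibble with a `seq` column (see [read_fasta()]),
#'   or a plain sequence string.
#' @param start,end Span in 0-based half-open coordinates.
#' @param x Second nucleotide, one of `"G"`, `"A"`, `"T"`, `"C"`.
#' @return A one-row tibble with columns `c_count`, `x_count`, `cpx_count`,
#'   `span_len`, `cx_percent` (a fraction in `[0, 1]`), `oe_ratio`.
#' @examples
#' window_stats("CGCGATCGAT", 0, 10, x = "G")
#' @export
window_stats <- function(record, start, end, x = c("G", "A", "T", "C")) {
  x <- match.arg(x)
  seq <- record_seq(record)
  n <- nchar(seq)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end > n || start >= end) {
    abort(sprintf("span [%s, %s) out of range for a %d bp sequence", start, end, n))
  }
  idx <- cpx_index(seq, x)
  cnt <- span_counts(idx, start, end)
  stats_row(cnt$c, cnt$x, cnt$p, end - start, x)
}

#' Shift a window's statistics one base to the right
#'
#' Constant-work rolling update: given the statistics of the window starting
#' at `old_start`, returns the statistics of the window starting at
#' `old_start + 1`, identical to recomputing [window_stats()] from scratch.
#'
#' @param stats One-row tibble as returned by [window_stats()].
#' @param record Sequence record or string the stats were computed on.
#' @param old_start 0-based start of the window `stats` describes.
#' @inheritParams window_stats
#' @return A one-row tibble of the same shape as [window_stats()].
#' @export
shift_stats <- function(stats, record, old_start, x = c("G", "A", "T", "C")) {
  x <- match.arg(x)
  seq <- record_seq(record)
  n <- nchar(seq)
  w <- stats$span_len
  old_start <- as.integer(old_start)
  if (old_start + 1L + w > n) abort("cannot shift: window would pass the sequence end")
  ch <- function(i) substr(seq, i + 1L, i + 1L)  # 0-based lookup
  pair_at <- function(i) (ch(i) == "C") && (ch(i + 1L) == x)
  c_count <- stats$c_count - (ch(old_start) == "C") + (ch(old_start + w) == "C")
  x_count <- stats$x_count - (ch(old_start) == x) + (ch(old_start + w) == x)
  cpx <- stats$cpx_count - pair_at(old_start) + pair_at(old_start + w - 1L)
  stats_row(c_count, x_count, cpx, w, x)
}

#' Does a window qualify as island material?
#'
#' Both thresholds are inclusive: a window qualifies iff
#' `cx_percent >= min_cx` and `oe_ratio >= min_oe`.
#'
#' @param stats One-row tibble from [window_stats()], computed with
#'   `params$x` as second nucleotide.
#' @param params A [detection_params()] object.
#' @return Logical scalar.
#' @export
qualifies <- function(stats, params = detection_params()) {
  stats$cx_percent >= params$min_cx && stats$oe_ratio >= params$min_oe
}

# Vectorized qualification over all window starts (the production scan path;
# numerically identical to per-window recomputation).
mask_from_index <- function(idx, params) {
  n <- idx$n; w <- params$window_size
  if (n < w) return(logical(0))
  s1 <- seq_len(n - w + 1L)               # 1-based window starts
  c_count <- idx$cum_c[s1 + w] - idx$cum_c[s1]
  x_count <- idx$cum_x[s1 + w] - idx$cum_x[s1]
  p_count <- idx$cum_p[s1 + w - 1L] - idx$cum_p[s1]
  x_eff <- if (idx$x == "C") c_count else x_count
  cx <- if (idx$x == "C") c_count / w else (c_count + x_count) / w
  oe <- ifelse(c_count > 0L & x_eff > 0L, p_count * w / (c_count * x_eff), 0)
  cx >= params$min_cx & oe >= params$min_oe
}

#' Per-position window qualification mask
#'
#' Element `i` is `TRUE` iff the window `[i - 1, i - 1 + W)` (0-based)
#' satisfies both island thresholds.
#'
#' @inheritParams window_stats
#' @param params A [detection_params()] object.
#' @return Logical vector of length `length - window_size + 1` (empty when
#'   the sequence is shorter than one window).
#' @export
qualification_mask <- function(record, params = detection_params()) {
  idx <- cpx_index(record_seq(record), params$x)
  mask_from_index(idx, params)
}

#' Find the next seed window
#'
#' Returns the smallest 0-based start `s >= from_pos` whose window qualifies,
#' or `NA` if none exists.
#'
#' @inheritParams qualification_mask
#' @param from_pos 0-based position the search starts from.
#' @return Integer position or `NA_integer_`.
#' @export
find_seed <- function(record, from_pos = 0L, params = detection_params()) {
  from_pos <- max(0L, as.integer(from_pos))
  mask <- qualification_mask(record, params)
  if (from_pos + 1L > length(mask)) return(NA_integer_)
  hit <- which(mask[(from_pos + 1L):length(mask)])
  if (!length(hit)) NA_integer_ else from_pos + hit[1L] - 1L
}

# Jump-extension with rollback. mask indexed 1-based by window start + 1.
extend_from_seed <- function(mask, seed, w, max_start) {
  cur <- seed
  repeat {
    nxt <- cur + w
    if (nxt <= max_start && mask[nxt + 1L]) {
      cur <- nxt
      next
    }
    e <- cur + w
    t <- min(nxt - 1L, max_start)      # failed window may not fit at the 3' end
    while (t > cur) {
      if (mask[t + 1L]) { e <- t + w; break }
      t <- t - 1L
    }
    return(c(start = seed, end = e))
  }
}

#' Extend a qualifying seed window into a candidate span
#'
#' Jump-extension: repeatedly tests the window displaced 3' by exactly one
#' window width and advances while it qualifies. On the first failure (or at
#' the sequence end) the failing window is rolled back 1 bp at a time toward
#' 5' until it qualifies or its start reaches the previous qualifying
#' window's start. The candidate runs from the seed to the end of the last
#' qualifying window.
#'
#' @inheritParams qualification_mask
#' @param seed 0-based start of a qualifying window.
#' @return Named integer vector `c(start, end)`, 0-based half-open.
#' @export
extend_candidate <- function(record, seed, params = detection_params()) {
  seq <- record_seq(record)
  w <- params$window_size
  mask <- qualification_mask(record, params)
  seed <- as.integer(seed)
  if (seed < 0L || seed + 1L > length(mask) || !mask[seed + 1L]) {
    abort("`seed` must be the 0-based start of a qualifying window")
  }
  extend_from_seed(mask, seed, w, nchar(seq) - w)
}

trim_span_idx <- function(idx, s, e, params, mask) {
  w <- params$window_size
  if (span_qualifies(idx, s, e, params)) return(c(start = s, end = e))
  s0 <- s; e0 <- e
  trim5 <- TRUE
  while (e - s > w) {
    if (trim5) s <- s + 1L else e <- e - 1L
    trim5 <- !trim5
    if (span_qualifies(idx, s, e, params)) return(c(start = s, end = e))
  }
  starts <- s0:(e0 - w)
  hit <- starts[mask[starts + 1L]]
  if (!length(hit)) abort("candidate span contains no qualifying window")
  c(start = hit[1L], end = hit[1L] + w)
}

#' Trim a candidate span down to a qualifying island
#'
#' If the whole span qualifies it is returned unchanged. Otherwise 1 bp is
#' trimmed alternately from the 5' then the 3' end, re-testing after each
#' trim, while the span is longer than one window. If the span reaches the
#' window size without qualifying, the 5'-most qualifying window-sized
#' stretch inside the original span is returned (the seed guarantees one
#' exists). Island statistics are recomputed over the final coordinates.
#'
#' @inheritParams qualification_mask
#' @param span Numeric vector or list with `start` and `end` (0-based
#'   half-open), as produced by [extend_candidate()].
#' @return One-row island tibble (see [detect_islands()]).
#' @export
trim_candidate <- function(record, span, params = detection_params()) {
  seq <- record_seq(record)
  idx <- cpx_index(seq, params$x)
  mask <- mask_from_index(idx, params)
  s <- as.integer(span[["start"]]); e <- as.integer(span[["end"]])
  tr <- trim_span_idx(idx, s, e, params, mask)
  island_tibble(record_id(record), tr[["start"]], tr[["end"]], 1L, idx, params)
}

island_tibble <- function(seq_id, starts, ends, merged_from, idx, params) {
  starts <- as.integer(starts); ends <- as.integer(ends)
  k <- length(starts)
  cx <- numeric(k); oe <- numeric(k)
  for (i in seq_len(k)) {
    cnt <- span_counts(idx, starts[i], ends[i])
    x_eff <- if (idx$x == "C") cnt$c else cnt$x
    n_i <- ends[i] - starts[i]
    cx[i] <- if (idx$x == "C") cnt$c / n_i else (cnt$c + cnt$x) / n_i
    oe[i] <- if (cnt$c > 0L && x_eff > 0L) cnt$p * n_i / (cnt$c * x_eff) else 0
  }
  tibble(
    seq_id = seq_id, start = starts, end = ends, length = ends - starts,
    cx_percent = cx, oe_ratio = oe, second_nt = params$x,
    merged_from = as.integer(merged_from)
  )
}

#' Merge nearby islands
#'
#' Consecutive islands on the same sequence whose gap
#' (`next start - previous end`, half-open coordinates) is at most
#' `max_merge_gap` are coalesced, transitively and unconditionally (the
#' merged span is not re-tested against the thresholds). Statistics are
#' recomputed over each merged span; `merged_from` counts the components.
#'
#' @param islands Island tibble for a single sequence, sorted and
#'   non-overlapping.
#' @param record The sequence record the islands were detected on (needed to
#'   recompute CX and O/E over merged spans).
#' @param params A [detection_params()] object.
#' @return Island tibble with all pairwise gaps `> max_merge_gap`.
#' @export
merge_islands <- function(islands, record, params = detection_params()) {
  if (nrow(islands) == 0L) return(islands)
  if (length(unique(islands$seq_id)) > 1L) {
    abort("`merge_islands()` expects islands from a single sequence")
  }
  if (is.unsorted(islands$start, strictly = TRUE) ||
      any(islands$start[-1L] < islands$end[-nrow(islands)])) {
    abort("islands must be sorted and non-overlapping")
  }
  idx <- cpx_index(record_seq(record), params$x)
  merge_island_rows(islands, idx, params)
}

merge_island_rows <- function(islands, idx, params) {
  gap_ok <- c(FALSE, islands$start[-1L] - islands$end[-nrow(islands)] <= params$max_merge_gap)
  grp <- factor(cumsum(!gap_ok), levels = unique(cumsum(!gap_ok)))
  starts <- vapply(split(islands$start, grp), min, numeric(1))
  ends <- vapply(split(islands$end, grp), max, numeric(1))
  sizes <- vapply(split(islands$merged_from, grp), sum, numeric(1))
  island_tibble(islands$seq_id[1L], starts, ends, sizes, idx, params)
}

scan_one <- function(seq_id, seq, params) {
  w <- params$window_size
  empty <- island_tibble(character(0), integer(0), integer(0), integer(0),
                         cpx_index("A", params$x), params)
  n <- nchar(seq)
  if (n < w) return(empty)
  idx <- cpx_index(seq, params$x)
  mask <- mask_from_index(idx, params)
  max_start <- n - w
  starts <- integer(0); ends <- integer(0)
  pos <- 0L
  while (pos <= max_start) {
    hit <- which(mask[(pos + 1L):(max_start + 1L)])
    if (!length(hit)) break
    s <- pos + hit[1L] - 1L
    span <- extend_from_seed(mask, s, w, max_start)
    tr <- trim_span_idx(idx, span[["start"]], span[["end"]], params, mask)
    starts <- c(starts, tr[["start"]]); ends <- c(ends, tr[["end"]])
    pos <- tr[["end"]]
  }
  if (!length(starts)) return(empty)
  raw <- island_tibble(seq_id, starts, ends, 1L, idx, params)
  merge_island_rows(raw, idx, params)
}

#' Detect CpX islands in genome sequences
#'
#' Runs the full sliding-window procedure on every record: seed search,
#' jump-extension with rollback, alternating trim, then gap merging. The seed
#' search resumes at each accepted island's end, so sequence trimmed away at
#' the 3' side can still seed a new island.
#'
#' @param seqs Sequence tibble from [read_fasta()] (columns `seq_id`,
#'   `length`, `seq`), or a single record.
#' @param params A [detection_params()] object.
#' @return A tibble of islands with columns `seq_id`, `start`, `end`
#'   (0-based half-open), `length`, `cx_percent` (fraction), `oe_ratio`,
#'   `second_nt`, `merged_from`; sorted and non-overlapping within each
#'   sequence, every island at least one window long. Sequences shorter than
#'   the window contribute no islands.
#' @examples
#' seqs <- tibble::tibble(seq_id = "toy",
#'                        seq = strrep("CG", 500), length = 1000L)
#' detect_islands(seqs)
#' @export
detect_islands <- function(seqs, params = detection_params()) {
  if (!all(c("seq_id", "seq") %in% names(seqs))) {
    abort("`seqs` must have `seq_id` and `seq` columns (see `read_fasta()`)")
  }
  purrr::map2(seqs$seq_id, seqs$seq, scan_one, params = params) |>
    bind_rows()
}
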