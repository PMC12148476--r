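#' Detection parameters for CpX island scanning
#'
#' Bundles the five tunables of the sliding-window island detector. The
#' defaults are the standard settings for CpG-island scanning generalized to
#' any second nucleotide: a 500 bp minimum window, 55% minimum CX content,
#' 0.65 minimum observed/expected CpX ratio, and a 100 bp merge gap. The
#' first nucleotide of the dinucleotide is always cytosine; only the second
#' nucleotide `x` is selectable.
#'
#' @param window_size Minimum island / scanning window size in bp (default
#'   500). Must be >= 2.
#' @param min_cx Minimum CX fraction of a qualifying window, in (0, 1]
#'   (default 0.55). When `x != "C"` the CX fraction of a span is
#'   `(count(C) + count(X)) / N`; when `x == "C"` it is `count(C) / N`.
#' @param min_oe Minimum observed/expected CpX ratio (default 0.65). The
#'   expected count under base independence is `count(C) * count(X) / N`.
#' @param max_merge_gap Maximum distance in bp between two detected islands
#'   for them to be coalesced (default 100).
#' @param x Second nucleotide of the dinucleotide, one of `"G"`, `"A"`,
#'   `"T"`, `"C"` (default `"G"`).
#'
#' @return A list of class `cpx_params`.
#' @examples
#' detection_params()
#' detection_params(x = "A", min_cx = 0.5)
#' @export
detection_params <- function(window_size = 500L, min_cx = 0.55, min_oe = 0.65,
                             max_merge_gap = 100L, x = c("G", "A", "T", "C")) {
  x <- match.arg(x)
  window_size <- as.integer(window_size)
  max_merge_gap <- as.integer(max_merge_gap)
  if (is.na(window_size) || window_size < 2L) {
    abort("`window_size` must be an integer >= 2.")
  }
  if (!is.numeric(min_cx) || is.na(min_cx) || min_cx <= 0 || min_cx > 1) {
    abort("`min_cx` must lie in (0, 1].")
  }
  if (!is.numeric(min_oe) || is.na(min_oe) || min_oe <= 0) {
    abort("`min_oe` must be > 0.")
  }
  if (is.na(max_merge_gap) || max_merge_gap < 0L) {
    abort("`max_merge_gap` must be an integer >= 0.")
  }
  structure(
    list(window_size = window_size, min_cx = min_cx, min_oe = min_oe,
         max_merge_gap = max_merge_gap, x = x),
    class = "cpx_params"
  )
}

#' @export
print.cpx_params <- function(x, ...) {
  cat("CpX detection parameters\n")
  cat(sprintf("  dinucleotide     : Cp%s\n", x$x))
  cat(sprintf("  window size      : %d bp\n", x$window_size))
  cat(sprintf("  min CX fraction  : %.4g\n", x$min_cx))
  cat(sprintf("  min O/E ratio    : %.4g\n", x$min_oe))
  cat(sprintf("  max merge gap    : %d bp\n", x$max_merge_gap))
  invisible(x)
}
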