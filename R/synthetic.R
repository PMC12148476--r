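# Synthetic genomes: order-1 Markov background with planted high-CpX
# segments, plus the naive full-recount qualification oracle used by the
# property tests. Order-1 chains (rather than i.i.d. bases) are used because
# both the CX fraction and the O/E ratio respond to dinucleotide structure,
# which is exactly the quantity under test.

BASES <- c("A", "C", "G", "T")

#' Construct a first-order Markov model over {A, C, G, T}
#'
#' @param initial Length-4 probability vector (A, C, G, T order).
#' @param transition 4x4 row-stochastic matrix; `transition[b1, b2]` is the
#'   probability that `b2` follows `b1`. Rows and columns in A, C, G, T
#'   order.
#' @return A list of class `markov_model`.
#' @export
markov_model <- function(initial, transition) {
  initial <- as.numeric(initial)
  transition <- as.matrix(transition)
  if (length(initial) != 4L || any(initial < 0) ||
      abs(sum(initial) - 1) > 1e-9) {
    abort("`initial` must be 4 nonnegative probabilities summing to 1")
  }
  if (!all(dim(transition) == c(4L, 4L)) || any(transition < 0) ||
      any(abs(rowSums(transition) - 1) > 1e-9)) {
    abort("`transition` must be a 4x4 row-stochastic matrix")
  }
  dimnames(transition) <- list(BASES, BASES)
  names(initial) <- BASES
  structure(list(initial = initial, transition = transition),
            class = "markov_model")
}

#' Default background model: CpX-depleted genome-like composition
#'
#' Fly-like base composition (A/T 0.29 each, C/G 0.21 each) with the C-to-X
#' transition suppressed to `p_cx` (default 0.05), emulating the
#' dinucleotide depletion that makes islands stand out against a genome
#' background. The removed mass is redistributed proportionally over the
#' other bases.
#'
#' @param x Second nucleotide the detector will look for.
#' @param p_cx Probability of X following C (default 0.05).
#' @return A `markov_model`.
#' @export
background_model <- function(x = c("G", "A", "T", "C"), p_cx = 0.05) {
  x <- match.arg(x)
  comp <- c(A = 0.29, C = 0.21, G = 0.21, T = 0.29)
  trans <- matrix(rep(comp, each = 4L), nrow = 4L, dimnames = list(BASES, BASES))
  row_c <- comp
  row_c[x] <- 0
  row_c <- row_c / sum(row_c) * (1 - p_cx)
  row_c[x] <- p_cx
  trans["C", ] <- row_c
  markov_model(comp, trans)
}

#' Default island model: C/X-rich with frequent CpX dinucleotides
#'
#' Calibrated by Monte-Carlo so that 500 bp windows drawn from it pass the
#' default detection thresholds essentially always (stationary CX fraction
#' around 0.64 and O/E around 1.26 for `x != "C"`; around 0.65 and 1.1 for
#' `x == "C"`), while keeping enough contrast with [background_model()] that
#' boundary windows straddling a planted segment stop qualifying quickly.
#'
#' @param x Second nucleotide.
#' @return A `markov_model`.
#' @export
island_model <- function(x = c("G", "A", "T", "C")) {
  x <- match.arg(x)
  trans <- matrix(0, 4L, 4L, dimnames = list(BASES, BASES))
  if (x == "C") {
    for (b in BASES) {
      row <- c(A = 0.15, C = 0.55, G = 0.15, T = 0.15)
      if (b == "C") row <- c(A = 0.1, C = 0.7, G = 0.1, T = 0.1)
      trans[b, ] <- row
    }
    init <- c(A = 0.15, C = 0.55, G = 0.15, T = 0.15)
  } else {
    others <- setdiff(BASES, c("C", x))
    for (b in BASES) {
      row <- stats::setNames(numeric(4), BASES)
      if (b == "C") {
        row[x] <- 0.45; row["C"] <- 0.19; row[others] <- 0.18
      } else {
        row["C"] <- 0.32; row[x] <- 0.32; row[others] <- 0.18
      }
      trans[b, ] <- row
    }
    init <- stats::setNames(numeric(4), BASES)
    init["C"] <- 0.32; init[x] <- 0.32; init[others] <- 0.18
  }
  markov_model(init, trans)
}

sample_chain <- function(model, length) {
  # cumulative rows once; then a plain indexed walk
  cum_init <- cumsum(model$initial)
  cum_rows <- apply(model$transition, 1L, cumsum)  # 4 x 4, column = from-state
  u <- stats::runif(length)
  state <- integer(length)
  state[1L] <- findInterval(u[1L], cum_init, left.open = TRUE) + 1L
  for (i in seq_len(length - 1L)) {
    state[i + 1L] <- findInterval(u[i + 1L], cum_rows[, state[i]],
                                  left.open = TRUE) + 1L
  }
  paste(BASES[state], collapse = "")
}

#' Sample a DNA sequence from a Markov model
#'
#' Base-by-base sampling with R's default generator; identical seeds give
#' identical sequences across runs and platforms.
#'
#' @param model A [markov_model()].
#' @param length Sequence length in bp (>= 1).
#' @param rng_seed Integer seed.
#' @param seq_id Record id for the returned tibble.
#' @return One-row sequence tibble (`seq_id`, `length`, `seq`).
#' @export
generate_markov <- function(model, length, rng_seed = 1L, seq_id = "synthetic") {
  if (!inherits(model, "markov_model")) abort("`model` must be a markov_model")
  length <- as.integer(length)
  if (is.na(length) || length < 1L) abort("`length` must be >= 1")
  seq <- withr::with_seed(rng_seed, sample_chain(model, length))
  tibble(seq_id = seq_id, length = length, seq = seq)
}

#' Generate a background genome with planted island segments
#'
#' Samples a background sequence, then overwrites the requested segments
#' with island-model sequence, recording the planted truth intervals.
#'
#' @param background_len Total sequence length in bp.
#' @param island_specs Tibble (or data frame) with columns `position`
#'   (0-based segment start) and `length` (bp); segments must fit and must
#'   not overlap.
#' @param background_model,island_model [markov_model()] objects.
#' @param rng_seed Integer seed (one stream drives background and segments).
#' @param seq_id Record id.
#' @return A list with `record` (one-row sequence tibble) and `truth`
#'   (tibble `seq_id`, `start`, `end` of planted segments, sorted).
#' @export
plant_islands <- function(background_len, island_specs,
                          background_model = cpxscan::background_model(),
                          island_model = cpxscan::island_model(),
                          rng_seed = 1L, seq_id = "synthetic") {
  specs <- as_tibble(island_specs)
  if (nrow(specs)) {
    specs <- arrange(specs, .data$position)
    if (any(specs$position < 0L) ||
        any(specs$position + specs$length > background_len)) {
      abort("island segment outside the background sequence")
    }
    if (nrow(specs) > 1L &&
        any(specs$position[-1L] < (specs$position + specs$length)[-nrow(specs)])) {
      abort("island segments overlap")
    }
  }
  seq <- withr::with_seed(rng_seed, {
    s <- sample_chain(background_model, background_len)
    for (i in seq_len(nrow(specs))) {
      seg <- sample_chain(island_model, specs$length[i])
      substr(s, specs$position[i] + 1L,
             specs$position[i] + specs$length[i]) <- seg
    }
    s
  })
  list(
    record = tibble(seq_id = seq_id, length = as.integer(background_len), seq = seq),
    truth = tibble(seq_id = rep(seq_id, nrow(specs)),
                   start = as.integer(specs$position),
                   end = as.integer(specs$position + specs$length))
  )
}

#' Naive window qualification mask (test oracle)
#'
#' Recounts every window from scratch — no rolling state, no prefix sums —
#' and applies the thresholds. Exists to cross-check the production scan;
#' slow by design.
#'
#' @inheritParams qualification_mask
#' @return Logical vector, same contract as [qualification_mask()].
#' @export
naive_qualification_mask <- function(record, params = detection_params()) {
  seq <- record_seq(record)
  b <- strsplit(seq, NULL)[[1L]]
  n <- length(b); w <- params$window_size
  if (n < w) return(logical(0))
  x <- params$x
  vapply(0:(n - w), function(s) {
    win <- b[(s + 1L):(s + w)]
    c_count <- sum(win == "C")
    x_count <- sum(win == x)
    p_count <- sum(win[-w] == "C" & win[-1L] == x)
    x_eff <- if (x == "C") c_count else x_count
    cx <- if (x == "C") c_count / w else (c_count + x_count) / w
    oe <- if (c_count > 0L && x_eff > 0L) p_count * w / (c_count * x_eff) else 0
    cx >= params$min_cx && oe >= params$min_oe
  }, logical(1))
}
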