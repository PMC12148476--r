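---
title: "Detecting CpX islands: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting CpX islands: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpxscan)
```

## The quantity being detected

Classical CpG islands are regions whose C+G content and whose
observed/expected CpG dinucleotide ratio both exceed thresholds over a
minimum length. `cpxscan` generalizes the dinucleotide to cytosine
followed by any base X ∈ {G, A, T, C}. For a span of length $N$ with
$n_C$ cytosines, $n_X$ copies of X and $n_{CpX}$ CpX occurrences,

$$\mathrm{CX} = \frac{n_C + n_X}{N}, \qquad
  \mathrm{O/E} = \frac{n_{CpX}}{n_C\, n_X / N}.$$

Dinucleotide occurrences are counted at every position, so overlapping
occurrences all count: this matters only for X = C, where `"CCC"` contains
two CpC dinucleotides; there the CX fraction reduces to $n_C / N$ and the
expected count uses $n_C^2 / N$. An `N` base counts as neither C nor X, and
a dinucleotide containing `N` never counts; `N`-rich windows are not
rejected by any special rule — they simply fail the thresholds. When
$n_C\,n_X = 0$ the O/E ratio is defined as 0, so such a window can never
qualify.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `window_size` | 500 bp | scanning window width and minimum island length |
| `min_cx` | 0.55 | minimum CX fraction of a qualifying window (inclusive) |
| `min_oe` | 0.65 | minimum O/E ratio (inclusive) |
| `max_merge_gap` | 100 bp | maximum gap between islands that are coalesced |
| `x` | `"G"` | the second nucleotide of the dinucleotide |

Both threshold comparisons are inclusive (they are *minimum* values). The
first nucleotide is always cytosine and is not a parameter.

## The scan

The detector is a Takai–Jones-style sliding-window procedure, pinned here
step by step so that independent implementations can agree exactly:

1. **Seed.** Find the smallest window start at or after the current scan
   position whose window qualifies.
2. **Jump-extend.** Repeatedly test the window displaced 3′ by exactly one
   window width; while it qualifies, advance to it.
3. **Rollback.** When a displaced window fails (or no longer fits on the
   sequence), roll it back 1 bp at a time toward 5′ until it qualifies or
   its start reaches the previous qualifying window's start. The candidate
   runs from the seed to the end of the last qualifying window.
4. **Trim.** If the whole candidate qualifies, keep it. Otherwise trim
   1 bp alternately from the 5′ then 3′ end, re-testing after every trim,
   while the span is longer than one window; if it reaches the window size
   without qualifying, fall back to the 5′-most qualifying window inside
   the original candidate (the seed guarantees one exists, so every seed
   yields an island and the procedure always terminates).
5. **Resume.** The seed search restarts at the accepted island's *end*
   (not the untrimmed candidate's end), so 3′ sequence trimmed away in
   step 4 can still seed a new island.
6. **Merge.** Islands separated by at most `max_merge_gap` bp (measured as
   `next start − previous end` in half-open coordinates, strict at
   `gap = 101` for the default 100) are coalesced transitively and
   *unconditionally* — the merged span is not re-tested against the
   thresholds, since the merge gap is a post-processing parameter and the
   merged span's statistics are what get reported. CX and O/E are
   recomputed over every merged span; `merged_from` records the component
   count.

Two consequences worth knowing: every *unmerged* island satisfies both
thresholds by construction, while a *merged* island is only guaranteed to
be a union of components that did; and island boundaries can extend a few
hundred bp beyond a sharp compositional transition, because a window that
straddles the boundary still qualifies as long as its average content
does.

Internally the scan uses prefix sums, giving constant-time statistics for
any span; `shift_stats()` exposes the equivalent one-step rolling update,
and `naive_qualification_mask()` recounts every window from scratch as the
independent oracle the test suite compares against.

## Coordinates and formats

Internal tables and the BED/BedGraph writers use 0-based half-open
coordinates; the CSV export is 1-based inclusive, genome-browser style.
Strict BedGraph permits only one value column, so the exporter offers a
choice (`cx_percent` or `oe_ratio`) plus a BED4+3 dialect carrying all
fields. FASTA input is uppercased and anything outside `{A,C,G,T,N}` —
IUPAC ambiguity codes, gaps — collapses to `N` rather than erroring,
because whole-genome FASTA routinely contains such characters. The CSV
sequence preview is 40 bases with an ellipsis marker when truncated.

## Summaries, shores, overlap

Per-chromosome summaries report island count, covered bp, median length,
frequency per 1000 bp (`count / chrom_length × 1000`) and percent coverage
(`covered bp / chrom_length × 100`); the genome `total` row sums counts and
pools all islands for its median. Medians use the mid-pair mean for even
counts (exports round them to integer bp; the convention is otherwise
invisible at that precision). Shores are the 2 kb flanks of each island,
clipped to the chromosome, with all island bodies subtracted and
overlapping fragments merged — collisions between the shores of adjacent
islands are resolved by that subtraction-then-merge order. Shores are
typically computed on a long-island subset (`filter_min_length()`, 3000 bp
by convention) but the operation is generic.

Overlap reports count (feature, island) *pairs* with at least 1 bp
intersection in half-open coordinates — touching intervals do not overlap.
Counting pairs rather than distinct features is what allows percentages
above 100 when one long feature spans several islands, matching how such
tables are conventionally reported; percentages round halves away from
zero to integers. The enrichment filter defaults (pct ≥ 75, total ≥ 10,
both inclusive) are the conventional arbitrary cut for calling a feature
type enriched while excluding rare types whose overlaps could be chance.

The permutation control relocates every island uniformly at random on its
own chromosome (start drawn from `[0, chrom_len − island_len]`), preserving
lengths and chromosome assignment but not inter-island spacing; shuffled
islands may overlap. Observed and permuted statistics are the *bp* of
intersection between the union of islands and the union of features,
computed identically, so with islands equal to features the observed value
is exactly the total island bp. The fold is observed over permuted mean
(0 when the observed intersection is 0, infinite when only the permuted
mean is); the empirical p-value uses the add-one estimator
$(1 + \#\{perm \ge obs\})/(n_{perm}+1)$, so it is never 0. One hundred
permutations is the default control size. Log p-values from external
enrichment services are deliberately not reproduced.

## The synthetic genome generator

Tests and the acceptance script run on generated genomes, not downloads.
Sequences are sampled from order-1 Markov chains — not i.i.d. bases —
because CX and O/E respond to *dinucleotide* structure. Two calibrated,
documented models ship as defaults:

- **Background** (`background_model()`): fly-like base composition
  (A/T 0.29, C/G 0.21 each) with the C→X transition suppressed to 0.05 and
  the removed mass redistributed proportionally. This emulates the CpG
  depletion that makes real islands detectable: background CX ≈ 0.42 sits
  well under the 0.55 threshold, so clean background yields no islands.
- **Island** (`island_model()`, X ≠ C): P(X|C) = 0.45, P(C|C) = 0.19,
  P(C|·) = P(X|·) = 0.32 elsewhere, giving stationary CX ≈ 0.64 and
  O/E ≈ 1.26. The model was calibrated by Monte-Carlo before the test
  expectations were frozen, balancing two pressures: windows fully inside
  a planted segment must qualify essentially always, while the contrast
  with the background must be modest enough that boundary-straddling
  windows stop qualifying quickly — a *stronger* island model paradoxically
  *worsens* boundary recovery, because windows containing mostly background
  still clear the thresholds. At these settings all of 100 calibration
  seeds recover a planted 800 bp segment with interval Jaccard ≥ 0.6
  (minimum 0.602) and 100% of island-model windows qualify.

`plant_islands()` overwrites segments of a background sequence with
island-model sequence and records the truth intervals; one RNG stream
seeded by `rng_seed` drives everything, so identical seeds reproduce
identical genomes bit for bit.

What the generator does **not** emulate: the dm6 genome's full
compositional heterogeneity, isochore-like long-range structure, assembly
gaps (`N` handling is tested with hand-built strings instead), and repeat
content. Passing the synthetic-recovery tests therefore demonstrates that
the algorithm finds dinucleotide-enriched segments against a depleted
background with correct coordinates — not that any particular biological
genome yields any particular island count.

## Numerical and degenerate-input choices

- All window statistics are integer counts combined at the end into two
  floating-point ratios; the rolling and recomputed paths are therefore
  bit-identical, which the suite asserts rather than assumes.
- A sequence shorter than one window yields an empty result, not an error.
- Writers require sorted input rather than sorting silently; sorting is
  the caller's decision.
- Detection is fully deterministic; only the generator and the permutation
  control consume randomness, always through an explicit seed argument.

## Problem sizes in the tests

The suite generates its data at run time: oracle-equality checks run on
200 random Markov sequences of 2–20 kb across all four X choices;
recovery checks plant 800/1500/3000 bp segments in 25 kb genomes; the
permutation null band uses a 1 Mb toy chromosome with 200 permutations.
These sizes were chosen to exercise every code path (multi-window
extension, rollback at sequence end, merging, boundary trimming) while
keeping the whole suite comfortably interactive.

## Known limitations

- Exact island coordinates depend on variant details the generic
  Takai–Jones description leaves open (rollback bound, merged-span
  re-testing, trim order); this package pins one variant, documented
  above, so counts on real genomes may differ slightly from other
  implementations.
- Boundary overshoot of up to roughly half a window on each side is
  inherent to window-averaged qualification.
- The permutation model shuffles islands independently; it preserves
  lengths and chromosome assignment but not spacing or clustering, so it
  tests only the simplest null.
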