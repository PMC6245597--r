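---
title: "Blocked score-only Smith-Waterman for long DNA pairs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blocked score-only Smith-Waterman for long DNA pairs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blocksw)
```

## The problem and the model

Exact local alignment of two DNA sequences `S1` (length `m`) and `S2`
(length `n`) under affine gap penalties is defined by the Gotoh
three-matrix recurrences

$$H_{i,j} = \max\{0,\; H_{i-1,j-1} + SM(S_1[i], S_2[j]),\; E_{i,j},\; F_{i,j}\}$$
$$E_{i,j} = \max\{H_{i,j-1} - (G_o + G_e),\; E_{i,j-1} - G_e\}$$
$$F_{i,j} = \max\{H_{i-1,j} - (G_o + G_e),\; F_{i-1,j} - G_e\}$$

with $H$, $E$ and $F$ all zero when $i = 0$ or $j = 0$, and
$1 \le i \le m$, $1 \le j \le n$. The optimal local alignment score is
the maximum of $H$; `blocksw` reports that score and the position of its
first maximal cell, and deliberately does **not** reconstruct the
alignment itself — score-only operation is what makes linear memory
possible, and for long-DNA validation work the score is the quantity of
interest.

Each cell depends only on its left, upper and upper-left neighbours, so
any processing order that respects those three dependences is exact.
The full matrix of a long-DNA comparison is far too large to hold
(a 1M x 1M pair is $10^{12}$ cells), which rules out the naive layout
and motivates the blocked one.

## The blocked kernel and the boundary-exchange contract

`sw_score_blocked()` divides $H$ into vertical blocks of `block_width`
(BW) columns by `m` rows. Each block is processed row by row, top to
bottom and left to right, holding only:

* two row buffers of length BW — the previous row of $H$ and of $F$;
* the running $E$ and left-$H$ scalars within the current row;
* two boundary vectors of length `m`.

Crossing a block seam, the recurrence for the first column of block
$k+1$ needs $H_{i,j-1}$, $E_{i,j-1}$ and $H_{i-1,j-1}$ from the last
column of block $k$. That is exactly what the boundary carries: the
last-column $H$ and $E$ vectors. $F$ needs no seam state because it
propagates vertically, entirely inside a block. Two boundary buffers
are kept — one read, one written — and swapped after every block, so a
block never reads a vector the same pass is writing. An all-zero
boundary encodes the $j = 0$ initialisation column, which is how the
first block starts; likewise $E$ and $F$ on the initialisation border
are taken as 0, so negative $E$/$F$ values appear only at interior
cells. The contract is tested directly: every block's outgoing boundary
must equal columns BW, 2BW, ... of the full-matrix engine's $H$ and $E$.

Peak memory is $O(m + \mathrm{BW})$, independent of $n$. Block width is
a locality/granularity tunable, never a correctness parameter: for every
BW $\ge$ 1 the blocked result (score *and* argmax) is identical to the
full-matrix reference, and the test suite exercises widths from 1 to
beyond $n$. The default BW = 512 is a mid-range choice — big enough
that per-block call overhead vanishes against the $m \times$ BW cell
work, small enough that the two row buffers stay cache-resident.

## Padding and the pad symbol

So the target always splits into whole blocks, it is extended to the
next multiple of BW with a reserved pad symbol (`X`). The pad scores
`mismatch` against every residue, itself included. With a negative
mismatch score every path through a pad column strictly loses score
relative to stopping at the last real column, so padding can change
neither the optimum nor its position; the engine asserts
`mismatch < 0` whenever padding is actually required and refuses
otherwise. Reported coordinates are always in unpadded target
coordinates, and an internal assertion verifies the maximum never lands
in a pad column.

## Ambiguity codes, case, and coordinates

Real sequence records contain `N` and other IUPAC ambiguity letters.
`blocksw` treats **every** non-ACGT residue as mismatch-to-all —
`N` vs `N` is a mismatch — which is conservative, deterministic, and
identical to the pad rule. Lowercase (soft-masked) input is uppercased
at parse time and treated as ordinary sequence. All positions are
1-based inclusive, $i \in [1, m]$ over the query and $j \in [1, n]$
over the target.

Ties for the maximum are broken by reporting the first maximal cell in
row-major order (smallest $i$, then smallest $j$); when no cell of $H$
is positive the score is 0 and the position is reported as `(0, 0)`,
meaning "no aligned cell". Position reporting is an extension beyond
score-only operation; the tie-break is documented precisely so results
are reproducible, and the cross-block combination (best score, then
smallest $i$, then smallest $j$) provably reproduces the row-major scan
of the full matrix.

## Integer width and the overflow guard

Narrow integer score types are attractive in accelerated settings, but
they shrink the representable score range: 8-, 16- and 32-bit maxima
are 127, 32767 and 2147483647. Since no local score can exceed
$\min(m, n) \times \mathrm{match}$ (each aligned column contributes at
most `match`, and at most $\min(m,n)$ columns can align), admissibility
is decided *a priori*: `check_width()` compares that bound with the
configured maximum and `sw_score_blocked()` refuses inadmissible runs,
naming the minimum admissible width in the error. This mirrors how
narrow-width runs fail in practice — whole comparisons become
uncomputable, rather than individual cells clipping — while keeping the
inner loop branch-free.

Arithmetic is carried out in native 32-bit integers regardless of the
requested width; the guard guarantees that any admissible run's values
fit the emulated width ($H \le \min(m,n) \times \mathrm{match}$ from
above, and $E, F \ge -(G_o + G_e)$ because both take a max with
$H - (G_o + G_e)$ and $H \ge 0$), so bit-exact narrow arithmetic would
change nothing. A post-hoc assertion double-checks the returned score
against the configured maximum. Consequently, whenever two widths are
both admissible their results are identical — a tested invariant.

## Runtime accounting and GCUPS

`runtime_s` covers buffer setup, padding, the blocked computation and
score retrieval, in a single process; FASTA parsing is excluded (it is
input acquisition, not alignment work, and its cost depends on storage,
not on the algorithm). Throughput is reported as
$\mathrm{GCUPS} = m \times n / (t \times 10^9)$ over the *unpadded*
matrix. `cmd_bench` repeats a run (default 10 repetitions), checks the
scores are identical across repetitions — the engine is deterministic —
and reports the mean runtime and the GCUPS derived from it. An empty
comparison (0 cells) reports 0 GCUPS by convention; if the clock
resolution returns a zero elapsed time the GCUPS field is `NA` rather
than infinite.

## The synthetic divergence model

Long-DNA validation inputs are multi-kilobase to megabase pairs whose
similarity ranges from near-identity to essentially unrelated. The
generator emulates exactly that and nothing more: `random_dna()` draws
i.i.d. uniform residues, and `mutate_dna()` applies one pass of
per-position mutation — delete with `deletion_rate`, else substitute to
a uniformly chosen *different* residue with `substitution_rate`, and
insert one uniform residue after each position with `insertion_rate`.
All randomness is governed by the model seed (the pair generator uses
seed for the base draw and seed + 1 for the mutation pass), so pairs
are byte-reproducible; the caller's RNG state is left untouched.

What it does not emulate — repeats, GC skew, rearrangements,
multi-residue indels, realistic substitution spectra — is deliberate:
the engine's claims are about exact score computation at any input
similarity, not about biological realism, so coarse similarity control
suffices. Passing tests on synthetic pairs therefore demonstrate
correctness of the dynamic programming over the full divergence range
and the exact size range of interest, but say nothing about, e.g.,
repeat-induced score landscapes in real genomes; for that the suite
includes an exact-score check against real NCBI records when the user
supplies them locally (they are not redistributable with the package,
and the package never downloads).

With substitutions only, the expected score of a length-$L$ pair is
approximately the per-column sum $L[(1-p)\,\mathrm{match} +
p\,\mathrm{mismatch}]$; the suite checks the Monte-Carlo mean over 20
seeds against this within four binomial standard errors — a sanity band
for the generator-engine pipeline, not an exact target, since the local
optimum may trim weak flanks.

## Numerical and degenerate-input choices

* Empty query or target: zero blocks (or zero rows) are processed; the
  result is score 0, position `(0, 0)`, 0 cells, 0 GCUPS.
* `gap_open = 0` and/or `gap_extend = 0` are legal (linear or free
  gaps); penalties are validated as nonnegative magnitudes and
  subtracted inside the recurrences, and the command line accepts them
  as positive numbers to avoid sign confusion.
* `match` must be positive — the score bound, the width guard and the
  self-alignment invariant all assume it.
* Cell counts are carried as doubles (exact up to $2^{53}$), so
  megabase pairs do not overflow R's 32-bit integers.
* FASTA input rejects `*` and `-` outright instead of skipping them:
  gapped or translated input signals an upstream mistake that silent
  cleanup would hide.

## Problem sizes used by the tests

The randomized equivalence battery runs 200 pairs of lengths 1-400
across block widths {1, 2, 7, 64, 256, n, n+3} and all admissible
integer widths, comparing score and argmax against the full-matrix
reference; the property battery adds symmetry, suffix monotonicity,
padding invariance, self-alignment, the $E/F \ge -(G_o+G_e)$ floor and
width consistency on independent draws. Larger sanity runs use 10 kb
pairs. These sizes exercise every seam case (blocks narrower than, equal
to and wider than the target; all three integer widths) while keeping
the default suite fast; the engine itself has no size-dependent code
paths, and sustains roughly 0.4 GCUPS on a single core — a 57 kb pair
scores in under ten seconds, a 1 Mb pair in under an hour.

## Known limitations

* Score-only: no traceback, no alignment reconstruction, no suboptimal
  alignments.
* DNA match/mismatch scoring only; no protein substitution matrices.
* Single-threaded; block processing is sequential by construction
  (each block consumes its predecessor's boundary).
* Only the first maximal cell is reported; the full set of co-optimal
  cells is not enumerated.
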