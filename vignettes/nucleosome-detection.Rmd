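---
title: "Detecting positioned nucleosomes: model, statistics, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting positioned nucleosomes: model, statistics, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoscan)
```

## The model

A nucleosome wraps ~146 bp of DNA. When MNase digests chromatin down to
mononucleosomes, sequencing the protected fragments from one end produces,
around every *positioned* nucleosome, a cluster of forward-strand 5′ ends
about 73 bp left of the dyad and a mirror cluster of reverse-strand 5′ ends
about 73 bp right of it. Delocalized nucleosomes and linker background
produce diffuse reads instead. Everything in this package is built on that
geometric signature.

**Read-to-center offset.** The distance from a read's 5′ end to its
nucleosome's center is modelled as a discrete random variable on
{68, …, 78}: 73 ± 5 bp of MNase cut-site ambiguity. Bin probabilities come
from integrating a beta(α, β) density rescaled onto [68, 79); under
u = (x − 68)/11 each bin is an exact difference of regularized incomplete
beta values (`pbeta`), so the pmf is exact, strictly positive, and sums to 1
at machine precision. The default shapes α = 1.9204, β = 1.8937 were fit to
published yeast paired-end half-distances; `fit_beta_shapes()` reproduces
that calibration on user data by solving

mean log((t−68)/11) = ψ(α) − ψ(α+β),  mean log((79−t)/11) = ψ(β) − ψ(α+β)

with damped Newton iteration (analytic trigamma Jacobian, start (2, 2),
residuals < 1e−8; non-convergence and n < 10 are errors, out-of-range values
are discarded first — half-distances may be real-valued, e.g. half-integers
from odd pair distances).

**Landscape.** Each forward read at y adds its pmf at y + 68 … y + 78; each
reverse read at y − 78 … y − 68. Sums over reads give the per-base center
probability landscape. A read overhanging a chromosome end keeps its
in-bounds bins (mass is dropped, not the read), so total mass equals the
read count only for interior reads.

## The scan statistics

**Triangle statistic.** A W = 200 bp window split A | B | C = 75 | 50 | 75
slides base-by-base. Writing A, B, C for the sub-window masses, the odds of
"center mass vs flank" are estimated median-unbiasedly: with m = B and
M = A + B (resp. C + B), the boundaries solve I_p(m+1, M−m) = ½ and
I_p(m, M−m+1) = ½ — i.e. they are medians of Beta(m+1, M−m) and
Beta(m, M−m+1), which `qbeta` inverts directly (the test suite keeps an
independent binomial-sum root-finding oracle). The midpoint p̂ gives odds
p̂/(1−p̂), and

t = min(odds_BA, odds_BC) / (2·B_w / (W − B_w)),

which is ≈1 for uniform coverage (the denominator, 50/75 by default, is the
null odds) and large when mass concentrates centrally. The MUE matters at
the low counts typical of per-window masses; it converges to the MLE B/A as
masses grow.

**Decorrelation.** Windows overlapping by W−1 give strongly autocorrelated
t. A window i is called (N_i = 1) only if t_i strictly exceeds the 25
values to its left, is ≥ the 26 to its right, reaches t_c, and the sums of
the ten t values at offsets +69…+78 and −77…−68 both stay ≤ 10 — "insurance"
that vetoes calls with a similar clump one nucleosome away. Candidate
centers are emitted at i + ⌊W/2⌋.

**FDR.** Each of S simulations shifts every read by an independent uniform
integer in {−73, …, 73} (clamped at chromosome ends) and re-runs the full
scan with the same configuration. For a candidate with statistic t_j, the
estimated FDR is the mean over simulations of m_kj/M_j, where M_j and m_kj
count real resp. simulated candidates with statistic ≥ t_j. The mean (not
the plain sum over simulations) keeps the estimate independent of S.
Ratios are clamped to [0, 1] for reporting, no cross-candidate monotone
adjustment is applied, and candidates with FDR > F are dropped from every
output.

## Tunables

| Parameter | Default | Units | Why |
|---|---|---|---|
| W | 200 | bp | spans one nucleosome plus flanking linker |
| A_w, B_w, C_w | 75, 50, 75 | bp | B_w = 50 allows ~two superhelical turns of dyad ambiguity |
| t_c | 1.7 | — | low enough that everything surviving FDR ≤ 0.01 is kept |
| F | 0.01 | — | FDR cutoff applied to every output |
| S | 3 | — | shaking simulations; larger S tightens FDR estimates |
| threads | 1 | — | forked workers over chunks; never changes results |
| α, β | 1.9204, 1.8937 | — | yeast-calibrated offset shapes |
| shake range | ±73 | bp | half a nucleosome: destroys positioning, keeps coverage |
| min_mapq | 0 | — | no quality filter by default (BED is never filtered) |

## Numerical and design choices

* **Coordinates** are 1-based inclusive internally; BED (0-based half-open)
  is converted on input: forward 5′ = chromStart+1, reverse 5′ = chromEnd.
  The 5′ end of a reverse-strand SAM/BAM record is its rightmost aligned
  reference base (CIGAR reference width from the alignment). Secondary,
  supplementary, and unmapped records are excluded; duplicates kept — MNase
  data legitimately stacks identical reads.
* **MUE boundary conventions.** At m = 0 the upper-tail condition holds for
  every p, so the satisfying interval is [0, 1 − 2^(−1/M)] and p̂₂ = 0;
  symmetrically p̂₁ = 1 at m = M. These follow from the inequality form of
  the median-unbiasedness conditions, not from an extra convention. Odds are
  capped at 1e12 (reachable only when p̂ = 1); an all-zero window scores
  t = 0 so empty regions scan cleanly; `qbeta`'s inversion is far below the
  ~1e−2 resolution at which t meets t_c.
* **Window sums** use ascending shifted-vector accumulation rather than
  prefix sums. Cost is still one vectorized add per sub-window position
  (linear in chromosome length), but the floating-point result is bitwise
  independent of where a landscape slice starts — this is what makes chunked
  and whole-chromosome scans identical to the last bit, and the scan equal
  to a naive per-window oracle exactly.
* **Chunking and threads.** Chromosomes are tiled by core intervals padded
  with W + 103 bp flanks — enough to compute every t value and every
  N-statistic neighborhood term (±25/26 comparisons, ±68…78 insurance sums)
  a core decision needs. Workers are pure functions of their chunk; results
  are concatenated in plan order, so any thread count, including 1, yields
  byte-identical candidate tables. Each FDR simulation derives its seed
  deterministically from the master seed.
* **Track edges.** Out-of-range terms in the N-statistic are neutral
  (treated as t = 0), keeping peaks near chromosome ends callable.
* **Tie-breaking is leftmost-wins**: the left product of the N-statistic is
  strict, the right one is not, so on a run of exactly equal t the leftmost
  window fires. A consequence worth knowing: two equal-or-descending peaks
  exactly 26 windows apart can *both* fire — the guaranteed invariant is
  that calls are ≥ 26 bp apart, not that any 51-bp neighborhood holds one
  call.
* **Open points resolved here.** The TXT output includes the triangle
  statistic column alongside chrom/center/FDR (costless and useful); the
  insurance sums are computed over triangle statistics, as the symbols are
  written; calibration accepts real-valued half-distances; S defaults to 3.

## The synthetic generator, and what a green test establishes

`simulate_reads()` plants nucleosomes at known centers: per nucleosome,
`reads_per_side` forward 5′ ends at c − 73 + round(N(0, jitter_sd)) and as
many reverse ends at c + 73 + round(N(0, jitter_sd)), over uniform
strand-balanced Poisson background. Jitter is Gaussian-rounded deliberately
— were it beta-distributed the generator would share the detector's model
and recovery tests would be circular. Defaults (50 reads/side, 5 bp jitter,
1e−4 background/bp) emulate a deeply covered, well-positioned array on an
otherwise quiet chromosome.

What the generator does **not** emulate: MNase sequence bias (AT-rich cut
preference), variable fragment lengths, overlapping/phased nucleosome
arrays at yeast-like ~165 bp spacing, and realistic genome-wide background
depth. Green end-to-end tests therefore establish that the statistics and
plumbing do what they claim on the stated world — not that the method's
published genome-scale operating characteristics are reproduced.

## Known limitations

Two behaviors of the method become visible in sparse synthetic data and are
asserted honestly (one acceptance test is expected to fail; it is not
weakened):

* **Plateau bias.** When the flank sub-windows hold exactly zero mass —
  routine at 1e−4 background, impossible in deep real data — every window
  whose central sub-window contains the whole cluster has identical
  (A, B, C), hence identical t. Leftmost-wins then places the call at the
  left edge of the plateau, ~6–8 bp left of the true center (the plateau
  midpoint would be nearly unbiased). All planted nucleosomes are still
  recovered within ~10 bp.
* **Isolated reads.** A single read with no neighbor within reach of the
  window scores t = 4.5 exactly (MUE at m = M = 1 gives p̂ = 3/4, odds 3)
  — above t_c = 1.7. On shaken sparse data this yields a handful of
  detections per 50 kb rather than none; the FDR filter is what removes
  them (they receive FDR ≈ 0.3 here), mirroring how the method relies on
  its FDR stage rather than t_c alone. In deep data, windows never have
  empty flanks and shaken runs produce essentially no calls.

Paired-end input, CRAM, indexed random access, GC/AT bias correction,
overlapping-nucleosome deconvolution, and per-candidate fuzziness scores
are out of scope.
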