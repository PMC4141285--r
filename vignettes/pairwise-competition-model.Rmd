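---
title: "The pairwise-competition model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pairwise-competition model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcmsim)
```

## The process

The pairwise-competition model (PCM) describes preference construction
over a sequence of $L$ options as a winner-stays tournament. The first
option encountered becomes the provisional favorite. Each later option, at
serial position $i$, either displaces the favorite or is discarded; the
survivor of the comparison at position $L$ is the final favorite. The
displacement probability combines two mechanisms:

$$p(\mathrm{new}) \;=\; (1 - \pi_i)\,
  \frac{Q_{\mathrm{new}}}{Q_{\mathrm{new}} + Q_{\mathrm{old}}},$$

a Luce (ratio-of-strengths) comparison on scalar option qualities $Q$, and
*choice inertia* $\pi_i$: with probability $\pi_i$ the favorite is kept
outright, with no quality comparison at all. The favorite is retained with
probability $1 - p(\mathrm{new})$. Inertia may grow over the sequence,

$$\pi_i \;=\; 1 - (1 - \pi_1)\,\frac{2}{1 + i^{\,c}},$$

anchored so that $\pi_1$ is the inertia at the first position for every
growth exponent $c$ (the factor $2/(1+1^c)$ is 1 analytically). $c = 0$
gives a static schedule; any $c > 0$ gives a schedule that is strictly
increasing in $i$ and approaches 1, at rate $\sim i^{-c}$, so convergence
is slow for small $c$.

Model assumptions worth keeping in view: quality is a scalar (no
attribute structure); episodes are independent; there is no memory or
forgetting mechanism — serial-position effects arise purely from the
comparison process; and only the current favorite is carried between
positions, which is what makes the process Markovian in the pair
(favorite position, favorite quality).

## Parameters

| parameter | meaning | units | default | why |
|---|---|---|---|---|
| `length` ($L$) | options per sequence | count | — | design factor; $\ge 2$, a single option has no comparison |
| `pi1` ($\pi_1$) | inertia at position 1 | probability | — | design factor on $\{0, 0.3, 0.6, 0.9\}$ in the canonical sweep |
| `c` | inertia growth exponent | unitless, $[0,1]$ | 0 | 0 = static; 0.3 in the sweep as a moderate increase |
| `mean` ($M$) | quality mean | quality units | 5 | centre of the $[0,10]$ quality scale |
| `spread` ($\delta$) | quality standard deviation | quality units | 5 | 0 = equal quality; 5 = substantial variability |
| `lower`, `upper` | truncation bounds | quality units | 0, 10 | qualities must be non-negative for the Luce ratio |
| `runs` | Monte-Carlo episodes per condition | count | 100{,}000 | binomial SE $\le 0.0016$ per position probability |

`mean` and `spread` parameterise the *untruncated* normal; the draws are
conditioned on landing in $[0, 10]$. The canonical
`factorial_design()` crosses 2 variability levels × 6 lengths
(2, 4, 6, 10, 12, 20) × 4 inertia levels × 2 dynamics levels = 96
conditions.

## What the simulator emulates — and what it does not

The quality generator emulates a population of options whose single-number
qualities scatter symmetrically around a mid-scale mean, with hard floor
and ceiling (a 0–10 rating scale). The degenerate `spread = 0` case
reproduces designs in which all options are objectively identical (the
classic same-bottle wine tasting). What it does not emulate: real option
sets with attribute structure, correlated qualities within a sequence,
learning or fatigue across episodes, or any memory contribution to
serial-position effects. Tests passing against this generator therefore
show that the *process model* is implemented correctly and behaves as
predicted under its own assumptions — not that those assumptions describe
any particular empirical data set.

## Exact solvers and the oracle chain

Three deterministic solvers cross-check the Monte-Carlo engine, each
derived independently of it:

1. **Closed form, equal quality** — with all qualities equal the
   acceptance probability at position $i$ is $a_i = (1-\pi_i)/2$, so
   $p(j) = a_j \prod_{k>j} (1-a_k)$ for $j \ge 2$ and
   $p(1) = \prod_{k\ge2} (1-a_k)$.
2. **Path dynamic program** (`path_dp()`) — for a fixed quality vector,
   propagate the distribution of the favorite's identity through the
   comparisons; $O(L^2)$, exact.
3. **Finite-support dynamic program** (`support_dp()`) — for i.i.d.
   qualities on a finite support, propagate the joint distribution of
   (favorite position, favorite quality), integrating the acceptance rule
   over the challenger's quality. This equals the exhaustive average of
   `path_dp()` over all $G^L$ quality tuples, and the test suite asserts
   that equality to 1e−13 on small cases.

`grid_dp()` reduces the continuous truncated-normal model to case 3 by
midpoint discretisation: $[0,10]$ is cut into `grid_size` equal cells,
each represented by its midpoint with weight equal to the truncated-normal
mass of the cell (normal CDF differences, renormalised). The
discretisation is mass-preserving and symmetric; successive grid doublings
contract the answer (asserted in the tests), and at the default
`grid_size = 400` the distance to a 1600-point grid is below $10^{-6}$ —
two orders of magnitude inside Monte-Carlo resolution at 100,000 runs.

## Numerical and design choices

* **Truncation by rejection.** Out-of-bounds normal draws are redrawn, not
  clipped: clipping would put point masses at 0 and 10 and break the
  symmetry of the distribution. The acceptance rate at the default
  parameters is $\Phi(1) - \Phi(-1) \approx 0.68$, so the loop terminates
  quickly.
* **The $0/0$ comparison.** If challenger and favorite both have quality
  exactly 0 the Luce ratio is undefined; it is completed symmetrically as
  $1/2$. With continuous qualities this is a measure-zero event, but it is
  reachable on discretised supports that include 0.
* **Position indexing.** $i$ in the inertia schedule is the serial
  position of the newly encountered option, $i \in \{2, \dots, L\}$, and
  positions are 1-based. $\pi_1$ itself is never used in a comparison
  (position 1 has none); it only anchors the schedule.
* **Random position assignment.** With i.i.d. quality draws, separately
  permuting drawn values over positions is distributionally redundant, so
  the engine draws directly into positions. For *user-supplied fixed*
  quality vectors, where the redundancy argument fails,
  `path_dp(..., average_permutations = TRUE)` averages exactly over all
  $L!$ orders (guarded to $L \le 8$).
* **Reproducible substreams.** `run_design(design, seed)` derives one
  sub-seed per condition from the master seed (a single
  `sample.int()` draw per condition, in enumeration order), so any
  condition can be re-run in isolation bit-for-bit, and the whole table is
  deterministic given the seed. Output rows are ordered by condition index
  then position, keeping sweep files diffable.
* **Effect definitions.** Primacy and recency are reported as
  $p(1) - 1/L$ and $p(L) - 1/L$, the deviations from the random-choice
  baseline (the dashed reference line in the standard figures); the raw
  probabilities are kept alongside, since length trends are usually
  plotted raw. Binomial standard errors
  $\sqrt{\hat p(1-\hat p)/\mathrm{runs}}$ accompany every Monte-Carlo
  probability; no multiplicity correction is applied to them.
* **Full-precision CSV.** Sweep files serialise doubles with the shortest
  decimal representation that parses back to the identical double, and are
  re-read through `strtod`, so a written table round-trips exactly.

## Degenerate and boundary cases

Three analytic facts shape how the qualitative predictions are asserted:

* **$L = 2$ is blind to quality variability.** With one comparison,
  $p(2) = (1-\pi)\,E[Q_2/(Q_1+Q_2)] = (1-\pi)/2$ for *any* symmetric
  i.i.d. quality distribution, so variability effects are exactly zero at
  $L = 2$. Strict variability contrasts are therefore asserted for
  $L \ge 4$, with the exact tie checked at $L = 2$.
* **The variability contrast fades with inertia at pattern level.** The
  claim that quality variability matters less at high inertia is true for
  whole preference curves (max-norm distance between the $\delta = 5$ and
  $\delta = 0$ curves shrinks from $\pi_1 = 0.3$ to $0.9$ at every
  length), but not endpoint-by-endpoint: at $L = 20$ the *first-position*
  gap is larger at $\pi_1 = 0.9$ (0.016) than at $0.3$ (0.0016), because
  primacy itself has nearly vanished at low inertia and long sequences.
  The tests assert the pattern-level version.
* **Recency at the high-inertia boundary.** At $\pi_1 = 0.9$, static,
  equal quality, $p(L) = (1-\pi_1)/2 = 0.05$ for every $L$; at $L = 20$
  this equals the $1/L$ baseline exactly. "Recency disappears" is
  therefore asserted as $p(L) - 1/L \le 0$, not as a strict inequality.

## Monte-Carlo calibration and multiplicity

The calibration check compares all $864$ simulated position probabilities
(96 conditions at 100,000 runs) with their exact counterparts. A perfectly
calibrated simulator exceeds 3 binomial standard errors in about
$0.27\% \times 864 \approx 2.3$ cells by chance alone, so an
every-cell-within-3-SE assertion fails for most seeds no matter how
correct the code is. The suite therefore asserts the chance-aware version
— no cell beyond 4.5 SEs, and at most 9 cells beyond 3 SEs — alongside a
strict 3-SE-everywhere check kept for reference, and the acceptance script
reports the observed maximum $z$ and exceedance count.

## Problem sizes and runtime

The test suite and the acceptance script run the full 96-condition design
at 100,000 runs per condition (the canonical sensitivity analysis) plus
the exact solvers at `grid_size = 400`; the sweep takes on the order of
ten seconds and the exact pass under a second on one CPU, so no scaled-down
surrogate designs are needed anywhere.

## Known limitations

Quality is scalar and i.i.d. across positions; inertia growth follows one
two-parameter family; no fitting to behavioural data is provided (none is
part of the model's specification); and the solvers' guarantees are about
the model itself, not about human choice. Extending the quality model
(correlated or attribute-based qualities) would require generalising
`support_dp()`'s i.i.d. integration step.
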