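---
title: "The scoring card method in thermoSCM: model, design choices, and benchmark"
author: "thermoSCM maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The scoring card method in thermoSCM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoSCM)
```

## The model

The scoring card method (SCM) classifies a protein from its primary sequence
alone. A sequence of length $L$ is reduced to its $g$-gap dipeptide
composition: for every ordered pair of standard residues $(a, b)$ separated
by $g$ intervening positions, the fraction

$$f_{ab} = \frac{n_{ab}}{L - g - 1}$$

of the $L-g-1$ such pairs in the sequence. With $g = 0$ this is classic
dipeptide composition; we write the 400 fractions in a fixed alphabetical
order (AA, AC, ..., YY). The model itself is a *scoring card*: a table
assigning each dipeptide a propensity score $PS_{ab} \in [0, 1000]$, plus a
decision threshold. A protein's score is the composition-weighted sum

$$S(P) = \sum_{ab} f_{ab} \, PS_{ab},$$

and $P$ is called thermophilic when $S(P) \ge$ threshold (equality counts
as positive; the underlying decision rule leaves ties undefined, so we fix
the inclusive convention and document it). Because the weights $f_{ab}$ sum
to one, $S(P)$ is a convex combination of the table entries: it is bounded
by the score range and independent of sequence length, which is what makes
scores of a 60-residue ribosomal protein and a 600-residue ATPase directly
comparable. A literal reading of the scoring formula in terms of raw pair
*counts* is preserved behind `scoreMode = "count"` in `scoreProteins()`,
but fraction weighting is the default: only a convex combination can keep
protein scores inside the [0, 1000] scale that propensity tables use.

### Phase 1 — statistical estimation

`estimateInitial()` computes, for every dipeptide, the difference between
its mean composition in the positive class and in the negative class. The
class mean averages *per-sequence fractions*, not pooled counts, so every
sequence contributes equally regardless of length — consistent with the
per-sequence feature definition. The 400 differences are min–max rescaled
onto $[0, 1000]$: the most positively enriched dipeptide scores exactly
1000, the most depleted exactly 0. Two consequences worth knowing:

* swapping the classes reflects the table through the midpoint,
  $s \mapsto 1000 - s$;
* if all differences are equal (identical classes), the rescale is
  undefined and every score is set to the midpoint 500 by convention.

### Phase 2 — genetic-algorithm refinement

The class-difference estimate ignores correlations between dipeptides;
`gaOptimize()` refines it against a discriminative objective. The fitness
of a candidate table is

$$\mathrm{Fit} = w_1 \cdot \mathrm{AUC}_{cv} + w_2 \cdot R,
\qquad w_1 = 0.9,\; w_2 = 0.1,$$

where $\mathrm{AUC}_{cv}$ is the mean held-out-fold AUC of the candidate's
protein scores under a stratified fold plan fixed once per run, and $R$ is
the Pearson correlation between the candidate's 400 scores and the initial
table's. The correlation term shrinks the search towards the statistical
estimate and is the method's overfitting guard; $R$ of a zero-variance
candidate is defined as 0 so fitness is total. Note the table is scored,
not re-fitted, inside each fold — fold averaging here is a smoothness
device for the objective, while honest reporting is the evaluation
module's job (below).

The GA internals follow standard continuous-GA practice, all settable via
`gaConfig()`:

| parameter | default | role |
|---|---|---|
| `populationSize` | 50 | candidate tables per generation |
| `generations` | 100 | search length |
| `crossoverRate` | 0.8 | probability of uniform per-gene crossover |
| `mutationRate` | 0.05 | per-gene Gaussian mutation probability |
| `mutationStep` | 50 | mutation and seeding SD, score units |
| `eliteCount` | 2 | individuals copied unchanged |
| `folds` | 10 | fitness cross-validation folds |
| `runs` | 10 | independent restarts in `gaOptimizeRepeated()` |

The seed population is the initial table plus Gaussian-perturbed copies;
selection is size-2 tournament; children are clipped to $[0, 1000]$ after
mutation. Elitism makes best-so-far fitness non-decreasing, and every
random choice flows from `seed`, so two runs with equal inputs are
bit-identical — both properties are asserted in the test suite.

After the search, the threshold is chosen by `chooseThreshold()`: the
midpoint between consecutive sorted unique training scores that maximizes
training accuracy, smallest midpoint on ties (when all scores are equal no
midpoint exists and the common score is returned). A post-hoc
accuracy-maximizing grid was preferred over encoding the threshold as a
401st gene because the AUC fitness is threshold-free and a deterministic
grid is exactly reproducible; one cutoff per model is what the method
reports.

`gaOptimizeRepeated()` restarts the GA `runs` times (seeds `seed + 0, ...,
seed + runs - 1`) and keeps the table with the highest fold-held-out MCC on
the training set, ties to the lower run index. Selection scores the fixed
optimized tables on held-out folds; it does *not* re-estimate per fold —
re-optimizing inside the selection loop would nest GA runs to no purpose,
since the choice is among already-trained tables.

### Evaluation

`computeMetrics()` implements accuracy, sensitivity, specificity and the
Matthews correlation coefficient from the 2×2 confusion tally, with
zero-denominator cases returning 0 so that reports are always complete.
`rocAUC()` is the rank statistic (probability a random positive outscores a
random negative, ties credited ½), which equals the trapezoidal ROC area
and needs no curve interpolation; it is cross-checked against an
independent ROC implementation in the tests. `crossValidate()` is the
honest protocol: inside every fold of a stratified seeded plan the table is
re-estimated, re-optimized and re-thresholded before touching the held-out
part, so reported numbers contain no leakage even though the GA's internal
fitness also fold-averages. `aggregateMetrics()` summarizes with the
arithmetic mean and the sample ($n-1$) standard deviation.

### Characterization

A residue's propensity is the average of the 40 dipeptide score slots that
contain it — 20 with the residue first and 20 with it second, so the
homodipeptide contributes twice. (Only 39 *distinct* dipeptides contain a
given residue; the 40-slot average with the homodipeptide double-counted is
the natural reading of "average over both positions" and keeps every
residue's denominator equal.) The 20 per-residue scores are correlated
(Pearson, pairwise deletion over residues present) against AAindex1
physicochemical scales by `correlateProperty()` and ranked by signed $R$ in
`rankProperties()`. The AAindex1 flat-file parser handles the canonical
two-row, ten-column `I` block with `NA` entries; a three-scale subset
(thermophile and mesophile intracellular surface composition, and a classic
hydrophobicity scale) ships in `inst/extdata/` together with a published
per-residue propensity column, so the characterization path is testable
offline — the bundled fixtures reproduce the published correlations 0.616,
0.348, 0.307 and 0.96 at their printed precision.

## The synthetic benchmark

`generateDataset()` builds a two-class dataset in which the ground truth is
known exactly. Negatives are drawn i.i.d. from a background residue
distribution (default uniform). Positives are drawn from a first-order
chain over positions $g+1$ apart: pair weights are the background products
multiplied by the planted enrichment map and renormalized per preceding
residue. Two construction details matter:

* **Markov, not residue shuffling** — the planted signal lives in pair
  composition, the quantity SCM actually models, rather than in
  single-residue frequencies alone.
* **Stationary start** — initial residues are drawn from the chain's
  stationary law, so every position is marginally stationary and the
  expected pair composition equals $\pi_a T_{ab}$ *exactly*;
  `plantedTruth()` returns these analytic expectations minus the
  background products, verified against a 5000-sequence Monte-Carlo
  estimate in the tests.

Defaults are 300 sequences per class with lengths uniform on 100–300 and
20 dipeptides enriched threefold at gap 0 — a clearly learnable but
non-trivial signal at a realistic protein-length scale. Randomness is
split into per-sequence substreams derived from one seed, so datasets are
reproducible and independent of generation order.

The default *layout* of the 20 enriched dipeptides deserves its own
paragraph, because it was a genuinely open design choice. A symmetric
layout (say, all pairs among a small residue set) makes the positive
chain's weight matrix symmetric, hence doubly stochastic after
normalization: the stationary law stays uniform and the analytic truth
collapses to just two distinct values — 380 dipeptides exactly tied. A
benchmark whose ground-truth ranking is degenerate cannot support recovery
analyses. The shipped default therefore grades both margins: first
residues E, K, R, V, I, D, G, L carry 5, 4, 3, 3, 2, 1, 1, 1 enriched
pairs, with second residues rotated through the remaining ten. Per-row
renormalization then depletes non-enriched pairs by a row-specific amount,
and column multiplicities spread the stationary frequencies, so the truth
vector takes many distinct values and its ranking is identifiable from
data of the default size. The first residues echo the charged/branched
enrichment observed in thermophilic proteomes. With these defaults the
rank correlation between `estimateInitial()` scores and `plantedTruth()`
is about 0.84 (asserted at $\ge 0.8$), a reduced GA reaches held-out AUC
near 0.99 (asserted at $\ge 0.9$), and null data stay at chance (CV
accuracy asserted inside [0.4, 0.6]).

What the simulator does **not** emulate: real thermophile background
composition (the default background is uniform), sequence redundancy and
family structure (no analogue of identity-based clustering), domain
architecture, or length–class correlations. Passing the benchmark
therefore shows the pipeline recovers planted pair-composition signal at
realistic noise levels — it does not certify performance on proteomes,
where redundancy control and distribution shift dominate.

## Numerical conventions and degenerate inputs

* Sequences shorter than $g+2$ are rejected with an explicit error, never
  zero-filled — a zero composition would break the sum-to-one invariant
  and silently score 0.
* Any character outside the 20 standard letters disqualifies a record in
  `filterStandard()` (ambiguity codes carry no composition information);
  case is folded and whitespace stripped at read time, and duplicate ids
  are an error because all reports key on id.
* The min–max rescale clamps at the bounds: floating-point arithmetic can
  overshoot $[0, 1000]$ by an ulp.
* Composition sums are exact to $10^{-9}$ by construction; equality
  assertions in the tests use that tolerance.
* Ranking tie-breaks are always lexicographic (protein ids, dipeptide
  names) so every ordering in the package is total and reproducible.
* Model files are JSON keyed by two-letter dipeptide strings: the internal
  alphabetical ordering is not observable on disk.

## Problem sizes in the test suite

The suite exercises the encoder against a naive double-loop oracle on 1250
random sequences across $g = 0\ldots9$; GA properties on datasets of 30–60
sequences per class with populations of 8–20 over 4–20 generations; and
the three end-to-end benchmark claims (recovery, held-out AUC, null
safety) at the full default 300 sequences per class with the reduced GA
configuration (population 20, 20 generations, 1–3 runs). These sizes keep
the complete suite under a minute on one core while leaving every claim
asserted at the benchmark's own study conditions.

## Known limitations

* The GA refines a linear scoring rule; interactions between dipeptides
  are only captured insofar as they project onto the 400 weights.
* Threshold selection maximizes training accuracy; on heavily imbalanced
  data a cost-sensitive criterion would be preferable (the package's
  balanced-split helper sidesteps this by construction).
* `splitBalanced()` discards surplus negatives; workflows needing all
  negatives should evaluate with `rocAUC()` directly, which is
  prevalence-free.
* Redundancy removal (identity clustering) is intentionally out of scope;
  users should supply pre-clustered sets, as inflated homology between
  train and test will inflate every reported metric.
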