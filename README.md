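# thermoSCM

Interpretable sequence-based prediction and characterization of thermophilic
proteins with the scoring card method (SCM).

## The problem and the method

Proteins from thermophilic organisms stay folded at 80–100 °C, which makes
them valuable in industrial enzymology — and makes rapid sequence-only
screening for thermostability useful long before a structure is available.
Black-box classifiers (SVMs and friends) predict this trait well but say
little a biochemist can act on. The scoring card method trades a little
accuracy for a model that *is* its own interpretation: a table of 400
propensity scores, one per ordered dipeptide.

A protein `P` of length `L` is encoded by its *g*-gap dipeptide composition

```
GDC(g) = [f_1, ..., f_400],   f_i = n_i / (L - g - 1)
```

where `n_i` counts ordered residue pairs separated by `g` intervening
residues (`g = 0` is classic dipeptide composition). Each dipeptide `i`
carries a propensity score `PS_i` on a [0, 1000] scale, and the protein's
score is the weighted sum

```
S(P) = sum_i  f_i * PS_i
```

classified as thermophilic when `S(P)` reaches a learned threshold. The
scores are first estimated statistically — the class-mean composition
difference of each dipeptide, min–max rescaled onto [0, 1000] — and then
refined by a genetic algorithm whose fitness

```
Fit = 0.9 * AUC_cv + 0.1 * R
```

balances cross-validated ranking performance against the Pearson correlation
`R` with the initial estimates (a guard against overfitting the search). The
GA is run several times and the table with the best cross-validated Matthews
correlation coefficient is kept. Averaging the 40 dipeptide scores that
contain a residue gives 20 amino-acid propensities, which can be correlated
against AAindex physicochemical scales to ask *why* the classifier works —
in thermophiles, chiefly the surface enrichment of charged residues.

The package implements the full workflow: FASTA input and nonstandard-letter
filtering, balanced train/test splitting, the GDC encoder, propensity
estimation and GA refinement, confusion-matrix/ROC evaluation with honest
cross-validation, AAindex-based characterization, and a two-class
Markov-chain sequence simulator with planted dipeptide biases for
benchmarking every stage without external data.

## Worked example

Train on a simulated benchmark (300 sequences per class, 20 dipeptides
enriched threefold in the positive class), then evaluate on a fresh draw:

```r
library(thermoSCM)

train <- generateDataset(simParams(seed = 7))
model <- trainSCM(train, g = 0,
                  gaConfig(populationSize = 20, generations = 20,
                           runs = 3, seed = 7))
model
#> PropensityTable ( optimized ) g = 0
#>   scores: [ 0 , 1000 ]  threshold: 288.17
#>   top dipeptides: LM DY GH RT RN

test <- generateDataset(simParams(seed = 8))
s <- scoreProteins(test, model)
m <- computeMetrics(confusionCounts(classLabels(test),
                                    classifyScores(s, cutoff(model))),
                    auc = rocAUC(s, classLabels(test)))
round(m[, c("acc", "sn", "sp", "mcc", "auc")], 3)
#>     acc   sn    sp   mcc   auc
#> 1 0.937 0.93 0.943 0.873 0.989

topDipeptides(model, 3)$highest
#>   dipeptide     score
#> 1        LM 1000.0000
#> 2        DY  991.1948
#> 3        GH  945.4130
```

The held-out accuracy of 0.937 and AUC of 0.989 say the planted signal is
recovered almost perfectly; the top-ranked dipeptides are all members of the
simulator's enriched set, which is exactly the interpretability the score
table is for. On real data, `aaPropensity(model)` and `rankProperties()`
against an AAindex1 file identify the physicochemical scales that track the
learned residue preferences (the bundled
`inst/extdata/aaindex1_thermo_subset.txt` carries the thermophile and
mesophile surface-composition scales and a hydrophobicity scale).

A command-line front end for shell pipelines lives at
`inst/scripts/scm-tool.R` (`simulate`, `train`, `predict`, `score-table`,
`characterize`, and an `experiment` subcommand that runs the full g-gap
sweep with honest cross-validation on user-supplied FASTA files).

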