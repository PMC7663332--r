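# corrqsar

QSAR modelling of F508del-CFTR corrector potency in R.

Cystic fibrosis is most often caused by the F508del mutation of the
CFTR chloride channel; *correctors* are small molecules that rescue
trafficking of the misfolded channel to the plasma membrane, with
potency measured as pEC₅₀ (−log₁₀ molar half-maximal concentration).
`corrqsar` implements a complete quantitative structure–activity
relationship pipeline for this problem:

* **Descriptors** — the six retained potency descriptors computed from
  a 3D structure: nonbonded energy `E_nb` and angle-bend energy `E_ang`
  (kcal/mol), negatively charged accessible surface `ASA_neg` (Å²),
  charge-weighted accessible surfaces `CASA_pos`/`CASA_neg` (Å²·e) and
  polar van der Waals surface `vsa_pol` (Å²), via a deterministic
  Shrake–Rupley surface engine, Gasteiger-type charge assignment and a
  generic LJ/Coulomb/harmonic force field (SDF V2000 and XYZ input).
* **Design** — Kennard–Stone maximin train/test selection on the
  autoscaled, response-augmented descriptor matrix; PCA display scores.
* **Pruning and regression** — contingency ranking (equal-frequency
  binning + Cramér's V, top-50 retention), NIPALS PLS1, leave-one-out
  q², relative-importance (RI) iterative elimination, and the external
  predictivity statistic r²pred = (SD − PRESS)/SD.
* **Reference data** — the 80-compound corrector corpus (VX-809,
  hybrids, tetrahydropyridopyrimidines, cyanoquinolines) with every
  individually printed pEC₅₀/descriptor value and the exact model A/B
  train/test rosters, plus the two published scoring equations as
  inspectable `ScoringEquation` objects.
* **Synthetic data** — a seeded generator of descriptor/activity tables
  with known ground truth (informative + decoy columns, collinearity,
  activity-window clipping, optional floor censoring) so every pipeline
  stage is testable end to end.

The model at the core is linear PLS regression
pEC₅₀ = b₀ + Σⱼ bⱼ·xⱼ fitted on autoscaled descriptors, with latent
dimension chosen by leave-one-out q², descriptors eliminated when
RIⱼ = |βⱼ*|/max|β*| falls below 0.10, and external validation by
r²pred. See `vignette("corrector-qsar")` for every methodological
choice and its rationale.

## Worked example

```r
library(corrqsar)

## the in-package corpus: printed potencies and descriptor values
corp <- loadCorpus()
head(corp[!is.na(corp$E_nb), c("id", "series", "pec50", "E_nb", "CASA_pos")], 3)
#>   id series pec50  E_nb CASA_pos
#> 3  3 hybrid  6.52 40.20  1154.36
#> 4  4 hybrid  6.26 40.07  1153.63
#> 5  5 hybrid  6.05 39.97  1154.36

## the published model-A equation, and a prediction from it
eqA <- builtinEquation("A")
eqA
#> ScoringEquation 'model_A' (raw descriptor scale)
#>   pEC50 = 12.91882 - 0.10591 * E_nb - 0.01931 * ASA_neg - 0.04699 * vsa_pol
#>           + 0.00260 * CASA_pos + 0.00658 * CASA_neg - 0.02034 * E_ang
v <- setNames(c(40.07, 25, 300, 1153.63, 350, 60), descriptorNameSet())
predictEquation(eqA, v)
#> [1] 4.856544

## full pipeline on a synthetic table with known ground truth
tab <- simulateTable(syntheticSpec(seed = 1))          # 80 x (6 + 44)
X   <- as.matrix(tab$X)
sp  <- kennardStoneSplit(X, tab$y, nTrain = 60, augment = TRUE)
cr  <- contingencyRank(X[sp$trainIdx, ], tab$y[sp$trainIdx], topK = 50)
el  <- iterativeElimination(X[sp$trainIdx, cr$retained, drop = FALSE],
                            tab$y[sp$trainIdx], riThreshold = 0.1)
el$model
#> PLSModel: 21 descriptors, 5 latent variable(s)
#>   r2_ncv = 0.9886, rmse = 0.0844, r2_cv = 0.9719
#>   top RI: E_nb, CASA_pos, ASA_neg
ev <- evaluateTest(el$model, tab$X[sp$testIdx, ], tab$y[sp$testIdx],
                   mean(tab$y[sp$trainIdx]))
round(ev$r2_pred, 3)
#> [1] 0.931
```

All six planted informative descriptors survive elimination and top the
RI ranking (`E_nb` 1.000, `CASA_pos` 0.785, `ASA_neg` 0.746, ...),
followed by the surviving decoys; the held-out r²pred of 0.93 reflects
the generator's noise level. A command-line wrapper with the same
stages as subcommands is installed at `inst/scripts/corrqsar`
(`corpus`, `descriptors`, `split`, `train`, `evaluate`, `predict`,
`simulate`).

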