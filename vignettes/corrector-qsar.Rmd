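---
title: "Methods: QSAR modelling of F508del-CFTR corrector potency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QSAR modelling of F508del-CFTR corrector potency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corrqsar)
```

## The problem

Correctors are small molecules that improve trafficking of the misfolded
F508del-CFTR chloride channel to the plasma membrane; their potency is
reported as pEC~50~ (negative log~10~ molar half-maximal concentration,
higher = more potent). `corrqsar` implements a quantitative
structure-activity relationship (QSAR) pipeline linking computed
molecular descriptors of a corrector's 3D structure to its pEC~50~:
descriptor computation, training/test design, descriptor pruning,
partial least squares (PLS) regression with variable elimination and
cross-validation, and external validation.

The package also ships, as fixed reference objects, the published
80-compound corrector roster (compound 1 = VX-809, 2--29
aminoarylthiazole-VX-809 hybrids, 30--56 tetrahydropyridopyrimidines,
57--80 cyanoquinolines) with every individually printed potency and
descriptor value, the two published train/test designs, and the two
published scoring equations.

## The six descriptors

The retained descriptor set mixes force-field energy terms with
charge-partitioned surface areas:

| name | definition | units |
|---|---|---|
| `E_nb` | nonbonded potential energy (Lennard-Jones + Coulomb over pairs not 1-2/1-3 bonded) | kcal/mol |
| `E_ang` | harmonic angle-bend energy, $\sum k_\theta (\theta - \theta_0)^2$ | kcal/mol |
| `ASA_neg` | water-accessible surface area of atoms with partial charge strictly below 0 | Å² |
| `CASA_pos` | ASA⁺ × max positive partial charge | Å²·e |
| `CASA_neg` | ASA⁻ × \|extreme negative partial charge\| | Å²·e |
| `vsa_pol` | van der Waals surface area of atoms that are both hydrogen-bond donors and acceptors | Å² |

Engine choices, each overridable through `descriptorConfig()` and the
force-field table:

* **Surface sampling.** Shrake-Rupley style numerical sampling on a
  deterministic Fibonacci lattice, default 960 points per atom and a
  1.4 Å probe (a water-sized probe; "water accessible" fixes the probe,
  not the point count, which we chose for <1% error on sphere
  fixtures). Sampling runs in the molecule's principal-axes frame, so
  areas are exactly invariant under rigid-body motion of the input
  coordinates; for molecules with exactly degenerate principal moments
  the frame is ambiguous and invariance holds only to the lattice
  error. `vsa_pol` uses the same engine at probe radius 0.
* **CASA⁻ convention.** "Extreme negative charge" is ambiguous: read
  literally, the maximum over negative charges is the *least* negative
  one. Both conventions are exposed
  (`casaNegMode = "least_negative"` (default, the literal reading) or
  `"most_negative"`), and the magnitude is reported positive so that a
  positive regression coefficient on `CASA_neg` stays interpretable.
* **Charges.** Input files may carry per-atom charges (SDF data field
  `ATOM.PARTIAL.CHARGES`, or a 4th XYZ column); otherwise
  `assignCharges()` computes Gasteiger-Marsili iterative partial
  equalization of orbital electronegativities (6 damped cycles). This
  is a classical empirical scheme, not the semi-empirical AM1
  population analysis used by commercial modelling suites, so absolute
  charge-weighted descriptor values are comparable only within one
  scheme.
* **Radii and force field.** Bondi van der Waals radii; a small generic
  Lennard-Jones/Coulomb/harmonic-angle parameter table of
  CHARMM/UFF-magnitude values shipped in `defaultForcefield()`. Any
  table can be substituted (`loadForcefield()`), including 1-4 scaling
  (default 1.0 = unscaled, a deliberate neutral default since no
  scaling convention is universal).
* **Donor/acceptor rule** (data-driven, for `vsa_pol`): O or N with at
  least one bonded H is a donor; any O is an acceptor; N is an acceptor
  unless π-deficient (amide-like: bonded to a carbon double-bonded to
  O; nitro-like: bonded to two or more oxygens).
* **Connectivity.** SDF bond blocks are taken verbatim; XYZ carries no
  bonds, so they are inferred when the separation is below 1.2 × the
  covalent-radius sum.

The engine reproduces the *definitions* of the descriptors. It does not
reproduce the numeric values a proprietary engine produced for the real
80 compounds: those depended on docking-derived conformers and a
proprietary force field, and neither structures nor conformers are
published. That is why the corpus carries printed values as data rather
than recomputing them.

## Training/test design

`kennardStoneSplit()` implements the classic deterministic maximin
design: autoscale columns (mean 0, sd 1; zero-variance columns dropped
with a warning), pick the most distant pair first, then repeatedly add
the sample maximizing its minimum Euclidean distance to the selected
set. With `augment = TRUE` (the default) the response is appended as an
additional autoscaled column, so training compounds cover the potency
range as well as descriptor space. Ties are broken by lowest row index,
making the split fully deterministic. Autoscaling before the distance
computation is standard chemometric practice and is switchable off
(`scale = FALSE`) since the original software's behaviour is not
documented. The published manual design (model A) is wrapped by
`manualSplit()` so both designs flow through one interface.
`pcaScores()` provides the usual autoscaled-PCA display of a design.

## Descriptor pruning and PLS

`contingencyRank()` discretizes each descriptor and the response into
equal-frequency bins (default 4) and scores the descriptor × response
contingency table with Cramér's V. The commercial contingency module it
stands in for is unpublished; Cramér's V is a transparent surrogate with
the right properties (in [0, 1], 1 for a descriptor identical to the
response, 0 for a constant, invariant to monotone transforms under
equal-frequency binning). The scorer operates per column, so any other
association measure can be swapped in. The top 50 descriptors are
retained by default.

`plsFit()` is NIPALS PLS1 on autoscaled descriptors with a centred
response; coefficients are back-transformed to the original descriptor
scale so `intercept + X %*% coef` reproduces fitted values to machine
precision. With full components it equals ordinary least squares, which
the tests verify against a normal-equations oracle. The component count
is chosen to maximize leave-one-out q² over 1..6
(`chooseComponents()`); the published work states leave-one-out
validation but no component rule, so the q²-maximizing rule is this
package's documented choice, and a fixed count can be forced.

Relative importance is defined as RI~j~ = \|standardized
coefficient~j~\| / max~k~ \|standardized coefficient~k~\|, so the
leading descriptor scores exactly 1 — consistent with the published RI
tables, whose top entry is printed as 1.000000. The original RI formula
is unpublished; this surrogate is pluggable. `iterativeElimination()`
repeats fit → RI → drop-below-threshold until a fixed point; the
threshold (default 0.10 per round) is again this package's choice since
only the principle, not the cutoff, is published. Because the maximum
RI is 1, at least one descriptor always survives, and the retained-set
sizes in the trace decrease strictly until the fixed point.

External validation uses r²~pred~ = (SD − PRESS)/SD with SD the squared
deviation of test activities from the *training* mean and PRESS the
squared test prediction error; `evaluateTest()` also returns the
per-compound predictions and residuals behind
predicted-vs-experimental and residual plots. Leave-one-out q² is
defined by the literal leave-out loop; the accelerated per-component
scan used internally is tested to agree with that loop to 1e-9.

`bootstrapCoefSE()` provides case-resampling standard errors of the
coefficients. Each bootstrap replicate re-runs the *whole* procedure,
including the leave-one-out component re-selection, because a CV-tuned
PLS coefficient's uncertainty includes which rank the tuning picks; a
fixed-rank bootstrap understates it, particularly on collinear
descriptor tables where low-rank PLS shrinks coefficients.

## The published equations

`builtinEquation("A")` and `"B"` ship the two published linear scoring
functions digit-for-digit. Two transcription issues are handled
explicitly rather than silently:

* Equation A's third term is printed as "ASA", but the retained
  descriptor set contains ASA⁻ and no plain ASA; the coefficient is
  mapped to `ASA_neg` and the reading is recorded in the equation's
  metadata.
* Equation B's coefficient magnitudes (e.g. −3.7 on an energy spanning
  tens of kcal/mol, against equation A's −0.106) are only compatible
  with autoscaled descriptors. It is therefore shipped with
  `descriptorScale = "autoscaled"`; since the centring/scaling vectors
  were never published, predicting raw descriptor vectors with model B
  requires user-supplied `center`/`scale` and errors otherwise.

No claim is made that these equations reproduce per-compound published
predictions: the descriptor matrix behind them is not available.

## The synthetic-data generator

`simulateTable()` emulates the *statistical shape* of the study:
80 compounds, six informative descriptor columns named after the real
ones, decoy columns of standard-normal noise (44 by default, giving a
50-column pruned-pool-sized table; 296 emulates a full 302-column
descriptor registry), and a linear response with Gaussian noise
(sd 0.2) clipped to the observed activity window [4.0, 7.1], with
clipping events logged. A `censor` switch shifts the response down
before clipping to reproduce the many-compounds-at-4.00 floor of the
real data.

Design of the defaults, chosen once and documented here:

* **Ranges** follow the printed per-series values: `E_nb` spans 35-160
  kcal/mol across the three series, `CASA_pos` 600-2300 Å²·e; the four
  descriptors without printed ranges use magnitudes plausible for
  drug-sized molecules (`E_ang` 5-45 kcal/mol, `ASA_neg` 150-600 Å²,
  `CASA_neg` 100-700 Å²·e, `vsa_pol` 10-120 Å²).
* **Coefficient signs** follow the published raw-scale equation;
  magnitudes are set so each informative descriptor contributes a
  response s.d. of ~0.13-0.25 pEC~50~ units, keeping the simulated
  response centred near 5.5 with s.d. ~0.75, i.e. inside the activity
  window with only occasional floor events.
* **Collinearity.** Real descriptor tables are strongly collinear —
  that is the reason the field fits them with PLS rather than OLS. The
  generator therefore includes a latent factor (default level 0.4
  through a Gaussian copula) loading on each informative descriptor in
  its potency-favourable direction: potent compounds have co-occurring
  favourable surface/energy profiles. With six *independent* columns
  the marginal descriptor-response correlations are bounded by
  $\sum_j r_j^2 \le 1$, which makes a binned association screen unable
  to separate the weakest informative column from hundreds of null
  decoys at n = 80 — an unrealistic regime, not a property of the
  method.
* Seeds are mandatory and the caller's RNG state is restored, so there
  is no hidden global randomness.

What passing tests on this generator do show: the screening, elimination,
fitting and validation machinery recovers planted structure under
realistic sample size, collinearity, noise and censoring. What they do
not show: anything about real chemistry — the generator draws
descriptor values directly and no molecular structures stand behind the
tables. The 3D toy molecules (`toyMolecule()`) exist solely to test the
descriptor engine against closed-form oracles.

## Numerical choices and degenerate inputs

* Kennard-Stone and elimination ties break deterministically (lowest
  row index; elimination drops all below-threshold descriptors per
  round).
* Zero-variance columns are dropped with a warning wherever autoscaling
  occurs; an all-zero coefficient vector, a test set with SD = 0,
  coincident atoms in an energy term, and a response orthogonal to all
  descriptors raise errors rather than returning quiet numbers.
* Descriptor computation is bit-deterministic given configuration;
  equal-frequency binning falls back to distinct values when a column
  has fewer distinct values than bins, and a constant column scores 0.

## Problem sizes used by the shipped checks

The test-suite and acceptance script exercise: 100 random Kennard-Stone
instances with n ≤ 12 against a brute-force maximin oracle; 60 × 6
full-rank tables for the PLS = OLS identity; a 30 × 4 table for the
leave-one-out loop identity; 20 seeds of the default 80 × 50 table for
the recovery study (with 60 procedure-bootstrap replicates per seed);
and single 80-row tables for the end-to-end Kennard-Stone pipeline.

## Known limitations

* Real-corpus descriptor values cannot be recomputed (structures and
  conformers unpublished); the corpus is reference data only.
* The charge scheme, radii and force-field parameters are generic and
  documented, not the proprietary ones behind the published models, so
  published per-compound statistics are stored reference metadata, not
  recomputable quantities.
* Model B predictions require user-supplied scaling (see above).
* The donor/acceptor rule is a small pattern table, adequate for the
  descriptor definition but not a full pharmacophore perception.
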