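---
title: "Methods: local-to-global scoring of protein-RNA binding affinity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: local-to-global scoring of protein-RNA binding affinity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panther)
```

## The model and its assumptions

`panther` treats protein–RNA binding as additive over local contacts. The
unit of decomposition is the (amino-acid residue, nucleotide) pair; for
each pair the *local interaction energy* is the sum of a Lennard-Jones and
a Coulomb term over all atom pairs of the two groups,

$$E_{ij} = \sum_{a \in i}\sum_{b \in j}
  4\varepsilon_{ab}\!\left[\left(\tfrac{\sigma_{ab}}{r_{ab}}\right)^{12}
  - \left(\tfrac{\sigma_{ab}}{r_{ab}}\right)^{6}\right]
  + \sum_{a \in i}\sum_{b \in j}
  \frac{k_e\, q_a q_b}{\varepsilon_r\, r_{ab}},$$

and the complex-level score is a normalized, distance-weighted sum of
per-pair energies,

$$\mathrm{score} = \sum_i \omega_i E_i,\qquad
  \omega_i = \frac{e^{-r_i/r_0}}{\sum_j e^{-r_j/r_0}},$$

with $r_i$ the pair's center-of-mass (COM) distance. The working
assumptions are: (1) binding energetics are approximately additive over
interface pairs; (2) the dominant signal in a pair's energy is carried by
four cheap features — residue type, base type, COM distance, hydrogen-bond
count — so a regression model can replace the physics (and the simulations
behind it) at prediction time; and (3) relative affinity (ranking) is the
quantity of interest: the score correlates with experimental $\Delta G$
without being calibrated to it. No solvent, entropy or long-range
correction terms are included; the regression absorbs overall scale.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `r_cut` | 12 | Å | COM cutoff for pair identification and trajectory presence |
| `window` | 10 | frames | averaging window $N$ in $\langle E_{ij}\rangle = \frac1N\sum_t E_{ij}(t)$ |
| `skip` | 40 | frames | frames skipped between windows (decorrelation) |
| `persistence_threshold` | 0.70 | — | minimum fraction of analyzed frames inside `r_cut`; inclusive ($\ge$) |
| `r0` | 9 | Å | decay length of the integration weights |
| `max_h_acceptor_dist` | 3.5 | Å | H···acceptor distance bound (strict `<`) |
| `min_angle`, `max_angle` | 120, 180 | degrees | donor–H···acceptor window, measured at H |
| `placed_bond_length` | 1.0 | Å | bond-vector hydrogen placement distance |
| `dielectric` | 1.0 | — | relative permittivity $\varepsilon_r$ |
| `coulomb_constant` | 332.0636 | kcal·Å·mol⁻¹·e⁻² | $k_e$, converts e²/Å to kcal/mol |
| `split_fraction`, `cv_folds` | 0.8, 10 | — | train/validation split and CV depth |
| `n_permutations` | 30 | — | permutation-importance repeats |

The identification cutoff (12 Å) and the decay length (9 Å) are distinct
knobs deliberately: pairs are *found* out to 12 Å, but the weighting
already suppresses them strongly beyond ~9 Å, so the two act as a coarse
gate plus a soft prior. Both are config keys (`default_config()`).

## Design choices where the design was open

**Combining rules.** Per-atom LJ parameters are combined with
Lorentz–Berthelot rules (geometric-mean $\varepsilon$, arithmetic-mean
$\sigma$), the standard for the additive biomolecular force-field family
this decomposition mimics. `parameter_table()` exposes `combine_eps` /
`combine_sigma` as function slots for pre-combined or exotic rules.

**Dielectric.** No implicit-solvent permittivity is canonical here; the
default is $\varepsilon_r = 1$ and the value is a prominent, documented
knob. Since the regression model is trained on energies computed under the
same convention, the choice cancels out of rankings.

**Persistence accounting.** "70 % of the simulation time" is
operationalized as the fraction of *analyzed* frames (frames inside
sampled windows) with COM distance ≤ `r_cut`, threshold inclusive. Only
analyzed frames have computed energies, so this is the only fraction the
pipeline can evaluate without extra cost. Window means are taken over
present frames only, and windows with no presence are excluded from the
pair's mean — treating out-of-cutoff frames as zero-energy would bias
retained means toward zero.

**Hydrogen-bond geometry.** Donors and acceptors are N/O heavy atoms
assigned from an editable table (backbone N/O, polar side-chain termini,
ribose 2'-OH, phosphate oxygens, base N/O); this is standard geometric
H-bond practice. When a donor has no explicit hydrogen, one is placed
`placed_bond_length` along the donor→acceptor unit vector. Note that this
placement makes the D–H···A angle exactly 180°, so for placed hydrogens
the angle window is vacuous and detection reduces to a distance test —
the package implements both the placed-H and explicit-H paths and the test
suite asserts this equivalence rather than hiding it. Counting covers
both directions (protein donor → RNA acceptor and vice versa).

**RNA decomposition unit.** The full nucleotide residue's atoms enter the
COM and the energy sums, while the reported type code is the base letter;
full-residue COMs are well defined for every input, whereas base-only
atom subsets are not always present.

**Score form.** The single canonical integration formula is the
normalized-$\omega$ discretization above. Because the weights are
normalized, the score is a weighted *average*; when all distances are
equal it coincides with the plain mean. No slope/intercept rescaling
toward experimental $\Delta G$ is fitted.

**Model zoo backends.** Families map to `stats::lm`, `randomForest`,
`xgboost` (twice: a conservative depth-3/η=0.1 profile for classical
gradient boosting and a depth-6/η=0.3 profile for extreme gradient
boosting), and `nnet`. The neural-network family is therefore a
single-hidden-layer sigmoid network (default 16 units, weight decay 1e-3)
rather than a deep ReLU stack — at the feature dimensionality involved
(26 columns) one hidden layer has ample capacity, and it keeps the
dependency footprint small. The stacked ensemble is the unweighted mean of
the three tree-based models ("direct aggregation"); no meta-learner is
fitted. Default grids are deliberately compact (e.g. forests search
`mtry` ∈ {5, 10} at 200 trees) and overridable; grid search minimizes
cross-validated MAE and ties break toward the first grid entry, so results
are reproducible run-to-run.

**Degenerate inputs.** Zero-variance numeric features standardize to 0
instead of raising, so degenerate fixtures run; constant regression
targets flag the fit as degenerate with undefined correlations rather than
reporting a number; a complex with no interface pairs is reported
*unscorable*, never given a fabricated score; coincident atoms raise a
clash error rather than returning infinities.

**Numerical details.** Weights are computed with a min-shifted exponent,
making the $r_0 \to 0^+$ limit (all weight on the closest pair) stable;
the $r_0 \to \infty$ limit recovers the unweighted mean. The COM cutoff
is inclusive (≤), the H-bond distance bound strict (<), both tested at
their boundaries. Trajectory windows start at frame 1 with no burn-in
discard — equilibration is upstream of this package.

## What the synthetic generators emulate — and what they do not

`gen_complex()` builds complexes from small residue templates recentred so
planted COM distances hold to PDB precision (±1e-3 Å), with donor/acceptor
geometry arranged to plant exactly 0 or 1 hydrogen bond per pair;
`gen_trajectory()` realizes exact presence fractions on the analyzed
frames by displacing a pair's RNA group far outside the cutoff;
`gen_feature_table()` draws features and computes energies from documented
closed forms (additive linear; a Morse-like distance decay whose depth and
equilibrium shift with residue type, giving a genuine type-by-distance
interaction; an H-bond-dominated form), plus Gaussian noise (default SD
0.5 kcal/mol at the study size of 5,000 records). These energy functions
are intentionally *not* the package's Lennard-Jones/Coulomb code, so
recovery tests cannot pass by circularity.

The generators do not mimic real force-field magnitudes, real RNA
backbone geometry, conformational correlation between frames, or the
feature distributions of crystallographic interfaces. Passing tests
therefore demonstrate that the machinery is correct — energies match
independent sums, bookkeeping is exact, models recover a known signal,
integration preserves ranking — not that any particular accuracy will be
achieved on experimental complexes; that depends on the quality of the
trajectory-derived training data supplied by the user.

## Problem sizes used in tests

The suite exercises: 100 random group pairs against a naive double-loop
energy oracle; a 10,000-frame trajectory (200 windows) with window means
checked against brute force; persistence boundaries planted at 139/200 and
140/200 analyzed frames; regression recovery at n = 5,000 records
(80/20 split, 10-fold CV); permutation importance at 30 permutations on a
2,000-record table; and ranking recovery over 20 synthetic complexes.
These sizes were chosen so each property is measured with comfortable
statistical margin while a full run stays cheap on one CPU.

## Known limitations

- Static-structure scoring ignores conformational averaging entirely; the
  regression carries whatever dynamics were present in its training data.
- The energy model is strictly pairwise LJ + Coulomb: no polarization,
  solvent, entropy, or long-range (Ewald-type) treatment.
- The feature set is minimal by design (type, type, distance, H-bonds);
  `fit_encoding()` accepts extra numeric columns as a registry hook but
  ships none.
- The donor/acceptor table covers standard residues only; nonstandard
  residues are skipped with a warning, not modelled.
- mmCIF input, protonation-state prediction and structure repair are out
  of scope; inputs are assumed chemically complete.
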