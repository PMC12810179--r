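# panther

Local-to-global scoring of protein–RNA binding affinity in R.

Predicting the binding free energy (ΔG) of a protein–RNA complex from its
structure is hard: experimental affinities are scarce, and global,
interface-averaged descriptors generalize poorly. `panther` implements a
*local-to-global* alternative: the binding interface is decomposed into
amino-acid/nucleotide pairs, each pair gets a **local interaction energy**,
and the per-pair energies are integrated into one per-complex score
(kcal/mol) that is intended to *correlate* with experimental ΔG and to rank
complexes — not to reproduce absolute ΔG values.

## The model

**Physics tier.** The local energy of amino acid *i* and nucleotide *j* is a
pairwise nonbonded sum over their atoms,

```
E_ij = E_vdw,ij + E_elec,ij
E_vdw,ij  = Σ_{a∈i} Σ_{b∈j} 4 ε_ab [ (σ_ab/r_ab)^12 − (σ_ab/r_ab)^6 ]
E_elec,ij = Σ_{a∈i} Σ_{b∈j} k_e q_a q_b / (ε_r r_ab)
```

with Lorentz–Berthelot combining rules and k_e = 332.0636 kcal·Å·mol⁻¹·e⁻².
Pairs are selected at a 12 Å center-of-mass (COM) cutoff. For multi-frame
trajectories (multi-model PDB), energies are averaged over 10-frame windows
separated by 40 skipped frames, ⟨E_ij⟩ = (1/N) Σ_t E_ij(t), and only pairs
present inside the cutoff for ≥ 70 % of analyzed frames are retained —
transient contacts are noise, not signal.

**Regression tier.** A model zoo (linear, random forest, gradient boosting,
extreme gradient boosting, stacked ensemble, neural network) learns E_ij
from four cheap interface features: amino-acid type, base type, COM
distance, and a geometric hydrogen-bond count (donor–H···acceptor < 3.5 Å,
angle 120–180°, with bond-vector hydrogen placement at ~1 Å when the
structure has no explicit hydrogens). Numeric features are standardized,
categories one-hot encoded; hyperparameters are grid-searched under 10-fold
cross-validation on MAE.

**Integration tier.** Predicted energies are combined with normalized
exponential-decay weights,

```
score = Σ_i ω_i E_i ,   ω_i = exp(−r_i/r₀) / Σ_j exp(−r_j/r₀) ,  r₀ = 9 Å
```

so closer pairs dominate. Because Σ ω_i = 1 the score is a weighted average
of local energies and lies within their range.

A synthetic-data module (`gen_complex()`, `gen_trajectory()`,
`gen_feature_table()`) generates geometrically valid complexes,
persistence-controlled trajectories and feature tables from documented
closed-form energy functions, so the whole pipeline is testable with known
ground truth and no simulations.

## Worked example

```r
library(panther)

# a synthetic complex with two planted interface pairs
b <- gen_complex(seed = 1)
x <- parse_structure(b$pdb, pdb_id = "SYN001")
find_pairs(x)
#>   p_group r_group chain_p res_p  aa chain_r res_r nt com_distance
#> 1       1       4       A     1 ASP       B     1  A     6.999186
#> 2       2       5       A     2 GLU       B     2  A     7.999902

# train a random forest on a synthetic feature table
ft <- gen_feature_table(5000, "nonlinear_interaction", noise_sd = 0.5, seed = 42)
s  <- split_train_validation(ft$records, 0.8, seed = 42)
rf <- train_model(s$train, model_spec("random_forest", seed = 42),
                  validation = s$validation)
rf
#> panther_model [random_forest], seed 42
#>   validation: r = 0.974, MAE = 0.543 kcal/mol

# score the complex
score_complex(x, rf)
#> complex SYN001: score -1.524 kcal/mol over 2 pair(s)
```

The validation line says the forest reproduces the generator's held-out
local energies with Pearson r = 0.974 and a mean absolute error of about
0.54 kcal/mol; the final line is the distance-weighted average of the two
predicted pair energies. For trajectory-mode training data, feed a
multi-model PDB through `decompose_trajectory()` and
`records_from_decomposition()`; a shell pipeline
(`decompose` / `train` / `score` / `evaluate`) lives at
`inst/cli/panther.R`.

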