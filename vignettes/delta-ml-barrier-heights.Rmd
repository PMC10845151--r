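---
title: "Correcting semiempirical barrier heights by delta-machine-learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting semiempirical barrier heights by delta-machine-learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Reaction barrier heights (BH) — the energy of the transition state above the
reactant, zero-point energies included — control gas-phase kinetics, but
DFT-quality barriers are too expensive for the large reaction networks of
combustion or astrochemistry. Semiempirical methods (PM7-style) are orders of
magnitude cheaper and orders of magnitude less accurate for transition
states. `deltaBH` implements the delta-ML strategy: learn the *correction*

$$\Delta = \mathrm{BH}^{\mathrm{DFT}} - \mathrm{BH}^{\mathrm{PM7}}$$

from descriptors that are free once the low-level calculation exists, and
report $\mathrm{BH}^{\mathrm{PM7}} + \hat\Delta$. Both barrier heights are
defined as $(E_{TS} + \mathrm{ZPE}_{TS}) - (E_{R} + \mathrm{ZPE}_{R})$ in
kcal/mol.

## Dataset curation

A record is usable only if the low-level surface connects the same reactant
and product as the reference surface. The screening flow implemented in
`curateRecord()` mirrors the standard practice:

1. discard records whose low-level TS optimization failed (an input flag —
   the package runs no quantum chemistry);
2. compare both IRC endpoints with the dataset reactant and product by the
   eigenvalues of the adjacency matrix with atomic numbers on the diagonal
   (`spectrumFingerprint`). Both direction assignments are tried, because
   nothing fixes which IRC direction is "forward"; ties break in favor of
   forward-as-reactant. Any unmatched endpoint discards the record;
3. compare the low-level *optimized* endpoint and dataset structures with a
   weighted fingerprint (`weightedFingerprint`) to reject conformer changes.

Eigenvalue comparison is permutation-invariant, which is the point: no atom
mapping is needed. The cost is that cospectral graphs and enantiomers are not
distinguished; both limitations are accepted and documented.

**Two weighted forms.** The conformation fingerprint weights *every* atom
pair with $w_{ij} = (r_i^{cov} + r_j^{cov})/d_{ij}$. Weighting only bonds
would be blind to torsions (no bonded distance changes between rotamers), so
the all-pairs form is required for the comparison to mean "same conformer".
The weighted Laplacian spectral gap $\lambda_1^{TS}$, by contrast, uses
bond-only weights: the Laplacian of a bond-weighted graph keeps one zero
eigenvalue per fragment, so the gap retains its meaning as a tightness /
connectivity measure and is reported as 0 for multi-fragment structures.
Defaults: bond detection at $d_{ij} \le 1.2\,(r_i^{cov}+r_j^{cov})$ with
Cordero-style radii for H/C/N/O; connectivity tolerance $10^{-4}$ on
eigenvalues; conformation tolerance $10^{-3}$ (looser, because the structures
compared come from different optimizers). All are config keys.

## Descriptors

Four families, assembled by `assembleFeatures()` with family-prefixed,
reproducibly ordered columns:

* **`rdkit.`** — standard 2D cheminformatics descriptors of reactant and
  product SMILES, computed with the ChemmineR/ChemmineOB (OpenBabel) backend
  (~18 registered descriptors: OpenBabel property set plus formula and graph
  counts). Each descriptor enters as the signed difference
  product − reactant; descriptors on a fixed declared invariant list
  (molecular weight, atom counts — conserved in any atom-balanced reaction)
  enter as raw values. The invariant list is declared rather than detected at
  runtime so column semantics never change per reaction. An averaged variant
  `(P+R)/2` is available behind the `mode` switch for auditability.
* **`topol.`** — topological indices of the TS graph: Randić connectivity,
  the weighted-Laplacian spectral gap $\lambda_1^{TS}$, the Estrada index,
  the first Zagreb index (the common unqualified meaning; the second Zagreb
  index sits behind a flag) and degree statistics. Randić/Estrada/Zagreb are
  computed on the unweighted graph; only $\lambda_1$ uses weights, tying it
  to the 3D tightness of the TS.
* **`bonds.`** — formed/broken bond counts per element pair (+HH, −CH, ...),
  20 fixed columns. Atom mapping is positional, valid because curation
  guarantees IRC-connected structures.
* **`pm7.`** — low-level scalars: the barrier height and its rate proxy
  $e^{-\mathrm{BH}}$ (the bare exponential of the kcal/mol value — a
  unit-bearing monotone transform, kept alongside the raw BH), the absolute
  imaginary TS wavenumber, the three pairwise ZPE differences among R/TS/P,
  Koopmans hardness $\eta = (\varepsilon_{LUMO}-\varepsilon_{HOMO})/2$ and
  Mulliken electronegativity
  $\alpha = -(\varepsilon_{LUMO}+\varepsilon_{HOMO})/2$ at the TS (eV), the
  reactant−product self-polarizability difference, the low-level reaction
  energy $\Delta E_r$, and the TS bond-order-matrix eigenvalues sorted
  descending and zero-padded to a fixed width (default 10) so feature vectors
  have constant width across molecule sizes.

**Correlation pruning.** Highly collinear columns are removed by a greedy
scan in column order: a column is dropped iff its absolute Pearson
correlation with an already-retained column exceeds 0.9 (the conventional
threshold for this filter; configurable). Keep-first tie-breaking makes the
retained set reproducible; the filter is computed on training rows only and
applied everywhere, to avoid test-set leakage. The filter is idempotent and
monotone in the threshold.

## Models

Data are split 85/5/10 (train/validation/test) by a seeded permutation.
Three heads predict $\Delta$ in kcal/mol:

* **Gradient-boosted trees (`xgb`)** — XGBoost with a small documented grid
  (learning rate × depth) scored by 5-fold cross-validated MAE, boosting
  rounds by early stopping on the validation split; single-threaded and
  bit-reproducible given the seed. Gain importances from this head define the
  reduced descriptor set X′ (top 49 by default) fed to the GP.
* **Gaussian process (`gp`)** — exact GP with a Matérn-5/2 kernel, a single
  shared lengthscale (ARD off: with ~49 standardized inputs and a few
  thousand points, per-dimension lengthscales overfit the marginal
  likelihood), and a noise term. Inputs standardized, target centered and
  scaled. Hyperparameters maximize the log marginal likelihood (L-BFGS-B on
  log parameters, lengthscale initialized at the median pairwise distance).
  Because the exact GP is cubic, hyperparameters are optimized on a seeded
  subsample (default 400 points) and the final posterior uses all training
  points. The GP also returns a predictive standard deviation (noise
  included), so 90% intervals can be checked for calibration.
* **Multitask neural network (`multitask_nn`)** — a shared two-hidden-layer
  tanh trunk (width 128) with two linear heads, predicting the correction and
  the reaction energy $\Delta E_r$ with equal loss weights; full-batch Adam,
  early stopping on the validation split. Written in plain matrix arithmetic,
  so training is deterministic for a given seed.

`correctedBH()` adds the predicted correction to the low-level barrier.
`explainModel()` returns per-record attributions: exact path-dependent
TreeSHAP for the tree head (attributions plus the expected value sum to the
prediction; XGBoost accumulates these in single precision, so the residual is
~10⁻⁶ relative to the prediction scale), and a Monte-Carlo permutation
Shapley estimator for the other heads.

## Thermochemistry

`gibbs()` implements textbook rigid-rotor/harmonic-oscillator ideal-gas
thermochemistry at 1 atm: Sackur–Tetrode translation, rigid-rotor rotation
from the principal moments of inertia (linear and monatomic species handled;
symmetry number applied, default 1 since symmetry assignments are rarely
available for TS structures), harmonic vibration over positive wavenumbers,
and spin-degeneracy electronics. Physical constants are pinned CODATA values;
the wavenumber→kcal/mol conversion is fixed at 1 cm⁻¹ = 2.85914×10⁻³
kcal/mol so ZPEs are bit-reproducible. `scaleFrequencies()` applies published
scaling factors (0.9914 is the recommended value for ωB97X-D-type
frequencies and ships as the reference-level default; the low-level factor
defaults to 1.0, with 0.976 as a documented literature example).
`deltaGActivation()` evaluates $\Delta G^\ddagger(T) = G_{TS} - G_R$ with the
TS imaginary mode excluded from all thermal sums, batched over 300/500/1000 K
by default. No hindered-rotor or quasi-RRHO corrections and no tunneling.

## The synthetic generator

Real curated CHNO datasets (thousands of gas-phase, mostly unimolecular
reactions with up to 7 heavy atoms) cannot ship with a package, so
`genDataset()` emulates their *statistical* structure:

* valence-respecting acyclic CHNO skeletons (2–7 heavy atoms, C:N:O drawn
  6:2:2) with hydrogens filling free valences; geometries embedded so bonded
  distances are covalent-radius sums ×(1±0.03) and non-bonded pairs stay
  safely outside the bond threshold — `buildGraph()` recovers the intended
  adjacency by construction;
* products generated by 1–3 valence-preserving edits (H migration,
  heavy-group migration, H₂ elimination), so bond-change counts are
  realistic and products may be multi-fragment;
* a TS geometry made from the reactant with the breaking bonds stretched 12%
  (a stand-in for a point along the reaction path) and exactly one planted
  imaginary frequency;
* low-level scalars from documented distributions (BH ~ 5 + Γ(4, 8) kcal/mol,
  energies N(0, 20), 3N−6 wavenumbers U(300, 3200) cm⁻¹, HOMO N(−9.5, 0.8) eV
  with a U(2, 8) eV gap);
* the ground-truth correction
  $\Delta_{true} = -2 + 0.12\,\mathrm{BH} - 1.0\,\eta^{TS} +
  1.5\,\lambda_1^{TS} + 1.2\,(+CH) - 0.8\,(-CH) + \mathcal{N}(0,\sigma^2)$,
  with $\sigma = 2$ kcal/mol by default. The deterministic part is computed
  with the package's own descriptor functions, so the map is exactly
  expressible by the feature set and a correct model's asymptotic test MAE is
  the analytic floor $\sigma\sqrt{2/\pi}$ — the key parameter-recovery
  property the tests exploit. A `hidden_driver` mode adds a term the features
  cannot see, for studying graceful degradation.

Curation failures can be planted at configured fractions (failed TS
optimization; endpoints replaced by the wrong isomer; endpoint bonds
stretched 10%, which preserves connectivity but moves the weighted spectrum),
and the curation report recovers the planted counts exactly.

What the generator does **not** emulate: real PES energetics (scalars are
statistical stand-ins), rings and multiple bonds in the skeletons, bimolecular
channels, correlated descriptor noise, or systematic low-level error
structure. Passing tests therefore demonstrate that the machinery — curation
logic, descriptor algebra, model training, uncertainty and attribution — is
correct and recoverable at realistic scales, not that any particular accuracy
will be achieved on real chemistry.

## Numerical choices and problem sizes

* Eigenvalue comparisons are element-wise on sorted spectra, never rounded
  hashes; numerical zeros in Laplacian spectra are anything ≤ 10⁻⁹.
* Degenerate inputs: single atoms give edgeless 1×1 graphs and
  translation-only thermochemistry; negative barriers are allowed with a
  warning; a TS with zero or several imaginary modes is an error.
* Splits are exhaustive and disjoint with sizes within one unit of the
  fractions; all randomness flows from explicit seeds (child seeds derived
  per stage), and the tree/GP pipeline is bit-reproducible end to end.
* Default problem sizes in the shipped tests and acceptance script: 2,000
  synthetic reactions for model recovery, 1,000 for curation, 500 for the
  determinism check, learning curves at 100/400/1600 × 3 repeats — sizes at
  which the statistical properties under test are already stable.

## Known limitations

* Eigenvalue screening cannot separate cospectral graphs or enantiomers.
* The exact GP is cubic in training size; beyond ~5,000 points a sparse
  approximation would be needed.
* The cheminformatics registry is the OpenBabel property set (~18
  descriptors), not the ~130 of a full RDKit build; the registry is
  extensible and nothing downstream depends on the roster size.
* TreeSHAP additivity holds to single precision (~10⁻⁶ relative), a property
  of the underlying library.
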