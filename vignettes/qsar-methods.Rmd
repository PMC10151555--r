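---
title: "Descriptor-based QSAR modelling with qsarmlr: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Descriptor-based QSAR modelling with qsarmlr: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarmlr)
```

qsarmlr implements a complete descriptor-based QSAR workflow of the kind
used to model arginase-I inhibition: molecular descriptors computed from 3D
structures, genetic-algorithm subset selection scored by cross-validated
fit, a full internal/external validation battery, a leverage-based
applicability domain, and virtual screening with a frozen published
equation. This vignette records the scientific and numerical choices behind
each stage, what the synthetic benchmark does and does not establish, and
the known limitations.

## The regression model and its assumptions

The core object is an ordinary least-squares multi-linear model of pIC50
(`pic50 = 9 − log10(IC50 in nM)`; IC50 inputs are assumed to be nanomolar
unless converted beforehand) on a handful of molecular descriptors,
fitted by `qsar_mlr()` through QR decomposition. The usual OLS
assumptions apply: a linear mean structure, homoscedastic independent
errors, and more compounds than descriptors. Rank deficiency is a hard
error naming the collinear column rather than a silent drop — in QSAR a
collinear descriptor pair indicates a curation problem upstream, not a
nuisance to work around.

The frozen arginase-I equation (`published_arginase_model()`) stores the
published coefficients and their printed ± values. Those uncertainties are
kept as annotations only and are not recomputed: the source does not state
how they were derived, so the package does not pretend to reproduce them.
One documented oddity of the source is that its narrative describes the
surface-area ratio as negatively correlated with potency while the printed
equation carries +19.791 for `rsa`; the package follows the printed
equation and leaves the contradiction to the reader.

## Descriptors

Six descriptors drive the model. Four are *pair counts at an exact bond
distance*: the number of unordered atom pairs (a, b), a ≠ b, with a in a
source category, b in a target category, and shortest-path distance
exactly k bonds on the explicit-hydrogen bond graph. "Frequency of
occurrence" is read as this unordered pair count — the most literal
reading — and each pair counts once even if both orientations qualify. A
`counting_mode = "target_atoms"` switch offers the per-target-atom
alternative for sensitivity analyses. Distances come from breadth-first
search (`bond_distance_matrix()`); disconnected pairs are infinitely far
apart and never counted.

Atom categories are derived as follows:

* **ring atoms** — atoms lying on a cycle of the bond graph. Only
  membership is consumed downstream, so the package computes "on some
  cycle" via bridge detection, which coincides with the union of
  smallest-set-of-smallest-rings memberships on molecular graphs; no ring
  decomposition is kept.
* **donor** — N or O bearing at least one bonded hydrogen, the
  conventional H-bond-donor definition (the source never defines "donor").
* **sp2 oxygen** — oxygen in a double bond (carbonyl, nitro, ...), the
  conventional hybridization reading.
* **lipophilic hydrogen** — hydrogen with |Gasteiger partial charge| ≤
  0.200, inclusive, matching the stated ±0.200 window.

`fsp2OC9B` carries an exclusion clause in its source description; it is
read as: a carbon is not counted for a qualifying sp2 oxygen if it also
lies exactly 9 bonds from *some other* oxygen atom. The reading is
switchable (`apply_exclusion = FALSE`) because the sentence admits
alternatives. Similarly, ring carbons remain eligible "carbon" targets in
`fringCC3B` (benzene scores 3) because the definition says "carbon atom",
not "non-ring carbon".

`com_lipohyd_3A` counts lipophilic hydrogens within 3 Å (Euclidean) of the
centre of mass, computed over all atoms including hydrogens; it is
rigid-body invariant because the centre of mass moves with the molecule.

`rsa` is the ratio of the van der Waals surface area to the
solvent-accessible surface area. Both come from the same Shrake–Rupley
integration: each atom's sphere (vdW radius, plus the 1.4 Å water probe
for SASA) is sampled with a deterministic Fibonacci lattice of 960 points
(configurable, minimum 92; doubling the density moves areas by well under
1% on the test fixtures), and a point is accessible when outside every
other inflated sphere. Radii are Bondi-style values. One numerical
subtlety: a sample point lying exactly on another atom's sphere — which
happens only for coincident atoms — is "owned" by the lower-indexed atom,
so degenerate duplicates expose the area of one sphere rather than zero
or two. The absolute areas of any given third-party implementation are
not reproducible (probe radii, radii tables and sampling all differ
between programs); only the ratio arithmetic is anchored, and the package
treats absolute areas accordingly.

Structure input uses the V2000 SDF reader of ChemmineR with per-record
isolation (a corrupt record is logged and skipped; an all-corrupt file is
an error). SMILES input is embedded in 3D by OpenBabel's distance-geometry
builder with explicit hydrogens; supplied coordinates are never altered.
Partial charges are Gasteiger–Marsili iterative partial equalization as
implemented by OpenBabel — the de facto default of the visualization
ecosystem around which this descriptor family grew — and the charge model
name is a parameter. Multi-fragment records (salts) are reduced to the
largest fragment before descriptor computation, the common QSAR curation
step.

## Objective feature selection

`ofs_prune()` removes constant columns, near-constant columns (default:
more than 95% identical values — the source says only "near-constant", and
95% is common practice), and one member of every pair with |Pearson r| >
0.90. The tie-break is deterministic: keep the column more correlated with
the activity when an activity vector is present, otherwise the earlier
column. Pruning is idempotent, and its output always passes its own
postcondition scan.

## Subset selection: GA with Q²LOO fitness and the QUIK rule

Candidate subsets of fixed size (default 6, the size of the published
equation; 3 in the canonical benchmark) are scored by leave-one-out Q²:
`1 − PRESS/TSS`, with PRESS from the hat-matrix shortcut
`e_i/(1 − h_ii)` — algebraically identical to n explicit refits, and
verified against that oracle in the tests to 1e-10. Singular subsets get
fitness −∞. A subset must also pass the QUIK rule: the Todeschini K
multivariate correlation of the descriptor block augmented with the
response must exceed that of the descriptor block alone by at least 0.05
(K = Σ|λ_j/Σλ − 1/p| / (2(p−1)/p) over correlation-matrix eigenvalues).
Subsets failing QUIK also score −∞, which yields the documented behaviour
that the returned best subset always satisfies the rule, and that a pool
admitting no valid subset is an explicit error.

The GA internals of the original modelling software are unpublished, so
the package fixes reproducible defaults and exposes all of them in
`ga_config()`: population 100, 200 generations, tournament selection of
size 2, uniform crossover drawing the child from the union of its
parents, point mutation swapping one descriptor (rate 0.3), elitism 2
(which makes the best-fitness trace monotone), and a mandatory seed for
byte-reproducible runs. Fitness values are cached per subset. For small
pools `exhaustive_select()` enumerates all subsets and serves as the
oracle the GA is tested against.

## Validation battery

`internal_stats()` uses textbook formulas: R²; adjusted R²
`1 − (1−R²)(n−1)/(n−p−1)`; RMSE = √(RSS/n); MAE; Lin's CCC with
population moments; s = √(RSS/(n−p−1)); F = (R²/p)/((1−R²)/(n−p−1));
Friedman's LOF with smoothing parameter d = 0.5 (configurable — the
source's printed LOF cannot pin d down, so it is not treated as an
anchor); and the LOO block (Q², RMSEcv, MAEcv, PRESS, CCC of LOO
predictions) from the hat shortcut. The source's printed s and F are not
consistent with its own RSS/n/p under these formulas; the package keeps
the textbook definitions and documents the discrepancy rather than
chasing it.

`lmo_cv()` leaves out a random 30% (configurable within (0, 0.5]) for
1000 repeats by default; each repeat computes 1 − PRESS_out/TSS_out with
TSS about the training mean, and the mean over repeats is reported.
Whether the original software uses random groups or contiguous blocks is
unstated; random groups were chosen. `y_scramble()` permutes the
response, refits, and reports mean R², mean Q²LOO and mean RMSE over
(by convention) 2000 iterations; an explicit permutation list can be
supplied for reproducibility studies.

`external_stats()` implements Q²F1 (training-mean reference), Q²F2
(external-mean reference; always ≤ Q²F1), Q²F3 (variance-scaled), CCC,
and the Golbraikh–Tropsha through-origin diagnostics in both regression
orientations: k = Σyŷ/Σŷ², k′ = Σyŷ/Σy², R²o-type quantities from
through-origin fits, and the r²m pair r² (1 − √(r² − r²o)) averaged over
orientations with its delta. Since r² − r²o can dip a hair below zero in
floating point, it is clamped at zero before the square root. The
regression angle is arctan(slope of predicted on observed) − 45°, in
degrees. Constant predictions (zero variance) yield NA for
correlation-based fields rather than an error, so screening edge cases
degrade gracefully.

`leverage_analysis()` computes hat values h = x(X′X)⁻¹x′ with the
intercept column, the warning leverage h* = 3(p+1)/n, standardized
residuals residual/s, and in-domain flags (h ≤ h* and |std residual| ≤ 3,
the conventional Williams-plot boundaries; the source shows but does not
number them). The 3(p+1)/n form matches the reported h* = 0.140 at
n = 149, p = 6; a figure caption elsewhere in the source prints
h* = 0.021, which is arithmetically impossible for any n, p in the study
and is treated as a typo. `plot()` on a fitted model draws the Williams
plot and returns its data for export.

## Virtual screening

`screen_library()` accepts an SDF/SMILES file, a list of molecules, or a
precomputed descriptor table; every entry is scored, failures are counted
and reported (never silently dropped), entries are ranked by predicted
pIC50 with ties broken by id, and hits are entries at or above the
threshold. The default threshold of pIC50 = 8 corresponds to predicted
IC50 ≤ 10 nM — "single-digit nanomolar or better" — and is configurable.
`annotate_ad()` adds leverage and in-domain flags against a fitted
training model's descriptor block. Screening is idempotent (re-screening
the hit subset reproduces identical scores) and monotone in the
threshold. The source reports both 1650 and 1615 for its FDA library
size; the pipeline is library-size-agnostic, so the conflict is noted and
nothing depends on it.

## The synthetic benchmark: what it shows and what it does not

`make_regression_dataset()` draws a compound-by-descriptor pool from an
equicorrelated multivariate normal (ρ = 0.2, unit variances) and
generates y = intercept + Xβ + N(0, σ²) over a planted informative
subset. σ is derived from a target population R² of 0.9 using the
realized variance of Xβ, so attained R² concentrates on the target; the
canonical benchmark is 150 compounds, a 43-descriptor pool and 3
informative descriptors — large enough for an honest subset search,
small enough that the whole battery runs in seconds. An optional
`descriptor_style` mapping squashes the first column to (0, 1) like a
surface ratio and rounds the rest to non-negative counts, mirroring the
mixed ratio/count nature of the real descriptors.

`make_molecules()` builds valence-legal 3D structures from ring and chain
templates (kekulized planar six-rings with optional ring nitrogens and
OH/NH2/CH3/F/CHO/CH2OH substituents; zig-zag chains of 3–12 heavy atoms
with ether/amine/carbonyl placements), then fills every open valence with
explicit hydrogens. The templates guarantee coverage of every atom
category the descriptors consume. `make_library()` writes such molecules
as an SDF library and, by default, adds a designed known hit — a
gem-dimethyl-rich branched alkane whose compact surface and crowded
lipophilic hydrogens score far above the hit threshold under the
published equation (the structure was designed by inverting the equation,
and its embedded 3D coordinates ship with the package, labelled
synthetic).

These generators emulate the *statistical* structure the analysis assumes
(a sparse linear signal in a correlated pool; molecules spanning the atom
categories). They do not emulate real inhibitor chemotypes, conformer
ensembles, tautomers or protonation states, measurement error structure
in IC50 assays, or the descriptor distributions of any real library. A
green test suite therefore demonstrates that the machinery is correct and
calibrated under its stated assumptions — not that the published equation
generalizes to new chemistry; that question belongs to the applicability
domain analysis on real data.

## Problem sizes and determinism

The shipped tests and the acceptance script use: the 150 × 43 planted
benchmark (GA with population 50, 40 generations — ample for a 43-column
pool; the defaults of 100/200 are sized for pools an order of magnitude
larger), 2000 Y-scrambling iterations, 1000 leave-many-out repeats, 960
surface points per atom, and a 60-molecule screening library. Every
stochastic step takes an explicit seed; GA runs, library files and
synthetic datasets are bit-reproducible given the seed.

## Known limitations

* Descriptor values for the source's own numbered molecules cannot be
  reproduced because those structures are not machine-readable here;
  per-molecule anchors are therefore limited to structures the package
  can build itself.
* Absolute MSA/SASA values depend on radius tables, probe and sampling;
  only their ratio is meaningful across implementations.
* The exact 119/30 training split of the original dataset is not
  published, so the original training statistics are emulated on
  synthetic data rather than reproduced.
* Gasteiger charges are connectivity-based; charge-sensitive flags
  (lipophilic hydrogens) will differ under quantum-derived charge models.
* The SDF reader handles V2000; V3000 records are reported as parse
  failures.
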