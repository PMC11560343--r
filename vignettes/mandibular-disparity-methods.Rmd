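---
title: "Methods: two-track mandibular disparity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-track mandibular disparity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jawdisp)
```

## The model

`jawdisp` treats the mandible as a lever rotating about the jaw joint.
Three mechanical-advantage ratios summarize force transmission:

* **AMA** (anterior mechanical advantage): the adductor in-lever — jaw
  joint to the coronoid tip, the anteriormost identifiable insertion
  point of the external adductor musculature — divided by the out-lever
  ending at the anterior tip of the jaw. This is the minimum closing
  mechanical advantage (an "anterior bite").
* **PMA**: the same in-lever over the out-lever ending at the posterior
  end of the triturating surface (a "posterior bite", the maximum
  closing advantage). When that point lies closer to the joint than the
  coronoid tip, the jaw acts as a second-order lever and PMA exceeds 1.
  Such values simply indicate still-greater force transmission at
  still-lower speed, so the package never clamps them.
* **OMA** (opening mechanical advantage): a first-order lever; the
  depressor in-lever runs from the joint backwards to the tip of the
  retroarticular process, and the out-lever is shared with AMA. A jaw
  with no retroarticular process has OMA 0, which is valid input.

Bending stiffness of the jaw ramus is proxied by **SMOI**, the area
moment of inertia of an ellipse fitted to the ramus cross-section
(I_na = πab³/4, with *a* the axis perpendicular to the applied force
and *b* the parallel axis) standardized by the equal-area circle
(radius √(ab), I_c = π(ab)²/4). The quotient collapses algebraically
to b/a, making the measurement dimensionless and scale-free; values
above 1 mean a taller-than-wide beam, stiffer against dorsoventral
bending. The package accepts the fitted axis lengths as data — ellipse
fitting to CT sections is image processing and out of scope; where the
section was taken is recorded as free-text metadata only.

Two shape ratios complete the profile: **LWR**, sagittal jaw length
over maximum 3D width (a size-free aspect ratio, since specimens of
identical ontogenetic stage are rarely available), and **RTW**, the
maximum triturating-surface width over jaw length (crushing-surface
development; suction feeders reduce it, durophages broaden it).

### The sagittal plane

Lever distances are conventionally measured "along the sagittal
plane", but specimen coordinate frames are not standardized. The
package makes the projection explicit: `sagittal_config()` names the
two in-plane axes (default x = anteroposterior, z = dorsoventral; the
mediolateral y component is discarded) and every lever distance is the
Euclidean distance between orthogonally projected points. Whether the
original measurements were projected or taken as 3D chords between
near-midline points is ambiguous in practice; projection is our
reading, and because lever landmarks lie close to the midline the two
readings differ only at second order. Width measurements are transverse
by construction and always use full 3D distances. A consequence worth
noting for testing: the six ratios are invariant under rigid motions
that preserve the configured sagittal plane (in-plane rotation,
arbitrary translation, uniform scaling), not under arbitrary 3D
rotations, which would change the projection.

### Degenerate geometry

Zero out-levers, coincident width landmarks and missing landmarks raise
errors naming the offending landmark rather than returning NaN, so
pipeline failures are loud and attributable. Two soft cases warn
instead of failing: a zero-width triturating surface (RTW 0 is
anatomically meaningful) and RTW ≥ 1 (implausible but computable).

## Jaw types

Extreme proportions of single lever arms produce recognizable jaw
types, named for the clades that display them: an extremely elongated
retroarticular process (high OMA at low AMA, the trionychid type), a
shortened pre-coronoid region (jointly elevated AMA and OMA, the
pelomedusoid type), and an elongated postcoronoid region without a
hypertrophied retroarticular process (high AMA at unremarkable OMA, the
chelid type). `classify_jaw_type()` operationalizes these qualitative
descriptions with sample-relative quantile rules, applied in that order
with first match winning:

1. *trionychid*: opening in-lever / jaw length above the sample's 75th
   percentile **and** AMA at or below the sample median;
2. *pelomedusoid*: AMA and OMA both above their 75th percentiles;
3. *chelid*: AMA above its 75th percentile with OMA inside the
   interquartile range;
4. otherwise *none*.

Two deliberate choices: ties at a cutoff count as *not exceeding* it,
except that the trionychid AMA condition is non-strict (≤ median). The
latter matters in calibrated test fixtures where all specimens share an
identical AMA: a strict "below the median" can never hold in such a
sample, while the intent of the rule is "AMA not elevated". Because the
cutoffs are sample quantiles, labels are relative to the sample
supplied — screening one candidate archetype against a homogeneous
background is reliable; mixtures of several extreme archetypes shift
each other's cutoffs. Samples of fewer than 8 specimens get `"none"`
throughout (quartiles are not meaningful), and fewer than 2 is an
error.

## Character track

Discrete characters are nominal, unordered and equally weighted (a
config hook for ordered treatment is deliberately left unimplemented
until a dataset declares ordered characters). Parsing accepts NEXUS
CHARACTERS/DATA blocks (honoring `MISSING=` and `GAP=` symbols, both
mapped to missing) and CSV; polymorphic cells `{01}`, `(01)` or `0/1`
become state multisets.

**Polymorphism resolution.** The majority rule replaces a polymorphic
cell with its most frequent state. A species-level matrix does not
carry the specimen-level frequencies the rule presupposes, so cells are
treated as multisets (the synthetic generator emits 3-element multisets
precisely so a majority exists) and frequency ties fall back to
missing — a conservative stand-in, exposed alongside `"missing"`
(discard all polymorphisms) and `"keep"`.

**Gower dissimilarity.** For taxa *i*, *j*: the mean of the mismatch
indicator over characters scored in both (pairwise-complete
renormalization, the standard behavior for factors). Output is in
[0, 1]; metricity is *not* guaranteed under missing data, and a pair
with no comparable characters is an error naming the pair rather than a
silent NA.

**PCoA.** Squared distances are double-centered (B = −½·J·D²·J) and
eigendecomposed. Axes are retained while the eigenvalue exceeds 1e-8 ×
the largest (rank tolerance); negative eigenvalues — expected for
missing-data Gower — are dropped, and variance-explained proportions
are computed over the positive eigenvalues only. No additive-constant
correction is applied by default since the analyses this package
mirrors report none; a Cailliez correction is available via
`pcoa(..., correction = "cailliez")`. Equal eigenvalues keep the
decomposition's stable order; the sign of each axis is fixed by making
its first nonzero score positive. On Euclidean input, PCoA reproduces
the PCA configuration (same variance proportions to 1e-8, distances
preserved), which the test suite uses as its oracle.

## Continuous track

Traits are Z-transformed (mean 0, sample SD 1, n−1 denominator;
constant traits are an error naming the trait) so all six measurements
carry equal weight, then ordinated by centered SVD. Eigenvalue k is
σ_k²/(n−1) — the variance of the k-th score axis — so eigenvalues sum
to the total trait variance (p, after Z-transformation). Published
variance tables in this literature sometimes print per-axis *standard
deviations* under an "eigenvalues" heading; the `ordination` object
therefore carries both `eigenvalues` and `sdevs`, and downstream
comparisons should pick the row that squares to the printed variance
proportions. Axis signs are fixed by making the largest-magnitude
loading of each axis positive, keeping regression output stable. All
axes are retained for disparity.

## Disparity and tests

The disparity metric is the **sum of variances** of a group's scores
over all ordination axes — the trace of the group's covariance matrix,
hence invariant under orthogonal rotation of the morphospace, equal to
the eigenvalue sum for the full sample, and relatively insensitive to
sample size. Group distributions are obtained by bootstrapping rows
with replacement at constant n (no rarefaction; `n_boot` defaults to
100, the cited disparity tooling's default, as no replicate count is
conventionally reported). Per-group resampling seeds derive from the
group's membership, so two groups with identical members receive
identical replicate vectors and a group compared against itself is an
exact tie (p = 1).

Pairs of replicate vectors are compared with a two-sided Mann–Whitney
test: exact by full enumeration of all C(n, n_x) labelings when the
combined size is ≤ 12 without ties, otherwise the normal approximation
with tie and continuity corrections (both paths agree with the standard
reference implementation to machine precision, and with each other
within 0.02 for per-sample sizes of 6–12). P-values are
Bonferroni-corrected over the number of pairs in the scheme under test.
Two caveats are inherited from the conventional procedure and
documented rather than "fixed": bootstrap replicates are not
independent samples, so these p-values grade separation of the
replicate distributions rather than controlling a literal error rate;
and with n_boot = 100 the smallest attainable two-sided p is bounded by
the replicate count. Groups with fewer than 3 members are reported but
excluded from testing with a warning. Degenerate comparisons (all
replicates identical, e.g. groups of duplicated points) are flagged in
the output table.

Univariate group-mean comparisons use pairwise t-tests with the pooled
standard deviation estimated across *all* groups (df = N − k, matching
the conventional pairwise procedure's default) and Bonferroni
correction; a Welch variant is available. Pearson correlations report
the t-based two-sided p with n − 2 df.

## What the synthetic generator emulates — and what it does not

The generator's defaults are a stated world, fixed once:

* **Archetypes.** The generic archetype's lever lengths are solved
  analytically from the target ratios (AMA 0.40, PMA 0.95, OMA 0.15,
  SMOI 1.76, LWR 1.06, RTW 0.13 — the published global means for
  extant turtles), with the out-lever normalized to 1; zero-noise
  output is therefore exact by construction, not fitted. The three
  jaw-type archetypes perturb single levers (retroarticular ×1.8,
  pre-coronoid ×0.7, closing in-lever ×1.5), chosen so the trionychid
  archetype's OMA (0.27) sits just inside the published OMA range
  (0.05–0.28) and each archetype trips exactly its classifier rule.
* **Noise** is isotropic Gaussian on landmark *coordinates* (SD as a
  fraction of jaw length, default 0.02 — roughly the digitization
  error of landmarking a jaw a few cm long), not on the derived
  ratios, so the measurement stage's geometry is genuinely exercised;
  cross-section axes get proportional noise of the same magnitude.
* **Character matrices** give each group a private modal state vector;
  cells copy it with probability 0.9, else draw a uniform alternative,
  with 5% missing and 2% polymorphic cells — magnitudes typical of
  compact morphological matrices (51 characters by default).
* **Ecological labels** are deliberately confounded with clade
  (default strength 0.8), because real comparative samples nest
  ecology within taxonomy; `confounding = 0` yields clade-independent
  labels for null testing.

What a green test on synthetic data does *not* establish: realistic 3D
jaw geometry (the template is planar with transverse width spans),
phylogenetic autocorrelation (no tree-based simulation; group structure
is exchangeable within clades), correlated evolution among the six
measurements, or measurement error structure of real CT-derived
landmarks. Synthetic results validate the *machinery* — calibration,
invariances, power against a constructed dispersion difference — not
any biological claim.

## Numerical conventions

* Quantiles use the default continuous definition (type 7).
* Variances and SDs use the n−1 denominator throughout.
* PCA/PCoA rank tolerance: 1e-8 relative to the leading eigenvalue;
  symmetry tolerance for distance input 1e-12.
* CSV artifacts print floating-point values with 12 significant
  digits, making pipeline reruns byte-identical and diffable.
* All randomness flows from a single integer seed; sub-seeds are
  derived deterministically (and kept within 32-bit range), and every
  generator restores the caller's RNG state.

## Known limitations

* The jaw-type classifier is sample-relative by design; it cannot
  label a single specimen in isolation.
* Gower + PCoA with heavy missing data can place a taxon pair at
  distance 0 that differs in characters scored in neither; the
  no-comparable-characters error only covers the fully incomparable
  case.
* The Mann–Whitney-on-bootstraps convention inflates significance for
  large n_boot; treat adjusted p-values comparatively.
* No phylogenetic comparative correction is offered anywhere — group
  comparisons are raw, as in the analyses this package mirrors.
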