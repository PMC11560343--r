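# jawdisp

Two-track mandibular disparity analysis for comparative functional
morphology.

Vertebrate lower jaws can be compared either through **biomechanical
measurements** — continuous ratios derived from lever mechanics and
beam theory — or through **discrete anatomical characters** of the kind
scored for phylogenetic analysis. The two data types capture different
things (function vs. phylogenetically conserved structure) and can
disagree sharply about which groups are most morphologically diverse.
`jawdisp` implements both tracks end to end for samples such as extant
turtles, where the edentulous triturating surface replaces tooth rows
and jaw types differ mainly in the relative proportions of lever arms.

## What it computes

**Six functional measurements** from named 3D landmarks (jaw joint,
coronoid tip, anterior/posterior jaw tips, posterior end of the
triturating surface, width spans) plus the cross-section ellipse of the
dentary ramus:

| Measurement | Definition |
|---|---|
| AMA | closing in-lever \|joint−coronoid\| / out-lever \|joint−anterior tip\| |
| PMA | same in-lever / \|joint−posterior end of triturating surface\| (may exceed 1: second-order lever) |
| OMA | opening in-lever \|joint−retroarticular tip\| / \|joint−anterior tip\| |
| SMOI | ellipse area moment I_na = πab³/4 over the equal-area circle's I_c = π(ab)²/4, which simplifies to b/a |
| LWR | sagittal jaw length / maximum 3D jaw width |
| RTW | maximum triturating-surface width / jaw length |

Lever distances are straight lines in a configurable sagittal plane
(default x–z); width spans are 3D. All six are dimensionless and
invariant to rigid motion and uniform scaling.

**Ordination.** Continuous traits are Z-transformed (mean 0, SD 1,
n−1 denominator) and ordinated by PCA (centered SVD). Discrete
character matrices — with `?` missing cells and `{01}`-style
polymorphisms, read from NEXUS or CSV — are resolved by a majority
rule (ties → missing), converted to Gower dissimilarities
(mean mismatch over pairwise-complete nominal characters), and
ordinated by PCoA (double-centered −½·J·D²·J; negative eigenvalues
dropped, variance proportions over positive eigenvalues).

**Disparity.** Group disparity is the sum over all ordination axes of
the group's per-axis score variance. Groups are compared by
bootstrapping the metric (row resampling with replacement, constant n)
and applying two-sided Mann–Whitney tests to the replicate
distributions — exact by full enumeration for small tie-free samples,
normal approximation with tie/continuity corrections otherwise — with
Bonferroni correction over the pairs. Pairwise pooled-SD t-tests (with
a Welch option) and Pearson correlations cover univariate group-mean
comparisons.

**Synthetic data.** A generator produces landmark sets from four
lever-proportion archetypes — a *generic* jaw calibrated analytically
so its zero-noise measurements are AMA 0.40, PMA 0.95, OMA 0.15,
SMOI 1.76, LWR 1.06, RTW 0.13, plus *trionychid* (1.8× retroarticular
process), *pelomedusoid* (0.7× pre-coronoid length) and *chelid* (1.5×
closing in-lever) variants — together with group-structured character
matrices and clade-confounded ecological labels, so the whole pipeline
is testable without specimen data.

## Worked example

```r
library(jawdisp)

# a zero-noise generic-archetype jaw reproduces the calibration targets
sim <- make_jaw_landmarks("generic", n = 1, noise_sd = 0)
profile_species(sim$landmarks[[1]], sim$cross_sections[[1]])
#> <functional_profile> generic_001
#>  ama  pma  oma smoi  lwr  rtw
#> 0.40 0.95 0.15 1.76 1.06 0.13

# full synthetic sample: 3 clades x 12 specimens
data <- simulate_dataset(n_per_clade = 12, noise_sd = 0.02, seed = 42)
prof <- profile_sample(data$landmarks, data$cross_sections)
traits <- as.matrix(prof[, c("ama","pma","oma","smoi","lwr","rtw")])
rownames(traits) <- prof$species_id
ord <- pca(z_transform(traits))
ord
#> <ordination> PCA: 36 objects, 6 axes
#> variance explained (%): 36.4 30.1 15.6 12.0 4.9 1.0

clades <- setNames(data$groups$clade, data$groups$species_id)
compare_disparities(ord$scores, clades, n_boot = 100, seed = 42)
#> <disparity_result> 3 groups, n_boot = 100
#>      group  n sum_of_variances boot_lower boot_upper tested
#> 1    Mixed 12            8.404      4.970     10.263   TRUE
#> 2 UniformA 12            2.838      1.616      3.682   TRUE
#> 3 UniformB 12            2.122      1.183      2.629   TRUE
#> pairwise two-sided Mann-Whitney (Bonferroni-adjusted):
#>     group1   group2     W         p     p_adj degenerate
#> 1    Mixed UniformA  9999 2.640e-34 7.921e-34      FALSE
#> 2    Mixed UniformB 10000 2.562e-34 7.686e-34      FALSE
#> 3 UniformA UniformB  8064 7.137e-14 2.141e-13      FALSE
```

The `Mixed` clade blends all three jaw-type archetypes, so it occupies
a far larger morphospace volume (sum of variances 8.40) than either
single-archetype clade (2.84, 2.12), and every pairwise comparison of
the bootstrap distributions is significant after Bonferroni correction.

## Command line

```sh
inst/scripts/jawdisp all --out results/run1 --seed 1 --n-boot 100 \
    --group-scheme clade --polymorphism majority
```

Subcommands `simulate`, `measure`, `ordinate`, `disparity`, `report`
(or `all`) exchange CSV artifacts in the output directory and write a
JSON manifest (inputs, configuration hash, seed, versions) sufficient
to reproduce the run; reruns with the same configuration and seed are
byte-identical.

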