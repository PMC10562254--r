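---
title: "Quantitative genomics of hybrid rice heterosis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genomics of hybrid rice heterosis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridsel)
```

# Scope

`hybridsel` implements the quantitative-genomics toolchain used to dissect
heterosis in hybrid rice and to rank untested crosses: (i) a synthetic-data
generator for founder panels, inbred parents, F1 hybrids and F2 progenies
with fully known ground truth; (ii) a subspecies-introgression scanner
built on indica–japonica differentiated SNPs; (iii) per-locus degree-of-
dominance (d/a) estimation with breeding-favorable allele calling and
pyramiding counts; (iv) regional variance partitioning with a four-kernel
mixed model; and (v) an additive(+dominance) GBLUP genomic-selection model
with cross-validation, pseudo-combination enumeration, a seven-trait
selection index and sterility screening. The numbered scripts under
`analysis/` chain these stages into one narrative study over a simulated
cohort; every computation they perform lives in the package and is covered
by the test suite.

The generator is first-class, not a fixture: real hybrid-rice cohorts
(thousands of resequenced cultivars and F2 individuals) are far beyond
desk scale, so every quantitative claim the package makes is validated on
simulations whose true marker origins, crossover positions and genetic
values are known and returned to the caller.

# The simulation model

**Founder subpopulations.** Two panels of fully homozygous inbred lines
emulate reference collections of 19 indica and 23 temperate japonica
accessions. A fraction `diff_fraction` of markers is truly differentiated:
each subpopulation carries its own major allele with within-panel
frequency `purity` (default 0.95, so the majority rules below are
exercised against realistic panel noise rather than fixed differences).
The remaining markers share one alternate-allele frequency drawn uniformly
on (0.1, 0.9). Marker truth (differentiated or not; which allele is which
subspecies' major) is returned for oracle tests.

**Crosses.** `make_f1()` implements the deterministic inbred-by-inbred
cross (heterozygous exactly at discordant sites; heterozygous parents are
rejected). `simulate_f2()` selfs the F1: each F2 is the sum of two
independent gametes, and gametes follow a Haldane process — crossovers are
Poisson along the genetic map, the recombination fraction between markers
d cM apart is (1 − e^(−2d/100))/2, no interference. Haldane was chosen
over an interference model (e.g. Kosambi chi-square) because it is the
standard neutral choice and is analytically checkable: the tests verify
1:2:1 segregation and the exact two-locus recombinant-class frequency
(r/2)^2 at 10 cM.

**Phenotypes.** A trait is defined by per-QTL additive effects `a_j` and
dominance effects `d_j`: the genetic value is
g_i = Σ_j a_j x_ij + d_j z_ij with x the −1/0/1 dosage coding and z the
heterozygosity indicator. Gaussian noise is calibrated *empirically* on
the simulated cohort so Var(g)/Var(y) equals the requested heritability —
an analytic calibration would be biased by linkage disequilibrium among
QTLs, which the meiosis model induces by construction. `h² = 1` returns
the noise-free trait; `h² = 0` is only accepted together with a null
architecture (pure-noise traits for null calibration).

**Seeds.** One master seed; each stage (founders, parents, F2, phenotypes,
cross-validation, …) derives a fixed child seed from it, so any stage can
be re-run in isolation and the full pipeline is byte-deterministic.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: genotyping error and missingness patterns of
low-coverage sequencing (an optional symmetric error rate can be imposed
downstream, but the default is error-free), population structure within
each subspecies panel, selection and drift across breeding generations,
epistasis, and genotype-by-environment interaction. Recovery results on
this generator are therefore upper bounds on what the same estimators
achieve on field data.

# Introgression scanning

Differentiated SNPs are called from the two panels by three criteria
applied marker-by-marker: at least 17 of the 19 indica accessions share
one genotype, at least 21 of the 23 japonica accessions share one
genotype, and the two panel major alleles differ. Missing panel genotypes
are excluded from both the counts and the majority denominators; the
thresholds are parameters with those defaults. Samples are then labelled
II/IJ/JJ/missing at the retained loci, and a 199-SNP sliding window with
1-SNP step calls a window homozygous-japonica when it contains at least
120 JJ labels and heterozygous-japonica when at least 120 IJ labels (the
two calls are mutually exclusive: 240 > 199). Missing labels count toward
neither state while the window length stays fixed — the conservative
reading of a fixed min-hits count.

Per state, the union of passing windows is reduced to maximal runs of
covered SNPs, which also implements the merging of adjacent same-state
fragments. Where hom and het coverage overlap (possible only at run
boundaries), each SNP goes to the state with more covering windows, ties
to the heterozygous state; the boundary between abutting opposite-state
runs is implementation-defined to that rule. Segments are reported
half-open in panel-SNP index space plus the bp positions of the terminal
SNPs — the bp extent never extrapolates beyond observed SNPs. The scanner
is tested for exact equality against an exhaustive all-windows oracle and
for the purity property: a pure japonica line yields wall-to-wall
homozygous-japonica segments on every chromosome long enough to hold one
window, a pure indica line yields none.

# Degree of dominance and favorable alleles

Genotype-class effects A (hom reference), M (het), C (hom alternate) are
estimated as class means of the phenotype. Association pipelines typically take
them from a mixed-model fit; class means are used here because the d/a
formulas operate on class effects regardless of the estimator and the
association scan itself is out of scope. Then a = |A − C|/2,
d = M − (A + C)/2, and the degree of dominance is d/a for traits where
higher values are favored and −d/a where lower values are favored, so
positive degrees always point toward breeding-favorable dominance. Loci
where either homozygote class has fewer than 5 observations are flagged
excluded (class means driven by so few plants are outlier-prone); a = 0
gives a flagged NaN degree rather than an error.

Degrees are categorized with boundaries at ±0.1 around 0 (additive) and
0.9–1.1 (complete dominance); the boundaries are configurable and were
chosen so that the conventional verbal labels — 0.15 "modest", 0.4
"partial", 1.24 "overdominant", −0.14 "negative" — fall in the intended
categories. Favorable alleles follow per-trait direction rules (higher
favorable for yield traits, lower for heading date and chalkiness, a
window of 13.0–22.0 for amylose content, with the lower in-window
homozygote winning when both qualify). Pyramiding counts sum
favorable-allele dosage over a loci panel, so K loci cap at 2K (200 for a
top-100 panel). Top-K panels are built from association tables by greedy
p-value ranking with a 1 Mb exclusion radius, matching the 1 Mb
candidate-region convention used in variance partitioning. Better-parent
heterosis is reported in both absolute (F1 − best parent, direction-
aware) and relative forms since no canonical formula exists; the positive/
negative indicator uses the absolute form.

# Variance partitioning

For a candidate region (default: the 1 Mb window centered on an
association peak — the anchoring is configurable since "a 1 Mb region
surrounding" admits either reading), the phenotype is modelled with four
genetic random effects: additive and dominance kernels built separately
from in-region and out-region markers, plus a residual,

y = Lb + u_a1 + u_d1 + u_a2 + u_d2 + e.

The genetic proportion of the region is
(σ²_ua1 + σ²_ud1)/(σ²_ua1 + σ²_ud1 + σ²_ua2 + σ²_ud2) and the PVE adds
σ²_e to the denominator, so PVE ≤ genetic proportion always. Fixed
effects default to an intercept with optional covariates.

The REML estimator is implemented in the package: average-information
updates with a fixed-point fallback whenever an AI step leaves the
parameter space or decreases the restricted likelihood, non-negativity
enforced by truncation at a small floor (boundary REML), convergence on
relative restricted-log-likelihood change below 1e-6, 200 iterations max,
and 1e-6 diagonal jitter for kernels whose smallest eigenvalue dips below
zero by rounding. The single-kernel case is rotated through the
eigendecomposition of the kernel, which diagonalizes every likelihood
evaluation and makes n ≈ 1000 fits fast; the multi-kernel path is tested
against the eigen path and against a direct grid maximization of the
restricted likelihood on small instances.

# Genomic selection

Relationship matrices are:
A = WW′/(2Σ p_j(1−p_j)) with W the column-centered −1/0/1 coding and
D = HH′/denominator with H the column-centered 0/1 heterozygosity coding.
The dominance denominator defaults to the same 2Σ p(1−p) as A, with the
canonical
Σ(2p_jq_j)² form available by flag; both normalizations appear in
practice and the choice only rescales σ²_d, not the dominance BLUPs'
ranking. Frequencies come from the input cohort;
monomorphic markers are dropped with a warning and missing genotypes are
mean-imputed per marker.

GBLUP fits y = Xβ + u_a (+ u_d) + ε by the same REML core; the GEBV is
the additive BLUP, with the dominance BLUP reported separately and summed
for total genetic value. The default model is additive-only, reflecting
the empirical finding that adding dominance need not improve prediction
accuracy; both models are available and the cross-validation report in
`analysis/05` shows both. Accuracy is the Pearson correlation between
held-out GEBV and observed phenotype under sixfold cross-validation
repeated three times with seeded fold assignments.

Unphenotyped candidates (e.g. in-silico F1s of parent pairs) are predicted
by the conditional expectation u_cand = G_ct(G_tt + λI)⁻¹u_train with
relationship blocks computed in the *training* cohort's coding (training
allele frequencies, centering and denominators), so a candidate identical
to a training line reproduces that line's GEBV. An equivalent
marker-effect back-solve is provided and tested to agree on full-rank
instances; λ is a 1e-8 relative ridge.

The selection index scores four yield-related traits against the
candidate set's own GEBV percentiles (>80%: 40, 60–80%: 30, 40–60%: 20,
20–40%: 10, <20%: 0; bins are right-closed so a GEBV exactly at the 80th
percentile scores 30) and three agronomic traits 40 inside their optimal
range (heading date 80–90 days, plant height 115–125 cm, grain shape
3.0–3.4) and 20 outside. Percentiles are taken over the candidate set
rather than the training cohort because the ranking the index expresses
is among the candidates being compared. The index is the sum over the
seven traits, bounded in [60, 280]; candidates at or above 80 are flagged
high-scoring. Sterility screening flags a combination whose F1 would be
homozygous for a sterility allele at a locus relevant to the female
line's system (wild-abortive restorers rf3/rf4; two-line tms5); a locus
missing in either parent leaves the flag undetermined rather than silently
clean.

# Numerical choices and degenerate inputs

- Variance components are floored at 1e-8 · Var(y); boundary estimates
  (null components) are reported as (near-)zero rather than negative.
- Ties in panel major alleles (exactly 0.5/0.5) disqualify the marker from
  the differentiated set; ties in homozygote class means leave the
  favorable allele unresolved and flagged.
- A chromosome shorter than one scan window produces no windows and no
  segments, silently.
- `enumerate_combinations()` tolerates residual parent heterozygosity up
  to 2% by re-coding those sites missing; above that it refuses, because
  the pseudo-F1 construction assumes inbred parents.
- All tables are written with fixed, locale-independent formatting; the
  pipeline's outputs are byte-identical across runs with one seed, and the
  run metadata records the configuration hash and seeds.

# Problem sizes

The bundled analyses and tests run at desk scale, chosen so the full suite
and the acceptance script each complete in about a minute while every
statistical check retains power: founder panels of 19 + 23 accessions over
2 × 400–500 markers, F2 cohorts of 300–5,000 individuals depending on the
check, GBLUP recovery at n = 1,000 with m = 500 markers over 10
replicates, four-kernel PVE recovery at n = 400 over 20 replicates, and
scanner-oracle equivalence over 100 random tracks of up to 5,000 labels.
Combination enumeration is exercised at the full 367 × 159 = 58,353 and
58 × 19 = 1,102 scales since it is instantaneous.

# Known limitations

- The d/a estimator uses raw class means; covariate-adjusted least-squares
  means are not yet wired through `estimate_genotype_effects()`.
- The regional model assumes one candidate region at a time; overlapping
  regions must be fitted separately.
- No HMM-based local-ancestry inference, phasing or introgression dating —
  the scanner is a deliberate re-implementation of the windowed majority
  rule and inherits its resolution limits (about one window width at
  segment edges).
- Prediction for candidates far outside the training cohort's allele-
  frequency spectrum extrapolates linearly and should be interpreted with
  the usual caution.
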