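---
title: "Fine-mapping under genotype imputation error: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-mapping under genotype imputation error: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finemapsim)
```

## The problem

Statistical fine-mapping tries to reduce an association signal to a minimal
set of variants — a 95% credible set — that contains the causal variant with
high probability. All credible-set constructions assume the causal variant is
present, and accurately typed, in the analyzed data. Most association studies
instead genotype an array and impute the remaining variants from a reference
panel, so the causal variant is usually an *imputed* dosage with error that
depends on the size and match of the reference panel.

DNA methylation at a CpG site that harbours a SNP (a CpG-SNP) offers a rare
model trait for studying this: the CpG-SNP destroys the methylatable
dinucleotide, so the causal variant is known, common, and of very large
effect. `finemapsim` recreates that study design entirely in simulation: it
generates haplotype populations with realistic local LD, simulates
methylation-like traits with the CpG-SNP as the (known) causal variant,
emulates array genotyping plus reference-panel imputation, builds 95%
credible sets with three methods, checks for multiple independent signals
with two conditional analyses, and scores everything by *coverage* — the
fraction of loci whose credible set contains the causal variant.

## The haplotype simulator

Real cohort haplotypes are restricted-access, so the package simulates its
own with a founder-mosaic model (`build_panel_mosaic()`):

* A random Kingman coalescent genealogy is drawn over `n_founders` (default
  24) founder haplotypes, and each site's derived allele is assigned to the
  founders below a branch picked with probability proportional to branch
  length (infinite-sites). Founder-level carrier sets are therefore nested or
  disjoint — adjacent sites show |D′| near 1 with widely varying r², which is
  exactly the configuration that makes fine-mapping hard and that real loci
  display — and allele frequencies follow a neutral-like spectrum.
* Each population haplotype copies founders in a mosaic: between adjacent
  sites it switches to a uniformly drawn founder with probability
  `1 − exp(−recomb_rate · distance)` (default `4e-5`/bp at a mean spacing of
  500 bp), so LD decays with distance.
* A small per-allele mutation rate (default `1e-3`) adds haplotype-private
  variation that no tag or reference haplotype carries — the irreducible
  error floor of imputation.

These defaults were chosen once, for qualitative realism of the resulting LD
(adjacent-site D′ ≈ 0.97, decaying r², best tag r² around 0.5–0.8), since no
quantitative description of the original cohort's local haplotype structure
is available. The generator does not attempt coalescent realism beyond this:
no demography, no gene conversion, biallelic sites only, autosomal only.

`build_panel_from_haplotype_table()` constructs exact small loci from
explicit haplotype frequencies (multinomial or largest-remainder "exact"
realization); it is used for the masking scenario below, where the *absence*
of one two-locus haplotype class is the point.

## Phenotypes

`simulate_phenotype()` implements the standard additive model
`y = Σ_c X_c β_c + ε` with effects drawn from N(0,1) and `ε` scaled so the
*population-level* genetic variance fraction equals the target narrow-sense
heritability (`β'Σβ` with `Σ` the empirical dosage covariance, exact under
LD). With a single causal variant the heritability is identical to the
variance explained by that variant. Simulated heritabilities follow the
study grid `h² ∈ {0.05, 0.1, 0.2}`, with `h² = 0.2` the headline condition;
causal variants are restricted to MAF > 0.05. Phenotypes are Gaussian —
methylation-array β-value bounding and covariate structure are deliberately
not emulated, matching the use of corrected, residualized methylation values.
Whether the noise is rescaled per replicate or at the population level is
not fixed by the model description; the population-level convention was
chosen, so per-replicate realized heritability fluctuates around the target.

## Imputation emulation

The array → phase → impute pipeline is emulated, not wrapped
(`mask_to_array()`, `impute_li_stephens()`):

* Array genotyping keeps a subset of sites (default ~30% of the locus) as
  hard genotypes.
* Imputation runs a Li–Stephens haplotype-copying HMM for each target
  haplotype over the reference panel (scaled forward–backward in C++):
  copying switches between reference haplotypes at rate `switch_rate`
  (default `1e-5`/bp) and observed array alleles are emitted with error
  `mismatch_rate` (default 0.01). Posterior-mean alleles are summed into
  dosages.
* Phasing is bypassed: the HMM runs on the sample's *true* haplotypes, which
  are known in simulation. This deliberately isolates imputation error from
  phasing error; reference panel **size** (and optionally divergence) is the
  experimental knob standing in for the contrast between a very large
  well-matched panel and a smaller, more heterogeneous one.
* The per-site info score is the standard observed/expected dosage-variance
  ratio: ML dosage variance over `2p(1−p)`, clipped to [0, 1].

Quality control (`apply_qc()`) applies the conventional filters — MAF < 0.01,
Hardy–Weinberg exact-test P < 1e-6 (Wigginton-style exact test on rounded
genotypes), missingness > 5%, info < 0.8 (with 0.3 as the documented lenient
alternative) — and logs per-filter removals. Dataset arms are compared on the
intersection of their surviving sites (`intersect_datasets()`).

For the panel-size degradation experiment the pipeline uses the lenient
info ≥ 0.3 filter so that the (imputed) causal site is not silently removed
from the intersection at small reference sizes; with the stringent 0.8
filter the coverage loss would be dominated by outright removal of the
causal site rather than by dosage error, which is a different failure mode
than the one under study.

## The three credible-set methods

All three assume a single causal variant, and all treat "complete LD"
(dosage r² = 1 within 1e-9, including allele-flipped copies) as one entity:
one member is tested/sampled, and partners share its fate.

**J-test confidence set** (`jtest_credible_set()`). Sites are ranked by
association strength (ascending p, ties by |t| then position). The top SNP
is regressed on the phenotype; for each rival N = 2, 3, … the phenotype is
regressed on the rival plus the top SNP's fitted values, and the
fitted-values coefficient λ_N is tested at the Bonferroni-corrected level
α/(N−1). A significant λ_N means the top SNP explains significantly more
variance than the rival — the rival and everything ranked below it are
excluded and iteration stops; otherwise the rival joins the set. The
"P_{N−1}" correction is read as α/(N−1), i.e. correcting for the N−1
comparisons performed so far; the indexing is switchable in principle but
α/(N−1) is the natural reading. Note the direction: *larger* α stops the
scan earlier and gives *smaller* sets.

**Bayes-factor / PPA set** (`ppa_credible_set()`). Each site receives the
Bayes factor of its one-SNP linear model against the null. The default is
Wakefield's approximate Bayes factor, `√(V/(V+W)) · exp(z²W/(2(V+W)))`,
computed from the OLS estimate and its standard error, with the phenotype
standardized and prior effect variance `W = 0.5` — generous enough for the
very large effects of methylation QTL (a standardized causal effect around
`√h²`). An exact conjugate-prior Bayes factor (normal slab `N(0, Wσ²)`,
reference priors on intercept and residual variance) is available as
`model = "conjugate_exact"`; the two are rank-equivalent in the regimes
exercised here. Under the single-causal assumption the posterior probability
of association is `PPA_i = BF_i / Σ_j BF_j` (computed in log space); sites
are added in descending PPA until the cumulative probability reaches 0.95.

**MCMC top-variant counting** (`mcmc_credible_set()`). A spike-and-slab
Gibbs sampler (Bayesian variable selection: per-site inclusion indicators
with a Beta(1, M) prior on the inclusion probability, a normal slab with an
inverse-gamma hyperprior on its variance, conjugate updates, standardized
inputs) stands in for the original mixed-model MCMC: the sparse prior is a
surrogate, because the *counting* procedure — not the exact prior — is the
construction under study. At every 10th post-burn-in iteration (default
11,000 iterations, 1,000 burn-in) the included site with the largest |β| is
counted as the predicted causal variant, with complete-LD partners counted
simultaneously; "largest effect" is read as raw |β| on standardized
genotypes. The 95% set accumulates sites in descending count order until 95%
of counted iterations are included. Count ties break deterministically by
position.

## Conditional analyses

`forward_selection()` repeats conditional scans, absorbing the top site into
the conditioned set while the minimum conditional p-value stays below
5e-8. `stepwise_joint_selection()` alternates that forward step with a
backward step that refits the chosen sites jointly and drops members no
longer significant, with a collinearity screen (pairwise r² < 0.9, the
conventional cap) before each admission. Both operate on individual-level
dosages: the summary-statistic algebra of the original stepwise tool is not
needed when individual genotypes are available, and the forward/backward/
collinearity logic is preserved. The whole simulated locus is the
conditioning window.

## The masking scenario

`build_masking_scenario()` constructs the configuration diagnosed in the
locus-level failures: three two-locus haplotypes (top-major/cpg-major,
top-minor/cpg-major, top-minor/cpg-minor), so every CpG-minor allele rides
on a top-minor haplotype — D′ = 1 with r² < 1 — and both variants lower the
trait, with the top SNP commoner and stronger. Defaults (CpG MAF 0.15, top
MAF 0.30, effects −0.5 and −1.0, h² = 0.2, n = 1366) were fixed from a power
calculation: the CpG-SNP's *conditional* non-centrality given the top SNP is
then ≈ 19 (z ≈ 4.3, p ≈ 1e-5), safely short of genome-wide significance, so
conditional analyses report a single signal, while the top SNP's marginal
advantage (variance explained 0.19 vs 0.13) makes the credible sets collapse
onto it and exclude the true causal variant. This is the package's
reproduction of the qualitative masking finding; it is a knife-edge
phenomenon in n and effect ratio, which the defaults deliberately avoid
sitting on.

## Evaluation

`coverage()` reports per method × arm: coverage, mean/median set size, and
the 95% set-size quantile by the nearest-rank convention (the empirical
quantile convention is not standardized; nearest-rank was chosen and is
stated here). Coverage is stored at full precision and only rendered as a
percentage. `stratify_by_provenance()` splits loci by whether the causal
site was genotyped or imputed; `variance_explained_comparison()` regresses
the phenotype on the causal dosage per arm — dosage error attenuates r²
roughly by the squared dosage correlation.

## Orchestration and problem sizes

`run_experiment()` drives the whole design from an `experiment_config()`:
per-locus child seeds are a pure function of the master seed and locus index
(`child_seed()`), so any locus can be reproduced in isolation; failed loci
are quarantined with a reason, and a run aborts only if more than half the
loci fail. Genotypes exchange as VCF (GT + DS fields, `II` info key,
`TYPED` flag).

The package's standard problem sizes, used by its tests and acceptance
script, are: 300 loci of ~150 sites at n = 1366 for the nominal-coverage
check on true genotypes; 500 replicates for heritability recovery; and 300
loci of ~100 sites at n = 500 with reference panels of 400 vs 40 haplotypes
for the degradation ordering. The last trio uses a smaller cohort per locus
because the contrast of interest — the coverage *ordering*
truth > large panel > small panel — is a between-arm comparison on matched
seeds and resolves comfortably at that size, with gaps of roughly 10–20
percentage points.

## Numerical choices and degenerate inputs

* OLS is computed from centered sufficient statistics; conditional tests by
  residualization on a QR factorization (equivalent to the joint fit with
  the correct degrees of freedom). Zero-variance sites are flagged and
  excluded from rankings; a zero-variance site requested in a Bayes-factor
  computation gets BF = 1 with a warning.
* Association ties break by |t| then position; PPA and count ties break by
  position; all tie-breaks are deterministic.
* Unphased LD uses the classic EM for two-locus haplotype frequencies,
  started at linkage equilibrium, 100 iterations or Δ < 1e-12.
* The HWE exact test uses the standard recurrence in log space.
* The Li–Stephens forward pass is rescaled per site; a numerically dead
  column resets to uniform (only reachable with pathological parameters).
* Monomorphic sites are dropped at panel construction (with a message);
  monomorphic info scores are NA sentinels that fail QC.
* `h2_target = 0` produces pure N(0,1) noise; an empty causal set with
  positive h² is an error.

## What passing tests do and do not show

The simulations demonstrate the *mechanisms* — nominal coverage with perfect
genotypes, coverage degradation ordered by reference-panel size, the
genotyped-vs-imputed causal gap, and D′ = 1 masking — at desk scale. They do
not reproduce cohort-specific magnitudes (real coverages, the exact 7% and
23% panel gaps), which depend on restricted data, real array content,
fine-scale LD, and population history that the founder-mosaic generator only
caricatures. Multi-causal credible sets, functional-annotation priors,
summary-statistic-only conditioning, phasing error, and multi-ancestry
reference mixtures are out of scope.
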