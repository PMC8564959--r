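---
title: "Models and methods in fishqg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in fishqg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fishqg` implements the quantitative-genetics workflow of a commercial
aquaculture breeding programme — pedigree and genomic relationship
matrices, animal-model variance components, Bayesian variable-selection
GWAS, and cross-validated genomic prediction — together with a simulator
that reproduces the statistical structure of a factorial-cross cohort, so
that every stage of the analysis can be exercised and checked at desk
scale. This vignette records the models, the tunable parameters, and the
design choices made where the design was genuinely open.

## The breeding-design simulator

The simulator emulates a mating design in which dams and sires are split
into factorial cross blocks and each full-sib family is one dam x sire
pair drawn from a within-block grid. The default
`breeding_design()` is 84 dams x 99 sires in 10 blocks giving 831
families and a mean of 1.7 phenotyped offspring per family (about 1,410
fish) — the scale of a production rainbow trout cohort. Family sizes are
a configuration, not an assumption: a single integer gives equal sizes, a
non-integer mean allocates offspring to families uniformly at random
(multinomial sizes), and a function can supply any size distribution,
because real designs rarely publish one.

Genotypes are produced by gene dropping. Founder haplotypes are drawn at
Hardy-Weinberg proportions with allele frequencies uniform on a
configurable interval (default 0.05-0.5, matching a post-QC array);
descendant gametes follow Mendelian transmission with Haldane
(no-interference) recombination at 1 cM/Mb. This is the simplest
defensible recombination model; nothing downstream depends on
interference. Missing calls are injected completely at random at a
configurable rate.

Phenotypes follow the additive animal model `y = mu + a + e`. The
polygenic part of the breeding value is simulated by the standard
recursive rule (child = mid-parent + Mendelian-sampling deviate with
variance half the founder genetic variance), so that with no planted QTLs
the pedigree relationship matrix A describes the genetic covariance
exactly. Planted QTLs add marker effects on centred dosages, sized
against the realised dosage variance so that each QTL contributes exactly
its requested fraction of additive variance. Residuals are scaled to the
realised breeding-value variance, so realised heritability targets the
nominal `h2` rather than drifting with pedigree sampling noise.
Mendelian-sampling variance uses the non-inbred value `G0/2`; for the
two-generation designs simulated here parents are non-inbred and the rule
is exact, while for deeper pedigrees it slightly overstates the variance
in inbred lines (a known simplification, stated here once).

Two features of real data are deliberately not emulated: compositional
closure (the twelve fatty-acid traits of the preset are simulated on the
unconstrained scale, as percentage traits are analysed in practice), and
linkage-disequilibrium structure matched to a real array. Passing tests
therefore demonstrate statistical correctness of the estimators under the
stated model, not robustness to every artefact of production genotyping.

The 12-trait preset `fa_trait_model()` uses heritabilities in the
0.03-0.24 range with block-structured genetic correlations — strongly
positive within the saturated/monounsaturated and polyunsaturated groups,
strongly negative between them — and means/SDs typical of a
plant-based-diet cohort. Three of the twelve heritabilities (oleic and
alpha-linolenic acid, EPA+DHA) are representative in-range values chosen
by the package. Residual correlations default to the genetic ones, which
yields phenotypic correlations of similar sign and size, the pattern seen
in such panels.

## Quality control

`run_qc()` applies, in a fixed order: SNP call rate (>= 0.97),
Hardy-Weinberg equilibrium (one-degree-of-freedom Pearson chi-square,
p > 1e-4), minor allele frequency (> 0.05), then sample call rate
(>= 0.90). Summaries are computed once on the input; they are not
recomputed after sample removal — a single pass is reproducible and the
order matches how array QC is normally described. HWE is tested on all
samples jointly rather than within families. An exclusion list handles
probe-level removals decided upstream. The two imputers are deliberately
naive — per-SNP rounded mean, optionally preceded by Mendelian-certain
fills from homozygous parent pairs — and are documented as such; they are
a transparent stand-in for family-based imputation software, adequate at
the < 3% missingness the call-rate filters leave behind.

## Relationship matrices

`pedigree_A()` is the tabular (recursive) method; unknown parents are
unrelated, non-inbred founders. `genomic_G()` is VanRaden's first method,
`G = ZZ'/(2 sum p(1-p))` with observed allele frequencies by default.
`blend_relmat()` shrinks a matrix towards the identity (`0.99 G + 0.01 I`
by default) before inversion; blending is exposed rather than hidden
because whether and how much to blend is a modelling choice.

## AI-REML variance components

`reml_animal()` fits the animal model with the overall mean as the sole
fixed effect, for one trait or two (unstructured genetic and residual
covariance). The kinship matrix is eigendecomposed once; in the rotated
basis the covariance is block-diagonal (1x1 or 2x2 per eigenvector), so
each iteration is O(n) and fits take milliseconds after the
decomposition. Updates are average-information steps with step halving,
an exact EM fallback, and projection of the covariance matrices onto the
positive-definite cone by eigenvalue clipping (floor 1e-6 of the mean
phenotypic variance — this floor is also what keeps the degenerate
duplicated-trait case solvable). A step is accepted only if it does not
decrease the restricted log-likelihood, so the likelihood trace is
monotone by construction. Convergence is declared when the change in
log-likelihood falls below 1e-8 (at most 200 iterations); non-convergence
is flagged, never silent. Initial values are half the phenotypic
(co)variance for both components.

Standard errors come from the inverse average-information matrix at
convergence; heritabilities and correlations get delta-method standard
errors. Correlations are clamped to [-1, 1] and flagged when clamping
occurred. The model-based phenotypic correlation (from `G0 + R0`) is the
default report; the raw Pearson correlation is also returned, since
published tables do not always say which was used. The optional log
transform is the natural log of the raw values (rejecting non-positive
records) — used to stabilise bivariate fits of skewed percentage traits.
Bivariate fits use individuals phenotyped for both traits.

## BayesCpi GWAS

`bayescpi()` is a Gibbs sampler for the mixture model in which SNP `j`
enters the model with probability `pi` and, when included, has effect
`a_j ~ N(0, sigma2_a)` with a variance common to all included SNPs.
Defaults mirror a 57K-array analysis: 200,000 cycles, 5,000 burn-in,
samples kept every 20 cycles (9,750 saved), and an inclusion-probability
prior of Beta(300, n_snps). With 29,652 SNPs that prior has mean ~1%,
about 300 SNPs per cycle, and its 300 pseudo-counts pin `pi` near 1%
throughout the run. The effect-variance prior is scaled inverse
chi-square with 4 degrees of freedom, scaled so the prior genetic
variance at the prior mean model size is half the phenotypic variance; the
residual prior is the analogous weak scaled inverse chi-square. The
sampler is written in C++ (RcppArmadillo) and uses R's RNG, so chains are
reproducible from `set.seed()` alone.

Evidence is scored as `2 ln BF` with
`BF = (P/(1-P)) / (pi/(1-pi))`, where `P` is the posterior inclusion
probability and `pi` in the denominator is the prior mean
`alpha/(alpha+beta)` (not the per-cycle sampled value — the sampled value
would make the score depend on chain noise). A SNP included in every
saved sample is capped at `P = (S-0.5)/S` for `S` saved samples so the
Bayes factor stays finite; `P = 0` maps to `2 ln BF = -Inf`.

`call_qtls()` treats peaks (>= 5) in decreasing score order, ties broken
by lower bp, and grows a credibility interval with a 1-Mb sliding window
admitting neighbours with score >= 3 until a window adds none. Peaks at
score >= 6 are evidence; peaks in [5, 6) are putative and kept only if
the region explains at least 0.5% of the additive genetic variance or
overlaps a region called for another trait. Overlapping same-trait
regions are merged and re-peaked. The variance explained by a region is
the sum over its SNPs of `2 p (1-p) E[(delta a)^2]` (posterior means),
divided by the genome-wide total of the same quantity — a marker-derived
denominator that is reproducible inside the module without importing a
REML estimate; the REML denominator can be substituted by the caller.
Reported Mb positions are bp/1e6 rounded to two decimals.

`check_convergence()` follows the practical criterion used with such
samplers: chains started from different seeds must produce genomic
estimated breeding values (dosages times posterior-mean effects) with
pairwise correlations above 0.99; density traces of the variance samples
are available through `plot(fit, type = "trace")`.

## BLUP, GBLUP and cross-validation

`blup()` solves Henderson's mixed-model equations with the overall mean
as the sole fixed effect. The pedigree flavour can carry non-phenotyped
ancestors (they receive values through relationships); the genomic
flavour covers genotyped individuals. At the scale this package targets,
direct inversion of K is used rather than sparse-inverse machinery.

`cross_validate()` is Monte Carlo leave-one-group-out validation: per
replicate a uniform random validation group (default 314 of 1,382, i.e.
1,068 training records) is masked, BLUP and/or GBLUP are fitted on the
training records, and two statistics are computed on the validation set:
accuracy `cor(EBV, y)/sqrt(h2)` with `h2` the pedigree-based estimate,
and the inflation (dispersion bias) coefficient, the OLS slope of
phenotypes on EBVs, which is 1 for unbiased dispersion. Variance
components are estimated once on the full data and reused across
replicates (refitting per training set is a flag); draws are independent
across replicates and each replicate is reproducible from
`(seed, replicate index)`.

One architectural point matters when interpreting the BLUP-vs-GBLUP
comparison on simulated data: genomic prediction can only beat pedigree
prediction if genetic variance is linked to the markers. The
cross-validation study shipped with the package therefore simulates a
marker-polygenic trait (300 planted QTLs carrying 90% of the additive
variance, the remainder pedigree-polygenic); under the pure
pedigree-recursive default the within-family information in G is
uninformative by construction and the comparison would be biased against
GBLUP.

## Problem sizes and reproducibility

The shipped checks run at desk scale by choice: cohorts of 120-1,000
fish, 100-2,000 SNPs on 2-5 chromosomes, chains of 1,500-20,000 cycles,
and 40 cross-validation replicates; the full-scale defaults (29,652 SNPs,
200,000 cycles) remain configuration values. All randomness flows through
R's RNG; pipeline stages derive their seeds from the global seed as
`seed + 1000 x stage index`. `run_pipeline()` writes every artifact as
TSV or PLINK-style text and reports md5 digests, so two runs with the
same configuration and seed are byte-identical.

## Known limitations

Single fixed effect only (the target design phenotypes one cohort reared
together); no maternal, common-environment or dominance components; at
most two traits per REML fit; no single-step (H-matrix) evaluation; the
imputers are not a substitute for family-based imputation at high
missingness; and the simulator's LD structure is whatever gene dropping
over a 2-5 chromosome map produces, not a calibrated match to any real
array.
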