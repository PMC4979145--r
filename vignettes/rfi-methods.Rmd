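---
title: "Models and methods behind rfikit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rfikit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rfikit` analyzes residual feed intake (RFI) in growing poultry: the part
of feed intake not explained by maintenance (body size) and production
(growth) demand. This vignette documents the models, the parameter
choices and their rationale, what the synthetic-data generator does and
does not emulate, and the package's numerical conventions.

## From longitudinal records to feeding traits

Body weight during a rapid-growth feeding trial is close to linear in
age, so each bird's trajectory is fitted by ordinary least squares,
`BW = μ + a·DOT + e`, with DOT (day of test) coded 1..40 for a 40-day
trial. The slope `a` is the average daily gain (ADG, g/day); the mid-test
body weight (MBW) is the predicted weight at DOT = 21 — the mid-day of
1..40, rounded up — and the metabolic mid-test weight is MMBW = MBW^0.75,
the classic allometric scaling of maintenance requirements. Fits with
R² < 0.80 are flagged (`low_fit_flag`) but retained: a poor growth fit is
a data-quality signal, not an exclusion criterion, and dropping such
birds would bias the cohort. ADFI is the mean of the recorded daily feed
intakes; missing feed days are tolerated (mean of available days, count
reported). FCR is computed per bird as ADFI/ADG — the ratio definition is
not uniquely determined by common usage (per-bird ratio vs ratio of
means); the per-bird ratio was chosen because group summaries of
per-bird ratios are what divergent-group tables report.

## The Koch intake model and RFI

Expected intake is modelled as `ADFI = b0 + b1·MMBW + b2·ADG + RFI`:
`b1` prices maintenance (g feed per g^0.75 per day), `b2` prices growth
(g feed per g gain), and the OLS residual is the bird's RFI. Two
properties follow exactly from least squares and are enforced to
numerical precision: mean(RFI) = 0 and zero correlation with both
regressors. They are the reason RFI can be selected on without dragging
growth along.

Sex and pen are tested by one-way F-tests and subtracted (level means,
re-centered) only when significant at P < 0.01 — with pens nested in sex
(three male, three female pens) a real sex difference usually surfaces
as a pen effect. The adjustment is idempotent. Because association tests
downstream assume Gaussian residuals, RFI is passed through a Johnson
transformation (below) when the Anderson–Darling test rejects
normality.

### Johnson transformation

Candidates from all three Johnson families (SU, SB, SL) are fitted by
the Slifker–Shapiro percentile method at sample quantiles taken at
normal scores ±z and ±3z, over a grid of selection constants
z = 0.25..1.25 in steps of 0.01 (type-6 quantiles). Every candidate that
is finite and strictly monotone on the sample range is scored by the
Anderson–Darling p-value of its transformed sample; the best one wins.
If no candidate fits, the identity transform is returned with a
warning. The Anderson–Darling statistic uses the estimated-parameters
small-sample correction A²* = A²(1 + 0.75/n + 2.25/n²) and the standard
piecewise p-value approximation for the composite-normality case; the
`nortest` implementation is used as an independent oracle in the tests,
never as the implementation.

## Variance components

The animal model is `y = Xb + Za + e` with `a ~ N(0, Φσ²_A)`. Φ is
either the VanRaden frequency-weighted genomic relationship matrix
(`Φ_ij = (1/m)Σ_k (g_ik−2p_k)(g_jk−2p_k)/(2p_k(1−p_k))`, missing
dosages mean-imputed) or, when only a pedigree exists, the additive NRM
via the tabular method. The frequency-weighted kinship was chosen over a
raw IBS matrix because it has the correct expectation for the covariance
of breeding values under the additive model the REML step assumes.

REML exploits the eigen-decomposition of Φ (after a 1e-8 diagonal
ridge): rotating by the eigenvectors diagonalizes the covariance, the
profile restricted likelihood becomes one-dimensional in the variance
ratio δ = σ²_e/σ²_A, and a bounded scalar search (tolerance 1e-10 on
log δ) finds the optimum. h² = 1/(1+δ); its SE comes from the numerical
curvature of the profile likelihood. Boundary optima are reported at 0
or 1 with `converged = FALSE`. The bivariate model uses the same
rotation — each rotated observation pair has covariance `G·d_i + R` —
parameterizes G and R by log-Cholesky factors, starts from the
univariate fits, and polishes a Nelder–Mead solution with BFGS; r_g =
G12/√(G11·G22) with a delta-method SE from the numerical Hessian.
Near-singular G triggers a warning and a wide SE rather than a silent
number.

## GWAS

QC removes, in order: SNPs with call rate < 0.95, individuals with call
rate < 0.95, SNPs with MAF < 0.01, and SNPs failing an exact
Hardy–Weinberg test at p < 1e-6 (the exact test is implemented directly
from the conditional distribution of heterozygote counts and checked
against full enumeration). These thresholds are package defaults — the
conventional array-QC values — and all are configurable.

The scan is the standard two-step mixed-model scheme: null variance
components estimated once by REML, then per SNP a GLS Wald test of the
dosage term using the fixed null covariance `V = Φσ̂²_G + Iσ̂²_e`. This
costs one eigen-decomposition total instead of one REML per SNP, and on
desk scales it agrees with the dense GLS oracle to machine precision.
Dosages are coded for the realized minor allele, so reported effects are
per minor-allele copy. When the phenotype is the transformed,
pre-adjusted RFI the fixed-effect design reduces to the intercept.

Genomic control divides the χ² statistics by
λ = median(χ²)/0.4549364; the genome-wide significance flag is
p < 10⁻⁴ on the λ-corrected p-value. FDR is computed chromosome-wise:
within each chromosome p-values are sorted, `m·P(i)/i` computed with m
the number of tested SNPs on that chromosome, the cumulative minimum
taken from the largest rank, and values capped at 1 — the step-up
procedure — with tiers flagged at 0.05 ("**") and 0.10 ("*"). Whether m
should be per-chromosome or genome-wide is ambiguous in common usage;
per-chromosome is implemented because the procedure is explicitly
chromosome-wise, and the `chrom` argument makes the genome-wide variant
a one-liner. Per-SNP variance explained is 100·R² of the one-way
genotype-class model on phenotypes; substituting REML breeding values
gives the additive-variance share.

## LD and haplotype blocks

Two-locus haplotype frequencies come from the standard EM over
double-heterozygote ambiguity (allele margins are invariant under the
M-step, so only D moves). D′ = D/Dmax, r² = D²/(p_A p_a p_B p_b).
One-sided 95 % bounds on |D′| are taken from the likelihood profile over
a 0..1 grid (step 0.001) with allele frequencies fixed at their
estimates, treating the normalized likelihood as a density; "strong LD"
means upper bound ≥ 0.98 and lower bound ≥ 0.7. Blocks are regions of
consecutive SNPs in which more than 95 % of informative pairs (MAF
≥ 0.05 at both SNPs, EM converged) are strong; overlapping candidates
are resolved greedily, longest span first. Pairwise evaluation is
limited to a 500-kb window. Block haplotype frequencies use a
multilocus EM capped at 12 SNPs (2¹² haplotype states); the EM
log-likelihood is asserted non-decreasing at every iteration.

The LD-*decay* profile uses squared genotype (dosage) correlation rather
than EM r²: for a profile averaged over tens of thousands of pairs the
two are nearly identical under HWE, and the dosage form vectorizes.

## Synthetic data: what it emulates, and what it does not

The generator mirrors a 40-day feeding trial on a medium-growth
dwarf meat-type line: 426 genotyped birds in six pens (pens nested in
sex), start weight ≈ 770 g, ADG ≈ 27.9 g/day, ADFI ≈ 105 g/day, RFI
standard deviation 8.36 g/day, RFI heritability 0.35, and 5000 SNPs at
≈1.8 kb spacing as the desk-scale stand-in for a dense array. The Koch
coefficient defaults (b0 = 16, b1 = 0.25, b2 = 1.2) were chosen once so
the implied ADFI matches the cohort means above.

Haplotypes follow a first-order copying process on latent per-site
uniforms: the latent state is kept with probability exp(−d/L) and
redrawn otherwise; the allele is the indicator that the state falls
below the site's frequency. This preserves the drawn allele frequencies
exactly (hence HWE by construction, since a genotype is the sum of two
independent haplotypes) while allelic correlation decays as exp(−d/L).
A pure one-parameter copying chain, however, cannot match both the
shallow decay (≈0.3 → ≈0.2 between short range and 40–60 kb) and the
absolute level seen on dense arrays — the exponential that fits the
slope implies short-range r² near 0.5. The `site_noise` parameter
therefore redraws each site's latent state independently with small
probability, a recurrent-mutation/gene-conversion analogue that
attenuates LD uniformly across distances. The shipped `ld_preset()`
(maf 0.1–0.5, L = 180 kb, site_noise = 0.12) was calibrated once by
Monte Carlo to the bin pattern ≈0.30 / ≈0.19 / ≈0.13 for 0–20, 40–60
and 80–100 kb and then frozen.

True RFI is built as QTL effects plus a polygenic background over all
remaining SNPs plus an environmental deviate; the environmental term is
residualized on the genetic value and scaled so Var(genetic)/Var(RFI)
equals the configured h² *exactly in-sample*, which keeps recovery tests
calibrated rather than adding generator sampling noise to the tolerance.
`simulate_genetic_traits()` extends the same construction to a trait
pair with an exact in-sample genetic correlation. RNA-seq counts are
negative binomial (Var = μ + φμ², default φ = 0.1) for two samples per
RFI group, with log-normal baseline means, ±fold-change on a configured
DE fraction, and mild log-normal library-size factors.

Not emulated: coalescent genealogies (no recombination hotspots or
allele-frequency spectra), genotyping error, selection or family
structure (individuals are unrelated, so kinship off-diagonals are
near zero), growth-curve nonlinearity, seasonal or age trends in feed
intake, and sequencing-read-level artifacts. Passing tests therefore
demonstrate correctness of the estimators under the assumed generative
models, not robustness to the violations real data bring.

## Differential expression

RPKM = 10⁹·C/(N·L). With two samples per group, per-replicate dispersion
estimation is hopeless, so counts are pooled within groups: the fold
change is the ratio of pooled RPKM (pseudocount 0.5 on pooled counts)
and the p-value a two-sided Fisher exact test of pooled gene counts
against pooled library remainders, followed by Benjamini–Hochberg.
A gene is DE when q < 0.05 and |log₂FC| ≥ 1; the fold-change filter is
what keeps the null call fraction below 5 % despite the exact test
ignoring biological overdispersion — an acknowledged property of
pooled-count testing at n = 2. Genes with zero pooled counts in exactly
one group and RPKM ≥ 1 in the other are reported as group-specific
rather than given an infinite fold change. miRNA–target consistency
labels a (miRNA, target) pair consistent when their directions in the
low-RFI group are opposite, as negative regulation predicts.

## Positional integration

Coordinates are 1-based inclusive throughout. Within a harbouring gene
the relation precedence is UTR-3/UTR-5 > exon > intron; outside,
upstream/downstream labels apply within 5 kb of the strand-oriented
gene ends (the window is configurable; 5 kb is the common annotator
default), else intergenic with the nearest gene named; ties break by
lexicographic gene id. Flank capture intersects closed intervals, so
the 50-kb capture set is provably a subset of the 500-kb set.
Annotation is read from GFF3 (`rtracklayer`); for purely synthetic runs
a synthetic tiling annotation (clearly labelled as such) keeps the
integrate stage exercisable.

## Problem sizes and reproducibility

All generators are bit-reproducible under a fixed seed, and the pipeline
writes a JSON manifest of seeds and per-stage row counts. The calibration
checks use the sizes the estimators are designed for: heritability and
genetic-correlation recovery at n = 1000, m = 5000 (10 phenotype
replicates on one genotype set — the phenotype draw, not the genotype
draw, is the randomness being averaged); null-scan calibration at
n = 426, m = 10⁴; oracle equalities at n = 30, m = 50; DEG error rates
over 20 replicates of 1000 genes; Johnson improvement over 100
replicates of n = 426. The unit suite re-runs scaled-down versions of
the same checks.

## Known limitations

- The two-step scan fixes the null variance components; for very large
  single-SNP effects the per-SNP REML would give slightly different
  (more powerful) statistics.
- With few, tightly linked SNPs the genomic kinship absorbs single-QTL
  signal; kinship should be built genome-wide, as the pipeline does.
- Bivariate REML r_g estimates at n = 1000 carry a small upward finite-
  sample bias (≈0.03–0.05 at r_g = 0.75) that sits well inside the
  reported SE.
- The Fisher-based DEG test understates variance for overdispersed
  counts; it is defensible only together with the fold-change filter and
  pooling, which is exactly how it is used.
- The copying-model LD is stationary along the chromosome; real genomes
  have block structure and hotspots that make empirical block
  inventories richer than the simulated ones.
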