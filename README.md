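# rfikit

Quantitative-genetic analysis of **residual feed intake (RFI)** in
meat-type poultry, from longitudinal feeding records to genome-wide
association and liver-transcriptome integration.

RFI is the part of a bird's feed intake that is not explained by its body
size and growth: birds with low RFI eat less without growing slower, so
RFI is the selection target of choice for improving feed efficiency
without sacrificing performance. `rfikit` implements the full analysis
chain a breeding study needs:

1. **Growth curves** — per-bird OLS of body weight on day of test,
   `BW = μ + a·DOT + e`, giving average daily gain (ADG) and the
   mid-test metabolic body weight `MMBW = MBW^0.75` (MBW predicted at
   day 21 of a 40-day test).
2. **Koch intake model** — `ADFI = b0 + b1·MMBW + b2·ADG + RFI`; the
   residual is the bird's RFI. One-way F-tests decide whether sex and pen
   fixed effects must be subtracted (at P < 0.01), and a Johnson
   transformation (SB/SL/SU, percentile method) maps RFI toward
   normality, checked by the Anderson–Darling test.
3. **Variance components** — REML under the animal model
   `y = Xb + Za + e`, `a ~ N(0, Φσ²_A)`, with a VanRaden genomic kinship
   or a pedigree NRM for Φ; univariate (heritability) and bivariate
   (genetic correlations) via eigen-decomposition of Φ.
4. **GWAS** — QC (call rate, MAF, exact HWE), then a two-step
   kinship-adjusted scan: null variance components once, per-SNP GLS Wald
   tests `Y = Xb + Sa + Zu + e`; genomic-control λ correction,
   genome-wide threshold 10⁻⁴ on corrected p, and chromosome-wise
   step-up FDR `m·P(i)/i` with 5 %/10 % tiers; per-SNP variance explained
   from the one-way genotype model.
5. **LD and haplotype blocks** — EM two-locus haplotype frequencies, D′
   and r², likelihood-profile one-sided 95 % confidence bounds on |D′|,
   confidence-interval ("strong LD": upper ≥ 0.98, lower ≥ 0.7) block
   construction, LD-decay profiles, and multilocus block haplotype
   frequencies.
6. **Differential expression** — RPKM (`10⁹·C/(N·L)`) between high- and
   low-RFI groups; pooled exact two-proportion tests,
   Benjamini–Hochberg q, DE at q < 0.05 and |log₂FC| ≥ 1, group-specific
   expression calls, and miRNA–target direction consistency.
7. **Integration** — SNP–gene relations (UTR/exon/intron/up/downstream),
   50-kb and 500-kb flank gene capture, and overlap of captured genes
   with the DEG set.

A seeded synthetic-data generator (`sim_config()`, `simulate_genotypes()`,
`simulate_growth_and_intake()`, `simulate_counts()`) produces cohorts with
the statistical structure the analysis assumes — HWE genotypes with
distance-decaying LD, linear growth, Koch-model intake with configurable
heritability, negative-binomial counts — plus ground-truth labels, so
every stage is testable against known truth.

## Worked example

```r
library(rfikit)

cfg    <- sim_config(seed = 42)            # 426 birds, 5000 SNPs, h2 = 0.35
G      <- simulate_genotypes(cfg)
sim    <- simulate_growth_and_intake(G, cfg)
traits <- derive_cohort_traits(sim$records)

kf <- fit_koch_rfi(traits)
kf
#> Koch intake model: ADFI = 36.456 + 0.1973*MMBW + 1.0149*ADG + RFI
#>   model R2 = 0.151; RFI sd = 9.645 g/day (n = 426)

adj <- test_fixed_effects_and_adjust(kf$rfi, traits$sex, traits$pen)
jt  <- johnson_transform(adj$rfi_adjusted)
jt
#> Johnson SB transform (selection constant z = 0.80)
#>   AD p-value: 0.4347 before -> 0.928 after

qc  <- qc_filter(G)
K   <- genomic_kinship(qc$G)
reml_univariate(adj$rfi_adjusted, K = K)
#> REML animal model: sigma_a2 = 16, sigma_e2 = 54.96
#>   h2 = 0.2255 (SE 0.1068), REML loglik = -1508.542

a <- mixed_model_scan(jt$z, qc$G, K)
a
#> assoc_table: 5000 SNPs, lambda = 1.002, 2 significant (p_gc < 1e-4 flag)

divergent_group_contrast(cbind(traits, rfi = kf$rfi))$table
#>   trait mean_low  se_low mean_high se_high  p_value
#> 1   rfi    -17.6  0.5193     16.18  0.6047 1.23e-56
#> 2  adfi     90.9  0.8104    124.98  0.8649 1.84e-44
#> 3   adg     27.6  0.3628     27.80  0.4186 7.49e-01
#> 4   mbw   1353.1 12.9214   1357.83 12.3159 7.91e-01
#> 5   fcr      3.3  0.0309     4.53   0.0594 1.27e-26
```

Reading the output: the intake model explains body-size and growth
demand; the residual spread (9.6 g/day) is the efficiency variation the
study analyzes. The divergent-tail contrast shows the defining RFI
signature — the low-RFI tail eats ~34 g/day less (P < 0.01) at
indistinguishable growth (ADG, MBW p ≈ 0.75–0.79). The scan's λ of 1.002
indicates the kinship correction removed population-structure inflation;
at n = 426 the REML h² estimate (0.23 ± 0.11) scatters around the
configured truth of 0.35.

The whole chain also runs as one call:

```r
res <- run_pipeline(run_config(out_dir = "run1", seed = 7))
```

which writes `traits.tsv`, `assoc.tsv`, `manhattan.tsv`, `blocks.tsv`,
`ld_decay.tsv`, `degs.tsv`, `overlap.tsv`, and `manifest.json` into the
run directory. A thin command-line wrapper is installed at
`inst/scripts/rfikit-pipeline.R`.

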