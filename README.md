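# pawprint

Population-genetic analysis of diploid **microsatellite** genotypes and
mitochondrial **D-loop** haplotypes, built for the kind of survey used to
characterize domestic cat breeds: a few closed populations of tens of
individuals, a panel of ~15 fragment-length markers, and a short mtDNA
alignment. It is aimed at researchers and breed registries who need
per-locus diversity tables, population-structure statistics, forensic
individual-identification and parentage numbers, a minimal marker panel,
and mtDNA demography — from one reproducible toolchain, with a synthetic
data generator so everything can be exercised offline.

## What it computes

**Diversity (per locus × group):** allele frequencies, N_a, effective
alleles N_ea = 1/Σp², rarefied allelic richness, Shannon's I, H_o,
H_e = 1 − Σp² (and unbiased uH_e), Botstein's PIC, fixation index
F = 1 − H_o/H_e, conditional-exact Hardy–Weinberg tests (enumeration or
Monte Carlo), Brookfield null-allele estimates, the M-ratio bottleneck
diagnostic, and a Welch test of H_o vs H_e.

**Structure:** Weir–Cockerham F_IS / F_ST / F_IT with locus-bootstrap CIs
and permutation p-values, Slatkin-style R_ST on allele sizes, Nei's (1972)
distance, three-level codominant AMOVA, Queller–Goodnight pairwise
relatedness, and a permutation G-test of genotypic linkage disequilibrium.

**Forensic identification**, from allele frequencies with power sums
a_k = Σp_i^k:

    P(ID)theoretical = 2a2² − a4
    P(ID)unbiased    = [n³(2a2² − a4) − 2n²(a3 + 2a2) + n(9a2 + 2) − 6] / [(n−1)(n−2)(n−3)]
    P(ID)sibs        = 0.25 + 0.5·a2 + 0.5·a2² − 0.25·a4
    PE               = 1 + 4a4 − 4a5 − 3a6 − 8a2² + 8a2·a3 + 2a3²

with matching probability MP = Σ(genotype frequency)², panel combination
(products; PE combines as 1 − Π(1 − PE)), genotype-accumulation curves,
and He-ordered P(ID)sibs locus curves.

**Marker-panel selection:** ant colony optimization for the smallest panel
meeting a distinguishability threshold (ties broken by mean PIC), with an
exhaustive-search oracle for verification up to 15 loci.

**mtDNA D-loop:** haplotype collapse with complete deletion, H, h, π, k,
θ_S, G_ST / F_ST / Φ_ST / D_xy / D_a / N_m between populations, Tajima's D,
Fu & Li's D* and F*, Fu's Fs (log-space Ewens recursion), and the mismatch
distribution with Harpending's raggedness index.

**Synthetic data:** Balding–Nichols multi-population genotype simulation
with inbreeding and null alleles, Mendelian pedigree simulation (trios and
sib pairs), haplotype alignments, and neutral-spectrum alignments for
calibration — all seeded and returning their true parameters.

## Worked example

```r
library(pawprint)

# a five-breed survey-shaped dataset: 184 cats, 15 loci, 423-bp D-loop
fx   <- make_fixture(tempdir(), seed = 1)
cats <- fx$data$genotypes
cats
#> genotype_table: 184 samples x 15 loci, 5 populations (pop1, pop2, pop3, pop4, pop5)

ids <- per_locus_id_stats(allele_frequencies(cats, "all"))
head(ids, 3)
#>   locus   n     MP PID_theoretical PID_unbiased PID_sibs    PE
#> 1   L01 184 0.2056          0.2056       0.2027    0.485 0.517
#> 2   L02 184 0.2012          0.2012       0.1965    0.503 0.561
#> 3   L03 184 0.0626          0.0626       0.0595    0.368 0.817
combine_panel(ids)
#>      locus   n       MP PID_theoretical PID_unbiased PID_sibs PE
#> 1 combined 184 4.64e-15        4.64e-15     2.85e-15 2.69e-06  1

aco_select_panel(cats, error_threshold = 5, seed = 1)
#> panel_solution (aco): 3 loci [L06, L07, L14]
#>   mean PIC 0.843, % distinguished 99.46, feasible: TRUE

ht <- collapse_haplotypes(fx$data$alignment)
subset(dloop_diversity(ht), population == "all")
#>   population   n  H    h   h_sd    k      pi   pi_sd  S theta_S
#>          all 184 14 0.81 0.0213 3.46 0.00818 0.00464 39  0.0159
```

Reading: across all 15 loci the probability that two random individuals
share a profile is ~5 × 10⁻¹⁵ (and ~3 × 10⁻⁶ even for full siblings), the
parentage-exclusion power is effectively 100%, and three well-chosen loci
already distinguish >95% of individuals in this synthetic survey. The
pooled D-loop alignment carries 14 haplotypes with haplotype diversity
0.81 and nucleotide diversity 0.008.

`run_full_pipeline()` chains every stage (diversity → structure →
identification → panel → D-loop) and writes TSV/JSON tables plus a
markdown report; same seed, byte-identical outputs.

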