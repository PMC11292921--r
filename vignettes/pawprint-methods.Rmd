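---
title: "Methods: microsatellite identity statistics, panel selection, and D-loop demography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microsatellite identity statistics, panel selection, and D-loop demography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`pawprint` implements the statistical toolkit used to characterize closed
domestic-cat breed populations from two marker systems: a panel of
microsatellite (SSR) loci scored as fragment sizes in base pairs, and an
aligned fragment of the mitochondrial D-loop. This vignette documents the
models, the conventions chosen where published practice varies, and the
limits of what the synthetic-data tests demonstrate.

## Data model

A `genotype_table` stores a rectangular samples-by-loci matrix of unordered
diploid allele pairs, plus a population (breed) and a locality label per
sample, so every analysis can be run on either grouping. A genotype is
missing when either allele is absent; all statistics use pairwise deletion
(a sample missing at a locus drops out of that locus only). Allele pairs
are stored sorted, so heterozygote identity never depends on scoring order.
Loci carry their repeat-unit length, which is needed whenever sizes are
converted to repeat units (R_ST, M-ratio).

## Per-locus diversity

For allele frequencies $p_i$ estimated per locus and group:

* $N_{ea} = 1/\sum p_i^2$, $I = -\sum p_i \ln p_i$,
  $H_e = 1 - \sum p_i^2$ and $uH_e = \frac{2n}{2n-1} H_e$. Both forms of
  expected heterozygosity are reported because software packages disagree
  on which one a "He" column holds; downstream code picks explicitly.
* $PIC = 1 - \sum p_i^2 - \left[(\sum p_i^2)^2 - \sum p_i^4\right]$
  (Botstein's index; always $\le H_e$).
* Allelic richness uses FSTAT-style rarefaction to a common depth of $g$
  gene copies, $AR_g = \sum_a \left[1 - \binom{2n - N_a}{g}/\binom{2n}{g}\right]$.
  The default depth is, per locus, the smallest $2n$ across groups; it is
  configurable because the appropriate depth depends on which grouping is
  being standardized.
* The Hardy–Weinberg test is the conditional exact test on genotype
  configurations given allele counts (Levene probabilities), with
  $p = \sum_{\text{configs}} \Pr(\text{config}) \,[\Pr \le \Pr(\text{obs})]$.
  Full enumeration is used when a cheap product bound shows the
  configuration space is at most $10^6$; otherwise Monte Carlo re-pairing
  of the observed gene copies, which samples the conditional distribution
  exactly (10^5 replicates by default for a standalone test, fewer in the
  table-wide sweep where 75 tests are run). Monomorphic loci return
  $p = 1$ by convention. Raw p-values are reported with a Holm-corrected
  column; no further multiple-testing dashboard is attempted.
* Null-allele frequency uses Brookfield's first estimator
  $r = (H_e - H_o)/(1 + H_e)$ truncated at zero, with Chakraborty's
  estimator behind a flag; the choice matters little at the observed
  heterozygote deficits and neither requires a null-homozygote count.
* The M-ratio is $M = k/(r+1)$ with $r$ the allele-size range in repeat
  units; values below 0.68 are flagged as bottleneck-consistent. Sizes off
  the repeat grid trigger a warning and a rounded $r$ rather than an error,
  since real panels contain odd-sized alleles.
* The observed-vs-expected heterozygosity comparison is a Welch unequal-
  variance t-test treating the per-locus $H_o$ and $H_e$ vectors as
  independent samples. They are in fact paired and positively correlated,
  so this test is conservative; it is kept because it is the convention in
  the surveys this package mirrors.

## Structure and relatedness

F-statistics use the Weir–Cockerham (1984) variance-component estimators
summed over alleles and loci; pairwise $\theta$ significance comes from
permuting individuals between the two groups (110 permutations by default
to mirror small-survey practice — at this resolution the smallest
achievable p is ~0.009, so ≥999 is recommended whenever runtime allows),
with Holm correction across pairs. R_ST applies the same variance
partition to gene-copy allele sizes in repeat units, making it invariant
to rescaling. Nei's (1972) standard distance is computed from the printed
closed form; disjoint allele sets give an infinite distance marker rather
than an arbitrary cap.

Pairwise relatedness is the Queller–Goodnight estimator, symmetric-averaged
and multilocus-weighted (numerators and denominators summed over loci
before the ratio), with reference frequencies from the pooled sample. It
was chosen over the Lynch–Ritland and other variants because it is the
most common default and unbiased near $r = 0$, which is the regime of the
breed surveys; the pedigree simulator confirms the expectations 0 and 0.5
for unrelated and parent–offspring pairs within Monte Carlo tolerance.
Per-individual inbreeding is reported as
$1 - (\text{observed heterozygous loci})/\sum_l H_{e,l}$ over the
individual's typed loci — a documented proxy, since the source surveys
report individual values without a formula. Group-level F_IS confidence
intervals are percentile bootstrap over loci (1000 draws, seeded).

AMOVA is the three-level codominant partition (among populations, among
individuals within populations, within individuals) computed per locus on
gene copies with the 0/1 allele-mismatch distance and summed over loci —
the Arlequin default for genotypic data without size weighting. Negative
components are truncated to zero for percentage reporting only; raw
components and Phi statistics keep their sign. The linkage test is a
G-statistic on the two-locus genotype table with significance from
permuting one locus among individuals.

## Identification and parentage statistics

The per-locus statistics are evaluated directly from the printed closed
forms, with $a_k = \sum p_i^k$:

* $P_{(ID)theoretical} = 2a_2^2 - a_4$;
* $P_{(ID)unbiased} = \frac{n^3(2a_2^2 - a_4) - 2n^2(a_3 + 2a_2) + n(9a_2 + 2) - 6}{(n-1)(n-2)(n-3)}$;
* $P_{(ID)sibs} = 0.25 + 0.5a_2 + 0.5a_2^2 - 0.25a_4$;
* $PE = 1 + 4a_4 - 4a_5 - 3a_6 - 8a_2^2 + 8a_2a_3 + 2a_3^2$.

Panels combine by multiplying MP and the P(ID) variants and complementing
PE ($1 - \prod(1 - PE_l)$).

Two interpretation questions were settled as follows. First, the product
form sometimes printed for the matching probability,
$\prod p_i^2 \times \prod 2p_ip_j$, collapses toward zero on any
polymorphic locus and cannot produce per-locus values on the reported
scale; MP is therefore implemented with the standard random-match
semantics $\sum(\text{genotype frequency})^2$ — algebraically identical to
$P_{(ID)theoretical}$ — and the literal product is kept behind
`mp_formula = "literal"` for auditability. Second, the exclusion
polynomial is described in different places as excluding one putative
father and as excluding two putative parents; rather than substituting a
different Jamieson–Taylor variant, the implemented polynomial's meaning is
pinned down empirically: the simulated rate at which a random non-parental
*pair* is excluded as joint parents of a true offspring (no-compatible-
allele-assignment rule) matches the polynomial within Monte Carlo error,
which is the two-parent reading.

The genotype accumulation curve resamples random locus subsets (1000
replicates by default, seeded) and reports the mean percentage of
*distinct* multilocus genotypes among individuals completely typed at the
subset; individuals missing at a subset locus are dropped from that
subset's denominator (a wildcard-matching alternative is available).
Identification frequencies are pooled across the dataset by default, with
a per-group mode, because combined panel values are conventionally quoted
for the whole survey. The sibling-identity locus curve accumulates
$P_{(ID)sibs}$ in order of decreasing (or increasing) expected
heterozygosity against the 0.01/0.001/0.0001 working thresholds.

## Ant-colony panel selection

The panel objective is encoded lexicographically: find the smallest locus
subset whose exact percent distinguished meets $100 - \text{threshold}$,
breaking size ties by higher mean PIC, then by name for determinism. The
cited applications of ant colony optimization to marker selection publish
no hyperparameters, so defaults (50 ants, 200 iterations, $\alpha = 1$,
$\beta = 2$, $\rho = 0.2$, $\tau_0 = 1$) were chosen for reliability on
panel-sized instances and are verified against exhaustive enumeration,
which is feasible up to 15 loci and is exposed as
`exhaustive_best_panel()`. Ants grow panels by pheromone-times-PIC weight
until feasible, then greedily drop redundant loci; the iteration-best
feasible panel deposits $1/\text{size} + \text{mean PIC}$. Candidate
panels are evaluated exactly (no resampling) and cached by subset, so the
search cost is bounded by the number of distinct subsets visited. An
infeasible threshold returns the full panel flagged infeasible rather
than erroring, so pipelines can report the failure.

## Mitochondrial D-loop statistics

Sites containing a gap or N in any sequence are removed before every
statistic (complete deletion, the DnaSP default); a pairwise-deletion
variant affects only pairwise-difference statistics and is not the
default. On the retained sites: haplotype diversity
$h = \frac{n}{n-1}(1 - \sum f_i^2)$ with Nei's sampling variance; mean
pairwise differences $k$; $\pi = k/L$; $\theta_S = S/(a_1 L)$.
Differentiation reports both the haplotype-frequency $G_{ST}$ and a
nucleotide-based $F_{ST} = 1 - \pi_{within}/\pi_{total}$, plus $\Phi_{ST}$
from a two-level AMOVA on pairwise difference counts. $D_{xy}$ is the mean
between-population difference per site and $D_a = D_{xy} - (\pi_X + \pi_Y)/2$
uses the plug-in (uncorrected) within-population diversities so that two
identical samples give exactly $D_a = 0$. The gene-flow proxy for a
maternally inherited haploid locus is $N_m = (1 - F_{ST})/(2F_{ST})$,
undefined at $F_{ST} \le 0$.

Neutrality tests: Tajima's D with the standard constants; Fu and Li's D*
and F* in the no-outgroup form, using the total mutation count $\eta$ and
singleton count $\eta_s$ (a site variant carried by exactly one sequence)
with the corrected small-sample coefficients; and Fu's Fs via the Ewens
sampling formula, $F_s = \ln\frac{S'}{1-S'}$ with
$S' = \Pr(K \ge k_{obs} \mid \theta = k)$, computed from the unsigned
Stirling-number recursion in log space so sample sizes in the hundreds do
not overflow. The recursion is verified against naive enumeration of the
Ewens distribution for small $n$.

The mismatch distribution compares observed pairwise-difference class
frequencies with the constant-size expectation
$F_i = \theta^i/(1+\theta)^{i+1}$ at $\theta = k$ (method of moments).
The raggedness index follows the Harpending convention with one trailing
zero class, $r = \sum_{i=1}^{d+1}(x_i - x_{i-1})^2$ with $x_{d+1} = 0$;
published conventions differ on that trailing class, so this one is locked
by fixture tests. Raggedness significance and mismatch-model p-values are
not computed — they require parametric bootstrap under an expansion model,
which is out of scope; the index is reported as a descriptive quantity.

## Synthetic data: what it emulates and what it does not

The generator's defaults are the survey shape the package is designed
around: five populations of 59/29/41/37/18 diploids, 15 loci with 5–12
alleles, ancestral frequencies from a symmetric Dirichlet with
concentration 0.5 (putting expected within-population heterozygosity near
0.69), and weak differentiation (Balding–Nichols parameter 0.01).
Inbreeding enters as a probability `f_is` of an identical-by-descent
homozygote; null alleles as a hidden allele at frequency `null_rate`
(null/visible is recorded as a visible homozygote, null/null as missing) —
the mechanism by which nulls inflate apparent homozygosity. All
randomness flows from one master seed through a documented splitting
scheme, so sub-simulations are independently reproducible. Expected
within-population heterozygosity under this law is
$(1 - F_{ST})(1 - \sum p_{anc}^2)$ per locus, which is the truth value
the recovery tests compare against (pooled-sample heterozygosity would
additionally carry a Wahlund excess).

The D-loop generator builds a star-like haplotype set (each non-backbone
haplotype carries a fixed number of private substitutions) and samples
individuals per population from explicit counts; it makes no attempt at
mutation-model realism. For neutrality-test calibration a second
generator draws segregating sites independently from the neutral site
frequency spectrum (derived-allele count $i$ with probability
$\propto 1/i$, site count Poisson with mean $\theta a_1$). Its first
moments match the constant-size neutral model, so Tajima's D centres on
zero, but between-site linkage is absent: the variance of all summary
statistics is smaller than under a shared genealogy, and haplotype-count
statistics (Fu's Fs) are strongly negative on such data. Passing tests
therefore demonstrate correctness of the estimators and their null
centring, not realistic genealogical variance — a deliberate trade that
avoids embedding a coalescent simulator.

Simulated genotypes inherit none of the artefacts of real fragment data:
no allele-calling error, no stutter, no size binning, no locus-specific
missingness structure. Conclusions about those failure modes cannot be
drawn from the test suite.

## Problem sizes and numerical choices

The test and validation suites run at deliberately chosen sizes: closed
forms at hand-checkable inputs; Monte Carlo validation of the
identification probabilities at 10^5 simulated pairs (3-standard-error
acceptance bands); ACO-versus-exhaustive comparison on twenty 8–12-locus
instances; parameter recovery at two populations of 250 diploids and 20
loci; neutrality calibration over 200 simulated alignments of 20
sequences. Frequencies are compared with tolerances no tighter than
10^-12 (closed forms) and binomial sampling error (simulations). Ties in
He-ordered locus lists break by locus name; permutation p-values use the
add-one estimator $(\text{hits}+1)/(\text{perms}+1)$ so a p of exactly
zero is never reported.

## Known limitations

Breed assignment, Bayesian clustering, ordination, migration and effective
population size estimation, null-allele-corrected F_ST, bottleneck
heterozygosity-excess tests, coalescent demography and haplogroup
assignment against reference panels are all outside this package's scope.
The M-ratio is reported without its simulation-based critical value (the
0.68 rule-of-thumb threshold is used); the paper-level raggedness test
p-values are likewise not computed.
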