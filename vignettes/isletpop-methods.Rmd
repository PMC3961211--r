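---
title: "isletpop: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{isletpop: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`isletpop` is a pipeline for SNP-array population genetics of isolate
cohorts: an island population subdivided into macro-areas, compared with a
mainland reference.  It covers quality control, population-structure
statistics, runs-of-homozygosity (RoH) calling with genomic-inbreeding
summaries, and a haplotype-based positive-selection scan.  Every stage is
exercised end to end on a synthetic-data generator with known truth, so the
whole pipeline is testable without any external download.  This vignette
records the models, the tunable parameters, the numerical choices, and what
the synthetic world does and does not establish.

## The synthetic world

`gen_balding_nichols()` draws, per SNP, an ancestral frequency
$p \sim U(\mathrm{maf\_range})$ (default $[0.05, 0.5]$), per population a
frequency

$$p_k \sim \mathrm{Beta}\!\left(\frac{p(1-F)}{F},\ \frac{(1-p)(1-F)}{F}\right),$$

with $p_k = p$ exactly when $F = 0$, and per sample a genotype with
inbreeding-adjusted probabilities
$\{(1-p_k)^2 + f p_k(1-p_k),\ 2p_k(1-p_k)(1-f),\ p_k^2 + f p_k(1-p_k)\}$.
Marker positions follow exponential spacing with mean 3 kb, matching a
post-QC array density of roughly 947k SNPs over a 2.84 Gb accessible
autosomal genome.  Defaults mirror the cohort the pipeline was designed
around: two populations ("island" and "mainland") at $F \approx 0.003$,
within-cohort inbreeding $f$ of order 0.005--0.01.

Background genotypes are site-independent: there is **no linkage
disequilibrium** except where the two planted constructions introduce it —
autozygous tracts (`plant_roh()`) and sweep founders
(`gen_sweep_haplotypes()`) — because those are exactly the signals the RoH
caller and the iHS scan detect.  A green test therefore establishes that
the algorithms recover planted signals against an LD-free background; it
does not establish behaviour under realistic background LD (e.g. the RoH
caller's false-positive rate on real data, which depends on haplotype
structure, is outside this world).

`gen_sweep_haplotypes()` draws site frequencies for the *derived* allele,
flipping the minor-allele draw to $1-q$ with probability $1/2$: derived
alleles can be major.  Without the flip, the upper standardization
frequency bins would contain only sweep-perturbed SNPs and the
standardization would cancel the planted signal — an artifact of the
generator, not of the scan.  Haplotypes carrying the derived core allele
copy one shared founder over an interval with Exponential one-sided
lengths (default mean 500 kb); non-carriers copy a distinct founder with a
much shorter mean (20 kb).  This is a planted-haplotype construction, not
a forward simulation: it gives a deterministic truth record (carriers and
copy intervals) at desk scale.

## Quality control

Filters run in a fixed order — sample call rate, chromosome allowlist,
minor allele frequency, Hardy–Weinberg — with MAF and HWE computed on the
post-sample-filter cohort.  All thresholds are strict in the documented
direction: call rate *lower than* 0.98 removes a sample, MAF *less than*
0.01 and HWE $p$ *below* $10^{-3}$ remove a SNP.  The HWE default is the
conditional exact test (summed probability of heterozygote configurations
no more probable than the observed one, given allele counts), which is
robust at small genotype counts; the 1-df chi-square is available as an
option.  The exact test is discrete and hence conservative: on null data
it removes *at most* the nominal fraction.

## Structure statistics

**PCA.** Each SNP column is centered by $2\hat p$ and scaled by
$\sqrt{2\hat p(1-\hat p)}$; missing entries contribute zero after
centering; monomorphic SNPs are excluded.  Scores are unit-norm
eigenvectors of the sample-by-sample cross-product (equivalently the SVD
of the standardized matrix), deterministic given the input.

**Group-prediction accuracy.** The first four PCs feed a multinomial
logistic model.  The environment provides no `nnet`, so the model is
glmnet's multinomial family with a negligible ridge penalty
($\lambda = 10^{-4}$).  "Iterations" are stratified bootstrap refits:
resample samples with replacement within groups, refit, and score the
most-probable class against the true label *on the full cohort*.  This
in-sample scoring inflates accuracy by overfitting when groups are small
(measurably so at 20 samples per group); at the cohort scale the package
targets (~180 per group) the inflation is within the tests' tolerance.
The procedure is this package's choice — repeated train/test splits or
probability draws would be defensible alternatives.

**λ_GC.** Per SNP the classic 1-df allelic chi-square from the 2×2
group-by-allele count table (no continuity correction), with
$\lambda = \mathrm{median}(\chi^2)/0.4549364$.  A Cochran–Armitage trend
variant is behind a flag.  SNPs monomorphic in the pooled pair are
excluded; all-zero statistics yield $\lambda = 0$ with a warning.

**Hudson Fst.** Per SNP,
$\hat N = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1}$
and $\hat D = p_1(1-p_2) + p_2(1-p_1)$ with $n$ the non-missing chromosome
count; the genome-wide estimate is $\sum \hat N / \sum \hat D$ — a ratio
of averages, never an average of ratios.  The 95% CI is a block jackknife
over contiguous blocks of 5,000 SNPs (a standard choice for genome-wide
ratio estimators; the block size is a parameter).  The permutation
p-value, when requested, is the one-sided $(1+k)/(B+1)$ with $k$ permuted
estimates at or above the observed one.

**Inbreeding-robust Fst.** Under inbreeding the two alleles within an
individual are correlated, so genotype-frequency estimators over-count
independent chromosomes.  The package first *haploidizes* — samples one
allele per individual per SNP under a seed — then applies the count-based
unbiased estimator: with $a$ derived copies among $n$ haploid chromosomes,
$h = \frac{a(n-a)}{n(n-1)}$,
$\hat N = (a_1/n_1 - a_2/n_2)^2 - h_1/n_1 - h_2/n_2$,
$\hat D = \hat N + h_1 + h_2$.  Haploidization provably removes the
within-individual correlation, which is the property the tests verify
(unbiasedness at $f = 0.3$ where the naive estimator's bias is
$\approx f/2N$).

One boundary case is worth recording: on two groups that are *copies* of
the same samples, the corrected estimator's expectation is not 0 but
$-\tfrac{1}{2(n-1)}$.  With $\Sigma v = n_\mathrm{het}/4$ the true
between-copy variance and $E[h]$ estimating the larger binomial variance
$\bar p \bar q$, $E[\hat N] = 2(\Sigma v - n\bar p\bar q)/(n(n-1)) =
-\bar p\bar q/(n-1)$ under HWE, giving $\hat N/\hat D \to -1/(2(n-1))$.
Copies violate the estimator's independent-sampling model; the artifact is
$O(1/n)$ and negligible at cohort scale.  The unit tests assert this
closed form rather than a vague "near zero".

**Per-sample inbreeding.** $\hat F = (O_\mathrm{hom} -
E_\mathrm{hom})/(L - E_\mathrm{hom})$ with $E_\mathrm{hom} = \sum_j [1 -
2\hat p_j(1-\hat p_j)\cdot\frac{2n_j}{2n_j-1}]$ over the sample's $L$
non-missing SNPs — the standard observed-versus-expected homozygosity
statistic with the small-sample correction on $\hat p$.

**Group comparisons** use the two-sided Welch (unequal-variance) t-test
against a chosen reference group; a group compared with itself reports
$t = 0, p = 1$ by definition, and single-sample groups are excluded with a
warning.

## RoH calling

The caller mirrors the classic PLINK `--homozyg` design.  The published
parameter phrase "a sliding window of 5000 kb, with a minimum of 50 SNPs"
is read as the PLINK pair — a window of **50 SNPs** whose physical span
may not exceed **5000 kb** — since a purely physical window with a SNP
minimum is not what that implementation computes; both numbers are
parameters (`window_snps`, `window_span_kb_cap`).  A window is homozygous
iff it contains at most 1 heterozygous and at most 5 missing calls.  Each
SNP's hit proportion is the fraction of enumerated (span-admissible)
windows containing it that are homozygous; SNPs strictly above 0.05 form
maximal runs; runs are kept at ≥ 500 kb and ≥ 50 SNPs.  The final-segment
SNP minimum is not stated separately from the window minimum in the source
description, so the two defaults deliberately coincide.  Segment length is
`pos_last − pos_first` with no half-SNP padding.  Missing calls inside a
kept segment are counted but do not break runs.  A SNP covered by no
admissible window has hit proportion 0.

Segments are classified into six half-open length classes
[0.5,1), [1,2), [2,4), [4,8), [8,16), [16,∞) Mb — a 2.0 Mb segment belongs
to "2–4 Mb" — and `froh()` reports
$F_\mathrm{RoH}\% = 100 \times \sum \mathrm{length} / 2.84\times10^9$ at
the 0.5 and 5 Mb thresholds, with the accessible-genome denominator a
parameter.

The caller is verified against an exhaustive oracle that materializes
every window explicitly, on random 5,000-SNP instances; planted tracts
≥ 0.5 Mb are recovered at base-pair Jaccard ≥ 0.95 (boundary smear of a
few SNPs is inherent to window voting), and sub-threshold tracts are never
reported.

## Selection scan

EHH at marker $x$ for a core allele is
$\sum_g \binom{e_g}{2} / \binom{c}{2}$ over groups of carrier haplotypes
identical from the core through $x$; it is 1 at the core and
non-increasing outward.  iHH is the trapezoid integral of
$(EHH - 0.05)_+$ against physical position, truncated where EHH falls
below the cutoff (the final clamped trapezoid is included), at
inter-marker gaps above 200 kb, or at the chromosome end.  Distances are
physical: the intended input is array data without a genetic map.  Raw
scores are $\ln(\mathrm{iHH}_A/\mathrm{iHH}_D)$ — negative marks long
derived haplotypes — standardized within derived-allele-frequency bins of
width 0.025, merging bins with fewer than 20 scored SNPs into their
neighbour.  SNPs with derived frequency outside [0.05, 0.95] or a zero iHH
are dropped with logged counts.  The inner walk is compiled (Rcpp), as in
the field's reference implementations; the test suite checks it against an
R-level pairwise-identity brute force to 12 digits.

`region_scan()` tiles each chromosome into non-overlapping 100 kb windows,
counts SNPs with $|iHS| > 4$, computes a nominal upper binomial tail
against the genome-wide extreme fraction, and corrects family-wise by
permutation: scores are shuffled across SNP positions, each permutation
contributes its minimum p over enrichment-eligible windows, and a
window's empirical p is the fraction of permutation minima at or below
its nominal p.  A window is enrichment-eligible only with at least
`min_extreme` (default 2) extreme SNPs — one extreme SNP alone is never
enrichment — applied identically to observed and permuted scans; without
this rule the min-p comparison is exactly calibrated at the nominal
level and the null family-wise rate hovers *at* 0.05 rather than safely
below it.  Adjacent
significant windows merge; a merged region's nominal p is recomputed from
its pooled counts and its empirical p is the minimum over member windows.
The fixed-tile-then-merge design, the window size, and the binomial-tail
nominal p are this package's choices — the source analysis reports
variable-size regions without describing its construction, and no numeric
equality with any published nominal p-value is claimed.

On the planted sweep the detection criterion is that the core SNP falls
inside a reported region (≥ 90% of seeds at default parameters).  The
core need not be the single most extreme SNP genome-wide: inside the
planted founder envelope many SNPs legitimately carry stronger
standardized scores, so the core-rank test compares the core against the
genome *background* (SNPs outside the truth-record envelope) at the 99th
percentile.

## Scaling choices in the test suite

The acceptance tests run inside a CI time budget, so three criteria use
reduced but stated sizes: sweep detection runs 100 seeds at 10,000 SNPs ×
100 haplotypes with 1,000 permutations; the null family-wise check runs
200 genomes of 20,000 SNPs at 1,000 permutations; the in-suite λ_GC check
runs at 20,000 SNPs × 300 samples, while `scripts/acceptance.R` runs the
full 100,000-SNP version.  All other criteria run at their stated scales.

## Known limitations

* No background LD in the generator: false-positive behaviour of the RoH
  caller and iHS scan under realistic haplotype structure is untested.
* The pipeline consumes already-phased haplotypes; phasing error is
  outside its model.
* Ancestry deconvolution (ADMIXTURE-style) and cross-population
  haplotype statistics (XP-EHH) are out of scope.
* PLINK binary (.bed/.bim/.fam) input is not parsed; text .ped/.map only.
* Coordinates are build-agnostic; no liftover.
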