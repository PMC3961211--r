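# isletpop

Population-genetic analysis of isolate cohorts from SNP-array data:
quality control, population-structure statistics, runs-of-homozygosity
(RoH) calling with genomic-inbreeding summaries, and a haplotype-based
positive-selection scan — with a synthetic-data generator so the whole
pipeline is testable end to end, offline, against known truth.

It is aimed at population geneticists studying isolated populations
(islands, linguistic enclaves, founder communities) who need the classic
isolate toolkit in one tested package:

* **QC**: sample call-rate (< 0.98 removed), MAF (< 0.01 removed),
  Hardy–Weinberg (exact test, p < 1e-3 removed), autosome restriction.
* **Structure**: PCA on standardized genotypes; multinomial prediction of
  group labels from leading PCs; pairwise genomic-control inflation
  factor λ_GC = median(χ²)/0.4549; Hudson Fst as a genome-wide ratio of
  averages, Σ N̂ / Σ D̂ with
  N̂ = (p₁−p₂)² − p₁(1−p₁)/(n₁−1) − p₂(1−p₂)/(n₂−1) and
  D̂ = p₁(1−p₂) + p₂(1−p₁), block-jackknife CIs and permutation p;
  an inbreeding-robust Fst (haploidize each individual, then the
  count-based unbiased estimator); per-sample inbreeding coefficients
  F̂ = (O_hom − E_hom)/(L − E_hom).
* **RoH**: PLINK-style sliding windows (50 SNPs, 5000 kb span cap, ≤ 1
  heterozygous and ≤ 5 missing calls per window, hit proportion > 0.05),
  segments ≥ 500 kb and ≥ 50 SNPs; six length classes (0.5–1, 1–2, 2–4,
  4–8, 8–16, > 16 Mb); F_RoH% = 100 × Σ length / 2.84 Gb at the 0.5 and
  5 Mb thresholds; Welch t-tests between groups.
* **Selection**: EHH for ancestral and derived alleles, iHH by trapezoid
  integration (cutoff 0.05, gap cap 200 kb), iHS =
  standardized ln(iHH_A/iHH_D) within derived-frequency bins, and a
  window scan for enrichment of |iHS| > 4 with permutation-based
  family-wise empirical p-values.
* **Simulation**: Balding–Nichols genotypes with per-sample inbreeding,
  planted autozygous tracts, planted-sweep phased haplotypes — all pure
  functions of (config, seed) with truth records.

## Worked example

Two simulated populations ("island" vs "mainland" differentiation,
F = 0.003, f = 0.01; 2 × 80 samples × 20,000 SNPs), QC, structure, and a
planted 3 Mb autozygous tract:

```r
library(isletpop)
sim <- gen_balding_nichols(sim_config(seed = 1, n_pops = 2,
                                      samples_per_pop = 80,
                                      n_snps = 20000, fst = 0.003,
                                      inbreeding_f = 0.01))
qc <- qc_pipeline(sim$geno)
qc$report
#> QC report:
#>   samples removed (call rate): 0
#>   SNPs removed (chromosome):   0
#>   SNPs removed (MAF):          0
#>   SNPs removed (HWE):          21

labels <- sim$info$group
fst_test(qc$geno, labels, c("pop1", "pop2"), n_perm = 199, seed = 2,
         block_snps = 2000)
#> Fst (hudson): 0.0031503  [95% CI 0.00296568, 0.00333492]  p = 0.005
```

The Hudson estimate recovers the simulated F = 0.003 (CI covers the
truth; p = 0.005 is the smallest value 199 permutations can report —
no permuted estimate reached the observed one).  λ_GC between the two
populations is 1.49, flagging the (real) stratification; between random
halves of one population it sits near 1 (that null is acceptance target
t1).

```r
tr <- tract_spec("s0001", "1", 10e6, 13e6, het_error_rate = 0.001)
segs <- call_roh(plant_roh(qc$geno, tr, seed = 3))
segs[segs$sample_id == "s0001", ]
#>   sample_id chrom start_bp   end_bp length_bp n_snps n_het n_missing
#> 1     s0001     1  9988280 12999118   3010838   1025     0         0
```

The planted 10–13 Mb tract is recovered to within a few SNPs of its true
bounds (class "2–4 Mb"; F_RoH% contribution 0.106 of the 2.84 Gb
accessible genome).

A complete synthetic study — QC, structure tables, RoH BED + summaries, a
planted-sweep iHS scan with its region table, and a text report — is one
command:

```r
run_demo(seed = 1, "demo_out")
```

or from the shell: `exec/isletpop demo --seed 1 --out demo_out`.

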