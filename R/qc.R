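# Quality control: sample call rate, autosome allowlist, MAF, and
# Hardy-Weinberg filters, applied in the fixed order
# samples -> chromosomes -> MAF -> HWE.  All thresholds are strict in the
# same direction as their defaults: "lower than 98%", "less than 0.01",
# "p < 1e-3".

#' Exact Hardy-Weinberg test p-value
#'
#' Conditional exact test on genotype counts: the p-value is the summed
#' probability of all heterozygote configurations (given allele counts) no
#' more probable than the observed one.
#'
#' @param n_aa,n_ab,n_bb genotype counts.
#' @return two-sided exact p-value in `(0, 1]`.
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(NA_real_)
  n_a <- 2L * n_aa + n_ab
  rare <- min(n_a, 2L * n - n_a)
  if (rare == 0L) return(1)
  hets <- seq(rare %% 2L, rare, by = 2L)
  lp <- vapply(hets, function(h) {
    aa <- (n_a - h) %/% 2L
    bb <- (2L * n - n_a - h) %/% 2L
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
      h * log(2) + lgamma(n_a + 1) + lgamma(2 * n - n_a + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- match(n_ab, hets)
  if (is.na(obs)) stop("inconsistent genotype counts")
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
}

#' Chi-square Hardy-Weinberg test p-value
#'
#' 1-df Pearson chi-square on genotype counts against `p^2, 2pq, q^2`
#' expectations, no continuity correction.
#'
#' @inheritParams hwe_exact_p
#' @return p-value.
#' @export
hwe_chisq_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(NA_real_)
  p <- (2 * n_aa + n_ab) / (2 * n)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  if (any(e == 0)) return(1)
  x2 <- sum((c(n_aa, n_ab, n_bb) - e)^2 / e)
  pchisq(x2, df = 1, lower.tail = FALSE)
}

qc_report <- function(n_samples_removed = 0L, n_snps_removed_maf = 0L,
                      n_snps_removed_hwe = 0L, n_snps_removed_chrom = 0L,
                      thresholds = list()) {
  structure(list(n_samples_removed = n_samples_removed,
                 n_snps_removed_maf = n_snps_removed_maf,
                 n_snps_removed_hwe = n_snps_removed_hwe,
                 n_snps_removed_chrom = n_snps_removed_chrom,
                 thresholds = thresholds),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:\n",
      "  samples removed (call rate): ", x$n_samples_removed, "\n",
      "  SNPs removed (chromosome):   ", x$n_snps_removed_chrom, "\n",
      "  SNPs removed (MAF):          ", x$n_snps_removed_maf, "\n",
      "  SNPs removed (HWE):          ", x$n_snps_removed_hwe, "\n", sep = "")
  invisible(x)
}

#' Remove samples with low call rate
#'
#' @param geno a [genotype_matrix()].
#' @param min_rate minimum non-missing fraction; samples strictly below it
#'   are removed (default 0.98).
#' @return list with `geno` and `report` (a `qc_report`).
#' @export
filter_sample_call_rate <- function(geno, min_rate = 0.98) {
  stopifnot(min_rate > 0, min_rate <= 1)
  rate <- rowMeans(!is.na(geno$calls))
  keep <- rate >= min_rate
  if (!any(keep)) stop("call-rate filter removed every sample")
  list(geno = subset_genotypes(geno, samples = keep),
       report = qc_report(n_samples_removed = sum(!keep),
                          thresholds = list(min_call_rate = min_rate)))
}

#' Keep only an allowlist of chromosomes
#'
#' Default allowlist is the numeric chromosome labels present (autosome
#' restriction: sex chromosomes and other non-numeric labels are dropped).
#'
#' @param geno a [genotype_matrix()].
#' @param allowed chromosome labels to keep; `NULL` keeps numeric labels.
#' @return list with `geno` and `report`.
#' @export
filter_chromosomes <- function(geno, allowed = NULL) {
  ch <- geno$variants$chrom
  if (is.null(allowed)) {
    allowed <- unique(ch[grepl("^[0-9]+$", sub("^chr", "", ch))])
  }
  keep <- ch %in% allowed
  list(geno = subset_genotypes(geno, variants = keep),
       report = qc_report(n_snps_removed_chrom = sum(!keep),
                          thresholds = list(chromosomes = allowed)))
}

#' Remove SNPs with low minor allele frequency
#'
#' @param geno a [genotype_matrix()].
#' @param min_maf SNPs with MAF strictly below this (computed on
#'   non-missing calls) are removed (default 0.01).
#' @return list with `geno` and `report`.
#' @export
filter_maf <- function(geno, min_maf = 0.01) {
  fr <- allele_freq_table(geno)
  maf <- pmin(fr$p, 1 - fr$p)
  keep <- !is.na(maf) & maf >= min_maf
  list(geno = subset_genotypes(geno, variants = keep),
       report = qc_report(n_snps_removed_maf = sum(!keep),
                          thresholds = list(min_maf = min_maf)))
}

#' Remove SNPs failing the Hardy-Weinberg test
#'
#' @param geno a [genotype_matrix()].
#' @param alpha SNPs with HWE p strictly below `alpha` are removed
#'   (default 1e-3).
#' @param method `"exact"` (default) or `"chisq"`.
#' @return list with `geno` and `report`; SNPs with zero observed
#'   genotypes are retained untested (counted in the report thresholds as
#'   `n_untested`).
#' @export
filter_hwe <- function(geno, alpha = 1e-3, method = c("exact", "chisq")) {
  method <- match.arg(method)
  fr <- allele_freq_table(geno)
  pfun <- if (method == "exact") hwe_exact_p else hwe_chisq_p
  pv <- mapply(pfun, fr$n_AA, fr$n_AB, fr$n_BB)
  keep <- is.na(pv) | pv >= alpha
  list(geno = subset_genotypes(geno, variants = keep),
       report = qc_report(n_snps_removed_hwe = sum(!keep),
                          thresholds = list(hwe_alpha = alpha,
                                            hwe_method = method,
                                            n_untested = sum(is.na(pv)))))
}

#' Run the full QC chain
#'
#' Fixed order: sample call rate, chromosome allowlist, MAF, HWE; MAF and
#' HWE are computed on the post-sample-filter cohort.
#'
#' @param geno a [genotype_matrix()].
#' @param min_call_rate,min_maf,hwe_alpha,hwe_method,chromosomes filter
#'   parameters (see the individual filters).
#' @return list with `geno` and a combined `report`.
#' @export
qc_pipeline <- function(geno, min_call_rate = 0.98, min_maf = 0.01,
                        hwe_alpha = 1e-3, hwe_method = "exact",
                        chromosomes = NULL) {
  s1 <- filter_sample_call_rate(geno, min_call_rate)
  s2 <- filter_chromosomes(s1$geno, chromosomes)
  s3 <- filter_maf(s2$geno, min_maf)
  s4 <- filter_hwe(s3$geno, hwe_alpha, hwe_method)
  rep <- qc_report(
    n_samples_removed = s1$report$n_samples_removed,
    n_snps_removed_chrom = s2$report$n_snps_removed_chrom,
    n_snps_removed_maf = s3$report$n_snps_removed_maf,
    n_snps_removed_hwe = s4$report$n_snps_removed_hwe,
    thresholds = c(s1$report$thresholds, s2$report$thresholds,
                   s3$report$thresholds, s4$report$thresholds)
  )
  list(geno = s4$geno, report = rep)
}
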