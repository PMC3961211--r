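# Fst estimation: the Hudson estimator on allele frequencies (ratio of
# averages, never average of ratios) and an inbreeding-robust variant that
# first haploidizes each individual to break the within-individual allele
# correlation that inbreeding induces, then applies the count-based
# unbiased estimator.

fst_result <- function(estimate, num_sum, den_sum, ci, p_value, name) {
  structure(list(estimate = estimate, numerator_sum = num_sum,
                 denominator_sum = den_sum, ci_low = ci[1L], ci_high = ci[2L],
                 p_value = p_value, estimator_name = name),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Fst (%s): %.6g  [95%% CI %.6g, %.6g]  p = %s\n",
              x$estimator_name, x$estimate, x$ci_low, x$ci_high,
              if (is.na(x$p_value)) "NA" else format(x$p_value)))
  invisible(x)
}

# genome-wide ratio of sums with a block jackknife over contiguous blocks
ratio_with_jackknife <- function(num, den, block_snps) {
  keep <- !is.na(num) & !is.na(den)
  num <- num[keep]; den <- den[keep]
  ns <- sum(num); ds <- sum(den)
  if (ds == 0) stop("degenerate input: denominator sum is zero")
  est <- ns / ds
  m <- length(num)
  blk <- ceiling(seq_len(m) / block_snps)
  nb <- max(blk)
  if (nb < 2L) return(list(estimate = est, num_sum = ns, den_sum = ds,
                           ci = c(NA_real_, NA_real_)))
  bn <- tapply(num, blk, sum)
  bd <- tapply(den, blk, sum)
  loo <- (ns - bn) / (ds - bd)
  se <- sqrt((nb - 1) / nb * sum((loo - mean(loo))^2))
  list(estimate = est, num_sum = ns, den_sum = ds,
       ci = est + c(-1, 1) * qnorm(0.975) * se)
}

hudson_components <- function(p1, p2, n1, n2) {
  ok <- !is.na(p1) & !is.na(p2) & n1 >= 2 & n2 >= 2
  num <- den <- rep(NA_real_, length(p1))
  num[ok] <- (p1[ok] - p2[ok])^2 -
    p1[ok] * (1 - p1[ok]) / (n1[ok] - 1) -
    p2[ok] * (1 - p2[ok]) / (n2[ok] - 1)
  den[ok] <- p1[ok] * (1 - p2[ok]) + p2[ok] * (1 - p1[ok])
  n_skipped <- sum(!ok)
  if (n_skipped > 0L) {
    message(n_skipped, " SNP(s) skipped (undersized or missing frequencies)")
  }
  list(num = num, den = den)
}

#' Hudson Fst from two allele-frequency tables
#'
#' Per SNP, numerator `(p1 - p2)^2 - p1 (1 - p1) / (n1 - 1) -
#' p2 (1 - p2) / (n2 - 1)` and denominator
#' `p1 (1 - p2) + p2 (1 - p1)`, with `n` the non-missing chromosome count;
#' the genome-wide estimate is the ratio of sums.  The 95% CI comes from a
#' block jackknife over contiguous SNP blocks.
#'
#' @param freq1,freq2 rows of [allele_freq_table()] for the two groups, in
#'   the same variant order.
#' @param block_snps jackknife block size (default 5000 consecutive SNPs).
#' @return an `fst_result` (p-value `NA`; see [fst_test()] for a
#'   permutation p-value).
#' @export
fst_hudson <- function(freq1, freq2, block_snps = 5000L) {
  stopifnot(nrow(freq1) == nrow(freq2))
  cmp <- hudson_components(freq1$p, freq2$p, freq1$n_chrom, freq2$n_chrom)
  r <- ratio_with_jackknife(cmp$num, cmp$den, block_snps)
  fst_result(r$estimate, r$num_sum, r$den_sum, r$ci, NA_real_, "hudson")
}

haploidize <- function(calls) {
  h <- matrix(NA_integer_, nrow = nrow(calls), ncol = ncol(calls))
  nm <- !is.na(calls)
  g <- calls[nm]
  a <- integer(length(g))
  a[g == 2L] <- 1L
  het <- g == 1L
  a[het] <- rbinom(sum(het), 1L, 0.5)
  h[nm] <- a
  h
}

reich_components <- function(a1, n1, a2, n2) {
  ok <- n1 >= 2 & n2 >= 2
  h1 <- a1 * (n1 - a1) / (n1 * (n1 - 1))
  h2 <- a2 * (n2 - a2) / (n2 * (n2 - 1))
  num <- den <- rep(NA_real_, length(a1))
  num[ok] <- (a1[ok] / n1[ok] - a2[ok] / n2[ok])^2 -
    h1[ok] / n1[ok] - h2[ok] / n2[ok]
  den[ok] <- num[ok] + h1[ok] + h2[ok]
  list(num = num, den = den)
}

#' Inbreeding-robust Fst between two groups
#'
#' Each individual is haploidized (one allele sampled per individual per
#' SNP under `seed`), removing the within-individual allele correlation
#' that inbreeding induces; the count-based unbiased estimator is then
#' applied to the haploid counts: with `a` derived copies among `n`
#' haploid chromosomes, `h = a (n - a) / (n (n - 1))`,
#' `N = (a1/n1 - a2/n2)^2 - h1/n1 - h2/n2`, `D = N + h1 + h2`, and the
#' genome-wide estimate is `sum(N) / sum(D)`.
#'
#' @param geno a [genotype_matrix()].
#' @param labels group label per sample (in `geno` sample order).
#' @param pair length-2 character: the two groups to compare.
#' @param seed RNG seed for haploidization.
#' @param block_snps jackknife block size.
#' @return an `fst_result` with `estimator_name = "inbreeding_corrected"`.
#' @export
fst_inbreeding_corrected <- function(geno, labels, pair, seed = 1L,
                                     block_snps = 5000L) {
  stopifnot(length(pair) == 2L)
  set.seed(seed)
  hap <- haploidize(geno$calls)
  i1 <- labels == pair[1L]; i2 <- labels == pair[2L]
  if (!any(i1) || !any(i2)) stop("empty group in pair")
  a1 <- colSums(hap[i1, , drop = FALSE], na.rm = TRUE)
  n1 <- colSums(!is.na(hap[i1, , drop = FALSE]))
  a2 <- colSums(hap[i2, , drop = FALSE], na.rm = TRUE)
  n2 <- colSums(!is.na(hap[i2, , drop = FALSE]))
  cmp <- reich_components(a1, n1, a2, n2)
  r <- ratio_with_jackknife(cmp$num, cmp$den, block_snps)
  fst_result(r$estimate, r$num_sum, r$den_sum, r$ci, NA_real_,
             "inbreeding_corrected")
}

#' Fst between two groups with a permutation p-value
#'
#' Convenience wrapper computing the chosen estimator from genotypes plus a
#' one-sided label-permutation p-value (`(1 + k) / (n_perm + 1)` with `k`
#' permuted estimates at least the observed one; with `k = 0` this is the
#' conventional "< 1/n_perm" bound).
#'
#' @inheritParams fst_inbreeding_corrected
#' @param estimator `"hudson"` or `"inbreeding_corrected"`.
#' @param n_perm number of label permutations (0 = no p-value).
#' @return an `fst_result`.
#' @export
fst_test <- function(geno, labels, pair, estimator = c("hudson",
                                                       "inbreeding_corrected"),
                     n_perm = 0L, seed = 1L, block_snps = 5000L) {
  estimator <- match.arg(estimator)
  sel <- labels %in% pair
  sub <- subset_genotypes(geno, samples = sel)
  lab <- labels[sel]
  one <- function(lab2, sd2) {
    if (estimator == "hudson") {
      fr <- allele_freq_table(sub, lab2)
      f1 <- fr[fr$group == pair[1L], ]
      f2 <- fr[fr$group == pair[2L], ]
      suppressMessages(fst_hudson(f1, f2, block_snps))
    } else {
      fst_inbreeding_corrected(sub, lab2, pair, seed = sd2, block_snps)
    }
  }
  obs <- one(lab, seed)
  p <- NA_real_
  if (n_perm > 0L) {
    set.seed(seed)
    k <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample(lab)
      if (one(perm, seed + b)$estimate >= obs$estimate) k <- k + 1L
    }
    p <- (1 + k) / (n_perm + 1)
  }
  obs$p_value <- p
  obs
}
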