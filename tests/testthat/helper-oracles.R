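# Independent brute-force oracles.  These deliberately avoid the package's
# own code paths: direct formulas, explicit window materialization, and
# pairwise haplotype comparison.

# exact HWE p by direct enumeration: P(n_ab | n, n_a) computed from the
# closed-form log-probability for every admissible heterozygote count
oracle_hwe_exact <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  hets <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  logp <- sapply(hets, function(h) {
    aa <- (n_a - h) / 2
    bb <- n - h - aa
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) + lfactorial(n_a) + lfactorial(2 * n - n_a) -
      lfactorial(2 * n)
  })
  pr <- exp(logp)
  p_obs <- pr[match(n_ab, hets)]
  sum(pr[pr <= p_obs * (1 + 1e-12)]) / sum(pr)
}

# exhaustive RoH caller: materializes every window explicitly
oracle_call_roh <- function(pos, g, params) {
  m <- length(pos)
  w <- params$window_snps
  if (m < w) return(NULL)
  starts <- 1:(m - w + 1)
  het <- !is.na(g) & g == 1
  mis <- is.na(g)
  valid <- homo <- logical(length(starts))
  for (j in starts) {
    idx <- j:(j + w - 1)
    valid[j] <- (pos[j + w - 1] - pos[j]) <= params$window_span_kb_cap * 1000
    homo[j] <- valid[j] &&
      sum(het[idx]) <= params$max_het_per_window &&
      sum(mis[idx]) <= params$max_missing_per_window
  }
  in_run <- logical(m)
  for (i in 1:m) {
    cover <- starts[starts <= i & starts + w - 1 >= i]
    cover <- cover[valid[cover]]
    prop <- if (length(cover) == 0) 0 else mean(homo[cover])
    in_run[i] <- prop > params$hit_proportion_threshold
  }
  segs <- NULL
  i <- 1
  while (i <= m) {
    if (in_run[i]) {
      j <- i
      while (j < m && in_run[j + 1]) j <- j + 1
      len <- pos[j] - pos[i]
      if (len >= params$min_segment_kb * 1000 &&
          (j - i + 1) >= params$min_segment_snps) {
        segs <- rbind(segs, data.frame(
          start_bp = pos[i], end_bp = pos[j], length_bp = len,
          n_snps = j - i + 1, n_het = sum(het[i:j]),
          n_missing = sum(mis[i:j])))
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  segs
}

# EHH by direct pairwise haplotype comparison over [core..x]
oracle_ehh <- function(haps, pos, core, allele_bit, x) {
  rows <- which(haps[, core] == allele_bit)
  c_n <- length(rows)
  rng <- min(core, x):max(core, x)
  same <- 0
  for (i in 1:(c_n - 1)) for (j in (i + 1):c_n) {
    if (all(haps[rows[i], rng] == haps[rows[j], rng])) same <- same + 1
  }
  same / choose(c_n, 2)
}

# iid-site neutral haplotypes (ancestral-coded), exponential marker spacing
neutral_haps <- function(n_hap, m, seed, spacing = 3000,
                         freq_range = c(0.05, 0.95)) {
  set.seed(seed)
  pos <- cumsum(pmax(1, round(rexp(m, 1 / spacing))))
  q <- runif(m, freq_range[1], freq_range[2])
  h <- matrix(rbinom(n_hap * m, 1, rep(q, each = n_hap)), nrow = n_hap)
  v <- variant_table(rep("1", m), pos, sprintf("snp%05d", 1:m),
                     rep("A", m), rep("G", m), rep("A", m))
  haplotype_matrix(h, sprintf("s%03d", 1:(n_hap / 2)), v)
}

# base-pair Jaccard between a called segment set and one truth interval
jaccard_bp <- function(segs, lo, hi) {
  if (is.null(segs) || nrow(segs) == 0) return(0)
  inter <- sum(pmax(0, pmin(segs$end_bp, hi) - pmax(segs$start_bp, lo)))
  union <- (hi - lo) + sum(segs$end_bp - segs$start_bp) - inter
  inter / union
}

# tiny genotype fixture: explicit calls matrix on one chromosome
tiny_geno <- function(calls, pos = NULL, chrom = "1") {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  v <- variant_table(rep(chrom, m), pos, sprintf("m%03d", seq_len(m)),
                     rep("A", m), rep("G", m))
  genotype_matrix(calls, sprintf("s%02d", seq_len(nrow(calls))), v)
}
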