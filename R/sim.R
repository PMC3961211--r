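# Synthetic-data generators.
#
# The stated world: a Balding-Nichols genotype generator with per-sample
# inbreeding, planted autozygous tracts, and planted-sweep phased
# haplotypes.  Background genotypes are site-independent (no LD); linkage
# enters only through planted tracts and sweep founders, which are exactly
# the signals the downstream callers detect.  Marker positions follow
# exponential spacing with mean 3 kb, matching a post-QC array density of
# roughly 947k SNPs over a 2.84 Gb accessible genome.

#' Simulation configuration
#'
#' @param seed RNG seed; every generator is a pure function of
#'   `(cfg, seed)`.
#' @param n_pops number of populations.
#' @param samples_per_pop diploid samples per population.
#' @param n_snps number of markers.
#' @param fst Balding-Nichols differentiation parameter F in `[0, 1)`.
#' @param inbreeding_f per-sample inbreeding coefficient f in `[0, 1)`.
#' @param maf_range interval from which ancestral allele frequencies are
#'   drawn uniformly.
#' @param snp_spacing_bp mean inter-marker distance (exponential spacing).
#' @param chrom chromosome label for the simulated markers.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_pops = 2L, samples_per_pop = 100L,
                       n_snps = 10000L, fst = 0.003, inbreeding_f = 0,
                       maf_range = c(0.05, 0.5), snp_spacing_bp = 3000,
                       chrom = "1") {
  stopifnot(fst >= 0, fst < 1, inbreeding_f >= 0, inbreeding_f < 1,
            length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] < 1,
            maf_range[1] <= maf_range[2], snp_spacing_bp > 0,
            n_pops >= 1L, samples_per_pop >= 1L, n_snps >= 1L)
  structure(list(seed = as.integer(seed), n_pops = as.integer(n_pops),
                 samples_per_pop = as.integer(samples_per_pop),
                 n_snps = as.integer(n_snps), fst = fst,
                 inbreeding_f = inbreeding_f, maf_range = maf_range,
                 snp_spacing_bp = snp_spacing_bp, chrom = as.character(chrom)),
            class = "sim_config")
}

sim_positions <- function(n_snps, spacing_bp) {
  cumsum(pmax(1L, round(rexp(n_snps, 1 / spacing_bp))))
}

sim_variants <- function(cfg, ancestral = NA_character_) {
  pos <- sim_positions(cfg$n_snps, cfg$snp_spacing_bp)
  variant_table(rep(cfg$chrom, cfg$n_snps), pos,
                sprintf("snp%06d", seq_len(cfg$n_snps)),
                rep("A", cfg$n_snps), rep("G", cfg$n_snps), ancestral)
}

#' Simulate genotypes under the Balding-Nichols model
#'
#' Per SNP an ancestral frequency `p ~ Uniform(maf_range)`; per population
#' `p_k ~ Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` (exactly `p` when
#' `F = 0`); per sample a genotype with inbreeding-adjusted probabilities
#' `{(1 - p_k)^2 + f p_k (1 - p_k), 2 p_k (1 - p_k)(1 - f),
#' p_k^2 + f p_k (1 - p_k)}` for 0/1/2 copies of the counted allele.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `geno` ([genotype_matrix()]), `info`
#'   ([sample_info()] with groups `pop1..popK`), and `truth` (list holding
#'   `F`, `f`, the ancestral frequencies `p_anc` and the per-population
#'   frequency matrix `p_pop`).
#' @export
gen_balding_nichols <- function(cfg) {
  set.seed(cfg$seed)
  variants <- sim_variants(cfg)
  m <- cfg$n_snps
  p_anc <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  p_pop <- matrix(NA_real_, nrow = m, ncol = cfg$n_pops)
  for (k in seq_len(cfg$n_pops)) {
    p_pop[, k] <- if (cfg$fst == 0) p_anc else
      rbeta(m, p_anc * (1 - cfg$fst) / cfg$fst,
            (1 - p_anc) * (1 - cfg$fst) / cfg$fst)
  }
  n <- cfg$n_pops * cfg$samples_per_pop
  f <- cfg$inbreeding_f
  calls <- matrix(NA_integer_, nrow = n, ncol = m)
  chunk <- max(1L, as.integer(5e6 / n))
  for (k in seq_len(cfg$n_pops)) {
    rows <- (k - 1L) * cfg$samples_per_pop + seq_len(cfg$samples_per_pop)
    for (j0 in seq(1L, m, by = chunk)) {
      jj <- j0:min(m, j0 + chunk - 1L)
      pk <- p_pop[jj, k]
      p0 <- rep((1 - pk)^2 + f * pk * (1 - pk), each = length(rows))
      p1 <- rep(2 * pk * (1 - pk) * (1 - f), each = length(rows))
      u <- runif(length(rows) * length(jj))
      calls[rows, jj] <- (u > p0) + (u > p0 + p1)
    }
  }
  samples <- sprintf("s%04d", seq_len(n))
  info <- sample_info(samples,
                      rep(paste0("pop", seq_len(cfg$n_pops)),
                          each = cfg$samples_per_pop))
  list(geno = genotype_matrix(calls, samples, variants), info = info,
       truth = list(seed = cfg$seed, F = cfg$fst, f = f,
                    p_anc = p_anc, p_pop = p_pop))
}

#' Specify autozygous tracts to plant
#'
#' @param sample_id sample carrying the tract.
#' @param chrom chromosome label.
#' @param start_bp,end_bp tract bounds (1-based, `end_bp > start_bp`).
#' @param het_error_rate probability that a tract SNP is rendered
#'   heterozygous (genotyping error inside a true autozygous run).
#' @return data.frame of class `tract_spec`.
#' @export
tract_spec <- function(sample_id, chrom, start_bp, end_bp,
                       het_error_rate = 0) {
  d <- data.frame(sample_id = as.character(sample_id),
                  chrom = as.character(chrom),
                  start_bp = as.numeric(start_bp), end_bp = as.numeric(end_bp),
                  het_error_rate = rep(as.numeric(het_error_rate),
                                       length.out = length(sample_id)),
                  stringsAsFactors = FALSE)
  if (any(d$end_bp <= d$start_bp)) stop("tract end_bp must exceed start_bp")
  sp <- split(d, paste(d$sample_id, d$chrom))
  for (g in sp) {
    if (nrow(g) > 1L) {
      o <- order(g$start_bp)
      if (any(g$start_bp[o][-1L] <= g$end_bp[o][-nrow(g)])) {
        stop("tracts for sample ", g$sample_id[1L], " overlap")
      }
    }
  }
  class(d) <- c("tract_spec", "data.frame")
  d
}

#' Plant autozygous tracts into a genotype matrix
#'
#' Within each tract every non-missing call is made homozygous
#' (heterozygotes resolved to one allele at random), then re-flipped to
#' heterozygous independently at the tract's `het_error_rate`.  Genotypes
#' outside tracts are untouched.
#'
#' @param geno a [genotype_matrix()].
#' @param tracts a [tract_spec()] (possibly empty).
#' @param seed RNG seed.
#' @return the modified [genotype_matrix()].
#' @export
plant_roh <- function(geno, tracts, seed = 1L) {
  if (nrow(tracts) == 0L) return(geno)
  set.seed(seed)
  v <- geno$variants
  calls <- geno$calls
  for (t in seq_len(nrow(tracts))) {
    s <- match(tracts$sample_id[t], geno$samples)
    if (is.na(s)) stop("unknown sample in tract spec: ", tracts$sample_id[t])
    idx <- which(v$chrom == tracts$chrom[t] & v$pos >= tracts$start_bp[t] &
                   v$pos <= tracts$end_bp[t])
    if (length(idx) == 0L) next
    g <- calls[s, idx]
    het <- which(!is.na(g) & g == 1L)
    g[het] <- 2L * rbinom(length(het), 1L, 0.5)
    err <- which(!is.na(g) & runif(length(g)) < tracts$het_error_rate[t])
    g[err] <- 1L
    calls[s, idx] <- g
  }
  genotype_matrix(calls, geno$samples, v)
}

#' Specify a planted selective sweep
#'
#' @param core_index column index of the swept SNP.
#' @param derived_freq frequency of the selected derived allele at the core.
#' @param shared_len_mean_bp mean one-sided length of the interval over
#'   which derived-core haplotypes copy the shared sweep founder.
#' @param background_shared_len_mean_bp same for ancestral-core haplotypes
#'   and their own (distinct) founder; must be smaller.
#' @return a `sweep_spec` list.
#' @export
sweep_spec <- function(core_index, derived_freq, shared_len_mean_bp,
                       background_shared_len_mean_bp) {
  stopifnot(derived_freq > 0, derived_freq < 1,
            shared_len_mean_bp > background_shared_len_mean_bp)
  structure(list(core_index = as.integer(core_index),
                 derived_freq = derived_freq,
                 shared_len_mean_bp = shared_len_mean_bp,
                 background_shared_len_mean_bp = background_shared_len_mean_bp),
            class = "sweep_spec")
}

#' Simulate phased haplotypes carrying a planted sweep
#'
#' Alleles are drawn independently per site at simulated derived-allele
#' frequencies, except that every haplotype carrying the derived core
#' allele copies a single shared sweep founder over an interval around the
#' core with Exponential one-sided lengths (`shared_len_mean_bp`);
#' non-carriers do the same with a distinct background founder and
#' `background_shared_len_mean_bp`.
#'
#' @param cfg a [sim_config()] (total haplotypes =
#'   `2 * n_pops * samples_per_pop`).
#' @param sweep a [sweep_spec()].
#' @return list with `haps` ([haplotype_matrix()]) and `truth` (carrier
#'   haplotype rows and founder-copy intervals).
#' @export
gen_sweep_haplotypes <- function(cfg, sweep) {
  set.seed(cfg$seed)
  stopifnot(inherits(sweep, "sweep_spec"))
  m <- cfg$n_snps
  if (sweep$core_index < 1L || sweep$core_index > m) {
    stop("core_index out of range")
  }
  variants <- sim_variants(cfg, ancestral = "A")
  pos <- variants$pos
  n_hap <- 2L * cfg$n_pops * cfg$samples_per_pop
  # site frequencies refer to the derived allele, which can be major: the
  # minor-allele draw is flipped to 1 - q with probability 1/2
  q <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  fl <- runif(m) < 0.5
  q[fl] <- 1 - q[fl]
  n_car <- round(sweep$derived_freq * n_hap)
  if (n_car < 1L) stop("derived_freq rounds to zero carriers")
  if (n_car >= n_hap) stop("derived_freq rounds to zero non-carriers")
  carriers <- sort(sample.int(n_hap, n_car))
  founder_sweep <- rbinom(m, 1L, q)
  founder_bg <- rbinom(m, 1L, q)
  founder_sweep[sweep$core_index] <- 1L
  founder_bg[sweep$core_index] <- 0L
  core_pos <- pos[sweep$core_index]
  haps <- matrix(rbinom(n_hap * m, 1L, rep(q, each = n_hap)),
                 nrow = n_hap, ncol = m)
  is_car <- seq_len(n_hap) %in% carriers
  mean_len <- ifelse(is_car, sweep$shared_len_mean_bp,
                     sweep$background_shared_len_mean_bp)
  left <- core_pos - rexp(n_hap, 1 / mean_len)
  right <- core_pos + rexp(n_hap, 1 / mean_len)
  for (h in seq_len(n_hap)) {
    idx <- which(pos >= left[h] & pos <= right[h])
    haps[h, idx] <- if (is_car[h]) founder_sweep[idx] else founder_bg[idx]
  }
  haps[, sweep$core_index] <- as.integer(is_car)
  samples <- sprintf("s%04d", seq_len(n_hap / 2L))
  list(haps = haplotype_matrix(haps, samples, variants),
       truth = list(seed = cfg$seed, carriers = carriers,
                    core_index = sweep$core_index, core_pos = core_pos,
                    intervals = data.frame(hap = seq_len(n_hap),
                                           left_bp = left, right_bp = right)))
}

#' Split samples into two random equal-size null groups
#'
#' Labels are `"g1"` and `"g2"`; with an odd count the larger group is
#' `"g1"`.
#'
#' @param geno a [genotype_matrix()] with at least 4 samples.
#' @param seed RNG seed.
#' @return a [sample_info()].
#' @export
null_split <- function(geno, seed = 1L) {
  n <- length(geno$samples)
  if (n < 4L) stop("need at least 4 samples to split")
  set.seed(seed)
  perm <- sample.int(n)
  n1 <- ceiling(n / 2)
  grp <- rep("g2", n)
  grp[perm[seq_len(n1)]] <- "g1"
  sample_info(geno$samples, grp)
}
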