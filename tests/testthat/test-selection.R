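# selection: EHH formula and brute-force oracle, iHH integration, iHS
# standardization and antisymmetry, region enrichment.

test_that("EHH matches its direct formula on a hand-built fixture", {
  # 6 haplotypes, 4 carriers of derived core; one marker to the right the
  # carriers split into groups {2, 1, 1}
  h <- rbind(c(0L, 0L, 0L),
             c(0L, 1L, 0L),
             c(1L, 0L, 0L),
             c(1L, 0L, 1L),
             c(1L, 1L, 0L),
             c(1L, 1L, 0L))
  v <- variant_table(rep("1", 3), c(100L, 200L, 300L), c("a", "b", "c"),
                     rep("A", 3), rep("G", 3), rep("A", 3))
  haps <- haplotype_matrix(h, c("s1", "s2", "s3"), v)
  cv <- ehh(haps, core_index = 1L, allele = "derived")
  expect_equal(cv$ehh[cv$positions == 100], 1)              # at the core
  # marker 2 splits the 4 carriers into {2, 2}
  expect_equal(cv$ehh[cv$positions == 200], 2 * choose(2, 2) / choose(4, 2))
  # marker 3 leaves groups {2, 1, 1}: EHH = C(2,2) / C(4,2) = 1/6
  expect_equal(cv$ehh[cv$positions == 300], 1 / 6)
  expect_equal(cv$ehh[cv$positions == 300],
               oracle_ehh(h, v$pos, 1L, 1L, 3L))
  # all carriers distinct -> EHH = 0
  h2 <- rbind(c(1L, 0L, 0L), c(1L, 1L, 0L), c(1L, 0L, 1L), c(1L, 1L, 1L))
  haps2 <- haplotype_matrix(h2, c("s1", "s2"), v)
  cv2 <- ehh(haps2, 1L, "derived")
  expect_equal(cv2$ehh[cv2$positions == 300], 0)
  expect_error(ehh(haps2, 1L, "ancestral"), "fewer than 2")
})

test_that("EHH equals the pairwise brute force on random instances", {
  for (seed in 1:5) {
    haps <- neutral_haps(40, 40, seed = 500 + seed)
    h <- haps$haps
    core <- 20L
    for (bit in c(0L, 1L)) {
      if (sum(h[, core] == bit) < 2L) next
      cv <- ehh(haps, core, if (bit == 1L) "derived" else "ancestral")
      for (x in c(5L, 15L, 25L, 35L)) {
        got <- cv$ehh[cv$positions == haps$variants$pos[x]]
        if (length(got) == 0L) got <- 0   # curve already decayed to 0
        expect_equal(got, oracle_ehh(h, haps$variants$pos, core, bit, x),
                     tolerance = 1e-12)
      }
      expect_true(all(diff(cv$ehh[cv$positions >= cv$core_pos]) <= 1e-12))
      expect_true(all(diff(cv$ehh[cv$positions <= cv$core_pos]) >= -1e-12))
    }
  }
})

test_that("iHH integrates the hand trapezoid", {
  # EHH 1 over a 100 kb flank each side, then 0: iHH = 2 * 100kb * 0.95
  curve <- structure(list(
    core_index = 3L, core_pos = 200000, allele = "derived",
    positions = c(100000, 100001, 200000, 299999, 300000),
    ehh = c(0, 1, 1, 1, 0)), class = "ehh_curve")
  val <- ihh(curve, ehh_cutoff = 0.05)
  hand <- 2 * (0.5 * (0.95 + 0.95) * 99999 + 0.5 * (0.95 + 0) * 1)
  expect_equal(val, hand)   # ~ 2 * 100 kb * (1 - 0.05)
  expect_equal(val, 190000, tolerance = 1e-4)
  # identical ancestral/derived curves give raw iHS of 0
  expect_equal(log(val / val), 0)
  # a gap beyond max_gap truncates integration
  curve2 <- structure(list(
    core_index = 1L, core_pos = 0, allele = "derived",
    positions = c(0, 100000, 400000),
    ehh = c(1, 0.8, 0.5)), class = "ehh_curve")
  with_gap <- ihh(curve2, max_gap_bp = 2e5)
  expect_equal(with_gap, 0.5 * (0.95 + 0.75) * 100000)
  # EHH below cutoff at the first flank on both sides -> flagged 0
  curve3 <- structure(list(
    core_index = 2L, core_pos = 100, allele = "derived",
    positions = c(50, 100, 150), ehh = c(0.01, 1, 0.01)),
    class = "ehh_curve")
  v3 <- ihh(curve3)
  expect_true(isTRUE(attr(v3, "flagged")))
})

test_that("scan iHH agrees with the R-level curve integration", {
  haps <- neutral_haps(60, 80, seed = 510)
  tab <- suppressMessages(ihs_scan(haps, min_maf = 0.05))
  for (j in c(30L, 40L, 50L)) {
    if (is.na(tab$ihh_a[j])) next
    ca <- ehh(haps, j, "ancestral")
    cd <- ehh(haps, j, "derived")
    expect_equal(tab$ihh_a[j], as.numeric(ihh(ca)), tolerance = 1e-9)
    expect_equal(tab$ihh_d[j], as.numeric(ihh(cd)), tolerance = 1e-9)
  }
})

test_that("allele swap negates raw scores exactly", {
  haps <- neutral_haps(50, 200, seed = 511)
  sw <- haps
  sw$haps <- 1L - sw$haps
  a <- suppressMessages(ihs_scan(haps))
  b <- suppressMessages(ihs_scan(sw))
  expect_equal(b$raw, -a$raw, tolerance = 1e-12)
  expect_equal(b$derived_freq, 1 - a$derived_freq, tolerance = 1e-12)
})

test_that("standardization is calibrated on neutral haplotypes", {
  haps <- neutral_haps(100, 4000, seed = 512)
  tab <- suppressMessages(ihs_scan(haps))
  scored <- tab[!is.na(tab$ihs), ]
  for (b in unique(scored$freq_bin)) {
    z <- scored$ihs[scored$freq_bin == b]
    if (length(z) < 20L) next
    expect_lt(abs(mean(z)), 3 / sqrt(length(z)) + 1e-9)
    expect_lt(abs(sd(z) - 1), 0.05)
  }
})

test_that("a planted sweep stands out against the genome background", {
  cfg <- sim_config(seed = 513, n_pops = 1, samples_per_pop = 100,
                    n_snps = 10000, snp_spacing_bp = 3000)
  sw <- sweep_spec(5000, 0.7, 5e5, 2e4)
  g <- gen_sweep_haplotypes(cfg, sw)
  tab <- suppressMessages(ihs_scan(g$haps))
  # genome background = SNPs outside every founder-copy interval
  ivl <- g$truth$intervals
  lo <- min(ivl$left_bp); hi <- max(ivl$right_bp)
  bg <- !is.na(tab$ihs) & (tab$pos < lo | tab$pos > hi)
  core_z <- abs(tab$ihs[5000L])
  expect_gt(core_z, stats::quantile(abs(tab$ihs[bg]), 0.99))
  reg <- suppressMessages(region_scan(tab, n_perm = 1000, seed = 1))
  expect_gt(nrow(reg), 0L)
  expect_true(any(reg$start_bp <= g$truth$core_pos &
                    reg$end_bp >= g$truth$core_pos))
})

test_that("scattered extremes and empty inputs give no regions", {
  set.seed(514)
  m <- 5000L
  tab <- data.frame(id = sprintf("s%05d", 1:m), chrom = "1",
                    pos = sort(sample.int(15e6, m)),
                    derived_freq = runif(m, 0.05, 0.95),
                    ihh_a = 1, ihh_d = 1, raw = 0,
                    ihs = rnorm(m), freq_bin = 1L,
                    stringsAsFactors = FALSE)
  # one extreme per distant window: no enrichment anywhere
  idx <- seq(50L, m, by = 500L)
  tab$ihs[idx] <- 5
  reg <- region_scan(tab, window_bp = 1e5, n_perm = 1000, seed = 2)
  expect_equal(nrow(reg), 0L)
  # no extremes at all
  tab$ihs <- rnorm(m)
  tab$ihs[abs(tab$ihs) > 3] <- 0
  expect_message(r0 <- region_scan(tab, n_perm = 1000, seed = 3),
                 "nothing to scan")
  expect_equal(nrow(r0), 0L)
})
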