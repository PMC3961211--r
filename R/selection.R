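# EHH, iHS and region-level enrichment scanning on phased,
# ancestral-coded haplotypes.
#
# Sign convention: raw = ln(iHH_ancestral / iHH_derived), so strongly
# negative standardized scores mark unusually long derived-allele
# haplotypes.  Distances are physical (bp).

#' Extended haplotype homozygosity curve at a core SNP
#'
#' At marker x, `EHH(x) = sum_g C(e_g, 2) / C(c, 2)` where `c` carriers of
#' the core allele split into identity groups of sizes `e_g` over every
#' marker between core and x inclusive; computed separately leftward and
#' rightward until the curve reaches 0 or the chromosome end.
#'
#' @param haps a [haplotype_matrix()] (one chromosome).
#' @param core_index column index of the core SNP.
#' @param allele `"ancestral"` (0) or `"derived"` (1).
#' @return list of class `ehh_curve`: `core_index`, `core_pos`, `allele`,
#'   and `positions` / `ehh` vectors covering both directions (sorted by
#'   position, the core included with EHH 1).
#' @export
ehh <- function(haps, core_index, allele = c("derived", "ancestral")) {
  allele <- match.arg(allele)
  h <- haps$haps
  pos <- haps$variants$pos
  if (length(unique(haps$variants$chrom)) != 1L) {
    stop("ehh expects a single-chromosome haplotype matrix")
  }
  bit <- if (allele == "derived") 1L else 0L
  rows <- which(h[, core_index] == bit)
  c_n <- length(rows)
  if (c_n < 2L) stop("fewer than 2 haplotypes carry the core allele")
  denom <- choose(c_n, 2L)
  walk <- function(dir) {
    ps <- numeric(0)
    es <- numeric(0)
    key <- rep("", c_n)
    k <- core_index + dir
    while (k >= 1L && k <= ncol(h)) {
      key <- paste0(key, h[rows, k])
      sizes <- table(key)
      e <- sum(choose(sizes, 2L)) / denom
      ps <- c(ps, pos[k])
      es <- c(es, e)
      if (e == 0) break
      k <- k + dir
    }
    list(pos = ps, ehh = es)
  }
  left <- walk(-1L)
  right <- walk(1L)
  o <- order(c(left$pos, pos[core_index], right$pos))
  structure(list(core_index = core_index, core_pos = pos[core_index],
                 allele = allele,
                 positions = c(left$pos, pos[core_index], right$pos)[o],
                 ehh = c(left$ehh, 1, right$ehh)[o]),
            class = "ehh_curve")
}

#' Integrate an EHH curve into iHH
#'
#' Trapezoid integration of `(EHH - ehh_cutoff)+` against position, walked
#' outward from the core on each side; integration stops where EHH falls
#' below the cutoff (the final below-cutoff trapezoid is still added with
#' its clamped value), at an inter-marker gap larger than `max_gap_bp`, or
#' at the chromosome end.  Both sides are summed.
#'
#' @param curve an [ehh()] curve.
#' @param ehh_cutoff integration cutoff (default 0.05).
#' @param max_gap_bp maximum tolerated inter-marker gap (default 200 kb).
#' @return the integrated value in bp; 0 (with attribute `flagged`) when
#'   EHH is already below the cutoff at the first flanking marker on both
#'   sides.
#' @export
ihh <- function(curve, ehh_cutoff = 0.05, max_gap_bp = 2e5) {
  ci <- which(curve$positions == curve$core_pos)[1L]
  integrate_side <- function(idx) {
    if (length(idx) == 0L) return(0)
    p_prev <- curve$core_pos
    e_prev <- 1
    total <- 0
    for (k in idx) {
      gap <- abs(curve$positions[k] - p_prev)
      if (gap > max_gap_bp) break
      e <- curve$ehh[k]
      total <- total + 0.5 * (max(e_prev - ehh_cutoff, 0) +
                                max(e - ehh_cutoff, 0)) * gap
      if (e < ehh_cutoff) break
      p_prev <- curve$positions[k]
      e_prev <- e
    }
    total
  }
  left <- integrate_side(rev(seq_len(ci - 1L)))
  right <- integrate_side(seq(ci + 1L, length.out = length(curve$positions) - ci))
  out <- left + right
  first_left <- if (ci > 1L) curve$ehh[ci - 1L] else 0
  first_right <- if (ci < length(curve$ehh)) curve$ehh[ci + 1L] else 0
  if (first_left < ehh_cutoff && first_right < ehh_cutoff) {
    attr(out, "flagged") <- TRUE
  }
  out
}

#' Genome-wide iHS scan
#'
#' Per SNP, `raw = ln(iHH_ancestral / iHH_derived)`; raw scores are
#' standardized within derived-allele-frequency bins (`ihs =
#' (raw - bin mean) / bin SD`), with bins holding fewer than
#' `min_bin_snps` scored SNPs merged into their left neighbour (the first
#' bin merges rightward).
#'
#' @param haps a [haplotype_matrix()].
#' @param min_maf SNPs with derived frequency outside
#'   `[min_maf, 1 - min_maf]` are skipped (default 0.05).
#' @param ehh_cutoff,max_gap_bp integration parameters (see [ihh()]).
#' @param bin_width derived-frequency bin width for standardization.
#' @param min_bin_snps minimum scored SNPs per bin before merging.
#' @return data.frame of class `ihs_table`: `id`, `chrom`, `pos`,
#'   `derived_freq`, `ihh_a`, `ihh_d`, `raw`, `ihs`, `freq_bin`.  SNPs
#'   where either iHH is 0 are left unstandardized (`NA`), with a logged
#'   count.
#' @export
ihs_scan <- function(haps, min_maf = 0.05, ehh_cutoff = 0.05,
                     max_gap_bp = 2e5, bin_width = 0.025,
                     min_bin_snps = 20L) {
  v <- haps$variants
  res <- matrix(NA_real_, nrow = nrow(v), ncol = 3L)
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    res[idx, ] <- .ihh_scan_cpp(haps$haps[, idx, drop = FALSE],
                                as.numeric(v$pos[idx]), min_maf,
                                ehh_cutoff, max_gap_bp)
  }
  out <- data.frame(id = v$id, chrom = v$chrom, pos = v$pos,
                    derived_freq = res[, 1L], ihh_a = res[, 2L],
                    ihh_d = res[, 3L], stringsAsFactors = FALSE)
  zero <- !is.na(out$ihh_a) & !is.na(out$ihh_d) &
    (out$ihh_a == 0 | out$ihh_d == 0)
  if (any(zero)) {
    message(sum(zero), " SNP(s) with a zero iHH dropped from standardization")
  }
  out$raw <- ifelse(!is.na(out$ihh_a) & !zero,
                    log(out$ihh_a / out$ihh_d), NA_real_)
  # frequency-binned standardization
  out$freq_bin <- NA_integer_
  scored <- which(!is.na(out$raw))
  if (length(scored) > 0L) {
    bin <- as.integer(pmin(floor(out$derived_freq[scored] / bin_width),
                           ceiling(1 / bin_width) - 1L))
    # merge small bins leftward (first occupied bin merges rightward)
    counts <- table(bin)
    ids <- sort(as.integer(names(counts)))
    merged <- setNames(ids, ids)
    for (i in seq_along(ids)) {
      b <- ids[i]
      if (sum(bin == merged[as.character(b)]) < min_bin_snps) {
        tgt <- if (i > 1L) merged[as.character(ids[i - 1L])] else
          if (length(ids) > 1L) ids[i + 1L] else b
        if (tgt != b) {
          message("frequency bin ", b, " merged into bin ", tgt)
          bin[bin == b] <- tgt
          merged[as.character(b)] <- tgt
        }
      }
    }
    out$freq_bin[scored] <- bin
    mu <- tapply(out$raw[scored], bin, mean)
    sg <- tapply(out$raw[scored], bin, sd)
    out$ihs <- NA_real_
    out$ihs[scored] <- (out$raw[scored] - mu[as.character(bin)]) /
      sg[as.character(bin)]
  } else {
    out$ihs <- NA_real_
  }
  class(out) <- c("ihs_table", "data.frame")
  out
}

#' Scan for regions enriched in extreme |iHS|
#'
#' The genome is tiled into non-overlapping `window_bp` windows.  Per
#' window, `n_extreme` counts SNPs with `|ihs| > extreme_threshold`;
#' `p_nominal` is the upper binomial tail
#' `P(X >= n_extreme), X ~ Binomial(n_snps, q)` with `q` the genome-wide
#' extreme fraction.  The family-wise empirical p compares each window's
#' nominal p with the minimum window p obtained in each of `n_perm`
#' permutations of the scores across SNP positions.  Adjacent windows with
#' empirical p below `alpha` merge into one region, trimmed to the first
#' and last member SNP; a merged region's nominal p is recomputed from its
#' pooled counts and its empirical p is the minimum over member windows.
#'
#' @param ihs an [ihs_scan()] table.
#' @param window_bp tile width (default 100 kb).
#' @param extreme_threshold |iHS| threshold (default 4).
#' @param n_perm number of permutations (>= 1000).
#' @param seed RNG seed for the permutations.
#' @param alpha family-wise significance level for reporting (default
#'   0.05).
#' @param min_extreme minimum extreme-SNP count for a window to count as
#'   enriched (default 2: one extreme SNP alone is never enrichment);
#'   applied identically to the observed and the permuted scans.
#' @return data.frame with the [region_table_schema()] columns (genes left
#'   `NA`), one row per merged region, ordered by decreasing
#'   `max_abs_ihs`.
#' @export
region_scan <- function(ihs, window_bp = 1e5, extreme_threshold = 4,
                        n_perm = 1000L, seed = 1L, alpha = 0.05,
                        min_extreme = 2L) {
  stopifnot(window_bp > 0, n_perm >= 1000L, min_extreme >= 1L)
  d <- ihs[!is.na(ihs$ihs), , drop = FALSE]
  m <- nrow(d)
  extreme <- abs(d$ihs) > extreme_threshold
  q <- mean(extreme)
  if (q == 0) {
    message("no SNP exceeds |iHS| > ", extreme_threshold, "; nothing to scan")
    return(empty_regions())
  }
  win_key <- paste(d$chrom, floor((d$pos - 1) / window_bp), sep = "@")
  wins <- unique(win_key)
  wid <- match(win_key, wins)
  n_w <- tabulate(wid, length(wins))
  k_w <- vapply(split(extreme, wid), sum, numeric(1))[as.character(
    seq_along(wins))]
  k_w[is.na(k_w)] <- 0
  p_nom <- pbinom(k_w - 1, n_w, q, lower.tail = FALSE)
  # permutation null: min p over enrichment-eligible windows (>=
  # min_extreme hits) when extremes land uniformly
  set.seed(seed)
  n_ext <- sum(extreme)
  perm_min <- vapply(seq_len(n_perm), function(b) {
    hit <- tabulate(wid[sample.int(m, n_ext)], length(wins))
    nz <- hit >= min_extreme
    if (!any(nz)) return(1)
    min(pbinom(hit[nz] - 1, n_w[nz], q, lower.tail = FALSE))
  }, numeric(1))
  p_emp <- vapply(p_nom, function(p) {
    (1 + sum(perm_min <= p)) / (n_perm + 1)
  }, numeric(1))
  sig <- which(p_emp < alpha & k_w >= min_extreme)
  if (length(sig) == 0L) return(empty_regions())
  # merge adjacent significant tiles on the same chromosome
  parts <- do.call(rbind, strsplit(wins[sig], "@", fixed = TRUE))
  ord <- order(parts[, 1L], as.numeric(parts[, 2L]))
  sig <- sig[ord]; parts <- parts[ord, , drop = FALSE]
  grp <- cumsum(c(1L, diff(as.numeric(parts[, 2L])) != 1L |
                    parts[-1L, 1L] != parts[-nrow(parts), 1L]))
  regions <- lapply(split(seq_along(sig), grp), function(ii) {
    wset <- sig[ii]
    snps <- which(wid %in% wset)
    kk <- sum(extreme[snps]); nn <- length(snps)
    mx <- which.max(abs(d$ihs[snps]))
    data.frame(chrom = d$chrom[snps][1L],
               start_bp = min(d$pos[snps]), end_bp = max(d$pos[snps]),
               size_kb = (max(d$pos[snps]) - min(d$pos[snps])) / 1000,
               n_extreme = kk, n_snps = nn,
               max_abs_ihs = abs(d$ihs[snps][mx]),
               max_snp_id = d$id[snps][mx],
               p_nominal = pbinom(kk - 1, nn, q, lower.tail = FALSE),
               p_empirical = min(p_emp[wset]),
               genes = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, regions)
  out <- out[order(-out$max_abs_ihs), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_regions <- function() {
  out <- data.frame(chrom = character(0), start_bp = numeric(0),
                    end_bp = numeric(0), size_kb = numeric(0),
                    n_extreme = integer(0), n_snps = integer(0),
                    max_abs_ihs = numeric(0), max_snp_id = character(0),
                    p_nominal = numeric(0), p_empirical = numeric(0),
                    genes = character(0), stringsAsFactors = FALSE)
  out
}

#' Annotate regions with overlapping gene intervals
#'
#' @param regions a [region_scan()] table.
#' @param gene_bed path to a BED file of gene intervals (chrom, start,
#'   end, name).
#' @return `regions` with the `genes` column filled (semicolon-joined).
#' @export
annotate_regions <- function(regions, gene_bed) {
  genes <- read.table(gene_bed, sep = "\t", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(regions))) {
    hit <- genes[[1L]] == regions$chrom[i] &
      genes[[2L]] < regions$end_bp[i] & genes[[3L]] >= regions$start_bp[i]
    if (any(hit)) {
      regions$genes[i] <- paste(genes[[4L]][hit], collapse = ";")
    }
  }
  regions
}
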