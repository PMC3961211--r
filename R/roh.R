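# Runs-of-homozygosity calling, classification and F_RoH summaries.
#
# The caller follows the classic sliding-window design: windows of
# `window_snps` consecutive SNPs (capped at a physical span), a window is
# homozygous when it holds at most `max_het_per_window` heterozygous and
# `max_missing_per_window` missing calls, and a SNP joins a run when the
# proportion of homozygous windows covering it exceeds
# `hit_proportion_threshold` (strict ">").  Segment length is
# pos_last - pos_first, with no half-SNP padding.

#' RoH caller parameters
#'
#' Defaults are the standard array-data settings: 50-SNP windows capped at
#' 5000 kb, at most 1 heterozygous and 5 missing calls per window, hit
#' proportion threshold 0.05, and a minimum final segment of 500 kb and 50
#' SNPs.
#'
#' @param window_snps SNPs per sliding window.
#' @param window_span_kb_cap maximum physical window span (kb); wider
#'   windows are not enumerated.
#' @param max_het_per_window,max_missing_per_window per-window tolerances.
#' @param hit_proportion_threshold strict lower bound on the per-SNP hit
#'   proportion, in (0, 1).
#' @param min_segment_kb,min_segment_snps minimum final segment length and
#'   SNP count.
#' @return a `roh_params` list.
#' @export
roh_params <- function(window_snps = 50L, window_span_kb_cap = 5000,
                       max_het_per_window = 1L, max_missing_per_window = 5L,
                       hit_proportion_threshold = 0.05,
                       min_segment_kb = 500, min_segment_snps = 50L) {
  stopifnot(window_snps >= 1L, window_span_kb_cap > 0,
            max_het_per_window >= 0L, max_missing_per_window >= 0L,
            hit_proportion_threshold > 0, hit_proportion_threshold < 1,
            min_segment_kb > 0, min_segment_snps >= 1L)
  structure(list(window_snps = as.integer(window_snps),
                 window_span_kb_cap = window_span_kb_cap,
                 max_het_per_window = as.integer(max_het_per_window),
                 max_missing_per_window = as.integer(max_missing_per_window),
                 hit_proportion_threshold = hit_proportion_threshold,
                 min_segment_kb = min_segment_kb,
                 min_segment_snps = as.integer(min_segment_snps)),
            class = "roh_params")
}

empty_segments <- function() {
  data.frame(sample_id = character(0), chrom = character(0),
             start_bp = integer(0), end_bp = integer(0),
             length_bp = integer(0), n_snps = integer(0),
             n_het = integer(0), n_missing = integer(0),
             stringsAsFactors = FALSE)
}

# sliding-sum of x over windows of width w: out[j] = sum(x[j:(j+w-1)])
window_sums <- function(x, w) {
  cs <- c(0, cumsum(x))
  cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]
}

call_roh_one <- function(pos, g, params) {
  m <- length(pos)
  w <- params$window_snps
  if (m < w) return(NULL)
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  span <- pos[w:m] - pos[1:(m - w + 1L)]
  valid <- span <= params$window_span_kb_cap * 1000
  homo <- valid &
    window_sums(het, w) <= params$max_het_per_window &
    window_sums(mis, w) <= params$max_missing_per_window
  # windows covering SNP i start at j in [i - w + 1, i] (clipped to range);
  # counts via cumulative sums over window-start indicators
  cs_valid <- c(0, cumsum(valid))
  cs_homo <- c(0, cumsum(homo))
  n_starts <- m - w + 1L
  i <- seq_len(m)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(i, n_starts)
  den <- num <- numeric(m)
  cov <- hi >= lo
  den[cov] <- cs_valid[hi[cov] + 1L] - cs_valid[lo[cov]]
  num[cov] <- cs_homo[hi[cov] + 1L] - cs_homo[lo[cov]]
  prop <- ifelse(den > 0, num / den, 0)
  in_run <- prop > params$hit_proportion_threshold
  if (!any(in_run)) return(NULL)
  r <- rle(in_run)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  out <- lapply(runs, function(k) {
    a <- starts[k]; b <- ends[k]
    len <- pos[b] - pos[a]
    n_snp <- b - a + 1L
    if (len < params$min_segment_kb * 1000 ||
        n_snp < params$min_segment_snps) return(NULL)
    data.frame(start_bp = pos[a], end_bp = pos[b], length_bp = len,
               n_snps = n_snp, n_het = sum(het[a:b]),
               n_missing = sum(mis[a:b]), stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

#' Call runs of homozygosity
#'
#' @param geno a [genotype_matrix()] with variants sorted by position
#'   within chromosome.
#' @param params a [roh_params()].
#' @return data.frame of segments (one row per sample x run): `sample_id`,
#'   `chrom`, `start_bp`, `end_bp` (positions of the first/last member
#'   SNP), `length_bp`, `n_snps`, `n_het`, `n_missing`, sorted by sample,
#'   chromosome, start.  Segments never span chromosomes.
#' @export
call_roh <- function(geno, params = roh_params()) {
  v <- geno$variants
  chroms <- unique(v$chrom)
  res <- list()
  for (ch in chroms) {
    idx <- which(v$chrom == ch)
    if (length(idx) < params$window_snps) {
      message("chromosome ", ch, " has fewer than ", params$window_snps,
              " SNPs; no calls there")
      next
    }
    pos <- v$pos[idx]
    for (s in seq_along(geno$samples)) {
      seg <- call_roh_one(pos, geno$calls[s, idx], params)
      if (!is.null(seg)) {
        seg <- cbind(sample_id = geno$samples[s], chrom = ch, seg,
                     stringsAsFactors = FALSE)
        res[[length(res) + 1L]] <- seg
      }
    }
  }
  if (length(res) == 0L) return(empty_segments())
  out <- do.call(rbind, res)
  out <- out[order(out$sample_id, out$chrom, out$start_bp), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, names(empty_segments())]
}

#' The six RoH length classes (Mb)
#'
#' Half-open intervals `[0.5,1) [1,2) [2,4) [4,8) [8,16) [16,Inf)`.
#'
#' @return data.frame with columns `class`, `lo_mb`, `hi_mb`.
#' @export
roh_classes <- function() {
  lo <- c(0.5, 1, 2, 4, 8, 16)
  hi <- c(1, 2, 4, 8, 16, Inf)
  data.frame(class = c("0.5-1 Mb", "1-2 Mb", "2-4 Mb", "4-8 Mb",
                       "8-16 Mb", ">16 Mb"),
             lo_mb = lo, hi_mb = hi, stringsAsFactors = FALSE)
}

#' Classify segments into the six length classes
#'
#' @param segments data.frame from [call_roh()].
#' @param samples optional character vector of all sample ids, so samples
#'   without segments appear with zero counts.
#' @return data.frame with one row per sample x class: `sample_id`,
#'   `class`, `n`, `sum_bp`.  Segments shorter than 0.5 Mb (possible only
#'   with non-default caller settings) are ignored with a message.
#' @export
classify_segments <- function(segments, samples = NULL) {
  if (is.null(samples)) samples <- unique(segments$sample_id)
  cls <- roh_classes()
  short <- segments$length_bp < 0.5e6
  if (any(short)) {
    message(sum(short), " segment(s) below 0.5 Mb ignored in classification")
    segments <- segments[!short, , drop = FALSE]
  }
  grid <- expand.grid(sample_id = samples, class = cls$class,
                      stringsAsFactors = FALSE)
  grid$n <- 0L
  grid$sum_bp <- 0
  if (nrow(segments) > 0L) {
    mb <- segments$length_bp / 1e6
    ci <- findInterval(mb, cls$lo_mb)   # half-open: boundary joins upper
    key <- paste(segments$sample_id, cls$class[ci])
    agg_n <- tapply(rep(1L, nrow(segments)), key, sum)
    agg_s <- tapply(as.numeric(segments$length_bp), key, sum)
    gk <- paste(grid$sample_id, grid$class)
    i <- match(names(agg_n), gk)
    grid$n[i] <- as.integer(agg_n)
    grid$sum_bp[i] <- as.numeric(agg_s)
  }
  grid[order(grid$sample_id), , drop = FALSE]
}

#' Genomic inbreeding from RoH coverage (F_RoH %)
#'
#' `F_RoH% = 100 * sum(length_bp of segments >= min_mb) / accessible_bp`.
#'
#' @param segments data.frame from [call_roh()].
#' @param min_mb minimum segment length in Mb (0.5 and 5 are the
#'   conventional thresholds).
#' @param accessible_bp accessible autosomal genome size (default
#'   2.84e9 bp).
#' @param samples optional full sample list (zero coverage included).
#' @return data.frame with `sample_id`, `froh_pct`, `sum_mb`.
#' @export
froh <- function(segments, min_mb = 0.5, accessible_bp = 2.84e9,
                 samples = NULL) {
  stopifnot(accessible_bp > 0)
  if (is.null(samples)) samples <- unique(segments$sample_id)
  keep <- segments$length_bp >= min_mb * 1e6
  s <- tapply(as.numeric(segments$length_bp[keep]),
              segments$sample_id[keep], sum)
  sum_bp <- setNames(rep(0, length(samples)), samples)
  sum_bp[names(s)] <- as.numeric(s)
  data.frame(sample_id = samples, froh_pct = 100 * sum_bp / accessible_bp,
             sum_mb = sum_bp / 1e6, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Group-level RoH summaries with Welch t-tests
#'
#' Produces the two standard report shapes: per-class percentage of the
#' accessible genome plus mean +/- SE summed RoH (six length classes), and
#' per-threshold F_RoH% (>= 0.5 and >= 5 Mb) with mean summed RoH, each
#' with a two-sided Welch t-test against the reference group (omitted when
#' `reference_group` is `NULL`).
#'
#' @param segments data.frame from [call_roh()].
#' @param samples full sample id vector.
#' @param labels group label per sample.
#' @param reference_group reference group name, or `NULL`.
#' @param accessible_bp accessible genome size (bp).
#' @return list with data.frames `by_class` and `froh`.
#' @export
summarize_roh_groups <- function(segments, samples, labels,
                                 reference_group = NULL,
                                 accessible_bp = 2.84e9) {
  stopifnot(length(samples) == length(labels))
  cl <- classify_segments(segments, samples)
  by_class <- do.call(rbind, lapply(roh_classes()$class, function(k) {
    v <- cl[cl$class == k, ]
    v <- v[match(samples, v$sample_id), ]
    sums_mb <- v$sum_bp / 1e6
    pct <- 100 * v$sum_bp / accessible_bp
    base <- data.frame(class = k,
                       group = unique(labels), stringsAsFactors = FALSE)
    base$pct_genome <- tapply(pct, labels, mean)[base$group]
    if (is.null(reference_group)) {
      cmp <- data.frame(group = base$group,
                        mean = tapply(sums_mb, labels, mean)[base$group],
                        se = tapply(sums_mb, labels,
                                    function(x) sd(x) / sqrt(length(x)))[
                                      base$group],
                        p = NA_real_, stringsAsFactors = FALSE)
    } else {
      cmp <- compare_groups(sums_mb, labels, reference_group)
    }
    merge(base, cmp[, c("group", "mean", "se", "p")], by = "group",
          sort = FALSE)
  }))
  fr <- do.call(rbind, lapply(c(0.5, 5), function(th) {
    f <- froh(segments, min_mb = th, accessible_bp = accessible_bp,
              samples = samples)
    base <- data.frame(threshold_mb = th, group = unique(labels),
                       stringsAsFactors = FALSE)
    base$froh_pct <- tapply(f$froh_pct, labels, mean)[base$group]
    base$mean_sum_mb <- tapply(f$sum_mb, labels, mean)[base$group]
    if (is.null(reference_group)) {
      base$p <- NA_real_
    } else {
      cmp <- compare_groups(f$froh_pct, labels, reference_group)
      base$p <- cmp$p[match(base$group, cmp$group)]
    }
    base
  }))
  rownames(by_class) <- rownames(fr) <- NULL
  list(by_class = by_class, froh = fr)
}
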