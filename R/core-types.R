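# Core containers shared by all pipeline stages.
#
# A genotype_matrix holds diploid calls as an n_samples x n_variants integer
# matrix counting copies of allele_b (0/1/2, NA = missing).  A
# haplotype_matrix holds phased, ancestral-coded haplotypes as a
# (2 n_samples) x m binary matrix (0 = ancestral, 1 = derived).  Variants
# travel as a data.frame with one row per marker.

#' Construct a variant table
#'
#' @param chrom chromosome labels.
#' @param pos 1-based base-pair positions (VCF convention).
#' @param id marker names.
#' @param allele_a,allele_b the two observed alleles; `allele_b` is the
#'   counted allele of a [genotype_matrix].
#' @param ancestral the ancestral allele, one of `allele_a`, `allele_b` or
#'   `NA` (unknown).
#' @return a data.frame with one row per variant, positions strictly
#'   increasing within each chromosome.
#' @export
variant_table <- function(chrom, pos, id, allele_a, allele_b,
                          ancestral = NA_character_) {
  v <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    id = as.character(id),
    allele_a = as.character(allele_a), allele_b = as.character(allele_b),
    ancestral = as.character(ancestral),
    stringsAsFactors = FALSE
  )
  if (any(v$pos < 1L)) stop("variant positions must be >= 1")
  if (any(v$allele_a == v$allele_b)) stop("allele_a must differ from allele_b")
  for (ch in unique(v$chrom)) {
    p <- v$pos[v$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("positions must be strictly increasing within chromosome ", ch)
    }
  }
  bad <- !is.na(v$ancestral) &
    v$ancestral != v$allele_a & v$ancestral != v$allele_b
  if (any(bad)) stop("ancestral allele must be one of the observed alleles")
  v
}

#' Construct a diploid genotype matrix
#'
#' @param calls integer matrix, samples x variants, entries in
#'   `{0, 1, 2, NA}` counting copies of `allele_b`.
#' @param samples character vector of sample ids (row order of `calls`).
#' @param variants a [variant_table()] (column order of `calls`).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, samples, variants) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != length(samples)) stop("calls rows must match samples")
  if (ncol(calls) != nrow(variants)) stop("calls columns must match variants")
  if (!all(calls %in% c(0L, 1L, 2L, NA))) {
    stop("genotype calls must be 0, 1, 2 or NA")
  }
  dimnames(calls) <- list(as.character(samples), variants$id)
  structure(list(calls = calls, samples = as.character(samples),
                 variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%d chromosome%s)\n",
              length(x$samples), nrow(x$variants),
              length(unique(x$variants$chrom)),
              if (length(unique(x$variants$chrom)) == 1L) "" else "s"))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by sample and/or variant index
#'
#' @param geno a [genotype_matrix()].
#' @param samples,variants integer or logical indices; `NULL` keeps all.
#' @return the subset `genotype_matrix`.
#' @export
subset_genotypes <- function(geno, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_along(geno$samples) else samples
  vi <- if (is.null(variants)) seq_len(nrow(geno$variants)) else variants
  genotype_matrix(geno$calls[si, vi, drop = FALSE], geno$samples[si],
                  geno$variants[vi, , drop = FALSE])
}

#' Construct a phased, ancestral-coded haplotype matrix
#'
#' @param haps integer matrix, `2 * n_samples` rows (two consecutive rows
#'   per sample) x m variants, binary entries: 0 = ancestral, 1 = derived.
#' @param samples character vector of sample ids (length `nrow(haps) / 2`).
#' @param variants a [variant_table()]; every row must have a known
#'   ancestral allele.
#' @return an object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(haps, samples, variants) {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  if (nrow(haps) != 2L * length(samples)) {
    stop("haplotype matrix must have exactly two rows per sample")
  }
  if (ncol(haps) != nrow(variants)) stop("haps columns must match variants")
  if (!all(haps %in% c(0L, 1L))) stop("haplotype entries must be 0 or 1")
  if (any(is.na(variants$ancestral))) {
    stop("all variants in a haplotype_matrix need a known ancestral allele")
  }
  rownames(haps) <- paste0(rep(as.character(samples), each = 2L),
                           c("_h1", "_h2"))
  colnames(haps) <- variants$id
  structure(list(haps = haps, samples = as.character(samples),
                 variants = variants),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("haplotype_matrix: %d haplotypes (%d samples) x %d variants\n",
              nrow(x$haps), length(x$samples), nrow(x$variants)))
  invisible(x)
}

#' Collapse phased haplotypes to diploid genotype calls
#'
#' Counts derived-allele copies per sample, recoded so that the counted
#' allele (`allele_b`) is the derived allele.
#'
#' @param haps a [haplotype_matrix()].
#' @return a [genotype_matrix()].
#' @export
haplotypes_to_genotypes <- function(haps) {
  h <- haps$haps
  calls <- h[seq(1L, nrow(h), by = 2L), , drop = FALSE] +
    h[seq(2L, nrow(h), by = 2L), , drop = FALSE]
  v <- haps$variants
  derived_is_b <- is.na(v$ancestral) | v$ancestral == v$allele_a
  # where the ancestral allele is allele_b, swap so allele_b stays derived
  sw <- !derived_is_b
  tmp <- v$allele_a[sw]
  v$allele_a[sw] <- v$allele_b[sw]
  v$allele_b[sw] <- tmp
  genotype_matrix(calls, haps$samples, v)
}

#' Per-group allele frequencies and genotype counts
#'
#' Frequencies refer to the counted allele (`allele_b`); `n_chrom` is the
#' number of non-missing allele copies observed in the group.
#'
#' @param geno a [genotype_matrix()].
#' @param labels optional character/factor of group labels per sample; when
#'   `NULL` the whole cohort is one group called `"all"`.
#' @return a data.frame with columns `group`, `id`, `chrom`, `pos`, `p`,
#'   `n_chrom`, `n_AA`, `n_AB`, `n_BB` (AA = homozygous `allele_a`).
#' @export
allele_freq_table <- function(geno, labels = NULL) {
  if (is.null(labels)) labels <- rep("all", length(geno$samples))
  labels <- as.character(labels)
  stopifnot(length(labels) == length(geno$samples))
  out <- lapply(unique(labels), function(g) {
    m <- geno$calls[labels == g, , drop = FALSE]
    n_AA <- colSums(m == 0L, na.rm = TRUE)
    n_AB <- colSums(m == 1L, na.rm = TRUE)
    n_BB <- colSums(m == 2L, na.rm = TRUE)
    n_chrom <- 2L * (n_AA + n_AB + n_BB)
    p <- ifelse(n_chrom > 0L, (2 * n_BB + n_AB) / n_chrom, NA_real_)
    data.frame(group = g, id = geno$variants$id, chrom = geno$variants$chrom,
               pos = geno$variants$pos, p = p, n_chrom = n_chrom,
               n_AA = n_AA, n_AB = n_AB, n_BB = n_BB,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Sample-to-group label table
#'
#' @param sample_id sample ids.
#' @param group group label per sample, drawn from a finite set.
#' @return data.frame of class `sample_info` with columns `sample_id`,
#'   `group`.
#' @export
sample_info <- function(sample_id, group) {
  stopifnot(length(sample_id) == length(group))
  structure(data.frame(sample_id = as.character(sample_id),
                       group = as.character(group),
                       stringsAsFactors = FALSE),
            class = c("sample_info", "data.frame"))
}

# align a label vector to the sample order of a genotype matrix
match_labels <- function(geno, info) {
  i <- match(geno$samples, info$sample_id)
  if (anyNA(i)) stop("sample_info is missing labels for some samples")
  info$group[i]
}
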