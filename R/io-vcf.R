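# VCF input/output.  Reading is backed by VariantAnnotation::readVcf;
# writing emits plain VCF 4.2 text (adequate for the fixture-scale files
# this pipeline produces).

#' Read a VCF file into a genotype or haplotype matrix
#'
#' Only biallelic SNP records are kept; multi-allelic records and indels are
#' skipped and counted (see the `n_skipped` attribute).  The ancestral
#' allele is taken from the `INFO/AA` tag when present, else from
#' `ancestral_tsv`, else left unknown.
#'
#' @param path path to a VCF file (uncompressed or bgzipped).
#' @param require_phased if `TRUE`, every genotype must use the phased
#'   separator `|` and the result is a [haplotype_matrix()] restricted to
#'   markers with a known ancestral allele; otherwise a
#'   [genotype_matrix()] counting ALT copies.
#' @param ancestral_tsv optional TSV with columns `chrom`, `pos`,
#'   `ancestral` supplying ancestral alleles for markers lacking `INFO/AA`.
#' @return a [genotype_matrix()] or [haplotype_matrix()] with attribute
#'   `n_skipped` (records dropped as multi-allelic/non-SNP).
#' @export
read_vcf <- function(path, require_phased = FALSE, ancestral_tsv = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  if (!("GT" %in% rownames(VariantAnnotation::geno(
    VariantAnnotation::header(vcf))))) {
    stop("VCF has no GT field: ", path)
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(ref))
  alt1[n_alt >= 1L] <- as.character(unlist(altl))[cumsum(n_alt)[n_alt >= 1L] -
                                                    n_alt[n_alt >= 1L] + 1L]
  keep <- n_alt == 1L & nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L &
    ref %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T")
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    message(n_skipped, " multi-allelic or non-SNP record(s) skipped")
  }
  gt <- VariantAnnotation::geno(vcf)$GT[keep, , drop = FALSE]
  ref <- ref[keep]; alt1 <- alt1[keep]
  chrom <- as.character(GenomicRanges::seqnames(rr))[keep]
  pos <- GenomicRanges::start(rr)[keep]
  id <- names(rr)[keep]
  if (is.null(id)) id <- paste0(chrom, ":", pos)

  anc <- rep(NA_character_, sum(keep))
  inf <- VariantAnnotation::info(vcf)
  if ("AA" %in% colnames(inf)) {
    aa <- toupper(as.character(inf$AA))[keep]
    aa[!(aa == ref | aa == alt1)] <- NA_character_
    anc <- aa
  }
  if (!is.null(ancestral_tsv)) {
    side <- read_ancestral_tsv(ancestral_tsv)
    i <- match(paste(chrom, pos), paste(side$chrom, side$pos))
    hit <- !is.na(i) & is.na(anc)
    a2 <- toupper(side$ancestral[i[hit]])
    ok <- a2 == ref[hit] | a2 == alt1[hit]
    anc[hit][ok] <- a2[ok]
  }

  if (require_phased) {
    unph <- matrix(grepl("/", gt, fixed = TRUE), nrow = nrow(gt))
    if (any(unph)) {
      w <- which(unph, arr.ind = TRUE)[1L, ]
      stop("unphased genotype at record ", id[w[1L]],
           " sample ", colnames(gt)[w[2L]],
           " but phased haplotypes were required")
    }
  }
  if (any(!grepl("^[.01]([/|][.01])?$", gt))) {
    stop("unsupported GT encoding in ", path)
  }

  samples <- colnames(gt)
  if (require_phased) {
    known <- !is.na(anc)
    n_drop <- sum(!known)
    if (n_drop > 0L) {
      message(n_drop, " marker(s) without ancestral allele dropped")
    }
    gt <- gt[known, , drop = FALSE]
    v <- variant_table(chrom[known], pos[known], id[known], ref[known],
                       alt1[known], anc[known])
    a1 <- substr(gt, 1L, 1L)
    a2 <- substr(gt, 3L, 3L)
    # bit = carries ALT; recode to derived when ancestral is ALT
    flip <- v$ancestral == v$allele_b
    hap <- matrix(0L, nrow = 2L * length(samples), ncol = nrow(v))
    for (s in seq_along(samples)) {
      h1 <- as.integer(a1[, s] == "1")
      h2 <- as.integer(a2[, s] == "1")
      h1[flip] <- 1L - h1[flip]
      h2[flip] <- 1L - h2[flip]
      hap[2L * s - 1L, ] <- h1
      hap[2L * s, ] <- h2
    }
    out <- haplotype_matrix(hap, samples, v)
  } else {
    v <- variant_table(chrom, pos, id, ref, alt1, anc)
    nalt <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
    ok <- !grepl(".", gt, fixed = TRUE)
    cnt <- (substr(gt, 1L, 1L) == "1") + (substr(gt, 3L, 3L) == "1")
    haploid <- nchar(gt) == 1L
    cnt[haploid] <- 2L * (substr(gt[haploid], 1L, 1L) == "1")
    nalt[ok] <- as.integer(cnt[ok])
    out <- genotype_matrix(t(nalt), samples, v)
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read an ancestral-allele side table
#'
#' @param path TSV with header columns `chrom`, `pos`, `ancestral`.
#' @return a data.frame with those columns.
#' @export
read_ancestral_tsv <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = c("character", "integer", "character"))
  stopifnot(all(c("chrom", "pos", "ancestral") %in% names(d)))
  d
}

#' Write a genotype or haplotype matrix as VCF text
#'
#' `allele_a` becomes REF and `allele_b` ALT; known ancestral alleles are
#' emitted as `INFO/AA`.  Haplotypes are written phased (`|`), genotypes
#' unphased (`/`).
#'
#' @param x a [genotype_matrix()] or [haplotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  v <- x$variants
  info <- ifelse(is.na(v$ancestral), ".", paste0("AA=", v$ancestral))
  if (inherits(x, "haplotype_matrix")) {
    h <- x$haps
    # columns are derived-coded; write as REF/ALT with ALT = allele_b
    derived_is_b <- v$ancestral == v$allele_a
    gt_fun <- function(s) {
      h1 <- h[2L * s - 1L, ]; h2 <- h[2L * s, ]
      b1 <- ifelse(derived_is_b, h1, 1L - h1)
      b2 <- ifelse(derived_is_b, h2, 1L - h2)
      paste0(b1, "|", b2)
    }
  } else {
    g <- x$calls
    codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gt_fun <- function(s) {
      out <- rep("./.", ncol(g))
      nm <- !is.na(g[s, ])
      out[nm] <- codes[as.character(g[s, nm])]
      out
    }
  }
  n <- length(x$samples)
  gt <- vapply(seq_len(n), gt_fun, character(nrow(v)))
  if (nrow(v) == 1L) gt <- matrix(gt, nrow = 1L)
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", x$samples), collapse = "\t"))
  body <- paste(v$chrom, v$pos, v$id, v$allele_a, v$allele_b, ".", "PASS",
                info, "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
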