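# PLINK text (.ped/.map) input/output.
#
# Counted-allele convention: when the .map carries allele columns (6-column
# .bim-style map, as written by write_plink_text) the counted allele is its
# sixth column.  With a plain 4-column .map the counted allele is the second
# distinct non-missing allele observed at the marker, scanning samples in
# file order -- deterministic, but orientation then depends on the data.

#' Read PLINK text genotypes
#'
#' @param ped_path path to a .ped file (6 leading columns, then two allele
#'   columns per marker; `0` encodes a missing allele).
#' @param map_path path to the matching .map file: either the plain
#'   4-column format (`chrom id cM pos`) or the 6-column variant with
#'   trailing `allele_a allele_b` columns.
#' @return a [genotype_matrix()] counting copies of the counted allele (see
#'   Details above); monomorphic markers under a 4-column map get the
#'   placeholder `"0"` as their uncounted allele.
#' @export
read_plink_text <- function(ped_path, map_path) {
  map <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (!ncol(map) %in% c(4L, 6L)) {
    stop("map file must have 4 or 6 columns, found ", ncol(map))
  }
  m <- nrow(map)
  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(ped_lines)]
  n <- length(ped_lines)
  if (n == 0L) stop("empty .ped file: ", ped_path)
  alle <- matrix(NA_character_, nrow = n, ncol = 2L * m)
  samples <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(ped_lines[i], "[ \t]+")[[1L]]
    f <- f[nzchar(f)]
    if (length(f) != 6L + 2L * m) {
      stop("line ", i, " of ", ped_path, " has ", length(f),
           " fields, expected ", 6L + 2L * m)
    }
    samples[i] <- f[2L]
    alle[i, ] <- f[-(1:6)]
  }
  alle[alle == "0"] <- NA_character_
  calls <- matrix(NA_integer_, nrow = n, ncol = m)
  allele_a <- character(m)
  allele_b <- character(m)
  for (j in seq_len(m)) {
    a1 <- alle[, 2L * j - 1L]
    a2 <- alle[, 2L * j]
    if (ncol(map) == 6L) {
      allele_a[j] <- map[j, 5L]
      allele_b[j] <- map[j, 6L]
    } else {
      seen <- unique(stats::na.omit(as.vector(rbind(a1, a2))))
      if (length(seen) == 0L) {
        allele_a[j] <- "0"; allele_b[j] <- "N"
      } else if (length(seen) == 1L) {
        allele_a[j] <- "0"; allele_b[j] <- seen
      } else {
        allele_a[j] <- seen[1L]; allele_b[j] <- seen[2L]
      }
      if (length(seen) > 2L) {
        stop("marker ", map[j, 2L], " has more than two alleles")
      }
    }
    ok <- !is.na(a1) & !is.na(a2)
    calls[ok, j] <- (a1[ok] == allele_b[j]) + (a2[ok] == allele_b[j])
  }
  v <- variant_table(map[, 1L], map[, 4L], map[, 2L], allele_a, allele_b)
  genotype_matrix(calls, samples, v)
}

#' Write PLINK text genotypes
#'
#' Writes `<prefix>.ped` and a 6-column `<prefix>.map` whose trailing
#' columns pin the allele orientation, so [read_plink_text()] recovers the
#' matrix exactly.
#'
#' @param geno a [genotype_matrix()].
#' @param prefix output path prefix.
#' @return the two paths written, invisibly.
#' @export
write_plink_text <- function(geno, prefix) {
  v <- geno$variants
  map <- data.frame(v$chrom, v$id, 0, v$pos, v$allele_a, v$allele_b)
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  write.table(map, map_path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  n <- length(geno$samples)
  lines <- character(n)
  for (i in seq_len(n)) {
    g <- geno$calls[i, ]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, v$allele_b, v$allele_a))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2L, v$allele_b, v$allele_a))
    lines[i] <- paste(c(geno$samples[i], geno$samples[i], 0, 0, 0, -9,
                        as.vector(rbind(a1, a2))), collapse = " ")
  }
  writeLines(lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}
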