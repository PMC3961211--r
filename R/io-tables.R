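# Tabular output: RoH BED, generic TSV writer with schema checking.

#' Write called RoH segments as BED
#'
#' Coordinates follow the BED convention: 0-based, half-open
#' (`chromStart = start_bp - 1`, `chromEnd = end_bp`).  The name column is
#' the sample id, the score column the segment SNP count.
#'
#' @param segments a data.frame of segments as returned by [call_roh()],
#'   sorted by sample, chromosome, start.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roh_bed <- function(segments, path) {
  cols <- c("sample_id", "chrom", "start_bp", "end_bp", "n_snps")
  if (!all(cols %in% names(segments))) {
    stop("segments must have columns ", paste(cols, collapse = ", "))
  }
  if (nrow(segments) > 1L) {
    o <- order(segments$sample_id, segments$chrom, segments$start_bp)
    if (!identical(o, seq_len(nrow(segments)))) {
      stop("segments must be sorted by sample, chromosome, start")
    }
  }
  hdr <- "#chrom\tchromStart\tchromEnd\tname\tscore"
  body <- character(0)
  if (nrow(segments) > 0L) {
    body <- paste(segments$chrom, segments$start_bp - 1L, segments$end_bp,
                  segments$sample_id, segments$n_snps, sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a BED file written by [write_roh_bed()]
#'
#' @param path BED path.
#' @return data.frame with columns `chrom`, `start_bp` (1-based),
#'   `end_bp`, `sample_id`, `n_snps`.
#' @export
read_roh_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(0), start_bp = integer(0),
                      end_bp = integer(0), sample_id = character(0),
                      n_snps = integer(0), stringsAsFactors = FALSE))
  }
  d <- read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = as.character(d[[1L]]), start_bp = d[[2L]] + 1L,
             end_bp = d[[3L]], sample_id = as.character(d[[4L]]),
             n_snps = d[[5L]], stringsAsFactors = FALSE)
}

#' Write a schema-checked TSV table
#'
#' Tab-separated with one header line; numeric columns are rendered at 6
#' significant digits; rows are written in the order given.
#'
#' @param rows a data.frame.
#' @param schema character vector of required column names, in order.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, schema, path) {
  if (!identical(names(rows), schema)) {
    stop("table columns (", paste(names(rows), collapse = ","),
         ") do not match schema (", paste(schema, collapse = ","), ")")
  }
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6L)
  }
  write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

#' Column schema of the selection-region report
#'
#' The column set mirrors the classic selection-scan region table: position,
#' size in kb, count of SNPs beyond the |iHS| threshold, total SNPs, the
#' most extreme score and its marker, nominal and permutation-corrected
#' empirical p-values, and a genes placeholder to be joined against a gene
#' BED by the user.
#'
#' @return character vector of column names.
#' @export
region_table_schema <- function() {
  c("chrom", "start_bp", "end_bp", "size_kb", "n_extreme", "n_snps",
    "max_abs_ihs", "max_snp_id", "p_nominal", "p_empirical", "genes")
}
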