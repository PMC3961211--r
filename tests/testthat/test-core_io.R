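# core_io: VCF / PLINK text / BED / TSV round trips and conventions.

make_vcf <- function(lines) {
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  path
}

vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

test_that("read_vcf decodes genotypes and skips multi-allelic records", {
  path <- make_vcf(c(
    vcf_header(c("sA", "sB", "sC")),
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tC\tA,T\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t300\trs3\tT\tC\t.\tPASS\t.\tGT\t0/0\t./.\t0/1"))
  g <- suppressMessages(suppressWarnings(read_vcf(path)))
  expect_s3_class(g, "genotype_matrix")
  expect_equal(attr(g, "n_skipped"), 1L)
  expect_equal(nrow(g$variants), 2L)
  expect_equal(unname(g$calls[, "rs1"]), c(0L, 1L, 2L))
  expect_equal(unname(g$calls[, "rs3"]), c(0L, NA, 1L))
})

test_that("read_vcf require_phased builds ancestral-coded haplotypes", {
  # AA=ref at every site: haplotype bit equals the ALT-carrier bit
  path <- make_vcf(c(
    vcf_header(c("sA", "sB")),
    "1\t100\trs1\tA\tG\t.\tPASS\tAA=A\tGT\t0|1\t1|1",
    "1\t200\trs2\tC\tT\t.\tPASS\tAA=C\tGT\t0|0\t1|0"))
  h <- suppressWarnings(read_vcf(path, require_phased = TRUE))
  expect_s3_class(h, "haplotype_matrix")
  expect_equal(unname(h$haps[, 1L]), c(0L, 1L, 1L, 1L))
  expect_equal(unname(h$haps[, 2L]), c(0L, 0L, 1L, 0L))
  # AA=alt flips the coding
  path2 <- make_vcf(c(
    vcf_header(c("sA", "sB")),
    "1\t100\trs1\tA\tG\t.\tPASS\tAA=G\tGT\t0|1\t1|1"))
  h2 <- suppressWarnings(read_vcf(path2, require_phased = TRUE))
  expect_equal(unname(h2$haps[, 1L]), c(1L, 0L, 0L, 0L))
})

test_that("read_vcf errors on unphased genotypes when phasing is required", {
  path <- make_vcf(c(
    vcf_header("sA"),
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0|1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0/1"))
  expect_error(suppressWarnings(read_vcf(path, require_phased = TRUE)),
               "rs2")
})

test_that("ancestral side TSV fills in missing AA annotations", {
  path <- make_vcf(c(
    vcf_header(c("sA", "sB")),
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1"))
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tancestral", "1\t100\tG"), tsv)
  h <- suppressWarnings(read_vcf(path, require_phased = TRUE,
                                 ancestral_tsv = tsv))
  expect_equal(h$variants$ancestral, "G")
  expect_equal(unname(h$haps[, 1L]), c(1L, 0L, 0L, 0L))
})

test_that("read_plink_text decodes alleles under the counted-allele rule", {
  ped <- tempfile(fileext = ".ped")
  map <- tempfile(fileext = ".map")
  writeLines(c("f1 s1 0 0 0 -9 A A 0 0", "f2 s2 0 0 0 -9 A G C C"), ped)
  writeLines(c("1\tm1\t0\t1000", "1\tm2\t0\t2000"), map)
  g <- read_plink_text(ped, map)
  # m1: alleles seen A then G -> counted G: s1 = 0 copies, s2 = 1
  expect_equal(unname(g$calls[, 1L]), c(0L, 1L))
  # m2: "0 0" decodes to missing
  expect_equal(unname(g$calls[, 2L]), c(NA_integer_, 2L))
  expect_error(
    {
      writeLines(c("f1 s1 0 0 0 -9 A A"), ped)
      read_plink_text(ped, map)
    },
    "line 1")
})

test_that("PLINK text round trip is exact over 100 markers", {
  set.seed(42)
  calls <- matrix(sample(c(0:2, NA), 5 * 100, replace = TRUE), nrow = 5)
  g <- tiny_geno(calls)
  prefix <- tempfile()
  write_plink_text(g, prefix)
  g2 <- read_plink_text(paste0(prefix, ".ped"), paste0(prefix, ".map"))
  expect_identical(g2$calls, g$calls)
  expect_equal(g2$variants$pos, g$variants$pos)
  expect_equal(g2$variants$id, g$variants$id)
})

test_that("VCF and PLINK text of the same cohort agree", {
  set.seed(7)
  calls <- matrix(sample(c(0:2, NA), 4 * 30, replace = TRUE,
                         prob = c(0.3, 0.3, 0.3, 0.1)), nrow = 4)
  g <- tiny_geno(calls)
  vp <- tempfile(fileext = ".vcf")
  write_vcf(g, vp)
  gv <- suppressWarnings(read_vcf(vp))
  prefix <- tempfile()
  write_plink_text(g, prefix)
  gp <- read_plink_text(paste0(prefix, ".ped"), paste0(prefix, ".map"))
  expect_identical(unname(gv$calls), unname(gp$calls))
})

test_that("write_roh_bed follows BED coordinates and round-trips", {
  segs <- data.frame(
    sample_id = c("s1", "s1", "s2"), chrom = "1",
    start_bp = c(1000001L, 5000001L, 2000001L),
    end_bp = c(2000000L, 6000000L, 3000000L),
    length_bp = 999999L, n_snps = c(300L, 310L, 320L), n_het = 0L,
    n_missing = 0L, stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".bed")
  write_roh_bed(segs, path)
  lines <- readLines(path)
  expect_equal(lines[2L], "1\t1000000\t2000000\ts1\t300")
  back <- read_roh_bed(path)
  expect_equal(back$start_bp, segs$start_bp)
  expect_equal(back$end_bp, segs$end_bp)
  expect_equal(nrow(back), 3L)
  # empty list -> header-only file
  write_roh_bed(segs[0, ], path)
  expect_equal(length(readLines(path)), 1L)
  # unsorted input refused
  expect_error(write_roh_bed(segs[c(2, 1, 3), ], path), "sorted")
})

test_that("write_table enforces its schema and renders region columns", {
  rows <- data.frame(a = c(1.2345678, 2), b = c("x", "y"),
                     stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_table(rows, c("a", "b"), path)
  expect_equal(length(readLines(path)), 3L)
  write_table(rows[0, ], c("a", "b"), path)
  expect_equal(length(readLines(path)), 1L)
  expect_error(write_table(rows, c("a", "c"), path), "schema")
  reg <- empty_regions <- isletpop:::empty_regions()
  write_table(reg, region_table_schema(), path)
  expect_equal(strsplit(readLines(path), "\t")[[1L]], region_table_schema())
})
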