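# Pipeline orchestration: qc -> structure -> roh -> selection over a flat
# key:value config, with a one-command synthetic demo.  Every output is a
# text table; a manifest lists each output with its md5 so reruns can be
# compared byte for byte.

#' Read a flat key:value pipeline config
#'
#' One `key: value` pair per line (a YAML subset); `#` starts a comment.
#' Values are parsed as numbers when they look numeric, as logicals for
#' true/false, and split on commas for list-valued keys.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^:]+):(.*)$", ln))[[1L]]
    if (length(kv) != 3L) stop("bad config line: ", ln)
    key <- trimws(kv[2L]); val <- trimws(kv[3L])
    if (grepl(",", val)) {
      val <- trimws(strsplit(val, ",")[[1L]])
    }
    num <- suppressWarnings(as.numeric(val))
    if (!anyNA(num)) {
      val <- num
    } else if (length(val) == 1L && tolower(val) %in% c("true", "false")) {
      val <- tolower(val) == "true"
    }
    cfg[[key]] <- val
  }
  cfg
}

default_pipeline_config <- function() {
  list(seed = 1, stages = c("qc", "structure", "roh", "selection"),
       synthetic = TRUE, n_pops = 2, samples_per_pop = 80, n_snps = 12000,
       fst = 0.003, inbreeding_f = 0.01, snp_spacing_bp = 3000,
       min_call_rate = 0.98, min_maf = 0.01, hwe_alpha = 1e-3,
       hwe_method = "exact",
       pca_k = 4, fst_n_perm = 0, accessible_gb = 2.84,
       window_snps = 50, window_span_kb_cap = 5000, max_het_per_window = 1,
       max_missing_per_window = 5, hit_proportion_threshold = 0.05,
       min_segment_kb = 500, min_segment_snps = 50,
       sel_n_snps = 10000, sel_samples = 50, sel_derived_freq = 0.7,
       sel_shared_len_bp = 5e5, sel_background_len_bp = 2e4,
       sel_min_maf = 0.05, sel_window_kb = 100, sel_threshold = 4,
       sel_n_perm = 1000)
}

write_config <- function(cfg, path) {
  writeLines(vapply(names(cfg), function(k) {
    paste0(k, ": ", paste(cfg[[k]], collapse = ","))
  }, character(1)), path)
}

#' Run the full pipeline
#'
#' Stages run in the fixed order qc, structure, roh, selection; each stage
#' reads only prior-stage outputs.  A failing stage aborts with its name;
#' partial outputs are preserved.  The config (with defaults filled in) is
#' echoed to `config.txt` and a `manifest.tsv` lists every output with a
#' content hash.
#'
#' @param config a named list or the path of a [read_pipeline_config()]
#'   file.  With `synthetic: true` (default) inputs are generated by
#'   [gen_balding_nichols()] (plus planted tracts for the first six
#'   samples and a planted-sweep haplotype set for the selection stage);
#'   otherwise `vcf` / (`ped`, `map`) and `labels_tsv` paths are read.
#' @param out_dir output directory (created).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("isletpop_run_")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(..., "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  write_config(cfg, file.path(out_dir, "config.txt"))
  for (k in names(cfg)) logf("param ", k, " = ",
                             paste(cfg[[k]], collapse = ","))
  seed <- as.integer(cfg$seed)

  stage <- function(name, expr) {
    if (!name %in% cfg$stages) {
      logf("stage ", name, ": skipped")
      return(invisible(NULL))
    }
    tryCatch(expr, error = function(e) {
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # ---- inputs -------------------------------------------------------
  if (isTRUE(cfg$synthetic)) {
    sim <- gen_balding_nichols(sim_config(
      seed = seed, n_pops = cfg$n_pops,
      samples_per_pop = cfg$samples_per_pop, n_snps = cfg$n_snps,
      fst = cfg$fst, inbreeding_f = cfg$inbreeding_f,
      snp_spacing_bp = cfg$snp_spacing_bp))
    geno <- sim$geno
    info <- sim$info
    span <- max(geno$variants$pos)
    lens <- c(0.7e6, 1.5e6, 3e6, 6e6, 12e6, 20e6)
    lens <- lens[lens < span * 0.8]
    tr <- tract_spec(sample_id = geno$samples[seq_along(lens)],
                     chrom = geno$variants$chrom[1L],
                     start_bp = rep(round(span * 0.1), length(lens)),
                     end_bp = round(span * 0.1) + lens,
                     het_error_rate = 0.001)
    geno <- plant_roh(geno, tr, seed = seed + 1L)
    logf("synthetic input: ", length(geno$samples), " samples x ",
         nrow(geno$variants), " SNPs; ", nrow(tr), " planted tracts")
  } else {
    if (!is.null(cfg$vcf)) {
      geno <- read_vcf(cfg$vcf)
    } else {
      geno <- read_plink_text(cfg$ped, cfg$map)
    }
    lab <- read.table(cfg$labels_tsv, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    info <- sample_info(lab[[1L]], lab[[2L]])
    logf("input: ", length(geno$samples), " samples x ",
         nrow(geno$variants), " SNPs")
  }
  labels <- match_labels(geno, info)

  # ---- qc -----------------------------------------------------------
  stage("qc", {
    qc <- qc_pipeline(geno, cfg$min_call_rate, cfg$min_maf, cfg$hwe_alpha,
                      cfg$hwe_method)
    geno <- qc$geno
    labels <- match_labels(geno, info)
    rep <- qc$report
    write_table(data.frame(metric = c("samples_removed",
                                      "snps_removed_chrom",
                                      "snps_removed_maf",
                                      "snps_removed_hwe",
                                      "snps_retained"),
                           value = c(rep$n_samples_removed,
                                     rep$n_snps_removed_chrom,
                                     rep$n_snps_removed_maf,
                                     rep$n_snps_removed_hwe,
                                     nrow(geno$variants))),
                c("metric", "value"), file.path(out_dir, "qc_report.tsv"))
    logf("stage qc: ", nrow(geno$variants), " SNPs retained")
  })

  # ---- structure ----------------------------------------------------
  stage("structure", {
    groups <- sort(unique(labels))
    pc <- pca(geno, k = min(cfg$pca_k, length(geno$samples) - 1L))
    sc <- data.frame(sample_id = geno$samples, group = labels,
                     pc$scores, stringsAsFactors = FALSE)
    write_table(sc, names(sc), file.path(out_dir, "pca_scores.tsv"))
    rows <- list()
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (i >= j) next
      pair <- c(groups[i], groups[j])
      fst <- fst_test(geno, labels, pair, "hudson",
                      n_perm = cfg$fst_n_perm, seed = seed)
      lam <- lambda_gc(geno, labels, pair)
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = pair[1L], group2 = pair[2L], fst = fst$estimate,
        fst_ci_low = fst$ci_low, fst_ci_high = fst$ci_high,
        fst_p = fst$p_value, lambda_gc = lam, stringsAsFactors = FALSE)
    }
    fst_tab <- do.call(rbind, rows)
    write_table(fst_tab, names(fst_tab), file.path(out_dir, "fst_lambda.tsv"))
    inb <- inbreeding_coefficient(geno)
    cmpi <- compare_groups(inb$f_hat, labels, groups[1L])
    write_table(cmpi, names(cmpi), file.path(out_dir, "inbreeding.tsv"))
    logf("stage structure: ", nrow(fst_tab), " pair(s)")
  })

  # ---- roh ----------------------------------------------------------
  stage("roh", {
    params <- roh_params(cfg$window_snps, cfg$window_span_kb_cap,
                         cfg$max_het_per_window, cfg$max_missing_per_window,
                         cfg$hit_proportion_threshold, cfg$min_segment_kb,
                         cfg$min_segment_snps)
    segs <- call_roh(geno, params)
    write_roh_bed(segs, file.path(out_dir, "roh_segments.bed"))
    acc <- cfg$accessible_gb * 1e9
    sm <- summarize_roh_groups(segs, geno$samples, labels,
                               reference_group = sort(unique(labels))[1L],
                               accessible_bp = acc)
    write_table(sm$by_class, names(sm$by_class),
                file.path(out_dir, "roh_by_class.tsv"))
    write_table(sm$froh, names(sm$froh), file.path(out_dir, "roh_froh.tsv"))
    logf("stage roh: ", nrow(segs), " segments")
  })

  # ---- selection ----------------------------------------------------
  stage("selection", {
    if (isTRUE(cfg$synthetic)) {
      scfg <- sim_config(seed = seed + 2L, n_pops = 1L,
                         samples_per_pop = cfg$sel_samples,
                         n_snps = cfg$sel_n_snps,
                         snp_spacing_bp = cfg$snp_spacing_bp)
      sw <- sweep_spec(core_index = round(cfg$sel_n_snps / 2),
                       derived_freq = cfg$sel_derived_freq,
                       shared_len_mean_bp = cfg$sel_shared_len_bp,
                       background_shared_len_mean_bp =
                         cfg$sel_background_len_bp)
      haps <- gen_sweep_haplotypes(scfg, sw)$haps
    } else {
      haps <- read_vcf(cfg$phased_vcf, require_phased = TRUE,
                       ancestral_tsv = cfg$ancestral_tsv)
    }
    tab <- ihs_scan(haps, min_maf = cfg$sel_min_maf)
    write_table(tab, names(tab), file.path(out_dir, "ihs.tsv"))
    reg <- region_scan(tab, window_bp = cfg$sel_window_kb * 1000,
                       extreme_threshold = cfg$sel_threshold,
                       n_perm = cfg$sel_n_perm, seed = seed)
    write_table(reg, region_table_schema(),
                file.path(out_dir, "regions.tsv"))
    logf("stage selection: ", nrow(reg), " region(s)")
  })

  # ---- manifest -----------------------------------------------------
  files <- setdiff(list.files(out_dir), c("manifest.tsv", "run.log"))
  man <- data.frame(file = files,
                    md5 = unname(tools::md5sum(file.path(out_dir, files))),
                    stringsAsFactors = FALSE)
  write.table(man, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' One-command synthetic demo
#'
#' Generates a small two-population study (planted autozygous tracts, one
#' planted sweep), runs the full pipeline and renders `report.txt` with the
#' structure / RoH / selection summary tables.
#'
#' @param seed RNG seed.
#' @param out_dir output directory.
#' @param stages stages to run (default all four).
#' @return `out_dir`, invisibly.
#' @export
run_demo <- function(seed = 1L, out_dir = tempfile("isletpop_demo_"),
                     stages = c("qc", "structure", "roh", "selection")) {
  run_pipeline(list(seed = seed, stages = stages), out_dir)
  rpt <- file.path(out_dir, "report.txt")
  cat("isletpop synthetic demo (seed ", seed, ")\n",
      "==========================================\n\n", sep = "", file = rpt)
  show <- function(title, fname) {
    path <- file.path(out_dir, fname)
    if (!file.exists(path)) return(invisible(NULL))
    cat(title, "\n", paste(readLines(path), collapse = "\n"), "\n\n",
        sep = "", file = rpt, append = TRUE)
  }
  show("QC summary", "qc_report.tsv")
  show("Pairwise Fst and genomic-control lambda", "fst_lambda.tsv")
  show("Per-group inbreeding coefficients", "inbreeding.tsv")
  show("RoH classes (% accessible genome, mean sum Mb, SE, p)",
       "roh_by_class.tsv")
  show("F_RoH% at 0.5 / 5 Mb thresholds", "roh_froh.tsv")
  show("Selection regions (|iHS| enrichment)", "regions.tsv")
  invisible(out_dir)
}
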