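# Genomic-control inflation factor, per-sample inbreeding coefficients,
# group comparisons, and PC-based group prediction accuracy.

#' Genomic-control inflation factor between two groups
#'
#' Per SNP a 1-df association chi-square from the 2x2 allele-count table
#' (group x allele, no continuity correction); the inflation factor is the
#' median chi-square divided by the null median of a 1-df chi-square
#' (0.4549364).  SNPs monomorphic in the pooled pair are excluded.
#'
#' @param geno a [genotype_matrix()].
#' @param labels group label per sample.
#' @param pair length-2 character: the two groups ("cases"/"controls").
#' @param stat `"allelic"` (classic 2x2 allele-count chi-square, default)
#'   or `"trend"` (Cochran-Armitage on genotypes).
#' @return the inflation factor (dimensionless); 0 with a warning when all
#'   chi-squares are 0 (degenerate input).
#' @export
lambda_gc <- function(geno, labels, pair, stat = c("allelic", "trend")) {
  stat <- match.arg(stat)
  i1 <- labels == pair[1L]; i2 <- labels == pair[2L]
  if (!any(i1) || !any(i2)) stop("both groups must be non-empty")
  g1 <- geno$calls[i1, , drop = FALSE]
  g2 <- geno$calls[i2, , drop = FALSE]
  if (stat == "allelic") {
    b1 <- colSums(g1, na.rm = TRUE)                 # counted-allele copies
    n1 <- 2 * colSums(!is.na(g1))
    b2 <- colSums(g2, na.rm = TRUE)
    n2 <- 2 * colSums(!is.na(g2))
    bt <- b1 + b2; nt <- n1 + n2
    testable <- nt > 0 & bt > 0 & bt < nt & n1 > 0 & n2 > 0
    # Pearson chi-square on the 2x2 table rows (b1, n1-b1), (b2, n2-b2)
    num <- (b1 * (n2 - b2) - b2 * (n1 - b1))^2 * nt
    den <- n1 * n2 * bt * (nt - bt)
    x2 <- (num / den)[testable]
  } else {
    x2 <- rep(NA_real_, ncol(g1))
    grp <- c(rep(0L, nrow(g1)), rep(1L, nrow(g2)))
    gg <- rbind(g1, g2)
    for (j in seq_len(ncol(gg))) {
      ok <- !is.na(gg[, j])
      x <- gg[ok, j]; y <- grp[ok]
      if (length(unique(x)) < 2L || length(unique(y)) < 2L) next
      r <- suppressWarnings(stats::cor(x, y))
      x2[j] <- length(x) * r^2
    }
    x2 <- x2[!is.na(x2)]
  }
  if (length(x2) == 0L) stop("no testable SNPs for lambda_GC")
  if (length(x2) < 100L) warning("fewer than 100 testable SNPs")
  if (all(x2 == 0)) {
    warning("all chi-squares are zero; lambda_GC degenerate")
    return(0)
  }
  median(x2) / qchisq(0.5, df = 1)
}

#' Per-sample genomic inbreeding coefficients
#'
#' `F = (O_hom - E_hom) / (L - E_hom)` where `O_hom` is the observed
#' homozygote count over the sample's `L` non-missing SNPs and
#' `E_hom = sum_j [1 - 2 p_j (1 - p_j) * 2 n_j / (2 n_j - 1)]`, with `p_j`
#' the cohort allele frequency and `n_j` the number of individuals it was
#' estimated from (the small-sample factor makes the expectation unbiased).
#'
#' @param geno a post-QC [genotype_matrix()].
#' @return data.frame with columns `sample_id`, `f_hat`, `o_hom`, `e_hom`,
#'   `n_snps_used`; `f_hat` is `NA` (flagged) when `L = E_hom`.
#' @export
inbreeding_coefficient <- function(geno) {
  g <- geno$calls
  nj <- colSums(!is.na(g))
  p <- colMeans(g, na.rm = TRUE) / 2
  usable <- nj > 1L & !is.na(p)
  # expected per-SNP homozygosity, unbiased for the sampling of p
  e_term <- 1 - 2 * p * (1 - p) * (2 * nj / (2 * nj - 1))
  hom <- !is.na(g) & g != 1L
  nm <- !is.na(g)
  hom[, !usable] <- FALSE
  nm[, !usable] <- FALSE
  o_hom <- rowSums(hom)
  L <- rowSums(nm)
  e_hom <- as.vector(nm %*% ifelse(usable, e_term, 0))
  denom <- L - e_hom
  f_hat <- ifelse(abs(denom) < .Machine$double.eps^0.5, NA_real_,
                  (o_hom - e_hom) / denom)
  data.frame(sample_id = geno$samples, f_hat = f_hat, o_hom = o_hom,
             e_hom = e_hom, n_snps_used = L, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Group means, standard errors and Welch t-tests against a reference
#'
#' @param values numeric value per sample.
#' @param labels group label per sample.
#' @param reference_group the group every other group is tested against
#'   (two-sided Welch t-test); the reference row gets `t = 0, p = 1`.
#' @return data.frame with columns `group`, `n`, `mean`, `se`, `t`, `p`.
#'   Groups with fewer than 2 samples are excluded with a warning.
#' @export
compare_groups <- function(values, labels, reference_group) {
  stopifnot(length(values) == length(labels))
  labels <- as.character(labels)
  if (!reference_group %in% labels) stop("reference group not found")
  sizes <- table(labels)
  small <- names(sizes)[sizes < 2L]
  if (length(small) > 0L) {
    warning("excluding single-sample group(s): ",
            paste(small, collapse = ", "))
  }
  groups <- setdiff(names(sizes)[sizes >= 2L], character(0))
  ref <- values[labels == reference_group]
  out <- lapply(groups, function(g) {
    v <- values[labels == g]
    if (g == reference_group) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- t.test(v, ref)
    }
    data.frame(group = g, n = length(v), mean = mean(v),
               se = sd(v) / sqrt(length(v)),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Accuracy of predicting group labels from leading PCs
#'
#' Fits a multinomial logistic model (ridge-regularized with a negligible
#' penalty) on a stratified bootstrap resample per iteration and scores the
#' fraction of the full cohort whose most-probable predicted group matches
#' the true label.
#'
#' @param pcs numeric matrix of PC scores (samples x components; typically
#'   the first 4).
#' @param labels true group label per sample; every group needs at least 2
#'   samples.
#' @param n_iter number of bootstrap refits.
#' @param seed RNG seed.
#' @return list with `min`, `max`, `mean` and the per-iteration
#'   `accuracies`.
#' @export
predict_group_accuracy <- function(pcs, labels, n_iter = 100L, seed = 1L) {
  pcs <- as.matrix(pcs)
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 groups")
  sizes <- table(labels)
  if (any(sizes < 2L)) {
    stop("group(s) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  if (n_iter < 1L) stop("n_iter must be >= 1")
  set.seed(seed)
  idx_by_group <- split(seq_along(labels), labels)
  acc <- vapply(seq_len(n_iter), function(it) {
    boot <- unlist(lapply(idx_by_group, function(i) {
      sample(i, length(i), replace = TRUE)
    }), use.names = FALSE)
    fit <- glmnet::glmnet(pcs[boot, , drop = FALSE], labels[boot],
                          family = "multinomial", lambda = c(0.01, 1e-4))
    pred <- predict(fit, newx = pcs, type = "class", s = 1e-4)
    mean(pred == as.character(labels))
  }, numeric(1))
  list(min = min(acc), max = max(acc), mean = mean(acc), accuracies = acc)
}
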