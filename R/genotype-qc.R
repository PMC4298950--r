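#' Genetic variation of one SNP
#'
#' Default metric is the minor-allele frequency of the 1/2/3-coded calls:
#' alternate-allele count is `sum(call - 1)` over samples and MAF is
#' `min(f, 1 - f)` with `f = alt count / (2 n)`. The alternative metric
#' `genotype_fraction` is the fraction of samples carrying a non-modal
#' genotype.
#'
#' @param calls integer vector of genotype codes in \{1, 2, 3\}.
#' @param metric `"maf"` (default) or `"genotype_fraction"`.
#' @return variation in \[0, 0.5\] (maf) or \[0, 1\] (genotype_fraction).
#' @export
genotype_variation <- function(calls, metric = c("maf", "genotype_fraction")) {
  metric <- match.arg(metric)
  if (length(calls) == 0L) stop("at least one call required")
  if (!all(calls %in% 1:3)) stop("calls must be coded 1/2/3")
  if (metric == "maf") {
    f <- sum(calls - 1L) / (2 * length(calls))
    min(f, 1 - f)
  } else {
    1 - max(table(calls)) / length(calls)
  }
}

#' Filter SNPs with low genetic variation
#'
#' Keeps a SNP iff its variation, computed on the given sample group, is at
#' least `threshold` (SNPs with less than the threshold are removed; the
#' boundary is kept). When `whole_set_kept` is supplied, SNPs removed from
#' the whole-sample analysis are removed from the subgroup as well (the
#' cascade rule: a whole-set removal propagates to subgroups).
#'
#' @param genotypes a `genotype_matrix`.
#' @param threshold minimum variation (default 0.25).
#' @param samples sample ids defining the analysis group (default: all).
#' @param metric see [genotype_variation()].
#' @param whole_set_kept optional character vector of SNP ids kept by the
#'   whole-sample run.
#' @return filtered `genotype_matrix`.
#' @export
filter_low_variation <- function(genotypes, threshold = 0.25, samples = NULL,
                                 metric = c("maf", "genotype_fraction"),
                                 whole_set_kept = NULL) {
  metric <- match.arg(metric)
  if (is.null(samples)) samples <- colnames(genotypes$calls)
  if (length(samples) == 0L) stop("sample group is empty")
  if (!all(samples %in% colnames(genotypes$calls))) {
    stop("unknown sample(s) in group")
  }
  calls <- genotypes$calls[, samples, drop = FALSE]
  v <- apply(calls, 1, genotype_variation, metric = metric)
  keep <- v >= threshold
  if (!is.null(whole_set_kept)) {
    keep <- keep & genotypes$snps$snp_id %in% whole_set_kept
  }
  .subset_genotypes(genotypes, keep)
}

#' Filter SNPs with a low-confidence call
#'
#' Removes a SNP if any analyzed sample has a call confidence strictly
#' below `min_conf` (a confidence of exactly `min_conf` is kept).
#'
#' @param genotypes a `genotype_matrix`.
#' @param min_conf minimum per-call confidence (default 0.9).
#' @param samples sample ids defining the analysis group (default: all).
#' @return filtered `genotype_matrix`.
#' @export
filter_low_confidence <- function(genotypes, min_conf = 0.9, samples = NULL) {
  if (is.null(samples)) samples <- colnames(genotypes$confidences)
  conf <- genotypes$confidences[, samples, drop = FALSE]
  keep <- apply(conf, 1, min) >= min_conf
  .subset_genotypes(genotypes, keep)
}

#' Exclude SNPs in copy-number or mosaic-gained regions
#'
#' Removes a SNP if its position lies in any reported CNV region of any
#' analyzed sample (closed-interval membership, boundaries included), or on
#' a chromosome reported as gained in a sample with a mosaic karyotype.
#'
#' @param genotypes a `genotype_matrix`.
#' @param regions list with `cnv` (data frame: chrom, start, end; a sample
#'   column is allowed and ignored for membership — any sample's region
#'   excludes the SNP) and optional `mosaic` (data frame: sample, chrom).
#' @return filtered `genotype_matrix`.
#' @export
exclude_region_snps <- function(genotypes, regions) {
  snps <- genotypes$snps
  drop <- rep(FALSE, nrow(snps))
  cnv <- regions$cnv
  if (!is.null(cnv) && nrow(cnv) > 0L) {
    if (any(cnv$start > cnv$end)) stop("malformed region (start > end)")
    for (i in seq_len(nrow(cnv))) {
      drop <- drop | (snps$chrom == cnv$chrom[i] &
                        .point_in(snps$pos, cnv$start[i], cnv$end[i]))
    }
  }
  mosaic <- regions$mosaic
  if (!is.null(mosaic) && nrow(mosaic) > 0L) {
    drop <- drop | snps$chrom %in% unique(mosaic$chrom)
  }
  .subset_genotypes(genotypes, !drop)
}

#' Run the SNP-side QC cascade for one or more analysis groups
#'
#' Applies, per group: the variation filter (with whole-set propagation for
#' subgroups), the confidence filter, and the CNV/mosaic region exclusion.
#' The whole-sample group must be named `all` (it is added when absent).
#'
#' @param genotypes a `genotype_matrix`.
#' @param groups named list of sample-id vectors (e.g. hESC, hiPSC, all).
#' @param threshold variation threshold (default 0.25).
#' @param min_conf confidence threshold (default 0.9).
#' @param regions exclusion regions, see [exclude_region_snps()].
#' @param metric variation metric, see [genotype_variation()].
#' @return list with one filtered `genotype_matrix` per group and a
#'   `report` of per-step SNP counts.
#' @export
run_genotype_qc <- function(genotypes, groups = NULL, threshold = 0.25,
                            min_conf = 0.9, regions = NULL,
                            metric = c("maf", "genotype_fraction")) {
  metric <- match.arg(metric)
  if (is.null(groups)) groups <- list(all = colnames(genotypes$calls))
  if (!"all" %in% names(groups)) {
    groups$all <- colnames(genotypes$calls)
  }
  report <- list(n_input = nrow(genotypes$snps))

  gt_all <- filter_low_variation(genotypes, threshold,
                                 samples = groups$all, metric = metric)
  kept_all <- gt_all$snps$snp_id

  out <- list()
  for (g in names(groups)) {
    gt <- if (g == "all") gt_all else {
      filter_low_variation(genotypes, threshold, samples = groups[[g]],
                           metric = metric, whole_set_kept = kept_all)
    }
    n_var <- nrow(gt$snps)
    gt <- filter_low_confidence(gt, min_conf, samples = groups[[g]])
    n_conf <- nrow(gt$snps)
    if (!is.null(regions)) gt <- exclude_region_snps(gt, regions)
    report[[g]] <- list(after_variation = n_var, after_confidence = n_conf,
                        after_regions = nrow(gt$snps))
    out[[g]] <- gt
  }
  list(genotypes = out, report = report)
}
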