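#' Simulate SNP genotype calls with confidences
#'
#' Draws an allele frequency per SNP and samples genotypes under
#' Hardy-Weinberg proportions, coded 1 (homozygous reference),
#' 2 (heterozygous), 3 (homozygous alternate). Each call carries a
#' confidence in (0, 1]; a configurable fraction of non-causal SNPs get one
#' call below 0.9 to exercise the confidence filter. SNP positions are
#' placed inside genes, in the 5 kb flanks, and far from any gene.
#'
#' SNPs designated causal by `causal_plan` are placed inside their target
#' feature span, drawn at allele frequencies in [0.35, 0.5], redrawn until
#' the sample minor-allele frequency is at least 0.25 with at least two
#' genotype classes, and given confidences of at least 0.9 throughout, so
#' that planted associations are testable after quality control.
#'
#' @param config a [sim_config()] object.
#' @param annotation a `feature_annotation` from [simulate_annotation()].
#' @param causal_plan optional data frame (snp_id, feature_id, level, chrom,
#'   start, end) fixing position windows for causal SNPs; built internally
#'   by [simulate_study()].
#' @param avoid_regions optional data frame (chrom, start, end) of intervals
#'   causal SNPs must not fall into (e.g. planted CNV segments).
#' @return object of class `genotype_matrix`: list with `snps` (snp_id,
#'   chrom, pos, ref, alt), `calls` and `confidences` (SNP x sample
#'   matrices), and `samples` (sample/group map).
#' @export
simulate_genotypes <- function(config, annotation, causal_plan = NULL,
                               avoid_regions = NULL) {
  validate_sim_config(config)
  set.seed(config$seed + 202L)
  smp <- .sim_samples(config)
  n <- config$n_samples
  n_snps <- config$n_snps
  n_causal <- if (is.null(causal_plan)) 0L else nrow(causal_plan)

  genes <- annotation$genes
  bases <- c("A", "C", "G", "T")

  snp_id <- sprintf("SNP_%04d", seq_len(n_snps))
  chrom <- character(n_snps); pos <- integer(n_snps)

  ## causal SNPs first: inside their target feature
  if (n_causal > 0L) {
    for (i in seq_len(n_causal)) {
      chrom[i] <- causal_plan$chrom[i]
      for (try in 1:200) {
        p <- causal_plan$start[i] +
          sample.int(causal_plan$end[i] - causal_plan$start[i] + 1L, 1L) - 1L
        ok <- TRUE
        if (!is.null(avoid_regions) && nrow(avoid_regions) > 0L) {
          hit <- avoid_regions$chrom == chrom[i] &
            .point_in(p, avoid_regions$start, avoid_regions$end)
          ok <- !any(hit)
        }
        if (ok) break
      }
      pos[i] <- p
    }
  }

  ## remaining SNPs: ~60% inside genes, 20% in 5 kb flanks, 20% far away
  for (i in seq(n_causal + 1L, length.out = n_snps - n_causal)) {
    cat_draw <- stats::runif(1)
    g <- genes[sample.int(nrow(genes), 1L), ]
    if (cat_draw < 0.6) {
      chrom[i] <- g$chrom
      pos[i] <- g$start + sample.int(g$end - g$start + 1L, 1L) - 1L
    } else if (cat_draw < 0.8) {
      chrom[i] <- g$chrom
      off <- sample.int(5000L, 1L)
      pos[i] <- if (stats::runif(1) < 0.5) max(1L, g$start - off) else g$end + off
    } else {
      chrom[i] <- sample(names(config$chrom_lengths), 1L)
      pos[i] <- sample.int(config$chrom_lengths[[chrom[i]]], 1L)
    }
  }

  ref <- sample(bases, n_snps, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))

  calls <- matrix(0L, n_snps, n, dimnames = list(snp_id, smp$sample))
  conf <- matrix(stats::runif(n_snps * n, 0.9, 1), n_snps, n,
                 dimnames = list(snp_id, smp$sample))

  maf <- stats::runif(n_snps, config$maf_range[1], config$maf_range[2])
  for (i in seq_len(n_snps)) {
    if (i <= n_causal) {
      maf[i] <- stats::runif(1, 0.35, 0.5)
      for (try in 1:100) {
        g <- stats::rbinom(n, 2, maf[i]) + 1L
        f <- sum(g - 1L) / (2 * n)
        if (min(f, 1 - f) >= 0.25 && length(unique(g)) >= 2L) break
      }
      calls[i, ] <- g
    } else {
      calls[i, ] <- stats::rbinom(n, 2, maf[i]) + 1L
    }
  }

  ## sprinkle low-confidence calls on non-causal SNPs
  if (n_snps > n_causal && config$low_conf_fraction > 0) {
    pool <- seq(n_causal + 1L, n_snps)
    n_low <- round(length(pool) * config$low_conf_fraction)
    if (n_low > 0L) {
      low <- sample(pool, n_low)
      for (i in low) conf[i, sample.int(n, 1L)] <- stats::runif(1, 0.5, 0.899)
    }
  }

  gt <- list(snps = data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                               ref = ref, alt = alt, stringsAsFactors = FALSE),
             calls = calls, confidences = conf, samples = smp)
  class(gt) <- "genotype_matrix"
  gt
}

## drop SNPs by id, keeping shapes aligned
.subset_genotypes <- function(gt, keep) {
  gt$snps <- gt$snps[keep, , drop = FALSE]
  rownames(gt$snps) <- NULL
  gt$calls <- gt$calls[keep, , drop = FALSE]
  gt$confidences <- gt$confidences[keep, , drop = FALSE]
  gt
}
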