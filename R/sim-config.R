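#' Simulation configuration
#'
#' Parameters controlling the synthetic study generator. Defaults emulate the
#' design of a small pluripotent stem cell panel: 20 samples in three groups
#' (9 hESC, 8 hiPSC, 3 fibroblast lines), two synthetic 10 Mb chromosomes,
#' gene/transcript/exon annotation, SNP genotypes coded 1/2/3 with per-call
#' confidences, per-sample CNV segments with dosage effects, and probe-level
#' expression with GC-dependent antigenomic background controls.
#'
#' Effects are planted additively on the log2 scale: a causal SNP shifts its
#' target feature by `eqtl_effect` per alternate-allele dose, and a CNV event
#' shifts all features of the affected gene by `cnv_effect` per copy-state
#' step (gain +, loss -). Probe-level Gaussian noise has SD `noise_sd`.
#'
#' @param n_samples total number of samples.
#' @param group_sizes named integer vector of samples per group; must sum to
#'   `n_samples`.
#' @param n_genes number of genes, split across `chrom_lengths`.
#' @param transcripts_per_gene integer range (min, max) of transcripts.
#' @param exons_per_transcript integer range (min, max) of exons.
#' @param n_snps number of SNPs (includes the causal ones).
#' @param maf_range uniform range of simulated allele frequencies.
#' @param eqtl_effect planted additive genotype effect, log2 units per allele
#'   dose.
#' @param cnv_effect planted copy-state effect, log2 units per state step.
#' @param noise_sd per-probe Gaussian noise SD, log2 units.
#' @param n_causal_snps number of SNPs with a planted expression effect.
#' @param n_cnv_events number of genes carrying a planted CNV dosage effect.
#' @param probes_per_set clean probes per probeset.
#' @param low_conf_fraction fraction of non-causal SNPs given one genotype
#'   call with confidence below 0.9 (exercises the confidence filter).
#' @param decoy_fraction fraction of probesets given one extra decoy probe
#'   (flagged cross-hyb/SNP-overlap, or background-level intensity).
#' @param antigenomic_per_bin antigenomic control probes per GC bin.
#' @param gc_range integer GC-count range per 25-mer probe.
#' @param n_motifs number of informative TF motifs to simulate.
#' @param n_planted_motif_hits number of SNPs given a consensus-on-ref,
#'   broken-on-alt motif hit.
#' @param flank flanking sequence length (bp) on each side of a SNP
#'   (default 9: one base short of the longest motif, so every motif can
#'   cover the SNP from any offset while alternative windows stay few).
#' @param chrom_lengths named vector of synthetic chromosome lengths (bp).
#' @param seed integer RNG seed; every generator derives its stream from it.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 20L,
                       group_sizes = c(hESC = 9L, hiPSC = 8L, fibroblast = 3L),
                       n_genes = 60L,
                       transcripts_per_gene = c(1L, 2L),
                       exons_per_transcript = c(2L, 4L),
                       n_snps = 150L,
                       maf_range = c(0.05, 0.5),
                       eqtl_effect = 1.0,
                       cnv_effect = 0.6,
                       noise_sd = 0.5,
                       n_causal_snps = 20L,
                       n_cnv_events = 10L,
                       probes_per_set = 4L,
                       low_conf_fraction = 0.05,
                       decoy_fraction = 0.15,
                       antigenomic_per_bin = 30L,
                       gc_range = c(6L, 18L),
                       n_motifs = 8L,
                       n_planted_motif_hits = 5L,
                       flank = 9L,
                       chrom_lengths = c(chr1 = 1e7, chr2 = 1e7),
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              group_sizes = group_sizes,
              n_genes = as.integer(n_genes),
              transcripts_per_gene = as.integer(transcripts_per_gene),
              exons_per_transcript = as.integer(exons_per_transcript),
              n_snps = as.integer(n_snps),
              maf_range = maf_range,
              eqtl_effect = eqtl_effect,
              cnv_effect = cnv_effect,
              noise_sd = noise_sd,
              n_causal_snps = as.integer(n_causal_snps),
              n_cnv_events = as.integer(n_cnv_events),
              probes_per_set = as.integer(probes_per_set),
              low_conf_fraction = low_conf_fraction,
              decoy_fraction = decoy_fraction,
              antigenomic_per_bin = as.integer(antigenomic_per_bin),
              gc_range = as.integer(gc_range),
              n_motifs = as.integer(n_motifs),
              n_planted_motif_hits = as.integer(n_planted_motif_hits),
              flank = as.integer(flank),
              chrom_lengths = chrom_lengths,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config object to validate.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with(config, {
    if (sum(group_sizes) != n_samples) {
      stop("group_sizes must sum to n_samples")
    }
    if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes)))) {
      stop("group_sizes must be named")
    }
    if (any(c(n_samples, n_genes, n_snps, probes_per_set) < 1L)) {
      stop("all counts must be >= 1")
    }
    if (n_causal_snps < 0L || n_cnv_events < 0L) {
      stop("planted-effect counts must be >= 0")
    }
    if (noise_sd <= 0) stop("noise_sd must be > 0")
    if (transcripts_per_gene[1] < 1L || exons_per_transcript[1] < 1L) {
      stop("feature counts per parent must be >= 1")
    }
    if (maf_range[1] < 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
      stop("maf_range must be an increasing range within [0, 0.5]")
    }
    if (n_causal_snps > n_snps) stop("n_causal_snps cannot exceed n_snps")
    if (n_cnv_events + n_causal_snps > n_genes) {
      stop("need n_genes >= n_cnv_events + n_causal_snps (disjoint targets)")
    }
    if (length(chrom_lengths) < 1L || any(chrom_lengths <= 0)) {
      stop("chrom_lengths must be positive")
    }
  })
  invisible(config)
}

## sample identifiers and group map implied by a config
.sim_samples <- function(config) {
  grp <- rep(names(config$group_sizes), config$group_sizes)
  ids <- unlist(lapply(names(config$group_sizes), function(g) {
    paste0(g, "_", seq_len(config$group_sizes[[g]]))
  }), use.names = FALSE)
  data.frame(sample = ids, group = grp, stringsAsFactors = FALSE)
}
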