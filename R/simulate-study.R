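#' Simulate a complete synthetic study with a truth table
#'
#' Orchestrates all fixture generators: annotation, CNV segments (with
#' planted dosage effects), genotypes (with planted causal SNPs placed
#' inside their target features, disjoint from the dosage genes), probe
#' level expression, motif fixtures with allele flanks, and ChIP-style
#' binding regions. Every planted causal pair is verified to be linkable
#' under the linking rule of its level; generation fails otherwise.
#'
#' Causal SNP targets cycle through the three expression levels (gene,
#' transcript, exon). When `eqtl_effect` is 0 no expression QTLs are
#' planted and the truth table lists zero causal entries; likewise a zero
#' `cnv_effect` leaves the dosage truth empty (segments are still emitted).
#'
#' @param config a [sim_config()] object.
#' @return object of class `sim_study`: list with `config`, `samples`,
#'   `annotation`, `genotypes`, `cnv`, `probes`, `motifs`, `chip_regions`
#'   and `truth` (list: `causal`, `dosage`, `motif_hits`).
#' @export
simulate_study <- function(config = sim_config()) {
  validate_sim_config(config)
  ann <- simulate_annotation(config)
  cnv <- simulate_cnv_segments(config, ann)

  ## causal plan: target features in genes that carry no dosage effect
  set.seed(config$seed + 707L)
  n_causal <- if (config$eqtl_effect != 0) config$n_causal_snps else 0L
  plan <- NULL
  if (n_causal > 0L) {
    free_genes <- setdiff(ann$genes$gene_id, cnv$dosage$gene_id)
    target_genes <- sample(free_genes, n_causal)
    levels <- rep(c("gene", "transcript", "exon"), length.out = n_causal)
    rows <- lapply(seq_len(n_causal), function(i) {
      gid <- target_genes[i]
      if (levels[i] == "gene") {
        g <- ann$genes[ann$genes$gene_id == gid, ]
        data.frame(feature_id = gid, level = "gene", chrom = g$chrom,
                   start = g$start, end = g$end, stringsAsFactors = FALSE)
      } else if (levels[i] == "transcript") {
        tx <- ann$transcripts[ann$transcripts$gene_id == gid, ]
        tx <- tx[sample.int(nrow(tx), 1L), ]
        data.frame(feature_id = tx$transcript_id, level = "transcript",
                   chrom = tx$chrom, start = tx$start, end = tx$end,
                   stringsAsFactors = FALSE)
      } else {
        ex <- ann$exons[ann$exons$gene_id == gid, ]
        ex <- ex[sample.int(nrow(ex), 1L), ]
        data.frame(feature_id = ex$exon_id, level = "exon", chrom = ex$chrom,
                   start = ex$start, end = ex$end, stringsAsFactors = FALSE)
      }
    })
    plan <- do.call(rbind, rows)
    plan$snp_id <- sprintf("SNP_%04d", seq_len(n_causal))
  }

  avoid <- cnv$segments[cnv$segments$planted,
                        c("chrom", "start", "end"), drop = FALSE]
  gt <- simulate_genotypes(config, ann, causal_plan = plan,
                           avoid_regions = avoid)

  causal <- if (is.null(plan)) {
    data.frame(snp_id = character(), feature_id = character(),
               level = character(), effect = numeric(),
               stringsAsFactors = FALSE)
  } else {
    data.frame(snp_id = plan$snp_id, feature_id = plan$feature_id,
               level = plan$level, effect = config$eqtl_effect,
               stringsAsFactors = FALSE)
  }

  probes <- simulate_expression(config, ann, gt, cnv, causal)

  motifs <- simulate_motifs(config, gt$snps)
  ## keep genotype table alleles consistent with planted motif fixtures
  if (nrow(motifs$planted) > 0L) {
    idx <- match(motifs$planted$snp_id, gt$snps$snp_id)
    gt$snps$ref[idx] <- motifs$planted$ref
    gt$snps$alt[idx] <- motifs$planted$alt
  }
  chip <- simulate_chip_regions(config, gt$snps)

  dosage_truth <- cnv$dosage[cnv$dosage$effect != 0, , drop = FALSE]
  rownames(dosage_truth) <- NULL

  study <- list(config = config, samples = .sim_samples(config),
                annotation = ann, genotypes = gt, cnv = cnv, probes = probes,
                motifs = motifs, chip_regions = chip,
                truth = list(causal = causal, dosage = dosage_truth,
                             motif_hits = motifs$planted))
  class(study) <- "sim_study"
  .check_truth_closure(study)
  study
}

## every planted causal pair must satisfy its level's linking rule
.check_truth_closure <- function(study) {
  tr <- study$truth$causal
  if (nrow(tr) == 0L) return(invisible(TRUE))
  snps <- study$genotypes$snps
  ann <- study$annotation
  for (i in seq_len(nrow(tr))) {
    s <- snps[snps$snp_id == tr$snp_id[i], , drop = FALSE]
    ok <- switch(tr$level[i],
      gene = {
        lp <- link_gene(s, ann)
        any(lp$feature_id == tr$feature_id[i])
      },
      transcript = {
        lp <- link_transcript(s, ann)
        any(lp$feature_id == tr$feature_id[i])
      },
      exon = {
        ls <- link_exon_short(s, ann)
        ll <- link_exon_long(s, ann)
        any(ls$feature_id == tr$feature_id[i]) &&
          any(ll$feature_id == tr$feature_id[i])
      },
      stop("unknown truth level: ", tr$level[i]))
    if (!ok) {
      stop(sprintf("planted causal SNP %s is not linkable to %s (%s)",
                   tr$snp_id[i], tr$feature_id[i], tr$level[i]))
    }
  }
  invisible(TRUE)
}
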