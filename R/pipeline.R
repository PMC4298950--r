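#' Pipeline configuration
#'
#' Collects every tunable threshold of the workflow with its default:
#' CNV significance 0.05, SNP significance 0.10, variation threshold 0.25,
#' call confidence 0.9, minimum probes per probeset 3, minimum markers per
#' segment 5, minimum segment length per CNV profile (10 kb hiPSC-style,
#' 50 kb hESC-style), 10000 permutations, PWM gate 0.8 and differential
#' binding threshold 0.2.
#'
#' @param sim a [sim_config()] for the synthetic study (its seed drives
#'   the whole run).
#' @param alpha_cnv adjusted-p cutoff for the CNV scan.
#' @param alpha_snp adjusted-p cutoff for the SNP scans.
#' @param variation_threshold minimum SNP variation.
#' @param variation_metric see [genotype_variation()].
#' @param min_conf minimum genotype call confidence.
#' @param min_probes minimum probes per probeset after QC.
#' @param min_markers minimum markers per CNV segment.
#' @param min_length minimum CNV segment length (bp); default the hiPSC
#'   profile (10 kb).
#' @param n_perm permutations for the weight-statistic null.
#' @param gate PWM relative-score gate.
#' @param diff_threshold differential-binding threshold.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), alpha_cnv = 0.05,
                            alpha_snp = 0.10, variation_threshold = 0.25,
                            variation_metric = "maf", min_conf = 0.9,
                            min_probes = 3L, min_markers = 5L,
                            min_length = 10000L, n_perm = 10000L,
                            gate = 0.8, diff_threshold = 0.2) {
  stopifnot(alpha_cnv > 0, alpha_cnv < 1, alpha_snp > 0, alpha_snp < 1,
            variation_threshold >= 0, variation_threshold <= 0.5,
            min_conf > 0, min_conf <= 1, min_probes >= 1, min_markers >= 1,
            min_length >= 0, n_perm >= 1, gate >= 0, gate <= 1)
  cfg <- list(sim = sim, alpha_cnv = alpha_cnv, alpha_snp = alpha_snp,
              variation_threshold = variation_threshold,
              variation_metric = variation_metric, min_conf = min_conf,
              min_probes = as.integer(min_probes),
              min_markers = as.integer(min_markers),
              min_length = as.integer(min_length),
              n_perm = as.integer(n_perm), gate = gate,
              diff_threshold = diff_threshold)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; a nested `sim`
#' section mirrors [sim_config()]. Absent keys keep their defaults.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim
  y$sim <- NULL
  sim <- if (is.null(sim_args)) sim_config() else {
    if (!is.null(sim_args$group_sizes)) {
      sim_args$group_sizes <- unlist(sim_args$group_sizes)
    }
    do.call(sim_config, sim_args)
  }
  do.call(pipeline_config, c(list(sim = sim), y))
}

#' Validate cross-input consistency
#'
#' Checks sample-name concordance across genotypes, probe intensities and
#' CNV segments, coordinate sanity of the annotation, and referential
#' integrity of CNV samples. Problems are returned as structured
#' diagnostics, not thrown.
#'
#' @param study a `sim_study` or a list with the same components.
#' @return data frame (severity, message); zero rows when consistent.
#' @export
validate_inputs <- function(study) {
  d <- list()
  note <- function(severity, message) {
    d[[length(d) + 1L]] <<- data.frame(severity = severity,
                                       message = message,
                                       stringsAsFactors = FALSE)
  }
  smp <- study$samples$sample
  gt_smp <- colnames(study$genotypes$calls)
  pr_smp <- probe_samples(study$probes)
  if (!setequal(smp, gt_smp)) {
    note("fatal", "sample sets differ between metadata and genotypes")
  }
  if (!setequal(smp, pr_smp)) {
    note("fatal", "sample sets differ between metadata and expression probes")
  }
  bad_seg <- setdiff(unique(study$cnv$segments$sample), smp)
  if (length(bad_seg)) {
    note("fatal", paste("CNV segment sample(s) not in metadata:",
                        paste(bad_seg, collapse = ", ")))
  }
  ann <- study$annotation
  if (any(ann$genes$start > ann$genes$end)) {
    note("fatal", "gene with start > end")
  }
  if (any(ann$transcripts$gene_id %in% ann$genes$gene_id == FALSE)) {
    note("fatal", "transcript references unknown gene")
  }
  if (any(ann$exons$transcript_id %in% ann$transcripts$transcript_id == FALSE)) {
    note("fatal", "exon references unknown transcript")
  }
  seg_chrom <- setdiff(unique(study$cnv$segments$chrom),
                       unique(ann$genes$chrom))
  if (length(seg_chrom)) {
    note("warning", paste("CNV segment chromosome(s) without genes:",
                          paste(seg_chrom, collapse = ", ")))
  }
  if (length(d) == 0L) {
    return(data.frame(severity = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, d)
}

#' Run the full integrative workflow
#'
#' Simulates the study (or takes one ready-made), runs the probe and SNP
#' QC cascades, the copy-number/expression association scan, the four
#' SNP linking rules with per-(level, group) regression scans, the overlap
#' summaries, the CNV cross-reference, and the allele-differential TFBS
#' scoring of the associated SNPs. The result is a list of the five
#' association tables plus summaries and a stage-by-stage count report;
#' with `out_dir` set, every table is also written as TSV/JSON.
#'
#' @param config a [pipeline_config()].
#' @param study optional pre-built `sim_study`; simulated from
#'   `config$sim` when NULL.
#' @param out_dir optional output directory.
#' @return list of class `pipeline_result` with elements `study`,
#'   `expression_qc`, `genotype_qc`, `cnv_labels`, `cnv`, `snp` (named
#'   `<level>.<group>`), `overlaps`, `cross_reference`, `tfbs`, `report`.
#' @export
run_pipeline <- function(config = pipeline_config(), study = NULL,
                         out_dir = NULL) {
  if (is.null(study)) study <- simulate_study(config$sim)

  diag <- validate_inputs(study)
  if (any(diag$severity == "fatal")) {
    stop("input validation failed: ",
         paste(diag$message[diag$severity == "fatal"], collapse = "; "))
  }

  ## expression QC
  eqc <- run_expression_qc(study$probes, min_probes = config$min_probes)

  ## genotype QC per analysis group
  groups <- list(
    hESC = study$samples$sample[study$samples$group == "hESC"],
    hiPSC = study$samples$sample[study$samples$group == "hiPSC"],
    all = study$samples$sample)
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  seg <- study$cnv$segments
  seg_keep <- seg[seg$n_markers >= config$min_markers &
                    (seg$end - seg$start + 1L) >= config$min_length, ,
                  drop = FALSE]
  regions <- list(cnv = seg_keep[, c("sample", "chrom", "start", "end")],
                  mosaic = NULL)
  gqc <- run_genotype_qc(study$genotypes, groups = groups,
                         threshold = config$variation_threshold,
                         min_conf = config$min_conf, regions = regions,
                         metric = config$variation_metric)

  ## CNV association on gene-level expression
  labels <- label_gene_states(study$annotation, study$cnv$segments,
                              samples = study$samples$sample,
                              min_markers = config$min_markers,
                              min_length = config$min_length)
  set.seed(study$config$seed + 808L)
  cnv_res <- run_cnv_scan(eqc$expression$gene, labels,
                          alpha = config$alpha_cnv, n_perm = config$n_perm)

  ## SNP association: four linking rules x analysis groups
  link_funs <- list(gene = link_gene, transcript = link_transcript,
                    exon_short = link_exon_short, exon_long = link_exon_long)
  expr_for <- list(gene = "gene", transcript = "transcript",
                   exon_short = "exon", exon_long = "exon")
  snp_res <- list()
  for (lv in names(link_funs)) {
    for (grp in names(groups)) {
      gt <- gqc$genotypes[[grp]]
      pairs <- link_funs[[lv]](gt, study$annotation)
      expr <- eqc$expression[[expr_for[[lv]]]]
      if (is.null(expr)) next
      snp_res[[paste(lv, grp, sep = ".")]] <- run_snp_scan(
        pairs, expr, gt, samples = groups[[grp]], alpha = config$alpha_snp,
        variation_threshold = config$variation_threshold,
        variation_metric = config$variation_metric)
    }
  }

  overlaps <- summarize_overlaps(snp_res, study$annotation)
  xref <- cross_reference_cnv(snp_res, cnv_res, study$annotation)

  ## TFBS scoring on SNPs significant in any family
  sig_snps <- unique(unlist(lapply(snp_res, function(r) {
    r$snp_id[r$significant]
  })))
  pwms <- lapply(names(study$motifs$counts), function(id) {
    build_pwm(study$motifs$counts[[id]], motif_id = id,
              tf_name = study$motifs$tf_names[[id]])
  })
  pwms <- Filter(function(p) !p$degenerate, pwms)
  alleles <- study$motifs$alleles[
    study$motifs$alleles$snp_id %in% sig_snps, , drop = FALSE]
  tfbs_pairs <- score_allele_pairs(pwms, alleles, gate = config$gate)
  tf_rank <- rank_differential_tfs(tfbs_pairs,
                                   diff_threshold = config$diff_threshold)
  chip_hits <- overlap_chip_regions(
    study$genotypes$snps[study$genotypes$snps$snp_id %in% sig_snps, ,
                         drop = FALSE],
    study$chip_regions)

  report <- list(
    seed = study$config$seed,
    diagnostics = diag,
    expression_qc = eqc$report,
    genotype_qc = gqc$report,
    cnv = list(n_tested = nrow(cnv_res),
               n_significant_gain = sum(cnv_res$significant &
                                          cnv_res$direction == "gain"),
               n_significant_loss = sum(cnv_res$significant &
                                          cnv_res$direction == "loss")),
    snp_families = overlaps$families,
    n_snps_for_tfbs = length(sig_snps),
    deviations = c(
      "probeset summarisation is mean-of-log2 (no RMA normalisation)",
      "Monte-Carlo permutation p uses the add-one plug-in",
      "relative PWM score is min-max between attainable bounds"))

  result <- list(study = study, expression_qc = eqc, genotype_qc = gqc,
                 cnv_labels = labels, cnv = cnv_res, snp = snp_res,
                 overlaps = overlaps, cross_reference = xref,
                 tfbs = list(pairs = tfbs_pairs, tfs = tf_rank,
                             chip_hits = chip_hits),
                 report = report)
  class(result) <- "pipeline_result"

  if (!is.null(out_dir)) .write_pipeline_outputs(result, out_dir)
  result
}

.write_pipeline_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_study(result$study, file.path(out_dir, "simulated"))
  .write_tsv(as.data.frame(result$cnv), file.path(out_dir, "cnv_gene.tsv"))
  for (nm in names(result$snp)) {
    .write_tsv(as.data.frame(result$snp[[nm]]),
               file.path(out_dir, paste0("snp_", nm, ".tsv")))
  }
  .write_tsv(result$overlaps$families, file.path(out_dir, "families.tsv"))
  .write_tsv(result$cross_reference, file.path(out_dir,
                                               "cnv_snp_crossref.tsv"))
  .write_tsv(result$tfbs$pairs, file.path(out_dir, "tfbs_pairs.tsv"))
  .write_tsv(result$tfbs$tfs, file.path(out_dir, "tfbs_ranked.tsv"))
  rep <- result$report
  rep$snp_families <- NULL  # lives in families.tsv
  rep$diagnostics <- NULL
  jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  venn <- as.list(result$overlaps$venn)
  venn$snps_significant_all_levels <-
    result$overlaps$snps_significant_all_levels
  jsonlite::write_json(venn, file.path(out_dir, "venn.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
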