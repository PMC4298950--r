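#' Simulate probe-level expression with planted effects
#'
#' Builds one probeset per annotated feature at each of the three levels
#' (gene, transcript, exon) with `probes_per_set` clean probes. The log2
#' intensity of a probe in a sample is
#' `baseline(feature) + affinity(probe) + effects(feature, sample) + noise`,
#' where effects are the planted additive genotype effect
#' (`eqtl_effect * (call - 2)` on the causal target feature) and the copy
#' state shift (`+/- cnv_effect` on all features of a dosage gene, in the
#' samples carrying the segment). Intensities are emitted on the linear
#' scale. Antigenomic control probes are emitted across the whole GC range
#' with a GC-dependent background intensity; decoy probes (cross-hyb or
#' SNP-overlap flagged, or background-level) and deliberately small
#' probesets exercise the QC cascade.
#'
#' @param config a [sim_config()] object.
#' @param annotation a `feature_annotation`.
#' @param genotypes a `genotype_matrix`.
#' @param cnv a `cnv_segment_set`.
#' @param causal data frame (snp_id, feature_id, level, effect) of planted
#'   expression QTLs; may be empty.
#' @return object of class `probe_table`: a data frame with columns
#'   probe_id, probeset_id, level, gc, is_antigenomic, is_crosshyb,
#'   overlaps_snp, then one intensity column per sample.
#' @export
simulate_expression <- function(config, annotation, genotypes, cnv,
                                causal = NULL) {
  validate_sim_config(config)
  set.seed(config$seed + 404L)
  smp <- .sim_samples(config)
  n <- config$n_samples
  gcr <- config$gc_range

  feats <- rbind(
    data.frame(feature_id = annotation$genes$gene_id, level = "gene",
               gene_id = annotation$genes$gene_id, stringsAsFactors = FALSE),
    data.frame(feature_id = annotation$transcripts$transcript_id,
               level = "transcript", gene_id = annotation$transcripts$gene_id,
               stringsAsFactors = FALSE),
    data.frame(feature_id = unique(annotation$exons$exon_id), level = "exon",
               gene_id = annotation$exons$gene_id[
                 !duplicated(annotation$exons$exon_id)],
               stringsAsFactors = FALSE))
  nf <- nrow(feats)

  ## per-feature per-sample planted effect, log2 units
  eff <- matrix(0, nf, n, dimnames = list(feats$feature_id, smp$sample))
  if (nrow(cnv$dosage) > 0L) {
    for (i in seq_len(nrow(cnv$dosage))) {
      d <- cnv$dosage[i, ]
      rows <- feats$gene_id == d$gene_id
      cols <- strsplit(d$samples, ",", fixed = TRUE)[[1]]
      eff[rows, cols] <- eff[rows, cols] + d$effect
    }
  }
  if (!is.null(causal) && nrow(causal) > 0L) {
    for (i in seq_len(nrow(causal))) {
      cs <- causal[i, ]
      dose <- genotypes$calls[cs$snp_id, ] - 2L
      row <- which(feats$feature_id == cs$feature_id)
      if (length(row) != 1L) stop("causal target feature not found: ",
                                  cs$feature_id)
      eff[row, ] <- eff[row, ] + cs$effect * dose
    }
  }

  baseline <- stats::runif(nf, 6, 10)
  ppt <- config$probes_per_set
  np <- nf * ppt
  affinity <- stats::rnorm(np, 0, 0.3)
  gc <- sample(gcr[1]:gcr[2], np, replace = TRUE)

  log2int <- matrix(rep(baseline, each = ppt), np, n) + affinity +
    eff[rep(seq_len(nf), each = ppt), , drop = FALSE] +
    matrix(stats::rnorm(np * n, 0, config$noise_sd), np, n)

  probes <- data.frame(
    probe_id = sprintf("P%06d", seq_len(np)),
    probeset_id = rep(feats$feature_id, each = ppt),
    level = rep(feats$level, each = ppt),
    gc = gc, is_antigenomic = FALSE, is_crosshyb = FALSE,
    overlaps_snp = FALSE, stringsAsFactors = FALSE)
  ints <- 2 ^ log2int
  colnames(ints) <- smp$sample
  probes <- cbind(probes, as.data.frame(ints))

  extra <- list()
  next_id <- np

  ## decoy probes on a fraction of probesets: flagged, or background-level
  n_decoy <- round(nf * config$decoy_fraction)
  if (n_decoy > 0L) {
    decoy_feats <- sample.int(nf, n_decoy)
    kinds <- sample(c("crosshyb", "snp", "background"), n_decoy, replace = TRUE)
    for (i in seq_len(n_decoy)) {
      f <- feats[decoy_feats[i], ]
      next_id <- next_id + 1L
      g <- sample(gcr[1]:gcr[2], 1L)
      if (kinds[i] == "background") {
        v <- 2 ^ stats::rnorm(n, 2 + 0.12 * g, 0.25)
      } else {
        v <- 2 ^ (stats::runif(1, 6, 10) + stats::rnorm(n, 0, config$noise_sd))
      }
      row <- data.frame(probe_id = sprintf("P%06d", next_id),
                        probeset_id = f$feature_id, level = f$level, gc = g,
                        is_antigenomic = FALSE,
                        is_crosshyb = kinds[i] == "crosshyb",
                        overlaps_snp = kinds[i] == "snp",
                        stringsAsFactors = FALSE)
      row <- cbind(row, as.data.frame(matrix(v, 1, n,
                                             dimnames = list(NULL, smp$sample))))
      extra[[length(extra) + 1L]] <- row
    }
  }

  ## deliberately small probesets (masked by the QC cascade)
  for (lev in c("gene", "transcript", "exon")) {
    for (k in 1:2) {
      set_id <- sprintf("SMALL_%s_%d", lev, k)
      for (j in seq_len(k)) {  # 1-probe and 2-probe sets
        next_id <- next_id + 1L
        v <- 2 ^ (stats::runif(1, 6, 10) + stats::rnorm(n, 0, config$noise_sd))
        row <- data.frame(probe_id = sprintf("P%06d", next_id),
                          probeset_id = set_id, level = lev,
                          gc = sample(gcr[1]:gcr[2], 1L),
                          is_antigenomic = FALSE, is_crosshyb = FALSE,
                          overlaps_snp = FALSE, stringsAsFactors = FALSE)
        row <- cbind(row, as.data.frame(matrix(v, 1, n,
                                               dimnames = list(NULL, smp$sample))))
        extra[[length(extra) + 1L]] <- row
      }
    }
  }

  ## antigenomic background controls across the full GC range
  for (g in gcr[1]:gcr[2]) {
    for (j in seq_len(config$antigenomic_per_bin)) {
      next_id <- next_id + 1L
      v <- 2 ^ stats::rnorm(n, 2 + 0.12 * g, 0.25)
      row <- data.frame(probe_id = sprintf("P%06d", next_id),
                        probeset_id = NA_character_, level = "control",
                        gc = g, is_antigenomic = TRUE, is_crosshyb = FALSE,
                        overlaps_snp = FALSE, stringsAsFactors = FALSE)
      row <- cbind(row, as.data.frame(matrix(v, 1, n,
                                             dimnames = list(NULL, smp$sample))))
      extra[[length(extra) + 1L]] <- row
    }
  }

  probes <- rbind(probes, do.call(rbind, extra))
  rownames(probes) <- NULL
  class(probes) <- c("probe_table", "data.frame")
  probes
}

#' Sample (intensity) column names of a probe table
#' @param probes a `probe_table` or compatible data frame.
#' @return character vector of sample column names.
#' @export
probe_samples <- function(probes) {
  meta <- c("probe_id", "probeset_id", "level", "gc", "is_antigenomic",
            "is_crosshyb", "overlaps_snp")
  setdiff(names(probes), meta)
}
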