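# Shared fixture builders. Everything is generated in code; no data files.

# minimal probe table: one row per probe, intensities on the linear scale
make_probes <- function(probeset_id, level = "gene", gc = 10L,
                        intensities, is_antigenomic = FALSE,
                        is_crosshyb = FALSE, overlaps_snp = FALSE,
                        samples = paste0("s", seq_len(ncol(intensities)))) {
  intensities <- as.matrix(intensities)
  n <- nrow(intensities)
  df <- data.frame(
    probe_id = sprintf("p%03d", seq_len(n)),
    probeset_id = rep_len(probeset_id, n),
    level = rep_len(level, n),
    gc = rep_len(gc, n),
    is_antigenomic = rep_len(is_antigenomic, n),
    is_crosshyb = rep_len(is_crosshyb, n),
    overlaps_snp = rep_len(overlaps_snp, n),
    stringsAsFactors = FALSE)
  colnames(intensities) <- samples
  out <- cbind(df, as.data.frame(intensities))
  class(out) <- c("probe_table", "data.frame")
  out
}

bind_probes <- function(...) {
  pieces <- list(...)
  pieces <- lapply(pieces, function(p) {
    p$probe_id <- NULL
    p
  })
  out <- do.call(rbind, pieces)
  out <- cbind(data.frame(probe_id = sprintf("p%03d", seq_len(nrow(out))),
                          stringsAsFactors = FALSE), out)
  class(out) <- c("probe_table", "data.frame")
  out
}

# hand-built annotation from per-feature coordinate lists
make_annotation <- function(genes, transcripts, exons) {
  ann <- list(genes = genes, transcripts = transcripts, exons = exons)
  class(ann) <- "feature_annotation"
  ann
}

# three-exon single-transcript gene used by the linking tests
three_exon_annotation <- function() {
  make_annotation(
    genes = data.frame(gene_id = "g1", chrom = "chr1", start = 1000L,
                       end = 9000L, strand = "+", stringsAsFactors = FALSE),
    transcripts = data.frame(transcript_id = "t1", gene_id = "g1",
                             chrom = "chr1", start = 1000L, end = 9000L,
                             stringsAsFactors = FALSE),
    exons = data.frame(
      exon_id = c("e1", "e2", "e3"), transcript_id = "t1", gene_id = "g1",
      chrom = "chr1", start = c(1000L, 4000L, 7000L),
      end = c(2000L, 5000L, 9000L), exon_rank = 1:3,
      stringsAsFactors = FALSE))
}

# small genotype_matrix from a call matrix
make_genotypes <- function(calls, confidences = NULL, chrom = "chr1",
                           pos = NULL, samples = NULL) {
  calls <- as.matrix(calls)
  n_snp <- nrow(calls)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(calls)))
  colnames(calls) <- samples
  snp_id <- sprintf("snp%03d", seq_len(n_snp))
  rownames(calls) <- snp_id
  if (is.null(confidences)) {
    confidences <- matrix(0.95, n_snp, ncol(calls),
                          dimnames = dimnames(calls))
  } else {
    confidences <- as.matrix(confidences)
    dimnames(confidences) <- dimnames(calls)
  }
  if (is.null(pos)) pos <- seq(100L, by = 100L, length.out = n_snp)
  gt <- list(snps = data.frame(snp_id = snp_id,
                               chrom = rep_len(chrom, n_snp), pos = pos,
                               ref = "A", alt = "G", stringsAsFactors = FALSE),
             calls = calls, confidences = confidences,
             samples = data.frame(sample = samples, group = NA_character_,
                                  stringsAsFactors = FALSE))
  class(gt) <- "genotype_matrix"
  gt
}

# expression_matrix from a feature x sample value matrix (log2 scale)
make_expression <- function(values, level = "gene",
                            feature_id = rownames(values)) {
  values <- as.matrix(values)
  out <- cbind(data.frame(feature_id = feature_id,
                          level = rep_len(level, nrow(values)),
                          stringsAsFactors = FALSE),
               as.data.frame(values, row.names = NULL))
  class(out) <- c("expression_matrix", "data.frame")
  out
}

# brute-force point-in-interval membership (closed intervals)
brute_overlap <- function(pos, start, end) pos >= start & pos <= end

`%||%` <- function(a, b) if (is.null(a)) b else a
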