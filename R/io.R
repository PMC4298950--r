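## ---- annotation (GTF) --------------------------------------------------

#' Write a feature annotation as GTF
#'
#' Emits gene, transcript and exon lines with gene_id / transcript_id /
#' exon_id attributes, 1-based inclusive coordinates.
#'
#' @param annotation a `feature_annotation`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_annotation_gtf <- function(annotation, path) {
  lines <- character(0)
  g <- annotation$genes
  lines <- c(lines, sprintf(
    '%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
    g$chrom, g$start, g$end, g$strand, g$gene_id))
  t <- annotation$transcripts
  st <- g$strand[match(t$gene_id, g$gene_id)]
  lines <- c(lines, sprintf(
    '%s\tsim\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    t$chrom, t$start, t$end, st, t$gene_id, t$transcript_id))
  e <- annotation$exons
  se <- g$strand[match(e$gene_id, g$gene_id)]
  lines <- c(lines, sprintf(
    paste0('%s\tsim\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; ',
           'transcript_id "%s"; exon_id "%s"; exon_number "%d";'),
    e$chrom, e$start, e$end, se, e$gene_id, e$transcript_id, e$exon_id,
    e$exon_rank))
  writeLines(lines, path)
  invisible(path)
}

#' Read a feature annotation from GTF
#'
#' Parses gene/transcript/exon lines written by [write_annotation_gtf()]
#' (or any GTF restricted to those feature types with the same attribute
#' keys).
#'
#' @param path GTF file.
#' @return a `feature_annotation`.
#' @export
read_annotation_gtf <- function(path) {
  gtf <- utils::read.table(path, sep = "\t", quote = "",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "source", "type", "start",
                                         "end", "score", "strand", "frame",
                                         "attr"))
  get_attr <- function(attr, key) {
    m <- regmatches(attr, regexpr(paste0(key, ' "[^"]+"'), attr))
    out <- rep(NA_character_, length(attr))
    hit <- vapply(regmatches(attr, gregexpr(paste0(key, ' "([^"]+)"'), attr)),
                  length, integer(1)) > 0
    out[hit] <- sub(paste0(key, ' "([^"]+)"'), "\\1", m)
    out
  }
  gg <- gtf[gtf$type == "gene", ]
  tt <- gtf[gtf$type == "transcript", ]
  ee <- gtf[gtf$type == "exon", ]
  ann <- list(
    genes = data.frame(gene_id = get_attr(gg$attr, "gene_id"),
                       chrom = gg$chrom, start = gg$start, end = gg$end,
                       strand = gg$strand, stringsAsFactors = FALSE),
    transcripts = data.frame(
      transcript_id = get_attr(tt$attr, "transcript_id"),
      gene_id = get_attr(tt$attr, "gene_id"),
      chrom = tt$chrom, start = tt$start, end = tt$end,
      stringsAsFactors = FALSE),
    exons = data.frame(
      exon_id = get_attr(ee$attr, "exon_id"),
      transcript_id = get_attr(ee$attr, "transcript_id"),
      gene_id = get_attr(ee$attr, "gene_id"),
      chrom = ee$chrom, start = ee$start, end = ee$end,
      exon_rank = as.integer(get_attr(ee$attr, "exon_number")),
      stringsAsFactors = FALSE))
  rownames(ann$genes) <- rownames(ann$transcripts) <- rownames(ann$exons) <- NULL
  class(ann) <- "feature_annotation"
  ann
}

## ---- genotypes ---------------------------------------------------------

#' Write genotype calls and confidences as TSV
#'
#' `<path_prefix>_calls.tsv` holds snp_id, chrom, pos, ref, alt and one
#' 1/2/3 call column per sample; `<path_prefix>_confidences.tsv` holds the
#' companion per-call confidences.
#'
#' @param genotypes a `genotype_matrix`.
#' @param path_prefix output prefix.
#' @return the two paths, invisibly.
#' @export
write_genotypes_tsv <- function(genotypes, path_prefix) {
  calls <- cbind(genotypes$snps, as.data.frame(genotypes$calls,
                                               row.names = NULL))
  conf <- cbind(genotypes$snps["snp_id"],
                as.data.frame(genotypes$confidences, row.names = NULL))
  p1 <- paste0(path_prefix, "_calls.tsv")
  p2 <- paste0(path_prefix, "_confidences.tsv")
  .write_tsv(calls, p1)
  .write_tsv(conf, p2)
  invisible(c(p1, p2))
}

#' Read genotype calls and confidences written by [write_genotypes_tsv()]
#'
#' @param path_prefix prefix used at write time.
#' @param samples data frame (sample, group); reconstructed from column
#'   names with group NA when omitted.
#' @return a `genotype_matrix`.
#' @export
read_genotypes_tsv <- function(path_prefix, samples = NULL) {
  calls_df <- .read_tsv(paste0(path_prefix, "_calls.tsv"))
  conf_df <- .read_tsv(paste0(path_prefix, "_confidences.tsv"))
  meta <- c("snp_id", "chrom", "pos", "ref", "alt")
  smp_cols <- setdiff(names(calls_df), meta)
  calls <- as.matrix(calls_df[, smp_cols, drop = FALSE])
  rownames(calls) <- calls_df$snp_id
  conf <- as.matrix(conf_df[, setdiff(names(conf_df), "snp_id"), drop = FALSE])
  rownames(conf) <- conf_df$snp_id
  if (is.null(samples)) {
    samples <- data.frame(sample = smp_cols, group = NA_character_,
                          stringsAsFactors = FALSE)
  }
  gt <- list(snps = calls_df[, meta], calls = calls,
             confidences = conf[, smp_cols, drop = FALSE], samples = samples)
  class(gt) <- "genotype_matrix"
  gt
}

## ---- CNV segments ------------------------------------------------------

#' Write CNV segments as BED-like TSV
#' @param segments data frame (sample, chrom, start, end, state, n_markers).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_cnv_tsv <- function(segments, path) .write_tsv(segments, path)

#' Read CNV segments written by [write_cnv_tsv()]
#' @param path input file.
#' @return data frame of segments.
#' @export
read_cnv_tsv <- function(path) .read_tsv(path)

## ---- probes and expression --------------------------------------------

#' Write a probe table as TSV
#' @param probes a `probe_table`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_probes_tsv <- function(probes, path) {
  .write_tsv(as.data.frame(probes), path)
}

#' Read a probe table written by [write_probes_tsv()]
#' @param path input file.
#' @return a `probe_table`.
#' @export
read_probes_tsv <- function(path) {
  out <- .read_tsv(path)
  out$probeset_id <- as.character(out$probeset_id)
  class(out) <- c("probe_table", "data.frame")
  out
}

#' Write an expression matrix as TSV
#' @param expression an `expression_matrix`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_expression_tsv <- function(expression, path) {
  .write_tsv(as.data.frame(expression), path)
}

#' Read an expression matrix written by [write_expression_tsv()]
#' @param path input file.
#' @return an `expression_matrix`.
#' @export
read_expression_tsv <- function(path) {
  out <- .read_tsv(path)
  class(out) <- c("expression_matrix", "data.frame")
  out
}

## ---- TRANSFAC-style motif matrices -------------------------------------

#' Write count matrices in TRANSFAC-style layout
#'
#' Each record: `ID <motif_id>`, `BF <tf_name>`, a `P0 A C G T` header,
#' one numbered row per motif position, and a `//` terminator.
#'
#' @param counts named list of 4 x L count matrices (rows A/C/G/T).
#' @param tf_names named character vector of TF names per motif id.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_transfac <- function(counts, tf_names, path) {
  lines <- character(0)
  for (id in names(counts)) {
    cm <- counts[[id]]
    lines <- c(lines, paste("ID", id), paste("BF", tf_names[[id]]),
               "P0\tA\tC\tG\tT")
    for (j in seq_len(ncol(cm))) {
      lines <- c(lines, sprintf("%02d\t%s", j,
                                paste(format(cm[, j], trim = TRUE),
                                      collapse = "\t")))
    }
    lines <- c(lines, "//")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read TRANSFAC-style count matrices
#'
#' Parses the layout of [write_transfac()]: ID/BF headers, a P0 column
#' header and numbered count rows, records separated by `//`.
#'
#' @param path input file.
#' @return list with `counts` (named list of matrices) and `tf_names`.
#' @export
read_transfac <- function(path) {
  lines <- readLines(path)
  counts <- list(); tf_names <- character(0)
  id <- NULL; tf <- NA_character_; rows <- list()
  flush <- function() {
    if (!is.null(id) && length(rows)) {
      cm <- t(do.call(rbind, rows))
      rownames(cm) <- c("A", "C", "G", "T")
      counts[[id]] <<- cm
      tf_names[id] <<- tf
    }
  }
  for (ln in lines) {
    if (grepl("^ID\\s", ln)) {
      id <- sub("^ID\\s+", "", ln); rows <- list(); tf <- NA_character_
    } else if (grepl("^BF\\s", ln)) {
      tf <- sub("^BF\\s+", "", ln)
    } else if (grepl("^P0", ln)) {
      next
    } else if (grepl("^//", ln)) {
      flush(); id <- NULL
    } else if (grepl("^[0-9]+\\s", ln)) {
      v <- strsplit(ln, "\\s+")[[1]]
      rows[[length(rows) + 1L]] <- as.numeric(v[2:5])
    }
  }
  flush()
  list(counts = counts, tf_names = tf_names)
}

## ---- allele flank FASTA -------------------------------------------------

#' Write SNP allele flanking sequences as FASTA
#'
#' Headers follow the `snpid|ref` / `snpid|alt` dialect.
#'
#' @param alleles data frame (snp_id, ref_seq, alt_seq).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_allele_fasta <- function(alleles, path) {
  seqs <- character(2 * nrow(alleles))
  nms <- character(2 * nrow(alleles))
  seqs[c(TRUE, FALSE)] <- alleles$ref_seq
  seqs[c(FALSE, TRUE)] <- alleles$alt_seq
  nms[c(TRUE, FALSE)] <- paste0(alleles$snp_id, "|ref")
  nms[c(FALSE, TRUE)] <- paste0(alleles$snp_id, "|alt")
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- nms
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read SNP allele flanking sequences written by [write_allele_fasta()]
#' @param path FASTA file with `snpid|ref` / `snpid|alt` headers.
#' @return data frame (snp_id, ref_seq, alt_seq).
#' @export
read_allele_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- names(x)
  snp <- sub("\\|(ref|alt)$", "", nm)
  which_allele <- sub("^.*\\|", "", nm)
  ids <- unique(snp)
  data.frame(
    snp_id = ids,
    ref_seq = as.character(x[match(paste0(ids, "|ref"), nm)]),
    alt_seq = as.character(x[match(paste0(ids, "|alt"), nm)]),
    stringsAsFactors = FALSE)
}

## ---- truth table --------------------------------------------------------

#' Write the simulation truth table as JSON
#' @param truth the `truth` element of a `sim_study`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a truth table written by [write_truth_json()]
#' @param path JSON file.
#' @return list with causal, dosage and motif_hits data frames.
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

## ---- whole study ---------------------------------------------------------

#' Write all fixtures of a simulated study to a directory
#'
#' Emits the GTF annotation, genotype and confidence TSVs, the CNV segment
#' TSV, the probe TSV, the TRANSFAC-style motif file, the allele-flank
#' FASTA, the ChIP-region TSV and the JSON truth table.
#'
#' @param study a `sim_study`.
#' @param dir output directory (created if missing).
#' @return named vector of paths, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    annotation = file.path(dir, "annotation.gtf"),
    cnv = file.path(dir, "cnv_segments.tsv"),
    probes = file.path(dir, "probes.tsv"),
    motifs = file.path(dir, "motifs.transfac"),
    alleles = file.path(dir, "allele_flanks.fasta"),
    chip = file.path(dir, "chip_regions.tsv"),
    truth = file.path(dir, "truth.json"),
    samples = file.path(dir, "samples.tsv"))
  write_annotation_gtf(study$annotation, paths["annotation"])
  write_genotypes_tsv(study$genotypes, file.path(dir, "genotypes"))
  write_cnv_tsv(study$cnv$segments, paths["cnv"])
  write_probes_tsv(study$probes, paths["probes"])
  write_transfac(study$motifs$counts, study$motifs$tf_names, paths["motifs"])
  write_allele_fasta(study$motifs$alleles, paths["alleles"])
  .write_tsv(study$chip_regions, paths["chip"])
  write_truth_json(study$truth, paths["truth"])
  .write_tsv(study$samples, paths["samples"])
  invisible(paths)
}
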