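## ---- SNP-to-feature linking -------------------------------------------
## All coordinates are 1-based inclusive; boundaries of every linking
## window are themselves linked. Strand is ignored throughout: the flank
## is an unstranded genomic distance.

.empty_pairs <- function(level) {
  data.frame(snp_id = character(), feature_id = character(),
             level = level, snp_inside_feature = logical(),
             stringsAsFactors = FALSE)
}

.overlap_pairs <- function(snps, feat, level, win_start, win_end,
                           inside_start = feat$start, inside_end = feat$end) {
  if (nrow(snps) == 0L || nrow(feat) == 0L) return(.empty_pairs(level))
  gr_snp <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(snps$pos, snps$pos))
  gr_win <- GenomicRanges::GRanges(feat$chrom,
                                   IRanges::IRanges(win_start, win_end))
  hits <- GenomicRanges::findOverlaps(gr_snp, gr_win)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (length(qi) == 0L) return(.empty_pairs(level))
  out <- data.frame(
    snp_id = snps$snp_id[qi],
    feature_id = feat$feature_id[si],
    level = level,
    snp_inside_feature = .point_in(snps$pos[qi], inside_start[si],
                                   inside_end[si]),
    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[, c("snp_id", "feature_id")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Link SNPs to genes (gene span plus 5 kb flanks)
#'
#' A SNP is linked to a gene iff its position lies within
#' `[gene start - flank, gene end + flank]`; the flank is unstranded and
#' the window boundaries are inclusive.
#'
#' @param snps data frame (snp_id, chrom, pos) of QC-passed SNPs, or a
#'   `genotype_matrix` (its `snps` table is used).
#' @param annotation a `feature_annotation`.
#' @param flank window extension in bp on each side (default 5000).
#' @return data frame (snp_id, feature_id, level = "gene",
#'   snp_inside_feature = within the gene span itself).
#' @export
link_gene <- function(snps, annotation, flank = 5000L) {
  snps <- .snp_frame(snps)
  g <- annotation$genes
  feat <- data.frame(feature_id = g$gene_id, chrom = g$chrom,
                     start = g$start, end = g$end, stringsAsFactors = FALSE)
  .overlap_pairs(snps, feat, "gene",
                 pmax(1L, feat$start - flank), feat$end + flank)
}

#' Link SNPs to transcripts (transcript span, no flank)
#'
#' A SNP inside the transcript span is linked, including intronic
#' positions (the rule is span-based, not exon-based).
#'
#' @inheritParams link_gene
#' @return data frame (snp_id, feature_id, level = "transcript",
#'   snp_inside_feature, always TRUE here).
#' @export
link_transcript <- function(snps, annotation) {
  snps <- .snp_frame(snps)
  t <- annotation$transcripts
  feat <- data.frame(feature_id = t$transcript_id, chrom = t$chrom,
                     start = t$start, end = t$end, stringsAsFactors = FALSE)
  .overlap_pairs(snps, feat, "transcript", feat$start, feat$end)
}

#' Link SNPs to exons via the short interval
#'
#' The short interval of an exon is the exon itself plus the immediately
#' adjacent intron(s) in each parent transcript: from the previous exon's
#' end (exclusive) to the next exon's start (exclusive). Terminal exons
#' have a single adjacent intron. An exon shared by several transcripts
#' uses the union of the per-transcript windows.
#'
#' @inheritParams link_gene
#' @return data frame (snp_id, feature_id, level = "exon_short",
#'   snp_inside_feature = within the exon span itself).
#' @export
link_exon_short <- function(snps, annotation) {
  snps <- .snp_frame(snps)
  ex <- annotation$exons
  if (nrow(ex) == 0L) return(.empty_pairs("exon_short"))
  ## per (transcript, exon) window: previous exon end + 1 .. next start - 1
  win <- do.call(rbind, lapply(split(ex, ex$transcript_id), function(e) {
    e <- e[order(e$start), , drop = FALSE]
    n <- nrow(e)
    ws <- ifelse(seq_len(n) == 1L, e$start, c(NA, e$end[-n] + 1L))
    we <- ifelse(seq_len(n) == n, e$end, c(e$start[-1] - 1L, NA))
    data.frame(feature_id = e$exon_id, chrom = e$chrom,
               start = e$start, end = e$end,
               win_start = ws, win_end = we, stringsAsFactors = FALSE)
  }))
  .overlap_pairs(snps, win, "exon_short", win$win_start, win$win_end,
                 inside_start = win$start, inside_end = win$end)
}

#' Link SNPs to exons via the long interval (whole gene span)
#'
#' A SNP anywhere in the exon's parent gene span is linked to the exon;
#' there is no flank at the exon level. The short-interval pair set is a
#' subset of this one on every input.
#'
#' @inheritParams link_gene
#' @return data frame (snp_id, feature_id, level = "exon_long",
#'   snp_inside_feature = within the exon span itself).
#' @export
link_exon_long <- function(snps, annotation) {
  snps <- .snp_frame(snps)
  ex <- annotation$exons[!duplicated(annotation$exons$exon_id), , drop = FALSE]
  if (nrow(ex) == 0L) return(.empty_pairs("exon_long"))
  g <- annotation$genes
  gi <- match(ex$gene_id, g$gene_id)
  feat <- data.frame(feature_id = ex$exon_id, chrom = ex$chrom,
                     start = ex$start, end = ex$end, stringsAsFactors = FALSE)
  .overlap_pairs(snps, feat, "exon_long", g$start[gi], g$end[gi])
}

.snp_frame <- function(snps) {
  if (inherits(snps, "genotype_matrix")) snps <- snps$snps
  .stopifnot_cols(snps, c("snp_id", "chrom", "pos"), "SNP table")
  snps
}

## ---- per-pair linear regression ---------------------------------------

#' Linear regression of expression on genotype code
#'
#' Ordinary least squares of per-sample expression on the numeric genotype
#' code (1/2/3, equivalent to allele dosage up to an affine transform).
#' The two-sided p-value for slope != 0 comes from the t distribution with
#' n - 2 degrees of freedom. A perfect fit (zero residual variance with a
#' non-zero slope) returns p = 0 and is flagged; constant expression
#' returns slope 0 with p = 1.
#'
#' @param expr numeric per-sample expression (log2).
#' @param calls integer genotype codes in \{1, 2, 3\}.
#' @return list: slope, intercept, t_statistic, raw_p, n, genotype_counts
#'   (named occurrences of codes 1/2/3), perfect_fit.
#' @export
fit_genotype_regression <- function(expr, calls) {
  n <- length(expr)
  if (n != length(calls)) stop("expr and calls lengths differ")
  if (n < 3L) stop("at least 3 samples required")
  if (length(unique(calls)) < 2L) {
    stop("monomorphic in tested group (fewer than 2 genotype codes)")
  }
  x <- as.numeric(calls); y <- as.numeric(expr)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  syy <- sum((y - my)^2)
  slope <- sxy / sxx
  intercept <- my - slope * mx
  counts <- vapply(1:3, function(k) sum(calls == k), integer(1))
  names(counts) <- c("g1", "g2", "g3")
  if (syy == 0) {
    return(list(slope = 0, intercept = my, t_statistic = 0, raw_p = 1,
                n = n, genotype_counts = counts, perfect_fit = FALSE))
  }
  rss <- max(syy - slope * sxy, 0)
  if (rss <= 1e-12 * syy) {
    return(list(slope = slope, intercept = intercept,
                t_statistic = sign(slope) * Inf, raw_p = 0, n = n,
                genotype_counts = counts, perfect_fit = TRUE))
  }
  se <- sqrt(rss / (n - 2) / sxx)
  t <- slope / se
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  list(slope = slope, intercept = intercept, t_statistic = t, raw_p = p,
       n = n, genotype_counts = counts, perfect_fit = FALSE)
}

#' Genotype-expression association scan over linked pairs
#'
#' Fits one regression per linked pair within the given sample group. The
#' variation filter is re-applied within the group (a pair whose SNP drops
#' below the variation threshold in the group, or is monomorphic there, is
#' skipped with a reason). Raw p-values are BH-adjusted within the family
#' formed by this (level, group) scan.
#'
#' @param pairs data frame from one of the `link_*` functions.
#' @param expression an `expression_matrix` at the matching level.
#' @param genotypes a `genotype_matrix` (QC-passed).
#' @param samples sample ids of the analysis group (default: all).
#' @param alpha significance level on adjusted p (default 0.10).
#' @param variation_threshold within-group variation threshold (default
#'   0.25; set 0 to disable re-filtering).
#' @param variation_metric see [genotype_variation()].
#' @return data frame of class `snp_association`: snp_id, feature_id,
#'   level, snp_inside_feature, slope, intercept, t_statistic, raw_p,
#'   adjusted_p, significant, n, n_g1, n_g2, n_g3, perfect_fit. Skipped
#'   pairs are recorded in `attr(., "skipped")`.
#' @export
run_snp_scan <- function(pairs, expression, genotypes, samples = NULL,
                         alpha = 0.10, variation_threshold = 0.25,
                         variation_metric = c("maf", "genotype_fraction")) {
  variation_metric <- match.arg(variation_metric)
  if (is.null(samples)) samples <- colnames(genotypes$calls)
  if (!all(samples %in% colnames(genotypes$calls))) {
    stop("unknown sample(s) in group")
  }
  smp_expr <- setdiff(names(expression), c("feature_id", "level"))
  if (!all(samples %in% smp_expr)) {
    stop("expression matrix lacks sample(s) of the group")
  }

  empty <- data.frame(snp_id = character(), feature_id = character(),
                      level = character(), snp_inside_feature = logical(),
                      slope = numeric(), intercept = numeric(),
                      t_statistic = numeric(), raw_p = numeric(),
                      adjusted_p = numeric(), significant = logical(),
                      n = integer(), n_g1 = integer(), n_g2 = integer(),
                      n_g3 = integer(), perfect_fit = logical(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("snp_association", "data.frame")
  if (nrow(pairs) == 0L) {
    attr(empty, "skipped") <- data.frame(snp_id = character(),
                                         feature_id = character(),
                                         reason = character(),
                                         stringsAsFactors = FALSE)
    return(empty)
  }

  pairs <- pairs[pairs$snp_id %in% rownames(genotypes$calls) &
                   pairs$feature_id %in% expression$feature_id, , drop = FALSE]
  calls <- genotypes$calls[, samples, drop = FALSE]
  exprm <- as.matrix(expression[, samples, drop = FALSE])
  rownames(exprm) <- expression$feature_id

  rows <- vector("list", nrow(pairs))
  skipped <- list()
  for (i in seq_len(nrow(pairs))) {
    sid <- pairs$snp_id[i]; fid <- pairs$feature_id[i]
    g <- calls[sid, ]
    if (length(unique(g)) < 2L) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        snp_id = sid, feature_id = fid,
        reason = "monomorphic in tested group", stringsAsFactors = FALSE)
      next
    }
    if (variation_threshold > 0 &&
        genotype_variation(g, variation_metric) < variation_threshold) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        snp_id = sid, feature_id = fid,
        reason = "below variation threshold in tested group",
        stringsAsFactors = FALSE)
      next
    }
    fit <- fit_genotype_regression(exprm[fid, ], g)
    rows[[i]] <- data.frame(
      snp_id = sid, feature_id = fid, level = pairs$level[i],
      snp_inside_feature = pairs$snp_inside_feature[i],
      slope = fit$slope, intercept = fit$intercept,
      t_statistic = fit$t_statistic, raw_p = fit$raw_p,
      n = fit$n, n_g1 = fit$genotype_counts[["g1"]],
      n_g2 = fit$genotype_counts[["g2"]], n_g3 = fit$genotype_counts[["g3"]],
      perfect_fit = fit$perfect_fit, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(snp_id = character(), feature_id = character(),
               reason = character(), stringsAsFactors = FALSE)
  if (length(rows) == 0L) {
    attr(empty, "skipped") <- skipped
    return(empty)
  }
  out <- do.call(rbind, rows)
  ## BH within this (level, group) family; p = 0 from perfect fits is kept
  ## out of bh_adjust's (0, 1] domain by substituting the smallest double
  praw <- pmax(out$raw_p, .Machine$double.xmin)
  out$adjusted_p <- bh_adjust(praw)
  out$adjusted_p[out$raw_p == 0] <- 0
  out$significant <- out$adjusted_p < alpha
  out <- out[, c("snp_id", "feature_id", "level", "snp_inside_feature",
                 "slope", "intercept", "t_statistic", "raw_p", "adjusted_p",
                 "significant", "n", "n_g1", "n_g2", "n_g3", "perfect_fit")]
  rownames(out) <- NULL
  class(out) <- c("snp_association", "data.frame")
  attr(out, "skipped") <- skipped
  out
}

## ---- summaries ---------------------------------------------------------

## map feature ids of any level to gene ids
.features_to_genes <- function(feature_id, level, annotation) {
  out <- character(length(feature_id))
  is_g <- level %in% c("gene")
  out[is_g] <- feature_id[is_g]
  is_t <- level == "transcript"
  if (any(is_t)) {
    out[is_t] <- annotation$transcripts$gene_id[
      match(feature_id[is_t], annotation$transcripts$transcript_id)]
  }
  is_e <- level %in% c("exon", "exon_short", "exon_long")
  if (any(is_e)) {
    out[is_e] <- annotation$exons$gene_id[
      match(feature_id[is_e], annotation$exons$exon_id)]
  }
  out
}

#' Summarise SNP-scan results across levels and groups
#'
#' Produces, per (level, group) family: significant and tested pair
#' counts, unique affected features, unique genes (exons and transcripts
#' mapped to their parent gene), and counts of significant SNPs inside vs
#' outside the feature span. Also computes the gene-resolution Venn of the
#' four linking levels for a chosen group and the number of SNPs
#' significant at all four levels.
#'
#' @param results named list of `snp_association` tables; names formatted
#'   `<level>.<group>` (e.g. `gene.all`).
#' @param annotation a `feature_annotation`.
#' @param venn_group group whose four level-analyses feed the Venn
#'   (default "all").
#' @return list with `families` (data frame of per-family counts), `venn`
#'   (named region counts over the four levels at gene resolution) and
#'   `snps_significant_all_levels`.
#' @export
summarize_overlaps <- function(results, annotation, venn_group = "all") {
  fam <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    sig <- r[r$significant, , drop = FALSE]
    genes <- unique(.features_to_genes(sig$feature_id, sig$level, annotation))
    data.frame(level = parts[1], group = parts[2],
               n_significant = nrow(sig), n_tested = nrow(r),
               n_features = length(unique(sig$feature_id)),
               n_genes = length(genes),
               snps_inside = length(unique(sig$snp_id[sig$snp_inside_feature])),
               snps_outside = length(unique(sig$snp_id[!sig$snp_inside_feature])),
               stringsAsFactors = FALSE)
  }))
  rownames(fam) <- NULL

  lv <- c("gene", "transcript", "exon_short", "exon_long")
  sets <- lapply(lv, function(l) {
    r <- results[[paste(l, venn_group, sep = ".")]]
    if (is.null(r)) return(character(0))
    sig <- r[r$significant, , drop = FALSE]
    unique(.features_to_genes(sig$feature_id, sig$level, annotation))
  })
  names(sets) <- lv
  all_genes <- unique(unlist(sets))
  venn <- integer(0)
  if (length(all_genes)) {
    member <- vapply(sets, function(s) all_genes %in% s,
                     logical(length(all_genes)))
    member <- matrix(member, ncol = length(lv),
                     dimnames = list(all_genes, lv))
    pattern <- apply(member, 1, function(m) paste(lv[m], collapse = "&"))
    venn <- table(pattern)
    venn <- stats::setNames(as.integer(venn), names(venn))
  }

  snp_sets <- lapply(lv, function(l) {
    r <- results[[paste(l, venn_group, sep = ".")]]
    if (is.null(r)) return(character(0))
    unique(r$snp_id[r$significant])
  })
  all_lv <- Reduce(intersect, snp_sets)

  list(families = fam, venn = venn,
       snps_significant_all_levels = length(all_lv))
}

#' Cross-reference SNP and CNV association results
#'
#' Genes significant in both the genotype-expression scan and the
#' copy-number/expression scan: their expression difference may reflect
#' the copy-number change rather than the genotype.
#'
#' @param snp_results a `snp_association` table (or list of them).
#' @param cnv_results a `cnv_association` table.
#' @param annotation a `feature_annotation`.
#' @return data frame (gene_id, snp_ids, cnv_directions, flag).
#' @export
cross_reference_cnv <- function(snp_results, cnv_results, annotation) {
  if (is.data.frame(snp_results)) snp_results <- list(snp_results)
  sig <- do.call(rbind, lapply(snp_results, function(r) {
    s <- r[r$significant, c("snp_id", "feature_id", "level"), drop = FALSE]
    if (nrow(s)) s$gene_id <- .features_to_genes(s$feature_id, s$level,
                                                 annotation)
    s
  }))
  cnv_sig <- cnv_results[cnv_results$significant, , drop = FALSE]
  shared <- intersect(unique(sig$gene_id), unique(cnv_sig$gene_id))
  if (length(shared) == 0L) {
    return(data.frame(gene_id = character(), snp_ids = character(),
                      cnv_directions = character(), flag = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(shared, function(g) {
    data.frame(
      gene_id = g,
      snp_ids = paste(sort(unique(sig$snp_id[sig$gene_id == g])),
                      collapse = ","),
      cnv_directions = paste(sort(unique(
        cnv_sig$direction[cnv_sig$gene_id == g])), collapse = ","),
      flag = "expression difference may reflect CNV, not genotype",
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
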