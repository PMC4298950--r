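#' GC-binned background thresholds from antigenomic probes
#'
#' For every GC bin the background limit is the mean plus two standard
#' deviations (n-1 denominator) of the intensities of the antigenomic
#' probes in that bin, pooled across samples. A bin with a single
#' antigenomic intensity gets its own value as the limit (SD defined 0).
#' Intensities are compared on the linear scale.
#'
#' @param probes a `probe_table` (see [simulate_expression()] for layout).
#' @return object of class `background_thresholds`: data frame with columns
#'   gc, n, mean, sd, limit.
#' @export
compute_background_thresholds <- function(probes) {
  .stopifnot_cols(probes, c("gc", "is_antigenomic"), "probe table")
  smp <- probe_samples(probes)
  anti <- probes[probes$is_antigenomic, , drop = FALSE]
  genomic <- probes[!probes$is_antigenomic, , drop = FALSE]
  if (nrow(anti) == 0L) stop("no antigenomic probes in the table")

  used_bins <- sort(unique(genomic$gc))
  missing <- setdiff(used_bins, unique(anti$gc))
  if (length(missing)) {
    stop("no antigenomic probes for GC bin(s): ",
         paste(missing, collapse = ", "))
  }

  bins <- sort(unique(anti$gc))
  out <- do.call(rbind, lapply(bins, function(g) {
    v <- as.numeric(as.matrix(anti[anti$gc == g, smp, drop = FALSE]))
    m <- mean(v); s <- .sd0(v)
    data.frame(gc = g, n = length(v), mean = m, sd = s, limit = m + 2 * s)
  }))
  rownames(out) <- NULL
  class(out) <- c("background_thresholds", "data.frame")
  out
}

#' Remove background probes
#'
#' A genomic probe is kept iff its maximum intensity across samples
#' strictly exceeds the background limit of its GC bin; probes at or below
#' the limit are considered background. Antigenomic probes are dropped from
#' the output.
#'
#' @param probes a `probe_table`.
#' @param thresholds a `background_thresholds` object.
#' @return filtered `probe_table` (genomic probes only).
#' @export
filter_background_probes <- function(probes, thresholds) {
  smp <- probe_samples(probes)
  genomic <- probes[!probes$is_antigenomic, , drop = FALSE]
  lim <- thresholds$limit[match(genomic$gc, thresholds$gc)]
  if (anyNA(lim)) {
    stop("no background limit for GC bin(s): ",
         paste(sort(unique(genomic$gc[is.na(lim)])), collapse = ", "))
  }
  mx <- do.call(pmax, as.list(genomic[, smp, drop = FALSE]))
  out <- genomic[mx > lim, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove cross-hybridising and SNP-overlapping probes
#'
#' Drops every probe whose `is_crosshyb` or `overlaps_snp` flag is set.
#' The flags are consumed as precomputed annotation; they are not derived
#' from probe sequence here.
#'
#' @param probes a `probe_table`.
#' @return filtered `probe_table`.
#' @export
filter_flagged_probes <- function(probes) {
  out <- probes[!(probes$is_crosshyb | probes$overlaps_snp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mask probesets with too few surviving probes
#'
#' Probesets left with fewer than `min_probes` probes after the earlier
#' filters are removed entirely (default 3: sets with only one or two
#' probes are considered unreliable).
#'
#' @param probes a `probe_table`, already background- and flag-filtered.
#' @param min_probes minimum surviving probes per probeset.
#' @return filtered `probe_table`.
#' @export
mask_small_probesets <- function(probes, min_probes = 3L) {
  cnt <- table(probes$probeset_id)
  keep_sets <- names(cnt)[cnt >= min_probes]
  out <- probes[!is.na(probes$probeset_id) &
                  probes$probeset_id %in% keep_sets, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarise probesets into feature-level log2 expression
#'
#' Feature value per sample is the mean of log2(intensity) over the
#' probeset's surviving probes (a simple summarisation standing in front of
#' the association stages; no normalisation is applied).
#'
#' @param probes a QC-passed `probe_table`.
#' @return object of class `expression_matrix`: data frame with feature_id,
#'   level, then one log2-expression column per sample.
#' @export
summarize_probesets <- function(probes) {
  smp <- probe_samples(probes)
  if (nrow(probes) == 0L) {
    out <- cbind(data.frame(feature_id = character(), level = character(),
                            stringsAsFactors = FALSE),
                 as.data.frame(matrix(numeric(0), 0, length(smp),
                                      dimnames = list(NULL, smp))))
    class(out) <- c("expression_matrix", "data.frame")
    return(out)
  }
  lg <- log2(as.matrix(probes[, smp, drop = FALSE]))
  grp <- probes$probeset_id
  sums <- rowsum(lg, grp)
  n <- as.vector(table(grp)[rownames(sums)])
  vals <- sums / n
  lev <- probes$level[match(rownames(vals), probes$probeset_id)]
  out <- cbind(data.frame(feature_id = rownames(vals), level = lev,
                          stringsAsFactors = FALSE),
               as.data.frame(vals, row.names = NULL))
  rownames(out) <- NULL
  class(out) <- c("expression_matrix", "data.frame")
  out
}

#' Run the full probe QC cascade
#'
#' Applies, in order: background filtering against GC-binned antigenomic
#' thresholds, removal of cross-hybridising and SNP-overlapping probes, and
#' masking of probesets with fewer than `min_probes` surviving probes; then
#' summarises the survivors into per-level expression matrices.
#'
#' @param probes a `probe_table`.
#' @param min_probes minimum surviving probes per probeset.
#' @return list with `expression` (named list of `expression_matrix` per
#'   level), `probes` (surviving probe table) and `report` (probe and
#'   probeset counts after each step).
#' @export
run_expression_qc <- function(probes, min_probes = 3L) {
  thresholds <- compute_background_thresholds(probes)
  n_input <- sum(!probes$is_antigenomic)
  p1 <- filter_background_probes(probes, thresholds)
  p2 <- filter_flagged_probes(p1)
  p3 <- mask_small_probesets(p2, min_probes)
  expr_all <- summarize_probesets(p3)
  levels_present <- intersect(c("gene", "transcript", "exon"),
                              unique(expr_all$level))
  expression <- lapply(levels_present, function(lv) {
    out <- expr_all[expr_all$level == lv, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  names(expression) <- levels_present
  report <- list(
    probes_input = n_input,
    probes_after_background = nrow(p1),
    probes_after_flags = nrow(p2),
    probes_after_mask = nrow(p3),
    removed_background = n_input - nrow(p1),
    removed_flagged = nrow(p1) - nrow(p2),
    removed_small_probesets = nrow(p2) - nrow(p3),
    probesets_input = length(unique(stats::na.omit(probes$probeset_id))),
    probesets_output = length(unique(p3$probeset_id)),
    probesets_per_level = as.list(table(expr_all$level)))
  list(expression = expression, probes = p3, thresholds = thresholds,
       report = report)
}
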