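#' Build a position weight matrix from base counts
#'
#' Column counts are normalised to frequencies, a pseudocount of 0.005 is
#' added to each frequency and the column renormalised (divide by 1.02),
#' and the log-odds against a uniform background of 0.25 are taken:
#' `log2(((c/sum + 0.005) / 1.02) / 0.25)`. The attainable score bounds are
#' the sums of the per-column maxima and minima.
#'
#' @param counts 4 x L numeric matrix of base counts, rows named A/C/G/T.
#' @param pseudocount pseudocount added to normalised frequencies
#'   (default 0.005).
#' @param motif_id,tf_name identifiers carried along.
#' @return object of class `pwm`: list with counts, freqs, logodds,
#'   min_score, max_score, length, degenerate flag, motif_id, tf_name.
#' @export
build_pwm <- function(counts, pseudocount = 0.005, motif_id = NA_character_,
                      tf_name = NA_character_) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("counts must have 4 rows (A, C, G, T)")
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  if (!identical(rownames(counts), c("A", "C", "G", "T"))) {
    counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  }
  if (any(counts < 0)) stop("counts must be >= 0")
  csum <- colSums(counts)
  if (any(csum == 0)) stop("all-zero column in count matrix")
  freqs <- sweep(counts, 2, csum, "/")
  freqs <- (freqs + pseudocount) / (1 + 4 * pseudocount)
  logodds <- log2(freqs / 0.25)
  max_score <- sum(apply(logodds, 2, max))
  min_score <- sum(apply(logodds, 2, min))
  out <- list(counts = counts, freqs = freqs, logodds = logodds,
              min_score = min_score, max_score = max_score,
              length = ncol(counts),
              degenerate = isTRUE(all.equal(max_score, min_score)) ||
                max_score == min_score,
              motif_id = motif_id, tf_name = tf_name)
  class(out) <- "pwm"
  out
}

.revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

## per-window summed log-odds; windows containing a base outside ACGT are
## NA (skipped)
.window_scores <- function(sequence, pwm) {
  b <- strsplit(toupper(sequence), "")[[1]]
  idx <- match(b, c("A", "C", "G", "T"))
  L <- pwm$length
  n_win <- length(b) - L + 1L
  scores <- rep(NA_real_, n_win)
  lo <- pwm$logodds
  for (w in seq_len(n_win)) {
    ii <- idx[w:(w + L - 1L)]
    if (anyNA(ii)) next
    scores[w] <- sum(lo[cbind(ii, seq_len(L))])
  }
  scores
}

#' Maximum PWM binding score over a sequence
#'
#' Slides the PWM over every window of the sequence (and of its reverse
#' complement when `scan_both_strands`), summing the per-position log-odds,
#' and returns the maximum. Windows containing a base outside A/C/G/T are
#' skipped with a warning.
#'
#' @param sequence character DNA string, length >= motif length.
#' @param pwm a [build_pwm()] object.
#' @param scan_both_strands also scan the reverse complement (default TRUE).
#' @return maximum summed log-odds score.
#' @export
max_binding_score <- function(sequence, pwm, scan_both_strands = TRUE) {
  if (nchar(sequence) < pwm$length) {
    stop("sequence shorter than the motif")
  }
  s <- .window_scores(sequence, pwm)
  if (scan_both_strands) s <- c(s, .window_scores(.revcomp(sequence), pwm))
  if (anyNA(s)) {
    warning(sum(is.na(s)), " window(s) skipped (ambiguous base)")
    s <- s[!is.na(s)]
  }
  if (length(s) == 0L) stop("no scorable window in sequence")
  max(s)
}

#' Relative binding score
#'
#' Min-max rescaling of a raw PWM score between the motif's attainable
#' bounds: `(score - min_score) / (max_score - min_score)`, 1 at the
#' consensus and 0 at the anti-consensus. The alternative raw-ratio scale
#' `score / max_score` is available via `method`.
#'
#' @param score raw summed log-odds score.
#' @param pwm a [build_pwm()] object.
#' @param method `"minmax"` (default) or `"ratio"`.
#' @return relative score in \[0, 1\] (minmax).
#' @export
relative_score <- function(score, pwm, method = c("minmax", "ratio")) {
  method <- match.arg(method)
  if (pwm$degenerate) {
    stop("degenerate motif (max_score == min_score): ", pwm$motif_id)
  }
  if (method == "minmax") {
    (score - pwm$min_score) / (pwm$max_score - pwm$min_score)
  } else {
    score / pwm$max_score
  }
}

#' Score a ref/alt allele pair against one motif
#'
#' Scores both allele flanking sequences, converts to relative scores, and
#' returns the pair only if the better allele reaches the gate (at least
#' 80% of the maximum possible binding score by default). The reported
#' difference is the absolute difference of the relative scores.
#'
#' @param pwm a [build_pwm()] object.
#' @param ref_seq,alt_seq allele flanking sequences, identical except at
#'   the SNP base.
#' @param gate minimum relative score on either allele (default 0.8).
#' @param scan_both_strands see [max_binding_score()].
#' @return one-row data frame (motif_id, tf_name, score_ref, score_alt,
#'   rel_ref, rel_alt, abs_difference), or NULL when gated out or the
#'   flank is too short for the motif.
#' @export
score_allele_pair <- function(pwm, ref_seq, alt_seq, gate = 0.8,
                              scan_both_strands = TRUE) {
  if (pwm$degenerate) return(NULL)
  if (nchar(ref_seq) < pwm$length || nchar(alt_seq) < pwm$length) {
    return(NULL)  # flank too short for this motif
  }
  s_ref <- max_binding_score(ref_seq, pwm, scan_both_strands)
  s_alt <- max_binding_score(alt_seq, pwm, scan_both_strands)
  r_ref <- relative_score(s_ref, pwm)
  r_alt <- relative_score(s_alt, pwm)
  if (max(r_ref, r_alt) < gate) return(NULL)
  data.frame(motif_id = pwm$motif_id, tf_name = pwm$tf_name,
             score_ref = s_ref, score_alt = s_alt,
             rel_ref = r_ref, rel_alt = r_alt,
             abs_difference = abs(r_ref - r_alt), stringsAsFactors = FALSE)
}

#' Score all SNP allele pairs against all motifs
#'
#' @param pwms list of [build_pwm()] objects.
#' @param alleles data frame (snp_id, ref_seq, alt_seq).
#' @param gate see [score_allele_pair()].
#' @param scan_both_strands see [max_binding_score()].
#' @return data frame (snp_id, motif_id, tf_name, score_ref, score_alt,
#'   rel_ref, rel_alt, abs_difference) of gated pairs.
#' @export
score_allele_pairs <- function(pwms, alleles, gate = 0.8,
                               scan_both_strands = TRUE) {
  rows <- list()
  for (i in seq_len(nrow(alleles))) {
    for (pwm in pwms) {
      r <- score_allele_pair(pwm, alleles$ref_seq[i], alleles$alt_seq[i],
                             gate = gate,
                             scan_both_strands = scan_both_strands)
      if (!is.null(r)) {
        r <- cbind(data.frame(snp_id = alleles$snp_id[i],
                              stringsAsFactors = FALSE), r)
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(snp_id = character(), motif_id = character(),
                      tf_name = character(), score_ref = numeric(),
                      score_alt = numeric(), rel_ref = numeric(),
                      rel_alt = numeric(), abs_difference = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank transcription factors by allele-differential binding
#'
#' Unique TF names whose best gated pair exceeds the difference threshold,
#' sorted by maximum absolute relative-score difference, descending.
#'
#' @param pairs output of [score_allele_pairs()].
#' @param diff_threshold minimum absolute difference (default 0.2 on the
#'   relative-score scale).
#' @return data frame (tf_name, max_abs_difference, n_pairs), sorted.
#' @export
rank_differential_tfs <- function(pairs, diff_threshold = 0.2) {
  if (nrow(pairs) == 0L) {
    return(data.frame(tf_name = character(), max_abs_difference = numeric(),
                      n_pairs = integer(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(abs_difference ~ tf_name, data = pairs, FUN = max)
  cnt <- stats::aggregate(abs_difference ~ tf_name, data = pairs,
                          FUN = length)
  out <- data.frame(tf_name = agg$tf_name,
                    max_abs_difference = agg$abs_difference,
                    n_pairs = cnt$abs_difference, stringsAsFactors = FALSE)
  out <- out[out$max_abs_difference > diff_threshold, , drop = FALSE]
  out <- out[order(-out$max_abs_difference, out$tf_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap SNP positions with ChIP-defined binding regions
#'
#' Returns the SNPs whose position falls in any region (closed-interval
#' membership, boundaries included), annotated with the TF of the region.
#'
#' @param snps data frame (snp_id, chrom, pos) or a `genotype_matrix`.
#' @param regions data frame (tf, chrom, start, end).
#' @return data frame (snp_id, tf, chrom, pos, region_start, region_end).
#' @export
overlap_chip_regions <- function(snps, regions) {
  snps <- .snp_frame(snps)
  out <- list()
  for (i in seq_len(nrow(regions))) {
    hit <- snps$chrom == regions$chrom[i] &
      .point_in(snps$pos, regions$start[i], regions$end[i])
    if (any(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        snp_id = snps$snp_id[hit], tf = regions$tf[i],
        chrom = snps$chrom[hit], pos = snps$pos[hit],
        region_start = regions$start[i], region_end = regions$end[i],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(snp_id = character(), tf = character(),
                      chrom = character(), pos = integer(),
                      region_start = integer(), region_end = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
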