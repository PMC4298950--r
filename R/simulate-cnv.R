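#' Simulate per-sample CNV segments with planted dosage effects
#'
#' Picks `n_cnv_events` genes as dosage-affected, alternating gain and loss,
#' and emits for each a segment covering the gene (length >= 12 kb, at least
#' five markers) in a subset of 4-8 samples. The first event reproduces the
#' fibroblast-to-hiPSC inheritance pattern: the segment is shared by a
#' fibroblast line and several hiPSC lines derived from it. Three decoy
#' segments deliberately violate the marker-count or length thresholds so
#' the segment filter is exercised; decoys carry no expression effect.
#'
#' @param config a [sim_config()] object.
#' @param annotation a `feature_annotation`.
#' @return object of class `cnv_segment_set`: list with `segments` (sample,
#'   chrom, start, end, state, n_markers, planted) and `dosage` truth
#'   (gene_id, direction, effect, samples as comma-joined ids).
#' @export
simulate_cnv_segments <- function(config, annotation) {
  validate_sim_config(config)
  set.seed(config$seed + 303L)
  smp <- .sim_samples(config)
  genes <- annotation$genes

  segs <- list(); dosage <- list()
  n_ev <- config$n_cnv_events
  if (n_ev > 0L) {
    ev_genes <- genes[sample.int(nrow(genes), n_ev), , drop = FALSE]
    states <- rep(c("gain", "loss"), length.out = n_ev)
    fib <- smp$sample[smp$group == "fibroblast"]
    hipsc <- smp$sample[smp$group == "hiPSC"]
    for (i in seq_len(n_ev)) {
      g <- ev_genes[i, ]
      glen <- g$end - g$start + 1L
      pad <- max(0L, ceiling((12000L - glen) / 2)) + sample.int(3000L, 1L)
      start <- max(1L, g$start - pad)
      end <- g$end + pad
      if (i == 1L && length(fib) > 0L && length(hipsc) >= 3L) {
        ev_samples <- c(fib[1], hipsc[seq_len(min(4L, length(hipsc)))])
      } else {
        k <- sample(4:8, 1L)
        ev_samples <- sample(smp$sample, k)
      }
      segs[[i]] <- data.frame(sample = ev_samples, chrom = g$chrom,
                              start = start, end = end, state = states[i],
                              n_markers = sample(5:40, 1L), planted = TRUE,
                              stringsAsFactors = FALSE)
      dosage[[i]] <- data.frame(
        gene_id = g$gene_id, direction = states[i],
        effect = if (states[i] == "gain") config$cnv_effect else -config$cnv_effect,
        samples = paste(ev_samples, collapse = ","),
        stringsAsFactors = FALSE)
    }

    ## sub-threshold decoys placed between genes (no expression effect)
    decoy <- list(
      list(n_markers = 4L, len = 15000L),   # too few markers
      list(n_markers = 8L, len = 8000L),    # too short
      list(n_markers = 3L, len = 6000L))    # both
    for (d in seq_along(decoy)) {
      chrom <- sample(names(config$chrom_lengths), 1L)
      start <- sample.int(config$chrom_lengths[[chrom]] - decoy[[d]]$len, 1L)
      segs[[length(segs) + 1L]] <- data.frame(
        sample = sample(smp$sample, 1L), chrom = chrom, start = start,
        end = start + decoy[[d]]$len - 1L,
        state = sample(c("gain", "loss"), 1L),
        n_markers = decoy[[d]]$n_markers, planted = FALSE,
        stringsAsFactors = FALSE)
    }
  }

  out <- list(segments = if (length(segs)) do.call(rbind, segs) else
                data.frame(sample = character(), chrom = character(),
                           start = integer(), end = integer(),
                           state = character(), n_markers = integer(),
                           planted = logical(), stringsAsFactors = FALSE),
              dosage = if (length(dosage)) do.call(rbind, dosage) else
                data.frame(gene_id = character(), direction = character(),
                           effect = numeric(), samples = character(),
                           stringsAsFactors = FALSE))
  rownames(out$segments) <- rownames(out$dosage) <- NULL
  class(out) <- "cnv_segment_set"
  out
}
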