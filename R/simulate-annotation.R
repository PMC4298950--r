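#' Simulate a nested gene/transcript/exon annotation
#'
#' Places non-overlapping genes on the configured synthetic chromosomes,
#' nests one or more transcripts inside each gene span and one or more
#' non-overlapping exons inside each transcript span. Introns are derivable
#' as the gaps between consecutive exons of a transcript. Coordinates are
#' 1-based inclusive (GTF convention); strand is assigned but ignored by all
#' downstream linking (distances are unstranded).
#'
#' @param config a [sim_config()] object.
#' @return object of class `feature_annotation`: a list with data frames
#'   `genes` (gene_id, chrom, start, end, strand), `transcripts`
#'   (transcript_id, gene_id, chrom, start, end) and `exons`
#'   (exon_id, transcript_id, gene_id, chrom, start, end, exon_rank).
#' @export
simulate_annotation <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 101L)

  chroms <- names(config$chrom_lengths)
  n_chrom <- length(chroms)
  ## spread genes over chromosomes (>= 2 chromosomes used when possible)
  per_chrom <- diff(floor(seq(0, config$n_genes, length.out = n_chrom + 1L)))

  genes <- list(); txs <- list(); exons <- list()
  gidx <- 0L
  margin <- 10000L   # leave room for 5 kb flanks at chromosome ends
  min_gap <- 15000L  # keeps flank windows of adjacent genes well separated

  for (ci in seq_along(chroms)) {
    ng <- per_chrom[ci]
    if (ng == 0L) next
    clen <- config$chrom_lengths[[ci]]
    glen <- sample(5000:30000, ng, replace = TRUE)
    spare <- clen - 2 * margin - sum(glen) - (ng + 1L) * min_gap
    if (spare < 0) {
      stop(sprintf("cannot fit %d genes on chromosome %s (%g bp)",
                   ng, chroms[ci], clen))
    }
    extra <- if (spare > 0) {
      as.vector(stats::rmultinom(1, size = min(spare, 1e6),
                                 prob = rep(1, ng + 1L)))
    } else rep(0L, ng + 1L)
    gaps <- min_gap + extra
    starts <- margin + cumsum(gaps[seq_len(ng)]) +
      c(0L, if (ng > 1L) cumsum(glen[-ng]))
    ends <- starts + glen - 1L

    for (gi in seq_len(ng)) {
      gidx <- gidx + 1L
      gene_id <- sprintf("G%04d", gidx)
      strand <- sample(c("+", "-"), 1L)
      genes[[gidx]] <- data.frame(gene_id = gene_id, chrom = chroms[ci],
                                  start = starts[gi], end = ends[gi],
                                  strand = strand, stringsAsFactors = FALSE)
      ntx <- sample(seq(config$transcripts_per_gene[1],
                        config$transcripts_per_gene[2]), 1L)
      for (ti in seq_len(ntx)) {
        tx_id <- sprintf("%s.T%d", gene_id, ti)
        gl <- ends[gi] - starts[gi] + 1L
        if (ti == 1L) {
          ts <- starts[gi]; te <- ends[gi]
        } else {
          ts <- starts[gi] + sample.int(max(1L, floor(gl * 0.2)), 1L) - 1L
          te <- ends[gi] - sample.int(max(1L, floor(gl * 0.2)), 1L) + 1L
        }
        txs[[length(txs) + 1L]] <-
          data.frame(transcript_id = tx_id, gene_id = gene_id,
                     chrom = chroms[ci], start = ts, end = te,
                     stringsAsFactors = FALSE)
        nex <- sample(seq(config$exons_per_transcript[1],
                          config$exons_per_transcript[2]), 1L)
        ex <- .partition_exons(ts, te, nex)
        exons[[length(exons) + 1L]] <-
          data.frame(exon_id = sprintf("%s:%d-%d", gene_id, ex$start, ex$end),
                     transcript_id = tx_id, gene_id = gene_id,
                     chrom = chroms[ci], start = ex$start, end = ex$end,
                     exon_rank = seq_len(nrow(ex)), stringsAsFactors = FALSE)
      }
    }
  }

  ann <- list(genes = do.call(rbind, genes),
              transcripts = do.call(rbind, txs),
              exons = do.call(rbind, exons))
  rownames(ann$genes) <- rownames(ann$transcripts) <- rownames(ann$exons) <- NULL
  class(ann) <- "feature_annotation"
  ann
}

## split [s, e] into n ordered exons separated by introns of length >= 1
.partition_exons <- function(s, e, n) {
  L <- e - s + 1L
  if (n == 1L) return(data.frame(start = s, end = e))
  if (L < n * 4L) stop("transcript too short for requested exon count")
  b <- s + floor(L * seq_len(n - 1L) / n)  # block boundaries
  block_start <- c(s, b)
  block_end <- c(b - 1L, e)
  start <- end <- integer(n)
  for (i in seq_len(n)) {
    bl <- block_end[i] - block_start[i] + 1L
    trim_s <- if (i == 1L) 0L else sample.int(max(1L, floor(bl * 0.3)), 1L)
    trim_e <- if (i == n) 0L else max(1L, sample.int(max(1L, floor(bl * 0.3)), 1L))
    start[i] <- block_start[i] + trim_s
    end[i] <- block_end[i] - trim_e
    if (end[i] < start[i]) { # tiny block fallback: single-base exon
      start[i] <- block_start[i]
      end[i] <- block_start[i]
    }
  }
  data.frame(start = start, end = end)
}
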