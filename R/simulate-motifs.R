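#' Simulate TF motif count matrices and allele flanking sequences
#'
#' Generates informative TRANSFAC-style count matrices (one dominant base
#' per column) plus one deliberately uniform (degenerate) motif, and a
#' ref/alt flanking-sequence pair for every SNP. For each planted hit the
#' reference flank carries the motif consensus centred on the SNP while the
#' alternate allele replaces the SNP base with the motif's weakest base,
#' breaking the site. The planted ref/alt bases are returned so the caller
#' can keep the genotype table's alleles consistent.
#'
#' @param config a [sim_config()] object.
#' @param snps data frame (snp_id, ref, alt); the flank set covers all rows.
#' @param planted_snp_ids SNP ids to receive a planted consensus hit
#'   (default: the first `n_planted_motif_hits` rows of `snps`).
#' @return object of class `pwm_set_fixture`: list with `counts` (named list
#'   of 4 x L count matrices, rows A/C/G/T), `tf_names`, `alleles`
#'   (snp_id, ref, alt, ref_seq, alt_seq), and `planted`
#'   (snp_id, motif_id, tf_name, ref, alt).
#' @export
simulate_motifs <- function(config, snps,
                            planted_snp_ids = utils::head(snps$snp_id,
                                                          config$n_planted_motif_hits)) {
  validate_sim_config(config)
  set.seed(config$seed + 505L)
  bases <- c("A", "C", "G", "T")

  ## mixed information content per column, as in real TF motifs: a few
  ## highly specific positions among weakly constrained ones, so that a
  ## single-base change at a specific position moves the relative score
  counts <- list(); tf_names <- character(0); strong_cols <- list()
  for (m in seq_len(config$n_motifs)) {
    L <- sample(6:8, 1L)
    n_strong <- 3L
    strong <- sort(sample.int(L, n_strong))
    cm <- matrix(0, 4, L, dimnames = list(bases, NULL))
    for (j in seq_len(L)) {
      dom <- sample.int(4, 1L)
      if (j %in% strong) {
        cm[, j] <- 0L
        cm[sample(setdiff(1:4, dom), 1L), j] <- 1L
        cm[dom, j] <- 18L
      } else {
        cm[, j] <- 1L + as.vector(stats::rmultinom(1, 4, rep(1, 4)))
        cm[dom, j] <- cm[dom, j] + 2L
      }
    }
    id <- sprintf("M%03d", m)
    counts[[id]] <- cm
    tf_names[id] <- sprintf("TF%02d", m)
    strong_cols[[id]] <- strong
  }
  ## degenerate motif: uniform counts (zero information)
  counts[["M_UNIF"]] <- matrix(5, 4, 6, dimnames = list(bases, NULL))
  tf_names["M_UNIF"] <- "TF_UNIF"

  flank <- config$flank
  width <- 2L * flank + 1L
  centre <- flank + 1L

  seqs <- matrix(sample(bases, width * nrow(snps), replace = TRUE),
                 nrow(snps), width)
  planted <- list()
  informative <- setdiff(names(counts), "M_UNIF")

  for (i in seq_len(nrow(snps))) {
    sid <- snps$snp_id[i]
    if (sid %in% planted_snp_ids) {
      mid <- sample(informative, 1L)
      cm <- counts[[mid]]
      L <- ncol(cm)
      ## the SNP sits at a high-information column so the alternate allele
      ## actually disrupts binding
      off <- sample(rep(strong_cols[[mid]], 2L), 1L)
      cons <- bases[apply(cm, 2, which.max)]
      worst <- bases[which.min(cm[, off])]
      if (worst == cons[off]) worst <- bases[order(cm[, off])][2]
      s <- centre - off + 1L
      seqs[i, s:(s + L - 1L)] <- cons
      ref_b <- cons[off]; alt_b <- worst
      planted[[length(planted) + 1L]] <-
        data.frame(snp_id = sid, motif_id = mid, tf_name = tf_names[[mid]],
                   ref = ref_b, alt = alt_b, stringsAsFactors = FALSE)
    } else {
      ref_b <- snps$ref[i]
    }
    seqs[i, centre] <- ref_b
  }

  ref_seq <- apply(seqs, 1, paste, collapse = "")
  alt_base <- snps$alt
  if (length(planted)) {
    pl <- do.call(rbind, planted)
    alt_base[match(pl$snp_id, snps$snp_id)] <- pl$alt
  } else {
    pl <- data.frame(snp_id = character(), motif_id = character(),
                     tf_name = character(), ref = character(),
                     alt = character(), stringsAsFactors = FALSE)
  }
  alt_seq <- ref_seq
  substr(alt_seq, centre, centre) <- alt_base

  ref_base <- substr(ref_seq, centre, centre)
  alleles <- data.frame(snp_id = snps$snp_id, ref = ref_base, alt = alt_base,
                        ref_seq = ref_seq, alt_seq = alt_seq,
                        stringsAsFactors = FALSE)

  out <- list(counts = counts, tf_names = tf_names, alleles = alleles,
              planted = pl)
  class(out) <- "pwm_set_fixture"
  out
}

#' Simulate ChIP-defined TF binding regions away from all SNPs
#'
#' Emits a handful of binding regions per core TF, placed so that no
#' simulated SNP overlaps any region (mirroring the observation that the
#' associated SNPs did not fall inside measured binding sites).
#'
#' @param config a [sim_config()] object.
#' @param snps data frame with chrom and pos columns.
#' @param tfs TF names to emit regions for.
#' @return data frame (tf, chrom, start, end).
#' @export
simulate_chip_regions <- function(config, snps,
                                  tfs = c("NANOG", "OCT4", "SOX2", "E2F4")) {
  set.seed(config$seed + 606L)
  out <- list()
  for (tf in tfs) {
    for (k in 1:5) {
      for (try in 1:100) {
        chrom <- sample(names(config$chrom_lengths), 1L)
        start <- sample.int(config$chrom_lengths[[chrom]] - 500L, 1L)
        end <- start + 399L
        here <- snps$chrom == chrom & .point_in(snps$pos, start, end)
        if (!any(here)) break
      }
      out[[length(out) + 1L]] <- data.frame(tf = tf, chrom = chrom,
                                            start = start, end = end,
                                            stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
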