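test_that("degenerate config collapses gene, transcript and exon spans", {
  cfg <- sim_config(n_genes = 1L, transcripts_per_gene = c(1L, 1L),
                    exons_per_transcript = c(1L, 1L), n_snps = 5L,
                    n_causal_snps = 0L, n_cnv_events = 0L,
                    chrom_lengths = c(chr1 = 1e6))
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann$genes), 1L)
  expect_equal(ann$transcripts$start, ann$genes$start)
  expect_equal(ann$transcripts$end, ann$genes$end)
  expect_equal(ann$exons$start, ann$genes$start)
  expect_equal(ann$exons$end, ann$genes$end)
})

test_that("annotation is deterministic under a fixed seed and nests cleanly", {
  cfg <- sim_config(n_genes = 10L, n_snps = 10L, n_causal_snps = 0L,
                    n_cnv_events = 0L)
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(a1, a2)

  # brute-force containment: every exon inside its transcript, every
  # transcript inside its gene, genes non-overlapping per chromosome
  ann <- simulate_annotation(sim_config(n_genes = 30L, seed = 7L))
  tx <- ann$transcripts
  g <- ann$genes[match(tx$gene_id, ann$genes$gene_id), ]
  expect_true(all(tx$start >= g$start & tx$end <= g$end))
  ex <- ann$exons
  t2 <- tx[match(ex$transcript_id, tx$transcript_id), ]
  expect_true(all(ex$start >= t2$start & ex$end <= t2$end))
  for (ch in unique(ann$genes$chrom)) {
    gg <- ann$genes[ann$genes$chrom == ch, ]
    gg <- gg[order(gg$start), ]
    if (nrow(gg) > 1) {
      expect_true(all(gg$start[-1] > gg$end[-nrow(gg)]))
    }
  }
  # introns derivable: consecutive exons of a transcript do not touch
  for (tid in unique(ex$transcript_id)) {
    e <- ex[ex$transcript_id == tid, ]
    e <- e[order(e$start), ]
    if (nrow(e) > 1) expect_true(all(e$start[-1] > e$end[-nrow(e)] + 1L))
  }
})

test_that("annotation errors when genes cannot fit the chromosomes", {
  expect_error(
    simulate_annotation(sim_config(n_genes = 60L,
                                   chrom_lengths = c(chr1 = 1e5, chr2 = 1e5))),
    "cannot fit")
})

test_that("genotypes follow Hardy-Weinberg sampling and are reproducible", {
  cfg <- sim_config(n_snps = 20L, n_causal_snps = 0L, n_cnv_events = 0L)
  ann <- simulate_annotation(cfg)
  g1 <- simulate_genotypes(cfg, ann)
  g2 <- simulate_genotypes(cfg, ann)
  expect_identical(g1$calls, g2$calls)
  expect_true(all(g1$calls %in% 1:3))
  expect_true(all(g1$confidences > 0 & g1$confidences <= 1))

  # binomial oracle: at allele frequency 0.5 the heterozygote fraction in a
  # large sample is 0.5 within 3 binomial SDs
  set.seed(42)
  n <- 10000L
  calls <- rbinom(n, 2, 0.5) + 1L
  het <- mean(calls == 2L)
  expect_lt(abs(het - 0.5), 3 * sqrt(0.5 * 0.5 / n))
  # allele frequency 0: all calls homozygous reference
  expect_true(all(rbinom(50, 2, 0) + 1L == 1L))
})

test_that("SNP positions cover inside-gene, flank and distal placements", {
  cfg <- sim_config(seed = 3L)
  ann <- simulate_annotation(cfg)
  gt <- simulate_genotypes(cfg, ann)
  g <- ann$genes
  cls <- vapply(seq_len(nrow(gt$snps)), function(i) {
    s <- gt$snps[i, ]
    same <- g[g$chrom == s$chrom, ]
    if (any(brute_overlap(s$pos, same$start, same$end))) return("inside")
    if (any(brute_overlap(s$pos, same$start - 5000L, same$end + 5000L))) {
      return("flank")
    }
    "far"
  }, character(1))
  expect_true(all(c("inside", "flank", "far") %in% cls))
})

test_that("CNV segments carry thresholds fodder and lineage sharing", {
  cfg <- sim_config()
  ann <- simulate_annotation(cfg)
  cnv <- simulate_cnv_segments(cfg, ann)
  seg <- cnv$segments
  expect_true(all(seg$state %in% c("gain", "loss")))
  # decoys below the marker or length thresholds exist and are marked
  sub <- seg[!seg$planted, ]
  expect_true(any(sub$n_markers < 5 | (sub$end - sub$start + 1) < 10000))
  # the first event is shared between a fibroblast line and derived hiPSCs
  ev1 <- seg[seg$planted & seg$start == seg$start[1] & seg$chrom == seg$chrom[1], ]
  expect_true(any(grepl("^fibroblast", ev1$sample)))
  expect_true(sum(grepl("^hiPSC", ev1$sample)) >= 3)

  # brute-force gene overlap oracle against the labelling used downstream
  labels <- label_gene_states(ann, seg, samples = unique(seg$sample),
                              min_markers = 0L, min_length = 0L)
  for (i in seq_len(nrow(seg))) {
    hit <- ann$genes$chrom == seg$chrom[i] &
      !(ann$genes$end < seg$start[i] | ann$genes$start > seg$end[i])
    for (gid in ann$genes$gene_id[hit]) {
      expect_true(labels[gid, seg$sample[i]] != "normal")
    }
  }

  # no events requested -> empty set
  cfg0 <- sim_config(n_cnv_events = 0L)
  cnv0 <- simulate_cnv_segments(cfg0, simulate_annotation(cfg0))
  expect_equal(nrow(cnv0$segments), 0L)
})

test_that("expression generator reproduces the additive model exactly at low noise", {
  # one causal SNP, effect 1.0, tiny noise: expression difference between
  # genotype 3 and genotype 1 approaches 2.0 log2 units
  cfg <- sim_config(n_genes = 10L, n_snps = 5L, n_causal_snps = 1L,
                    n_cnv_events = 0L, eqtl_effect = 1.0, noise_sd = 1e-4,
                    transcripts_per_gene = c(1L, 1L),
                    exons_per_transcript = c(2L, 2L), seed = 11L)
  st <- simulate_study(cfg)
  tr <- st$truth$causal
  expect_equal(nrow(tr), 1L)
  eqc <- run_expression_qc(st$probes)
  lev <- tr$level
  expr <- eqc$expression[[lev]]
  vals <- as.numeric(expr[expr$feature_id == tr$feature_id,
                          st$samples$sample])
  calls <- st$genotypes$calls[tr$snp_id, ]
  m3 <- mean(vals[calls == 3]); m1 <- mean(vals[calls == 1])
  expect_equal(m3 - m1, 2.0, tolerance = 1e-2)
})

test_that("planted gain of 0.589 log2 realises a linear fold change near 1.50", {
  cfg <- sim_config(n_genes = 20L, n_snps = 5L, n_causal_snps = 0L,
                    n_cnv_events = 2L, cnv_effect = 0.589, noise_sd = 0.05,
                    seed = 5L)
  st <- simulate_study(cfg)
  gain <- st$truth$dosage[st$truth$dosage$direction == "gain", ][1, ]
  eqc <- run_expression_qc(st$probes)
  expr <- eqc$expression$gene
  vals <- as.numeric(expr[expr$feature_id == gain$gene_id,
                          st$samples$sample])
  names(vals) <- st$samples$sample
  carriers <- strsplit(gain$samples, ",")[[1]]
  lfc <- mean(vals[carriers]) - mean(vals[setdiff(names(vals), carriers)])
  expect_equal(2^lfc, 1.50, tolerance = 0.05)
})

test_that("null simulation has an empty truth table", {
  cfg <- sim_config(eqtl_effect = 0, cnv_effect = 0, n_cnv_events = 2L,
                    n_causal_snps = 5L)
  st <- simulate_study(cfg)
  expect_equal(nrow(st$truth$causal), 0L)
  expect_equal(nrow(st$truth$dosage), 0L)
})

test_that("every planted causal pair is linkable under its level's rule", {
  st <- simulate_study(sim_config(seed = 9L))
  tr <- st$truth$causal
  expect_gt(nrow(tr), 0L)
  pairs <- list(gene = link_gene(st$genotypes, st$annotation),
                transcript = link_transcript(st$genotypes, st$annotation),
                exon = link_exon_short(st$genotypes, st$annotation))
  for (i in seq_len(nrow(tr))) {
    p <- pairs[[tr$level[i]]]
    expect_true(any(p$snp_id == tr$snp_id[i] &
                      p$feature_id == tr$feature_id[i]),
                label = paste("linkable", tr$snp_id[i]))
  }
})

test_that("motif fixtures plant a consensus hit on the reference allele", {
  st <- simulate_study(sim_config(seed = 2L))
  pl <- st$truth$motif_hits
  expect_gt(nrow(pl), 0L)
  for (i in seq_len(nrow(pl))) {
    pwm <- build_pwm(st$motifs$counts[[pl$motif_id[i]]],
                     motif_id = pl$motif_id[i])
    a <- st$motifs$alleles[st$motifs$alleles$snp_id == pl$snp_id[i], ]
    expect_equal(relative_score(max_binding_score(a$ref_seq, pwm), pwm), 1.0)
    r <- score_allele_pair(pwm, a$ref_seq, a$alt_seq)
    expect_false(is.null(r))
    expect_gt(r$abs_difference, 0)
  }
  # degenerate motif is emitted and is flagged by build_pwm
  expect_true("M_UNIF" %in% names(st$motifs$counts))
  expect_true(build_pwm(st$motifs$counts[["M_UNIF"]])$degenerate)
  # same seed -> identical fixtures
  st2 <- simulate_study(sim_config(seed = 2L))
  expect_identical(st$motifs$alleles, st2$motifs$alleles)
})

test_that("simulated study is byte-identical under a fixed seed", {
  s1 <- simulate_study(sim_config(seed = 4L))
  s2 <- simulate_study(sim_config(seed = 4L))
  expect_identical(s1$probes, s2$probes)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$cnv, s2$cnv)
})
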