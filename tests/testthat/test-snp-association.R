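snps_at <- function(pos, chrom = "chr1") {
  data.frame(snp_id = sprintf("snp%03d", seq_along(pos)),
             chrom = rep_len(chrom, length(pos)), pos = pos,
             stringsAsFactors = FALSE)
}

test_that("gene linking honours the 5 kb flank boundaries", {
  ann <- three_exon_annotation()
  ann$genes$start <- 11000L; ann$genes$end <- 19000L
  snps <- snps_at(c(11000L - 4999L,  # inside upstream flank
                    11000L - 5000L,  # exactly 5000 upstream -> linked
                    11000L - 5001L,  # 5001 upstream -> not linked
                    19000L + 5000L,  # exactly 5000 downstream -> linked
                    19000L + 5001L,  # 5001 downstream -> not linked
                    15000L))         # inside the gene
  lp <- link_gene(snps, ann)
  expect_setequal(lp$snp_id, c("snp001", "snp002", "snp004", "snp006"))
  expect_true(lp$snp_inside_feature[lp$snp_id == "snp006"])
  expect_false(any(lp$snp_inside_feature[lp$snp_id != "snp006"]))
})

test_that("transcript linking is span-based, introns included", {
  ann <- three_exon_annotation()
  snps <- snps_at(c(3000L,   # intron of t1 -> linked
                    9001L,   # 1 bp past the transcript end -> not linked
                    999L))   # 1 bp before -> not linked
  lp <- link_transcript(snps, ann)
  expect_equal(lp$snp_id, "snp001")
  expect_true(all(lp$snp_inside_feature))
})

test_that("short-interval exon linking uses only adjacent introns", {
  ann <- three_exon_annotation()
  # exons: e1 1000-2000, e2 4000-5000, e3 7000-9000
  # introns: 2001-3999 (e1|e2), 5001-6999 (e2|e3)
  lp <- link_exon_short(snps_at(c(4500L, 3000L, 6000L, 1500L, 500L)), ann)
  get <- function(id) sort(lp$feature_id[lp$snp_id == id])
  expect_equal(get("snp001"), "e2")             # inside e2
  expect_equal(get("snp002"), c("e1", "e2"))    # intron 1 adjacent to both
  expect_equal(get("snp003"), c("e2", "e3"))    # intron 2 adjacent to both
  expect_equal(get("snp004"), "e1")             # inside e1
  expect_equal(get("snp005"), character(0))     # upstream of the gene
  # a SNP two introns away from e1 is not linked to it
  expect_false("e1" %in% get("snp003"))
  # inside flag marks the exon body only
  expect_true(lp$snp_inside_feature[lp$snp_id == "snp001"])
  expect_false(any(lp$snp_inside_feature[lp$snp_id == "snp002"]))
})

test_that("multi-transcript exons use the union of adjacent introns", {
  ann <- make_annotation(
    genes = data.frame(gene_id = "g1", chrom = "chr1", start = 1000L,
                       end = 9000L, strand = "+", stringsAsFactors = FALSE),
    transcripts = data.frame(transcript_id = c("t1", "t2"), gene_id = "g1",
                             chrom = "chr1", start = 1000L, end = 9000L,
                             stringsAsFactors = FALSE),
    exons = data.frame(
      exon_id = c("eA", "eShared", "eB", "eShared"),
      transcript_id = c("t1", "t1", "t2", "t2"),
      gene_id = "g1", chrom = "chr1",
      start = c(1000L, 4000L, 2500L, 4000L),
      end = c(2000L, 5000L, 2600L, 5000L),
      exon_rank = c(1L, 2L, 1L, 2L), stringsAsFactors = FALSE))
  # eShared's left intron is 2001-3999 under t1 but 2601-3999 under t2;
  # a SNP at 2300 reaches eShared only via t1's adjacency
  lp <- link_exon_short(snps_at(2300L), ann)
  expect_true("eShared" %in% lp$feature_id)
})

test_that("long-interval exon linking spans the gene and contains the short set", {
  ann <- three_exon_annotation()
  lp_long <- link_exon_long(snps_at(c(3000L, 500L, 9000L)), ann)
  # whole gene span: SNP in any intron links to every exon
  expect_setequal(lp_long$feature_id[lp_long$snp_id == "snp001"],
                  c("e1", "e2", "e3"))
  # upstream of the gene: no flank at the exon level
  expect_false("snp002" %in% lp_long$snp_id)
  set.seed(19)
  for (rep in 1:25) {
    cfg <- sim_config(n_genes = 8L, n_snps = 40L, n_causal_snps = 0L,
                      n_cnv_events = 0L, seed = 100L + rep)
    ann_r <- simulate_annotation(cfg)
    gt <- simulate_genotypes(cfg, ann_r)
    short <- link_exon_short(gt, ann_r)
    long <- link_exon_long(gt, ann_r)
    key <- function(d) paste(d$snp_id, d$feature_id)
    expect_true(all(key(short) %in% key(long)))
  }
})

test_that("all four linking rules equal brute-force all-pairs scans", {
  set.seed(23)
  for (rep in 1:5) {
    cfg <- sim_config(n_genes = 10L, n_snps = 60L, n_causal_snps = 0L,
                      n_cnv_events = 0L, seed = 200L + rep)
    ann <- simulate_annotation(cfg)
    gt <- simulate_genotypes(cfg, ann)
    snps <- gt$snps
    key <- function(d) sort(paste(d$snp_id, d$feature_id))

    # gene +- 5 kb
    bf <- list()
    for (i in seq_len(nrow(snps))) {
      g <- ann$genes
      hit <- g$chrom == snps$chrom[i] &
        brute_overlap(snps$pos[i], g$start - 5000L, g$end + 5000L)
      if (any(hit)) bf[[length(bf) + 1L]] <-
          paste(snps$snp_id[i], g$gene_id[hit])
    }
    expect_identical(key(link_gene(snps, ann)),
                     sort(unlist(bf) %||% character(0)))

    # transcript span
    bf <- list()
    for (i in seq_len(nrow(snps))) {
      t <- ann$transcripts
      hit <- t$chrom == snps$chrom[i] &
        brute_overlap(snps$pos[i], t$start, t$end)
      if (any(hit)) bf[[length(bf) + 1L]] <-
          paste(snps$snp_id[i], t$transcript_id[hit])
    }
    expect_identical(key(link_transcript(snps, ann)),
                     sort(unlist(bf) %||% character(0)))

    # exon short: exon plus adjacent introns per parent transcript
    bf <- character(0)
    for (tid in unique(ann$exons$transcript_id)) {
      e <- ann$exons[ann$exons$transcript_id == tid, ]
      e <- e[order(e$start), ]
      for (j in seq_len(nrow(e))) {
        ws <- if (j == 1) e$start[j] else e$end[j - 1] + 1L
        we <- if (j == nrow(e)) e$end[j] else e$start[j + 1] - 1L
        hit <- snps$chrom == e$chrom[j] & brute_overlap(snps$pos, ws, we)
        if (any(hit)) bf <- c(bf, paste(snps$snp_id[hit], e$exon_id[j]))
      }
    }
    expect_identical(key(link_exon_short(snps, ann)), sort(unique(bf)))

    # exon long: whole parent gene span
    bf <- character(0)
    ex <- ann$exons[!duplicated(ann$exons$exon_id), ]
    for (j in seq_len(nrow(ex))) {
      g <- ann$genes[ann$genes$gene_id == ex$gene_id[j], ]
      hit <- snps$chrom == g$chrom & brute_overlap(snps$pos, g$start, g$end)
      if (any(hit)) bf <- c(bf, paste(snps$snp_id[hit], ex$exon_id[j]))
    }
    expect_identical(key(link_exon_long(snps, ann)), sort(unique(bf)))
  }
})

test_that("regression matches lm() and handles degenerate inputs", {
  calls <- c(1, 1, 2, 2, 3, 3)
  expr <- c(1.0, 1.2, 1.9, 2.1, 3.0, 3.2)
  fit <- fit_genotype_regression(expr, calls)
  oracle <- summary(lm(expr ~ calls))
  expect_equal(fit$slope, unname(coef(oracle)["calls", "Estimate"]),
               tolerance = 1e-12)
  expect_equal(fit$slope, 1.0, tolerance = 1e-12)  # hand OLS: Sxy/Sxx = 4/4
  expect_equal(fit$t_statistic, unname(coef(oracle)["calls", "t value"]),
               tolerance = 1e-10)
  expect_equal(fit$raw_p, unname(coef(oracle)["calls", "Pr(>|t|)"]),
               tolerance = 1e-10)
  expect_equal(unname(fit$genotype_counts), c(2L, 2L, 2L))

  # constant expression: slope 0, p 1
  f0 <- fit_genotype_regression(rep(5, 6), calls)
  expect_equal(f0$slope, 0)
  expect_equal(f0$raw_p, 1)
  # perfect linear fit: slope recovered exactly, p = 0, flagged
  fp <- fit_genotype_regression(2 * calls, calls)
  expect_equal(fp$slope, 2)
  expect_equal(fp$raw_p, 0)
  expect_true(fp$perfect_fit)
  # monomorphic genotype is an error (scan skips such pairs)
  expect_error(fit_genotype_regression(expr, rep(2, 6)), "monomorphic")
})

test_that("regression equals lm() on many random fixtures", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(5:25, 1)
    calls <- sample(1:3, n, replace = TRUE)
    if (length(unique(calls)) < 2) next
    expr <- rnorm(n, 8, 1) + 0.3 * calls
    fit <- fit_genotype_regression(expr, calls)
    co <- summary(lm(expr ~ calls))$coefficients
    expect_equal(fit$slope, unname(co["calls", "Estimate"]),
                 tolerance = 1e-10)
    expect_equal(fit$t_statistic, unname(co["calls", "t value"]),
                 tolerance = 1e-10)
    expect_equal(fit$raw_p, unname(co["calls", "Pr(>|t|)"]),
                 tolerance = 1e-10)
  }
})

test_that("the scan skips monomorphic and low-variation pairs with reasons", {
  ann <- three_exon_annotation()
  gt <- make_genotypes(rbind(c(1, 2, 3, 2, 1, 3),
                             rep(2, 6),
                             c(1, 1, 1, 1, 1, 2)),
                       pos = c(5000L, 5100L, 5200L))
  expr <- make_expression(matrix(rnorm(6, 8), 1, 6,
                                 dimnames = list("g1", paste0("s", 1:6))))
  pairs <- link_gene(gt, ann)
  res <- run_snp_scan(pairs, expr, gt)
  expect_equal(res$snp_id, "snp001")
  skipped <- attr(res, "skipped")
  expect_setequal(skipped$snp_id, c("snp002", "snp003"))
  expect_true("monomorphic in tested group" %in%
                skipped$reason[skipped$snp_id == "snp002"])
  expect_true("below variation threshold in tested group" %in%
                skipped$reason[skipped$snp_id == "snp003"])
  # zero pairs -> empty table
  none <- run_snp_scan(pairs[0, ], expr, gt)
  expect_equal(nrow(none), 0L)
})

test_that("overlap summaries match brute-force set algebra", {
  ann <- three_exon_annotation()
  mk <- function(snp, feat, level, sig, inside = TRUE) {
    data.frame(snp_id = snp, feature_id = feat, level = level,
               snp_inside_feature = inside, slope = 1, intercept = 0,
               t_statistic = 3, raw_p = 0.01, adjusted_p = 0.05,
               significant = sig, n = 6L, n_g1 = 2L, n_g2 = 2L, n_g3 = 2L,
               perfect_fit = FALSE, stringsAsFactors = FALSE)
  }
  results <- list(
    "gene.all" = mk(c("s1", "s2"), c("g1", "g1"), "gene", c(TRUE, FALSE)),
    "transcript.all" = mk("s1", "t1", "transcript", TRUE),
    "exon_short.all" = mk("s9", "e2", "exon_short", FALSE),
    "exon_long.all" = mk("s1", "e1", "exon_long", TRUE, inside = FALSE))
  ov <- summarize_overlaps(results, ann)
  fam <- ov$families
  expect_equal(fam$n_significant[fam$level == "gene"], 1L)
  expect_equal(fam$n_tested[fam$level == "gene"], 2L)
  expect_equal(fam$n_genes[fam$level == "transcript"], 1L)
  # all three significant families resolve to gene g1: one region pattern
  expect_equal(sum(ov$venn), 1L)
  expect_equal(names(ov$venn), "gene&transcript&exon_long")
  # s1 is significant at gene, transcript, exon_long but not exon_short
  expect_equal(ov$snps_significant_all_levels, 0L)
  results$exon_short.all$significant <- TRUE
  results$exon_short.all$snp_id <- "s1"
  ov2 <- summarize_overlaps(results, ann)
  expect_equal(ov2$snps_significant_all_levels, 1L)

  # single significant gene-level pair only -> gene-only Venn region
  ov3 <- summarize_overlaps(results["gene.all"], ann)
  expect_equal(as.integer(ov3$venn["gene"]), 1L)
})

test_that("CNV cross-reference is the set intersection at gene resolution", {
  ann <- three_exon_annotation()
  snp_res <- data.frame(snp_id = "s1", feature_id = "t1",
                        level = "transcript", snp_inside_feature = TRUE,
                        slope = 1, intercept = 0, t_statistic = 3,
                        raw_p = 0.01, adjusted_p = 0.05, significant = TRUE,
                        n = 6L, n_g1 = 2L, n_g2 = 2L, n_g3 = 2L,
                        perfect_fit = FALSE, stringsAsFactors = FALSE)
  cnv_res <- data.frame(gene_id = "g1", direction = "gain", n_altered = 2L,
                        n_normal = 4L, weight = 2, log2_fc = 1,
                        linear_fc = 2, raw_p = 0.001, adjusted_p = 0.01,
                        significant = TRUE, negative_direction = FALSE,
                        stringsAsFactors = FALSE)
  hit <- cross_reference_cnv(snp_res, cnv_res, ann)
  expect_equal(hit$gene_id, "g1")
  expect_match(hit$flag, "may reflect CNV")
  # disjoint sets -> empty
  cnv2 <- transform(cnv_res, significant = FALSE)
  expect_equal(nrow(cross_reference_cnv(snp_res, cnv2, ann)), 0L)
})
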