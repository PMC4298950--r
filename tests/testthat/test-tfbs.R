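simple_pwm <- function() {
  # consensus ACGT, strongly informative
  counts <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts[cbind(1:4, 1:4)] <- 18
  counts[cbind(c(2, 3, 4, 1), 1:4)] <- 1
  build_pwm(counts, motif_id = "m1", tf_name = "TF1")
}

test_that("PWM construction follows the pseudocount arithmetic", {
  # single column (1,0,0,0): f_A = (1 + 0.005)/1.02, log-odds ~ 1.9786
  pwm <- build_pwm(matrix(c(1, 0, 0, 0), 4, 1,
                          dimnames = list(c("A", "C", "G", "T"), NULL)))
  f_a <- (1 + 0.005) / 1.02
  expect_equal(unname(pwm$freqs["A", 1]), f_a, tolerance = 1e-12)
  expect_equal(unname(pwm$logodds["A", 1]), log2(f_a / 0.25), tolerance = 1e-12)
  expect_equal(round(unname(pwm$logodds["A", 1]), 4), 1.9786)
  # every column sums to 1 after pseudocount normalisation
  set.seed(3)
  cm <- matrix(rpois(20, 5) + 1, 4, 5,
               dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm2 <- build_pwm(cm)
  expect_equal(unname(colSums(pwm2$freqs)), rep(1, 5), tolerance = 1e-12)
  # uniform column: frequencies exactly 0.25, log-odds exactly 0
  pu <- build_pwm(matrix(3, 4, 2, dimnames = list(c("A", "C", "G", "T"),
                                                  NULL)))
  expect_true(all(pu$logodds == 0))
  expect_true(pu$degenerate)
  expect_error(build_pwm(matrix(c(0, 0, 0, 0, 1, 1, 1, 1), 4, 2)),
               "all-zero")
  # attainable bounds are sums of column extrema
  expect_equal(pwm2$max_score, sum(apply(pwm2$logodds, 2, max)))
  expect_equal(pwm2$min_score, sum(apply(pwm2$logodds, 2, min)))
})

test_that("sliding max equals exhaustive window enumeration on both strands", {
  pwm <- simple_pwm()
  # consensus attains the maximum attainable score
  expect_equal(max_binding_score("ACGT", pwm, scan_both_strands = FALSE),
               pwm$max_score, tolerance = 1e-12)
  expect_equal(relative_score(max_binding_score("TTACGTTT", pwm), pwm), 1.0)

  set.seed(6)
  for (rep in 1:25) {
    seq <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    # brute force over all windows of both strands
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq)))
    score_window <- function(w) {
      b <- strsplit(w, "")[[1]]
      sum(pwm$logodds[cbind(match(b, c("A", "C", "G", "T")),
                            seq_along(b))])
    }
    wins <- c(vapply(1:(30 - 4 + 1),
                     function(i) score_window(substr(seq, i, i + 3)),
                     numeric(1)),
              vapply(1:(30 - 4 + 1),
                     function(i) score_window(substr(rc, i, i + 3)),
                     numeric(1)))
    expect_equal(max_binding_score(seq, pwm), max(wins), tolerance = 1e-12)
  }
})

test_that("scores are strand-invariant", {
  pwm <- simple_pwm()
  set.seed(9)
  for (rep in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq)))
    expect_equal(max_binding_score(seq, pwm), max_binding_score(rc, pwm),
                 tolerance = 1e-12)
  }
})

test_that("ambiguous bases skip windows with a warning; short sequences error", {
  pwm <- simple_pwm()
  expect_warning(s <- max_binding_score("ACGTNACGT", pwm), "ambiguous")
  expect_equal(s, pwm$max_score, tolerance = 1e-12)
  expect_error(max_binding_score("ACG", pwm), "shorter")
})

test_that("relative score spans [0, 1] with consensus and anti-consensus", {
  pwm <- simple_pwm()
  expect_equal(relative_score(pwm$max_score, pwm), 1.0)
  expect_equal(relative_score(pwm$min_score, pwm), 0.0)
  mid <- (pwm$max_score + pwm$min_score) / 2
  expect_equal(relative_score(mid, pwm), 0.5)
  set.seed(4)
  for (rep in 1:20) {
    seq <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
    r <- relative_score(max_binding_score(seq, pwm), pwm)
    expect_gte(r, 0); expect_lte(r, 1)
  }
  # ratio alternative is available
  expect_equal(relative_score(pwm$max_score, pwm, method = "ratio"), 1.0)
  # degenerate motifs are rejected
  uni <- build_pwm(matrix(5, 4, 3, dimnames = list(c("A", "C", "G", "T"),
                                                   NULL)))
  expect_error(relative_score(1, uni), "degenerate")
})

test_that("allele pairs gate at 80% and report the absolute difference", {
  pwm <- simple_pwm()
  ref <- "TTTACGTTTT"   # consensus at offset 4
  alt <- "TTTACTTTTT"   # G -> T breaks the third motif position
  r <- score_allele_pair(pwm, ref, alt, gate = 0.8)
  expect_false(is.null(r))
  expect_equal(r$rel_ref, 1.0)
  expect_gt(r$abs_difference, 0)
  expect_equal(r$abs_difference, abs(r$rel_ref - r$rel_alt))
  # identical alleles: zero difference
  r0 <- score_allele_pair(pwm, ref, ref)
  expect_equal(r0$abs_difference, 0)
  # both alleles below the gate -> nothing returned
  expect_null(score_allele_pair(pwm, "TTTTTTTTTT", "TTTTTTTTTT"))
  # gate monotonicity: raising the gate never returns more pairs
  alleles <- data.frame(snp_id = c("a", "b"),
                        ref_seq = c(ref, "TTTTTTTTTT"),
                        alt_seq = c(alt, "TTTTTTTTTA"),
                        stringsAsFactors = FALSE)
  n_prev <- Inf
  for (g in c(0, 0.5, 0.8, 0.95, 1)) {
    n_now <- nrow(score_allele_pairs(list(pwm), alleles, gate = g))
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
  # reverse-complementing both alleles leaves the pair unchanged
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  r_rc <- score_allele_pair(pwm, rc(ref), rc(alt))
  expect_equal(r_rc$rel_ref, r$rel_ref, tolerance = 1e-12)
  expect_equal(r_rc$rel_alt, r$rel_alt, tolerance = 1e-12)
})

test_that("TF ranking filters by threshold and sorts by difference", {
  pairs <- data.frame(
    snp_id = c("s1", "s2", "s3"),
    motif_id = c("m1", "m2", "m1"),
    tf_name = c("TFa", "TFb", "TFa"),
    score_ref = 1, score_alt = 0,
    rel_ref = c(1, 1, 0.9), rel_alt = c(0.7, 0.95, 0.8),
    abs_difference = c(0.3, 0.05, 0.1), stringsAsFactors = FALSE)
  # threshold 0: every TF with a gated pair
  expect_setequal(rank_differential_tfs(pairs, 0)$tf_name, c("TFa", "TFb"))
  # default threshold keeps only the large difference, best pair per TF
  top <- rank_differential_tfs(pairs, 0.2)
  expect_equal(top$tf_name, "TFa")
  expect_equal(top$max_abs_difference, 0.3)
  # threshold above the maximum -> empty
  expect_equal(nrow(rank_differential_tfs(pairs, 0.5)), 0L)
})

test_that("ChIP region overlap is closed-interval point membership", {
  snps <- data.frame(snp_id = c("s1", "s2", "s3"), chrom = "chr1",
                     pos = c(100L, 200L, 300L), stringsAsFactors = FALSE)
  regions <- data.frame(tf = "NANOG", chrom = "chr1", start = 100L,
                        end = 250L, stringsAsFactors = FALSE)
  hits <- overlap_chip_regions(snps, regions)
  expect_setequal(hits$snp_id, c("s1", "s2"))  # boundary start included
  expect_equal(nrow(overlap_chip_regions(snps, regions[0, ])), 0L)
  # random fixture equals the brute-force oracle
  set.seed(13)
  snps_r <- data.frame(snp_id = sprintf("r%02d", 1:50),
                       chrom = sample(c("chr1", "chr2"), 50, TRUE),
                       pos = sample.int(10000L, 50), stringsAsFactors = FALSE)
  reg_r <- data.frame(tf = sample(c("A", "B"), 8, TRUE),
                      chrom = sample(c("chr1", "chr2"), 8, TRUE),
                      start = sample.int(9000L, 8))
  reg_r$end <- reg_r$start + sample.int(800L, 8)
  got <- overlap_chip_regions(snps_r, reg_r)
  want <- character(0)
  for (i in seq_len(nrow(reg_r))) {
    hit <- snps_r$chrom == reg_r$chrom[i] &
      brute_overlap(snps_r$pos, reg_r$start[i], reg_r$end[i])
    if (any(hit)) want <- c(want, paste(snps_r$snp_id[hit], reg_r$tf[i]))
  }
  expect_setequal(paste(got$snp_id, got$tf), want)
})

test_that("TRANSFAC round-trip preserves counts and TF names", {
  st <- simulate_study(sim_config(seed = 8L))
  path <- tempfile(fileext = ".transfac")
  write_transfac(st$motifs$counts, st$motifs$tf_names, path)
  back <- read_transfac(path)
  expect_equal(names(back$counts), names(st$motifs$counts))
  for (id in names(back$counts)) {
    expect_equal(unname(back$counts[[id]]),
                 unname(st$motifs$counts[[id]]))
  }
  expect_equal(unname(back$tf_names), unname(st$motifs$tf_names))
})
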