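#' Label per-gene copy states from CNV segments
#'
#' Segments failing the marker-count or length thresholds are discarded.
#' A gene is labelled `gain` or `loss` in a sample iff its span overlaps a
#' surviving segment of that state by at least one base; overlap with both
#' states in one sample yields `ambiguous` (excluded from testing);
#' otherwise the state is `normal`.
#'
#' @param annotation a `feature_annotation`.
#' @param segments data frame (sample, chrom, start, end, state, n_markers).
#' @param samples sample ids defining the label matrix columns.
#' @param min_markers minimum markers per segment (default 5).
#' @param min_length minimum segment length in bp (default 10000, the hiPSC
#'   profile; use 50000 for the hESC profile).
#' @return character matrix genes x samples with values gain/normal/loss/
#'   ambiguous, of class `cnv_label_matrix`.
#' @export
label_gene_states <- function(annotation, segments, samples,
                              min_markers = 5L, min_length = 10000L) {
  if (nrow(segments) > 0L && !all(segments$state %in% c("gain", "loss"))) {
    stop("unknown CNV state: ",
         paste(setdiff(unique(segments$state), c("gain", "loss")),
               collapse = ", "))
  }
  genes <- annotation$genes
  lab <- matrix("normal", nrow(genes), length(samples),
                dimnames = list(genes$gene_id, samples))
  keep <- segments$n_markers >= min_markers &
    (segments$end - segments$start + 1L) >= min_length
  seg <- segments[keep, , drop = FALSE]
  if (nrow(seg) > 0L) {
    gr_genes <- GenomicRanges::GRanges(genes$chrom,
                                       IRanges::IRanges(genes$start, genes$end))
    gr_seg <- GenomicRanges::GRanges(seg$chrom,
                                     IRanges::IRanges(seg$start, seg$end))
    hits <- GenomicRanges::findOverlaps(gr_genes, gr_seg)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    for (h in seq_along(qh)) {
      gi <- qh[h]
      si <- sh[h]
      sm <- seg$sample[si]
      if (!sm %in% samples) next
      st <- seg$state[si]
      cur <- lab[gi, sm]
      lab[gi, sm] <- if (cur == "normal" || cur == st) st else "ambiguous"
    }
  }
  class(lab) <- c("cnv_label_matrix", class(lab))
  lab
}

#' Group summary feeding the weight statistic
#'
#' @param altered log2 expression values of the altered-state samples.
#' @param normal log2 expression values of the normal-state samples.
#' @return object of class `cnv_group_summary`: list with means `m1`/`m0`,
#'   SDs `s1`/`s0` (n-1 denominator, 0 for singletons) and counts.
#' @export
cnv_group_summary <- function(altered, normal) {
  if (length(altered) < 1L || length(normal) < 1L) {
    stop("both groups must be non-empty")
  }
  out <- list(m1 = mean(altered), s1 = .sd0(altered),
              m0 = mean(normal), s0 = .sd0(normal),
              n1 = length(altered), n0 = length(normal))
  class(out) <- "cnv_group_summary"
  out
}

#' Copy-number/expression weight statistic
#'
#' `w = (m1 - m0) / (s1 + s0)`: the difference of the altered-group and
#' normal-group means divided by the sum of their standard deviations. A
#' high value for a gained gene indicates over-expression attributable to
#' the duplication. A zero denominator with non-zero numerator returns a
#' signed infinity (ranked as most extreme); 0/0 returns 0.
#'
#' @param summary a `cnv_group_summary`.
#' @return the weight (dimensionless).
#' @export
weight_statistic <- function(summary) {
  stopifnot(inherits(summary, "cnv_group_summary"))
  .weight(summary$m1 - summary$m0, summary$s1 + summary$s0)
}

#' Loss-direction weight
#'
#' Oriented so that a positive weight means the loss is associated with low
#' expression: `w = (m0 - m_loss) / (s_loss + s0)`, with the summary built
#' from the loss-state samples as the altered group.
#'
#' @param summary a `cnv_group_summary` (altered = loss samples).
#' @return the weight.
#' @export
loss_weight <- function(summary) {
  stopifnot(inherits(summary, "cnv_group_summary"))
  .weight(summary$m0 - summary$m1, summary$s1 + summary$s0)
}

.weight <- function(num, den) {
  if (den == 0) {
    if (num == 0) return(0)
    return(sign(num) * Inf)
  }
  num / den
}

## weights of many altered-index assignments at once;
## idx: k x n_assign matrix of altered indices into x
.weights_for_assignments <- function(x, idx, direction) {
  k <- nrow(idx); n <- length(x)
  tot <- sum(x); tot2 <- sum(x^2)
  xs <- matrix(x[idx], k)
  x2 <- matrix(x[idx]^2, k)
  s1 <- colSums(xs); ss1 <- colSums(x2)
  s0 <- tot - s1; ss0 <- tot2 - ss1
  m1 <- s1 / k; m0 <- s0 / (n - k)
  v1 <- if (k > 1L) pmax(ss1 - s1^2 / k, 0) / (k - 1L) else rep(0, ncol(idx))
  v0 <- if (n - k > 1L) pmax(ss0 - s0^2 / (n - k), 0) / (n - k - 1L)
        else rep(0, ncol(idx))
  den <- sqrt(v1) + sqrt(v0)
  num <- if (direction == "loss") m0 - m1 else m1 - m0
  w <- ifelse(den == 0, ifelse(num == 0, 0, sign(num) * Inf), num / den)
  as.numeric(w)
}

## random altered-index matrix: k of n, n_perm columns
.perm_index <- function(n, k, n_perm) {
  matrix(vapply(seq_len(n_perm), function(i) sample.int(n, k), integer(k)),
         nrow = k)
}

#' Permutation p-value for the weight statistic
#'
#' The null is generated by reassigning the altered/normal labels uniformly
#' at random, preserving the group sizes. The one-sided Monte-Carlo p-value
#' uses the add-one plug-in, `p = (1 + #\{w_perm >= w_obs\}) / (1 + n_perm)`,
#' so p is never exactly 0. When the number of distinct label assignments
#' `choose(n, k)` is at most `n_perm` and `exhaustive_if_possible` is set,
#' all assignments are enumerated and the plain proportion
#' `#\{w_perm >= w_obs\} / choose(n, k)` is returned instead.
#'
#' @param expr per-sample expression values (log2).
#' @param altered logical vector marking the altered-state samples.
#' @param direction `"gain"` (tests altered high) or `"loss"` (altered low).
#' @param n_perm number of Monte-Carlo permutations (default 10000).
#' @param exhaustive_if_possible enumerate all assignments when feasible.
#' @param two_sided compare permuted |w| against observed |w|.
#' @param perm_index optional precomputed k x n_perm index matrix (shared
#'   across genes with the same group sizes).
#' @return raw p-value in (0, 1].
#' @export
permutation_pvalue <- function(expr, altered, direction = c("gain", "loss"),
                               n_perm = 10000L, exhaustive_if_possible = FALSE,
                               two_sided = FALSE, perm_index = NULL) {
  direction <- match.arg(direction)
  n <- length(expr)
  stopifnot(length(altered) == n)
  k <- sum(altered)
  if (k < 1L || k >= n) stop("both groups must be non-empty")
  w_obs <- .weights_for_assignments(expr, matrix(which(altered), ncol = 1),
                                    direction)
  cmp <- function(w) if (two_sided) abs(w) >= abs(w_obs) else w >= w_obs
  if (exhaustive_if_possible && choose(n, k) <= n_perm) {
    idx <- utils::combn(n, k)
    w <- .weights_for_assignments(expr, idx, direction)
    return(sum(cmp(w)) / ncol(idx))
  }
  if (is.null(perm_index)) perm_index <- .perm_index(n, k, n_perm)
  w <- .weights_for_assignments(expr, perm_index, direction)
  (1 + sum(cmp(w))) / (1 + ncol(perm_index))
}

#' Fold change between altered and normal groups
#'
#' Expression is already log2, so the log2 fold change is the difference of
#' group means and the linear fold change is its power of two.
#'
#' @param summary a `cnv_group_summary`.
#' @return list with `log2_fc` (m1 - m0) and `linear_fc` (2^log2_fc).
#' @export
fold_change <- function(summary) {
  stopifnot(inherits(summary, "cnv_group_summary"))
  lfc <- summary$m1 - summary$m0
  list(log2_fc = lfc, linear_fc = 2^lfc)
}

#' Copy-number/expression association scan
#'
#' Tests every gene altered in at least one sample, separately for the gain
#' and loss directions. For each (gene, direction), the altered group is
#' the samples labelled with that state and the reference group the samples
#' labelled normal; samples with the opposite state or an ambiguous label
#' are excluded from that test. Raw permutation p-values are BH-adjusted
#' within each direction family. Genes whose expression shifts against the
#' expected direction (negative weight) are reported with a flag but carry
#' no significance claim in that direction.
#'
#' @param expression a gene-level `expression_matrix`.
#' @param labels a `cnv_label_matrix` from [label_gene_states()].
#' @param alpha significance level on adjusted p (default 0.05).
#' @param n_perm permutations per test (default 10000).
#' @param seed optional RNG seed for the permutation streams.
#' @param exhaustive_if_possible see [permutation_pvalue()].
#' @param two_sided see [permutation_pvalue()].
#' @return data frame of class `cnv_association`: gene_id, direction,
#'   n_altered, n_normal, weight, log2_fc, linear_fc, raw_p, adjusted_p,
#'   significant, negative_direction.
#' @export
run_cnv_scan <- function(expression, labels, alpha = 0.05, n_perm = 10000L,
                         seed = NULL, exhaustive_if_possible = FALSE,
                         two_sided = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  smp <- setdiff(names(expression), c("feature_id", "level"))
  if (!setequal(smp, colnames(labels))) {
    stop("expression and label samples do not match")
  }
  genes <- intersect(expression$feature_id, rownames(labels))
  exprm <- as.matrix(expression[match(genes, expression$feature_id),
                                colnames(labels), drop = FALSE])
  rownames(exprm) <- genes

  cache <- new.env(parent = emptyenv())
  rows <- list()
  for (direction in c("gain", "loss")) {
    for (g in genes) {
      st <- labels[g, ]
      altered <- st == direction
      normal <- st == "normal"
      if (!any(altered) || !any(normal)) next
      use <- altered | normal
      x <- exprm[g, use]
      a <- altered[use]
      summ <- cnv_group_summary(x[a], x[!a])
      w <- if (direction == "gain") weight_statistic(summ) else loss_weight(summ)
      fc <- fold_change(summ)
      key <- paste0(sum(a), "_", length(x))
      pi <- NULL
      if (!exhaustive_if_possible || choose(length(x), sum(a)) > n_perm) {
        if (!exists(key, envir = cache, inherits = FALSE)) {
          assign(key, .perm_index(length(x), sum(a), n_perm), envir = cache)
        }
        pi <- get(key, envir = cache, inherits = FALSE)
      }
      p <- permutation_pvalue(x, a, direction, n_perm = n_perm,
                              exhaustive_if_possible = exhaustive_if_possible,
                              two_sided = two_sided, perm_index = pi)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, direction = direction, n_altered = sum(a),
        n_normal = sum(!a), weight = w, log2_fc = fc$log2_fc,
        linear_fc = fc$linear_fc, raw_p = p, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(gene_id = character(), direction = character(),
                      n_altered = integer(), n_normal = integer(),
                      weight = numeric(), log2_fc = numeric(),
                      linear_fc = numeric(), raw_p = numeric(),
                      adjusted_p = numeric(), significant = logical(),
                      negative_direction = logical(),
                      stringsAsFactors = FALSE)
    class(out) <- c("cnv_association", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$adjusted_p <- NA_real_
  for (direction in c("gain", "loss")) {
    i <- out$direction == direction
    if (any(i)) out$adjusted_p[i] <- bh_adjust(out$raw_p[i])
  }
  out$significant <- out$adjusted_p < alpha
  out$negative_direction <- out$weight < 0
  rownames(out) <- NULL
  class(out) <- c("cnv_association", "data.frame")
  out
}
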