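#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment of raw p-values: sort ascending,
#' multiply p_(i) by m/i, enforce monotonicity from the largest rank down,
#' cap at 1 and restore the input order. Backed by [stats::p.adjust()] with
#' input validation (p-values must lie in (0, 1]).
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return numeric vector of adjusted p-values, same order as `p`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

## sd with the n-1 denominator, defined as 0 for a single observation
.sd0 <- function(x) {
  if (length(x) < 2L) return(0)
  stats::sd(x)
}

.stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")))
  }
}

## point-in-closed-interval membership for 1-based inclusive coordinates
.point_in <- function(pos, start, end) pos >= start & pos <= end

## deterministic TSV writer (no quoting, no row names)
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
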