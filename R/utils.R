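#' @importFrom stats prcomp predict quantile rnbinom rnorm runif rpois rbeta
#'   sd qt wilcox.test chisq.test fisher.test p.adjust setNames aggregate
#'   complete.cases reshape
#' @importFrom utils head read.csv write.csv read.delim write.table
#' @importFrom data.table data.table as.data.table rbindlist :=
#' @importFrom IRanges IRanges countOverlaps findOverlaps
#' @importFrom S4Vectors queryHits
NULL

.datatable.aware <- TRUE

# All genomic coordinates in this package are 0-based, half-open [start, end),
# the BED convention. IRanges is 1-based closed, so conversion adds 1 to start.

as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

#' Count overlaps between query and subject intervals on shared chromosomes
#'
#' Intervals overlap if they share at least 1 bp. Both frames use 0-based
#' half-open coordinates and must have columns `chrom`, `start`, `end`.
#'
#' @param query,subject data.frames of intervals.
#' @return Integer vector: for each query row, the number of subject rows
#'   overlapping it.
#' @keywords internal
count_interval_overlaps <- function(query, subject) {
  out <- integer(nrow(query))
  if (nrow(subject) == 0L || nrow(query) == 0L) return(out)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    if (length(si) == 0L) next
    out[qi] <- IRanges::countOverlaps(
      as_iranges0(query$start[qi], query$end[qi]),
      as_iranges0(subject$start[si], subject$end[si]))
  }
  out
}

# Distance between an interval [start, end) and a point position:
# 0 if the point lies inside, else distance to the nearer closed endpoint
# (end - 1 being the last base inside the interval).
interval_point_distance <- function(start, end, pos) {
  inside <- pos >= start & pos < end
  d <- pmin(abs(start - pos), abs(pos - (end - 1L)))
  d[inside] <- 0L
  d
}

# For each query point, distance to the nearest of a sorted set of points on
# the same chromosome. Returns Inf when the set is empty.
nearest_point_distance <- function(chrom, start, end, point_chrom, point_pos) {
  n <- length(start)
  out <- rep(Inf, n)
  for (ch in unique(chrom)) {
    qi <- which(chrom == ch)
    pp <- sort(point_pos[point_chrom == ch])
    if (length(pp) == 0L) next
    for (i in qi) {
      d <- interval_point_distance(start[i], end[i], pp)
      out[i] <- min(d)
    }
  }
  out
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Shared routine for the distance comparisons and the crispant analysis.
#' Uses the exact null distribution when the combined sample size is at most
#' 20 and there are no ties; otherwise the normal approximation with the
#' tie-corrected variance.
#'
#' @param x,y Numeric samples.
#' @param alternative Passed to [stats::wilcox.test()].
#' @return List with `statistic` (W, number of (x, y) pairs with x > y plus
#'   half the ties) and `p.value`.
#' @export
rank_sum_test <- function(x, y, alternative = "two.sided") {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  ties <- anyDuplicated(c(x, y)) > 0L
  ex <- (length(x) + length(y)) <= 20L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = ex,
                       correct = !ex))
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

# Deterministic check that a data.frame has the named columns.
check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L)
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}
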