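#' Filter and trim CUT&RUN fragments
#'
#' Keeps mononucleosome-sized fragments (pair-spanned length 140-250 bp
#' inclusive), replaces each by the 73-bp window centered on the fragment
#' midpoint (`[mid - 36, mid + 37)` with `mid = floor((start + end) / 2)`),
#' then removes exact duplicates (identical chrom/start/end within a
#' sample), keeping the first in input order. Spans of exactly 73 bp are
#' treated as already trimmed and only deduplicated, which makes the
#' filter idempotent.
#'
#' @param fragments data.frame/data.table with `chrom`, `start`, `end` and
#'   optionally `sample_id` (absent = single sample).
#' @return data.table of filtered, trimmed, deduplicated fragments.
#' @export
filter_fragments <- function(fragments) {
  dt <- data.table::as.data.table(fragments)
  has_sample <- "sample_id" %in% names(dt)
  span <- dt$end - dt$start
  dt <- dt[(span >= 140L & span <= 250L) | span == 73L]
  mid <- (dt$start + dt$end) %/% 2L
  dt[, `:=`(start = mid - 36L, end = mid + 37L)]
  key <- if (has_sample) c("sample_id", "chrom", "start", "end") else
    c("chrom", "start", "end")
  dt[!duplicated(dt, by = key)]
}

# window table used for counting: left flank, center, right flank per region
.coverage_windows <- function(regions) {
  if (anyNA(regions$left_start))
    stop("regions passed to count_coverage must have flanks built and kept",
         call. = FALSE)
  nr <- nrow(regions)
  data.frame(
    region = rep(seq_len(nr), 3),
    chrom = rep(regions$chrom, 3),
    start = c(regions$left_start, regions$start, regions$right_start),
    end = c(regions$left_end, regions$end, regions$right_end),
    sub = rep(c("left", "center", "right"), each = nr))
}

#' Count fragment coverage on region subintervals
#'
#' Counts filtered fragments overlapping (by at least 1 bp) each of the
#' three subintervals (left flank, open interval, right flank) per region
#' per sample. The per-sample library size is the total number of filtered
#' fragments in the sample, wherever they fall.
#'
#' @param fragments Filtered fragments (with `sample_id`).
#' @param regions Regions with flanks built (no discarded rows).
#' @param manifest data.frame: `sample_id`, `mark`, `replicate`, `stage`,
#'   `is_control`, and optionally `spike_pairs`.
#' @return A `cov_matrix` object: list with `region_id`, `counts` (regions x
#'   (sample x subinterval) matrix), `cols` (column metadata), `lib_sizes`,
#'   `center_len`, `normalized`, `oriented`.
#' @export
count_coverage <- function(fragments, regions, manifest) {
  check_columns(manifest, c("sample_id", "mark", "replicate", "stage",
                            "is_control"), "manifest")
  dt <- data.table::as.data.table(fragments)
  unknown <- setdiff(unique(dt$chrom), unique(regions$chrom))
  if (length(unknown) > 0)
    warning(sprintf("skipping fragments on unknown chromosome(s): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  win <- .coverage_windows(regions)
  nr <- nrow(regions)
  samples <- manifest$sample_id
  counts <- matrix(0L, nr, 3L * length(samples))
  cols <- data.frame(
    sample_id = rep(samples, each = 3),
    mark = rep(manifest$mark, each = 3),
    replicate = rep(manifest$replicate, each = 3),
    stage = rep(manifest$stage, each = 3),
    is_control = rep(manifest$is_control, each = 3),
    subinterval = rep(c("left", "center", "right"), length(samples)))
  colnames(counts) <- paste(cols$sample_id, cols$subinterval, sep = "|")
  lib <- stats::setNames(numeric(length(samples)), samples)
  for (si in seq_along(samples)) {
    fs <- dt[dt$sample_id == samples[si]]
    lib[si] <- nrow(fs)
    if (nrow(fs) == 0) next
    for (ch in unique(win$chrom)) {
      wi <- which(win$chrom == ch)
      fc <- fs[fs$chrom == ch]
      if (nrow(fc) == 0) next
      n <- IRanges::countOverlaps(
        as_iranges0(win$start[wi], win$end[wi]),
        as_iranges0(fc$start, fc$end))
      for (sub in c("left", "center", "right")) {
        sel <- win$sub[wi] == sub
        counts[win$region[wi][sel], paste(samples[si], sub, sep = "|")] <-
          n[sel]
      }
    }
  }
  structure(list(region_id = regions$region_id, counts = counts, cols = cols,
                 lib_sizes = lib, center_len = regions$end - regions$start,
                 normalized = FALSE, oriented = FALSE),
            class = "cov_matrix")
}

# subinterval lengths per (region, column)
.sub_lengths <- function(cov) {
  len <- matrix(500, nrow(cov$counts), ncol(cov$counts))
  cen <- cov$cols$subinterval == "center"
  len[, cen] <- cov$center_len
  len
}

#' Normalize coverage counts as log2 RPK500 with a pseudocount
#'
#' Counts are normalized by region length per 500 bp and by library size
#' per million fragments, i.e. `log2(count / (len/500) / (lib/1e6) + 1)`,
#' which equals log2 of RPKM/2 plus a pseudocount of 1. A zero count maps
#' to exactly 0.
#'
#' @param cov A raw `cov_matrix`.
#' @return The `cov_matrix` with normalized values.
#' @export
normalize_log2_rpk500 <- function(cov) {
  stopifnot(!cov$normalized)
  if (any(cov$lib_sizes <= 0)) stop("zero library size", call. = FALSE)
  len <- .sub_lengths(cov)
  lib <- cov$lib_sizes[cov$cols$sample_id]
  cov$counts <- log2(sweep(cov$counts / (len / 500), 2, lib / 1e6, "/") + 1)
  cov$normalized <- TRUE
  cov
}

#' Scale track values by the spike-in factor
#'
#' Multiplies every value by `1e6 / spike_pairs`. Used for cross-sample
#' track comparison; within-stage mark/IgG enrichment ratios are spike-in
#' invariant and are not rescaled.
#'
#' @param values Numeric vector or matrix of coverage values.
#' @param spike_pairs Spike-in (yeast) read-pair count (> 0).
#' @return Scaled values.
#' @export
spike_in_scale <- function(values, spike_pairs) {
  if (length(spike_pairs) != 1 || is.na(spike_pairs) || spike_pairs <= 0)
    stop("spike_pairs must be a single positive number", call. = FALSE)
  values * (1e6 / spike_pairs)
}

#' Pool replicates per mark and stage
#'
#' Sums raw counts and library sizes across replicates of the same mark and
#' stage. Normalization is applied after pooling, so pooled RPK500 differs
#' from the mean of per-replicate RPK500 when depths differ.
#'
#' @param cov A raw `cov_matrix`.
#' @return A raw `cov_matrix` with one pooled sample per (mark, stage).
#' @export
pool_replicates <- function(cov) {
  stopifnot(!cov$normalized)
  grp <- paste(cov$cols$mark, cov$cols$stage, sep = ".")
  ugrp <- unique(grp)
  subints <- c("left", "center", "right")
  if (cov$oriented) subints <- c("upstream", "center", "downstream")
  counts <- matrix(0L, nrow(cov$counts), 3L * length(ugrp))
  cols <- NULL
  lib <- stats::setNames(numeric(length(ugrp)), paste0(ugrp, ".pooled"))
  k <- 0L
  for (g in ugrp) {
    gi <- grp == g
    first <- which(gi)[1]
    sid <- paste0(g, ".pooled")
    reps <- unique(cov$cols$sample_id[gi])
    lib[sid] <- sum(cov$lib_sizes[reps])
    for (sub in subints) {
      k <- k + 1L
      sel <- gi & cov$cols$subinterval == sub
      counts[, k] <- as.integer(rowSums(cov$counts[, sel, drop = FALSE]))
      cols <- rbind(cols, data.frame(
        sample_id = sid, mark = cov$cols$mark[first], replicate = NA,
        stage = cov$cols$stage[first],
        is_control = cov$cols$is_control[first], subinterval = sub))
    }
  }
  colnames(counts) <- paste(cols$sample_id, cols$subinterval, sep = "|")
  structure(list(region_id = cov$region_id, counts = counts, cols = cols,
                 lib_sizes = lib, center_len = cov$center_len,
                 normalized = FALSE, oriented = cov$oriented),
            class = "cov_matrix")
}

#' Relabel flanks as upstream/downstream using the orientation
#'
#' Swaps the left/right flank columns for regions whose higher-coverage
#' flank is the genomic-left one, and relabels subintervals to
#' upstream/center/downstream.
#'
#' @param cov A `cov_matrix` with left/right flank columns.
#' @param regions Regions carrying `down_is_right` from [orient_flanks()].
#' @return Oriented `cov_matrix`.
#' @export
apply_orientation <- function(cov, regions) {
  stopifnot(!cov$oriented,
            identical(cov$region_id, regions$region_id))
  flip <- !regions$down_is_right
  left <- which(cov$cols$subinterval == "left")
  for (li in left) {
    ri <- which(cov$cols$sample_id == cov$cols$sample_id[li] &
                  cov$cols$subinterval == "right")
    tmp <- cov$counts[flip, li]
    cov$counts[flip, li] <- cov$counts[flip, ri]
    cov$counts[flip, ri] <- tmp
  }
  cov$cols$subinterval[cov$cols$subinterval == "left"] <- "upstream"
  cov$cols$subinterval[cov$cols$subinterval == "right"] <- "downstream"
  colnames(cov$counts) <- paste(cov$cols$sample_id, cov$cols$subinterval,
                                sep = "|")
  cov$oriented <- TRUE
  cov
}

# RPK500 on a combined set of subintervals (default center + downstream)
# from a raw pooled cov_matrix, per mark
region_rpk500 <- function(cov, stage,
                          interval = c("center", "downstream")) {
  stopifnot(!cov$normalized)
  sel_stage <- cov$cols$stage == stage
  marks <- unique(cov$cols$mark[sel_stage])
  len <- .sub_lengths(cov)
  out <- matrix(0, nrow(cov$counts), length(marks),
                dimnames = list(cov$region_id, marks))
  for (m in marks) {
    sel <- sel_stage & cov$cols$mark == m & cov$cols$subinterval %in% interval
    sid <- unique(cov$cols$sample_id[sel])
    stopifnot(length(sid) == 1)
    cnt <- rowSums(cov$counts[, sel, drop = FALSE])
    totlen <- rowSums(len[, sel, drop = FALSE])
    out[, m] <- cnt / (totlen / 500) / (cov$lib_sizes[sid] / 1e6)
  }
  out
}

#' Fold-enrichment of each mark over the IgG control
#'
#' Per region, fold = (RPK500_mark + eps) / (RPK500_IgG + eps), computed on
#' the combined center + downstream subintervals of a replicate-pooled
#' matrix, with a stabilizing pseudocount `eps` (default 0.1).
#'
#' @param cov A raw pooled, oriented `cov_matrix`.
#' @param stage Stage to compute enrichment for.
#' @param control_mark Name of the control mark (default `"IgG"`).
#' @param eps Ratio pseudocount.
#' @param interval Subintervals entering the ratio.
#' @return List with `fold` (regions x marks matrix), `rpk500` (same shape,
#'   the mark RPK500 values), `rpkm` (= 2 x rpk500), and `stage`.
#' @export
enrichment_over_control <- function(cov, stage, control_mark = "IgG",
                                    eps = 0.1,
                                    interval = c("center", "downstream")) {
  rpk <- region_rpk500(cov, stage, interval)
  if (!control_mark %in% colnames(rpk))
    stop(sprintf("control mark '%s' missing for stage %s", control_mark,
                 stage), call. = FALSE)
  marks <- setdiff(colnames(rpk), control_mark)
  fold <- (rpk[, marks, drop = FALSE] + eps) / (rpk[, control_mark] + eps)
  list(fold = fold, rpk500 = rpk[, marks, drop = FALSE],
       rpkm = 2 * rpk[, marks, drop = FALSE], stage = stage)
}
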