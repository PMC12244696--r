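#' Merge two open-chromatin region sources
#'
#' All primary regions are kept, in input order, with identifiers
#' `atac_L00001`, `atac_L00002`, ... Secondary regions are kept only when
#' they overlap no primary region (any overlap of at least 1 bp excludes
#' them) and receive `atac_P#####` identifiers. Duplicate identical
#' intervals within a source are collapsed with a warning.
#'
#' @param primary_regions,secondary_regions data.frames with columns
#'   `chrom`, `start`, `end` (0-based half-open).
#' @return data.frame: `region_id`, `chrom`, `start`, `end`, `source`.
#' @export
merge_region_sources <- function(primary_regions, secondary_regions) {
  dedup <- function(d, lab) {
    if (nrow(d) == 0) return(d)
    stopifnot(all(d$start >= 0), all(d$end > d$start))
    dup <- duplicated(paste(d$chrom, d$start, d$end))
    if (any(dup))
      warning(sprintf("%d duplicate interval(s) removed from %s source",
                      sum(dup), lab), call. = FALSE)
    d[!dup, , drop = FALSE]
  }
  p <- dedup(primary_regions, "primary")
  s <- dedup(secondary_regions, "secondary")
  keep_s <- if (nrow(s) > 0) count_interval_overlaps(s, p) == 0L else logical(0)
  s <- s[keep_s, , drop = FALSE]
  out <- rbind(
    if (nrow(p) > 0)
      data.frame(region_id = sprintf("atac_L%05d", seq_len(nrow(p))),
                 chrom = p$chrom, start = p$start, end = p$end, source = "L"),
    if (nrow(s) > 0)
      data.frame(region_id = sprintf("atac_P%05d", seq_len(nrow(s))),
                 chrom = s$chrom, start = s$start, end = s$end, source = "P"))
  rownames(out) <- NULL
  out
}

#' Select the promoter TSS per gene
#'
#' Keeps, per gene, the candidate with the maximal CAGE tag count, retained
#' only when supported by more than 20 tags (strict). Genes present only in
#' the secondary annotation contribute their TSS regardless of tag support.
#' Ties in the maximal tag count are broken towards the most 5' position on
#' the gene strand.
#'
#' @param tss_candidates data.frame: `gene_id`, `chrom`, `pos`, `strand`,
#'   `tag_count`, `source` (`"primary-annotation"` or
#'   `"secondary-annotation"`).
#' @return data.frame of selected TSSs, one row per retained gene.
#' @export
select_promoter_tss <- function(tss_candidates) {
  check_columns(tss_candidates,
                c("gene_id", "chrom", "pos", "strand", "tag_count", "source"),
                "tss_candidates")
  pieces <- lapply(split(tss_candidates, tss_candidates$gene_id), function(d) {
    if (all(d$source == "secondary-annotation")) {
      # gene absent from the primary annotation: keep its best TSS regardless
      best <- d[d$tag_count == max(d$tag_count), , drop = FALSE]
    } else {
      d <- d[d$source == "primary-annotation", , drop = FALSE]
      best <- d[d$tag_count == max(d$tag_count), , drop = FALSE]
      if (best$tag_count[1] <= 20) return(NULL)
    }
    fivep <- if (best$strand[1] == "+") which.min(best$pos) else which.max(best$pos)
    best[fivep, , drop = FALSE]
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Assign the promoter/proximal/distal taxonomy
#'
#' A region overlapping a selected promoter TSS is a `promoter`; otherwise
#' a region whose distance to the nearest annotated TSS (any transcript
#' isoform) is below 2,000 bp is `proximal`; regions at least 2,000 bp from
#' every TSS are `distal`. Regions on chromosomes or scaffolds without any
#' annotated gene are `discarded-scaffold`. Distance between a region and a
#' TSS is 0 when the TSS lies inside the half-open interval, else the
#' distance to the nearer end base.
#'
#' @param regions data.frame with `region_id`, `chrom`, `start`, `end`.
#' @param tss Selected promoter TSSs from [select_promoter_tss()].
#' @param all_isoform_tss data.frame `chrom`, `pos` of every annotated
#'   transcript TSS.
#' @param scaffold_genes Named vector: annotated gene count per chromosome.
#' @return `regions` with a `taxonomy` column added.
#' @export
classify_taxonomy <- function(regions, tss, all_isoform_tss, scaffold_genes) {
  geneless <- names(scaffold_genes)[scaffold_genes == 0]
  tax <- rep(NA_character_, nrow(regions))
  tax[regions$chrom %in% geneless |
        !regions$chrom %in% names(scaffold_genes)] <- "discarded-scaffold"
  todo <- is.na(tax)
  ov <- count_interval_overlaps(
    regions[, c("chrom", "start", "end")],
    data.frame(chrom = tss$chrom, start = tss$pos, end = tss$pos + 1L))
  tax[todo & ov > 0] <- "promoter"
  todo <- is.na(tax)
  d <- nearest_point_distance(regions$chrom, regions$start, regions$end,
                              all_isoform_tss$chrom, all_isoform_tss$pos)
  tax[todo & d < 2000] <- "proximal"
  tax[todo & d >= 2000] <- "distal"
  regions$taxonomy <- tax
  regions
}

#' Construct 500-bp flanking intervals
#'
#' Each surviving region gains two 500-bp flanks abutting the open
#' interval. Regions where either flank would extend past a chromosome
#' boundary are marked `discarded-no-flank`.
#'
#' @param regions Regions with taxonomy assigned.
#' @param chrom_lengths Named chromosome lengths (bp).
#' @return `regions` with `left_start`, `left_end`, `right_start`,
#'   `right_end` columns; discarded regions keep `NA` flanks.
#' @export
build_flanks <- function(regions, chrom_lengths) {
  lo <- regions$start - 500L
  hi <- regions$end + 500L
  bad <- lo < 0L | hi > chrom_lengths[regions$chrom]
  keepable <- !regions$taxonomy %in% c("discarded-scaffold")
  regions$taxonomy[bad & keepable] <- "discarded-no-flank"
  ok <- !bad & keepable
  regions$left_start <- ifelse(ok, lo, NA_integer_)
  regions$left_end <- ifelse(ok, regions$start, NA_integer_)
  regions$right_start <- ifelse(ok, regions$end, NA_integer_)
  regions$right_end <- ifelse(ok, hi, NA_integer_)
  regions
}

#' Orient flanks by total coverage
#'
#' The flank with the larger raw coverage summed over all marks and samples
#' is labeled "downstream"; ties orient the genomic-right flank downstream.
#' Orientation is invariant to multiplying all samples' coverage by a
#' constant.
#'
#' @param regions Regions with flanks built.
#' @param coverage A raw coverage matrix from [count_coverage()] (left/right
#'   flank columns, i.e. not yet oriented).
#' @return `regions` with a logical `down_is_right` column.
#' @export
orient_flanks <- function(regions, coverage) {
  stopifnot(!isTRUE(coverage$oriented))
  left <- rowSums(coverage$counts[, coverage$cols$subinterval == "left",
                                  drop = FALSE])
  right <- rowSums(coverage$counts[, coverage$cols$subinterval == "right",
                                   drop = FALSE])
  regions$down_is_right <- right >= left
  regions
}
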