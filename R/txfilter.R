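#' Strand-specific RNA-seq coverage in 100-bp flanks
#'
#' Computes RPKM per strand in the 100-bp windows immediately upstream and
#' downstream (in genomic coordinates) of each open interval, per stage.
#'
#' @param reads data.frame of read intervals: `stage`, `strand`, `chrom`,
#'   `start`, `end`.
#' @param regions Region data.frame (`region_id`, `chrom`, `start`, `end`).
#' @param lib_sizes Named vector: library size (reads) per stage.
#' @return data.frame: `region_id`, `stage`, `plus_up`, `plus_down`,
#'   `minus_up`, `minus_down` (RPKM).
#' @export
compute_flank_coverage <- function(reads, regions, lib_sizes) {
  stages <- names(lib_sizes)
  up <- data.frame(chrom = regions$chrom, start = regions$start - 100L,
                   end = regions$start)
  down <- data.frame(chrom = regions$chrom, start = regions$end,
                     end = regions$end + 100L)
  out <- list()
  for (st in stages) {
    rpkm <- function(win, sd_) {
      sel <- reads$stage == st & reads$strand == sd_
      n <- count_interval_overlaps(win, reads[sel, , drop = FALSE])
      n / 0.1 / (lib_sizes[st] / 1e6)
    }
    out[[st]] <- data.frame(
      region_id = regions$region_id, stage = st,
      plus_up = rpkm(up, "+"), plus_down = rpkm(down, "+"),
      minus_up = rpkm(up, "-"), minus_down = rpkm(down, "-"))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Detect regions behaving like directional gene TSSs
#'
#' A region is flagged on the (+) strand when downstream (+)-strand
#' coverage is at least 1 RPKM and at least twice the upstream (+)-strand
#' coverage, in at least `min_stages` stages; symmetrically on the (-)
#' strand with upstream coverage dominating. Zero upstream coverage with
#' downstream coverage >= 1 RPKM qualifies (infinite ratio).
#'
#' @param flank_coverage Output of [compute_flank_coverage()].
#' @param min_stages Minimum number of qualifying stages (default 2).
#' @return Character vector of flagged region ids.
#' @export
detect_directional_tss <- function(flank_coverage, min_stages = 2) {
  fc <- flank_coverage
  plus <- fc$plus_down >= 1 & fc$plus_down >= 2 * fc$plus_up
  minus <- fc$minus_up >= 1 & fc$minus_up >= 2 * fc$minus_down
  hit <- fc$region_id[plus | minus]
  plus_n <- table(fc$region_id[plus])
  minus_n <- table(fc$region_id[minus])
  flagged <- union(names(plus_n)[plus_n >= min_stages],
                   names(minus_n)[minus_n >= min_stages])
  sort(flagged)
}

#' Regions whose flanks fall within annotated exons
#'
#' A region is exempt from the directional-TSS filter when either of its
#' 100-bp flanks lies entirely within a single annotated exon (RNA-seq
#' signal there is attributable to the surrounding gene).
#'
#' @param regions Region data.frame.
#' @param exons data.frame of exon intervals (`chrom`, `start`, `end`).
#' @return Character vector of exempt region ids.
#' @export
exonic_flank_mask <- function(regions, exons) {
  if (nrow(exons) == 0) return(character(0))
  contained <- function(win) {
    out <- logical(nrow(win))
    for (ch in unique(win$chrom)) {
      wi <- which(win$chrom == ch)
      ei <- which(exons$chrom == ch)
      if (length(ei) == 0) next
      hits <- IRanges::findOverlaps(
        as_iranges0(win$start[wi], win$end[wi]),
        as_iranges0(exons$start[ei], exons$end[ei]),
        type = "within")
      out[wi[unique(S4Vectors::queryHits(hits))]] <- TRUE
    }
    out
  }
  up <- data.frame(chrom = regions$chrom, start = regions$start - 100L,
                   end = regions$start)
  down <- data.frame(chrom = regions$chrom, start = regions$end,
                     end = regions$end + 100L)
  sort(regions$region_id[contained(up) | contained(down)])
}

#' Remove flagged cryptic-TSS regions from the enhancer classes
#'
#' Flagged, non-exempt regions are removed from both enhancer classes; the
#' report lists removed ids and per-class removed fractions. Retained and
#' removed sets partition the input.
#'
#' @param calls Element calls from [call_elements()].
#' @param flagged Ids from [detect_directional_tss()].
#' @param exempt Ids from [exonic_flank_mask()].
#' @param classes Calls subject to removal.
#' @return List with `calls` (filtered), `removed` (removed rows), and
#'   `report` (per-class counts and removed fraction).
#' @export
apply_filter <- function(calls, flagged, exempt,
                         classes = c("H3K4me1-enhancer", "H3K4me2-enhancer")) {
  drop_ids <- setdiff(flagged, exempt)
  rm_row <- calls$call %in% classes & calls$region_id %in% drop_ids
  report <- do.call(rbind, lapply(classes, function(cl) {
    n <- sum(calls$call == cl)
    r <- sum(rm_row & calls$call == cl)
    data.frame(call = cl, n_input = n, n_removed = r,
               fraction_removed = if (n > 0) r / n else NA_real_)
  }))
  list(calls = calls[!rm_row, , drop = FALSE],
       removed = calls[rm_row, , drop = FALSE],
       report = report)
}
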