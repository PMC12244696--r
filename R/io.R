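#' Write and read regions as BED6
#'
#' Name column carries the region id (optionally suffixed with the
#' taxonomy), score 0, strand ".".
#'
#' @param regions Region data.frame.
#' @param path Output path.
#' @return `write_regions_bed` returns the path invisibly;
#'   `read_regions_bed` returns a region data.frame.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(regions$chrom, regions$start, regions$end,
                    regions$region_id, 0L, ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_regions_bed
#' @export
read_regions_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE,
                           col.names = c("chrom", "start", "end",
                                         "region_id", "score", "strand"))
  data.frame(region_id = bed$region_id, chrom = bed$chrom,
             start = bed$start, end = bed$end)
}

#' Write and read fragment intervals as BED3
#'
#' @param fragments data.frame with `chrom`, `start`, `end`.
#' @param path File path.
#' @export
write_fragments_bed <- function(fragments, path) {
  utils::write.table(fragments[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments_bed
#' @export
read_fragments_bed <- function(path) {
  utils::read.delim(path, header = FALSE,
                    col.names = c("chrom", "start", "end"))
}

#' Write and read the methylation table
#'
#' Four tab-separated columns: region id, embryo, egg, sperm proportions.
#'
#' @param methylation data.frame from [simulate_methylation()].
#' @param path File path.
#' @export
write_methylation_table <- function(methylation, path) {
  utils::write.table(methylation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_methylation_table
#' @export
read_methylation_table <- function(path) {
  utils::read.delim(path)
}

#' Write and read the TSS table (TSV)
#'
#' @param tss TSS data.frame.
#' @param path File path.
#' @export
write_tss_table <- function(tss, path) {
  utils::write.table(tss, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tss_table
#' @export
read_tss_table <- function(path) {
  utils::read.delim(path)
}

#' Write and read a Ct table (CSV)
#'
#' Columns: `embryo_id`, `group`, `primer`, `rep`, `ct`.
#'
#' @param ct_table Ct data.frame.
#' @param path File path.
#' @export
write_ct_table <- function(ct_table, path) {
  utils::write.csv(ct_table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path) {
  utils::read.csv(path)
}
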