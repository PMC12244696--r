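# Shared fixtures built in code. Coordinates are 0-based half-open.

# a minimal genome spec with explicit genes (one chromosome unless stated)
tiny_spec <- function(tss = c(5000L, 25000L), tags = c(50L, 60L),
                      chrom_len = 60000L, strand = NULL) {
  n <- length(tss)
  if (is.null(strand)) strand <- rep("+", n)
  genes <- data.frame(
    gene_id = sprintf("g%02d", seq_len(n)), chrom = "chr1", tss = tss,
    strand = strand, cage_tags = tags,
    expr_group = rep_len(c("NPS-down", "unaffected"), n),
    contribution = rep_len(c("maternal-zygotic", "strictly-zygotic"), n),
    annotation = "primary")
  exons <- data.frame(gene_id = genes$gene_id, chrom = "chr1",
                      start = tss - 50L, end = tss + 250L)
  synthetic_genome_spec(
    data.frame(chrom = "chr1", length = chrom_len), genes, exons)
}

# hand-built coverage matrix for classifier/orientation tests
make_cov <- function(counts, sample_id, mark, replicate = 1, stage = "dome",
                     is_control = FALSE, subinterval, region_id = NULL,
                     lib_sizes = NULL, center_len = NULL,
                     normalized = FALSE, oriented = FALSE) {
  if (is.null(region_id)) region_id <- sprintf("r%03d", seq_len(nrow(counts)))
  cols <- data.frame(sample_id = sample_id, mark = mark,
                     replicate = replicate, stage = stage,
                     is_control = is_control, subinterval = subinterval)
  if (is.null(lib_sizes))
    lib_sizes <- stats::setNames(rep(1e6, length(unique(sample_id))),
                                 unique(sample_id))
  if (is.null(center_len)) center_len <- rep(500L, nrow(counts))
  colnames(counts) <- paste(cols$sample_id, cols$subinterval, sep = "|")
  structure(list(region_id = region_id, counts = counts, cols = cols,
                 lib_sizes = lib_sizes, center_len = center_len,
                 normalized = normalized, oriented = oriented),
            class = "cov_matrix")
}

# regions data.frame with flanks already built
flanked_regions <- function(chrom, start, end, id = NULL) {
  n <- length(start)
  if (is.null(id)) id <- sprintf("r%03d", seq_len(n))
  data.frame(region_id = id, chrom = chrom, start = start, end = end,
             left_start = start - 500L, left_end = start,
             right_start = end, right_end = end + 500L)
}

# brute-force overlap count oracle: O(F x R) scan
brute_overlap_count <- function(win, frags) {
  vapply(seq_len(nrow(win)), function(i) {
    sum(frags$chrom == win$chrom[i] &
          frags$start < win$end[i] & frags$end > win$start[i])
  }, integer(1))
}

# exact two-sided rank-sum p-value by enumeration of group assignments
brute_wilcox_p <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(m + n, m)
  ws <- apply(combs, 2, function(ix) sum(rank(pooled)[ix]) - m * (m + 1) / 2)
  mu <- m * n / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# small complete synthetic study for pipeline-level unit tests
small_sim <- function(seed = 7, regions_per_class = 40, depth = 4e5,
                      replicates = 2) {
  simulate_study(
    spec = default_genome_spec(n_genes = 200, seed = seed),
    config = sim_config(regions_per_class = regions_per_class,
                        depth = depth, replicates = replicates,
                        seed = seed))
}
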