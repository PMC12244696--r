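#' Synthetic genome specification
#'
#' Bundles the chromosome table and gene annotation used by the synthetic
#' data generator. Genes carry a TSS, strand, exon intervals, a CAGE-like
#' tag count, an expression-group label (whether zygotic activation of the
#' gene depends on the maternal NPS pioneer factors) and a contribution
#' label (maternal-zygotic versus strictly zygotic).
#'
#' @param chromosomes data.frame with columns `chrom`, `length` (bp).
#' @param genes data.frame with columns `gene_id`, `chrom`, `tss`, `strand`
#'   (`"+"` or `"-"`), `cage_tags` (non-negative integer),
#'   `expr_group` (`"NPS-down"` or `"unaffected"`),
#'   `contribution` (`"maternal-zygotic"` or `"strictly-zygotic"`),
#'   `annotation` (`"primary"` or `"secondary"`).
#' @param exons data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open). The first exon of each gene must contain its TSS.
#' @return An object of class `genome_spec`.
#' @export
synthetic_genome_spec <- function(chromosomes, genes, exons) {
  check_columns(chromosomes, c("chrom", "length"), "chromosomes")
  check_columns(genes, c("gene_id", "chrom", "tss", "strand", "cage_tags",
                         "expr_group", "contribution", "annotation"), "genes")
  check_columns(exons, c("gene_id", "chrom", "start", "end"), "exons")
  stopifnot(all(genes$strand %in% c("+", "-")),
            all(genes$cage_tags >= 0),
            all(genes$cage_tags == as.integer(genes$cage_tags)),
            all(genes$expr_group %in% c("NPS-down", "unaffected")),
            all(genes$contribution %in% c("maternal-zygotic", "strictly-zygotic")),
            all(genes$annotation %in% c("primary", "secondary")))
  # reject genes duplicated at the same TSS on the same strand
  key <- paste(genes$chrom, genes$strand, genes$tss)
  if (anyDuplicated(key))
    stop("overlapping genes on the same strand at the same TSS", call. = FALSE)
  clen <- stats::setNames(chromosomes$length, chromosomes$chrom)
  if (!all(exons$chrom %in% chromosomes$chrom) ||
      any(exons$start < 0) || any(exons$end > clen[exons$chrom]))
    stop("exon intervals must lie within their chromosome", call. = FALSE)
  # TSS inside the first exon (first by gene order in `exons`)
  first <- exons[!duplicated(exons$gene_id), ]
  tss <- stats::setNames(genes$tss, genes$gene_id)[first$gene_id]
  if (any(tss < first$start | tss >= first$end))
    stop("each TSS must lie inside the gene's first exon", call. = FALSE)
  structure(list(chromosomes = chromosomes, genes = genes, exons = exons),
            class = "genome_spec")
}

#' Default synthetic genome
#'
#' Lays out `n_genes` genes on two chromosomes at a regular 12-kb spacing
#' (with positional jitter), leaving room between genes for TSS-distal
#' elements. A fraction of genes is tagged as coming from a secondary
#' annotation source, and a fraction receives a CAGE tag count at or below
#' the promoter-support cutoff.
#'
#' @param n_genes Number of genes.
#' @param seed Integer seed.
#' @param secondary_fraction Fraction of genes from the secondary annotation.
#' @param low_tag_fraction Fraction of primary genes with <= 20 CAGE tags.
#' @return A `genome_spec`.
#' @export
default_genome_spec <- function(n_genes = 450, seed = 20250710,
                                secondary_fraction = 0.05,
                                low_tag_fraction = 0.02) {
  set.seed(seed %% .Machine$integer.max)
  spacing <- 60000L
  per_chrom <- ceiling(n_genes / 2)
  chroms <- data.frame(
    chrom = c("chr1", "chr2"),
    length = as.integer(50000L + per_chrom * spacing + 50000L))
  idx <- seq_len(n_genes)
  chrom <- ifelse(idx <= per_chrom, "chr1", "chr2")
  slot <- ifelse(idx <= per_chrom, idx, idx - per_chrom)
  tss <- as.integer(50000L + (slot - 1L) * spacing +
                      sample(-200:200, n_genes, replace = TRUE))
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  tags <- as.integer(21L + stats::rnbinom(n_genes, mu = 80, size = 5))
  low <- runif(n_genes) < low_tag_fraction
  tags[low] <- sample(0:20, sum(low), replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("gene%04d", idx),
    chrom = chrom, tss = tss, strand = strand, cage_tags = tags,
    expr_group = rep_len(c("NPS-down", "unaffected"), n_genes),
    contribution = ifelse(runif(n_genes) < 0.6,
                          "maternal-zygotic", "strictly-zygotic"),
    annotation = ifelse(runif(n_genes) < secondary_fraction,
                        "secondary", "primary"))
  # two exons per gene: a 300-bp first exon containing the TSS and a second
  # exon 500 bp further along the strand
  e1s <- ifelse(strand == "+", tss - 50L, tss - 249L)
  exons <- rbind(
    data.frame(gene_id = genes$gene_id, chrom = chrom,
               start = as.integer(e1s), end = as.integer(e1s + 300L)),
    data.frame(gene_id = genes$gene_id, chrom = chrom,
               start = as.integer(ifelse(strand == "+", e1s + 800L, e1s - 700L)),
               end = as.integer(ifelse(strand == "+", e1s + 1000L, e1s - 500L))))
  exons <- exons[order(match(exons$gene_id, genes$gene_id)), ]
  synthetic_genome_spec(chroms, genes, exons)
}

#' Element classes simulated by the generator
#' @return Character vector of the six chromatin classes.
#' @export
element_classes <- function() {
  c("active-promoter", "weak-promoter", "H3K4me1-enhancer",
    "H3K4me2-enhancer", "poised-enhancer", "unmarked")
}

#' Chromatin class profiles
#'
#' Mean fold-enrichment over the IgG baseline per histone mark and class,
#' plus methylation means (embryo, egg, sperm), NPS motif densities, and
#' per-stage activation multipliers. The profiles encode the empirical
#' structure of dome-stage embryonic chromatin: promoters form an activity
#' continuum (weak promoters are active-promoter enrichments raised to
#' `weak_exponent`); H3K4me2 enhancers share the acetylation and H3K4me2
#' levels of promoters but lack H3K4me3 and are hypomethylated with reduced
#' NPS motif content; H3K4me1 enhancers carry H3K4me1/H2BNTac and
#' acetylation only and are hypermethylated; poised enhancers lack H3K27ac;
#' unmarked regions sit at baseline for every antibody. H3K56ac is given
#' large region-to-region variability unrelated to class, mirroring its
#' behaviour as a non-class-defining mark.
#'
#' @param weak_exponent Exponent scaling weak-promoter fold-enrichments.
#' @param shared_gamete_fraction Fraction of embryo-hypomethylated regions
#'   that are also hypomethylated in both gametes.
#' @return An object of class `class_profiles`.
#' @export
class_profiles <- function(weak_exponent = 0.85,
                           shared_gamete_fraction = 0.69) {
  marks <- c("H3K4me1", "H3K4me2", "H3K4me3", "H3K27ac", "H3K9ac",
             "H4K16ac", "H2BNTac", "H3K56ac")
  active <- c(2.5, 8, 2, 8, 5, 3, 2, 2.5)
  fold <- rbind(
    `active-promoter`  = active,
    `weak-promoter`    = exp(weak_exponent * log(active)),
    `H3K4me1-enhancer` = c(8,   1, 1,   8, 4, 2.5, 6, 2.5),
    `H3K4me2-enhancer` = c(2.5, 8, 1.1, 8, 5, 3,   2, 2.5),
    `poised-enhancer`  = c(4,   1, 1,   1, 1, 1,   2, 1.2),
    `unmarked`         = c(1,   1, 1,   1, 1, 1,   1, 1))
  colnames(fold) <- marks
  # accessibility latent (natural-log scale): mean and sd per class; the
  # H3K4me2-enhancer latent is drawn from the same two-component mixture as
  # the promoter continuum (see `simulate_coverage`)
  access <- data.frame(
    class = rownames(fold),
    mean = c(0, -0.7, 0, NA, -1, -1),
    sd = c(0.4, 0.45, 0.4, 0.38, 0.5, 0.5))
  meth <- data.frame(
    class = rownames(fold),
    embryo = c(0.10, 0.15, 0.85, 0.10, 0.50, 0.80),
    egg    = c(0.08, 0.10, 0.85, 0.08, 0.55, 0.80),
    sperm  = c(0.08, 0.10, 0.80, 0.08, 0.50, 0.78))
  motif <- data.frame(
    class = rownames(fold),
    nanog  = c(0.8, 0.8, 1.2, 0.35, 1.0, 0.6),
    pou5f3 = c(0.7, 0.7, 1.0, 0.30, 0.9, 0.5),
    sox19b = c(0.6, 0.6, 0.8, 0.25, 0.8, 0.4))
  # per-stage multipliers applied to (fold - 1): H3K4me2 enhancers activate
  # earliest, H3K4me1 enhancers late, mirroring the temporal asymmetry of
  # the two classes
  stage_mult <- rbind(
    `active-promoter`  = c(`1K-cell` = 0.5,  dome = 1, shield = 1.1),
    `weak-promoter`    = c(0.3, 1, 1.1),
    `H3K4me1-enhancer` = c(0.15, 1, 1.1),
    `H3K4me2-enhancer` = c(0.7, 1, 1.05),
    `poised-enhancer`  = c(0.3, 1, 1),
    `unmarked`         = c(1, 1, 1))
  obj <- list(fold = fold, access = access, methylation = meth,
              motif = motif, stage_mult = stage_mult,
              shared_gamete_fraction = shared_gamete_fraction,
              fold_sdlog = 0.25, flat_sdlog = 0.10, k56_sdlog = 0.9)
  class(obj) <- "class_profiles"
  stopifnot(fold["H3K4me2-enhancer", "H3K4me2"] >= 2,
            fold["H3K4me2-enhancer", "H3K4me3"] < 1.25,
            fold["H3K4me1-enhancer", "H3K4me2"] < 1.25,
            all(abs(fold["unmarked", ] - 1) < 1e-9))
  obj
}

#' Simulation configuration
#'
#' @param regions_per_class Regions planted per chromatin class.
#' @param depth Fragments emitted per sample (before span filtering).
#' @param dispersion Negative-binomial dispersion (1/size); counts are drawn
#'   with `size = 1/dispersion`.
#' @param spike_pairs Spike-in pair count recorded per sample.
#' @param seed Integer random seed; fixed seed gives bit-identical output.
#' @param stages Developmental stages to simulate coverage for.
#' @param replicates CUT&RUN replicates per mark.
#' @param background_fraction Fraction of each library falling outside the
#'   region universe (genomic background).
#' @param cryptic_fraction Fraction (relative to the H3K4me2-enhancer count)
#'   of additional distal regions planted as cryptic gene TSSs: they carry
#'   H3K4me2-enhancer chromatin but produce directional stable transcripts.
#' @param region_width_range Range of open-interval widths (bp).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(regions_per_class = 200, depth = 1.5e6,
                       dispersion = 0.02, spike_pairs = 5e5,
                       seed = 20250710,
                       stages = "dome", replicates = 3,
                       background_fraction = 0.85,
                       cryptic_fraction = 0.07,
                       region_width_range = c(700L, 1100L)) {
  stopifnot(depth > 0, dispersion > 0, regions_per_class >= 1,
            replicates >= 1, background_fraction >= 0,
            background_fraction < 1,
            all(stages %in% c("1K-cell", "dome", "shield")))
  structure(list(regions_per_class = regions_per_class, depth = depth,
                 dispersion = dispersion, spike_pairs = spike_pairs,
                 seed = as.integer(seed), stages = stages,
                 replicates = replicates,
                 background_fraction = background_fraction,
                 cryptic_fraction = cryptic_fraction,
                 region_width_range = as.integer(region_width_range)),
            class = "sim_config")
}
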