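#' Read a JASPAR-format position frequency matrix
#'
#' Parses the four `A/C/G/T [ ... ]` rows of a JASPAR PFM file and converts
#' counts to column probabilities with a pseudocount of 0.5 per cell.
#'
#' @param path Path to a JASPAR PFM file.
#' @return List with `id` and `matrix` (4 x L probability matrix, rows
#'   A, C, G, T; columns sum to 1).
#' @export
read_jaspar_pwm <- function(path) {
  lines <- readLines(path)
  id <- sub("^>\\s*", "", lines[grepl("^>", lines)][1])
  rows <- lines[grepl("^[ACGT]", lines)]
  m <- do.call(rbind, lapply(rows, function(l) {
    nums <- regmatches(l, gregexpr("[0-9.]+", l))[[1]]
    as.numeric(nums)
  }))
  rownames(m) <- substr(rows, 1, 1)
  m <- m[c("A", "C", "G", "T"), , drop = FALSE] + 0.5
  m <- sweep(m, 2, colSums(m), "/")
  list(id = id, matrix = m)
}

# log-odds scores of a PWM at every start position of an integer-coded
# sequence (1=A..4=T, NA for other letters); uniform background
.pwm_scores <- function(codes, lo) {
  L <- ncol(lo)
  n <- length(codes) - L + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(L)) {
    v <- lo[cbind(codes[j:(j + n - 1L)], j)]
    v[is.na(v)] <- -Inf
    s <- s + v
  }
  s
}

.code_seq <- function(x) {
  match(strsplit(toupper(x), "")[[1]], c("A", "C", "G", "T"))
}

#' Count motif hits around region centers
#'
#' Scans both strands of the window of `half_width` bp either side of each
#' open-interval center with a position weight matrix, counting positions
#' whose log-odds score (uniform background) reaches `threshold_frac` of
#' the maximal achievable score. Brute-force position-by-position
#' semantics; a palindromic motif present at one position counts once per
#' strand. Sequences shorter than the motif yield 0 hits.
#'
#' @param sequences Named character vector of chromosome sequences.
#' @param regions Region data.frame (`region_id`, `chrom`, `start`, `end`).
#' @param pwm A probability matrix (4 x L, rows A, C, G, T) or the list
#'   returned by [read_jaspar_pwm()].
#' @param threshold_frac Fraction of the maximum log-odds score required.
#' @param half_width Half-width of the scanned window (bp).
#' @return Integer vector of hit counts named by region id.
#' @export
scan_motif_density <- function(sequences, regions, pwm,
                               threshold_frac = 0.8, half_width = 100) {
  if (is.list(pwm)) pwm <- pwm$matrix
  stopifnot(nrow(pwm) == 4, all(abs(colSums(pwm) - 1) < 1e-6))
  lo <- log2(pmax(pwm, 1e-12) / 0.25)
  thr <- threshold_frac * sum(apply(lo, 2, max))
  out <- stats::setNames(integer(nrow(regions)), regions$region_id)
  for (i in seq_len(nrow(regions))) {
    chrseq <- sequences[[regions$chrom[i]]]
    mid <- (regions$start[i] + regions$end[i]) %/% 2L
    ws <- max(0L, mid - half_width)
    we <- min(nchar(chrseq), mid + half_width)
    if (we - ws < ncol(lo)) next
    win <- substr(chrseq, ws + 1L, we)
    fwd <- .code_seq(win)
    rev_ <- .code_seq(as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(win))))
    out[i] <- sum(.pwm_scores(fwd, lo) >= thr) +
      sum(.pwm_scores(rev_, lo) >= thr)
  }
  out
}

#' Chi-squared test of motif presence between two region classes
#'
#' Categorizes per-region hit counts as absence/presence (0 versus >= 1;
#' 1 d.o.f.) or, with `levels = 3`, as 0 / 1 / >= 2 hits (2 d.o.f.), and
#' applies Pearson's chi-squared test without continuity correction.
#'
#' @param counts_a,counts_b Per-region hit counts for the two classes.
#' @param levels 2 or 3 presence categories.
#' @return List with `statistic`, `df`, `p.value`, `table`.
#' @export
motif_presence_test <- function(counts_a, counts_b, levels = 2) {
  stopifnot(levels %in% c(2, 3))
  cut_counts <- function(x) {
    if (levels == 2) ifelse(x == 0, "0", ">=1")
    else ifelse(x == 0, "0", ifelse(x == 1, "1", ">=2"))
  }
  lv <- if (levels == 2) c("0", ">=1") else c("0", "1", ">=2")
  tab <- rbind(A = table(factor(cut_counts(counts_a), levels = lv)),
               B = table(factor(cut_counts(counts_b), levels = lv)))
  exp_ <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_ < 1))
    warning("expected cell count below 1", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, table = tab)
}

#' Stratify regions by embryonic DNA methylation
#'
#' Embryo methylation below 20% is `low`, above 80% is `high`, and the
#' closed interval between (including both boundaries) is `medium`.
#'
#' @param records data.frame: `region_id`, `embryo`, `egg`, `sperm`.
#' @return Character vector (`low`/`medium`/`high`) named by region id.
#' @export
methylation_stratify <- function(records) {
  check_columns(records, c("region_id", "embryo"), "records")
  x <- records$embryo
  stats::setNames(ifelse(x < 0.2, "low", ifelse(x > 0.8, "high", "medium")),
                  records$region_id)
}

#' Fraction of hypomethylated regions shared with both gametes
#'
#' Among regions hypomethylated in the embryo (< 20%), the fraction also
#' hypomethylated (< 20%) in both egg and sperm. Undefined (NA) when no
#' region is embryo-hypomethylated.
#'
#' @param records data.frame: `region_id`, `embryo`, `egg`, `sperm`.
#' @return List with `fraction`, `n_hypo`, `shared_ids`, `unshared_ids`.
#' @export
shared_hypomethylation <- function(records) {
  check_columns(records, c("region_id", "embryo", "egg", "sperm"), "records")
  hypo <- records$embryo < 0.2
  if (!any(hypo))
    return(list(fraction = NA_real_, n_hypo = 0L,
                shared_ids = character(0), unshared_ids = character(0)))
  shared <- hypo & records$egg < 0.2 & records$sperm < 0.2
  list(fraction = sum(shared) / sum(hypo), n_hypo = sum(hypo),
       shared_ids = records$region_id[shared],
       unshared_ids = records$region_id[hypo & !shared])
}

#' CpG count and C+G fraction in the element center
#'
#' Counts `CG` dinucleotides (forward strand) and the C+G base fraction in
#' the 500-bp window centered on the open-interval midpoint. Both values
#' are strand-symmetric. Windows falling off the chromosome are skipped
#' with a warning (NA).
#'
#' @param sequences Named character vector of chromosome sequences.
#' @param regions Region data.frame.
#' @param width Center window width (bp).
#' @return data.frame: `region_id`, `cpg`, `gc_fraction`.
#' @export
base_composition <- function(sequences, regions, width = 500) {
  out <- data.frame(region_id = regions$region_id, cpg = NA_integer_,
                    gc_fraction = NA_real_)
  skipped <- 0L
  for (i in seq_len(nrow(regions))) {
    chrseq <- sequences[[regions$chrom[i]]]
    mid <- (regions$start[i] + regions$end[i]) %/% 2L
    ws <- mid - width %/% 2L
    if (ws < 0L || ws + width > nchar(chrseq)) { skipped <- skipped + 1L; next }
    win <- toupper(substr(chrseq, ws + 1L, ws + width))
    d <- Biostrings::DNAString(win)
    out$cpg[i] <- Biostrings::countPattern("CG", d)
    bases <- Biostrings::alphabetFrequency(d)
    out$gc_fraction[i] <- (bases[["C"]] + bases[["G"]]) / width
  }
  if (skipped > 0)
    warning(sprintf("%d region window(s) off chromosome; skipped", skipped),
            call. = FALSE)
  out
}

#' Enhancer distances to gene groups, with a rank-sum comparison
#'
#' For each enhancer, the distance (bp; 0 when overlapping) to the nearest
#' gene TSS of each group, followed by a two-sided Wilcoxon rank-sum test
#' comparing the two enhancer classes' distance distributions per gene
#' group (exact when the combined sample size is at most 20).
#'
#' @param enhancers data.frame: `region_id`, `chrom`, `start`, `end`,
#'   `call` (two classes expected).
#' @param gene_tss data.frame: `gene_id`, `chrom`, `pos`, `group`.
#' @return List with `distances` (long data.frame) and `tests` (one row
#'   per gene group).
#' @export
nearest_gene_distances <- function(enhancers, gene_tss) {
  stopifnot(nrow(enhancers) > 0, nrow(gene_tss) > 0)
  groups <- unique(gene_tss$group)
  dist_list <- lapply(groups, function(g) {
    sel <- gene_tss$group == g
    d <- nearest_point_distance(enhancers$chrom, enhancers$start,
                                enhancers$end,
                                gene_tss$chrom[sel], gene_tss$pos[sel])
    data.frame(region_id = enhancers$region_id, call = enhancers$call,
               gene_group = g, distance = d)
  })
  distances <- do.call(rbind, dist_list)
  classes <- sort(unique(enhancers$call))
  tests <- NULL
  if (length(classes) == 2) {
    tests <- do.call(rbind, lapply(groups, function(g) {
      d <- distances[distances$gene_group == g, ]
      ht <- rank_sum_test(d$distance[d$call == classes[1]],
                          d$distance[d$call == classes[2]])
      data.frame(gene_group = g, class_a = classes[1], class_b = classes[2],
                 statistic = ht$statistic, p.value = ht$p.value)
    }))
  }
  list(distances = distances, tests = tests)
}

#' Fraction of genes with an enhancer within a radius
#'
#' Distance is measured from the gene TSS to the nearest edge of the
#' enhancer interval (0 when the TSS lies inside it).
#'
#' @param gene_tss data.frame: `gene_id`, `chrom`, `pos`.
#' @param enhancers data.frame of enhancer intervals.
#' @param radius Distance cutoff in bp (e.g. 1e5 or 1e6).
#' @return Fraction in [0, 1].
#' @export
proximity_fraction <- function(gene_tss, enhancers, radius) {
  if (nrow(gene_tss) == 0) return(NA_real_)
  hit <- vapply(seq_len(nrow(gene_tss)), function(i) {
    sel <- enhancers$chrom == gene_tss$chrom[i]
    if (!any(sel)) return(FALSE)
    d <- interval_point_distance(enhancers$start[sel], enhancers$end[sel],
                                 gene_tss$pos[i])
    any(d <= radius)
  }, logical(1))
  mean(hit)
}

#' Term enrichment between genes near two enhancer classes
#'
#' Per annotation term, builds the 2x2 table (annotated or not) x (near
#' class A, near class B), applies a two-sided Fisher's exact test, and
#' adjusts across terms with Benjamini-Hochberg. Terms annotating no gene
#' in either list are skipped.
#'
#' @param annotation data.frame: `gene_id`, `term`.
#' @param genes_a,genes_b Gene id vectors (genes near each class).
#' @return data.frame: `term`, `a_in`, `b_in`, `odds_ratio`, `p.value`,
#'   `q.value`.
#' @export
go_enrichment <- function(annotation, genes_a, genes_b) {
  terms <- unique(annotation$term)
  rows <- lapply(terms, function(tm) {
    ann <- unique(annotation$gene_id[annotation$term == tm])
    a_in <- sum(genes_a %in% ann); b_in <- sum(genes_b %in% ann)
    if (a_in + b_in == 0) return(NULL)
    tab <- matrix(c(a_in, length(genes_a) - a_in,
                    b_in, length(genes_b) - b_in), 2, byrow = TRUE)
    ht <- stats::fisher.test(tab)
    data.frame(term = tm, a_in = a_in, b_in = b_in,
               odds_ratio = unname(ht$estimate), p.value = ht$p.value)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$q.value <- stats::p.adjust(out$p.value, method = "BH")
  out[order(out$p.value), ]
}
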