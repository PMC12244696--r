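# uniform-background log-odds scan oracle: score every start position on
# both strands, count scores >= frac * max
naive_motif_scan <- function(win, pwm, frac = 0.8) {
  lo <- log2(pmax(pwm, 1e-12) / 0.25)
  thr <- frac * sum(apply(lo, 2, max))
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                                 collapse = ""))
  count_one <- function(s) {
    L <- ncol(lo); n <- nchar(s) - L + 1
    if (n < 1) return(0L)
    hits <- 0L
    for (i in seq_len(n)) {
      sc <- 0
      for (j in seq_len(L)) {
        b <- match(substr(s, i + j - 1, i + j - 1), c("A", "C", "G", "T"))
        sc <- sc + if (is.na(b)) -Inf else lo[b, j]
      }
      if (sc >= thr) hits <- hits + 1L
    }
    hits
  }
  count_one(win) + count_one(rc(win))
}

consensus_pwm <- function(motif) {
  m <- matrix(0.01, 4, nchar(motif), dimnames = list(c("A", "C", "G", "T")))
  for (j in seq_len(nchar(motif)))
    m[substr(motif, j, j), j] <- 0.97
  m
}

test_that("motif counting enumerates both strands around the center", {
  # window is [mid - 100, mid + 100): plant ACGC twice forward, its
  # reverse complement GCGT once
  seqs <- c(chr1 = paste0(strrep("T", 380), "ACGC", strrep("T", 16), "ACGC",
                          strrep("T", 16), "GCGT", strrep("T", 180)))
  reg <- data.frame(region_id = "r1", chrom = "chr1", start = 300L,
                    end = 500L)  # mid 400, window [300, 500)
  pwm <- consensus_pwm("ACGC")
  expect_equal(unname(scan_motif_density(seqs, reg, pwm)), 3L)
  # all-N sequence yields no hits
  seqs_n <- c(chr1 = strrep("N", 1000))
  expect_equal(unname(scan_motif_density(seqs_n, reg, pwm)), 0L)
  # palindromic motif counts once per strand
  seqs_p <- c(chr1 = paste0(strrep("T", 398), "ACGT", strrep("T", 198)))
  expect_equal(unname(scan_motif_density(seqs_p, reg, consensus_pwm("ACGT"))),
               2L)
})

test_that("motif scan equals naive scoring on random sequences", {
  set.seed(12)
  pwm <- consensus_pwm("TGCAT")
  pwm[, 3] <- c(0.45, 0.05, 0.45, 0.05)  # degenerate position
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
    reg <- data.frame(region_id = "r", chrom = "chr1", start = 400L,
                      end = 600L)
    got <- unname(scan_motif_density(c(chr1 = s), reg, pwm))
    win <- substr(s, 401, 600)
    expect_equal(got, naive_motif_scan(win, pwm))
  }
})

test_that("JASPAR PFM files parse into probability columns", {
  path <- withr::local_tempfile(lines = c(
    ">MA0000.1 testmotif",
    "A [ 10  0  2 ]",
    "C [  0 12  2 ]",
    "G [  2  0  8 ]",
    "T [  0  0  0 ]"))
  pwm <- read_jaspar_pwm(path)
  expect_equal(pwm$id, "MA0000.1 testmotif")
  expect_equal(colSums(pwm$matrix), rep(1, 3), tolerance = 1e-9)
  expect_gt(pwm$matrix["A", 1], 0.7)
})

test_that("presence chi-squared matches Pearson's formula", {
  # class A: 30 regions without hits, 70 with; class B: 60 and 40
  a <- c(rep(0, 30), rep(1, 70))
  b <- c(rep(0, 60), rep(2, 40))
  ht <- motif_presence_test(a, b)
  expect_equal(ht$statistic, 18.1818, tolerance = 1e-4)
  expect_equal(ht$df, 1)
  # identical proportions
  ht0 <- motif_presence_test(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(ht0$statistic, 0)
  expect_equal(ht0$p.value, 1)
  # three presence levels give 2 d.o.f.
  ht3 <- motif_presence_test(c(0, 1, 2, 2, 1, 0), c(0, 1, 1, 2, 0, 0),
                             levels = 3)
  expect_equal(ht3$df, 2)
  expect_warning(motif_presence_test(0, 1), "below 1")
})

test_that("methylation strata use strict 20/80 boundaries", {
  rec <- data.frame(region_id = letters[1:5],
                    embryo = c(0.15, 0.85, 0.20, 0.80, 0.5),
                    egg = 0, sperm = 0)
  s <- methylation_stratify(rec)
  expect_equal(unname(s), c("low", "high", "medium", "medium", "medium"))
  # a partition of the record set
  expect_equal(sum(table(s)), nrow(rec))
})

test_that("gamete-shared hypomethylation enumerates correctly", {
  rec <- data.frame(region_id = c("a", "b", "c"),
                    embryo = c(0.1, 0.1, 0.1),
                    egg = c(0.1, 0.5, 0.1),
                    sperm = c(0.1, 0.1, 0.1))
  sh <- shared_hypomethylation(rec)
  expect_equal(sh$fraction, 2 / 3)
  expect_setequal(sh$shared_ids, c("a", "c"))
  # no embryo-hypomethylated regions: undefined
  hyper <- transform(rec, embryo = 0.9)
  expect_true(is.na(shared_hypomethylation(hyper)$fraction))
})

test_that("base composition counts CpG and C+G in the center window", {
  seqs <- c(chr1 = paste0(strrep("A", 150), "CGCG", strrep("A", 846)))
  reg <- data.frame(region_id = "r1", chrom = "chr1", start = 100L,
                    end = 500L)  # mid 300, window [50, 550)
  bc <- base_composition(seqs, reg)
  expect_equal(bc$cpg, 2L)
  expect_equal(bc$gc_fraction, 4 / 500)
  # all-A window
  bc0 <- base_composition(c(chr1 = strrep("A", 1000)), reg)
  expect_equal(bc0$cpg, 0L)
  expect_equal(bc0$gc_fraction, 0)
  # reverse complement leaves both unchanged
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(seqs[[1]], "")[[1]]),
                                     collapse = ""))
  reg_rc <- data.frame(region_id = "r1", chrom = "chr1",
                       start = nchar(rc) - 500L, end = nchar(rc) - 100L)
  bc_rc <- base_composition(c(chr1 = rc), reg_rc)
  expect_equal(bc_rc$cpg, bc$cpg)
  expect_equal(bc_rc$gc_fraction, bc$gc_fraction)
  # off-chromosome window skipped with a warning
  reg_off <- data.frame(region_id = "r2", chrom = "chr1", start = 0L,
                        end = 100L)
  expect_warning(bc_off <- base_composition(seqs, reg_off), "off chromosome")
  expect_true(is.na(bc_off$cpg))
})

test_that("nearest-gene distances and the rank-sum comparison", {
  enh <- data.frame(region_id = c("e1", "e2"), chrom = "chr1",
                    start = c(5000L, 20000L), end = c(5100L, 20100L),
                    call = c("H3K4me1-enhancer", "H3K4me2-enhancer"))
  tss <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                    pos = c(4000L, 9000L), group = "unaffected")
  out <- nearest_gene_distances(enh, tss)
  expect_equal(out$distances$distance[out$distances$region_id == "e1"], 1000)
  # exact rank-sum p-values
  expect_equal(rank_sum_test(1:3, 4:6)$p.value, 0.1, tolerance = 1e-12)
  expect_equal(rank_sum_test(1:3, 4:6, alternative = "less")$p.value, 0.05,
               tolerance = 1e-12)
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
})

test_that("proximity fractions agree with an all-pairs scan", {
  tss <- data.frame(gene_id = "g1", chrom = "chr1", pos = 100000L)
  enh <- data.frame(chrom = "chr1", start = 150000L, end = 150500L)
  expect_equal(proximity_fraction(tss, enh, 1e5), 1)
  expect_equal(proximity_fraction(tss, enh, 1e4), 0)
  set.seed(13)
  genes <- data.frame(gene_id = paste0("g", 1:100), chrom = "chr1",
                      pos = sample(1:1e6, 100))
  enh <- data.frame(chrom = "chr1", start = sort(sample(1:1e6, 30)))
  enh$end <- enh$start + 500L
  brute <- mean(vapply(genes$pos, function(p) {
    d <- ifelse(p >= enh$start & p < enh$end, 0,
                pmin(abs(enh$start - p), abs(p - (enh$end - 1))))
    any(d <= 5e4)
  }, logical(1)))
  expect_equal(proximity_fraction(genes, enh, 5e4), brute)
})

test_that("term enrichment applies Fisher tests with BH correction", {
  ann <- data.frame(gene_id = c(paste0("a", 1:8), "b1"),
                    term = "GO:1")
  genes_a <- c(paste0("a", 1:8), paste0("x", 1:2))
  genes_b <- c("b1", paste0("y", 1:9))
  out <- go_enrichment(ann, genes_a, genes_b)
  # 2x2 table [[8,2],[1,9]]: two-sided Fisher
  expect_equal(out$p.value, fisher.test(matrix(c(8, 2, 1, 9), 2,
                                               byrow = TRUE))$p.value,
               tolerance = 1e-12)
  expect_equal(out$p.value, 0.005477, tolerance = 1e-4)
  # identical gene lists: all p = 1
  same <- go_enrichment(ann, genes_a, genes_a)
  expect_true(all(same$p.value == 1))
  # unannotated terms are skipped
  ann2 <- rbind(ann, data.frame(gene_id = "zz", term = "GO:2"))
  expect_equal(nrow(go_enrichment(ann2, genes_a, genes_b)), 1L)
})
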