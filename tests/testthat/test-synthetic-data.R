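test_that("annotation passes gene attributes through and is deterministic", {
  spec <- tiny_spec(tss = 5000L, tags = 25L)
  ann <- generate_annotation(spec, seed = 3)
  expect_equal(nrow(ann$tss), 1L)
  expect_equal(ann$tss$tag_count, 25L)
  ann2 <- generate_annotation(spec, seed = 3)
  expect_identical(ann, ann2)
})

test_that("genes duplicated at the same TSS and strand are rejected", {
  expect_error(tiny_spec(tss = c(5000L, 5000L), strand = c("+", "+")),
               "same TSS")
  expect_silent(tiny_spec(tss = c(5000L, 5000L), strand = c("+", "-")))
})

test_that("NPS-independent genes activate earlier, NPS-dependent higher", {
  spec <- default_genome_spec(n_genes = 100, seed = 5)
  ann <- generate_annotation(spec, seed = 5)
  traj <- rna_activation_trajectory(
    ann$expression,
    data.frame(gene_id = spec$genes$gene_id, group = spec$genes$expr_group),
    t0 = "2cell", stages = c("2cell", "1K-cell", "dome", "shield"))
  first <- traj[traj$stage == "1K-cell", ]
  expect_gt(first$mean[first$group == "unaffected"],
            first$mean[first$group == "NPS-down"])
  last <- traj[traj$stage == "shield", ]
  expect_gt(last$mean[last$group == "NPS-down"],
            last$mean[last$group == "unaffected"])
})

test_that("planted regions respect class geometry and source tagging", {
  spec <- default_genome_spec(n_genes = 100, seed = 2)
  cfg <- sim_config(regions_per_class = 10, seed = 2)
  reg <- generate_regions(spec, cfg)
  me2 <- reg[reg$class_true == "H3K4me2-enhancer", ]
  expect_equal(nrow(me2), 10L)
  d <- vapply(seq_len(nrow(me2)), function(i) {
    tssd <- spec$genes$tss[spec$genes$chrom == me2$chrom[i]]
    min(pmin(abs(me2$start[i] - tssd), abs(tssd - (me2$end[i] - 1L))))
  }, numeric(1))
  expect_true(all(d >= 2000))
  # promoter-class regions overlap a TSS
  prom <- reg[reg$class_true %in% c("active-promoter", "weak-promoter"), ]
  inside <- vapply(seq_len(nrow(prom)), function(i) {
    any(spec$genes$chrom == prom$chrom[i] & spec$genes$tss >= prom$start[i] &
          spec$genes$tss < prom$end[i])
  }, logical(1))
  expect_true(all(inside))
  expect_true(all(grepl("^atac_[LP][0-9]{5}$", reg$region_id)))
  expect_setequal(unique(reg$source), c("L", "P"))
  expect_identical(reg, generate_regions(spec, cfg))
})

test_that("region placement fails loudly on a too-short chromosome", {
  spec <- tiny_spec(tss = seq(5000L, by = 3000L, length.out = 30L),
                    tags = rep(50L, 30), chrom_len = 120000L)
  cfg <- sim_config(regions_per_class = 3, seed = 1)
  expect_error(generate_regions(spec, cfg), "chr1")
})

test_that("coverage simulation errors on a class without a profile", {
  sim <- small_sim(regions_per_class = 5, depth = 1e4)
  reg <- sim$regions
  reg$class_true[1] <- "mystery-class"
  expect_error(
    simulate_coverage(reg, sim$profiles, sim$config, sim$chrom_lengths),
    "mystery-class")
})

test_that("spike-in counts are emitted exactly as configured", {
  sim <- small_sim(regions_per_class = 5, depth = 1e4)
  expect_true(all(sim$coverage$manifest$spike_pairs == sim$config$spike_pairs))
})

test_that("an all-unity profile yields enrichment ratios centered on 1", {
  sim <- small_sim(regions_per_class = 20, depth = 2e5)
  prof <- sim$profiles
  prof$fold[] <- 1
  cov <- simulate_coverage(sim$regions, prof, sim$config, sim$chrom_lengths)
  filt <- filter_fragments(cov$fragments)
  reg <- flanked_regions(sim$regions$chrom, sim$regions$start,
                         sim$regions$end, sim$regions$region_id)
  reg$down_is_right <- TRUE
  cm <- count_coverage(filt, reg, cov$manifest)
  cm <- apply_orientation(cm, reg)
  enr <- enrichment_over_control(pool_replicates(cm), stage = "dome")
  med <- apply(enr$fold, 2, median)
  expect_true(all(abs(med - 1) < 0.15))
})

test_that("the generator recovers a planted 4-fold enrichment", {
  # per-replicate depth kept low so duplicate removal stays far from
  # saturating the 73-bp position space; replicates supply the counts
  sim <- small_sim(regions_per_class = 50, depth = 2.5e5, replicates = 8)
  prof <- sim$profiles
  prof$fold[] <- 1
  prof$fold["H3K4me2-enhancer", "H3K4me2"] <- 4
  prof$fold_sdlog <- 0.05
  cfg <- sim$config
  cfg$dispersion <- 0.002
  cov <- simulate_coverage(sim$regions, prof, cfg, sim$chrom_lengths)
  filt <- filter_fragments(cov$fragments)
  reg <- flanked_regions(sim$regions$chrom, sim$regions$start,
                         sim$regions$end, sim$regions$region_id)
  reg$down_is_right <- TRUE
  cm <- count_coverage(filt, reg, cov$manifest)
  cm <- apply_orientation(cm, reg)
  # the planted fold is a property of the open interval; flanks carry an
  # attenuated version, so self-consistency is read off the center window
  enr <- enrichment_over_control(pool_replicates(cm), stage = "dome",
                                 interval = "center")
  f <- enr$fold[sim$regions$class_true == "H3K4me2-enhancer", "H3K4me2"]
  expect_gte(mean(f >= 3 & f <= 5), 0.9)
})

test_that("fixed seed gives bit-identical fragments", {
  cfg <- sim_config(regions_per_class = 5, depth = 2e4, seed = 99)
  spec <- default_genome_spec(n_genes = 60, seed = 99)
  r1 <- generate_regions(spec, cfg)
  lens <- stats::setNames(spec$chromosomes$length, spec$chromosomes$chrom)
  c1 <- simulate_coverage(r1, class_profiles(), cfg, lens)
  c2 <- simulate_coverage(r1, class_profiles(), cfg, lens)
  expect_identical(c1$fragments, c2$fragments)
})

test_that("methylation honors zero-noise profile means and clipping", {
  sim <- small_sim(regions_per_class = 10, depth = 1e4)
  prof <- sim$profiles
  prof$methylation$embryo[] <- 0
  prof$methylation$egg[] <- 0
  prof$methylation$sperm[] <- 0
  prof$shared_gamete_fraction <- 1
  m0 <- simulate_methylation(sim$regions, prof, sim$config, noise_sd = 0)
  expect_true(all(m0$embryo == 0 & m0$egg == 0 & m0$sperm == 0))
  m <- simulate_methylation(sim$regions, sim$profiles, sim$config)
  expect_true(all(m$embryo >= 0 & m$embryo <= 1))
  expect_true(all(m$egg >= 0 & m$egg <= 1 & m$sperm >= 0 & m$sperm <= 1))
})

test_that("planted gamete-sharing fraction is recovered", {
  spec <- default_genome_spec(seed = 7)
  cfg <- sim_config(regions_per_class = 150, seed = 7)
  sim <- list(regions = generate_regions(spec, cfg),
              profiles = class_profiles(), config = cfg)
  m <- simulate_methylation(sim$regions, sim$profiles, sim$config)
  sh <- shared_hypomethylation(m)
  expect_gt(sh$n_hypo, 200)
  expect_lt(abs(sh$fraction - 0.69), 0.08)
})

test_that("ct table simulation plants the requested fold", {
  cfg <- sim_config(seed = 21)
  expect_error(simulate_ct_table(cfg, planted_fold = 0), "positive")
  # zero noise: exact recovery
  ct0 <- simulate_ct_table(cfg, planted_fold = 2, noise = 0)
  expect_equal(analyze_ct_table(ct0)$test$fold, 2, tolerance = 1e-12)
  # null fold: groups equal within noise
  ct1 <- simulate_ct_table(cfg, planted_fold = 1)
  expect_lt(abs(log2(analyze_ct_table(ct1)$test$fold)), 0.5)
  # moderate fold, low noise: recovery within the expected band
  ct <- simulate_ct_table(cfg, planted_fold = 1.7, noise = 0.5)
  expect_gt(analyze_ct_table(ct)$test$fold, 1.4)
  expect_lt(analyze_ct_table(ct)$test$fold, 2.0)
})

test_that("emitted files round-trip through the module readers", {
  sim <- small_sim(regions_per_class = 5, depth = 1e4)
  d <- withr::local_tempdir()
  p <- write_regions_bed(sim$regions, file.path(d, "regions.bed"))
  rt <- read_regions_bed(p)
  expect_equal(rt$region_id, sim$regions$region_id)
  expect_equal(rt$start, sim$regions$start)
  fr <- as.data.frame(sim$coverage$fragments[1:100, ])
  p <- write_fragments_bed(fr, file.path(d, "frags.bed"))
  expect_equal(read_fragments_bed(p), fr[, c("chrom", "start", "end")],
               ignore_attr = TRUE)
  m <- simulate_methylation(sim$regions, sim$profiles, sim$config)
  p <- write_methylation_table(m, file.path(d, "meth.tsv"))
  expect_equal(read_methylation_table(p), m, tolerance = 1e-12,
               ignore_attr = TRUE)
  ct <- simulate_ct_table(sim$config, 1.5)
  p <- write_ct_table(ct, file.path(d, "ct.csv"))
  expect_equal(read_ct_table(p), ct, tolerance = 1e-12, ignore_attr = TRUE)
})
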