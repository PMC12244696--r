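#' Generate TSS, exon and expression tables from a genome specification
#'
#' Produces the annotation inputs the pipeline consumes: a TSS table with
#' CAGE-like tag support, the exon interval set, and a per-gene, per-stage
#' expression table in which genes whose activation does not depend on the
#' NPS pioneer factors switch on earlier but are later overtaken in
#' magnitude by the NPS-dependent group.
#'
#' @param spec A [synthetic_genome_spec()].
#' @param seed Integer seed.
#' @return List with `tss`, `exons`, and `expression` (long data.frame:
#'   `gene_id`, `stage`, `value` in RPKM-like units, plus group columns).
#' @export
generate_annotation <- function(spec, seed = 20250710) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(seed %% .Machine$integer.max)
  g <- spec$genes
  tss <- data.frame(gene_id = g$gene_id, chrom = g$chrom, pos = g$tss,
                    strand = g$strand, tag_count = g$cage_tags,
                    source = ifelse(g$annotation == "primary",
                                    "primary-annotation", "secondary-annotation"))
  stages <- c("2cell", "1K-cell", "dome", "shield")
  # baseline maternal contribution, then stage-wise zygotic increments:
  # the NPS-independent ("unaffected") group activates one stage earlier,
  # the NPS-dependent ("NPS-down") group rises later but higher
  base <- ifelse(g$contribution == "maternal-zygotic",
                 2 * exp(rnorm(nrow(g), 0, 0.3)), 0.02)
  inc_unaff <- c(0, 1.5, 3, 4.5)
  inc_down  <- c(0, 0, 2.5, 12)
  expr <- do.call(rbind, lapply(seq_along(stages), function(si) {
    inc <- ifelse(g$expr_group == "unaffected", inc_unaff[si], inc_down[si])
    data.frame(gene_id = g$gene_id, stage = stages[si],
               value = base + inc * exp(rnorm(nrow(g), 0, 0.2)),
               expr_group = g$expr_group, contribution = g$contribution)
  }))
  list(tss = tss, exons = spec$exons, expression = expr)
}

#' Plant labeled regions on the synthetic genome
#'
#' Places `regions_per_class` open-chromatin regions per chromatin class:
#' promoter classes centered on gene TSSs, all other classes in intergenic
#' slots at least 2 kb from every TSS. A further `cryptic_fraction` (of the
#' H3K4me2-enhancer count) of distal regions is planted as cryptic gene TSSs
#' (class `"cryptic-tss"`). Regions are split across two sources and merged
#' with [merge_region_sources()], so each record carries an `atac_L#####` or
#' `atac_P#####` identifier, its source tag and its true class label.
#'
#' @param spec A [synthetic_genome_spec()].
#' @param config A [sim_config()].
#' @return data.frame with columns `region_id`, `chrom`, `start`, `end`,
#'   `source`, `class_true`.
#' @export
generate_regions <- function(spec, config) {
  stopifnot(inherits(spec, "genome_spec"), inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$regions_per_class
  n_cryptic <- round(config$cryptic_fraction * n)
  g <- spec$genes
  eligible <- which(g$cage_tags > 20)
  n_prom <- 2L * n
  if (length(eligible) < n_prom)
    stop(sprintf("not enough promoter-eligible genes (%d) for %d promoter regions",
                 length(eligible), n_prom), call. = FALSE)
  wr <- config$region_width_range

  # distal slots: three per inter-gene gap, each >= 2 kb from both TSSs
  slots <- do.call(rbind, lapply(split(g, g$chrom), function(gc) {
    p <- sort(gc$tss)
    if (length(p) < 2) return(NULL)
    left <- p[-length(p)]
    gap <- diff(p)
    ok <- gap >= 9000
    if (!any(ok)) return(NULL)
    mids <- c(left[ok] + 2600, left[ok] + gap[ok] / 2, left[ok] + gap[ok] - 2600)
    data.frame(chrom = gc$chrom[1], center = as.integer(round(mids)))
  }))
  n_distal <- 4L * n + n_cryptic
  if (is.null(slots) || nrow(slots) < n_distal) {
    short <- spec$chromosomes$chrom[which.min(spec$chromosomes$length)]
    stop(sprintf("chromosome %s is too short to place %d distal regions",
                 short, n_distal), call. = FALSE)
  }
  prom_genes <- sample(eligible, n_prom)
  slot_pick <- sample(nrow(slots), n_distal)
  widths_p <- sample(wr[1]:wr[2], n_prom, replace = TRUE)
  widths_d <- sample(wr[1]:wr[2], n_distal, replace = TRUE)
  prom <- data.frame(
    chrom = g$chrom[prom_genes],
    start = as.integer(g$tss[prom_genes] - widths_p %/% 2),
    end = as.integer(g$tss[prom_genes] - widths_p %/% 2 + widths_p),
    class_true = rep(c("active-promoter", "weak-promoter"), each = n))
  dist <- data.frame(
    chrom = slots$chrom[slot_pick],
    start = as.integer(slots$center[slot_pick] - widths_d %/% 2),
    end = as.integer(slots$center[slot_pick] - widths_d %/% 2 + widths_d),
    class_true = c(rep(c("H3K4me1-enhancer", "H3K4me2-enhancer",
                         "poised-enhancer", "unmarked"), each = n),
                   rep("cryptic-tss", n_cryptic)))
  all <- rbind(prom, dist)
  src <- ifelse(runif(nrow(all)) < 0.85, "L", "P")
  merged <- merge_region_sources(all[src == "L", c("chrom", "start", "end")],
                                 all[src == "P", c("chrom", "start", "end")])
  key <- function(d) paste(d$chrom, d$start, d$end)
  merged$class_true <- all$class_true[match(key(merged), key(all))]
  merged
}

# per-(region, mark) natural-log fold latents including the accessibility
# latent shared with IgG; used by simulate_coverage
.region_fold_latents <- function(regions, profiles, stage) {
  cls <- regions$class_true
  cls_prof <- ifelse(cls == "cryptic-tss", "H3K4me2-enhancer", cls)
  nr <- nrow(regions)
  acc <- profiles$access
  access <- numeric(nr)
  for (k in seq_len(nrow(acc))) {
    i <- which(cls_prof == acc$class[k])
    if (length(i) == 0) next
    if (acc$class[k] == "H3K4me2-enhancer") {
      # same two-component activity mixture as the promoter continuum
      comp <- sample(c(acc$mean[acc$class == "active-promoter"],
                       acc$mean[acc$class == "weak-promoter"]),
                     length(i), replace = TRUE)
      access[i] <- rnorm(length(i), comp, acc$sd[k])
    } else {
      access[i] <- rnorm(length(i), acc$mean[k], acc$sd[k])
    }
  }
  marks <- colnames(profiles$fold)
  sm <- profiles$stage_mult[, stage]
  lf <- matrix(0, nr, length(marks), dimnames = list(NULL, marks))
  for (j in seq_along(marks)) {
    base_fold <- profiles$fold[cls_prof, marks[j]]
    fold <- 1 + (base_fold - 1) * sm[cls_prof]
    sdl <- ifelse(base_fold > 1.3,
                  ifelse(marks[j] == "H3K56ac", profiles$k56_sdlog,
                         profiles$fold_sdlog),
                  profiles$flat_sdlog)
    lf[, j] <- rnorm(nr, log(fold), sdl)
  }
  list(access = access, logfold = lf)
}

#' Simulate multi-mark fragment coverage with an IgG baseline
#'
#' Emits paired-end-like fragments (chrom, start, end spans of 100-400 bp)
#' for every histone mark in the profiles plus an IgG control, per replicate
#' and stage. Per-region counts on the open interval and its two 500-bp
#' flanks are negative-binomially distributed with mean = baseline x class
#' fold-enrichment; a per-region accessibility latent multiplies every
#' track including IgG, and a `background_fraction` of each library is
#' scattered uniformly across the genome. The configured spike-in pair
#' count is recorded per sample.
#'
#' @param regions Regions from [generate_regions()].
#' @param profiles A [class_profiles()].
#' @param config A [sim_config()].
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return List with `fragments` (data.table: `sample_id`, `chrom`, `start`,
#'   `end`) and `manifest` (data.frame: `sample_id`, `mark`, `replicate`,
#'   `stage`, `is_control`, `spike_pairs`).
#' @export
simulate_coverage <- function(regions, profiles, config, chrom_lengths) {
  stopifnot(inherits(profiles, "class_profiles"), inherits(config, "sim_config"))
  missing_cls <- setdiff(setdiff(unique(regions$class_true), "cryptic-tss"),
                         rownames(profiles$fold))
  if (length(missing_cls) > 0)
    stop(sprintf("no class profile for: %s", paste(missing_cls, collapse = ", ")),
         call. = FALSE)
  set.seed(config$seed + 1L)
  marks <- colnames(profiles$fold)
  nr <- nrow(regions)
  # subinterval windows: upstream flank, center, downstream flank
  win <- data.frame(
    chrom = rep(regions$chrom, 3),
    start = c(regions$start - 500L, regions$start, regions$end),
    end = c(regions$start, regions$end, regions$end + 500L),
    sub = rep(c("upstream", "center", "downstream"), each = nr))
  wlen <- win$end - win$start
  size <- 1 / config$dispersion
  glen <- sum(chrom_lengths)
  cum <- cumsum(c(0, as.numeric(chrom_lengths)))
  frag_list <- list()
  manifest <- list()
  for (stage in config$stages) {
    lat <- .region_fold_latents(regions, profiles, stage)
    relmu <- matrix(0, nr * 3L, length(marks) + 1L,
                    dimnames = list(NULL, c(marks, "IgG")))
    for (j in seq_along(marks)) {
      fold <- exp(lat$logfold[, j])
      # flanks carry a slightly attenuated version of the center enrichment
      f3 <- c(1 + 0.8 * (fold - 1), fold, 1 + 0.8 * (fold - 1))
      relmu[, j] <- f3 * exp(lat$access) * (wlen / 500)
    }
    relmu[, "IgG"] <- rep(exp(lat$access), 3) * (wlen / 500)
    # a common genomic-background mass competes with the in-region signal:
    # for the IgG control, background_fraction of the library lies outside
    # the regions; enriched antibodies allocate proportionally more of
    # their fixed depth in-region
    bg_mass <- sum(relmu[, "IgG"]) * config$background_fraction /
      (1 - config$background_fraction)
    for (smp in colnames(relmu)) {
      total_mass <- bg_mass + sum(relmu[, smp])
      mu <- relmu[, smp] * config$depth / total_mass
      n_bg <- as.integer(round(config$depth * bg_mass / total_mass))
      for (r in seq_len(config$replicates)) {
        sid <- sprintf("%s.%s.rep%d", smp, stage, r)
        cnt <- rnbinom(length(mu), mu = mu, size = size)
        tot <- sum(cnt)
        wi <- rep.int(seq_along(cnt), cnt)
        span <- sample(100:400, tot + n_bg, replace = TRUE)
        mid_in <- win$start[wi] +
          floor(runif(tot) * (win$end[wi] - win$start[wi]))
        # genomic background falls outside the region windows (the
        # region-local background is already carried by the IgG-shared
        # accessibility mass); overlapping draws are rejected
        gpos <- floor(runif(n_bg) * glen)
        bg_chr <- findInterval(gpos, cum, rightmost.closed = TRUE)
        bg <- data.frame(chrom = names(chrom_lengths)[bg_chr],
                         start = as.integer(gpos - cum[bg_chr]))
        bg_keep <- count_interval_overlaps(
          data.frame(chrom = bg$chrom, start = pmax(0L, bg$start - 200L),
                     end = bg$start + 200L),
          data.frame(chrom = regions$chrom,
                     start = regions$start - 500L,
                     end = regions$end + 500L)) == 0L
        bg <- bg[bg_keep, , drop = FALSE]
        frag <- data.table::data.table(
          sample_id = sid,
          chrom = c(win$chrom[wi], bg$chrom),
          start = as.integer(c(mid_in, bg$start) -
                               span[seq_len(tot + nrow(bg))] %/% 2L))
        span <- span[seq_len(tot + nrow(bg))]
        frag[, end := start + span]
        frag[start < 0L, `:=`(end = end - start, start = 0L)]
        frag_list[[sid]] <- frag
        manifest[[sid]] <- data.frame(
          sample_id = sid, mark = smp, replicate = r, stage = stage,
          is_control = smp == "IgG", spike_pairs = config$spike_pairs)
      }
    }
  }
  list(fragments = data.table::rbindlist(frag_list),
       manifest = do.call(rbind, c(manifest, make.row.names = FALSE)))
}

#' Simulate embryo and gamete DNA-methylation proportions
#'
#' Embryo methylation follows each class's profile mean. For regions whose
#' class is embryo-hypomethylated, a `shared_gamete_fraction` of regions is
#' hypomethylated in both gametes; the remainder is methylated in the egg
#' and hypomethylated in sperm (embryonic methylation is reprogrammed
#' towards the paternal pattern). Proportions are clipped to [0, 1].
#'
#' @param regions Regions with `class_true`.
#' @param profiles A [class_profiles()].
#' @param config A [sim_config()].
#' @param noise_sd Gaussian noise added to each proportion before clipping.
#' @return data.frame: `region_id`, `embryo`, `egg`, `sperm`.
#' @export
simulate_methylation <- function(regions, profiles, config, noise_sd = 0.04) {
  set.seed(config$seed + 2L)
  cls <- ifelse(regions$class_true == "cryptic-tss",
                "H3K4me2-enhancer", regions$class_true)
  m <- profiles$methylation
  rowi <- match(cls, m$class)
  embryo <- m$embryo[rowi]
  sperm <- m$sperm[rowi]
  egg <- m$egg[rowi]
  hypo <- embryo < 0.2
  shared <- runif(nrow(regions)) < profiles$shared_gamete_fraction
  # shared regions keep the profile's (hypomethylated) gamete means; the
  # rest were methylated in the egg and reprogrammed towards the sperm
  egg[hypo] <- ifelse(shared[hypo], egg[hypo], 0.70)
  clip <- function(x) pmin(1, pmax(0, x + rnorm(length(x), 0, noise_sd)))
  data.frame(region_id = regions$region_id, embryo = clip(embryo),
             egg = clip(egg), sperm = clip(sperm))
}

#' Simulate per-region NPS motif hit counts
#'
#' Emits the motif-density table directly (Poisson counts per factor), with
#' H3K4me2-enhancer regions depleted for all three NPS motifs relative to
#' H3K4me1 enhancers.
#'
#' @inheritParams simulate_methylation
#' @return data.frame: `region_id`, `nanog`, `pou5f3`, `sox19b`.
#' @export
simulate_motif_table <- function(regions, profiles, config) {
  set.seed(config$seed + 3L)
  cls <- ifelse(regions$class_true == "cryptic-tss",
                "H3K4me2-enhancer", regions$class_true)
  mm <- profiles$motif
  rowi <- match(cls, mm$class)
  data.frame(region_id = regions$region_id,
             nanog = rpois(nrow(regions), mm$nanog[rowi]),
             pou5f3 = rpois(nrow(regions), mm$pou5f3[rowi]),
             sox19b = rpois(nrow(regions), mm$sox19b[rowi]))
}

#' Simulate stranded RNA-seq reads around regions
#'
#' Cryptic-TSS regions produce directional stable transcripts: reads on one
#' strand concentrated in the TSS-downstream 100-bp flank across several
#' stages. All other coverage is sparse uniform background.
#'
#' @param regions Regions with `class_true`.
#' @param config A [sim_config()].
#' @param chrom_lengths Named chromosome lengths.
#' @param stages RNA-seq stages.
#' @param lib_size Nominal library size (reads) per stage.
#' @param signal_reads Reads planted per cryptic flank window per stage.
#' @param background_per_strand Background reads per strand per stage.
#' @return List with `reads` (data.frame: `stage`, `strand`, `chrom`,
#'   `start`, `end`) and `lib_sizes` (named by stage).
#' @export
simulate_rna_reads <- function(regions, config, chrom_lengths,
                               stages = c("dome", "epi50", "shield", "epi75"),
                               lib_size = 1e6, signal_reads = 12,
                               background_per_strand = 1000) {
  set.seed(config$seed + 4L)
  glen <- sum(chrom_lengths)
  cum <- cumsum(c(0, as.numeric(chrom_lengths)))
  cry <- regions[regions$class_true == "cryptic-tss", , drop = FALSE]
  cry_strand <- sample(c("+", "-"), nrow(cry), replace = TRUE)
  out <- list()
  for (st in stages) {
    for (sd_ in c("+", "-")) {
      gpos <- floor(runif(background_per_strand) * glen)
      ci <- findInterval(gpos, cum, rightmost.closed = TRUE)
      out[[paste(st, sd_)]] <- data.frame(
        stage = st, strand = sd_,
        chrom = names(chrom_lengths)[ci],
        start = as.integer(gpos - cum[ci]),
        end = as.integer(gpos - cum[ci]) + 50L)
    }
  }
  # plant directional signal at cryptic TSSs in every stage after the first
  for (st in stages[-1]) {
    if (nrow(cry) == 0) break
    for (i in seq_len(nrow(cry))) {
      wstart <- if (cry_strand[i] == "+") cry$end[i] else cry$start[i] - 100L
      pos <- wstart + sample(0:50, signal_reads, replace = TRUE)
      out[[paste(st, cry$region_id[i])]] <- data.frame(
        stage = st, strand = cry_strand[i], chrom = cry$chrom[i],
        start = as.integer(pos), end = as.integer(pos) + 50L)
    }
  }
  list(reads = do.call(rbind, c(out, make.row.names = FALSE)),
       lib_sizes = stats::setNames(rep(lib_size, length(stages)), stages))
}

#' Simulate a crispant qRT-PCR Ct table
#'
#' Three technical replicates per embryo per primer pair. Crispant embryos'
#' target delta-Ct is shifted by `log2(planted_fold)` on average, with
#' per-embryo heterogeneity modeled as a Beta-distributed edited fraction
#' (CRISPR mosaicism) scaling the shift.
#'
#' @param config A [sim_config()] (its seed is used).
#' @param planted_fold True fold-decrease in crispants (> 0).
#' @param embryos_per_group Embryos per group.
#' @param noise Noise multiplier; 0 gives a deterministic table from which
#'   the planted fold is recovered exactly.
#' @param mosaic_mean Mean edited fraction across crispant embryos.
#' @return data.frame: `embryo_id`, `group`, `primer`, `rep`, `ct`.
#' @export
simulate_ct_table <- function(config, planted_fold, embryos_per_group = 10,
                              noise = 1, mosaic_mean = 0.8) {
  if (planted_fold <= 0) stop("planted_fold must be positive", call. = FALSE)
  set.seed(config$seed + 5L)
  groups <- rep(c("control", "crispant"), each = embryos_per_group)
  ne <- length(groups)
  eid <- sprintf("emb%02d", seq_len(ne))
  ct_ref <- 18 + rnorm(ne, 0, 0.3 * noise)
  dct <- 2 + rnorm(ne, 0, 0.25 * noise)
  edited <- if (noise == 0) rep(mosaic_mean, ne) else
    stats::rbeta(ne, mosaic_mean * 25, (1 - mosaic_mean) * 25)
  shift <- ifelse(groups == "crispant",
                  log2(planted_fold) * edited / mosaic_mean, 0)
  reps <- 3L
  long <- expand.grid(i = seq_len(ne), primer = c("target", "reference"),
                      rep = seq_len(reps), stringsAsFactors = FALSE)
  mu <- ifelse(long$primer == "reference", ct_ref[long$i],
               ct_ref[long$i] + dct[long$i] + shift[long$i])
  data.frame(embryo_id = eid[long$i], group = groups[long$i],
             primer = long$primer, rep = long$rep,
             ct = mu + rnorm(nrow(long), 0, 0.15 * noise))
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper producing every input the pipeline consumes.
#'
#' @param spec A [synthetic_genome_spec()]; default [default_genome_spec()].
#' @param profiles A [class_profiles()].
#' @param config A [sim_config()].
#' @return List with `spec`, `profiles`, `config`, `chrom_lengths`,
#'   `annotation`, `regions`, `coverage`, `methylation`, `motif_counts`,
#'   `rna`.
#' @export
simulate_study <- function(spec = default_genome_spec(),
                           profiles = class_profiles(),
                           config = sim_config()) {
  chrom_lengths <- stats::setNames(spec$chromosomes$length,
                                   spec$chromosomes$chrom)
  annotation <- generate_annotation(spec, seed = config$seed)
  regions <- generate_regions(spec, config)
  coverage <- simulate_coverage(regions, profiles, config, chrom_lengths)
  list(spec = spec, profiles = profiles, config = config,
       chrom_lengths = chrom_lengths,
       annotation = annotation, regions = regions, coverage = coverage,
       methylation = simulate_methylation(regions, profiles, config),
       motif_counts = simulate_motif_table(regions, profiles, config),
       rna = simulate_rna_reads(regions, config, chrom_lengths))
}
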