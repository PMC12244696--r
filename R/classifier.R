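#' Principal component analysis of normalized coverage features
#'
#' Runs PCA (centered, not variance-scaled) on the normalized coverage
#' features, excluding control (IgG) samples. The sign of each loading
#' vector is fixed so that its largest-magnitude entry is positive, making
#' scores deterministic across linear-algebra backends.
#'
#' @param cov A normalized, oriented `cov_matrix` (per-replicate columns
#'   for the replicate-feature PCA, or pooled columns for the pooled PCA).
#' @param stage Restrict features to one stage (default: all stages).
#' @return A `pca_model`: list with `center`, `rotation`, `scores`, `sdev`,
#'   `var_explained`, `features`, `region_id`.
#' @export
fit_pca <- function(cov, stage = NULL) {
  stopifnot(inherits(cov, "cov_matrix"), cov$normalized)
  keep <- !cov$cols$is_control
  if (!is.null(stage)) keep <- keep & cov$cols$stage == stage
  x <- cov$counts[, keep, drop = FALSE]
  if (anyNA(x)) stop("missing values in coverage features", call. = FALSE)
  if (nrow(x) < ncol(x))
    stop("fewer regions than features", call. = FALSE)
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  structure(list(center = p$center, rotation = p$rotation, scores = p$x,
                 sdev = p$sdev,
                 var_explained = p$sdev^2 / sum(p$sdev^2),
                 features = colnames(x), region_id = cov$region_id),
            class = "pca_model")
}

#' Fit the SVM reference classifier on PCA scores
#'
#' Trains a radial-basis SVM (gamma = 1, cost = 1, features standardized)
#' on the scores of the first `n_pc` principal components. Training uses
#' only promoter-taxonomy regions (label `"promoter"`) and distal-taxonomy
#' regions (label `"enhancer"`); proximal regions are excluded.
#'
#' @param pca A `pca_model`.
#' @param taxonomy Taxonomy label per region (aligned with the PCA rows).
#' @param n_pc Number of leading PCs used as features.
#' @param gamma,cost RBF kernel width and soft-margin cost.
#' @return A `reference_classifier`: list with the fitted `model`, `n_pc`,
#'   `gamma`, `cost`, `training_accuracy`.
#' @export
fit_reference_classifier <- function(pca, taxonomy, n_pc = 3,
                                     gamma = 1, cost = 1) {
  stopifnot(inherits(pca, "pca_model"), length(taxonomy) == nrow(pca$scores))
  train <- taxonomy %in% c("promoter", "distal")
  y <- factor(ifelse(taxonomy[train] == "promoter", "promoter", "enhancer"),
              levels = c("enhancer", "promoter"))
  if (length(unique(y)) < 2)
    stop("training set contains a single class", call. = FALSE)
  if (min(table(y)) < 2)
    stop("need at least 2 training examples per class", call. = FALSE)
  x <- pca$scores[train, seq_len(n_pc), drop = FALSE]
  model <- e1071::svm(x = x, y = y, kernel = "radial", gamma = gamma,
                      cost = cost, scale = TRUE)
  acc <- mean(predict(model, x) == y)
  if (acc <= 0.5)
    stop("reference classifier failed the >50% training-accuracy sanity bound",
         call. = FALSE)
  structure(list(model = model, n_pc = n_pc, gamma = gamma, cost = cost,
                 training_accuracy = acc),
            class = "reference_classifier")
}

#' Predict the SVM label for every region
#'
#' Applies the reference classifier to all regions (promoter, proximal and
#' distal alike); discordant calls, e.g. a distal region with promoter-like
#' marks labeled `"promoter"`, drive the downstream element definitions.
#'
#' @param classifier A `reference_classifier`.
#' @param pca The `pca_model` the classifier was trained on.
#' @return Character vector of `"promoter"`/`"enhancer"` labels named by
#'   region id.
#' @export
predict_all <- function(classifier, pca) {
  x <- pca$scores[, seq_len(classifier$n_pc), drop = FALSE]
  stats::setNames(as.character(predict(classifier$model, x)), pca$region_id)
}

#' Element-call thresholds
#'
#' @param ac_active H3K27ac fold for active elements (poised at or below).
#' @param me2_hi,me2_lo H3K4me2 fold thresholds (marked vs unmarked).
#' @param me1_hi H3K4me1 fold threshold.
#' @param me3_lo H3K4me3 fold threshold for proximal potential enhancers.
#' @param rescue_quantile Coverage quantile among first-pass H3K4me2
#'   enhancer calls gating the rescue rule; `NA` disables the rescue step.
#' @return Named list of thresholds.
#' @export
element_thresholds <- function(ac_active = 1.5, me2_hi = 2, me2_lo = 1.25,
                               me1_hi = 2, me3_lo = 1.25,
                               rescue_quantile = 0.75) {
  list(ac_active = ac_active, me2_hi = me2_hi, me2_lo = me2_lo,
       me1_hi = me1_hi, me3_lo = me3_lo, rescue_quantile = rescue_quantile)
}

#' Final element calls from SVM labels and enrichment thresholds
#'
#' Distal regions are called in order: (a) H3K4me2-enhancer when the SVM
#' label is "promoter" with H3K27ac >= 1.5-fold and H3K4me2 >= 2-fold; (b)
#' rescue of SVM-"enhancer" regions meeting the same enrichment thresholds
#' whose H3K4me2 coverage reaches the top quartile of the first-pass calls;
#' (c) H3K4me1-enhancer when SVM-"enhancer" with H3K4me1 >= 2-fold,
#' H3K4me2 < 1.25-fold and H3K27ac >= 1.5-fold; (d) poised-enhancer for
#' remaining mark-bearing regions with H3K27ac <= 1.5-fold (at exactly
#' 1.5-fold the active calls take precedence); (e) unclassified. Proximal
#' regions with < 1.25-fold H3K4me3 are annotated as potential enhancers of
#' either flavour. Promoter-taxonomy regions are split by SVM concordance
#' into high- and low-H3K4me2/3 promoters.
#'
#' @param svm_labels Labels from [predict_all()].
#' @param enrichment Result of [enrichment_over_control()].
#' @param taxonomy Taxonomy per region.
#' @param thresholds An [element_thresholds()] list.
#' @return data.frame: `region_id`, `taxonomy`, `svm_label`, the four mark
#'   folds, `call`, `rescued`.
#' @export
call_elements <- function(svm_labels, enrichment, taxonomy,
                          thresholds = element_thresholds()) {
  need <- c("H3K4me1", "H3K4me2", "H3K4me3", "H3K27ac")
  miss <- setdiff(need, colnames(enrichment$fold))
  if (length(miss) > 0)
    stop(sprintf("enrichment is missing required mark(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  th <- thresholds
  fold <- enrichment$fold
  me1 <- fold[, "H3K4me1"]; me2 <- fold[, "H3K4me2"]
  me3 <- fold[, "H3K4me3"]; ac <- fold[, "H3K27ac"]
  me2_cov <- enrichment$rpk500[, "H3K4me2"]
  n <- length(me1)
  stopifnot(length(svm_labels) == n, length(taxonomy) == n)
  call <- rep("unclassified", n)
  rescued <- rep(FALSE, n)
  distal <- taxonomy == "distal"

  a <- distal & svm_labels == "promoter" & ac >= th$ac_active & me2 >= th$me2_hi
  call[a] <- "H3K4me2-enhancer"
  if (any(a) && !is.na(th$rescue_quantile)) {
    gate <- stats::quantile(me2_cov[a], th$rescue_quantile, names = FALSE)
    b <- distal & !a & svm_labels == "enhancer" & ac >= th$ac_active &
      me2 >= th$me2_hi & me2_cov >= gate
    call[b] <- "H3K4me2-enhancer"
    rescued[b] <- TRUE
  }
  open <- distal & call == "unclassified"
  cc <- open & svm_labels == "enhancer" & me1 >= th$me1_hi &
    me2 < th$me2_lo & ac >= th$ac_active
  call[cc] <- "H3K4me1-enhancer"
  open <- distal & call == "unclassified"
  dd <- open & (me1 >= th$me1_hi | me2 >= th$me2_hi) & ac <= th$ac_active
  call[dd] <- "poised-enhancer"

  prox <- taxonomy == "proximal"
  p2 <- prox & me3 < th$me3_lo & me2 >= th$me2_hi
  call[p2] <- "proximal-potential-H3K4me2"
  p1 <- prox & me3 < th$me3_lo & me1 >= th$me1_hi & me2 < th$me2_lo
  call[p1] <- "proximal-potential-H3K4me1"

  prom <- taxonomy == "promoter"
  call[prom & svm_labels == "promoter"] <- "high-K4me23-promoter"
  call[prom & svm_labels == "enhancer"] <- "low-K4me23-promoter"

  # the two enhancer classes are disjoint by construction
  stopifnot(sum(call == "H3K4me2-enhancer" & me2 < th$me2_lo) == 0 ||
              is.na(th$rescue_quantile))
  data.frame(region_id = rownames(fold), taxonomy = taxonomy,
             svm_label = unname(svm_labels),
             H3K4me1 = unname(me1), H3K4me2 = unname(me2),
             H3K4me3 = unname(me3), H3K27ac = unname(ac),
             call = call, rescued = rescued, row.names = NULL)
}

#' Four region groups for the first-pass heatmap view
#'
#' Regions with >= 2-fold H3K4me1 enrichment and >= 10 RPKM H3K4me1
#' coverage (center + downstream) are grouped by taxonomy x SVM label:
#' typical enhancers (distal, SVM "enhancer"), H3K4me2 enhancers (distal,
#' SVM "promoter"), high-H3K4me2/3 promoters (promoter, SVM "promoter"),
#' and low-H3K4me2/3 promoters (promoter, SVM "enhancer").
#'
#' @inheritParams call_elements
#' @return List of four region-id vectors.
#' @export
initial_heatmap_groups <- function(svm_labels, enrichment, taxonomy) {
  gate <- enrichment$fold[, "H3K4me1"] >= 2 &
    enrichment$rpkm[, "H3K4me1"] >= 10
  id <- rownames(enrichment$fold)
  list(
    typical_enhancers =
      id[gate & taxonomy == "distal" & svm_labels == "enhancer"],
    H3K4me2_enhancers =
      id[gate & taxonomy == "distal" & svm_labels == "promoter"],
    high_K4me23_promoters =
      id[gate & taxonomy == "promoter" & svm_labels == "promoter"],
    low_K4me23_promoters =
      id[gate & taxonomy == "promoter" & svm_labels == "enhancer"])
}

#' Run the full classification pipeline on a synthetic study
#'
#' Region taxonomy and flanks, fragment filtering, coverage counting,
#' flank orientation, replicate pooling, PCA, SVM reference classification,
#' threshold-based element calls, and the directional-transcription filter.
#'
#' @param sim Output of [simulate_study()].
#' @param stage Stage used for classification (default `"dome"`).
#' @param thresholds An [element_thresholds()] list.
#' @return List with the per-step results; `final_calls` holds the element
#'   calls after cryptic-TSS removal.
#' @export
classify_study <- function(sim, stage = "dome",
                           thresholds = element_thresholds()) {
  tss_sel <- select_promoter_tss(sim$annotation$tss)
  all_tss <- data.frame(chrom = sim$annotation$tss$chrom,
                        pos = sim$annotation$tss$pos)
  gene_counts <- table(factor(sim$annotation$tss$chrom,
                              levels = names(sim$chrom_lengths)))
  regions <- classify_taxonomy(sim$regions, tss_sel, all_tss,
                               stats::setNames(as.integer(gene_counts),
                                               names(gene_counts)))
  regions <- build_flanks(regions, sim$chrom_lengths)
  regions <- regions[regions$taxonomy %in%
                       c("promoter", "proximal", "distal"), ]
  filt <- filter_fragments(sim$coverage$fragments)
  cov <- count_coverage(filt, regions, sim$coverage$manifest)
  regions <- orient_flanks(regions, cov)
  cov <- apply_orientation(cov, regions)
  pooled <- pool_replicates(cov)
  pooled_norm <- normalize_log2_rpk500(pooled)
  pca <- fit_pca(pooled_norm, stage = stage)
  classifier <- fit_reference_classifier(pca, regions$taxonomy)
  svm_labels <- predict_all(classifier, pca)
  enrichment <- enrichment_over_control(pooled, stage = stage)
  calls <- call_elements(svm_labels, enrichment, regions$taxonomy,
                         thresholds)
  fc <- compute_flank_coverage(sim$rna$reads, regions,
                               lib_sizes = sim$rna$lib_sizes)
  flagged <- detect_directional_tss(fc)
  exempt <- exonic_flank_mask(regions, sim$annotation$exons)
  txf <- apply_filter(calls, flagged, exempt)
  list(regions = regions, pca = pca, classifier = classifier,
       svm_labels = svm_labels, enrichment = enrichment, calls = calls,
       flank_coverage = fc, flagged = flagged, exempt = exempt,
       txfilter = txf, final_calls = txf$calls)
}
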