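#' Stage-stacked H3K4 methylation PCA
#'
#' Represents each region by one row per stage, with 9 features: H3K4me1,
#' H3K4me2 and H3K4me3 normalized coverage on the upstream, center and
#' downstream subintervals (replicates pooled). Regions missing any stage
#' are excluded with a warning. The returned scores carry region and stage,
#' so per-group mean trajectories through PC space can be drawn.
#'
#' @param cov A normalized, oriented, pooled `cov_matrix` covering the
#'   three H3K4 methylation marks at every requested stage.
#' @param stages Ordered stages to stack.
#' @return List with `pca` (a `pca_model` fit on the stacked matrix) and
#'   `scores` (data.frame: `region_id`, `stage`, PC columns).
#' @export
timecourse_pca <- function(cov, stages) {
  stopifnot(inherits(cov, "cov_matrix"), cov$normalized)
  marks <- c("H3K4me1", "H3K4me2", "H3K4me3")
  subints <- c("upstream", "center", "downstream")
  nr <- length(cov$region_id)
  blocks <- list()
  for (st in stages) {
    sel <- cov$cols$stage == st & cov$cols$mark %in% marks
    block <- cov$counts[, sel, drop = FALSE]
    ord <- order(match(cov$cols$mark[sel], marks),
                 match(cov$cols$subinterval[sel], subints))
    block <- block[, ord, drop = FALSE]
    if (ncol(block) != 9L)
      stop(sprintf("stage %s does not provide 9 H3K4 features", st),
           call. = FALSE)
    colnames(block) <- paste(rep(marks, each = 3), subints, sep = ".")
    blocks[[st]] <- block
  }
  x <- do.call(rbind, blocks)
  fake <- structure(list(
    counts = x, region_id = rep(cov$region_id, length(stages)),
    cols = data.frame(sample_id = colnames(x), mark = NA, replicate = NA,
                      stage = NA, is_control = FALSE,
                      subinterval = NA),
    lib_sizes = NULL, center_len = NULL, normalized = TRUE,
    oriented = TRUE), class = "cov_matrix")
  pca <- fit_pca(fake)
  scores <- data.frame(region_id = rep(cov$region_id, length(stages)),
                       stage = rep(stages, each = nr))
  scores <- cbind(scores, as.data.frame(pca$scores))
  list(pca = pca, scores = scores)
}

#' RNA activation trajectories with confidence bounds
#'
#' Per gene and stage, computes log2(x_t + 0.1) - log2(x_0 + 0.1) relative
#' to the `t0` stage, then per group and stage the mean, sample standard
#' deviation, and a 95% confidence half-width qt(0.975, n - 1) * sd /
#' sqrt(n). Groups with n < 2 report the mean with undefined bounds. Genes
#' missing any stage are dropped listwise.
#'
#' @param expression Long data.frame: `gene_id`, `stage`, `value` (>= 0).
#' @param groups data.frame: `gene_id`, `group`.
#' @param t0 Reference stage.
#' @param stages Ordered stages (default: unique stages of `expression`).
#' @return data.frame: `group`, `stage`, `mean`, `lower`, `upper`, `n`.
#' @export
rna_activation_trajectory <- function(expression, groups, t0,
                                      stages = unique(expression$stage)) {
  check_columns(expression, c("gene_id", "stage", "value"), "expression")
  check_columns(groups, c("gene_id", "group"), "groups")
  stopifnot(t0 %in% stages, all(expression$value >= 0))
  wide <- stats::reshape(
    expression[expression$stage %in% stages,
               c("gene_id", "stage", "value")],
    idvar = "gene_id", timevar = "stage", direction = "wide")
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  lfi <- log2(as.matrix(wide[, paste0("value.", stages), drop = FALSE]) + 0.1) -
    log2(wide[[paste0("value.", t0)]] + 0.1)
  grp <- groups$group[match(wide$gene_id, groups$gene_id)]
  out <- list()
  for (g in unique(grp[!is.na(grp)])) for (si in seq_along(stages)) {
    v <- lfi[which(grp == g), si]
    n <- length(v)
    m <- mean(v)
    if (n >= 2) {
      half <- stats::qt(0.975, n - 1) * stats::sd(v) / sqrt(n)
      lo <- m - half; hi <- m + half
    } else lo <- hi <- NA_real_
    out[[paste(g, stages[si])]] <-
      data.frame(group = g, stage = stages[si], mean = m,
                 lower = lo, upper = hi, n = n)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Stratify genes as maternal-zygotic versus strictly zygotic
#'
#' Genes with pooled 2-cell expression above 0.5 RPKM (strictly greater)
#' carry a maternal contribution; the rest are strictly zygotic.
#'
#' @param expression Long data.frame: `gene_id`, `stage`, `value`.
#' @param two_cell_stage Name of the 2-cell stage in `expression`.
#' @return data.frame: `gene_id`, `contribution`.
#' @export
stratify_maternal_zygotic <- function(expression, two_cell_stage = "2cell") {
  e <- expression[expression$stage == two_cell_stage, , drop = FALSE]
  data.frame(gene_id = e$gene_id,
             contribution = ifelse(e$value > 0.5, "maternal-zygotic",
                                   "strictly-zygotic"))
}
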