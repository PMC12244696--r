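#' Average technical replicates of a Ct table
#'
#' @param ct_table data.frame: `embryo_id`, `group`, `primer`, `rep`, `ct`.
#' @return data.frame: `embryo_id`, `group`, `primer`, `ct` (mean of the
#'   technical replicates). Errors if any embryo lacks a primer.
#' @export
collapse_technical <- function(ct_table) {
  check_columns(ct_table, c("embryo_id", "group", "primer", "ct"), "ct_table")
  agg <- stats::aggregate(ct ~ embryo_id + group + primer, data = ct_table,
                          FUN = mean)
  per_embryo <- table(agg$embryo_id)
  n_primers <- length(unique(ct_table$primer))
  bad <- names(per_embryo)[per_embryo < n_primers]
  if (length(bad) > 0)
    stop(sprintf("embryo(s) missing a primer: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  agg[order(agg$embryo_id, agg$primer), ]
}

#' Per-embryo relative expression (2^-dCt, control-normalized)
#'
#' delta-Ct is the target Ct minus the reference Ct per embryo; values are
#' converted to 2^-dCt and divided by the control-group mean, so the
#' control average is exactly 1.
#'
#' @param collapsed Output of [collapse_technical()].
#' @param target,reference Primer names.
#' @param control_group Name of the control group.
#' @return data.frame: `embryo_id`, `group`, `dct`, `rel`, `norm`.
#' @export
relative_expression <- function(collapsed, target = "target",
                                reference = "reference",
                                control_group = "control") {
  t_ct <- collapsed[collapsed$primer == target, ]
  r_ct <- collapsed[collapsed$primer == reference, ]
  stopifnot(nrow(t_ct) == nrow(r_ct))
  r_ct <- r_ct[match(t_ct$embryo_id, r_ct$embryo_id), ]
  dct <- t_ct$ct - r_ct$ct
  rel <- 2^(-dct)
  ctrl <- t_ct$group == control_group
  if (!any(ctrl)) stop("empty control group", call. = FALSE)
  data.frame(embryo_id = t_ct$embryo_id, group = t_ct$group,
             dct = dct, rel = rel, norm = rel / mean(rel[ctrl]))
}

#' Knockdown fold-decrease and rank-sum test
#'
#' Fold decrease is the control-group mean divided by the crispant-group
#' mean of the normalized values (since the control mean is 1, this is the
#' reciprocal of the crispant mean). The alternative per-embryo estimator
#' (mean of reciprocals) is reported alongside. The p-value is a two-sided
#' Wilcoxon rank-sum test, exact for combined sample sizes up to 20.
#'
#' @param normalized Output of [relative_expression()].
#' @param control_group,crispant_group Group names.
#' @return List with `fold` (ratio of group means), `fold_mean_reciprocal`,
#'   `p.value`, `n_control`, `n_crispant`.
#' @export
knockdown_test <- function(normalized, control_group = "control",
                           crispant_group = "crispant") {
  ctrl <- normalized$norm[normalized$group == control_group]
  cri <- normalized$norm[normalized$group == crispant_group]
  stopifnot(length(ctrl) >= 2, length(cri) >= 2)
  if (mean(cri) == 0) {
    warning("crispant mean is 0; fold reported as Inf", call. = FALSE)
    fold <- Inf
  } else fold <- mean(ctrl) / mean(cri)
  ht <- rank_sum_test(ctrl, cri)
  list(fold = fold, fold_mean_reciprocal = mean(1 / cri) * mean(ctrl),
       p.value = ht$p.value,
       n_control = length(ctrl), n_crispant = length(cri))
}

#' Full crispant qRT-PCR analysis of a Ct table
#'
#' @param ct_table data.frame of technical-replicate Ct values.
#' @return List with `per_embryo` (normalized values) and `test`
#'   (fold decrease and p-value).
#' @export
analyze_ct_table <- function(ct_table) {
  norm <- relative_expression(collapse_technical(ct_table))
  list(per_embryo = norm, test = knockdown_test(norm))
}
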