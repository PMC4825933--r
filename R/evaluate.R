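#' Observable class label of every gene under the classification pipeline
#'
#' Maps each gene of a classified dataset to the label the pipeline can
#' identify: `low_expression` (failed the expression floor),
#' `contaminant_gfp` / `contaminant_dsred` (failed the 36 hpf enrichment
#' ratio, attributed to the single-positive fraction with the smaller
#' double-positive ratio), a regulated label from the list-membership
#' pattern (same-direction dual membership gives `co_regulated_positive` /
#' `co_regulated_negative`; antagonistic dual membership gives explicit
#' cross-pair labels), or `unregulated`.
#'
#' @param result output of [classify_genes()].
#' @param matrix expression matrix the result was computed from.
#' @param design sample-design data.frame.
#' @return data.frame with columns `gene_id`, `predicted`.
#' @export
predict_classes <- function(result, matrix, design) {
  genes <- rownames(matrix)
  predicted <- rep("unregulated", length(genes))
  names(predicted) <- genes

  low <- setdiff(genes, result$arch$min_expressed)
  predicted[low] <- "low_expression"
  excluded <- setdiff(result$arch$min_expressed, result$universe)
  if (length(excluded) > 0L) {
    dp <- stage_sample(design, 36L, "double_positive", "wt")
    gfp <- stage_sample(design, 36L, "gfp_only", "wt")
    dsred <- stage_sample(design, 36L, "dsred_only", "wt")
    zr <- 0.01
    r_gfp <- matrix[excluded, dp] / .replace_zero(matrix[excluded, gfp], zr)
    r_dsr <- matrix[excluded, dp] / .replace_zero(matrix[excluded, dsred], zr)
    predicted[excluded] <- ifelse(r_gfp <= r_dsr, "contaminant_gfp",
                                  "contaminant_dsred")
  }
  # exclusive label from the full membership pattern: within a pathway the
  # activated and inhibited lists are disjoint, so the pattern is a pair
  # (notch status, edn1 status)
  notch_st <- ifelse(genes %in% result$notch$activated, "act",
                     ifelse(genes %in% result$notch$inhibited, "inh", "none"))
  edn1_st <- ifelse(genes %in% result$edn1$activated, "act",
                    ifelse(genes %in% result$edn1$inhibited, "inh", "none"))
  in_universe <- genes %in% result$universe
  pattern <- paste(notch_st, edn1_st, sep = "/")
  pattern_label <- c(
    "act/none" = "notch_activated", "inh/none" = "notch_inhibited",
    "none/act" = "edn1_activated", "none/inh" = "edn1_inhibited",
    "act/act" = "co_regulated_positive",
    "inh/inh" = "co_regulated_negative",
    "inh/act" = "notch_inhibited_and_edn1_activated",
    "act/inh" = "notch_activated_and_edn1_inhibited",
    "none/none" = "unregulated")
  predicted[in_universe] <- pattern_label[pattern[in_universe]]
  data.frame(gene_id = genes, predicted = unname(predicted),
             stringsAsFactors = FALSE)
}

# Planted truth label -> label the pipeline can observe. Erythroid and
# macrophage contaminants share the GFP-only FACS signature and the explicit
# arch background class behaves like the unregulated remainder, so each maps
# onto its observable label for scoring.
.truth_to_observable <- c(
  arch_enriched = "unregulated",
  unregulated = "unregulated",
  contaminant_erythroid = "contaminant_gfp",
  contaminant_macrophage = "contaminant_gfp",
  contaminant_ear = "contaminant_dsred",
  notch_inhibited = "notch_inhibited",
  notch_activated = "notch_activated",
  edn1_inhibited = "edn1_inhibited",
  edn1_activated = "edn1_activated",
  co_regulated_positive = "co_regulated_positive",
  co_regulated_negative = "co_regulated_negative")

#' Precision / recall / F1 of planted-class recovery
#'
#' Scores predicted labels against the planted truth per planted class,
#' after mapping each truth class to its observable label (see
#' [predict_classes()]). Precision of a class is the precision of its
#' observable label; classes sharing an observable label (the two GFP-sourced
#' contaminant classes; the arch background and unregulated remainder) share
#' that precision.
#'
#' @param truth truth data.frame from [generate_dataset()].
#' @param predicted data.frame from [predict_classes()].
#' @return data.frame with columns `class`, `observable`, `n_true`,
#'   `n_predicted`, `tp`, `precision`, `recall`, `f1`.
#' @export
evaluate_recovery <- function(truth, predicted) {
  stopifnot(identical(sort(truth$gene_id), sort(predicted$gene_id)))
  pred <- predicted$predicted[match(truth$gene_id, predicted$gene_id)]
  expected <- .truth_to_observable[truth$class]
  classes <- intersect(names(.truth_to_observable), unique(truth$class))
  rows <- lapply(classes, function(cl) {
    obs <- .truth_to_observable[[cl]]
    in_class <- truth$class == cl
    in_obs_truth <- expected == obs
    pred_obs <- pred == obs
    tp_class <- sum(in_class & pred_obs)
    precision <- if (sum(pred_obs) == 0L) NA_real_ else
      sum(in_obs_truth & pred_obs) / sum(pred_obs)
    recall <- tp_class / sum(in_class)
    f1 <- if (is.na(precision) || precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    data.frame(class = cl, observable = obs, n_true = sum(in_class),
               n_predicted = sum(pred_obs), tp = tp_class,
               precision = precision, recall = recall, f1 = f1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
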