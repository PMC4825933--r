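#' Thresholds for the fold-change-ratio classifier
#'
#' All comparisons are inclusive, matching the printed >= / <= rules: a gene
#' is pathway-activated when its OE-fold-change / mut-fold-change ratio is
#' >= `activation_ratio` with an OE-RPKM/control-RPKM ratio >=
#' `oe_over_control_min`, pathway-inhibited when the ratio is <=
#' `inhibition_ratio` with a mut-RPKM/control-RPKM ratio >=
#' `mut_over_control_min`. The Notch lists are further refined against the
#' DBZ contrast at `dbz_up_min` / `dbz_down_max`.
#'
#' @param activation_ratio minimum OE-fc/mut-fc ratio for "activated"
#'   (default 1.5, inclusive).
#' @param inhibition_ratio maximum OE-fc/mut-fc ratio for "inhibited"
#'   (default 0.667, inclusive).
#' @param oe_over_control_min minimum OE/control RPKM ratio guard (default 1).
#' @param mut_over_control_min minimum mutant/control RPKM ratio guard
#'   (default 1).
#' @param dbz_up_min minimum NICD-fc/DBZ-fc ratio to stay on the activated
#'   list (default 1.25, inclusive).
#' @param dbz_down_max maximum NICD-fc/DBZ-fc ratio to stay on the inhibited
#'   list (default 0.8, inclusive).
#' @param zero_replacement value substituted for zero numerators and
#'   denominators before ratios are formed (default 0.01).
#' @return list of class `classifier_thresholds`.
#' @export
classifier_thresholds <- function(activation_ratio = 1.5,
                                  inhibition_ratio = 0.667,
                                  oe_over_control_min = 1,
                                  mut_over_control_min = 1,
                                  dbz_up_min = 1.25,
                                  dbz_down_max = 0.8,
                                  zero_replacement = 0.01) {
  if (!(activation_ratio > 1 && 1 > inhibition_ratio &&
          inhibition_ratio > 0)) {
    stop("need activation_ratio > 1 > inhibition_ratio > 0", call. = FALSE)
  }
  if (!(dbz_up_min > 1 && 1 > dbz_down_max && dbz_down_max > 0)) {
    stop("need dbz_up_min > 1 > dbz_down_max > 0", call. = FALSE)
  }
  if (zero_replacement <= 0) {
    stop("zero_replacement must be > 0", call. = FALSE)
  }
  structure(list(activation_ratio = activation_ratio,
                 inhibition_ratio = inhibition_ratio,
                 oe_over_control_min = oe_over_control_min,
                 mut_over_control_min = mut_over_control_min,
                 dbz_up_min = dbz_up_min,
                 dbz_down_max = dbz_down_max,
                 zero_replacement = zero_replacement),
            class = "classifier_thresholds")
}

#' Per-gene fold-changes for a set of contrasts
#'
#' fc(g, c) = RPKM(g, perturbed) / RPKM(g, control), with any zero numerator
#' or denominator replaced by `zero_replacement` before division, so every
#' fold-change is finite and positive.
#'
#' @param matrix expression matrix.
#' @param contrasts data.frame from [resolve_contrasts()].
#' @param zero_replacement replacement for zero cells (default 0.01).
#' @return numeric matrix (genes x contrasts) with contrast names as columns.
#' @export
compute_fold_changes <- function(matrix, contrasts, zero_replacement = 0.01) {
  absent <- setdiff(c(contrasts$perturbed_sample, contrasts$control_sample),
                    colnames(matrix))
  if (length(absent) > 0L) {
    stop("contrast sample(s) absent from matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  fc <- vapply(seq_len(nrow(contrasts)), function(i) {
    num <- .replace_zero(matrix[, contrasts$perturbed_sample[i]],
                         zero_replacement)
    den <- .replace_zero(matrix[, contrasts$control_sample[i]],
                         zero_replacement)
    num / den
  }, numeric(nrow(matrix)))
  fc <- matrix(fc, nrow = nrow(matrix),
               dimnames = list(rownames(matrix), contrasts$name))
  fc
}

.pathway_contrasts <- list(
  notch = c(oe = "nicd_oe", mut = "jag1b_mut"),
  edn1  = c(oe = "edn1_oe", mut = "edn1_mut")
)

#' Classify genes as pathway-activated or pathway-inhibited
#'
#' For each gene the ratio of the overexpression fold-change to the mutant
#' fold-change is compared against the activation / inhibition thresholds;
#' the RPKM-ratio guards (OE vs its control for activation, mutant vs its
#' control for inhibition) equal the per-contrast fold-changes already in the
#' table, so only the fold-change table is needed. For Notch, OE = nicd_oe
#' and mut = jag1b_mut; for Edn1, OE = edn1_oe and mut = edn1_mut.
#'
#' @param fc fold-change matrix from [compute_fold_changes()].
#' @param pathway "notch" or "edn1".
#' @param thresholds a [classifier_thresholds()] object.
#' @param universe gene ids to classify (the arch-enriched 36 hpf set in the
#'   standard pipeline); default all genes in `fc`.
#' @return list with `activated` and `inhibited` gene id vectors (disjoint,
#'   in matrix row order) and `ratio`, the named OE-fc/mut-fc vector over the
#'   universe.
#' @export
classify_pathway <- function(fc, pathway = c("notch", "edn1"),
                             thresholds = classifier_thresholds(),
                             universe = rownames(fc)) {
  pathway <- match.arg(pathway)
  cn <- .pathway_contrasts[[pathway]]
  miss <- setdiff(cn, colnames(fc))
  if (length(miss) > 0L) {
    stop(sprintf("fold-change table lacks contrast(s) for pathway '%s': %s",
                 pathway, paste(miss, collapse = ", ")), call. = FALSE)
  }
  genes <- rownames(fc)[rownames(fc) %in% universe]
  fc_oe <- fc[genes, cn[["oe"]]]
  fc_mut <- fc[genes, cn[["mut"]]]
  ratio <- fc_oe / fc_mut
  activated <- genes[ratio >= thresholds$activation_ratio &
                       fc_oe >= thresholds$oe_over_control_min]
  inhibited <- genes[ratio <= thresholds$inhibition_ratio &
                       fc_mut >= thresholds$mut_over_control_min]
  list(activated = activated, inhibited = inhibited,
       ratio = stats::setNames(ratio, genes))
}

#' Ratio of NICD to DBZ fold-changes (or samples)
#'
#' Default mode forms the ratio of the two control-normalised fold-changes,
#' fc(nicd_oe)/fc(dbz), since the NICD and DBZ arms have different controls.
#' `mode = "sample_ratio"` instead compares the raw NICD and DBZ sample RPKM
#' directly; it requires `matrix` and `contrasts`.
#'
#' @param fc fold-change matrix containing `nicd_oe` and `dbz` columns.
#' @param mode "fc_ratio" (default) or "sample_ratio".
#' @param matrix,contrasts required for `mode = "sample_ratio"`.
#' @param zero_replacement replacement for zero cells in sample-ratio mode.
#' @return named numeric vector over the genes of `fc`.
#' @export
nicd_dbz_ratio <- function(fc, mode = c("fc_ratio", "sample_ratio"),
                           matrix = NULL, contrasts = NULL,
                           zero_replacement = 0.01) {
  mode <- match.arg(mode)
  if (mode == "fc_ratio") {
    miss <- setdiff(c("nicd_oe", "dbz"), colnames(fc))
    if (length(miss) > 0L) {
      stop("fold-change table lacks contrast(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    return(stats::setNames(fc[, "nicd_oe"] / fc[, "dbz"], rownames(fc)))
  }
  if (is.null(matrix) || is.null(contrasts)) {
    stop("sample_ratio mode needs `matrix` and `contrasts`", call. = FALSE)
  }
  nicd <- contrasts$perturbed_sample[contrasts$name == "nicd_oe"]
  dbz <- contrasts$perturbed_sample[contrasts$name == "dbz"]
  if (length(nicd) != 1L || length(dbz) != 1L) {
    stop("contrasts must contain nicd_oe and dbz", call. = FALSE)
  }
  stats::setNames(
    .replace_zero(matrix[, nicd], zero_replacement) /
      .replace_zero(matrix[, dbz], zero_replacement),
    rownames(matrix))
}

#' Refine the Notch lists with the DBZ contrast
#'
#' Keeps on the activated list only genes also elevated in NICD versus DBZ
#' (ratio >= `dbz_up_min`) and on the inhibited list only genes also
#' decreased (ratio <= `dbz_down_max`); removed genes are returned for audit.
#' Refinement can only shrink the lists.
#'
#' @param activated,inhibited gene id vectors from [classify_pathway()].
#' @param fc fold-change matrix containing `nicd_oe` and `dbz`.
#' @param thresholds a [classifier_thresholds()] object.
#' @param ratio optional precomputed NICD/DBZ ratio (see [nicd_dbz_ratio()]);
#'   default is the fold-change-ratio mode.
#' @return list with `activated`, `inhibited`, `removed_activated`,
#'   `removed_inhibited`.
#' @export
refine_notch_with_dbz <- function(activated, inhibited, fc,
                                  thresholds = classifier_thresholds(),
                                  ratio = NULL) {
  if (is.null(ratio)) ratio <- nicd_dbz_ratio(fc)
  miss <- setdiff(c(activated, inhibited), names(ratio))
  if (length(miss) > 0L) {
    stop("NICD/DBZ ratio missing for gene(s): ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  keep_act <- activated[ratio[activated] >= thresholds$dbz_up_min]
  keep_inh <- inhibited[ratio[inhibited] <= thresholds$dbz_down_max]
  list(activated = keep_act,
       inhibited = keep_inh,
       removed_activated = setdiff(activated, keep_act),
       removed_inhibited = setdiff(inhibited, keep_inh))
}

#' Cross-pathway set intersections (Venn summary)
#'
#' Reports |A|, |B|, |A n B|, |A \ B| and |B \ A| for the four cross-pathway
#' pairings: the two antagonistic pairs (Notch-inhibited vs Edn1-activated,
#' Notch-activated vs Edn1-inhibited) and the two same-direction pairs.
#'
#' @param classification list with `notch` and `edn1` elements, each holding
#'   `activated` and `inhibited` gene id vectors (see [classify_genes()]).
#' @return data.frame with columns `pair`, `set_a`, `set_b`, `n_a`, `n_b`,
#'   `n_intersect`, `n_a_only`, `n_b_only`.
#' @export
intersect_lists <- function(classification) {
  pairs <- list(
    c("notch_inhibited", "edn1_activated"),
    c("notch_activated", "edn1_inhibited"),
    c("notch_activated", "edn1_activated"),
    c("notch_inhibited", "edn1_inhibited"))
  get_set <- function(nm) {
    parts <- strsplit(nm, "_", fixed = TRUE)[[1L]]
    classification[[parts[1L]]][[parts[2L]]]
  }
  rows <- lapply(pairs, function(p) {
    a <- get_set(p[1L]); b <- get_set(p[2L])
    data.frame(pair = paste(p, collapse = " vs "),
               set_a = p[1L], set_b = p[2L],
               n_a = length(a), n_b = length(b),
               n_intersect = length(intersect(a, b)),
               n_a_only = length(setdiff(a, b)),
               n_b_only = length(setdiff(b, a)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Top-k up- or down-regulated genes of a contrast
#'
#' Sorts by fold-change (descending for "up", ascending for "down"), breaking
#' ties by plain lexicographic gene id order, and returns the first
#' min(k, n) genes. Applied to the pre-enrichment gene universe in the
#' standard pipeline.
#'
#' @param fc fold-change matrix.
#' @param contrast contrast name (a column of `fc`).
#' @param k number of genes to return (> 0).
#' @param direction "up" or "down".
#' @return character vector of gene ids, ordered.
#' @export
top_k_regulated <- function(fc, contrast, k = 20L,
                            direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (!is.numeric(k) || length(k) != 1L || k <= 0) {
    stop("k must be a positive integer", call. = FALSE)
  }
  if (!contrast %in% colnames(fc)) {
    stop("unknown contrast: ", contrast, call. = FALSE)
  }
  v <- fc[, contrast]
  ids <- rownames(fc)
  ord <- order(if (direction == "up") -v else v, ids, method = "radix")
  ids[ord][seq_len(min(as.integer(k), length(ids)))]
}

#' Full classification of a dataset
#'
#' Convenience wrapper running the standard pipeline order: arch-enrichment
#' filtering, fold-change computation for the five contrasts, Edn1 and Notch
#' classification over the 36 hpf arch-enriched universe, DBZ refinement of
#' the Notch lists, and the cross-pathway Venn summary.
#'
#' @param matrix expression matrix.
#' @param design sample-design data.frame.
#' @param enrichment an [enrichment_thresholds()] object.
#' @param thresholds a [classifier_thresholds()] object.
#' @param dbz_mode mode passed to [nicd_dbz_ratio()].
#' @return list with `arch` (per-stage sets, see [arch_enriched_sets()]),
#'   `universe` (36 hpf arch set), `contrasts`, `fc`, `notch` (refined),
#'   `notch_prerefine`, `edn1`, `dbz_removed`, `venn`.
#' @export
classify_genes <- function(matrix, design,
                           enrichment = enrichment_thresholds(),
                           thresholds = classifier_thresholds(),
                           dbz_mode = c("fc_ratio", "sample_ratio")) {
  dbz_mode <- match.arg(dbz_mode)
  arch <- arch_enriched_sets(matrix, design, thresholds = enrichment)
  universe <- arch$sets[["36"]]
  contrasts <- resolve_contrasts(design, contrast_names())
  fc <- compute_fold_changes(matrix, contrasts, thresholds$zero_replacement)
  notch0 <- classify_pathway(fc, "notch", thresholds, universe)
  edn1 <- classify_pathway(fc, "edn1", thresholds, universe)
  ratio <- nicd_dbz_ratio(fc, dbz_mode, matrix = matrix,
                          contrasts = contrasts,
                          zero_replacement = thresholds$zero_replacement)
  refined <- refine_notch_with_dbz(notch0$activated, notch0$inhibited, fc,
                                   thresholds, ratio = ratio)
  classification <- list(
    notch = list(activated = refined$activated,
                 inhibited = refined$inhibited),
    edn1 = list(activated = edn1$activated, inhibited = edn1$inhibited))
  list(arch = arch,
       universe = universe,
       contrasts = contrasts,
       fc = fc,
       notch = classification$notch,
       notch_prerefine = list(activated = notch0$activated,
                              inhibited = notch0$inhibited),
       edn1 = classification$edn1,
       dbz_removed = list(activated = refined$removed_activated,
                          inhibited = refined$removed_inhibited),
       venn = intersect_lists(classification))
}
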