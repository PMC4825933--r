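#' Thresholds for the arch-enrichment filter
#'
#' @param min_rpkm expression floor; genes with RPKM <= `min_rpkm` in the
#'   reference sample are excluded (default 3).
#' @param enrichment_ratio minimum double-positive over single-positive
#'   expression ratio, inclusive (default 1.5).
#' @param zero_replacement value substituted for a zero denominator before a
#'   ratio is formed (default 0.01, the smallest positive RPKM scale of the
#'   assay).
#' @return list of class `enrichment_thresholds`.
#' @export
enrichment_thresholds <- function(min_rpkm = 3, enrichment_ratio = 1.5,
                                  zero_replacement = 0.01) {
  if (min_rpkm < 0) stop("min_rpkm must be >= 0", call. = FALSE)
  if (enrichment_ratio <= 0) {
    stop("enrichment_ratio must be > 0", call. = FALSE)
  }
  if (zero_replacement <= 0) {
    stop("zero_replacement must be > 0", call. = FALSE)
  }
  structure(list(min_rpkm = min_rpkm, enrichment_ratio = enrichment_ratio,
                 zero_replacement = zero_replacement),
            class = "enrichment_thresholds")
}

.replace_zero <- function(x, zero_replacement) {
  ifelse(x == 0, zero_replacement, x)
}

#' Minimum-expression filter
#'
#' Keeps exactly the genes whose RPKM in the reference sample is strictly
#' greater than the floor (genes at or below the floor are excluded).
#'
#' @param matrix expression matrix.
#' @param reference_sample sample id used as the expression reference
#'   (the wild-type 36 hpf double-positive sample in the standard pipeline).
#' @param thresholds an [enrichment_thresholds()] object.
#' @return character vector of retained gene ids, in matrix row order.
#' @export
filter_min_expression <- function(matrix, reference_sample,
                                  thresholds = enrichment_thresholds()) {
  if (!reference_sample %in% colnames(matrix)) {
    stop("unknown sample: ", reference_sample, call. = FALSE)
  }
  rownames(matrix)[matrix[, reference_sample] > thresholds$min_rpkm]
}

#' Double-positive enrichment filter for one stage
#'
#' Retains gene g iff DP(g)/GFPonly(g) >= enrichment_ratio AND
#' DP(g)/DsRedonly(g) >= enrichment_ratio (both inclusive), with zero
#' denominators replaced by `zero_replacement`. Intended to run on the gene
#' set that already passed [filter_min_expression()].
#'
#' @param matrix expression matrix.
#' @param design sample-design data.frame; must contain wild-type
#'   double-positive, GFP-only and DsRed-only samples for the stage.
#' @param stage stage in hpf.
#' @param thresholds an [enrichment_thresholds()] object.
#' @param genes candidate gene ids (default: all genes in the matrix).
#' @param condition condition of the reference samples (default "wt").
#' @return character vector of retained gene ids, in matrix row order.
#' @export
filter_arch_enriched <- function(matrix, design, stage,
                                 thresholds = enrichment_thresholds(),
                                 genes = rownames(matrix),
                                 condition = "wt") {
  dp <- stage_sample(design, stage, "double_positive", condition)
  gfp <- stage_sample(design, stage, "gfp_only", condition)
  dsred <- stage_sample(design, stage, "dsred_only", condition)
  genes <- rownames(matrix)[rownames(matrix) %in% genes]
  dp_v <- matrix[genes, dp]
  r_gfp <- dp_v / .replace_zero(matrix[genes, gfp], thresholds$zero_replacement)
  r_dsr <- dp_v / .replace_zero(matrix[genes, dsred],
                                thresholds$zero_replacement)
  genes[r_gfp >= thresholds$enrichment_ratio &
          r_dsr >= thresholds$enrichment_ratio]
}

#' Per-stage arch-enriched gene sets
#'
#' Runs the two-step filter of the standard pipeline: the minimum-expression
#' floor against the wild-type 36 hpf double-positive sample, then the
#' stage-matched double-positive enrichment ratio at each requested stage.
#' The 36 hpf set is the "total" arch gene universe used by all downstream
#' classification and temporal analyses.
#'
#' @param matrix expression matrix.
#' @param design sample-design data.frame.
#' @param stages stages (hpf) to filter; default all three.
#' @param thresholds an [enrichment_thresholds()] object.
#' @return list with `sets` (named list of per-stage gene id vectors, names
#'   "20"/"28"/"36"), `counts` (named integer vector) and `min_expressed`
#'   (the floor-passing gene set).
#' @export
arch_enriched_sets <- function(matrix, design, stages = c(20L, 28L, 36L),
                               thresholds = enrichment_thresholds()) {
  validate_sample_design(design, matrix)
  ref <- stage_sample(design, 36L, "double_positive", "wt")
  keep <- filter_min_expression(matrix, ref, thresholds)
  sets <- lapply(stages, function(st) {
    filter_arch_enriched(matrix, design, st, thresholds, genes = keep)
  })
  names(sets) <- as.character(as.integer(stages))
  list(sets = sets,
       counts = vapply(sets, length, integer(1)),
       min_expressed = keep)
}
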