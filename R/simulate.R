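#' Parameters for the synthetic arch-transcriptome generator
#'
#' Defines the planted gene classes and noise model used to emulate the full
#' FACS/RNA-seq experimental design: wild-type double-positive (arch NCC)
#' samples at 20/28/36 hpf, GFP-only and DsRed-only contaminant fractions at
#' each wild-type stage, and perturbed-plus-control double-positive samples at
#' 36 hpf for the five contrasts (edn1_mut, jag1b_mut, edn1_oe, nicd_oe, dbz).
#'
#' Class fractions that do not sum to 1 leave the remainder as unregulated
#' arch genes. `co_regulated_positive` genes are activated by both pathways
#' and `co_regulated_negative` genes inhibited by both (the same-direction
#' co-regulated groups); antagonistically regulated overlaps are not planted
#' classes and arise only through noise. The default fractions scale the
#' published within-universe list sizes (67 Notch-inhibited, 93
#' Notch-activated, 107 Edn1-activated, 137 Edn1-inhibited, same-direction
#' co-groups of 9 and 6, in a 741-gene arch universe) to the simulated gene
#' count, with the cross-pathway overlap genes left out since a planted class
#' carries exactly one label.
#'
#' @param n_genes number of genes to simulate.
#' @param class_fractions named non-negative fractions for the ten planted
#'   classes; must sum to <= 1.
#' @param baseline_log_mean,baseline_log_sd natural-log mean and sd of the
#'   log-normal baseline RPKM distribution.
#' @param baseline_min truncation floor (RPKM) applied to baselines so every
#'   planted gene is quantifiable above the default expression filter.
#' @param effect_multiplier multiplicative perturbation response (> 1);
#'   up-responses multiply by it, down-responses divide.
#' @param induction_multiplier_20_28,induction_multiplier_28_36 temporal
#'   induction multipliers (>= 1) planted in strongly induced genes.
#' @param induced_fraction_within_notch_inhibited fraction of the
#'   Notch-inhibited genes that carry the planted temporal induction.
#' @param arch_dp_ratio double-positive over single-positive expression ratio
#'   of arch genes.
#' @param contaminant_ratio source-fraction over double-positive ratio of
#'   contaminant genes.
#' @param noise_sd sd of the multiplicative log-normal noise (natural-log
#'   scale); 0 gives a deterministic expression surface.
#' @param seed integer seed owning all randomness of the generator.
#' @return a list of class `simulation_params`.
#' @export
simulation_params <- function(n_genes = 5000L,
                              class_fractions = c(
                                arch_enriched = 0.35,
                                contaminant_erythroid = 0.05,
                                contaminant_macrophage = 0.05,
                                contaminant_ear = 0.05,
                                notch_inhibited = 0.045,
                                notch_activated = 0.063,
                                edn1_inhibited = 0.117,
                                edn1_activated = 0.087,
                                co_regulated_positive = 0.010,
                                co_regulated_negative = 0.007),
                              baseline_log_mean = log(50),
                              baseline_log_sd = 1,
                              baseline_min = 10,
                              effect_multiplier = 4,
                              induction_multiplier_20_28 = 12,
                              induction_multiplier_28_36 = 1,
                              induced_fraction_within_notch_inhibited = 0.5,
                              arch_dp_ratio = 5,
                              contaminant_ratio = 10,
                              noise_sd = 0,
                              seed = 1L) {
  need <- c("arch_enriched", "contaminant_erythroid", "contaminant_macrophage",
            "contaminant_ear", "notch_inhibited", "notch_activated",
            "edn1_inhibited", "edn1_activated", "co_regulated_positive",
            "co_regulated_negative")
  miss <- setdiff(need, names(class_fractions))
  if (length(miss) > 0L) {
    stop("class_fractions lacks: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  class_fractions <- class_fractions[need]
  if (any(class_fractions < 0)) {
    stop("class fractions must be non-negative", call. = FALSE)
  }
  if (sum(class_fractions) > 1 + 1e-12) {
    stop("class fractions must sum to <= 1", call. = FALSE)
  }
  if (effect_multiplier <= 1) {
    stop("effect_multiplier must be > 1", call. = FALSE)
  }
  if (induction_multiplier_20_28 < 1 || induction_multiplier_28_36 < 1) {
    stop("induction multipliers must be >= 1", call. = FALSE)
  }
  if (induced_fraction_within_notch_inhibited < 0 ||
      induced_fraction_within_notch_inhibited > 1) {
    stop("induced_fraction_within_notch_inhibited must lie in [0, 1]",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  structure(list(
    n_genes = as.integer(n_genes),
    class_fractions = class_fractions,
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    baseline_min = baseline_min,
    effect_multiplier = effect_multiplier,
    induction_multiplier_20_28 = induction_multiplier_20_28,
    induction_multiplier_28_36 = induction_multiplier_28_36,
    induced_fraction_within_notch_inhibited =
      induced_fraction_within_notch_inhibited,
    arch_dp_ratio = arch_dp_ratio,
    contaminant_ratio = contaminant_ratio,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "simulation_params")
}

# Sample layout shared by the generator and the worked example.
.simulated_design <- function() {
  wt <- expand.grid(
    population = c("double_positive", "gfp_only", "dsred_only"),
    stage_hpf = c(20L, 28L, 36L),
    stringsAsFactors = FALSE)
  wt$condition <- "wt"
  pop_tag <- c(double_positive = "dp", gfp_only = "gfp", dsred_only = "dsred")
  wt$sample_id <- sprintf("wt_%s_%d", pop_tag[wt$population], wt$stage_hpf)
  pert <- data.frame(
    sample_id = c("edn1_mut_36", "edn1_ctrl_36", "jag1b_mut_36",
                  "jag1b_ctrl_36", "edn1_oe_36", "nicd_oe_36", "hs_ctrl_36",
                  "dbz_36", "vehicle_ctrl_36"),
    population = "double_positive",
    stage_hpf = 36L,
    condition = c("edn1_mut", "edn1_ctrl", "jag1b_mut", "jag1b_ctrl",
                  "edn1_oe", "nicd_oe", "hs_ctrl", "dbz", "vehicle_ctrl"),
    stringsAsFactors = FALSE)
  rbind(wt[, c("sample_id", "population", "stage_hpf", "condition")], pert)
}

# `contaminant` retained for clarity of the truth table; contamination is
# expressed through the single-positive population multipliers below.
# Multiplicative perturbation response of each class under each condition.
# m = effect multiplier; up-responses are m, down-responses 1/m.
.response_multiplier <- function(class, condition, m) {
  up <- switch(class,
    notch_inhibited = c("jag1b_mut", "dbz"),
    notch_activated = "nicd_oe",
    edn1_inhibited = "edn1_mut",
    edn1_activated = "edn1_oe",
    co_regulated_positive = c("nicd_oe", "edn1_oe"),
    co_regulated_negative = c("jag1b_mut", "dbz", "edn1_mut"),
    character())
  down <- switch(class,
    notch_inhibited = "nicd_oe",
    notch_activated = c("jag1b_mut", "dbz"),
    edn1_inhibited = "edn1_oe",
    edn1_activated = "edn1_mut",
    co_regulated_positive = c("jag1b_mut", "dbz", "edn1_mut"),
    co_regulated_negative = c("nicd_oe", "edn1_oe"),
    character())
  ifelse(condition %in% up, m, ifelse(condition %in% down, 1 / m, 1))
}

#' Generate a synthetic arch-transcriptome dataset with planted truth
#'
#' Expression is baseline x population multiplier x stage multiplier x
#' perturbation-response multiplier x exp(N(0, noise_sd)). Arch genes are
#' enriched in the double-positive fraction; contaminant genes are high in
#' exactly one single-positive fraction (erythroid and macrophage in the
#' GFP-only fraction, ear in the DsRed-only fraction) and low in the
#' double-positive fraction. Identical parameters and seed give byte-identical
#' output.
#'
#' @param params a [simulation_params()] object.
#' @return list with elements `matrix` (expression matrix), `design`
#'   (sample-design data.frame) and `truth` (data.frame: `gene_id`, `class`,
#'   `source` of contamination or "none", `induced`, and the planted temporal
#'   multipliers `induction_20_28`, `induction_28_36`).
#' @export
generate_dataset <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  old_seed <- if (exists(".Random.seed", envir = globalenv(),
                         inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(params$seed)

  n <- params$n_genes
  gene_ids <- sprintf("g%05d", seq_len(n))
  counts <- round(params$class_fractions * n)
  # planted labels, remainder unregulated, positions shuffled by the seeded RNG
  labels <- c(rep(names(counts), counts),
              rep("unregulated", max(0L, n - sum(counts))))[seq_len(n)]
  labels <- sample(labels)
  source <- ifelse(labels %in% c("contaminant_erythroid",
                                 "contaminant_macrophage"), "gfp",
                   ifelse(labels == "contaminant_ear", "dsred", "none"))

  baseline <- pmax(exp(stats::rnorm(n, params$baseline_log_mean,
                                    params$baseline_log_sd)),
                   params$baseline_min)

  induced <- labels == "notch_inhibited" &
    stats::runif(n) < params$induced_fraction_within_notch_inhibited
  ind_20_28 <- ifelse(induced, params$induction_multiplier_20_28, 1)
  ind_28_36 <- ifelse(induced, params$induction_multiplier_28_36, 1)

  design <- .simulated_design()
  contaminant <- source != "none"
  mat <- matrix(NA_real_, nrow = n, ncol = nrow(design),
                dimnames = list(gene_ids, design$sample_id))
  for (j in seq_len(nrow(design))) {
    pop <- design$population[j]
    stage <- design$stage_hpf[j]
    cond <- design$condition[j]
    pop_mult <- if (pop == "double_positive") {
      rep(1, n)
    } else if (pop == "gfp_only") {
      ifelse(source == "gfp", params$contaminant_ratio,
             1 / params$arch_dp_ratio)
    } else { # dsred_only
      ifelse(source == "dsred", params$contaminant_ratio,
             1 / params$arch_dp_ratio)
    }
    stage_mult <- if (stage == 20L) 1 else if (stage == 28L) ind_20_28 else
      ind_20_28 * ind_28_36
    resp_mult <- .response_multiplier_vec(labels, cond,
                                          params$effect_multiplier)
    noise <- if (params$noise_sd > 0)
      exp(stats::rnorm(n, 0, params$noise_sd)) else 1
    mat[, j] <- baseline * pop_mult * stage_mult * resp_mult * noise
  }
  validate_expression_matrix(mat)
  truth <- data.frame(gene_id = gene_ids, class = labels, source = source,
                      induced = induced, induction_20_28 = ind_20_28,
                      induction_28_36 = ind_28_36, stringsAsFactors = FALSE)
  list(matrix = mat, design = design, truth = truth)
}

.response_multiplier_vec <- function(labels, condition, m) {
  out <- rep(1, length(labels))
  for (cl in unique(labels)) {
    idx <- labels == cl
    out[idx] <- .response_multiplier(cl, condition, m)
  }
  out
}

#' Noise-free worked example sitting exactly on every threshold boundary
#'
#' A fixed 20-gene dataset over the full sample layout, with hand-chosen
#' values landing exactly on each decision boundary of the classification
#' procedure: the RPKM = 3 expression floor (excluded), the 1.5-fold
#' double-positive enrichment ratio (retained), the 1.5 / 0.667 fold-change
#' ratio thresholds (both retained) with their RPKM-ratio guards, and the DBZ
#' refinement ratios 1.25 / 0.8 (both retained). Boundary genes use control
#' values of 1 so that the computed ratios are exact in double precision.
#'
#' @return list with `matrix`, `design` and `truth` as in
#'   [generate_dataset()]; `truth$note` describes each planted behaviour.
#' @export
plant_worked_example <- function() {
  design <- .simulated_design()
  genes <- c("boundary_rpkm", "above_rpkm", "boundary_enrich",
             "below_enrich", "contam_gfp", "contam_dsred", "notch_inh_1",
             "notch_act_1", "boundary_act", "boundary_inh", "boundary_dbz_up",
             "boundary_dbz", "dbz_removed_act", "dbz_removed_inh",
             "edn1_inh_1", "edn1_act_1", "co_pos_1", "co_neg_1",
             "antag_induced", "zero_at_20")
  # default: arch-enriched, unregulated, constant across stages
  mat <- matrix(100, nrow = length(genes), ncol = nrow(design),
                dimnames = list(genes, design$sample_id))
  single <- design$sample_id[design$population %in% c("gfp_only",
                                                      "dsred_only")]
  mat[, single] <- 10
  set_cells <- function(gene, values) {
    mat[gene, names(values)] <<- values
  }
  # expression floor: RPKM exactly 3 at wild-type 36 hpf is excluded (<= 3),
  # 3.01 is retained (strict >)
  set_cells("boundary_rpkm", c(wt_dp_36 = 3, wt_gfp_36 = 0.5,
                               wt_dsred_36 = 0.5))
  set_cells("above_rpkm", c(wt_dp_36 = 3.01, wt_gfp_36 = 1, wt_dsred_36 = 1))
  # enrichment ratio exactly 1.5 vs GFP-only retained; 6/4.1 < 1.5 excluded
  set_cells("boundary_enrich", c(wt_dp_36 = 6, wt_gfp_36 = 4,
                                 wt_dsred_36 = 1))
  set_cells("below_enrich", c(wt_dp_36 = 6, wt_gfp_36 = 4.1, wt_dsred_36 = 1))
  # contaminants: high in exactly one single-positive fraction
  for (st in c(20, 28, 36)) {
    set_cells("contam_gfp", stats::setNames(
      c(50, 500, 5), sprintf(c("wt_dp_%d", "wt_gfp_%d", "wt_dsred_%d"), st)))
    set_cells("contam_dsred", stats::setNames(
      c(50, 5, 500), sprintf(c("wt_dp_%d", "wt_gfp_%d", "wt_dsred_%d"), st)))
  }
  # clear pathway responders (controls at 100)
  set_cells("notch_inh_1", c(jag1b_mut_36 = 400, nicd_oe_36 = 25,
                             dbz_36 = 400))
  set_cells("notch_act_1", c(jag1b_mut_36 = 25, nicd_oe_36 = 400,
                             dbz_36 = 25))
  set_cells("edn1_inh_1", c(edn1_mut_36 = 400, edn1_oe_36 = 25))
  set_cells("edn1_act_1", c(edn1_mut_36 = 25, edn1_oe_36 = 400))
  # boundary: OE-fc / mut-fc exactly 1.5 -> activated
  set_cells("boundary_act", c(nicd_oe_36 = 300, hs_ctrl_36 = 100,
                              jag1b_mut_36 = 200, jag1b_ctrl_36 = 100,
                              dbz_36 = 100, vehicle_ctrl_36 = 100))
  # boundary: ratio exactly 0.667 -> inhibited (controls of 1 keep it exact)
  set_cells("boundary_inh", c(nicd_oe_36 = 0.667, hs_ctrl_36 = 1,
                              edn1_oe_36 = 1,
                              jag1b_mut_36 = 1, jag1b_ctrl_36 = 1,
                              dbz_36 = 1, vehicle_ctrl_36 = 1))
  # DBZ refinement boundaries: NICD-fc / DBZ-fc exactly 1.25 and 0.8 retained
  set_cells("boundary_dbz_up", c(nicd_oe_36 = 2.5, hs_ctrl_36 = 1,
                              edn1_oe_36 = 1,
                                 jag1b_mut_36 = 1, jag1b_ctrl_36 = 1,
                                 dbz_36 = 2, vehicle_ctrl_36 = 1))
  set_cells("boundary_dbz", c(nicd_oe_36 = 0.5, hs_ctrl_36 = 1,
                              edn1_oe_36 = 1,
                              jag1b_mut_36 = 2, jag1b_ctrl_36 = 1,
                              dbz_36 = 0.625, vehicle_ctrl_36 = 1))
  # DBZ refinement removals: 4/3.4 < 1.25 and 0.5/0.6 > 0.8
  set_cells("dbz_removed_act", c(nicd_oe_36 = 4, hs_ctrl_36 = 1,
                              edn1_oe_36 = 1,
                                 jag1b_mut_36 = 1, jag1b_ctrl_36 = 1,
                                 dbz_36 = 3.4, vehicle_ctrl_36 = 1))
  set_cells("dbz_removed_inh", c(nicd_oe_36 = 0.5, hs_ctrl_36 = 1,
                              edn1_oe_36 = 1,
                                 jag1b_mut_36 = 2, jag1b_ctrl_36 = 1,
                                 dbz_36 = 0.6, vehicle_ctrl_36 = 1))
  # same-direction co-regulated genes: activated (or inhibited) by both
  # pathways
  set_cells("co_pos_1", c(nicd_oe_36 = 400, jag1b_mut_36 = 25, dbz_36 = 25,
                          edn1_oe_36 = 400, edn1_mut_36 = 25))
  set_cells("co_neg_1", c(nicd_oe_36 = 25, jag1b_mut_36 = 400, dbz_36 = 400,
                          edn1_oe_36 = 25, edn1_mut_36 = 400))
  # antagonistic dual responder (Notch-inhibited AND Edn1-activated),
  # strongly induced 20 -> 28 hpf like the published common genes
  set_cells("antag_induced", c(wt_dp_20 = 10, wt_dp_28 = 120, wt_dp_36 = 120,
                               wt_gfp_20 = 1, wt_gfp_28 = 1, wt_gfp_36 = 1,
                               wt_dsred_20 = 1, wt_dsred_28 = 1,
                               wt_dsred_36 = 1,
                               jag1b_mut_36 = 400, nicd_oe_36 = 25,
                               dbz_36 = 400, edn1_mut_36 = 25,
                               edn1_oe_36 = 400))
  # temporal zero-replacement case: RPKM 0 at 20 hpf
  set_cells("zero_at_20", c(wt_dp_20 = 0, wt_dp_28 = 50, wt_dp_36 = 60))

  truth <- data.frame(
    gene_id = genes,
    class = c("low_expression", "unregulated", "unregulated",
              "enrichment_excluded", "contaminant_gfp", "contaminant_dsred",
              "notch_inhibited", "notch_activated", "notch_activated",
              "notch_inhibited", "notch_activated", "notch_inhibited",
              "unregulated", "unregulated", "edn1_inhibited",
              "edn1_activated", "co_regulated_positive",
              "co_regulated_negative", "antagonistic_pair", "unregulated"),
    note = c(
      "RPKM exactly 3 at wt 36 hpf: excluded by the expression floor",
      "RPKM 3.01: retained (floor is a strict inequality)",
      "DP/GFP-only ratio exactly 1.5: retained (inclusive)",
      "DP/GFP-only ratio 6/4.1 < 1.5: excluded",
      "GFP-only contaminant, excluded by the enrichment ratio",
      "DsRed-only contaminant, excluded by the enrichment ratio",
      "strong Notch-inhibited responder",
      "strong Notch-activated responder",
      "OE-fc/mut-fc exactly 1.5: activated (inclusive)",
      "OE-fc/mut-fc exactly 0.667: inhibited (inclusive)",
      "NICD-fc/DBZ-fc exactly 1.25: survives refinement",
      "NICD-fc/DBZ-fc exactly 0.8: survives refinement",
      "activated pre-DBZ, NICD/DBZ 1.176 < 1.25: removed",
      "inhibited pre-DBZ, NICD/DBZ 0.833 > 0.8: removed",
      "strong Edn1-inhibited responder",
      "strong Edn1-activated responder",
      "activated by both pathways",
      "inhibited by both pathways",
      "Notch-inhibited + Edn1-activated, 12x induced 20->28 hpf",
      "zero RPKM at 20 hpf: temporal ratio uses the 0.01 replacement"),
    stringsAsFactors = FALSE)
  list(matrix = mat, design = design, truth = truth)
}
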