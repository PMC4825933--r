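test_that("expression floor excludes at the boundary and keeps strictly above", {
  mat <- tiny_matrix(c(3, 3.01, 0, 100), paste0("g", 1:4), "ref")
  keep <- filter_min_expression(mat, "ref")
  expect_setequal(keep, c("g2", "g4"))
  zero <- tiny_matrix(rep(0, 4), paste0("g", 1:4), "ref")
  expect_length(filter_min_expression(zero, "ref"), 0L)
  expect_error(filter_min_expression(mat, "nope"), "unknown sample")
})

test_that("enrichment ratio is inclusive and zero denominators are replaced", {
  design <- data.frame(
    sample_id = c("dp", "gfp", "dsr"),
    population = c("double_positive", "gfp_only", "dsred_only"),
    stage_hpf = 36L, condition = "wt", stringsAsFactors = FALSE)
  mat <- tiny_matrix(c(6, 4, 1,     # ratio vs GFP exactly 1.5 -> keep
                       6, 4.1, 1,   # 1.46 -> drop
                       1, 0, 0,     # zero denominators -> 1/0.01 = 100 -> keep
                       10, 10, 1),  # ratio 1 vs GFP -> drop
                     paste0("g", 1:4), c("dp", "gfp", "dsr"))
  keep <- filter_arch_enriched(mat, design, 36L)
  expect_setequal(keep, c("g1", "g3"))
})

test_that("raising thresholds never grows the retained set", {
  design <- plant_worked_example()$design
  set.seed(9)
  n <- 120
  mat <- matrix(exp(rnorm(n * nrow(design), 2, 1.5)), nrow = n,
                dimnames = list(sprintf("g%03d", 1:n), design$sample_id))
  base <- arch_enriched_sets(mat, design,
                             thresholds = enrichment_thresholds(3, 1.5))
  for (th in list(enrichment_thresholds(5, 1.5),
                  enrichment_thresholds(3, 2.5),
                  enrichment_thresholds(8, 3))) {
    tighter <- arch_enriched_sets(mat, design, thresholds = th)
    for (st in names(base$sets)) {
      expect_true(all(tighter$sets[[st]] %in% base$sets[[st]]))
    }
  }
})

test_that("filtering is invariant under gene-row permutation", {
  design <- plant_worked_example()$design
  set.seed(10)
  n <- 60
  mat <- matrix(exp(rnorm(n * nrow(design), 2, 1.5)), nrow = n,
                dimnames = list(sprintf("g%03d", 1:n), design$sample_id))
  perm <- mat[sample(n), ]
  a <- arch_enriched_sets(mat, design)
  b <- arch_enriched_sets(perm, design)
  for (st in names(a$sets)) expect_setequal(a$sets[[st]], b$sets[[st]])
})

test_that("noise-free synthetic arch set equals the planted non-contaminants", {
  sim <- generate_dataset(simulation_params(n_genes = 600L, noise_sd = 0))
  arch <- arch_enriched_sets(sim$matrix, sim$design)
  contaminants <- sim$truth$gene_id[sim$truth$source != "none"]
  expect_setequal(arch$sets[["36"]],
                  setdiff(sim$truth$gene_id, contaminants))
  expect_length(intersect(arch$sets[["36"]], contaminants), 0L)
  # contaminants are excluded at every stage
  for (st in c("20", "28")) {
    expect_length(intersect(arch$sets[[st]], contaminants), 0L)
  }
})
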