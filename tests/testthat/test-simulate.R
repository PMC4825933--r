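test_that("same parameters and seed give byte-identical datasets", {
  p <- simulation_params(n_genes = 300L, noise_sd = 0.3, seed = 42L)
  a <- generate_dataset(p)
  b <- generate_dataset(p)
  expect_identical(a, b)
  # a different seed changes the noise realisation
  c <- generate_dataset(simulation_params(n_genes = 300L, noise_sd = 0.3,
                                          seed = 43L))
  expect_false(identical(a$matrix, c$matrix))
})

test_that("truth table has one label per gene with fractions honoured", {
  p <- simulation_params(n_genes = 500L)
  sim <- generate_dataset(p)
  expect_equal(nrow(sim$truth), 500L)
  expect_equal(sort(sim$truth$gene_id), sort(rownames(sim$matrix)))
  counts <- table(sim$truth$class)
  for (cl in names(p$class_fractions)) {
    expect_equal(unname(counts[cl]), round(p$class_fractions[[cl]] * 500),
                 tolerance = 0, ignore_attr = TRUE)
  }
  expect_error(
    simulation_params(class_fractions = c(
      arch_enriched = 0.5, contaminant_erythroid = 0.2,
      contaminant_macrophage = 0.2, contaminant_ear = 0.2,
      notch_inhibited = 0, notch_activated = 0, edn1_inhibited = 0,
      edn1_activated = 0, co_regulated_positive = 0,
      co_regulated_negative = 0)),
    "sum")
})

test_that("noise-free planted responses equal the effect multiplier exactly", {
  p <- simulation_params(n_genes = 400L, noise_sd = 0, effect_multiplier = 4)
  sim <- generate_dataset(p)
  contrasts <- resolve_contrasts(sim$design)
  fc <- compute_fold_changes(sim$matrix, contrasts)
  pick <- function(cl) sim$truth$gene_id[sim$truth$class == cl]
  expect_equal(unname(fc[pick("notch_inhibited"), "jag1b_mut"]),
               rep(4, length(pick("notch_inhibited"))))
  expect_equal(unname(fc[pick("notch_inhibited"), "nicd_oe"]),
               rep(0.25, length(pick("notch_inhibited"))))
  expect_equal(unname(fc[pick("edn1_activated"), "edn1_oe"]),
               rep(4, length(pick("edn1_activated"))))
  expect_equal(unname(fc[pick("co_regulated_negative"), "dbz"]),
               rep(4, length(pick("co_regulated_negative"))))
  # unregulated genes sit at exactly 1
  expect_equal(unname(fc[pick("unregulated"), "edn1_mut"]),
               rep(1, length(pick("unregulated"))))
})

test_that("planted temporal induction shows up only in induced genes", {
  p <- simulation_params(n_genes = 400L, noise_sd = 0,
                         induction_multiplier_20_28 = 12,
                         induction_multiplier_28_36 = 1)
  sim <- generate_dataset(p)
  tf <- temporal_fold_changes(sim$matrix, sim$design)
  ind <- sim$truth$gene_id[sim$truth$induced]
  not_ind <- sim$truth$gene_id[!sim$truth$induced]
  expect_true(length(ind) > 0)
  expect_equal(tf$fc_20_28[match(ind, tf$gene_id)], rep(12, length(ind)))
  expect_equal(tf$fc_20_28[match(not_ind, tf$gene_id)],
               rep(1, length(not_ind)))
  expect_true(all(sim$truth$class[sim$truth$induced] == "notch_inhibited"))
})

test_that("worked example covers every class in at most 20 genes", {
  wx <- plant_worked_example()
  expect_lte(nrow(wx$matrix), 20L)
  expect_identical(wx$truth$gene_id, rownames(wx$matrix))
  validate_expression_matrix(wx$matrix)
  validate_sample_design(wx$design, wx$matrix)
  for (cl in c(pathway_classes, "contaminant_gfp", "contaminant_dsred",
               "low_expression", "unregulated")) {
    expect_true(cl %in% wx$truth$class, label = paste("class", cl))
  }
})

test_that("shipped worked-example fixtures match the generating function", {
  wx <- plant_worked_example()
  mat <- read_expression_matrix(
    system.file("extdata", "worked_example_matrix.tsv",
                package = "archexpr"))
  design <- read_sample_design(
    system.file("extdata", "worked_example_design.tsv",
                package = "archexpr"))
  expect_identical(mat, wx$matrix)
  expect_equal(design, wx$design, ignore_attr = TRUE)
})
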