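test_that("worked-example predictions match the planted behaviours", {
  wx <- plant_worked_example()
  res <- classify_genes(wx$matrix, wx$design)
  pred <- predict_classes(res, wx$matrix, wx$design)
  got <- setNames(pred$predicted, pred$gene_id)
  expect_equal(got[["boundary_rpkm"]], "low_expression")
  expect_equal(got[["contam_gfp"]], "contaminant_gfp")
  expect_equal(got[["contam_dsred"]], "contaminant_dsred")
  expect_equal(got[["below_enrich"]], "contaminant_gfp")
  expect_equal(got[["notch_inh_1"]], "notch_inhibited")
  expect_equal(got[["co_pos_1"]], "co_regulated_positive")
  expect_equal(got[["co_neg_1"]], "co_regulated_negative")
  expect_equal(got[["antag_induced"]], "notch_inhibited_and_edn1_activated")
  expect_equal(got[["dbz_removed_act"]], "unregulated")
  expect_equal(got[["zero_at_20"]], "unregulated")
})

test_that("noise-free recovery is exact for every planted class", {
  ev <- recover_f1(simulation_params(n_genes = 1000L, noise_sd = 0))
  expect_equal(ev$precision, rep(1, nrow(ev)))
  expect_equal(ev$recall, rep(1, nrow(ev)))
  expect_equal(ev$f1, rep(1, nrow(ev)))
  expect_setequal(ev$class, c("arch_enriched", "unregulated",
                              "contaminant_erythroid",
                              "contaminant_macrophage", "contaminant_ear",
                              pathway_classes))
})
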