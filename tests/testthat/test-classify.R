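test_that("fold-changes follow the zero-replacement rule", {
  mat <- tiny_matrix(c(10, 5,
                       5, 0,
                       0, 0), paste0("g", 1:3), c("pert", "ctrl"))
  contrasts <- data.frame(name = "edn1_mut", perturbed_sample = "pert",
                          control_sample = "ctrl", stringsAsFactors = FALSE)
  fc <- compute_fold_changes(mat, contrasts)
  expect_equal(unname(fc[, "edn1_mut"]), c(2, 500, 1))
})

test_that("fold-changes are invariant to common scaling of a contrast", {
  set.seed(3)
  mat <- tiny_matrix(exp(rnorm(8, 2, 1)), paste0("g", 1:4), c("a", "b"))
  contrasts <- data.frame(name = "dbz", perturbed_sample = "a",
                          control_sample = "b", stringsAsFactors = FALSE)
  fc1 <- compute_fold_changes(mat, contrasts)
  fc2 <- compute_fold_changes(mat * 7.3, contrasts)
  expect_equal(fc1, fc2)
})

test_that("classification thresholds are inclusive with RPKM-ratio guards", {
  fc <- fc_table(
    nicd_oe   = c(3.0, 0.667, 1.2, 1.5, 0.9),
    jag1b_mut = c(2.0, 1.0,   1.0, 1.0, 1.35),
    genes = c("act_boundary", "inh_boundary", "between", "act_lowguard",
              "inh_lowguard"))
  # act_lowguard: ratio 1.5 but OE fc 1.5 >= 1 guard passes -> activated;
  # force a guard failure by dropping OE fc below 1 instead
  fc["act_lowguard", "nicd_oe"] <- 0.9
  fc["act_lowguard", "jag1b_mut"] <- 0.6    # ratio 1.5, guard 0.9 < 1
  # inh_lowguard: ratio 0.667 with mut fc 1.35 >= 1 -> inhibited
  cls <- classify_pathway(fc, "notch")
  expect_setequal(cls$activated, "act_boundary")
  expect_setequal(cls$inhibited, c("inh_boundary", "inh_lowguard"))
  expect_false("between" %in% c(cls$activated, cls$inhibited))
  expect_false("act_lowguard" %in% cls$activated)
})

test_that("activated and inhibited are disjoint for random fold-changes", {
  set.seed(21)
  for (i in 1:20) {
    fc <- fc_table(nicd_oe = exp(rnorm(50, 0, 1)),
                   jag1b_mut = exp(rnorm(50, 0, 1)))
    cls <- classify_pathway(fc, "notch")
    expect_length(intersect(cls$activated, cls$inhibited), 0L)
  }
})

test_that("DBZ refinement is an inclusive-boundary contraction", {
  fc <- fc_table(
    nicd_oe = c(2.5, 4, 0.5, 0.5),
    jag1b_mut = c(1, 1, 2, 2),
    dbz = c(2, 3.4, 0.625, 0.6),
    genes = c("up_boundary", "up_removed", "down_boundary", "down_removed"))
  refined <- refine_notch_with_dbz(
    activated = c("up_boundary", "up_removed"),
    inhibited = c("down_boundary", "down_removed"), fc)
  expect_setequal(refined$activated, "up_boundary")     # 1.25 retained
  expect_setequal(refined$inhibited, "down_boundary")   # 0.8 retained
  expect_setequal(refined$removed_activated, "up_removed")   # 1.176 < 1.25
  expect_setequal(refined$removed_inhibited, "down_removed") # 0.833 > 0.8
  # contraction property on random inputs
  set.seed(31)
  for (i in 1:10) {
    fc <- fc_table(nicd_oe = exp(rnorm(40)), jag1b_mut = exp(rnorm(40)),
                   dbz = exp(rnorm(40)))
    act <- sample(rownames(fc), 15)
    inh <- sample(setdiff(rownames(fc), act), 15)
    r <- refine_notch_with_dbz(act, inh, fc)
    expect_true(all(r$activated %in% act))
    expect_true(all(r$inhibited %in% inh))
    expect_setequal(c(r$activated, r$removed_activated), act)
    expect_setequal(c(r$inhibited, r$removed_inhibited), inh)
  }
})

test_that("Venn summaries satisfy the set identities", {
  classification <- list(
    notch = list(activated = paste0("g", 1:10),
                 inhibited = c("a", "b", "c", "d", "e")),
    edn1 = list(activated = c("c", "d", "e", "f", "g"),
                inhibited = paste0("g", 8:15)))
  venn <- intersect_lists(classification)
  expect_equal(nrow(venn), 4L)
  expect_equal(venn$n_a_only + venn$n_intersect, venn$n_a)
  expect_equal(venn$n_b_only + venn$n_intersect, venn$n_b)
  ni_ea <- venn[venn$set_a == "notch_inhibited" &
                  venn$set_b == "edn1_activated", ]
  expect_equal(ni_ea$n_intersect, 3L)
  # disjoint and subset cases
  classification$edn1$activated <- c("x", "y")
  venn2 <- intersect_lists(classification)
  row <- venn2[venn2$set_b == "edn1_activated" &
                 venn2$set_a == "notch_inhibited", ]
  expect_equal(row$n_intersect, 0L)
  expect_equal(row$n_a_only, row$n_a)
  classification$edn1$activated <- c("a", "b")  # subset of notch inhibited
  venn3 <- intersect_lists(classification)
  row <- venn3[venn3$set_b == "edn1_activated" &
                 venn3$set_a == "notch_inhibited", ]
  expect_equal(row$n_intersect, row$n_b)
})

test_that("top-k ordering is by fold-change with lexicographic ties", {
  fc <- fc_table(dbz = c(4, 3, 2), genes = c("g1", "g2", "g3"))
  expect_equal(top_k_regulated(fc, "dbz", 2, "up"), c("g1", "g2"))
  expect_equal(top_k_regulated(fc, "dbz", 10, "down"), c("g3", "g2", "g1"))
  fc <- fc_table(dbz = c(2, 2, 5), genes = c("g2", "g10", "g3"))
  # tie at 2: plain string order puts g10 before g2
  expect_equal(top_k_regulated(fc, "dbz", 3, "up"), c("g3", "g10", "g2"))
  expect_error(top_k_regulated(fc, "dbz", 0, "up"), "positive")
})
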