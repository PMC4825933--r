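test_that("temporal fold-changes use wild-type stages with zero replacement", {
  wx <- plant_worked_example()
  mat <- wx$matrix
  mat["above_rpkm", c("wt_dp_20", "wt_dp_28", "wt_dp_36")] <- c(2, 4, 4)
  tf <- temporal_fold_changes(mat, wx$design)
  row <- tf[tf$gene_id == "above_rpkm", ]
  expect_equal(row$fc_20_28, 2)
  expect_equal(row$fc_28_36, 1)
  zero <- tf[tf$gene_id == "zero_at_20", ]
  expect_equal(zero$fc_20_28, 50 / 0.01)
  const <- tf[tf$gene_id == "co_pos_1", ]
  expect_equal(c(const$fc_20_28, const$fc_28_36), c(1, 1))
})

test_that("list summaries match an independent order-statistic computation", {
  s <- summarize_list(c(1, 2, 4))
  expect_equal(s$median, 2)
  expect_equal(summarize_list(c(11, 9, 12), threshold = 10)$count_over_threshold,
               2L)
  # linear interpolation between order statistics of 1..8:
  # h = (n - 1) p + 1 gives 1.35, 2.75, 4.5, 6.25, 7.65
  s8 <- summarize_list(1:8)
  expect_equal(s8$p5, 1.35)
  expect_equal(s8$q1, 2.75)
  expect_equal(s8$median, 4.5)
  expect_equal(s8$q3, 6.25)
  expect_equal(s8$p95, 7.65)
  expect_true(s8$p5 <= s8$q1 && s8$q1 <= s8$median &&
                s8$median <= s8$q3 && s8$q3 <= s8$p95)
  expect_error(summarize_list(numeric()), "empty")
})

test_that("Mann-Whitney exact enumeration handles separation, identity, ties", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)  # 2 of the 20 assignments are this extreme
  same <- mann_whitney_u(c(1, 2, 2, 5), c(2, 5, 1, 2))
  expect_equal(same$p, 1)
  # agrees with the pair-counting brute-force oracle, ties included
  set.seed(13)
  for (i in 1:10) {
    x <- sample(1:5, sample(2:5, 1), replace = TRUE)
    y <- sample(1:5, sample(2:5, 1), replace = TRUE)
    expect_equal(mann_whitney_u(x, y, mode = "exact")$p,
                 brute_force_mw_p(x, y), tolerance = 1e-12)
    expect_equal(mann_whitney_u(x, y, mode = "exact")$U, pair_count_u(x, y))
  }
})

test_that("Mann-Whitney p is invariant under monotone transforms", {
  set.seed(14)
  x <- rnorm(5); y <- rnorm(6)
  p0 <- mann_whitney_u(x, y, mode = "exact")$p
  expect_equal(mann_whitney_u(exp(x), exp(y), mode = "exact")$p, p0)
  expect_equal(mann_whitney_u(x^3, y^3, mode = "exact")$p, p0)
})

test_that("normal approximation tracks the exact enumeration", {
  set.seed(15)
  x <- c(rnorm(4), 1.2); y <- c(rnorm(3, 0.5), 1.2)
  exact <- mann_whitney_u(x, y, mode = "exact")$p
  approx <- mann_whitney_u(x, y, mode = "approximate")$p
  expect_lt(abs(exact - approx), 0.1)
  # auto switches on the combined-size cutoff
  expect_equal(mann_whitney_u(x, y, exact_limit = 20L)$method, "exact")
  expect_equal(mann_whitney_u(rnorm(15), rnorm(15))$method, "approximate")
})

test_that("Kruskal-Wallis matches hand computation and degenerates to 0", {
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))$H, 0)
  # fully separated groups, no ties: rank means 1.5 / 3.5 / 5.5
  h <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(h$H, 32 / 7)
  expect_equal(h$df, 2L)
  # two-group H equals the squared Mann-Whitney z (no ties)
  set.seed(16)
  x <- rnorm(12); y <- rnorm(9, 0.8)
  kw <- kruskal_wallis(list(x, y))
  mw <- mann_whitney_u(x, y, mode = "approximate")
  expect_equal(kw$p, mw$p, tolerance = 1e-10)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
})

test_that("compare_lists flags only genuinely shifted lists", {
  genes <- sprintf("g%03d", 1:60)
  fast <- genes[1:12]
  temporal <- data.frame(
    gene_id = genes,
    fc_20_28 = c(rep(12, 12), runif(48, 0.8, 1.6)),
    fc_28_36 = rep(1, 60), stringsAsFactors = FALSE)
  lists <- list(total = genes, induced = fast, same = genes)
  rep <- compare_lists(temporal, lists, "20_28")
  expect_equal(rep$m, 2L)
  srow <- rep$summaries
  expect_true(srow$flagged[srow$list == "induced"])
  expect_false(srow$flagged[srow$list == "same"])
  expect_gt(srow$median[srow$list == "induced"],
            srow$median[srow$list == "total"])
  expect_equal(srow$count_over_threshold[srow$list == "induced"], 12L)
  # Bonferroni: adjusted = min(1, raw * m), order-independent
  ok <- !is.na(srow$p_raw)
  expect_equal(srow$p_adj[ok], pmin(1, srow$p_raw[ok] * rep$m))
  # lists with < 2 members are skipped with a warning, not an error
  expect_warning(
    compare_lists(temporal, c(lists, list(tiny = genes[1])), "20_28"),
    "tiny")
})

test_that("penetrance chi-square matches the 2x2 closed form", {
  flat <- chi_square_penetrance(rbind(c(10, 10), c(10, 10)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  # posterior-Pq rescue counts: 16/16 affected vs 11/27
  tab <- rbind(jag1b = c(16, 0), jag1b_barx1 = c(11, 16))
  got <- chi_square_penetrance(tab)
  a <- 16; b <- 0; c <- 11; d <- 16
  closed <- (a + b + c + d) * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(got$statistic, closed)
  expect_equal(got$df, 1L)
  expect_false(got$expected_below_5)  # smallest expected cell is 16*16/43
  expect_true(chi_square_penetrance(rbind(c(4, 1), c(2, 5)))$expected_below_5)
  fisher <- chi_square_penetrance(tab, mode = "fisher")
  expect_true(fisher$p > 0 && fisher$p < 1e-3)
  expect_error(chi_square_penetrance(rbind(c(0, 0), c(3, 4), c(5, 6))),
               "degenerate")
})
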