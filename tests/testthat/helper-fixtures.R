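# Small builders shared across tests.

tiny_matrix <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), byrow = TRUE,
         dimnames = list(genes, samples))
}

# fold-change table with the columns classify_pathway() expects
fc_table <- function(..., genes = NULL) {
  cols <- list(...)
  m <- do.call(cbind, cols)
  rownames(m) <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# definitional Mann-Whitney U: pair counting, independent of the rank-sum
# formula used by the implementation
pair_count_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# brute-force two-sided exact p over all group assignments of the pooled data
brute_force_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  u_obs <- pair_count_u(x, y)
  picks <- utils::combn(length(pooled), n1)
  us <- apply(picks, 2L, function(idx) {
    pair_count_u(pooled[idx], pooled[-idx])
  })
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

pathway_classes <- c("notch_inhibited", "notch_activated", "edn1_inhibited",
                     "edn1_activated", "co_regulated_positive",
                     "co_regulated_negative")

recover_f1 <- function(params) {
  sim <- generate_dataset(params)
  res <- classify_genes(sim$matrix, sim$design)
  evaluate_recovery(sim$truth, predict_classes(res, sim$matrix, sim$design))
}
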