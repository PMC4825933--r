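#' Wild-type temporal fold-changes over a gene universe
#'
#' fc_20_28(g) = RPKM28(g)/RPKM20(g) and fc_28_36(g) = RPKM36(g)/RPKM28(g)
#' from the wild-type double-positive samples, with zero values replaced by
#' `zero_replacement` before division (the same rule that rescues genes with
#' zero RPKM at 20 hpf from a division error).
#'
#' @param matrix expression matrix.
#' @param design sample-design data.frame with wild-type double-positive
#'   samples at 20, 28 and 36 hpf.
#' @param universe gene ids to evaluate (default all genes).
#' @param zero_replacement replacement for zero cells (default 0.01).
#' @return data.frame with columns `gene_id`, `fc_20_28`, `fc_28_36`.
#' @export
temporal_fold_changes <- function(matrix, design,
                                  universe = rownames(matrix),
                                  zero_replacement = 0.01) {
  s20 <- stage_sample(design, 20L)
  s28 <- stage_sample(design, 28L)
  s36 <- stage_sample(design, 36L)
  genes <- rownames(matrix)[rownames(matrix) %in% universe]
  v20 <- .replace_zero(matrix[genes, s20], zero_replacement)
  v28 <- .replace_zero(matrix[genes, s28], zero_replacement)
  v36 <- .replace_zero(matrix[genes, s36], zero_replacement)
  data.frame(gene_id = genes,
             fc_20_28 = v28 / v20,
             fc_28_36 = v36 / v28,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summary of a fold-change distribution
#'
#' Median, quartiles and 5th/95th percentiles use linear interpolation
#' between order statistics (the [stats::quantile()] type-7 convention).
#' `count_over_threshold` counts values strictly greater than `threshold`
#' ("induced more than `threshold`-fold").
#'
#' @param fcs non-empty numeric vector of positive fold-changes.
#' @param threshold induction threshold for the strict count (default 10).
#' @return list with `n`, `median`, `q1`, `q3`, `p5`, `p95`,
#'   `count_over_threshold`.
#' @export
summarize_list <- function(fcs, threshold = 10) {
  if (length(fcs) == 0L) stop("empty fold-change list", call. = FALSE)
  q <- stats::quantile(fcs, probs = c(0.05, 0.25, 0.5, 0.75, 0.95),
                       names = FALSE, type = 7)
  list(n = length(fcs),
       median = q[3L], q1 = q[2L], q3 = q[4L], p5 = q[1L], p95 = q[5L],
       count_over_threshold = sum(fcs > threshold))
}

# Mann-Whitney U for the first sample, via midranks:
# U1 = R1 - n1(n1+1)/2 where R1 is the rank sum of x in the pooled data.
.mw_u <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney U test with exact enumeration under ties
#'
#' The U statistic uses midranks for ties. In exact mode the two-sided
#' p-value is computed by full enumeration of all choose(n1+n2, n1) group
#' assignments of the pooled values: p = P(|U - n1 n2 / 2| >= |u_obs -
#' n1 n2 / 2|) under the permutation distribution, which handles ties
#' correctly (unlike the classical exact tables). In approximate mode a
#' normal approximation with the usual tie correction of the variance is
#' used, without continuity correction. `mode = "auto"` enumerates when
#' n1 + n2 <= `exact_limit` and approximates otherwise.
#'
#' @param x,y non-empty numeric vectors.
#' @param mode "auto" (default), "exact" or "approximate".
#' @param exact_limit combined-size cutoff for enumeration in auto mode
#'   (default 20).
#' @return list with `U` (for `x`), `p` (two-sided), and `method`.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "approximate"),
                           exact_limit = 20L) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  u_obs <- .mw_u(x, y)
  mu <- n1 * n2 / 2
  if (mode == "auto") {
    mode <- if (n <= exact_limit) "exact" else "approximate"
  }
  if (mode == "exact") {
    pooled <- c(x, y)
    r <- rank(pooled)
    offset <- n1 * (n1 + 1) / 2
    idx <- utils::combn(n, n1)
    us <- colSums(matrix(r[idx], nrow = n1)) - offset
    eps <- 1e-9
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - eps)
  } else {
    ties <- table(c(x, y))
    sigma2 <- n1 * n2 / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1 # all pooled values identical
    } else {
      z <- (u_obs - mu) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(U = u_obs, p = p, method = mode)
}

#' Kruskal-Wallis rank test over groups
#'
#' Wraps [stats::kruskal.test()]: H with tie correction, p from the
#' chi-square approximation with (number of groups - 1) degrees of freedom.
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return list with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need >= 2 groups", call. = FALSE)
  }
  if (any(vapply(groups, length, integer(1)) == 0L)) {
    stop("all groups must be non-empty", call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (length(unique(values)) == 1L) {
    # all observations identical: H = 0 by the rank formula; kruskal.test
    # would error on a constant response
    return(list(H = 0, p = 1, df = length(groups) - 1L))
  }
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

#' Compare gene lists' temporal fold-changes against the total list
#'
#' Runs a Kruskal-Wallis test over all lists' fold-changes, then compares
#' each non-total list with the total list by two-sided Mann-Whitney tests
#' with Bonferroni correction over the number of pairwise tests actually
#' performed; lists with fewer than 2 members are skipped with a warning.
#'
#' @param temporal data.frame from [temporal_fold_changes()].
#' @param lists named list of gene id vectors; must include an entry named
#'   `total` (the full arch-enriched universe).
#' @param interval "20_28" or "28_36".
#' @param alpha significance level after correction (default 0.05).
#' @param threshold induction threshold for the per-list strict count.
#' @param exact_limit passed to [mann_whitney_u()].
#' @return list with `summaries` (data.frame: list, n, median, q1, q3, p5,
#'   p95, count_over_threshold, p_raw, p_adj, flagged), `kruskal_wallis`
#'   (H, p, df), `m` (number of pairwise tests), `alpha`, `interval`.
#' @export
compare_lists <- function(temporal, lists, interval = c("20_28", "28_36"),
                          alpha = 0.05, threshold = 10, exact_limit = 20L) {
  interval <- match.arg(interval)
  if (!"total" %in% names(lists)) {
    stop("`lists` must include a 'total' entry", call. = FALSE)
  }
  col <- paste0("fc_", interval)
  fc_of <- function(genes) {
    miss <- setdiff(genes, temporal$gene_id)
    if (length(miss) > 0L) {
      stop("gene(s) outside the temporal universe: ",
           paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
    }
    temporal[[col]][match(genes, temporal$gene_id)]
  }
  fcs <- lapply(lists, fc_of)
  usable <- vapply(fcs, length, integer(1)) >= 2L
  skipped <- names(lists)[!usable]
  if (length(skipped) > 0L) {
    warning("skipping list(s) with < 2 members: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  kw <- kruskal_wallis(fcs[usable])
  others <- setdiff(names(lists)[usable], "total")
  m <- length(others)
  p_raw <- vapply(others, function(nm) {
    mann_whitney_u(fcs[[nm]], fcs$total, exact_limit = exact_limit)$p
  }, numeric(1))
  p_adj <- if (m > 0L) {
    stats::p.adjust(p_raw, method = "bonferroni")
  } else numeric(0)
  rows <- lapply(names(lists)[usable], function(nm) {
    s <- summarize_list(fcs[[nm]], threshold)
    data.frame(list = nm, n = s$n, median = s$median, q1 = s$q1, q3 = s$q3,
               p5 = s$p5, p95 = s$p95,
               count_over_threshold = s$count_over_threshold,
               p_raw = if (nm == "total") NA_real_ else p_raw[[nm]],
               p_adj = if (nm == "total") NA_real_ else p_adj[[nm]],
               stringsAsFactors = FALSE)
  })
  summaries <- do.call(rbind, rows)
  summaries$flagged <- !is.na(summaries$p_adj) & summaries$p_adj < alpha
  list(summaries = summaries, kruskal_wallis = kw, m = m, alpha = alpha,
       interval = interval, skipped = skipped)
}

#' Contingency test of phenotype penetrance across genotypes
#'
#' Pearson chi-square without continuity correction on an r x 2 (or r x c)
#' genotype-by-outcome count table, df = (r - 1)(c - 1); Fisher's exact test
#' is available for small tables. A warning flag is reported when any
#' expected cell count is below 5.
#'
#' @param table integer matrix of counts, genotypes in rows and outcomes
#'   (e.g. affected / unaffected) in columns; >= 2 rows, no all-zero row or
#'   column margin.
#' @param mode "pearson" (default) or "fisher".
#' @return list with `statistic` (NA for Fisher), `p`, `df`,
#'   `expected_below_5` and `mode`.
#' @export
chi_square_penetrance <- function(table, mode = c("pearson", "fisher")) {
  mode <- match.arg(mode)
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) {
    stop("need >= 2 genotype rows and >= 2 outcome columns", call. = FALSE)
  }
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate table: zero row or column margin", call. = FALSE)
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  low <- any(expected < 5)
  if (mode == "pearson") {
    ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
    list(statistic = unname(ct$statistic), p = ct$p.value,
         df = unname(ct$parameter), expected_below_5 = low,
         mode = "pearson")
  } else {
    ft <- stats::fisher.test(table)
    list(statistic = NA_real_, p = ft$p.value, df = NA_integer_,
         expected_below_5 = low, mode = "fisher")
  }
}
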