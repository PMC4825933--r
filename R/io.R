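#' Validate an RPKM expression matrix
#'
#' An expression matrix is a plain numeric matrix of non-negative RPKM values
#' with unique gene identifiers as row names and unique sample identifiers as
#' column names. Every (gene, sample) cell must be present; missing values are
#' not allowed.
#'
#' @param mat numeric matrix with gene row names and sample column names.
#' @return the matrix, invisibly, if valid; otherwise an error is raised.
#' @export
validate_expression_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  }
  genes <- rownames(mat)
  samples <- colnames(mat)
  if (is.null(genes) || is.null(samples)) {
    stop("expression matrix must have gene row names and sample column names",
         call. = FALSE)
  }
  dup_g <- genes[duplicated(genes)]
  if (length(dup_g) > 0L) {
    stop("duplicate gene identifier(s): ", paste(unique(dup_g), collapse = ", "),
         call. = FALSE)
  }
  dup_s <- samples[duplicated(samples)]
  if (length(dup_s) > 0L) {
    stop("duplicate sample identifier(s): ",
         paste(unique(dup_s), collapse = ", "), call. = FALSE)
  }
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at gene '%s', sample '%s'",
                 genes[idx[1L]], samples[idx[2L]]), call. = FALSE)
  }
  if (any(mat < 0)) {
    idx <- which(mat < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value at gene '%s', sample '%s'",
                 genes[idx[1L]], samples[idx[2L]]), call. = FALSE)
  }
  invisible(mat)
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-delimited UTF-8 file whose first column holds gene
#' identifiers and whose header row holds sample identifiers; all remaining
#' cells must be non-negative numbers. Row and column order are preserved.
#'
#' @param path path to a TSV file.
#' @return a validated numeric matrix (genes x samples).
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "",
                          fileEncoding = "UTF-8")
  if (ncol(df) < 2L) {
    stop("expression matrix TSV needs a gene_id column plus >= 1 sample",
         call. = FALSE)
  }
  genes <- df[[1L]]
  samples <- colnames(df)[-1L]
  vals <- matrix(NA_real_, nrow = nrow(df), ncol = length(samples),
                 dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    x <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(x) & !is.na(df[[j + 1L]]))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric cell at row %d (gene '%s'), column '%s'",
                   bad[1L], genes[bad[1L]], samples[j]), call. = FALSE)
    }
    vals[, j] <- x
  }
  validate_expression_matrix(vals)
  vals
}

#' Write an expression matrix to TSV
#'
#' Values are written with 17 significant digits so that a write/read
#' round-trip reproduces the matrix bit-exactly.
#'
#' @param mat validated expression matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  validate_expression_matrix(mat)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(mat)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], sprintf("%.17g", mat[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

.populations <- c("double_positive", "gfp_only", "dsred_only",
                  "double_negative")
.stages <- c(20L, 28L, 36L)

#' Validate a sample-design table
#'
#' @param design data.frame with columns `sample_id`, `population`
#'   (double_positive / gfp_only / dsred_only / double_negative), `stage_hpf`
#'   (20, 28 or 36) and `condition` (free label such as `wt`, `edn1_mut`,
#'   `hs_ctrl`).
#' @param matrix optional expression matrix; if given, every sample in the
#'   design must be a column of the matrix.
#' @return the design, invisibly.
#' @export
validate_sample_design <- function(design, matrix = NULL) {
  need <- c("sample_id", "population", "stage_hpf", "condition")
  miss <- setdiff(need, colnames(design))
  if (length(miss) > 0L) {
    stop("sample design lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dup <- design$sample_id[duplicated(design$sample_id)]
  if (length(dup) > 0L) {
    stop("duplicate sample_id(s) in design: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad_pop <- setdiff(unique(design$population), .populations)
  if (length(bad_pop) > 0L) {
    stop("unknown population(s): ", paste(bad_pop, collapse = ", "),
         call. = FALSE)
  }
  bad_stage <- setdiff(unique(as.integer(design$stage_hpf)), .stages)
  if (length(bad_stage) > 0L) {
    stop("unknown stage_hpf value(s): ", paste(bad_stage, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(matrix)) {
    absent <- setdiff(design$sample_id, colnames(matrix))
    if (length(absent) > 0L) {
      stop("design sample(s) absent from matrix: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
  }
  invisible(design)
}

#' Read / write a sample-design table (TSV)
#'
#' @param path file path.
#' @return `read_sample_design`: validated design data.frame.
#' @export
read_sample_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "",
                          fileEncoding = "UTF-8")
  df$stage_hpf <- as.integer(df$stage_hpf)
  validate_sample_design(df)
  df
}

#' @rdname read_sample_design
#' @param design sample-design data.frame.
#' @export
write_sample_design <- function(design, path) {
  validate_sample_design(design)
  con <- file(path, open = "wb")
  on.exit(close(con))
  cols <- c("sample_id", "population", "stage_hpf", "condition")
  writeLines(paste(cols, collapse = "\t"), con)
  writeLines(apply(design[, cols], 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Compute RPKM from raw counts
#'
#' RPKM(g, s) = 1e9 * count(g, s) / (length(g) * total(s)), i.e. reads per
#' kilobase of transcript per million mapped reads. Accepting counts is
#' optional plumbing: matrices already expressed in RPKM can be used directly.
#'
#' @param counts non-negative integer matrix (genes x samples) with dimnames.
#' @param lengths positive gene lengths in bp, one per row of `counts`.
#' @param totals positive per-sample total mapped read counts, one per column.
#' @return RPKM expression matrix with the dimnames of `counts`.
#' @export
compute_rpkm <- function(counts, lengths, totals) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("counts must be a numeric matrix", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (length(lengths) != nrow(counts)) {
    stop("lengths must have one entry per gene", call. = FALSE)
  }
  if (length(totals) != ncol(counts)) {
    stop("totals must have one entry per sample", call. = FALSE)
  }
  if (any(lengths <= 0)) stop("gene lengths must be positive", call. = FALSE)
  if (any(totals <= 0)) stop("library totals must be positive", call. = FALSE)
  rpkm <- 1e9 * counts / outer(as.numeric(lengths), as.numeric(totals))
  dimnames(rpkm) <- dimnames(counts)
  validate_expression_matrix(rpkm)
  rpkm
}

# Perturbed / control condition labels behind each named contrast. The two
# heat-shock overexpression arms share the hsp70I:Gal4-only control condition.
.contrast_conditions <- data.frame(
  name      = c("edn1_mut", "jag1b_mut", "edn1_oe", "nicd_oe", "dbz"),
  perturbed = c("edn1_mut", "jag1b_mut", "edn1_oe", "nicd_oe", "dbz"),
  control   = c("edn1_ctrl", "jag1b_ctrl", "hs_ctrl", "hs_ctrl",
                "vehicle_ctrl"),
  stringsAsFactors = FALSE
)

#' Contrast names understood by the pipeline
#' @return character vector of the five perturbation-vs-control contrast names.
#' @export
contrast_names <- function() .contrast_conditions$name

#' Resolve named contrasts against a sample design
#'
#' Each contrast maps to exactly one perturbed and one control sample of the
#' double-positive (arch NCC) population; the result is deterministic and
#' independent of the row order of the design.
#'
#' @param design sample-design data.frame.
#' @param requested character vector of contrast names (subset of
#'   [contrast_names()]).
#' @return data.frame with columns `name`, `perturbed_sample`,
#'   `control_sample`.
#' @export
resolve_contrasts <- function(design, requested = contrast_names()) {
  validate_sample_design(design)
  if (length(requested) == 0L) {
    return(data.frame(name = character(), perturbed_sample = character(),
                      control_sample = character(), stringsAsFactors = FALSE))
  }
  unknown <- setdiff(requested, .contrast_conditions$name)
  if (length(unknown) > 0L) {
    stop("unknown contrast name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(requested)) {
    stop("contrast names must be unique within a run", call. = FALSE)
  }
  dp <- design[design$population == "double_positive", , drop = FALSE]
  one_sample <- function(condition, contrast, role) {
    hits <- sort(dp$sample_id[dp$condition == condition])
    if (length(hits) == 0L) {
      stop(sprintf(
        "contrast '%s': no double-positive %s sample with condition '%s'",
        contrast, role, condition), call. = FALSE)
    }
    if (length(hits) > 1L) {
      stop(sprintf(
        "contrast '%s': ambiguous %s sample for condition '%s' (%s)",
        contrast, role, condition, paste(hits, collapse = ", ")),
        call. = FALSE)
    }
    hits
  }
  out <- lapply(requested, function(nm) {
    row <- .contrast_conditions[.contrast_conditions$name == nm, ]
    data.frame(
      name = nm,
      perturbed_sample = one_sample(row$perturbed, nm, "perturbed"),
      control_sample = one_sample(row$control, nm, "control"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Locate a wild-type double-positive sample for a stage
#'
#' @param design sample-design data.frame.
#' @param stage stage in hpf (20, 28 or 36).
#' @param population population label, default double_positive.
#' @param condition condition label, default "wt".
#' @return a single sample id.
#' @export
stage_sample <- function(design, stage, population = "double_positive",
                         condition = "wt") {
  hits <- sort(design$sample_id[design$population == population &
                                  as.integer(design$stage_hpf) ==
                                    as.integer(stage) &
                                  design$condition == condition])
  if (length(hits) == 0L) {
    stop(sprintf("no %s sample at %d hpf with condition '%s'",
                 population, as.integer(stage), condition), call. = FALSE)
  }
  if (length(hits) > 1L) {
    stop(sprintf("ambiguous %s sample at %d hpf (condition '%s'): %s",
                 population, as.integer(stage), condition,
                 paste(hits, collapse = ", ")), call. = FALSE)
  }
  hits
}

#' Read / write a one-column gene list (TSV with header `gene_id`)
#' @param path file path.
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  df[[1L]]
}

#' @rdname read_gene_list
#' @param genes character vector of gene ids.
#' @export
write_gene_list <- function(genes, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("gene_id", genes), con)
  invisible(path)
}
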