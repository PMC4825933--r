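#' Configuration for a full pipeline run
#'
#' Collects everything a run needs: input paths (or a simulation block in
#' place of inputs), the two threshold blocks, statistics options and the
#' output directory. Every default equals the published threshold values.
#'
#' @param output_dir directory the run writes into (created if needed).
#' @param matrix_path,design_path input TSV paths; ignored when `simulate`
#'   is non-NULL.
#' @param simulate optional [simulation_params()] object; when given, the
#'   run generates its own dataset and writes it alongside the results.
#' @param enrichment an [enrichment_thresholds()] object.
#' @param classifier a [classifier_thresholds()] object.
#' @param alpha significance level for the list comparison (default 0.05).
#' @param induction_threshold strict fold-change count threshold (default 10).
#' @param exact_limit Mann-Whitney enumeration cutoff (default 20).
#' @param dbz_mode NICD-vs-DBZ comparison mode (see [nicd_dbz_ratio()]).
#' @param stages stages (hpf) filtered for arch enrichment.
#' @param contrasts contrast names to resolve.
#' @param phenotype_table optional genotype x outcome count matrix for the
#'   penetrance stage.
#' @param seed integer seed recorded in the manifest (drives the simulation).
#' @return list of class `run_config`.
#' @export
run_config <- function(output_dir,
                       matrix_path = NULL, design_path = NULL,
                       simulate = NULL,
                       enrichment = enrichment_thresholds(),
                       classifier = classifier_thresholds(),
                       alpha = 0.05, induction_threshold = 10,
                       exact_limit = 20L,
                       dbz_mode = c("fc_ratio", "sample_ratio"),
                       stages = c(20L, 28L, 36L),
                       contrasts = contrast_names(),
                       phenotype_table = NULL,
                       seed = 1L) {
  structure(list(output_dir = output_dir, matrix_path = matrix_path,
                 design_path = design_path, simulate = simulate,
                 enrichment = enrichment, classifier = classifier,
                 alpha = alpha, induction_threshold = induction_threshold,
                 exact_limit = as.integer(exact_limit),
                 dbz_mode = match.arg(dbz_mode),
                 stages = as.integer(stages), contrasts = contrasts,
                 phenotype_table = phenotype_table, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Threshold blocks appear under `enrichment`, `classifier` and `simulate`
#' keys with the field names of their constructors; scalar options at the
#' top level.
#'
#' @param path YAML file path.
#' @return a [run_config()] object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(
    output_dir = y$output_dir,
    matrix_path = y$matrix_path, design_path = y$design_path,
    simulate = if (!is.null(y$simulate)) {
      sim <- y$simulate
      if (!is.null(sim$class_fractions)) {
        sim$class_fractions <- unlist(sim$class_fractions)
      }
      do.call(simulation_params, sim)
    },
    enrichment = do.call(enrichment_thresholds,
                         as.list(y$enrichment %||% list())),
    classifier = do.call(classifier_thresholds,
                         as.list(y$classifier %||% list())))
  for (k in c("alpha", "induction_threshold", "exact_limit", "dbz_mode",
              "stages", "contrasts", "seed")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$phenotype_table)) {
    args$phenotype_table <- do.call(rbind, lapply(y$phenotype_table, unlist))
  }
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a run configuration without executing it
#'
#' @param config a [run_config()] object (or a bare list with the same
#'   fields, so that invalid threshold combinations can be reported rather
#'   than thrown).
#' @return character vector of findings; empty when the config is valid.
#' @export
validate_config <- function(config) {
  findings <- character()
  say <- function(...) findings <<- c(findings, sprintf(...))
  if (is.null(config$output_dir)) say("output_dir: missing")
  if (is.null(config$simulate)) {
    for (p in c("matrix_path", "design_path")) {
      if (is.null(config[[p]])) {
        say("%s: missing (and no simulate block)", p)
      } else if (!file.exists(config[[p]])) {
        say("%s: file not found (%s)", p, config[[p]])
      }
    }
  }
  en <- config$enrichment
  if (!is.null(en)) {
    if (en$min_rpkm < 0) say("enrichment$min_rpkm: must be >= 0")
    if (en$enrichment_ratio <= 0) say("enrichment$enrichment_ratio: must be > 0")
    if (en$zero_replacement <= 0) say("enrichment$zero_replacement: must be > 0")
  }
  cl <- config$classifier
  if (!is.null(cl)) {
    if (!(cl$activation_ratio > 1 && 1 > cl$inhibition_ratio &&
            cl$inhibition_ratio > 0)) {
      say("classifier: need activation_ratio > 1 > inhibition_ratio > 0")
    }
    if (!(cl$dbz_up_min > 1 && 1 > cl$dbz_down_max && cl$dbz_down_max > 0)) {
      say("classifier: need dbz_up_min > 1 > dbz_down_max > 0")
    }
  }
  if (!is.null(config$alpha) &&
      (config$alpha <= 0 || config$alpha >= 1)) {
    say("alpha: must lie in (0, 1)")
  }
  if (!is.null(config$contrasts)) {
    unknown <- setdiff(config$contrasts, contrast_names())
    if (length(unknown) > 0L) {
      say("contrasts: unknown name(s) %s", paste(unknown, collapse = ", "))
    }
    if (!"dbz" %in% config$contrasts) {
      say("contrasts: dbz contrast required for Notch list refinement")
    }
  }
  if (!is.null(config$phenotype_table)) {
    tab <- config$phenotype_table
    if (nrow(tab) < 2L || any(tab < 0)) {
      say("phenotype_table: need >= 2 genotype rows of non-negative counts")
    }
  }
  findings
}

.write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  num <- vapply(df, is.double, logical(1))
  for (j in which(num)) df[[j]] <- sprintf("%.17g", df[[j]])
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df) > 0L) {
    writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
  }
  invisible(path)
}

#' Execute the full pipeline
#'
#' Stage order: simulate (optional) -> read/validate inputs -> arch
#' enrichment filter per stage -> fold-change classification with DBZ
#' refinement and Venn summary -> temporal list comparison -> phenotype
#' contingency test (optional). All stage outputs are written under
#' `config$output_dir` together with `manifest.json` recording the config,
#' package version, per-stage gene counts and MD5 checksums of every output
#' file. Identical config and inputs give a byte-identical output tree.
#'
#' @param config a [run_config()] object.
#' @return the manifest, invisibly (a list).
#' @export
run_pipeline <- function(config) {
  findings <- validate_config(config)
  if (length(findings) > 0L) {
    stop("invalid configuration:\n  ", paste(findings, collapse = "\n  "),
         call. = FALSE)
  }
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(name, writer) {
    path <- file.path(out, name)
    writer(path)
    files <<- c(files, name)
    path
  }

  # stage: input
  if (!is.null(config$simulate)) {
    sim <- generate_dataset(config$simulate)
    mat <- sim$matrix; design <- sim$design
    emit("matrix.tsv", function(p) write_expression_matrix(mat, p))
    emit("design.tsv", function(p) write_sample_design(design, p))
    emit("truth.tsv", function(p) .write_tsv(sim$truth, p))
  } else {
    mat <- read_expression_matrix(config$matrix_path)
    design <- read_sample_design(config$design_path)
  }
  validate_sample_design(design, mat)

  # stage: filter + classify
  result <- classify_genes(mat, design, config$enrichment, config$classifier,
                           config$dbz_mode)
  for (st in names(result$arch$sets)) {
    emit(sprintf("arch_enriched_%s.tsv", st), local({
      genes <- result$arch$sets[[st]]
      function(p) write_gene_list(genes, p)
    }))
  }
  fc_df <- data.frame(gene_id = rownames(result$fc), result$fc,
                      check.names = FALSE, stringsAsFactors = FALSE)
  emit("fold_changes.tsv", function(p) .write_tsv(fc_df, p))
  list_df <- function(genes) {
    fc_df[match(genes, fc_df$gene_id), , drop = FALSE]
  }
  for (pw in c("notch", "edn1")) {
    for (dir in c("activated", "inhibited")) {
      emit(sprintf("%s_%s.tsv", pw, dir), local({
        genes <- result[[pw]][[dir]]
        function(p) .write_tsv(list_df(genes), p)
      }))
    }
  }
  removed <- rbind(
    data.frame(gene_id = result$dbz_removed$activated,
               removed_from = rep("activated",
                                  length(result$dbz_removed$activated)),
               stringsAsFactors = FALSE),
    data.frame(gene_id = result$dbz_removed$inhibited,
               removed_from = rep("inhibited",
                                  length(result$dbz_removed$inhibited)),
               stringsAsFactors = FALSE))
  emit("dbz_removed.tsv", function(p) .write_tsv(removed, p))
  emit("venn.json", function(p) {
    jsonlite::write_json(result$venn, p, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  })

  # stage: temporal
  temporal <- temporal_fold_changes(mat, design, result$universe,
                                    config$classifier$zero_replacement)
  emit("temporal_fold_changes.tsv", function(p) .write_tsv(temporal, p))
  lists <- list(total = result$universe,
                notch_activated = result$notch$activated,
                notch_inhibited = result$notch$inhibited,
                edn1_activated = result$edn1$activated,
                edn1_inhibited = result$edn1$inhibited,
                notch_inhibited_and_edn1_activated =
                  intersect(result$notch$inhibited, result$edn1$activated))
  comparisons <- lapply(c("20_28", "28_36"), function(iv) {
    suppressWarnings(
      compare_lists(temporal, lists, iv, config$alpha,
                    config$induction_threshold, config$exact_limit))
  })
  names(comparisons) <- c("20_28", "28_36")
  emit("temporal_report.json", function(p) {
    jsonlite::write_json(
      lapply(comparisons, function(cm) {
        list(summaries = cm$summaries, kruskal_wallis = cm$kruskal_wallis,
             m = cm$m, alpha = cm$alpha)
      }), p, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  })

  # stage: phenotype (optional)
  phenotype <- NULL
  if (!is.null(config$phenotype_table)) {
    phenotype <- chi_square_penetrance(config$phenotype_table)
    emit("phenotype.json", function(p) {
      jsonlite::write_json(phenotype, p, auto_unbox = TRUE, digits = NA)
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("archexpr")),
    seed = config$seed,
    dbz_mode = config$dbz_mode,
    counts = list(
      genes = nrow(mat), samples = ncol(mat),
      arch_enriched = as.list(result$arch$counts),
      notch_activated_prerefine = length(result$notch_prerefine$activated),
      notch_inhibited_prerefine = length(result$notch_prerefine$inhibited),
      notch_activated = length(result$notch$activated),
      notch_inhibited = length(result$notch$inhibited),
      edn1_activated = length(result$edn1$activated),
      edn1_inhibited = length(result$edn1$inhibited),
      dbz_removed = length(removed$gene_id)),
    thresholds = list(enrichment = unclass(config$enrichment),
                      classifier = unclass(config$classifier)),
    alpha = config$alpha,
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out, files))), files)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
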