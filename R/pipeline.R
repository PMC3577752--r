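#' Configure an end-to-end discovery-to-repositioning run
#'
#' Bundles the file paths and stage configurations for
#' [run_pipeline()]: one or two expression datasets (discovery and
#' optional validation), a gene-set collection, the interaction/compound
#' tables, and the GSA and filter settings.
#'
#' @param expr_a,pheno_a Discovery expression and phenotype TSV paths.
#' @param gmt Gene-set collection (GMT path).
#' @param interactions,compounds Interaction and compound TSV paths.
#' @param expr_b,pheno_b Optional validation dataset paths (both or
#'   neither).
#' @param group_levels Ordered phenotype levels shared by both datasets.
#' @param gsa A [gsa_config()].
#' @param filter A [filter_config()].
#' @param selected_sets Optional explicit restriction of which significant
#'   (or replicated) sets feed the drug stage; hand-picking is always an
#'   explicit list here, never implicit.
#' @param out_dir Output directory for per-stage TSVs, the summary JSON and
#'   the log.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(expr_a, pheno_a, gmt, interactions, compounds,
                            expr_b = NULL, pheno_b = NULL,
                            group_levels = c("D0", "STA", "BL", "ARIA", "ARIB"),
                            gsa = gsa_config(), filter = filter_config(),
                            selected_sets = NULL, out_dir = tempfile("pipeline_")) {
  two <- !is.null(expr_b) || !is.null(pheno_b)
  if (two && (is.null(expr_b) || is.null(pheno_b))) {
    stop("two-dataset mode requires both expr_b and pheno_b", call. = FALSE)
  }
  paths <- c(expr_a, pheno_a, gmt, interactions, compounds, expr_b, pheno_b)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(expr_a = expr_a, pheno_a = pheno_a, gmt = gmt,
                 interactions = interactions, compounds = compounds,
                 expr_b = expr_b, pheno_b = pheno_b,
                 group_levels = group_levels, gsa = gsa, filter = filter,
                 selected_sets = selected_sets, out_dir = out_dir),
            class = "pipeline_config")
}

.stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the discovery - replication - repositioning pipeline
#'
#' Executes gene-set analysis on the discovery dataset (and on the
#' validation dataset when configured), intersects significant sets across
#' datasets, takes the union of the selected sets' member genes restricted
#' to scored genes, and feeds that gene list through the compound lookup,
#' filtering and ranking. Per-stage TSVs, a machine-readable
#' `summary.json` and a log with seeds and versions are written to the
#' output directory; partial outputs are retained if a later stage fails.
#' Deterministic given the configured seeds.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report`: the stage results, the selected sets and
#'   input gene list, the ranked candidates, the summary list and its
#'   md5 hash.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("graftgsa %s | seed %d | mode %s",
       as.character(utils::packageVersion("graftgsa")),
       config$gsa$rng_seed, config$gsa$mode)

  gsa_one <- function(expr_path, pheno_path, tag) {
    .stage(paste0("gsa_", tag), {
      expr <- filter_complete_genes(read_expression_table(expr_path))
      ann <- read_phenotype_table(pheno_path, levels = config$group_levels)
      coll <- read_gmt(config$gmt)
      res <- run_gsa(expr, ann, coll, config$gsa)
      write_gsa_result(res, file.path(config$out_dir, sprintf("gsa_%s.tsv", tag)))
      logf("gsa_%s: %d sets scored, %d significant", tag, nrow(res$result),
           sum(res$result$significant))
      list(result = res, genes = rownames(expr), collection = coll)
    })
  }

  a <- gsa_one(config$expr_a, config$pheno_a, "a")
  two <- !is.null(config$expr_b)
  scored_genes <- a$genes
  if (two) {
    b <- gsa_one(config$expr_b, config$pheno_b, "b")
    scored_genes <- union(scored_genes, b$genes)
    replicated <- .stage("replication", {
      r <- replicate_across_datasets(a$result, b$result, config$gsa$fdr_threshold)
      readr::write_tsv(r, file.path(config$out_dir, "replicated.tsv"))
      logf("replication: %d set(s) replicate at FDR <= %.2f", nrow(r),
           config$gsa$fdr_threshold)
      r
    })
    selected <- replicated$set
  } else {
    b <- NULL
    replicated <- NULL
    selected <- a$result$result$set[a$result$result$significant]
    logf("single-dataset mode: %d significant set(s) selected", length(selected))
  }
  if (!is.null(config$selected_sets)) selected <- intersect(selected, config$selected_sets)
  if (!length(selected)) stop("pipeline stage 'set_selection' failed: no set selected",
                              call. = FALSE)

  input_genes <- .stage("gene_union", {
    g <- sort(intersect(
      unique(unlist(lapply(selected, function(s) set_members(a$collection, s)))),
      scored_genes))
    readr::write_lines(g, file.path(config$out_dir, "input_genes.txt"))
    logf("gene union over %d selected set(s): %d gene(s)", length(selected), length(g))
    g
  })

  ranked <- .stage("repositioning", {
    it <- read_interaction_table(config$interactions)
    cmp <- read_compound_table(config$compounds)
    lk <- lookup_compounds(it, input_genes)
    report <- filter_candidates(lk, cmp, it, config$filter, input_genes = input_genes)
    rk <- rank_candidates(report)
    readr::write_tsv(dplyr::select(report, -"matched_genes", -"qualifying_targets"),
                     file.path(config$out_dir, "candidate_report.tsv"))
    readr::write_tsv(dplyr::select(rk, -"matched_genes", -"qualifying_targets"),
                     file.path(config$out_dir, "candidates_ranked.tsv"))
    logf("repositioning: %d compound(s) looked up, %d pass", nrow(report), nrow(rk))
    list(report = report, ranked = rk)
  })

  summary <- list(
    package_version = as.character(utils::packageVersion("graftgsa")),
    seed = config$gsa$rng_seed,
    mode = config$gsa$mode,
    two_dataset = two,
    n_sets_scored_a = nrow(a$result$result),
    n_significant_a = sum(a$result$result$significant),
    n_significant_b = if (two) sum(b$result$result$significant) else NA,
    n_replicated = if (two) nrow(replicated) else NA,
    selected_sets = selected,
    n_input_genes = length(input_genes),
    n_compounds = nrow(ranked$report),
    n_pass = nrow(ranked$ranked),
    top_candidate = if (nrow(ranked$ranked)) ranked$ranked$compound_id[1] else NA
  )
  summary_path <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  hash <- unname(tools::md5sum(summary_path))
  logf("summary written (md5 %s)", hash)

  structure(list(gsa_a = a$result, gsa_b = if (two) b$result else NULL,
                 replicated = replicated, selected_sets = selected,
                 input_genes = input_genes, report = ranked$report,
                 ranked = ranked$ranked, summary = summary,
                 summary_md5 = hash, out_dir = config$out_dir),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Discovery-to-repositioning pipeline run\n")
  cat(sprintf("  selected sets: %s\n", paste(x$selected_sets, collapse = ", ")))
  cat(sprintf("  input genes: %d; compounds looked up: %d; passing: %d\n",
              length(x$input_genes), nrow(x$report), nrow(x$ranked)))
  if (nrow(x$ranked)) {
    cat(sprintf("  top candidate: %s (%d qualifying targets)\n",
                x$ranked$name[1], x$ranked$n_qualifying[1]))
  }
  invisible(x)
}
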