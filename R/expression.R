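#' Read a genes-by-samples expression table
#'
#' Reads a tab-separated expression table (first column gene or probe
#' identifiers, header row of sample identifiers) into a numeric matrix on
#' the log2 scale. Values are assumed already normalised upstream; this
#' reader does no background correction or normalisation. Non-numeric cells
#' are recorded as `NA` so that [filter_complete_genes()] can apply the
#' completeness rule before any statistics are computed.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix (genes x samples) with gene ids as rownames and
#'   sample ids as colnames, in file order. Genes containing at least one
#'   missing value are listed in the `"incomplete_genes"` attribute.
#' @export
read_expression_table <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop("expression table needs a header line and at least one gene row", call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1L])) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("ragged row in expression table: line %d has %d fields, expected %d",
                 bad, nf[bad], nf[1L]), call. = FALSE)
  }
  header <- fields[[1L]]
  sample_ids <- header[-1L]
  if (anyDuplicated(sample_ids)) {
    dup <- unique(sample_ids[duplicated(sample_ids)])
    stop("duplicate sample ids in expression table: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  body <- fields[-1L]
  gene_ids <- vapply(body, `[[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(length(sample_ids)))
  )
  mat <- if (length(sample_ids) == 1L) matrix(vals, ncol = 1L) else t(vals)
  dimnames(mat) <- list(gene_ids, sample_ids)
  incomplete <- gene_ids[rowSums(is.na(mat)) > 0L]
  attr(mat, "incomplete_genes") <- incomplete
  mat
}

#' Write an expression matrix as TSV
#'
#' @param mat Numeric matrix, genes x samples, with dimnames.
#' @param path Output path.
#' @param id_column Name for the first (gene id) column.
#' @export
write_expression_table <- function(mat, path, id_column = "gene") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- tibble::as_tibble(mat, rownames = id_column)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Keep only genes observed in every sample
#'
#' Applies the completeness rule used throughout the pipeline: a gene is
#' retained only if it has a finite expression value in every sample. Row
#' order is preserved; the number of dropped genes is reported via message
#' and the `"n_dropped"` attribute. Idempotent.
#'
#' @param mat Expression matrix possibly containing `NA` entries.
#' @return The sub-matrix of complete genes.
#' @export
filter_complete_genes <- function(mat) {
  stopifnot(is.matrix(mat))
  keep <- rowSums(!is.finite(mat)) == 0L
  if (!any(keep)) {
    stop("no gene has a complete set of expression values; input unusable", call. = FALSE)
  }
  out <- mat[keep, , drop = FALSE]
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(sprintf("filter_complete_genes: dropped %d gene(s) with missing values", n_dropped))
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Collapse probes to gene symbols by minimum standard error of the mean
#'
#' When several array probe-sets map to the same gene symbol, the probe-set
#' with the smallest standard error of the mean (SEM, sd/sqrt(n), sample sd
#' with n-1 denominator) across the declared reference samples is retained.
#' Ties are broken by probe id lexicographic order. Probes absent from the
#' probe map are excluded and listed in the `"unmapped_probes"` attribute.
#'
#' With `keep_discordant = TRUE` and `discordant_groups` given (two named
#' character vectors of sample ids), a gene whose minimum-SEM probe differs
#' between the two sample subsets keeps both probes, with rownames
#' `"symbol|probe"` to stay unambiguous. Off by default.
#'
#' @param mat Probe-level expression matrix (probes x samples).
#' @param probe_map Data frame with columns `probe_id`, `gene_symbol`.
#' @param reference_samples Character vector of sample ids used for the SEM.
#' @param keep_discordant Keep both probes when the two reference subsets
#'   disagree on the minimum-SEM probe.
#' @param discordant_groups List of two character vectors of sample ids,
#'   required when `keep_discordant = TRUE`.
#' @return Expression matrix with one row per mapped gene symbol (or
#'   `symbol|probe` rows for discordant genes).
#' @export
collapse_probes <- function(mat, probe_map, reference_samples,
                            keep_discordant = FALSE, discordant_groups = NULL) {
  stopifnot(is.matrix(mat), all(c("probe_id", "gene_symbol") %in% names(probe_map)))
  if (!all(reference_samples %in% colnames(mat))) {
    stop("reference_samples must be a subset of the matrix sample ids", call. = FALSE)
  }
  pm <- tibble::as_tibble(probe_map)
  pm$gene_symbol <- trimws(pm$gene_symbol)
  if (any(!nzchar(pm$gene_symbol))) stop("probe_map contains empty gene symbols", call. = FALSE)
  if (anyDuplicated(pm$probe_id)) stop("probe_map maps a probe to more than one symbol", call. = FALSE)

  probes <- rownames(mat)
  unmapped <- setdiff(probes, pm$probe_id)
  if (length(unmapped)) {
    message(sprintf("collapse_probes: %d probe(s) absent from probe_map, excluded", length(unmapped)))
  }
  pm <- pm[pm$probe_id %in% probes, , drop = FALSE]

  sem_of <- function(probe, samples) {
    x <- mat[probe, samples]
    stats::sd(x) / sqrt(length(x))
  }
  pick <- function(probe_ids, samples) {
    sems <- vapply(probe_ids, sem_of, numeric(1), samples = samples)
    ord <- order(sems, probe_ids)  # lexicographic tie-break on probe id
    probe_ids[ord[1L]]
  }

  by_gene <- split(pm$probe_id, pm$gene_symbol)
  chosen <- lapply(names(by_gene), function(sym) {
    pr <- sort(by_gene[[sym]])
    best <- pick(pr, reference_samples)
    if (keep_discordant && length(pr) > 1L) {
      if (is.null(discordant_groups) || length(discordant_groups) != 2L) {
        stop("keep_discordant = TRUE requires discordant_groups (two sample-id vectors)",
             call. = FALSE)
      }
      best_a <- pick(pr, discordant_groups[[1L]])
      best_b <- pick(pr, discordant_groups[[2L]])
      if (best_a != best_b) {
        return(tibble::tibble(symbol = paste(sym, c(best_a, best_b), sep = "|"),
                              probe = c(best_a, best_b)))
      }
    }
    tibble::tibble(symbol = sym, probe = best)
  })
  sel <- dplyr::bind_rows(chosen)
  out <- mat[sel$probe, , drop = FALSE]
  rownames(out) <- sel$symbol
  attr(out, "unmapped_probes") <- unmapped
  out
}

#' Build a sample annotation table with ordinal phenotype coding
#'
#' Annotates samples with an ordered group label (defaults follow the
#' Banff-style severity scale D0 < STA < BL < ARIA < ARIB) and the integer
#' ordinal code used by quantitative gene-set analysis (0-based rank of the
#' group in the declared order).
#'
#' @param sample_id Character vector of unique sample ids.
#' @param group Character vector of group labels, same length.
#' @param levels Ordered character vector of allowed group labels
#'   (lowest first). Must have at least two levels.
#' @param ... Additional covariate vectors (e.g. `c4d = ...`), recycled rules
#'   as in [tibble::tibble()].
#' @return A tibble with columns `sample_id`, `group` (factor with the
#'   declared level order), `ordinal_code`, plus covariates.
#' @export
sample_annotation <- function(sample_id, group,
                              levels = c("D0", "STA", "BL", "ARIA", "ARIB"),
                              ...) {
  if (length(levels) < 2L) stop("group order must declare at least two levels", call. = FALSE)
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in annotation", call. = FALSE)
  if (!all(group %in% levels)) {
    stop("unknown group label(s): ", paste(unique(setdiff(group, levels)), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    sample_id = as.character(sample_id),
    group = factor(group, levels = levels),
    ordinal_code = match(group, levels) - 1L,
    ...
  )
}

#' Read a phenotype table
#'
#' Expects a TSV with columns `sample_id` and `group` plus optional covariate
#' columns; the group order is declared by the caller, not inferred from the
#' file.
#'
#' @param path Path to a TSV file.
#' @param levels Ordered group levels, lowest first.
#' @return A sample annotation tibble (see [sample_annotation()]).
#' @export
read_phenotype_table <- function(path, levels = c("D0", "STA", "BL", "ARIA", "ARIB")) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop("phenotype table must have columns sample_id and group", call. = FALSE)
  }
  extra <- df[setdiff(names(df), c("sample_id", "group"))]
  ann <- sample_annotation(df$sample_id, df$group, levels = levels)
  dplyr::bind_cols(ann, extra)
}

#' Write a phenotype table
#' @param annotation A sample annotation tibble.
#' @param path Output path.
#' @export
write_phenotype_table <- function(annotation, path) {
  df <- annotation
  df$group <- as.character(df$group)
  readr::write_tsv(df[setdiff(names(df), "ordinal_code")], path)
  invisible(path)
}
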