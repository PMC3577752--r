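# run code under a local, restored RNG state
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Describe a planted gene-set effect
#'
#' @param name Set name.
#' @param size Number of member genes.
#' @param effect `"two_class_shift"` (a mean shift of `delta` noise-SDs in
#'   the affected groups) or `"ordinal_trend"` (a slope of `beta` noise-SDs
#'   per ordinal step).
#' @param delta Shift size in units of the noise SD (default 0.5).
#' @param beta Trend slope in noise-SDs per ordinal step (default 0.25).
#' @param fraction Fraction of members carrying the effect, in (0, 1]
#'   (default 0.6, emulating partial pathway activation).
#' @param affected_groups Groups receiving the two-class shift; default all
#'   levels after the first.
#' @return A list describing the planted set.
#' @export
planted_set <- function(name, size, effect = c("two_class_shift", "ordinal_trend"),
                        delta = 0.5, beta = 0.25, fraction = 0.6,
                        affected_groups = NULL) {
  effect <- match.arg(effect)
  stopifnot(size >= 1L, fraction > 0, fraction <= 1)
  list(name = name, size = as.integer(size), effect = effect,
       delta = delta, beta = beta, fraction = fraction,
       affected_groups = affected_groups)
}

#' Specification for a synthetic rejection-cohort expression study
#'
#' Defaults emulate the discovery cohort structure: five ordered phenotype
#' groups with sizes 33/16/4/7/6 (D0 through ARIB), log-normal-style
#' expression noise on the log2 scale, planted enriched sets with partial
#' penetrance, and null sets drawn from unaffected genes.
#'
#' @param n_genes Number of genes.
#' @param group_sizes Named integer vector, names in severity order
#'   (lowest first).
#' @param baseline_mean,baseline_sd Per-gene baseline log2 expression is
#'   drawn once from `N(baseline_mean, baseline_sd)`.
#' @param noise_sd Residual SD on the log2 scale (default 1).
#' @param planted_sets List of [planted_set()] descriptions.
#' @param n_null_sets,null_set_size Null sets drawn uniformly from
#'   unaffected genes.
#' @param seed RNG seed.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_genes = 2000L,
                            group_sizes = c(D0 = 33L, STA = 16L, BL = 4L,
                                            ARIA = 7L, ARIB = 6L),
                            baseline_mean = 8, baseline_sd = 1.5, noise_sd = 1,
                            planted_sets = list(), n_null_sets = 30L,
                            null_set_size = 50L, seed = 1L) {
  stopifnot(n_genes >= 1L, all(group_sizes >= 0L), length(group_sizes) >= 2L,
            !is.null(names(group_sizes)), noise_sd >= 0, n_null_sets >= 0L)
  total_planted <- sum(vapply(planted_sets, `[[`, integer(1), "size"))
  if (total_planted > n_genes) stop("planted sets larger than the gene pool", call. = FALSE)
  if (n_null_sets > 0L && null_set_size > n_genes - total_planted) {
    stop("null sets cannot fit in the unaffected gene pool", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes), group_sizes = group_sizes,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 noise_sd = noise_sd, planted_sets = planted_sets,
                 n_null_sets = as.integer(n_null_sets),
                 null_set_size = as.integer(null_set_size),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate an expression study with known ground truth
#'
#' Gene g in sample s is `baseline_g + effect_g(group_s) + N(0, noise_sd)`.
#' Two-class shifts add `delta * noise_sd` to the affected fraction of a
#' planted set's members in the designated groups; ordinal trends add
#' `beta * noise_sd * ordinal_code`. Null sets are drawn uniformly from
#' unaffected genes. Deterministic given the spec seed.
#'
#' @param spec A [simulation_spec()].
#' @return List with `expression` (matrix), `annotation` (tibble),
#'   `collection` (planted + null sets), and `truth` (planted set names,
#'   per-gene effects, null set names).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  .with_seed(spec$seed, {
    levels <- names(spec$group_sizes)
    group <- rep(levels, times = spec$group_sizes)
    sample_id <- sprintf("%s_%02d", group, unlist(lapply(spec$group_sizes, seq_len)))
    ann <- sample_annotation(sample_id, group, levels = levels)
    n <- spec$n_genes
    genes <- sprintf("G%05d", seq_len(n))
    baseline <- stats::rnorm(n, spec$baseline_mean, spec$baseline_sd)

    effect <- matrix(0, nrow = n, ncol = length(sample_id),
                     dimnames = list(genes, sample_id))
    next_gene <- 1L
    planted_members <- list()
    affected_all <- character()
    gene_effects <- list()
    for (ps in spec$planted_sets) {
      members <- genes[next_gene:(next_gene + ps$size - 1L)]
      next_gene <- next_gene + ps$size
      n_aff <- max(1L, round(ps$fraction * ps$size))
      aff <- members[seq_len(n_aff)]
      if (ps$effect == "two_class_shift") {
        groups_hit <- ps$affected_groups %||% levels[-1L]
        cols <- ann$sample_id[as.character(ann$group) %in% groups_hit]
        effect[aff, cols] <- effect[aff, cols] + ps$delta * spec$noise_sd
        par <- ps$delta
      } else {
        codes <- ann$ordinal_code
        effect[aff, ] <- effect[aff, ] +
          matrix(rep(ps$beta * spec$noise_sd * codes, each = length(aff)),
                 nrow = length(aff))
        par <- ps$beta
      }
      planted_members[[ps$name]] <- members
      affected_all <- c(affected_all, aff)
      gene_effects[[ps$name]] <- tibble::tibble(
        gene = members, set = ps$name, effect = ps$effect,
        parameter = par, affected = members %in% aff
      )
    }

    pool <- setdiff(genes, affected_all)
    null_members <- lapply(seq_len(spec$n_null_sets), function(i) {
      sort(sample(pool, spec$null_set_size))
    })
    null_names <- sprintf("NULL_SET_%03d", seq_len(spec$n_null_sets))
    names(null_members) <- null_names

    all_members <- c(planted_members, null_members)
    collection <- geneset_collection(names(all_members), unname(all_members),
                                     description = "synthetic",
                                     provenance = "synthetic")

    noise <- matrix(stats::rnorm(n * length(sample_id), 0, spec$noise_sd),
                    nrow = n)
    expr <- baseline + effect + noise
    dimnames(expr) <- list(genes, sample_id)

    list(expression = expr, annotation = ann, collection = collection,
         truth = list(planted_sets = names(planted_members),
                      gene_effects = dplyr::bind_rows(gene_effects),
                      null_sets = null_names,
                      spec = spec))
  })
}

#' Simulate a compound-gene interaction table with planted candidates
#'
#' Generates a compound table and interaction records over an input gene
#' list such that exactly `n_qualifying` compounds satisfy all default
#' repositioning filters (direct inhibition of at least `min_targets` input
#' genes including the required gene, FDA-approved small molecule). Decoy
#' compounds each violate exactly one report flag (target count, required
#' gene, FDA status, modality), covering every filter; background
#' compounds carry too few qualifying interactions to ever pass.
#'
#' @param input_genes Character vector of disease input genes; must contain
#'   `config$required_genes`.
#' @param n_compounds Total compounds appearing in the lookup (default 300).
#' @param n_qualifying Number of planted passing compounds (default 4).
#' @param config The [filter_config()] the planted compounds must satisfy.
#' @param seed RNG seed.
#' @return List with `interactions`, `compounds`, `truth` (qualifying ids
#'   and decoy flag assignments).
#' @export
simulate_interactions <- function(input_genes, n_compounds = 300L,
                                  n_qualifying = 4L, config = filter_config(),
                                  seed = 1L) {
  req <- config$required_genes
  if (!all(req %in% input_genes)) stop("required gene(s) must be in input_genes", call. = FALSE)
  others <- setdiff(input_genes, req)
  if (length(others) < config$min_targets + 1L) {
    stop("need more input genes than min_targets to build decoys", call. = FALSE)
  }
  decoy_classes <- c("enough_targets", "has_required", "fda_ok", "modality_ok")
  if (n_compounds < n_qualifying + length(decoy_classes)) {
    stop("n_compounds too small for the planted structure", call. = FALSE)
  }
  .with_seed(seed, {
    ids <- sprintf("C%04d", seq_len(n_compounds))
    qual_ids <- ids[seq_len(n_qualifying)]
    decoy_ids <- ids[n_qualifying + seq_along(decoy_classes)]
    bg_ids <- setdiff(ids, c(qual_ids, decoy_ids))

    rec <- function(cid, gene, mech, direct) {
      tibble::tibble(compound_id = cid, gene = gene, mechanism = mech,
                     direct = direct,
                     evidence_id = sprintf("PMID:%07d",
                                           sample.int(9999999, length(gene), replace = TRUE)))
    }
    inter <- list()
    meta <- list()

    for (cid in qual_ids) {
      k <- config$min_targets + sample.int(3, 1) - 1L   # >= min_targets targets
      g <- c(req, sample(others, k - length(req)))
      inter[[length(inter) + 1L]] <- rec(cid, g, "inhibition", TRUE)
      meta[[length(meta) + 1L]] <- tibble::tibble(
        compound_id = cid, name = paste0("drug_", cid),
        fda_approved = TRUE, modality = "small_molecule")
    }
    for (j in seq_along(decoy_classes)) {
      cid <- decoy_ids[j]
      fails <- decoy_classes[j]
      fda <- fails != "fda_ok"
      modality <- if (fails == "modality_ok") "biologic" else "small_molecule"
      if (fails == "enough_targets") {
        g <- c(req, sample(others, max(0L, config$min_targets - 1L - length(req))))
        inter[[length(inter) + 1L]] <- rec(cid, g, "inhibition", TRUE)
      } else if (fails == "has_required") {
        g <- sample(others, config$min_targets)
        inter[[length(inter) + 1L]] <- rec(cid, g, "inhibition", TRUE)
        inter[[length(inter) + 1L]] <- rec(cid, req, "activation", TRUE)
      } else {
        g <- c(req, sample(others, config$min_targets - length(req) + 1L))
        inter[[length(inter) + 1L]] <- rec(cid, g, "inhibition", TRUE)
      }
      meta[[length(meta) + 1L]] <- tibble::tibble(
        compound_id = cid, name = paste0("drug_", cid),
        fda_approved = fda, modality = modality)
    }
    for (cid in bg_ids) {
      k <- sample.int(config$min_targets - 1L, 1)       # can never reach the count
      g <- sample(others, k)
      mech <- sample(c("inhibition", "activation", "unspecified"), k, replace = TRUE)
      direct <- sample(c(TRUE, FALSE), k, replace = TRUE)
      inter[[length(inter) + 1L]] <- rec(cid, g, mech, direct)
      meta[[length(meta) + 1L]] <- tibble::tibble(
        compound_id = cid, name = paste0("drug_", cid),
        fda_approved = sample(c(TRUE, FALSE), 1), modality = "small_molecule")
    }

    list(interactions = dplyr::bind_rows(inter),
         compounds = dplyr::bind_rows(meta),
         truth = list(qualifying = qual_ids,
                      decoys = tibble::tibble(compound_id = decoy_ids,
                                              fails = decoy_classes)))
  })
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' The endogenous-control gene gets a constant base Ct plus noise; each
#' target gene's Ct is its base Ct minus log2 of the sample's true relative
#' expression plus noise, replicated per specimen. A calibrator specimen
#' (relative expression 1 for every gene) is included. With zero noise the
#' delta-delta-Ct pipeline recovers the planted values exactly.
#'
#' @param rel_expr Tibble `gene`, `group`, `rel` of true relative
#'   expression per target gene and group (calibrator scale: 1 means equal
#'   to calibrator).
#' @param group_sizes Named integer vector of specimens per group.
#' @param control_gene Endogenous control gene name.
#' @param calibrator Calibrator sample id.
#' @param target_base_ct,control_base_ct Base cycle thresholds.
#' @param noise_sd Ct noise SD in cycles (default 0.3).
#' @param n_replicates Technical replicates per specimen/gene (default 2).
#' @param seed RNG seed.
#' @return List with `ct` (tibble `sample`, `gene`, `role`, `ct`,
#'   `replicate`) and `truth` (the `rel_expr` table plus naming).
#' @export
simulate_ct <- function(rel_expr, group_sizes, control_gene = "RNA18S",
                        calibrator = "universal", target_base_ct = 24,
                        control_base_ct = 15, noise_sd = 0.3,
                        n_replicates = 2L, seed = 1L) {
  rel_expr <- tibble::as_tibble(rel_expr)
  stopifnot(all(c("gene", "group", "rel") %in% names(rel_expr)),
            all(rel_expr$rel > 0), all(names(group_sizes) %in% rel_expr$group))
  .with_seed(seed, {
    samples <- tibble::tibble(
      sample = sprintf("%s_%02d", rep(names(group_sizes), group_sizes),
                       unlist(lapply(group_sizes, seq_len))),
      group = rep(names(group_sizes), group_sizes)
    )
    genes <- unique(rel_expr$gene)
    grid <- tidyr::expand_grid(samples, gene = genes,
                               replicate = seq_len(n_replicates)) |>
      dplyr::left_join(rel_expr, by = c("gene", "group")) |>
      dplyr::mutate(
        role = "target",
        ct = target_base_ct - log2(.data$rel) +
          stats::rnorm(dplyr::n(), 0, noise_sd)
      )
    ctrl <- tidyr::expand_grid(samples, gene = control_gene,
                               replicate = seq_len(n_replicates)) |>
      dplyr::mutate(role = "endogenous_control",
                    ct = control_base_ct + stats::rnorm(dplyr::n(), 0, noise_sd))
    cal <- tidyr::expand_grid(sample = calibrator,
                              gene = c(genes, control_gene),
                              replicate = seq_len(n_replicates)) |>
      dplyr::mutate(
        role = ifelse(.data$gene == control_gene, "endogenous_control", "target"),
        ct = ifelse(.data$gene == control_gene, control_base_ct, target_base_ct) +
          stats::rnorm(dplyr::n(), 0, noise_sd)
      )
    ct <- dplyr::bind_rows(
      dplyr::select(grid, "sample", "gene", "role", "ct", "replicate"),
      dplyr::select(ctrl, "sample", "gene", "role", "ct", "replicate"),
      dplyr::select(cal, "sample", "gene", "role", "ct", "replicate")
    )
    list(ct = ct,
         truth = list(rel_expr = rel_expr, control_gene = control_gene,
                      calibrator = calibrator, groups = samples))
  })
}

#' Write a simulated expression study to disk
#'
#' Emits `expr.tsv`, `pheno.tsv`, `sets.gmt` and `truth.json`, all readable
#' by the package's own readers.
#'
#' @param sim Output of [simulate_expression()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulated_expression <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_table(sim$expression, file.path(dir, "expr.tsv"))
  write_phenotype_table(sim$annotation, file.path(dir, "pheno.tsv"))
  write_gmt(sim$collection, file.path(dir, "sets.gmt"))
  truth <- sim$truth
  truth$spec <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Write a simulated interaction study to disk
#' @param sim Output of [simulate_interactions()].
#' @param dir Output directory.
#' @export
write_simulated_interactions <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(sim$interactions, file.path(dir, "interactions.tsv"))
  readr::write_tsv(sim$compounds, file.path(dir, "compounds.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
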