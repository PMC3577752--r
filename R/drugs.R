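#' Filter settings for drug-repositioning candidates
#'
#' Defaults encode the screening rule used for the rejection gene list:
#' direct inhibition of at least five input genes including IL17A, by an
#' FDA-approved small molecule.
#'
#' @param min_targets Minimum number of qualifying input-gene targets.
#' @param required_genes Genes that must be among the qualifying targets.
#' @param mechanism_required Interaction mechanism that counts
#'   (`"inhibition"`, `"activation"`, or `NA` for any).
#' @param direct_required Only direct interactions count (default TRUE).
#' @param fda_only Require FDA approval (default TRUE).
#' @param modality_allowed Allowed compound modalities.
#' @param count_requires_mechanism If FALSE, the target count uses any
#'   interaction on input genes while the required genes still need the
#'   mechanism/direct match (the looser reading of "targeting at least 5
#'   genes").
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_targets = 5L, required_genes = "IL17A",
                          mechanism_required = "inhibition",
                          direct_required = TRUE, fda_only = TRUE,
                          modality_allowed = "small_molecule",
                          count_requires_mechanism = TRUE) {
  stopifnot(min_targets >= 1L)
  structure(list(min_targets = as.integer(min_targets),
                 required_genes = required_genes,
                 mechanism_required = mechanism_required,
                 direct_required = direct_required,
                 fda_only = fda_only,
                 modality_allowed = modality_allowed,
                 count_requires_mechanism = count_requires_mechanism),
            class = "filter_config")
}

#' Map compounds to the input genes they interact with
#'
#' Every compound with at least one interaction record touching the input
#' gene list appears in the output, with its deduplicated matched gene set
#' (any mechanism; the mechanism constraints are applied later by
#' [filter_candidates()]).
#'
#' @param interactions Data frame with columns `compound_id`, `gene`,
#'   `mechanism`, `direct`, `evidence_id`.
#' @param input_genes Nonempty character vector of disease genes.
#' @return Tibble `compound_id`, `matched_genes` (list-column),
#'   `n_matched`.
#' @export
lookup_compounds <- function(interactions, input_genes) {
  if (!length(input_genes)) stop("input_genes must be nonempty", call. = FALSE)
  it <- tibble::as_tibble(interactions)
  if (!nrow(it)) {
    warning("empty interaction table; no compounds matched", call. = FALSE)
    return(tibble::tibble(compound_id = character(), matched_genes = list(),
                          n_matched = integer()))
  }
  it |>
    dplyr::filter(.data$gene %in% input_genes) |>
    dplyr::distinct(.data$compound_id, .data$gene) |>
    dplyr::summarise(matched_genes = list(sort(.data$gene)),
                     .by = "compound_id") |>
    dplyr::mutate(n_matched = lengths(.data$matched_genes)) |>
    dplyr::arrange(.data$compound_id)
}

#' Apply the repositioning filters to looked-up compounds
#'
#' A compound passes when (a) it targets at least `min_targets` input genes
#' with the required mechanism and directness, (b) those qualifying targets
#' include every required gene, (c) it is FDA-approved if `fda_only`, and
#' (d) its modality is allowed. Every compound in the lookup map is
#' reported exactly once with per-filter flags; compounds without a
#' metadata row fail with the `no_metadata` flag.
#'
#' @param lookup Output of [lookup_compounds()].
#' @param compounds Data frame with columns `compound_id`, `name`,
#'   `fda_approved`, `modality`.
#' @param interactions The interaction table (for the mechanism-constrained
#'   counts). Input genes are taken from the lookup's matched genes.
#' @param config A [filter_config()].
#' @param input_genes Character vector of input genes (defaults to the
#'   union of matched genes in `lookup`).
#' @return A `candidate_report` tibble: per-compound flags, qualifying
#'   target count and list, and `pass`.
#' @export
filter_candidates <- function(lookup, compounds, interactions,
                              config = filter_config(),
                              input_genes = NULL) {
  it <- tibble::as_tibble(interactions)
  cmp <- tibble::as_tibble(compounds)
  if (anyDuplicated(cmp$compound_id)) stop("duplicate compound_id in compound table", call. = FALSE)
  if (is.null(input_genes)) input_genes <- unique(unlist(lookup$matched_genes))

  qual <- it |>
    dplyr::filter(.data$gene %in% input_genes)
  if (!is.na(config$mechanism_required)) {
    qual <- dplyr::filter(qual, .data$mechanism == config$mechanism_required)
  }
  if (isTRUE(config$direct_required)) qual <- dplyr::filter(qual, .data$direct)
  qual_map <- qual |>
    dplyr::distinct(.data$compound_id, .data$gene) |>
    dplyr::summarise(qualifying_targets = list(sort(.data$gene)), .by = "compound_id")

  count_map <- if (config$count_requires_mechanism) {
    qual_map |> dplyr::mutate(n_qualifying = lengths(.data$qualifying_targets)) |>
      dplyr::select("compound_id", "n_qualifying")
  } else {
    lookup |> dplyr::transmute(.data$compound_id, n_qualifying = .data$n_matched)
  }

  rep <- lookup |>
    dplyr::left_join(qual_map, by = "compound_id") |>
    dplyr::left_join(count_map, by = "compound_id") |>
    dplyr::left_join(cmp, by = "compound_id") |>
    dplyr::mutate(
      qualifying_targets = purrr::map(.data$qualifying_targets,
                                      \(x) if (is.null(x)) character() else x),
      n_qualifying = dplyr::coalesce(.data$n_qualifying, 0L),
      has_metadata = !is.na(.data$name),
      enough_targets = .data$n_qualifying >= config$min_targets,
      has_required = purrr::map_lgl(.data$qualifying_targets,
                                    \(x) all(config$required_genes %in% x)),
      fda_ok = if (config$fda_only) dplyr::coalesce(.data$fda_approved, FALSE) else TRUE,
      modality_ok = dplyr::coalesce(.data$modality %in% config$modality_allowed, FALSE),
      no_metadata = !.data$has_metadata,
      pass = .data$has_metadata & .data$enough_targets & .data$has_required &
        .data$fda_ok & .data$modality_ok
    )
  if (any(rep$no_metadata)) {
    message("compound(s) without metadata failed with flag no_metadata: ",
            paste(rep$compound_id[rep$no_metadata], collapse = ", "))
  }
  out <- rep |>
    dplyr::select("compound_id", "name", "matched_genes", "n_matched",
                  "qualifying_targets", "n_qualifying", "enough_targets",
                  "has_required", "fda_ok", "modality_ok", "has_metadata", "pass")
  class(out) <- c("candidate_report", class(out))
  attr(out, "config") <- config
  out
}

#' Rank passing repositioning candidates
#'
#' Descending by qualifying target count, ties broken by compound name
#' lexicographically; deterministic.
#'
#' @param report A `candidate_report`.
#' @return Tibble of passing compounds in rank order.
#' @export
rank_candidates <- function(report) {
  report |>
    dplyr::filter(.data$pass) |>
    dplyr::arrange(dplyr::desc(.data$n_qualifying), .data$name) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
}

#' Plot a candidate report
#'
#' Qualifying target counts per compound, pass/fail coloured, passing
#' compounds labelled.
#' @param object A `candidate_report`.
#' @param top Show at most this many compounds (by count; default 30).
#' @param ... Unused.
#' @export
autoplot.candidate_report <- function(object, top = 30, ...) {
  d <- object |>
    dplyr::arrange(dplyr::desc(.data$n_qualifying)) |>
    utils::head(top)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$compound_id, .data$n_qualifying),
                                  y = .data$n_qualifying, fill = .data$pass)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "qualifying input-gene targets", fill = "passes filters") +
    ggplot2::theme_minimal()
}

#' Read / write interaction and compound tables
#'
#' Interactions: TSV `compound_id`, `gene`, `mechanism`, `direct`,
#' `evidence_id`. Compounds: TSV `compound_id`, `name`, `fda_approved`,
#' `modality`.
#' @param path File path.
#' @export
read_interaction_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(compound_id = "c", gene = "c",
                                          mechanism = "c", direct = "l",
                                          evidence_id = "c"))
}

#' @rdname read_interaction_table
#' @export
read_compound_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(compound_id = "c", name = "c",
                                          fda_approved = "l", modality = "c"))
}
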