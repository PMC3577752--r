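#' Curate an activated-immune-cell gene-set from a differential table
#'
#' Builds a gene-set from a differential-expression table by the rule used
#' for the activated-immune-cell (AcIc) sets: a gene is a member when its
#' fold change reaches the threshold (non-strict, linear scale), its
#' direction matches, and its p-value is below the threshold (strict).
#' Membership is deduplicated by symbol: a symbol passing in any row is
#' included once.
#'
#' @param diff_table Data frame with columns `gene`, `fold_change`
#'   (non-negative, linear scale), `direction` (`"up"` or `"down"`),
#'   `p_value` (in `[0, 1]`).
#' @param set_name Name for the curated set.
#' @param fc_threshold Minimum fold change (default 2, i.e. 2-fold).
#' @param p_threshold p-value must be strictly below this (default 0.05).
#' @param direction Required direction, `"up"` (default) or `"down"`.
#' @param description Description stored with the set.
#' @return A `geneset` (list with `name`, `description`, `members`).
#' @export
curate_set <- function(diff_table, set_name, fc_threshold = 2, p_threshold = 0.05,
                       direction = c("up", "down"),
                       description = sprintf("curated: fc>=%g, p<%g", fc_threshold, p_threshold)) {
  direction <- match.arg(direction)
  stopifnot(fc_threshold >= 1, p_threshold > 0, p_threshold <= 1)
  df <- tibble::as_tibble(diff_table)
  req <- c("gene", "fold_change", "direction", "p_value")
  if (!all(req %in% names(df))) {
    stop("differential table needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (!nrow(df)) stop("differential table is empty", call. = FALSE)
  if (any(df$fold_change < 0, na.rm = TRUE)) stop("fold_change must be non-negative", call. = FALSE)
  if (any(df$p_value < 0 | df$p_value > 1, na.rm = TRUE)) stop("p_value outside [0, 1]", call. = FALSE)
  pass <- df$fold_change >= fc_threshold &
    df$direction == direction &
    df$p_value < p_threshold
  members <- sort(unique(trimws(df$gene[pass & !is.na(pass)])))
  if (!length(members)) {
    stop("no gene passes the curation thresholds; a gene-set must be nonempty", call. = FALSE)
  }
  structure(list(name = set_name, description = description, members = members),
            class = "geneset")
}

#' Assemble curated gene-sets into a collection
#'
#' @param sets A list of `geneset` objects (see [curate_set()]).
#' @param provenance Label for the collection (default "AcIc-curated").
#' @return A `geneset_collection`; per-set member counts are reported via
#'   message.
#' @export
assemble_collection <- function(sets, provenance = "AcIc-curated") {
  if (!length(sets)) stop("need at least one gene-set", call. = FALSE)
  nm <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate set names: ", paste(unique(nm[duplicated(nm)]), collapse = ", "),
         call. = FALSE)
  }
  coll <- geneset_collection(
    set = nm,
    members = lapply(sets, `[[`, "members"),
    description = vapply(sets, `[[`, character(1), "description"),
    provenance = provenance
  )
  message(paste(sprintf("%s: %d genes", coll$set, lengths(coll$members)), collapse = "; "))
  coll
}

#' Read a differential-expression table
#'
#' TSV with columns `gene`, `fold_change`, `direction`, `p_value`.
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_differential_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(gene = "c", fold_change = "d",
                                          direction = "c", p_value = "d"))
}
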