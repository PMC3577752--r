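#' Relative quantity by the delta-delta-Ct method
#'
#' Classic comparative-Ct quantification with amplification efficiency
#' fixed at 2: `dCt = target - control` per specimen,
#' `ddCt = dCt_sample - dCt_calibrator`, `RQ = 2^(-ddCt)`. Inputs are mean
#' Ct values (average replicates on the Ct scale first); any missing
#' component (non-detect) yields `NA`.
#'
#' @param target_ct,control_ct Mean Ct of the target and endogenous-control
#'   gene in the specimen.
#' @param calibrator_target_ct,calibrator_control_ct Same for the
#'   calibrator (e.g. universal reference RNA).
#' @return Relative quantity (dimensionless, > 0), vectorised.
#' @export
delta_delta_ct <- function(target_ct, control_ct,
                           calibrator_target_ct, calibrator_control_ct) {
  ddct <- (target_ct - control_ct) - (calibrator_target_ct - calibrator_control_ct)
  2^(-ddct)
}

#' Per-sample relative quantities from a Ct table
#'
#' Averages replicate Ct values per sample and gene, forms delta-Ct against
#' the endogenous control, references against the calibrator sample, and
#' returns one RQ per sample per target gene. Samples with a non-detect
#' (missing Ct) in any component are returned with `NA` RQ and
#' `complete = FALSE`.
#'
#' @param ct_table Data frame with columns `sample`, `gene`, `role`
#'   (`"target"` or `"endogenous_control"`), `ct`, `replicate`. Non-detects
#'   are `NA` in `ct`.
#' @param control_gene Endogenous control gene name (e.g. `"RNA18S"`).
#' @param calibrator_sample Sample id of the calibrator specimen.
#' @param ct_range Plausible Ct range; values outside are an error.
#' @return Tibble `sample`, `gene`, `rq`, `complete` (targets only,
#'   calibrator excluded).
#' @export
relative_quantity <- function(ct_table, control_gene, calibrator_sample,
                              ct_range = c(0, 40)) {
  ct <- tibble::as_tibble(ct_table)
  req <- c("sample", "gene", "ct")
  if (!all(req %in% names(ct))) {
    stop("Ct table needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  bad <- !is.na(ct$ct) & (ct$ct < ct_range[1] | ct$ct > ct_range[2])
  if (any(bad)) {
    stop(sprintf("%d Ct value(s) outside the plausible range [%g, %g]",
                 sum(bad), ct_range[1], ct_range[2]), call. = FALSE)
  }
  if (!control_gene %in% ct$gene) {
    stop("endogenous control gene '", control_gene, "' absent from Ct table", call. = FALSE)
  }
  if (!calibrator_sample %in% ct$sample) {
    stop("calibrator sample '", calibrator_sample, "' absent from Ct table", call. = FALSE)
  }
  mean_ct <- ct |>
    dplyr::summarise(ct = mean(.data$ct), .by = c("sample", "gene"))
  ctrl <- mean_ct |>
    dplyr::filter(.data$gene == control_gene) |>
    dplyr::select("sample", control_ct = "ct")
  targ <- mean_ct |>
    dplyr::filter(.data$gene != control_gene) |>
    dplyr::left_join(ctrl, by = "sample") |>
    dplyr::mutate(dct = .data$ct - .data$control_ct)
  cal <- targ |>
    dplyr::filter(.data$sample == calibrator_sample) |>
    dplyr::select("gene", cal_dct = "dct")
  targ |>
    dplyr::filter(.data$sample != calibrator_sample) |>
    dplyr::left_join(cal, by = "gene") |>
    dplyr::mutate(rq = 2^(-(.data$dct - .data$cal_dct)),
                  complete = is.finite(.data$rq)) |>
    dplyr::select("sample", "gene", "rq", "complete")
}

#' Group fold change and t-test on relative quantities
#'
#' Compares two groups of per-sample RQ values: the fold change is the
#' ratio of group mean RQs, reported as a magnitude of at least 1 with a
#' direction (`"up"` when group A exceeds group B), and the p-value comes
#' from a two-sided Student t-test — pooled-variance unpaired by default,
#' paired when `paired = TRUE` with subject-aligned vectors.
#'
#' @param rq_a,rq_b Numeric RQ vectors (group A compared against group B).
#'   Non-finite or non-positive values are excluded with a message.
#' @param paired Paired t-test with aligned subjects.
#' @return One-row `rq_result` tibble: `fold_change` (>= 1), `direction`,
#'   `p_value`, `n_a`, `n_b`.
#' @export
group_fold_change <- function(rq_a, rq_b, paired = FALSE) {
  if (paired && length(rq_a) != length(rq_b)) {
    stop("paired comparison needs equal-length, subject-aligned vectors", call. = FALSE)
  }
  ok_a <- is.finite(rq_a) & rq_a > 0
  ok_b <- is.finite(rq_b) & rq_b > 0
  if (paired) {
    keep <- ok_a & ok_b
    if (any(!keep)) message(sum(!keep), " pair(s) excluded (undefined or non-positive RQ)")
    rq_a <- rq_a[keep]; rq_b <- rq_b[keep]
  } else {
    if (any(!ok_a) || any(!ok_b)) {
      message(sum(!ok_a) + sum(!ok_b), " RQ value(s) excluded (undefined or non-positive)")
    }
    rq_a <- rq_a[ok_a]; rq_b <- rq_b[ok_b]
  }
  if (length(rq_a) < 2L || length(rq_b) < 2L) {
    stop("each group needs at least two usable RQ values", call. = FALSE)
  }
  ratio <- mean(rq_a) / mean(rq_b)
  p_value <- tryCatch(
    stats::t.test(rq_a, rq_b, paired = paired, var.equal = !paired)$p.value,
    error = function(e) {
      message("t-test undefined (constant data); p reported as NA")
      NA_real_
    })
  out <- tibble::tibble(
    fold_change = max(ratio, 1 / ratio),
    direction = if (ratio >= 1) "up" else "down",
    p_value = p_value,
    n_a = length(rq_a), n_b = length(rq_b)
  )
  class(out) <- c("rq_result", class(out))
  out
}

#' Read a Ct table
#'
#' TSV with columns `sample`, `gene`, `role`, `ct`, `replicate`;
#' non-detects are empty cells or `NA`.
#' @param path File path.
#' @export
read_ct_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(sample = "c", gene = "c", role = "c",
                                          ct = "d", replicate = "i"),
                  na = c("", "NA", "ND"))
}
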