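#' Configuration for maxmean gene-set analysis
#'
#' @param mode `"two_class"` (pooled-t gene scores between two groups) or
#'   `"quantitative"` (regression-t gene scores on the ordinal phenotype
#'   code).
#' @param n_permutations Number of phenotype-label permutations for the
#'   null (default 1000). When the number of distinct label arrangements is
#'   at most this, exhaustive enumeration is used instead.
#' @param n_randomization_draws Random equal-size gene-sets drawn per score
#'   vector to estimate the restandardization moments (default 1000).
#' @param fdr_threshold Sets with estimated FDR at or below this are called
#'   significant (default 0.5, the discovery screen's permissive cutoff).
#' @param min_set_size Minimum overlap between a set and the scored genes
#'   (default 5); smaller sets are excluded with a reason.
#' @param s0 Additive offset on the gene-score denominator (default 0).
#' @param rng_seed Integer seed; the whole analysis is deterministic given
#'   it.
#' @return A list of class `gsa_config`.
#' @export
gsa_config <- function(mode = c("two_class", "quantitative"),
                       n_permutations = 1000L, n_randomization_draws = 1000L,
                       fdr_threshold = 0.5, min_set_size = 5L, s0 = 0,
                       rng_seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_permutations >= 1L, n_randomization_draws >= 2L,
            min_set_size >= 2L, s0 >= 0,
            fdr_threshold >= 0, fdr_threshold <= 1)
  structure(list(mode = mode,
                 n_permutations = as.integer(n_permutations),
                 n_randomization_draws = as.integer(n_randomization_draws),
                 fdr_threshold = fdr_threshold,
                 min_set_size = as.integer(min_set_size),
                 s0 = s0, rng_seed = as.integer(rng_seed)),
            class = "gsa_config")
}

# ---- gene-level scores -------------------------------------------------

#' Two-class gene scores (pooled-variance t)
#'
#' Scores every gene by the pooled-variance two-sample t-statistic between
#' the two groups present in the annotation, with an optional additive
#' offset `s0` on the standard error. The sign is positive when the second
#' (higher) group level has the larger mean. Genes whose denominator is
#' exactly zero (constant within both groups when `s0 = 0`) receive score 0
#' and are listed in the `"zero_variance"` attribute: a constant gene
#' carries no ordering information and the finite-score invariant rules out
#' infinities.
#'
#' @param expr Complete expression matrix (genes x samples).
#' @param annotation Sample annotation containing exactly two group levels,
#'   each with at least two samples.
#' @param s0 Non-negative denominator offset.
#' @return Named numeric score vector with attributes `"mode"` and
#'   `"zero_variance"`.
#' @export
gene_scores_two_class <- function(expr, annotation, s0 = 0) {
  g <- droplevels(annotation$group)
  if (nlevels(g) != 2L) stop("two-class scoring needs exactly two groups", call. = FALSE)
  if (any(table(g) < 2L)) stop("each group needs at least two samples", call. = FALSE)
  X <- expr[, annotation$sample_id, drop = FALSE]
  z <- .scores_two_class(X, g == levels(g)[2L], s0)
  zero <- attr(z, "zero_den")
  attr(z, "zero_den") <- NULL
  structure(z, mode = "two_class", zero_variance = names(z)[zero])
}

.scores_two_class <- function(X, in_group2, s0) {
  X1 <- X[, !in_group2, drop = FALSE]
  X2 <- X[, in_group2, drop = FALSE]
  n1 <- ncol(X1); n2 <- ncol(X2)
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  ss <- rowSums((X1 - m1)^2) + rowSums((X2 - m2)^2)
  se <- sqrt(ss / (n1 + n2 - 2) * (1 / n1 + 1 / n2))
  den <- se + s0
  zero <- den == 0
  z <- ifelse(zero, 0, (m2 - m1) / den)
  z <- stats::setNames(as.numeric(z), rownames(X))
  attr(z, "zero_den") <- zero
  z
}

#' Quantitative (ordinal) gene scores (regression t)
#'
#' Scores every gene by the t-statistic of the slope from simple linear
#' regression of expression on the integer ordinal phenotype code, with an
#' optional offset `s0` on the slope's standard error. With a binary 0/1
#' code this reduces algebraically to the two-class pooled t. Zero-residual
#' genes follow the same zero-variance rule as
#' [gene_scores_two_class()].
#'
#' @inheritParams gene_scores_two_class
#' @param annotation Sample annotation with an `ordinal_code` column taking
#'   at least two distinct values over at least three samples.
#' @export
gene_scores_quantitative <- function(expr, annotation, s0 = 0) {
  x <- annotation$ordinal_code
  if (length(unique(x)) < 2L) stop("constant phenotype: ordinal code never varies", call. = FALSE)
  if (length(x) < 3L) stop("quantitative scoring needs at least three samples", call. = FALSE)
  X <- expr[, annotation$sample_id, drop = FALSE]
  z <- .scores_quantitative(X, as.numeric(x), s0)
  zero <- attr(z, "zero_den")
  attr(z, "zero_den") <- NULL
  structure(z, mode = "quantitative", zero_variance = names(z)[zero])
}

.scores_quantitative <- function(X, x, s0) {
  n <- length(x)
  xc <- x - mean(x)
  Sxx <- sum(xc^2)
  b <- as.numeric(X %*% xc) / Sxx
  Syy <- rowSums((X - rowMeans(X))^2)
  s2 <- pmax(Syy - b^2 * Sxx, 0) / (n - 2)
  se <- sqrt(s2 / Sxx)
  den <- se + s0
  zero <- den == 0
  z <- stats::setNames(as.numeric(ifelse(zero, 0, b / den)), rownames(X))
  attr(z, "zero_den") <- zero
  z
}

# ---- set-level statistic ----------------------------------------------

#' Raw maxmean statistic for one gene-set
#'
#' For the member scores `z` present in the score vector, the maxmean
#' statistic is the larger of the mean positive part
#' `mean(pmax(z, 0))` and the mean negative part `mean(pmax(-z, 0))`;
#' the winning side gives the enrichment direction (ties go to positive).
#'
#' @param scores Named gene-score vector.
#' @param members Character vector of member gene symbols.
#' @return List with `n_used`, `raw` (non-negative magnitude), `direction`
#'   (`"positive"`/`"negative"`), and `signed` (`raw` with the direction's
#'   sign).
#' @export
maxmean <- function(scores, members) {
  idx <- match(members, names(scores))
  idx <- idx[!is.na(idx)]
  if (!length(idx)) {
    return(list(n_used = 0L, raw = NA_real_, direction = NA_character_, signed = NA_real_))
  }
  z <- scores[idx]
  mp <- mean(pmax(z, 0))
  mm <- mean(pmax(-z, 0))
  raw <- max(mp, mm)
  direction <- if (mp >= mm) "positive" else "negative"
  list(n_used = length(idx), raw = raw, direction = direction,
       signed = if (direction == "positive") raw else -raw)
}

#' Randomization moments of the maxmean statistic
#'
#' Draws `n_draws` random gene subsets of the given size (without
#' replacement within a draw) from the score vector and returns the mean
#' and standard deviation of the signed and raw maxmean statistic over the
#' draws. These moments standardise a set score against "gene-sets of the
#' same size sampled at random from the scored genes". Consumes the current
#' RNG stream; the caller (normally [run_gsa()]) controls seeding.
#'
#' @param scores Named gene-score vector.
#' @param set_size Subset size (at most `length(scores)`).
#' @param n_draws Number of random subsets (at least 2).
#' @return List with `mean_signed`, `sd_signed`, `mean_raw`, `sd_raw`,
#'   `n_draws`.
#' @export
randomization_moments <- function(scores, set_size, n_draws) {
  n <- length(scores)
  stopifnot(set_size >= 1L, set_size <= n, n_draws >= 2L)
  idx <- vapply(seq_len(n_draws), function(i) sample.int(n, set_size),
                integer(set_size))
  S <- matrix(scores[idx], nrow = set_size)
  mp <- colMeans(pmax(S, 0))
  mm <- colMeans(pmax(-S, 0))
  raw <- pmax(mp, mm)
  signed <- ifelse(mp >= mm, raw, -raw)
  list(mean_signed = mean(signed), sd_signed = stats::sd(signed),
       mean_raw = mean(raw), sd_raw = stats::sd(raw), n_draws = n_draws)
}

#' Restandardize a signed maxmean statistic
#'
#' `s* = (signed - mean) / sd` with the randomization moments of the signed
#' statistic from the same score-vector context. When the randomization SD
#' is zero (e.g. constant scores or a subset as large as the gene pool) the
#' statistic is centred only and the fallback is flagged.
#'
#' @param signed_raw Signed raw maxmean value.
#' @param moments Output of [randomization_moments()] on the same score
#'   vector.
#' @return Restandardized score with attribute `"centered_only"`.
#' @export
restandardize <- function(signed_raw, moments) {
  if (isTRUE(moments$sd_signed > 0)) {
    structure((signed_raw - moments$mean_signed) / moments$sd_signed,
              centered_only = FALSE)
  } else {
    structure(signed_raw - moments$mean_signed, centered_only = TRUE)
  }
}

# restandardized statistics for every set under one score vector.
# Moments are computed once per distinct overlap size, in increasing size
# order (this ordering is part of the documented RNG policy).
.context_stats <- function(scores, member_idx, n_draws) {
  sizes <- sort(unique(lengths(member_idx)))
  moments <- lapply(sizes, function(m) randomization_moments(scores, m, n_draws))
  names(moments) <- as.character(sizes)
  out <- matrix(NA_real_, nrow = length(member_idx), ncol = 3,
                dimnames = list(names(member_idx), c("raw", "signed", "rest")))
  for (k in seq_along(member_idx)) {
    z <- scores[member_idx[[k]]]
    mp <- mean(pmax(z, 0))
    mm <- mean(pmax(-z, 0))
    raw <- max(mp, mm)
    signed <- if (mp >= mm) raw else -raw
    out[k, ] <- c(raw, signed,
                  as.numeric(restandardize(signed, moments[[as.character(length(z))]])))
  }
  out
}

# ---- permutation machinery --------------------------------------------

# distinct permutations of a (small) multiset, as columns; used only when
# their number is at most the permutation budget
.multiset_perms <- function(values) {
  uv <- sort(unique(values))
  counts <- vapply(uv, function(v) sum(values == v), integer(1))
  n <- length(values)
  res <- list()
  rec <- function(prefix, counts) {
    if (length(prefix) == n) {
      res[[length(res) + 1L]] <<- prefix
      return(invisible())
    }
    for (i in seq_along(uv)) {
      if (counts[i] > 0L) {
        counts[i] <- counts[i] - 1L
        rec(c(prefix, uv[i]), counts)
        counts[i] <- counts[i] + 1L
      }
    }
  }
  rec(numeric(0), counts)
  do.call(cbind, res)
}

.n_arrangements <- function(values) {
  uv <- unique(values)
  counts <- vapply(uv, function(v) sum(values == v), integer(1))
  round(exp(lgamma(length(values) + 1) - sum(lgamma(counts + 1))))
}

#' Permutation null distribution of restandardized set statistics
#'
#' Permutes the phenotype over samples (group labels in two-class mode,
#' ordinal codes in quantitative mode), recomputes gene scores and each
#' set's restandardized maxmean statistic per permutation. When the number
#' of distinct label arrangements is at most `config$n_permutations`, all
#' arrangements are enumerated exhaustively (flagged via the
#' `"exhaustive"` attribute); otherwise arrangements are sampled with the
#' RNG, without deduplication. Does not seed the RNG itself: [run_gsa()]
#' seeds once and lets the observed context and the null share one stream.
#'
#' @param expr Complete expression matrix, columns already matching
#'   `annotation$sample_id` order.
#' @param annotation Sample annotation.
#' @param collection A `geneset_collection`; sets overlapping fewer than
#'   `config$min_set_size` scored genes are silently skipped here (they are
#'   reported by [run_gsa()]).
#' @param config A [gsa_config()].
#' @return Matrix of restandardized null statistics (scored sets x
#'   effective permutations) with attribute `"exhaustive"`.
#' @export
permutation_null <- function(expr, annotation, collection, config) {
  X <- expr[, annotation$sample_id, drop = FALSE]
  member_idx <- .member_index(X, collection, config$min_set_size)
  if (!length(member_idx)) stop("no gene-set overlaps the scored genes", call. = FALSE)
  B <- config$n_permutations

  if (config$mode == "two_class") {
    g <- droplevels(annotation$group)
    in2 <- g == levels(g)[2L]
    n <- length(in2); n2 <- sum(in2)
    total <- choose(n, n2)
    exhaustive <- total <= B
    if (exhaustive) {
      picks <- utils::combn(n, n2)
      label_list <- lapply(seq_len(ncol(picks)), function(j) {
        v <- logical(n); v[picks[, j]] <- TRUE; v
      })
    } else {
      label_list <- lapply(seq_len(B), function(j) sample(in2))
    }
    score_fun <- function(lab) .scores_two_class(X, lab, config$s0)
  } else {
    x <- as.numeric(annotation$ordinal_code)
    total <- .n_arrangements(x)
    exhaustive <- total <= B
    if (exhaustive) {
      perms <- .multiset_perms(x)
      label_list <- lapply(seq_len(ncol(perms)), function(j) perms[, j])
    } else {
      label_list <- lapply(seq_len(B), function(j) sample(x))
    }
    score_fun <- function(lab) .scores_quantitative(X, lab, config$s0)
  }

  null <- vapply(label_list, function(lab) {
    sc <- score_fun(lab)
    .context_stats(as.numeric(sc) |> stats::setNames(names(sc)),
                   member_idx, config$n_randomization_draws)[, "rest"]
  }, numeric(length(member_idx)))
  null <- matrix(null, nrow = length(member_idx),
                 dimnames = list(names(member_idx), NULL))
  attr(null, "exhaustive") <- exhaustive
  null
}

.member_index <- function(X, collection, min_set_size) {
  genes <- rownames(X)
  idx <- lapply(collection$members, function(m) {
    i <- match(unique(m), genes)
    i[!is.na(i)]
  })
  names(idx) <- collection$set
  idx[lengths(idx) >= min_set_size]
}

#' Permutation p-values and plug-in FDR
#'
#' Two-sided attained p per set: the fraction of that set's permuted
#' absolute restandardized statistics at or above the observed one (0 is
#' possible and is labelled `< 1/B` downstream). Plug-in FDR at each
#' observed threshold `t = |s*|`: the median over permutations of the
#' number of null statistics (across all sets) at or above `t`, divided by
#' the number of observed statistics at or above `t`, capped at 1 and made
#' monotone non-increasing in `t`.
#'
#' @param observed Numeric vector of observed restandardized statistics.
#' @param null_array Null matrix from [permutation_null()] (sets x
#'   permutations, same set order).
#' @return Tibble with columns `p` and `fdr`.
#' @export
estimate_significance <- function(observed, null_array) {
  if (!length(observed)) stop("no sets scored", call. = FALSE)
  stopifnot(nrow(null_array) == length(observed))
  absS <- abs(observed)
  N <- abs(null_array)
  p <- vapply(seq_along(absS), function(i) mean(N[i, ] >= absS[i]), numeric(1))
  R <- vapply(absS, function(t) sum(absS >= t), numeric(1))
  V <- vapply(absS, function(t) stats::median(colSums(N >= t)), numeric(1))
  fdr <- pmin(1, V / R)
  ord <- order(absS, decreasing = TRUE)
  fdr[ord] <- cummax(fdr[ord])
  tibble::tibble(p = p, fdr = fdr)
}

# ---- driver ------------------------------------------------------------

#' Run maxmean gene-set analysis with restandardization and permutation FDR
#'
#' The full competitive gene-set test: gene scores (two-class pooled t or
#' ordinal regression t), raw maxmean per set, restandardization against
#' random equal-size gene-sets, a phenotype-permutation null (exhaustive
#' when feasible), two-sided p-values and plug-in FDR. Samples are
#' canonicalised by sorting on sample id before any random draw, so results
#' are bit-identical for the same seed regardless of input column order.
#'
#' @param expr Expression matrix with no missing values (apply
#'   [filter_complete_genes()] first).
#' @param annotation Sample annotation tibble (see [sample_annotation()]).
#' @param collection A `geneset_collection`.
#' @param config A [gsa_config()].
#' @return A `gsa_result` object: `result` tibble (`set`, `n_used`, `raw`,
#'   `direction`, `restandardized`, `p`, `p_label`, `fdr`, `significant`),
#'   `excluded` tibble (`set`, `reason`), the config, the effective
#'   permutation count, exhaustiveness flag, and zero-variance gene log.
#' @export
run_gsa <- function(expr, annotation, collection, config) {
  stopifnot(inherits(config, "gsa_config"))
  if (any(!is.finite(expr))) {
    stop("expression matrix has missing values; apply filter_complete_genes() first",
         call. = FALSE)
  }
  if (!setequal(colnames(expr), annotation$sample_id)) {
    stop("annotation sample ids do not match expression columns", call. = FALSE)
  }
  ord <- order(annotation$sample_id)
  annotation <- annotation[ord, , drop = FALSE]
  expr <- expr[, annotation$sample_id, drop = FALSE]

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$rng_seed)

  scores <- if (config$mode == "two_class") {
    gene_scores_two_class(expr, annotation, config$s0)
  } else {
    gene_scores_quantitative(expr, annotation, config$s0)
  }
  zero_var <- attr(scores, "zero_variance")

  member_idx <- .member_index(expr, collection, config$min_set_size)
  n_overlap <- vapply(collection$members,
                      function(m) sum(unique(m) %in% rownames(expr)), integer(1))
  excluded <- tibble::tibble(
    set = collection$set[!(collection$set %in% names(member_idx))],
    reason = ifelse(n_overlap[!(collection$set %in% names(member_idx))] == 0L,
                    "no overlap with scored genes",
                    sprintf("overlap below min_set_size (%d)", config$min_set_size))
  )
  if (!length(member_idx)) stop("every gene-set was excluded; nothing to score", call. = FALSE)

  obs <- .context_stats(stats::setNames(as.numeric(scores), names(scores)),
                        member_idx, config$n_randomization_draws)
  null <- permutation_null(expr, annotation, collection, config)
  sig <- estimate_significance(obs[, "rest"], null)
  B_eff <- ncol(null)

  result <- tibble::tibble(
    set = names(member_idx),
    n_used = unname(lengths(member_idx)),
    raw = unname(obs[, "raw"]),
    direction = unname(ifelse(obs[, "signed"] >= 0, "positive", "negative")),
    restandardized = unname(obs[, "rest"]),
    p = sig$p,
    p_label = ifelse(sig$p == 0, sprintf("< %.4g", 1 / B_eff),
                     formatC(sig$p, digits = 4, format = "g")),
    fdr = sig$fdr,
    significant = sig$fdr <= config$fdr_threshold
  )

  structure(list(result = result, excluded = excluded, config = config,
                 n_permutations_effective = B_eff,
                 exhaustive = attr(null, "exhaustive"),
                 zero_variance_genes = zero_var,
                 n_genes = nrow(expr), n_samples = ncol(expr)),
            class = "gsa_result")
}

#' @export
print.gsa_result <- function(x, ...) {
  cat(sprintf("Gene-set analysis (%s mode): %d sets scored, %d excluded\n",
              x$config$mode, nrow(x$result), nrow(x$excluded)))
  cat(sprintf("  %s permutations: %d; significant at FDR <= %.2f: %d\n",
              if (x$exhaustive) "exhaustive" else "sampled",
              x$n_permutations_effective, x$config$fdr_threshold,
              sum(x$result$significant)))
  print(dplyr::arrange(x$result, .data$p, dplyr::desc(abs(.data$restandardized))), ...)
  invisible(x)
}

#' Tidy a gene-set analysis result
#' @param x A `gsa_result`.
#' @param ... Unused.
#' @return The per-set result tibble.
#' @export
tidy.gsa_result <- function(x, ...) x$result

#' One-row summary of a gene-set analysis
#' @param x A `gsa_result`.
#' @param ... Unused.
#' @export
glance.gsa_result <- function(x, ...) {
  tibble::tibble(
    mode = x$config$mode,
    n_genes = x$n_genes,
    n_samples = x$n_samples,
    n_sets_scored = nrow(x$result),
    n_sets_excluded = nrow(x$excluded),
    n_significant = sum(x$result$significant),
    n_permutations = x$n_permutations_effective,
    exhaustive = x$exhaustive,
    fdr_threshold = x$config$fdr_threshold
  )
}

#' Plot gene-set analysis results
#'
#' Restandardized maxmean score per set against permutation significance,
#' coloured by the FDR call.
#'
#' @param object A `gsa_result`.
#' @param ... Unused.
#' @export
autoplot.gsa_result <- function(object, ...) {
  d <- object$result
  eps <- 1 / (2 * object$n_permutations_effective)
  d$neglog_p <- -log10(d$p + eps)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$restandardized, y = .data$neglog_p,
                                  colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "restandardized maxmean score",
                  y = expression(-log[10] ~ "permutation p"),
                  colour = sprintf("FDR <= %.2f", object$config$fdr_threshold)) +
    ggplot2::theme_minimal()
}

#' Sets significantly enriched in both of two datasets
#'
#' Cross-dataset replication: the sets whose estimated FDR is at or below
#' the threshold in both results, with per-dataset p and FDR attached.
#' Replication asks for enrichment in the disease direction in both
#' cohorts, so by default only sets scored `"positive"` in both results
#' qualify: with a strong enriched signal present, the competitive
#' restandardization baseline shifts and unrelated sets drift toward
#' artifactual negative scores coherently across datasets, which would
#' otherwise masquerade as replication. `direction = "any"` disables the
#' restriction; `"match"` requires equal directions without fixing which;
#' `"negative"` selects shared depletion.
#'
#' @param result_a,result_b `gsa_result` objects (or their tidied tibbles,
#'   which must retain the `direction` column) computed over collections
#'   sharing set names.
#' @param fdr_threshold Replication cutoff (default 0.5).
#' @param direction Required enrichment direction (see above).
#' @return Tibble with columns `set`, `direction_a`, `direction_b`, `p_a`,
#'   `fdr_a`, `p_b`, `fdr_b`.
#' @export
replicate_across_datasets <- function(result_a, result_b, fdr_threshold = 0.5,
                                      direction = c("positive", "negative",
                                                    "match", "any")) {
  direction <- match.arg(direction)
  ta <- if (inherits(result_a, "gsa_result")) result_a$result else tibble::as_tibble(result_a)
  tb <- if (inherits(result_b, "gsa_result")) result_b$result else tibble::as_tibble(result_b)
  if (!length(intersect(ta$set, tb$set))) {
    stop("the two results share no gene-set names", call. = FALSE)
  }
  cols <- c("set", "direction", "p", "fdr")
  joined <- dplyr::inner_join(ta[, cols], tb[, cols],
                              by = "set", suffix = c("_a", "_b")) |>
    dplyr::filter(.data$fdr_a <= fdr_threshold, .data$fdr_b <= fdr_threshold)
  joined <- switch(direction,
    positive = dplyr::filter(joined, .data$direction_a == "positive",
                             .data$direction_b == "positive"),
    negative = dplyr::filter(joined, .data$direction_a == "negative",
                             .data$direction_b == "negative"),
    match = dplyr::filter(joined, .data$direction_a == .data$direction_b),
    any = joined
  )
  dplyr::arrange(joined, .data$p_a + .data$p_b)
}

#' Write / read a GSA result table
#'
#' Round-trippable TSV of the per-set results (the `gsa_result` tibble plus
#' nothing else; use the object for config provenance).
#' @param x A `gsa_result` or its tidied tibble.
#' @param path Output path.
#' @export
write_gsa_result <- function(x, path) {
  tab <- if (inherits(x, "gsa_result")) x$result else tibble::as_tibble(x)
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname write_gsa_result
#' @export
read_gsa_result <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
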