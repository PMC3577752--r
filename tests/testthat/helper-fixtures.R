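# shared fixture builders and independent oracles

# small expression matrix with ids
make_expr <- function(n_genes, n_samples, seed = 1, prefix = "S") {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, 8, 1), nrow = n_genes,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("%s%02d", prefix, seq_len(n_samples))))
  m
}

two_group_annotation <- function(n1, n2, levels = c("STA", "AR")) {
  sample_annotation(
    sprintf("S%02d", seq_len(n1 + n2)),
    rep(levels, c(n1, n2)),
    levels = levels
  )
}

# independent two-sample pooled-t oracle, gene by gene via stats::t.test
oracle_scores_two_class <- function(X, in_group2) {
  apply(X, 1, function(y) {
    unname(stats::t.test(y[in_group2], y[!in_group2], var.equal = TRUE)$statistic)
  })
}

# independent regression-t oracle via lm()
oracle_scores_quantitative <- function(X, x) {
  apply(X, 1, function(y) summary(stats::lm(y ~ x))$coefficients[2, 3])
}

# independent signed maxmean
oracle_signed_maxmean <- function(z) {
  mp <- mean(pmax(z, 0))
  mn <- mean(pmax(-z, 0))
  if (mp >= mn) mp else -mn
}

# independent direct-counting p/FDR (mirrors the published plug-in rule,
# written from the definition, not the package code)
oracle_significance <- function(observed, null_mat) {
  a <- abs(observed)
  N <- abs(null_mat)
  p <- numeric(length(a))
  fdr <- numeric(length(a))
  for (i in seq_along(a)) {
    p[i] <- sum(N[i, ] >= a[i]) / ncol(N)
    counts <- apply(N, 2, function(col) sum(col >= a[i]))
    fdr[i] <- min(1, stats::median(counts) / sum(a >= a[i]))
  }
  # enforce monotone non-increasing in the threshold by running maximum
  ord <- order(a, decreasing = TRUE)
  fdr[ord] <- cummax(fdr[ord])
  list(p = p, fdr = fdr)
}

# exhaustive two-class GSA oracle: enumerates all label arrangements in
# combn order, computes gene scores with t.test and the maxmean statistic
# from its definition; the restandardization moments reuse the exported
# randomization_moments() under the documented RNG policy (seed once,
# observed context first, then arrangements; moment sizes ascending)
oracle_exhaustive_p <- function(expr, annotation, collection, config) {
  ord <- order(annotation$sample_id)
  ann <- annotation[ord, ]
  X <- expr[, ann$sample_id]
  g <- droplevels(ann$group)
  in2_obs <- g == levels(g)[2]
  member_idx <- lapply(collection$members, function(m) which(rownames(X) %in% m))
  names(member_idx) <- collection$set
  member_idx <- member_idx[lengths(member_idx) >= config$min_set_size]

  ctx <- function(z) {
    sizes <- sort(unique(lengths(member_idx)))
    mom <- lapply(sizes, function(m)
      randomization_moments(z, m, config$n_randomization_draws))
    names(mom) <- as.character(sizes)
    vapply(member_idx, function(idx) {
      s <- oracle_signed_maxmean(z[idx])
      mo <- mom[[as.character(length(idx))]]
      if (mo$sd_signed > 0) (s - mo$mean_signed) / mo$sd_signed
      else s - mo$mean_signed
    }, numeric(1))
  }

  set.seed(config$rng_seed)
  obs <- ctx(oracle_scores_two_class(X, in2_obs))
  picks <- utils::combn(length(g), sum(in2_obs))
  null <- vapply(seq_len(ncol(picks)), function(j) {
    in2 <- seq_along(g) %in% picks[, j]
    ctx(oracle_scores_two_class(X, in2))
  }, numeric(length(member_idx)))
  null <- matrix(null, nrow = length(member_idx))
  p <- vapply(seq_along(obs), function(i) mean(abs(null[i, ]) >= abs(obs[i])),
              numeric(1))
  stats::setNames(p, names(member_idx))
}
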