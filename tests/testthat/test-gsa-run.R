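tiny_study <- function(n_genes = 20, n1 = 4, n2 = 4, seed = 13, set_sizes = c(6, 5, 7)) {
  X <- make_expr(n_genes, n1 + n2, seed = seed)
  ann <- two_group_annotation(n1, n2)
  set.seed(seed + 1)
  members <- lapply(set_sizes, function(k) sample(rownames(X), k))
  coll <- geneset_collection(sprintf("SET%d", seq_along(set_sizes)), members)
  list(X = X, ann = ann, coll = coll)
}

test_that("small designs are enumerated exhaustively with the right arrangement count", {
  st <- tiny_study(n1 = 2, n2 = 2, n_genes = 15, set_sizes = c(5, 6))
  cfg <- gsa_config("two_class", n_permutations = 100,
                    n_randomization_draws = 20, rng_seed = 1)
  set.seed(1)
  null <- permutation_null(st$X, st$ann, st$coll, cfg)
  expect_true(attr(null, "exhaustive"))
  expect_identical(ncol(null), 6L)  # choose(4, 2) distinct arrangements
  expect_identical(nrow(null), 2L)              # one row per scored set
})

test_that("quantitative-mode enumeration covers the multiset arrangements", {
  st <- tiny_study(n1 = 2, n2 = 2, n_genes = 15, set_sizes = c(5, 6))
  ann <- sample_annotation(st$ann$sample_id, c("D0", "D0", "STA", "ARIA"),
                           levels = c("D0", "STA", "ARIA"))
  cfg <- gsa_config("quantitative", n_permutations = 100,
                    n_randomization_draws = 20, rng_seed = 1)
  set.seed(1)
  null <- permutation_null(st$X, ann, st$coll, cfg)
  expect_true(attr(null, "exhaustive"))
  expect_identical(ncol(null), 12L)  # 4!/2! distinct code orders
})

test_that("significance estimates match an independent direct-counting oracle", {
  set.seed(23)
  observed <- rnorm(20, sd = 2)
  null_mat <- matrix(rnorm(20 * 200), nrow = 20)
  est <- estimate_significance(observed, null_mat)
  oracle <- oracle_significance(observed, null_mat)
  expect_equal(est$p, oracle$p)
  expect_equal(est$fdr, oracle$fdr)

  # forced extremes
  est2 <- estimate_significance(c(0.1, 10), matrix(rep(c(5, 5), 50), nrow = 2))
  expect_equal(est2$p, c(1, 0))
  expect_equal(est2$fdr[1], 1)
})

test_that("FDR estimates are capped at one and monotone non-increasing in the statistic", {
  set.seed(31)
  for (i in 1:5) {
    obs <- rnorm(15)
    nl <- matrix(rnorm(15 * 100), nrow = 15)
    est <- estimate_significance(obs, nl)
    expect_true(all(est$fdr >= 0 & est$fdr <= 1))
    ord <- order(abs(obs), decreasing = TRUE)
    expect_true(all(diff(est$fdr[ord]) >= -1e-12))
  }
})

test_that("run_gsa is deterministic under the seed and invariant to column order", {
  st <- tiny_study(n_genes = 40, n1 = 5, n2 = 5, set_sizes = c(8, 10))
  cfg <- gsa_config("two_class", n_permutations = 60,
                    n_randomization_draws = 50, rng_seed = 99)
  r1 <- run_gsa(st$X, st$ann, st$coll, cfg)
  r2 <- run_gsa(st$X, st$ann, st$coll, cfg)
  expect_identical(r1$result, r2$result)

  perm <- sample(ncol(st$X))
  r3 <- run_gsa(st$X[, perm], st$ann[perm, ], st$coll, cfg)
  expect_identical(r1$result, r3$result)
})

test_that("duplicated member lists under different names report identically", {
  st <- tiny_study(n_genes = 30, set_sizes = c(6, 6))
  coll <- geneset_collection(c("ORIG", "COPY"),
                             list(st$coll$members[[1]], st$coll$members[[1]]))
  cfg <- gsa_config("two_class", n_permutations = 40,
                    n_randomization_draws = 30, rng_seed = 4)
  res <- run_gsa(st$X, st$ann, coll, cfg)
  a <- res$result[res$result$set == "ORIG", -1]
  b <- res$result[res$result$set == "COPY", -1]
  expect_equal(a, b)
})

test_that("undersized and non-overlapping sets are excluded with reasons", {
  st <- tiny_study(n_genes = 30, set_sizes = c(8))
  coll <- geneset_collection(
    c("OK", "TINY", "ALIEN"),
    list(st$coll$members[[1]], rownames(st$X)[1:2], c("ZZ1", "ZZ2", "ZZ3", "ZZ4", "ZZ5"))
  )
  cfg <- gsa_config("two_class", n_permutations = 20,
                    n_randomization_draws = 20, rng_seed = 1)
  res <- run_gsa(st$X, st$ann, coll, cfg)
  expect_identical(res$result$set, "OK")
  expect_setequal(res$excluded$set, c("TINY", "ALIEN"))
  expect_match(res$excluded$reason[res$excluded$set == "ALIEN"], "no overlap")
  expect_match(res$excluded$reason[res$excluded$set == "TINY"], "min_set_size")
})

test_that("a planted enrichment attains the minimum p among all sets", {
  spec <- simulation_spec(
    n_genes = 400, group_sizes = c(STA = 10, AR = 10),
    planted_sets = list(planted_set("HIT", 40, "two_class_shift",
                                    delta = 1, fraction = 0.8)),
    n_null_sets = 10, null_set_size = 40, seed = 55
  )
  sim <- simulate_expression(spec)
  cfg <- gsa_config("two_class", n_permutations = 100,
                    n_randomization_draws = 100, rng_seed = 8)
  res <- run_gsa(sim$expression, sim$annotation, sim$collection, cfg)
  tab <- tidy(res)
  expect_equal(tab$p[tab$set == "HIT"], min(tab$p))
  expect_identical(unname(tab$direction[tab$set == "HIT"]), "positive")
})

test_that("replication returns exactly the sets significant in both datasets", {
  a <- tibble::tibble(set = c("S1", "S2", "S3"), direction = "positive",
                      p = c(0.01, 0.2, 0.9), fdr = c(0.1, 0.4, 1))
  b <- tibble::tibble(set = c("S1", "S2", "S3"),
                      direction = c("positive", "positive", "negative"),
                      p = c(0.02, 0.8, 0.05), fdr = c(0.2, 0.9, 0.3))
  rep1 <- replicate_across_datasets(a, b, 0.5)
  expect_identical(rep1$set, "S1")
  expect_named(rep1, c("set", "direction_a", "p_a", "fdr_a",
                       "direction_b", "p_b", "fdr_b"))

  # identical results replicate their whole significant list
  rep2 <- replicate_across_datasets(a, a, 0.5)
  expect_setequal(rep2$set, c("S1", "S2"))

  # a set depleted in one dataset does not count as shared enrichment
  a3 <- dplyr::mutate(a, fdr = 0.1)
  b3 <- dplyr::mutate(b, fdr = 0.1)
  expect_false("S3" %in% replicate_across_datasets(a3, b3, 0.5)$set)
  expect_true("S3" %in% replicate_across_datasets(a3, b3, 0.5, direction = "any")$set)

  # disjoint significant lists yield nothing
  b2 <- tibble::tibble(set = c("S1", "S2"), direction = "positive",
                       p = c(0.9, 0.9), fdr = c(1, 1))
  expect_identical(nrow(replicate_across_datasets(a, b2, 0.5)), 0L)

  c2 <- tibble::tibble(set = "OTHER", direction = "positive", p = 0.1, fdr = 0.1)
  expect_error(replicate_across_datasets(a, c2), "share no gene-set")
})

test_that("gsa_result exposes tidy, glance and a plot", {
  st <- tiny_study(set_sizes = c(6, 8))
  cfg <- gsa_config("two_class", n_permutations = 30,
                    n_randomization_draws = 20, rng_seed = 2)
  res <- run_gsa(st$X, st$ann, st$coll, cfg)
  expect_s3_class(tidy(res), "tbl_df")
  expect_identical(nrow(glance(res)), 1L)
  expect_s3_class(autoplot(res), "ggplot")
})
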