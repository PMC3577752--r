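test_that("expression tables round-trip through TSV with ids and values intact", {
  m <- make_expr(3, 2, seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(m, path)
  back <- read_expression_table(path)
  expect_identical(dim(back), c(3L, 2L))
  expect_identical(rownames(back), rownames(m))
  expect_identical(colnames(back), colnames(m))
  expect_equal(unclass(back)[, ], m[, ], tolerance = 1e-12)
})

test_that("malformed expression tables are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS1", "G1\t1\t2"), path)
  expect_error(read_expression_table(path), "duplicate sample ids")

  writeLines(c("gene\tS1\tS2", "G1\t1\t2", "G2\t3"), path)
  expect_error(read_expression_table(path), "line 3")
})

test_that("non-numeric cells become missing and the gene is flagged", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS2", "G1\t1.5\tabc", "G2\t3\t4"), path)
  m <- read_expression_table(path)
  expect_true(is.na(m["G1", "S2"]))
  expect_identical(attr(m, "incomplete_genes"), "G1")
})

test_that("filter_complete_genes keeps exactly the complete rows and is idempotent", {
  m <- make_expr(5, 4)
  expect_identical(filter_complete_genes(m)[, ], m[, ])  # no missing: unchanged

  m["G002", 3] <- NA
  f <- suppressMessages(filter_complete_genes(m))
  expect_identical(rownames(f), setdiff(rownames(m), "G002"))
  expect_identical(attr(f, "n_dropped"), 1L)

  # 10% missing-at-random fixture against a brute-force row scan
  big <- make_expr(200, 10, seed = 42)
  set.seed(99)
  big[sample(length(big), 200)] <- NA
  kept <- suppressMessages(filter_complete_genes(big))
  brute <- rownames(big)[apply(big, 1, function(r) !anyNA(r))]
  expect_identical(rownames(kept), brute)
  expect_identical(rownames(suppressMessages(filter_complete_genes(kept))),
                   rownames(kept))  # idempotent

  all_na <- matrix(NA_real_, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(filter_complete_genes(all_na), "unusable")
})

test_that("collapse_probes picks the minimum-SEM probe with lexicographic ties", {
  m <- matrix(c(1, 1, 1, 1, 2, 3), nrow = 2, byrow = TRUE,
              dimnames = list(c("p1", "p2"), c("S1", "S2", "S3")))
  pm <- data.frame(probe_id = c("p1", "p2"), gene_symbol = c("GENE", "GENE"))
  out <- collapse_probes(m, pm, reference_samples = c("S1", "S2", "S3"))
  expect_identical(rownames(out), "GENE")
  expect_equal(out["GENE", ], m["p1", ])  # SEM 0 beats SEM 0.577

  # single probe: identity (reference subset only affects the SEM)
  one <- collapse_probes(m[1, , drop = FALSE], pm[1, ], c("S1", "S2"))
  expect_equal(one["GENE", ], m["p1", ])

  # exact tie broken by probe id order
  tie <- matrix(rep(c(5, 6, 7), each = 2), nrow = 2,
                dimnames = list(c("pB", "pA"), c("S1", "S2", "S3")))
  pm2 <- data.frame(probe_id = c("pB", "pA"), gene_symbol = "G")
  out2 <- collapse_probes(tie, pm2, c("S1", "S2", "S3"))
  expect_equal(unname(out2["G", 1]), unname(tie["pA", 1]))
})

test_that("collapse_probes matches a brute-force minimum-SEM scan on a random fixture", {
  set.seed(7)
  n_probes <- 50
  m <- make_expr(n_probes, 8, seed = 7)
  rownames(m) <- sprintf("probe%02d", seq_len(n_probes))
  genes <- sprintf("SYM%02d", sample(1:18, n_probes, replace = TRUE))
  pm <- data.frame(probe_id = rownames(m), gene_symbol = genes)
  refs <- colnames(m)[1:5]
  out <- collapse_probes(m, pm, refs)

  sem <- apply(m[, refs], 1, function(x) sd(x) / sqrt(length(x)))
  brute <- vapply(split(rownames(m), genes), function(pr) {
    pr <- sort(pr)
    pr[order(sem[pr], pr)][1]
  }, character(1))
  expect_setequal(rownames(out), names(brute))
  for (g in names(brute)) expect_equal(out[g, ], m[brute[[g]], ])

  # invariant to probe row order apart from the stated tie-break
  perm <- sample(n_probes)
  out_perm <- collapse_probes(m[perm, ], pm, refs)
  expect_equal(out_perm[rownames(out), ], out[, ])
})

test_that("unmapped probes are excluded and reported", {
  m <- make_expr(3, 3)
  rownames(m) <- c("p1", "p2", "p3")
  pm <- data.frame(probe_id = c("p1", "p2"), gene_symbol = c("A", "B"))
  expect_message(out <- collapse_probes(m, pm, colnames(m)), "absent from probe_map")
  expect_identical(attr(out, "unmapped_probes"), "p3")
  expect_setequal(rownames(out), c("A", "B"))
})

test_that("GMT files parse, deduplicate members, and round-trip identically", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines("S1\tdesc\tA\tB", path)
  coll <- read_gmt(path)
  expect_identical(coll$set, "S1")
  expect_setequal(coll$members[[1]], c("A", "B"))

  writeLines("S1\tdesc\tA\tA\tB", path)
  expect_warning(coll2 <- read_gmt(path), "deduplicated")
  expect_setequal(coll2$members[[1]], c("A", "B"))

  writeLines(c("S1\td\tA", "S1\td\tB"), path)
  expect_error(read_gmt(path), "duplicate gene-set name")
  writeLines(c("S1\td\tA", "S2\tonly-two-fields"), path)
  expect_error(read_gmt(path), "line 2")

  # larger synthetic collection round-trips bit-identically
  set.seed(3)
  big <- geneset_collection(
    sprintf("SET%03d", 1:200),
    lapply(1:200, function(i) sprintf("G%04d", sample(5000, sample(5:40, 1)))),
    description = sprintf("d%03d", 1:200)
  )
  p1 <- withr::local_tempfile(fileext = ".gmt")
  p2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(big, p1)
  write_gmt(read_gmt(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("sample annotation enforces the declared ordinal coding", {
  ann <- sample_annotation(c("a", "b", "c"), c("D0", "STA", "ARIB"))
  expect_identical(ann$ordinal_code, c(0L, 1L, 4L))
  expect_error(sample_annotation("a", "XX"), "unknown group")
  expect_error(sample_annotation(c("a", "a"), c("D0", "D0")), "duplicate sample")
  expect_error(sample_annotation("a", "x", levels = "x"), "two levels")
})
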