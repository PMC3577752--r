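demo_interactions <- function() {
  tibble::tibble(
    compound_id = c("FEN", "FEN", "FEN", "FEN", "FEN", "FEN",
                    "ACT", "ACT", "ACT", "ACT", "ACT", "ACT",
                    "BIO", "BIO", "BIO", "BIO", "BIO",
                    "DUP", "DUP"),
    gene = c("IL17A", "IFNG", "IL6", "TNF", "IL1B", "STAT3",
             "IL17A", "IFNG", "IL6", "TNF", "IL1B", "STAT3",
             "IL17A", "IFNG", "IL6", "TNF", "IL1B",
             "IL6", "IL6"),
    mechanism = c(rep("inhibition", 6),
                  "activation", rep("inhibition", 5),
                  rep("inhibition", 5),
                  "inhibition", "inhibition"),
    direct = c(rep(TRUE, 6), rep(TRUE, 6), rep(TRUE, 5), TRUE, TRUE),
    evidence_id = "PMID:1"
  )
}

demo_compounds <- function() {
  tibble::tibble(
    compound_id = c("FEN", "ACT", "BIO", "DUP"),
    name = c("fenofibrate", "activator_drug", "biologic_drug", "dup_drug"),
    fda_approved = c(TRUE, TRUE, TRUE, TRUE),
    modality = c("small_molecule", "small_molecule", "biologic", "small_molecule")
  )
}

input_genes <- c("IL17A", "IFNG", "IL6", "TNF", "IL1B", "STAT3", "RORC")

test_that("lookup maps compounds to deduplicated matched input genes", {
  lk <- lookup_compounds(demo_interactions(), input_genes)
  expect_setequal(lk$compound_id, c("FEN", "ACT", "BIO", "DUP"))
  expect_identical(lk$n_matched[lk$compound_id == "DUP"], 1L)  # same gene twice

  none <- lookup_compounds(demo_interactions(), "UNRELATED_GENE")
  expect_identical(nrow(none), 0L)
  expect_warning(lookup_compounds(demo_interactions()[0, ], input_genes), "empty")
})

test_that("lookup equals a brute-force scan on a random 1000-record table", {
  set.seed(71)
  it <- tibble::tibble(
    compound_id = sprintf("C%03d", sample(80, 1000, replace = TRUE)),
    gene = sprintf("G%02d", sample(40, 1000, replace = TRUE)),
    mechanism = sample(c("inhibition", "activation", "unspecified"), 1000, TRUE),
    direct = sample(c(TRUE, FALSE), 1000, TRUE),
    evidence_id = "x"
  )
  genes <- sprintf("G%02d", 1:15)
  lk <- lookup_compounds(it, genes)
  brute <- lapply(split(it, it$compound_id), function(d) sort(unique(d$gene[d$gene %in% genes])))
  brute <- brute[lengths(brute) > 0]
  expect_setequal(lk$compound_id, names(brute))
  for (i in seq_len(nrow(lk))) {
    expect_identical(lk$matched_genes[[i]], brute[[lk$compound_id[i]]])
  }
})

test_that("the default filters pass direct FDA small-molecule inhibitors of >=5 genes incl IL17A", {
  it <- demo_interactions(); cmp <- demo_compounds()
  lk <- lookup_compounds(it, input_genes)
  rep <- filter_candidates(lk, cmp, it, filter_config(), input_genes = input_genes)
  expect_identical(rep$compound_id[rep$pass], "FEN")

  # required gene activated but not inhibited fails on the required flag only
  act <- rep[rep$compound_id == "ACT", ]
  expect_false(act$pass)
  expect_false(act$has_required)
  expect_true(act$enough_targets && act$fda_ok && act$modality_ok)

  # biologic fails modality only
  bio <- rep[rep$compound_id == "BIO", ]
  expect_false(bio$modality_ok)
  expect_true(bio$enough_targets && bio$has_required && bio$fda_ok)

  # every looked-up compound is reported exactly once
  expect_identical(sort(rep$compound_id), sort(lk$compound_id))
})

test_that("compounds without metadata fail with the no_metadata flag", {
  it <- demo_interactions(); cmp <- demo_compounds()[-1, ]  # drop FEN metadata
  lk <- lookup_compounds(it, input_genes)
  expect_message(
    rep <- filter_candidates(lk, cmp, it, filter_config(), input_genes = input_genes),
    "no_metadata"
  )
  expect_false(rep$pass[rep$compound_id == "FEN"])
  expect_false(rep$has_metadata[rep$compound_id == "FEN"])
})

test_that("filters are monotone and invariant to interaction row order and duplication", {
  it <- demo_interactions(); cmp <- demo_compounds()
  lk <- lookup_compounds(it, input_genes)
  pass5 <- filter_candidates(lk, cmp, it, filter_config(min_targets = 5),
                             input_genes = input_genes)
  pass6 <- filter_candidates(lk, cmp, it, filter_config(min_targets = 6),
                             input_genes = input_genes)
  expect_true(all(pass6$compound_id[pass6$pass] %in% pass5$compound_id[pass5$pass]))

  relaxed <- filter_candidates(lk, cmp, it,
                               filter_config(fda_only = FALSE,
                                             modality_allowed = c("small_molecule", "biologic")),
                               input_genes = input_genes)
  expect_true(all(pass5$compound_id[pass5$pass] %in% relaxed$compound_id[relaxed$pass]))

  it2 <- it[sample(nrow(it)), ]
  it2 <- dplyr::bind_rows(it2, it2[1:5, ])  # duplicated records
  lk2 <- lookup_compounds(it2, input_genes)
  rep2 <- filter_candidates(lk2, cmp, it2, filter_config(), input_genes = input_genes)
  expect_setequal(rep2$compound_id[rep2$pass],
                  pass5$compound_id[pass5$pass])
})

test_that("ranking is by qualifying count then name, matching a sort oracle", {
  rep <- tibble::tibble(
    compound_id = c("a", "b", "c", "d"),
    name = c("zeta", "alpha", "beta", "gamma"),
    matched_genes = list("g", "g", "g", "g"),
    n_matched = 1L,
    qualifying_targets = list("g", "g", "g", "g"),
    n_qualifying = c(5L, 6L, 5L, 2L),
    enough_targets = TRUE, has_required = TRUE, fda_ok = TRUE,
    modality_ok = TRUE, has_metadata = TRUE,
    pass = c(TRUE, TRUE, TRUE, FALSE)
  )
  rk <- rank_candidates(rep)
  oracle <- rep[rep$pass, ][order(-rep$n_qualifying[rep$pass], rep$name[rep$pass]), ]
  expect_identical(rk$compound_id, oracle$compound_id)
  expect_identical(rk$compound_id, c("b", "c", "a"))  # 6 first, then beta < zeta

  single <- rank_candidates(rep[2, ])
  expect_identical(nrow(single), 1L)
})

test_that("the planted interaction simulation yields exactly the qualifying compounds", {
  genes <- c("IL17A", sprintf("RG%02d", 1:19))
  sim <- simulate_interactions(genes, n_compounds = 300, n_qualifying = 4, seed = 12)
  lk <- lookup_compounds(sim$interactions, genes)
  rep <- filter_candidates(lk, sim$compounds, sim$interactions, filter_config(),
                           input_genes = genes)
  expect_setequal(rep$compound_id[rep$pass], sim$truth$qualifying)

  # each decoy fails on its designated flag only
  flags <- c(enough_targets = "enough_targets", has_required = "has_required",
             fda_ok = "fda_ok", modality_ok = "modality_ok")
  for (i in seq_len(nrow(sim$truth$decoys))) {
    row <- rep[rep$compound_id == sim$truth$decoys$compound_id[i], ]
    failing <- names(flags)[!unlist(row[names(flags)])]
    expect_identical(failing, sim$truth$decoys$fails[i])
  }

  # zero qualifying compounds leave an empty pass list
  sim0 <- simulate_interactions(genes, n_compounds = 50, n_qualifying = 0, seed = 3)
  lk0 <- lookup_compounds(sim0$interactions, genes)
  rep0 <- filter_candidates(lk0, sim0$compounds, sim0$interactions, filter_config(),
                            input_genes = genes)
  expect_identical(nrow(rank_candidates(rep0)), 0L)
})
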