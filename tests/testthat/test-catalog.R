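cat_fixture <- read_catalog()

test_that("packaged catalog loads with the expected composition", {
  expect_s3_class(cat_fixture, "homeolog_catalog")
  expect_equal(sum(cat_fixture$role == "ligand"), 31L)
  expect_equal(sum(cat_fixture$role == "receptor"), 17L)
  expect_false(anyDuplicated(cat_fixture$gene_symbol) > 0)
  # every entry exists somewhere
  expect_true(all(cat_fixture$present_xtr | cat_fixture$present_L |
                    cat_fixture$present_S))
})

test_that("catalog loader validates its input", {
  empty <- write_catalog_file(minimal_catalog_row()[0, ])
  expect_equal(nrow(read_catalog(empty)), 0L)

  dup <- write_catalog_file(rbind(minimal_catalog_row("genea"),
                                  minimal_catalog_row("genea")))
  expect_error(read_catalog(dup), "duplicate gene symbol")

  neg <- write_catalog_file(minimal_catalog_row(dnds_L = "-0.1"))
  expect_error(read_catalog(neg), "dnds_L")

  badpct <- write_catalog_file(minimal_catalog_row(identity_pct = "12x"))
  expect_error(read_catalog(badpct), "identity_pct")

  badcat <- write_catalog_file(minimal_catalog_row(category_tissue = "HCXX"))
  expect_error(read_catalog(badcat), "unknown category")

  orphan <- write_catalog_file(minimal_catalog_row(present_xtr = "0",
                                                   present_L = "0",
                                                   present_S = "0",
                                                   identity_pct = "NA",
                                                   dnds_L = "NA", dnds_S = "NA"))
  expect_error(read_catalog(orphan), "present in no genome")
})

test_that("retention summary reproduces subgenome retention from presence flags", {
  lig <- retention_summary(cat_fixture, "ligand")
  expect_equal(lig[c("n_xtr", "n_L", "n_S")], list(n_xtr = 30L, n_L = 28L, n_S = 23L))
  expect_equal(lig$rate_L, 28 / 30)
  expect_equal(lig$rate_S, 23 / 30)

  rec <- retention_summary(cat_fixture, "receptor")
  expect_equal(rec[c("n_xtr", "n_L", "n_S")], list(n_xtr = 17L, n_L = 17L, n_S = 9L))

  # all flags true -> full retention
  full <- write_catalog_file(rbind(minimal_catalog_row("genea"),
                                   minimal_catalog_row("geneb")))
  r <- retention_summary(read_catalog(full))
  expect_equal(r$rate_L, 1)
  expect_equal(r$rate_S, 1)

  # no reference genes -> rates undefined, not 0
  noref <- write_catalog_file(minimal_catalog_row(present_xtr = "0",
                                                  identity_pct = "NA",
                                                  dnds_L = "NA", dnds_S = "NA"))
  r0 <- retention_summary(read_catalog(noref))
  expect_true(is.na(r0$rate_L) && is.na(r0$rate_S))
})

test_that("retention rates are invariant under row permutation", {
  set.seed(7)
  shuffled <- cat_fixture[sample(nrow(cat_fixture)), ]
  class(shuffled) <- class(cat_fixture)
  for (role in c("ligand", "receptor"))
    expect_identical(retention_summary(shuffled, role)[-1],
                     retention_summary(cat_fixture, role)[-1])
})

test_that("pair/singleton tally satisfies the copy-count identity", {
  expect_equal(pair_singleton_tally(cat_fixture, "ligand"),
               list(n_pairs = 22L, n_singletons = 8L, n_genes = 52L))
  expect_equal(pair_singleton_tally(cat_fixture, "receptor"),
               list(n_pairs = 9L, n_singletons = 8L, n_genes = 26L))

  single <- write_catalog_file(minimal_catalog_row(present_S = "0",
                                                   identity_pct = "NA",
                                                   dnds_S = "NA"))
  expect_equal(pair_singleton_tally(read_catalog(single)),
               list(n_pairs = 0L, n_singletons = 1L, n_genes = 1L))

  # property: 2 * pairs + singletons = polyploid copies on random catalogs
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(1:40, 1)
    pl <- sample(c(TRUE, FALSE), n, replace = TRUE)
    ps <- sample(c(TRUE, FALSE), n, replace = TRUE)
    keep <- pl | ps
    pl <- pl[keep]; ps <- ps[keep]
    if (!length(pl)) next
    df <- minimal_catalog_row(sprintf("gene%03d", seq_along(pl)),
                              present_L = ifelse(pl, "1", "0"),
                              present_S = ifelse(ps, "1", "0"),
                              identity_pct = ifelse(pl & ps, "80", "NA"),
                              dnds_L = ifelse(pl, "0.5", "NA"),
                              dnds_S = ifelse(ps, "0.5", "NA"))
    tal <- pair_singleton_tally(read_catalog(write_catalog_file(df)))
    expect_equal(tal$n_genes, sum(pl) + sum(ps))
    expect_equal(2L * tal$n_pairs + tal$n_singletons, tal$n_genes)
  }
})

test_that("mean homeolog identity is averaged over non-missing values", {
  rec <- mean_identity(cat_fixture, "receptor")
  expect_equal(rec$mean, 789 / 9, tolerance = 1e-12)
  expect_equal(rec$rounded, 88)
  expect_equal(rec$n, 9L)

  lig <- mean_identity(cat_fixture, "ligand")
  expect_equal(lig$rounded, 77)
  expect_equal(lig$n, 21L)  # ccl34b has no identity value

  one <- write_catalog_file(minimal_catalog_row(identity_pct = "50"))
  expect_equal(mean_identity(read_catalog(one))$mean, 50)

  none <- write_catalog_file(minimal_catalog_row(identity_pct = "NA"))
  expect_true(is.na(mean_identity(read_catalog(none))$mean))
})

test_that("omega exceedance flags the right copies and is monotone in threshold", {
  lig <- omega_exceedance(cat_fixture, "ligand", threshold = 1)
  expect_equal(lig$n_exceeding_pairs, 4L)
  expect_setequal(lig$flagged_copies,
                  c("cxcl8b.1.S", "cxcl18.S", "ccl21.S", "xcl1.L"))
  # xcl2.L sits exactly at 1.00 and must not be flagged (strict inequality)
  expect_false("xcl2.L" %in% lig$flagged_copies)

  rec <- omega_exceedance(cat_fixture, "receptor", threshold = 1)
  expect_equal(rec$n_exceeding_pairs, 0L)
  expect_length(rec$flagged_copies, 0L)

  expect_equal(omega_exceedance(cat_fixture, "all", 1e9)$n_exceeding_pairs, 0L)

  thresholds <- c(0.1, 0.3, 0.5, 1, 1.5, 2, 3)
  flags <- vapply(thresholds, function(t)
    omega_exceedance(cat_fixture, "all", t)$n_exceeding_pairs, integer(1))
  expect_true(all(diff(flags) <= 0))
})

test_that("category tallies partition the labeled entries", {
  tis <- category_tally(cat_fixture, "tissue")
  expect_equal(tis[["HCSE"]], 6L)
  expect_equal(tis[["HCDE"]], 10L)
  expect_equal(tis[["NCSE"]], 0L)
  expect_equal(tis[["NCDE"]], 3L)
  # the fixture's tissue column carries 10 inconsistent rows; one further row
  # has no tissue call at all and is reported as unlabeled, so both readings
  # of the printed total can be inspected
  expect_equal(tis[["inc"]], 10L)
  expect_equal(sum(tis), nrow(cat_fixture))

  emb <- category_tally(cat_fixture, "embryonic")
  expect_equal(sum(emb), nrow(cat_fixture))

  empty <- read_catalog(write_catalog_file(minimal_catalog_row()[0, ]))
  expect_true(all(category_tally(empty, "tissue") == 0L))
})
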