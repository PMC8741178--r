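test_that("amino-acid fractions count correctly and exclude ambiguity codes", {
  f <- aa_fractions("GGGG")
  expect_equal(unname(f["G"]), 1)
  expect_equal(sum(f), 1)

  f <- aa_fractions("GALA")
  expect_equal(unname(f[c("A", "G", "L")]), c(0.5, 0.25, 0.25))

  # X excluded from numerator and denominator
  expect_equal(unname(aa_fractions("GXGG")["G"]), 1)
  expect_error(aa_fractions("XXXX"), "no standard")
})

test_that("aa_fractions sum to 1 for random sequences", {
  set.seed(1)
  for (i in 1:50) {
    s <- random_sequence(sample(5:200, 1),
                         letters = c(AA20, "X", "B", "Z"))
    if (!any(strsplit(s, "")[[1]] %in% AA20)) next
    expect_equal(sum(aa_fractions(s)), 1, tolerance = 1e-12)
  }
})

test_that("GRAVY matches hand-computed and brute-force oracle values", {
  expect_equal(gravy("GALA"), (-0.4 + 1.8 + 3.8 + 1.8) / 4)
  expect_equal(gravy("AAAA"), 1.8)
  set.seed(2)
  for (i in 1:50) {
    s <- random_sequence(30)
    expect_equal(gravy(s), unname(oracle_gravy(s)), tolerance = 1e-14)
  }
})

test_that("global descriptors: aromaticity, flexibility, pI, charge", {
  g <- global_descriptors("WYF")
  expect_equal(unname(g["aromaticity"]), 1)

  # homopolymer: window weights normalize to 1, so flexibility equals
  # the per-residue scale value of A
  g <- global_descriptors("AAAAAAAAAA")
  expect_equal(unname(g["mean_flexibility"]), 0.984, tolerance = 1e-12)

  # flexibility fallback below one full window
  expect_message(global_descriptors("GAL"), "flexibility window")

  # polylysine: basic pI, and the net charge at the returned pI is ~0
  g <- suppressMessages(global_descriptors("KKKKK"))
  pi_val <- unname(g["isoelectric_point"])
  expect_gt(pi_val, 9)
  expect_lt(abs(coronaRF:::charge_at_ph("KKKKK", pi_val)), 0.01)

  # acidic protein carries negative charge at pH 7
  expect_lt(unname(suppressMessages(
    global_descriptors("DDEEDDEE"))["charge_ph7"]), 0)
})

test_that("molecular weight equals residue masses minus peptide waters", {
  g <- suppressMessages(global_descriptors("GG"))
  expect_equal(unname(g["molecular_weight"]), 2 * 75.0666 - 18.0153,
               tolerance = 1e-6)
})

test_that("instability index matches the brute-force dipeptide oracle", {
  set.seed(3)
  for (i in 1:30) {
    s <- random_sequence(sample(10:80, 1))
    expect_equal(unname(suppressMessages(
      global_descriptors(s))["instability_index"]),
      unname(oracle_instability(s)), tolerance = 1e-12)
  }
})

test_that("structure-set fractions respect the overlapping sets", {
  f <- ss_fractions("VVVV")
  expect_equal(unname(f), c(1, 0, 0, 0))
  expect_equal(unname(ss_fractions("RRRR")["nonstructure"]), 1)
  # L is both helix- and sheet-associated
  f <- ss_fractions("LLLL")
  expect_equal(unname(f["helix"]), 1)
  expect_equal(unname(f["sheet"]), 1)
})

test_that("nonstructure is exactly one minus the set-union fraction", {
  set.seed(4)
  for (i in 1:30) {
    s <- random_sequence(sample(10:100, 1))
    f <- ss_fractions(s)
    expect_equal(unname(f), unname(oracle_ss_fractions(s)),
                 tolerance = 1e-14)
  }
})

test_that("featurize assembles the registry in order and is pure", {
  reg <- default_registry()
  expect_equal(nrow(reg), 75)
  rec <- protein_records("P1", random_sequence(60))
  v1 <- featurize(rec)
  v2 <- featurize(rec)
  expect_identical(v1, v2)
  expect_equal(names(v1), reg$name)
  expect_equal(attr(v1, "exposure_source"), "heuristic")
})

test_that("featurize uses supplied exposure and checks alignment", {
  seq <- "GALAG"
  expo <- heuristic_exposure(seq)
  v <- featurize(seq, exposure = expo)
  expect_equal(attr(v, "exposure_source"), "netsurfp")
  expect_error(featurize("GALAGG", exposure = expo), "does not match")

  v0 <- featurize(seq, fallback = "none")
  expect_true(all(v0[paste0("exp_total_", AA20)] == 0))
  expect_equal(attr(v0, "exposure_source"), "none")
})

test_that("featurize_set builds a table with provenance column", {
  recs <- protein_records(c("a", "b"), c("GALAGALAGALA", "KVFGRKVFGR"))
  ft <- featurize_set(recs)
  expect_equal(ft$accession, c("a", "b"))
  expect_true(all(ft$exposure_source == "heuristic"))
  expect_equal(setdiff(names(ft), c("accession", "exposure_source")),
               default_registry()$name)
})

test_that("min-max scaling: examples, constants, clipping, name checks", {
  x <- cbind(f1 = c(2, 4, 6), f2 = c(3, 3, 3))
  fit <- minmax_fit(x)
  s <- minmax_apply(fit, x)
  expect_equal(unname(s[, "f1"]), c(0, 0.5, 1))
  expect_equal(unname(s[, "f2"]), c(0, 0, 0))

  # unseen values clip into [0, 1]
  out <- minmax_apply(fit, cbind(f1 = 10, f2 = -5))
  expect_equal(unname(out[1, ]), c(1, 0))

  expect_error(minmax_apply(fit, cbind(f1 = 1, other = 2)), "unknown")
  expect_error(minmax_fit(cbind(f1 = 1)), "at least 2")
})

test_that("after scaling, every non-constant feature attains 0 and 1", {
  set.seed(6)
  x <- matrix(rnorm(200), ncol = 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  s <- minmax_apply(minmax_fit(x), x)
  expect_true(all(apply(s, 2, min) == 0))
  expect_true(all(apply(s, 2, max) == 1))
})
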