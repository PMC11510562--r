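test_that("additive ground truth is exact and seeded generation is reproducible", {
  # zero noise, one fragment: logS follows the additive formula exactly
  spec <- solubility_spec(n_molecules = 40, fragment_vocab = "hydroxyl",
                          true_contribution = c(hydroxyl = 1),
                          intercept_true = -2, noise_sd = 0, seed = 3)
  ds <- generate_solubility_dataset(spec)
  n_oh <- ds$truth$fragment_counts[, "hydroxyl"]
  expect_equal(ds$table$logS, -2 + n_oh, tolerance = 1e-12)
  two_oh <- which(n_oh == 2)
  if (length(two_oh) > 0) expect_equal(ds$table$logS[two_oh[1]], 0)

  # byte-identical regeneration from the same spec
  expect_identical(generate_solubility_dataset(spec),
                   generate_solubility_dataset(spec))
  # a different seed gives a different table
  spec2 <- solubility_spec(n_molecules = 40, fragment_vocab = "hydroxyl",
                           true_contribution = c(hydroxyl = 1),
                           intercept_true = -2, noise_sd = 0, seed = 4)
  expect_false(identical(generate_solubility_dataset(spec2)$table, ds$table))
})

test_that("noiseless logS recomputes from fragment counts to 1e-12", {
  ds <- make_fixture_dataset(n = 200, seed = 17)
  contrib <- numeric(ncol(ds$truth$fragment_counts))
  names(contrib) <- colnames(ds$truth$fragment_counts)
  contrib[names(ds$truth$true_contribution)] <- ds$truth$true_contribution
  recomputed <- ds$truth$intercept_true +
    as.numeric(ds$truth$fragment_counts %*% contrib)
  expect_equal(ds$truth$noiseless, recomputed, tolerance = 1e-12)
})

test_that("emitted noise matches the requested level", {
  ds <- generate_solubility_dataset(
    solubility_spec(n_molecules = 500, noise_sd = 0.3, seed = 7))
  resid_sd <- sd(ds$table$logS - ds$truth$noiseless)
  expect_gt(resid_sd, 0.25)
  expect_lt(resid_sd, 0.35)
})

test_that("every generated SMILES parses back to the stored graph", {
  ds <- make_fixture_dataset(n = 80, seed = 29)
  canon_bonds <- function(b) {
    lo <- pmin(b$from, b$to); hi <- pmax(b$from, b$to)
    o <- order(lo, hi)
    data.frame(from = lo[o], to = hi[o], order = b$order[o])
  }
  for (i in seq_len(nrow(ds$table))) {
    reparsed <- parse_smiles(ds$table$smiles[i])
    stored <- ds$truth$molecules[[i]]
    expect_equal(reparsed$atoms, stored$atoms, info = ds$table$smiles[i])
    expect_equal(canon_bonds(reparsed$bonds), canon_bonds(stored$bonds),
                 info = ds$table$smiles[i])
    expect_length(ds$truth$atom_fragments[[i]], nrow(stored$atoms))
  }
})

test_that("atom fragment classes are chemically coherent", {
  ds <- make_fixture_dataset(n = 100, seed = 41)
  for (i in seq_len(nrow(ds$table))) {
    mol <- ds$truth$molecules[[i]]
    frag <- ds$truth$atom_fragments[[i]]
    expect_true(all(mol$atoms$n_h[frag == "methyl"] == 3L))
    expect_true(all(mol$atoms$element[frag == "hydroxyl"] == "O"))
    expect_true(all(mol$atoms$aromatic[frag == "phenyl"]))
    # instance counts match atom counts for multi-atom fragments
    expect_equal(sum(frag == "phenyl") %% 6, 0)
    expect_equal(sum(frag == "carboxyl") %% 3, 0)
  }
})

test_that("invalid fragment identifiers are refused by name", {
  expect_error(solubility_spec(fragment_vocab = c("hydroxyl", "nitro")),
               "nitro")
  expect_error(solubility_spec(true_contribution = c(sulfate = 1)),
               "sulfate")
  expect_error(solubility_spec(n_molecules = 0), "at least 1")
  expect_error(solubility_spec(noise_sd = -0.1), "non-negative")
})

test_that("mulliken fixtures are analytic and electron-count consistent", {
  for (case in c("orthonormal_neutral", "h2_symmetric", "asymmetric_ionic")) {
    fx <- make_mulliken_fixture(case)
    expect_equal(sum(diag(fx$P %*% fx$S)),
                 sum(fx$Z) - fx$total_charge, tolerance = 1e-10)
  }
  # h2_symmetric by hand: P = ones/(1+s), S = [[1,s],[s,1]] gives
  # diag(PS) = (1, 1) for any s; the fixture freezes s = 0.659
  fx <- make_mulliken_fixture("h2_symmetric")
  expect_equal(diag(fx$P %*% fx$S), c(1, 1), tolerance = 1e-12)
  expect_equal(fx$S[1, 2], 0.659)

  expect_error(make_mulliken_fixture("no_such_case"), "orthonormal_neutral")
})

test_that("mulliken fixtures round-trip through the plain-text format", {
  dir <- tempfile()
  fx <- make_mulliken_fixture("h2_symmetric", dir = dir)
  expect_true(all(file.exists(file.path(dir, c("P.txt", "S.txt",
                                               "header.json",
                                               "expected.json")))))
  inp <- read_population_dir(dir)
  expect_equal(inp$P, fx$P, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(inp$S, fx$S, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(inp$Z, fx$Z)
})

test_that("contact fixtures transcribe the observed cross-peak lists", {
  t2 <- make_contact_fixture("2mM")
  expect_equal(nrow(t2), 2L)
  expect_setequal(paste(t2$solute_proton, t2$surfactant_proton),
                  c("H4 Hc", "H22 Hc"))
  t5 <- make_contact_fixture("5mM")
  expect_equal(nrow(t5), 3L)
  expect_setequal(paste(t5$solute_proton, t5$surfactant_proton),
                  c("H4 Hc", "H20 He", "H22 Hc"))
  expect_error(make_contact_fixture("10mM"), "2mM")

  # round trip through the CSV writer/parser
  f <- tempfile(fileext = ".csv")
  write_contact_table(t5, f)
  back <- parse_contact_table(f, concentration_mM = 5)
  expect_equal(back$solute_proton, t5$solute_proton)
  expect_equal(back$surfactant_proton, t5$surfactant_proton)
  expect_equal(back$intensity, t5$intensity)
})
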