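test_that("contact tables validate labels, duplicates and intensities", {
  ok <- contact_table(data.frame(solute_proton = "H4",
                                 surfactant_proton = "Hc"))
  expect_s3_class(ok, "contact_table")
  expect_equal(ok$intensity, 1)

  expect_error(contact_table(data.frame(solute_proton = "H99",
                                        surfactant_proton = "Hc")), "H99")
  expect_error(contact_table(data.frame(solute_proton = "H4",
                                        surfactant_proton = "Hz")), "Hz")
  expect_error(contact_table(data.frame(
    solute_proton = c("H4", "H4"), surfactant_proton = c("Hc", "Hc"))),
    "duplicate")
  expect_error(contact_table(data.frame(solute_proton = "H4",
                                        surfactant_proton = "Hc",
                                        intensity = -1)), "non-negative")
})

test_that("CSV parsing enforces the schema and supports empty tables", {
  f <- tempfile(fileext = ".csv")
  writeLines("solute_proton,surfactant_proton,intensity", f)
  empty <- parse_contact_table(f)
  expect_equal(nrow(empty), 0L)
  expect_equal(nrow(region_summary(empty)), 0L)

  writeLines(c("solute_proton,surfactant_proton", "H99,Hc"), f)
  expect_error(parse_contact_table(f), "H99")
})

test_that("region summary produces the expected contingency counts", {
  t5 <- make_contact_fixture("5mM")
  summ <- region_summary(t5)
  expect_equal(summ["H4", "chain"], 1)
  expect_equal(summ["H20", "headgroup"], 1)
  expect_equal(summ["H22", "chain"], 1)
  expect_equal(sum(summ), nrow(t5))     # marginals equal table size

  # uncovered surfactant label is an error
  partial <- region_map(c(Hc = "chain"))
  expect_error(region_summary(t5, partial), "He")

  # weighted mode sums intensities
  tw <- contact_table(data.frame(solute_proton = c("H4", "H4"),
                                 surfactant_proton = c("Hc", "He"),
                                 intensity = c(2.5, 0.5)))
  sw <- region_summary(tw, weighted = TRUE)
  expect_equal(sw["H4", "chain"], 2.5)
  expect_equal(sw["H4", "headgroup"], 0.5)
})

test_that("localization scores follow the core-surface contrast formula", {
  # chain-only contacts: score +1, "core"
  t2 <- make_contact_fixture("2mM")
  loc <- localization_index(region_summary(t2))
  expect_equal(loc$score[loc$proton == "H22"], 1)
  expect_equal(loc$label[loc$proton == "H22"], "core")
  expect_equal(loc$label[loc$proton == "H4"], "core")

  # at 5 mM H20 contacts only the headgroup region: surface, score -1
  t5 <- make_contact_fixture("5mM")
  loc5 <- localization_index(region_summary(t5))
  expect_equal(loc5$score[loc5$proton == "H20"], -1)
  expect_equal(loc5$label[loc5$proton == "H20"], "surface")
  expect_equal(loc5$label[loc5$proton == "H22"], "core")

  # balanced contacts sit at the interface
  tb <- contact_table(data.frame(solute_proton = c("H1", "H1"),
                                 surfactant_proton = c("Ha", "He")))
  locb <- localization_index(region_summary(tb))
  expect_equal(locb$score, 0)
  expect_equal(locb$label, "interface")
})

test_that("swapping core and surface regions negates every score", {
  flipped <- region_map(c(Ha = "headgroup", Hb = "headgroup",
                          Hc = "headgroup", Hd = "chain", He = "chain",
                          Hf = "chain"))
  for (label in c("2mM", "5mM")) {
    tab <- make_contact_fixture(label)
    s1 <- localization_index(region_summary(tab))
    s2 <- localization_index(region_summary(tab, flipped))
    expect_equal(s2$score, -s1$score)
  }
})

test_that("adding a chain contact never decreases a proton's score", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(1:4, 1)
    surf <- sample(c("Ha", "Hc", "He", "Hf"), n, replace = FALSE)
    base <- contact_table(data.frame(solute_proton = rep("H4", n),
                                     surfactant_proton = surf))
    s_before <- localization_index(region_summary(base))$score
    extra_label <- setdiff(c("Hb"), surf)   # Hb -> chain in the default map
    augmented <- contact_table(data.frame(
      solute_proton = rep("H4", n + 1),
      surfactant_proton = c(surf, "Hb")))
    s_after <- localization_index(region_summary(augmented))$score
    expect_gte(s_after, s_before)
  }
})

test_that("region maps validate and load from JSON", {
  expect_error(region_map(c(Hz = "chain")), "Hz")
  expect_error(region_map(c(Hc = "middle")), "middle")
  expect_error(region_map("chain"), "named")

  f <- tempfile(fileext = ".json")
  jsonlite::write_json(as.list(unclass(default_region_map())), f,
                       auto_unbox = TRUE)
  rm2 <- read_region_map(f)
  expect_equal(unclass(rm2), unclass(default_region_map()))
})

test_that("the markdown report summarizes contacts and labels", {
  lines <- roe_report(make_contact_fixture("5mM"))
  expect_true(any(grepl("H22", lines) & grepl("core", lines)))
  expect_true(any(grepl("H20", lines) & grepl("surface", lines)))
  f <- tempfile(fileext = ".md")
  roe_report(make_contact_fixture("2mM"), file = f)
  expect_true(file.exists(f))
})
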