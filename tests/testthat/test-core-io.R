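test_that("surveys round-trip through CSV bit-identically", {
  s <- toy_survey()
  f <- withr::local_tempfile(fileext = ".csv")
  write_survey(s, f)
  s2 <- read_survey(f)
  for (col in c("pH", "As", "Cd", "Cr", "Hg", "Pb")) {
    expect_identical(s2[[col]], s[[col]])
  }
  expect_identical(s2$sample_id, s$sample_id)

  # same round trip for a generated survey, field by field
  g <- generate_survey(generator_spec(n = 120), seed = 31)
  fg <- withr::local_tempfile(fileext = ".csv")
  write_survey(g, fg)
  g2 <- read_survey(fg)
  expect_equal(nrow(g2), 120)
  for (col in c("pH", "As", "Cd", "Cr", "Hg", "Pb", "x", "y")) {
    expect_identical(g2[[col]], g[[col]])
  }
  expect_match(attr(g, "provenance"), "^synthetic:31$")
})

test_that("invalid samples are rejected with row-level diagnostics", {
  bad <- tibble::tibble(sample_id = c("r1", "r2"), pH = c(6, 6),
                        As = c(2, 3), Cd = c(0.2, -0.1))
  expect_error(as_survey(bad), "r2.*Cd|Cd.*r2")
  expect_error(as_survey(tibble::tibble(sample_id = "q", pH = 15, As = 1)),
               "pH")
  expect_error(as_survey(tibble::tibble(sample_id = c("x", "x"),
                                        pH = c(6, 6), As = c(1, 2))),
               "duplicated")
  expect_error(as_survey(tibble::tibble(pH = 6.5)), "metal")
})

test_that("column-name mapping accepts arbitrary survey exports", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(id = "s1", soil_ph = 6.0,
                                  as_mgkg = 5, cd_mgkg = 0.2), f)
  s <- read_survey(f, schema = c(sample_id = "id", pH = "soil_ph",
                                 As = "as_mgkg", Cd = "cd_mgkg"))
  expect_equal(s$As, 5)
  expect_error(read_survey(f, schema = c(pH = "no_such_col")),
               "no_such_col")
  expect_error(read_survey(f), "pH")
})

test_that("ph_class follows right-closed regulatory boundaries", {
  expect_equal(as.character(ph_class(5.5)), "<=5.5")
  expect_equal(as.character(ph_class(6.5)), "(5.5,6.5]")
  expect_equal(as.character(ph_class(6.14)), "(5.5,6.5]")
  expect_equal(as.character(ph_class(7.5)), "(6.5,7.5]")
  expect_equal(as.character(ph_class(8.06)), ">7.5")
  expect_error(ph_class(0), "pH")
  expect_error(ph_class(14), "pH")

  # total function partitioning (0, 14): every value lands in exactly one class
  grid <- seq(0.01, 13.99, length.out = 2000)
  cls <- ph_class(grid)
  expect_false(anyNA(cls))
  expect_setequal(levels(cls),
                  c("<=5.5", "(5.5,6.5]", "(6.5,7.5]", ">7.5"))
})

test_that("bundled reference defaults match the regulatory tables", {
  scr <- load_screening_values()
  # full screening grid of GB 15618-2018 for the five metals
  expected <- expand.grid(
    metal = c("As", "Cd", "Cr", "Hg", "Pb"),
    ph_class = c("<=5.5", "(5.5,6.5]", "(6.5,7.5]", ">7.5"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  expected$screening <- c(
    30, 0.30, 250, 0.50, 80,
    30, 0.4, 250, 0.50, 100,
    25, 0.6, 300, 0.6, 140,
    20, 0.8, 350, 1.0, 240)
  got <- merge(expected, scr, by = c("metal", "ph_class"),
               suffixes = c("_want", ""))
  expect_equal(got$screening, got$screening_want)

  bg <- load_background_values()
  expect_equal(setNames(bg$background, bg$metal)[c("As", "Cd", "Cr", "Hg", "Pb")],
               c(As = 20, Cd = 0.66, Cr = 95.9, Hg = 0.1, Pb = 35.2))
  expect_equal(setNames(bg$toxic_response, bg$metal)[c("As", "Cd", "Cr", "Hg", "Pb")],
               c(As = 10, Cd = 30, Cr = 2, Hg = 40, Pb = 5))
})

test_that("user reference tables are validated against the vocabulary", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(metal = "Zn", background = 50,
                                  toxic_response = 1), f)
  expect_error(suppressMessages(load_background_values(f)),
               "unknown metal.*accepted metals")
  f2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(metal = "As", organ = "hepatic",
                                  ttd = 1e-3), f2)
  expect_error(suppressMessages(load_ttd_table(f2)),
               "unknown organ.*accepted organs")
  # overrides are reported
  f3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(load_background_values(), f3)
  expect_message(load_background_values(f3), "user-supplied")
})

test_that("exposure profiles expose positive point values and valid specs", {
  for (pop in c("adults", "children")) {
    prof <- load_exposure_profile(pop)
    expect_true(all(prof$table$value > 0))
    abs_val <- prof$table$value[prof$table$parameter == "ABS"]
    expect_true(abs_val > 0 && abs_val <= 1)
    specs <- soilhmrisk:::profile_specs(prof)
    expect_true(all(vapply(specs, inherits, logical(1), "dist_spec")))
  }
  # toxicity absences are explicit NAs, mirroring the blank reference cells
  tox <- load_toxicity_table()
  expect_true(is.na(tox$rfd[tox$metal == "Hg" & tox$pathway == "inh"]))
  expect_true(all(is.na(tox$sf[tox$metal == "Hg"])))
  expect_true(is.na(tox$sf[tox$metal == "Cd" & tox$pathway == "dermal"]))
  expect_true(is.na(tox$sf[tox$metal == "Pb" & tox$pathway == "dermal"]))
})
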