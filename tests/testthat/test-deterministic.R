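test_that("dose equations: null, linearity and limit behaviour", {
  prof <- load_exposure_profile("adults")
  expect_equal(add_ingestion(0, prof), 0)
  expect_equal(add_inhalation(0, prof), 0)
  expect_equal(add_ingestion(2 * 9.08, prof), 2 * add_ingestion(9.08, prof))

  p <- profile_as_list("adults")
  # ABS = 0 zeroes the dermal dose; scaling SA scales it linearly
  p0 <- p; p0$ABS <- 1e-300
  expect_lt(add_dermal(10, p0), 1e-290)
  p2 <- p; p2$SA <- 3 * p$SA
  expect_equal(add_dermal(10, p2), 3 * add_dermal(10, p))
  # dose -> 0 monotonically as PEF grows
  pefs <- 10^(7:12)
  doses <- vapply(pefs, function(pef) {
    pp <- p; pp$PEF <- pef
    add_inhalation(5, pp)
  }, numeric(1))
  expect_true(all(diff(doses) < 0))

  pneg <- p; pneg$BW <- -1
  expect_error(add_ingestion(1, pneg), "BW")
  pmiss <- p; pmiss$R_ing <- NULL
  expect_error(add_ingestion(1, pmiss), "R_ing")
})

test_that("vectorised risk pipeline equals scalar formula evaluation", {
  s <- random_survey(4, seed = 21)
  tox <- load_toxicity_table()
  risk <- deterministic_risk(s, quiet = TRUE)
  for (pop in c("adults", "children")) {
    p <- profile_as_list(pop)
    for (i in seq_len(nrow(s))) {
      for (m in c("As", "Cd", "Cr", "Hg", "Pb")) {
        dn <- oracle_doses(s[[m]][i], p, "nc")
        dc <- oracle_doses(s[[m]][i], p, "ca")
        hi <- cr <- 0
        for (pw in c("ing", "inh", "dermal")) {
          rfd <- tox$rfd[tox$metal == m & tox$pathway == pw]
          sf <- tox$sf[tox$metal == m & tox$pathway == pw]
          if (!is.na(rfd)) hi <- hi + dn[[pw]] / rfd
          if (!is.na(sf)) cr <- cr + dc[[pw]] * sf
        }
        row <- risk$by_metal[risk$by_metal$scenario == s$sample_id[i] &
                               risk$by_metal$population == pop &
                               risk$by_metal$metal == m, ]
        expect_equal(row$HI, hi, tolerance = 1e-12)
        if (m != "Hg") expect_equal(row$CR, cr, tolerance = 1e-12)
      }
    }
  }
})

test_that("reference-mean risks match the published per-pathway values", {
  risk <- deterministic_risk(ref_mean_conc(), quiet = TRUE)
  cell <- function(pop, m, pw, what) {
    r <- risk$by_pathway
    r[[what]][r$population == pop & r$metal == m & r$pathway == pw]
  }
  expect_equal(cell("adults", "As", "ing", "hi"), 4.51e-2, tolerance = 0.02)
  expect_equal(cell("adults", "As", "inh", "hi"), 3.36e-4, tolerance = 0.02)
  expect_equal(cell("adults", "As", "dermal", "hi"), 4.35e-4, tolerance = 0.02)
  expect_equal(cell("children", "Cr", "dermal", "hi"), 6.81e-2, tolerance = 0.02)
  expect_equal(cell("children", "As", "ing", "cr"), 1.36e-4, tolerance = 0.02)
  tot <- risk$totals
  expect_equal(tot$HI_ing[tot$population == "children"], 7.54e-1,
               tolerance = 0.02)
  expect_equal(tot$HI_dermal[tot$population == "children"], 7.22e-2,
               tolerance = 0.02)
})

test_that("absent RfD/SF cells contribute exactly zero and are reported", {
  conc <- ref_mean_conc()
  expect_message(deterministic_risk(conc), "no SF.*Hg")
  risk <- deterministic_risk(conc, quiet = TRUE)
  bp <- risk$by_pathway
  expect_true(is.na(bp$hi[bp$metal == "Pb" & bp$pathway == "inh" &
                            bp$population == "adults"]))
  expect_true(all(is.na(bp$cr[bp$metal == "Hg"])))
  expect_true(is.na(risk$by_metal$CR[risk$by_metal$metal == "Hg"][1]))
  # THI/TCR are exact sums over the present cells
  for (pop in c("adults", "children")) {
    bm <- risk$by_metal[risk$by_metal$population == pop, ]
    tt <- risk$totals[risk$totals$population == pop, ]
    expect_identical(tt$THI, sum(bm$HI, na.rm = TRUE))
    expect_identical(tt$TCR, sum(bm$CR, na.rm = TRUE))
  }
  # a metal with no RfD anywhere is excluded with a warning
  expect_warning(res <- hazard_index(c(inh = 1e-6), load_toxicity_table(), "Hg"),
                 "no RfD")
  expect_true(is.na(res))
  expect_equal(hazard_index(c(ing = 3e-4), load_toxicity_table(), "As"), 1)
  expect_warning(carcinogenic_risk(c(ing = 1e-6), load_toxicity_table(), "Hg"),
                 "no slope factor")
})

test_that("children carry higher risks than adults for every metal", {
  risk <- deterministic_risk(ref_mean_conc(), quiet = TRUE)
  wide <- tidyr::pivot_wider(risk$by_metal, names_from = population,
                             values_from = c(HI, CR))
  expect_true(all(wide$HI_children > wide$HI_adults))
  expect_true(all(wide$CR_children > wide$CR_adults, na.rm = TRUE))
})
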