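test_that("distribution sampling honours kinds, truncation and seeds", {
  expect_equal(sample_dist(dist_point(3.7), 5), rep(3.7, 5))

  # truncated-normal oracle: closed-form mean of N(100,10) on [80, 120]
  a <- (80 - 100) / 10; b <- (120 - 100) / 10
  m_true <- 100 + 10 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  x <- withr::with_seed(77, sample_dist(dist_normal(100, 10, 80, 120), 2e4))
  expect_true(all(x >= 80 & x <= 120))
  expect_lt(abs(mean(x) - m_true), 3 * sd(x) / sqrt(length(x)))

  # lognormal draws reproduce the requested arithmetic moments
  y <- withr::with_seed(78, sample_dist(dist_lognormal(100, 60), 5e4))
  expect_lt(abs(mean(y) - 100), 3 * sd(y) / sqrt(length(y)))

  # determinism contract
  d1 <- sample_parameters(list(a = dist_normal(0, 1), b = dist_uniform(2, 3)),
                          n = 50, seed = 11)
  d2 <- sample_parameters(list(a = dist_normal(0, 1), b = dist_uniform(2, 3)),
                          n = 50, seed = 11)
  expect_identical(d1, d2)
  expect_error(sample_parameters(list(bad = 5), 10, 1), "bad")

  # triangular CDF/quantile are mutual inverses
  tri <- dist_triangular(0, 1, 4)
  u <- seq(0.01, 0.99, by = 0.01)
  q <- sample_dist(tri, length(u), u = u)
  expect_true(all(q >= 0 & q <= 4))
  expect_equal(soilhmrisk:::ptri(q, 0, 1, 4), u, tolerance = 1e-10)
})

test_that("moment matching yields truncated laws with the target moments", {
  m <- load_survey_moments()
  for (v in c("As", "Cr", "Hg")) {
    r <- m[m$variable == v, ]
    spec <- match_truncated(r$mean, r$sd, r$min, r$max, "lognormal")
    x <- withr::with_seed(5, sample_dist(spec, 2e5))
    expect_true(all(x >= r$min & x <= r$max))
    expect_lt(abs(mean(x) - r$mean), 3 * sd(x) / sqrt(length(x)))
    expect_equal(sd(x), r$sd, tolerance = 0.02)
  }
  expect_error(match_truncated(5, 1, 10, 20), "outside")
})

test_that("degenerate point-mass specs reproduce the deterministic results", {
  conc <- ref_mean_conc()
  for (pop in c("adults", "children")) {
    prof <- point_profile(pop)
    mc <- run_monte_carlo(conc, pop, prof, n = 200, seed = 4)
    det <- deterministic_risk(conc, pop, setNames(list(prof), pop),
                              quiet = TRUE)
    hi_det <- setNames(det$by_metal$HI, det$by_metal$metal)
    cr_det <- setNames(det$by_metal$CR, det$by_metal$metal)
    for (m in colnames(mc$hi)) {
      expect_equal(unname(mc$hi[, m]), rep(hi_det[[m]], 200), tolerance = 1e-14)
      if (!is.na(cr_det[[m]])) {
        expect_equal(unname(mc$cr[, m]), rep(cr_det[[m]], 200),
                     tolerance = 1e-14)
      }
    }
    expect_equal(mean(mc$thi), det$totals$THI, tolerance = 1e-14)
    expect_equal(mean(mc$tcr), det$totals$TCR, tolerance = 1e-14)
  }
})

test_that("Monte Carlo runs are reproducible and consistent across n", {
  mc1 <- run_monte_carlo(population = "adults", n = 2000, seed = 99)
  mc2 <- run_monte_carlo(population = "adults", n = 2000, seed = 99)
  expect_identical(mc1$hi, mc2$hi)
  expect_identical(mc1$summary, mc2$summary)

  # mean estimates at different n agree within combined Monte Carlo error
  big <- run_monte_carlo(population = "adults", n = 2e4, seed = 100)
  se1 <- sd(mc1$hi[, "Cr"]) / sqrt(mc1$n)
  se2 <- sd(big$hi[, "Cr"]) / sqrt(big$n)
  expect_lt(abs(mean(mc1$hi[, "Cr"]) - mean(big$hi[, "Cr"])),
            3 * sqrt(se1^2 + se2^2))
  expect_warning(run_monte_carlo(population = "adults", n = 50, seed = 1),
                 "unstable")
})

test_that("symmetric body-weight uncertainty leaves the HI median at the deterministic value", {
  conc <- ref_mean_conc()
  prof <- point_profile("adults")
  prof$table$dist[prof$table$parameter == "BW"] <- "uniform"
  prof$table$p1[prof$table$parameter == "BW"] <- 54.3
  prof$table$p2[prof$table$parameter == "BW"] <- 74.3
  mc <- run_monte_carlo(conc, "adults", prof, n = 2e4, seed = 8)
  det <- deterministic_risk(conc, "adults",
                            list(adults = point_profile("adults")),
                            quiet = TRUE)
  med_se <- 1.2533 * sd(mc$thi) / sqrt(mc$n)  # asymptotic SE of a median
  expect_lt(abs(median(mc$thi) - det$totals$THI), 4 * med_se)
})

test_that("risk draws scale linearly with concentration", {
  k <- 2.5
  mc1 <- run_monte_carlo(c(As = 9.08, Cr = 73.06), "adults", n = 500, seed = 12)
  mc2 <- run_monte_carlo(c(As = 9.08, Cr = 73.06) * k, "adults", n = 500,
                         seed = 12)
  expect_equal(mc2$hi, k * mc1$hi, tolerance = 1e-12)
  expect_equal(mc2$cr, k * mc1$cr, tolerance = 1e-12)
})

test_that("exceedance probabilities equal brute-force counts over the draws", {
  mc <- run_monte_carlo(population = "children", n = 1000, seed = 55)
  thr <- median(mc$thi)
  expect_equal(exceedance_probability(mc, thr, "thi"),
               sum(mc$thi > thr) / length(mc$thi))
  expect_equal(exceedance_probability(mc, -1, "thi"), 1)
  expect_equal(exceedance_probability(mc, max(mc$thi) + 1, "thi"), 0)
  expect_equal(exceedance_probability(mc, 1e-4, "cr", metal = "Cr"),
               mean(mc$cr[, "Cr"] > 1e-4))
})

test_that("contribution shares are normalised and symmetric", {
  expect_equal(contribution_shares(c(A = 2, B = 2))$share_pct, c(50, 50))
  mc <- run_monte_carlo(population = "adults", n = 1000, seed = 2)
  sh <- contribution_shares(mc, "hi")
  expect_equal(sum(sh$share_pct), 100, tolerance = 1e-12)
  sh_cr <- contribution_shares(mc, "cr")
  expect_equal(sum(sh_cr$share_pct), 100, tolerance = 1e-12)
  expect_false("Hg" %in% sh_cr$metal)  # no slope factors for Hg
  expect_error(contribution_shares(c(A = 1)), "two metals")
})
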