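# Shared fixtures, all built in code.

# reference survey-mean concentrations (mg/kg) from the bundled moments table
ref_mean_conc <- function() {
  m <- load_survey_moments()
  m <- m[m$variable %in% c("As", "Cd", "Cr", "Hg", "Pb"), ]
  setNames(m$mean, m$variable)
}

# three hand-written valid samples spanning the pH classes
toy_survey <- function() {
  as_survey(tibble::tibble(
    sample_id = c("a", "b", "c"),
    pH = c(5.0, 6.2, 7.8),
    As = c(3.0, 9.0, 22.0),
    Cd = c(0.5, 0.2, 0.9),
    Cr = c(40, 80, 120),
    Hg = c(0.05, 0.12, 0.25),
    Pb = c(15, 30, 45)
  ), provenance = "toy")
}

# random valid survey for property checks
random_survey <- function(n, seed) {
  withr::with_seed(seed, {
    as_survey(tibble::tibble(
      pH = runif(n, 4, 8),
      As = runif(n, 0.5, 40),
      Cd = runif(n, 0.01, 1.2),
      Cr = runif(n, 5, 400),
      Hg = runif(n, 0.005, 1.2),
      Pb = runif(n, 2, 300)
    ))
  })
}

# all-point exposure profile (collapses every distribution to its point value)
point_profile <- function(population) {
  prof <- load_exposure_profile(population)
  prof$table$dist <- "point"
  prof
}

# scalar, formula-by-formula evaluation of the dose equations; independent of
# the package's vectorised kernel
oracle_doses <- function(conc, p, averaging) {
  at <- if (averaging == "nc") p$AT_nc else p$AT_ca
  list(
    ing = conc * p$R_ing * p$EF * p$ED / (p$BW * at) * 1e-6,
    inh = conc * p$R_inh * p$EF * p$ED / (p$PEF * p$BW * at),
    dermal = conc * p$AF * p$SA * p$ABS * p$EF * p$ED / (p$BW * at) * 1e-6
  )
}

profile_as_list <- function(population) {
  tbl <- load_exposure_profile(population)$table
  setNames(as.list(tbl$value), tbl$parameter)
}
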