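#' Concentration distribution specs from tabulated survey moments
#'
#' Builds, for each metal, a truncated distribution moment-matched to the
#' tabulated mean/SD on the tabulated [min, max] (see [match_truncated()]).
#' This is the default concentration model for reproducing survey-level
#' probabilistic results when only summary moments - not per-sample data -
#' are available.
#'
#' @param moments A moments table ([load_survey_moments()] format); the `pH`
#'   row is ignored.
#' @param law `"lognormal"` (default; positive, right-skewed, the usual
#'   model for trace-element surveys) or `"normal"`.
#' @return Named list of [dist_spec] objects, one per metal.
#' @export
conc_specs_from_moments <- function(moments = NULL, law = "lognormal") {
  moments <- moments %||% load_survey_moments()
  rows <- moments[moments$variable %in% hm_metals(), ]
  specs <- lapply(seq_len(nrow(rows)), function(i) {
    match_truncated(rows$mean[i], rows$sd[i], rows$min[i], rows$max[i], law)
  })
  setNames(specs, rows$variable)
}

#' Monte Carlo probabilistic risk assessment
#'
#' Draws `n` joint realisations of the uncertain exposure parameters (from
#' the distribution column of the exposure profile) and of the soil
#' concentrations, pushes every draw through the same dose/risk kernel as
#' [deterministic_risk()], and summarises the resulting HI and CR
#' distributions. Parameters are drawn independently; draws are reproducible
#' bit-for-bit given `(seed, n)`. When every specification is a point mass
#' the draws equal the deterministic results to machine precision.
#'
#' @param conc Concentration input: a named list of [dist_spec] (e.g.
#'   [conc_specs_from_moments()]), a named numeric vector (point values), or
#'   an [as_survey] object (joint bootstrap resampling of its rows).
#'   `NULL` uses the bundled survey moments.
#' @param population `"adults"` or `"children"`.
#' @param profile,toxicity Optional overrides of the bundled tables.
#' @param n Number of iterations (default 10000). Fewer than 100 draws give
#'   unstable percentiles and trigger a warning.
#' @param seed Integer seed.
#' @return Object of class `hm_mc`: draw matrices `hi` and `cr`
#'   (`n` x metals), vectors `thi`/`tcr`, a per-metal `summary` tibble
#'   (means, 5th/50th/95th percentiles, exceedance probabilities of the
#'   HI > 1 and CR > 1e-4 thresholds, contribution shares in %), a `totals`
#'   tibble, and the `seed`/`n` used.
#' @examples
#' mc <- run_monte_carlo(c(As = 9.08, Cd = 0.36), n = 500, seed = 1)
#' mc$summary
#' @export
run_monte_carlo <- function(conc = NULL, population = c("adults", "children"),
                            profile = NULL, toxicity = NULL,
                            n = 10000, seed = NULL) {
  population <- match.arg(population)
  if (n < 1) stopf("`n` must be >= 1")
  if (n < 100) warnf("n = %d draws: percentile estimates will be unstable", n)
  profile <- profile %||% load_exposure_profile(population)
  toxicity <- toxicity %||% load_toxicity_table()
  conc <- conc %||% conc_specs_from_moments()

  draws <- withr::with_seed(seed %||% sample.int(.Machine$integer.max, 1), {
    params <- lapply(profile_specs(profile), sample_dist, n = n)
    C <- draw_concentrations(conc, n)
    list(params = params, C = C)
  })
  C <- draws$C
  params <- draws$params
  metals <- colnames(C)

  hi <- matrix(0, n, length(metals), dimnames = list(NULL, metals))
  cr <- matrix(0, n, length(metals), dimnames = list(NULL, metals))
  hi_any <- cr_any <- setNames(rep(FALSE, length(metals)), metals)
  for (pw in hm_pathways()) {
    f_nc <- dose_factor(params, pw, "nc")
    f_ca <- dose_factor(params, pw, "ca")
    rfd <- tox_lookup(toxicity, metals, pw, "rfd")
    sf <- tox_lookup(toxicity, metals, pw, "sf")
    add_nc <- C * f_nc
    add_ca <- C * f_ca
    ok <- !is.na(rfd)
    hi[, ok] <- hi[, ok] + sweep(add_nc[, ok, drop = FALSE], 2, rfd[ok], `/`)
    hi_any <- hi_any | ok
    ok <- !is.na(sf)
    cr[, ok] <- cr[, ok] + sweep(add_ca[, ok, drop = FALSE], 2, sf[ok], `*`)
    cr_any <- cr_any | ok
  }
  hi[, !hi_any] <- NA_real_
  cr[, !cr_any] <- NA_real_

  thi <- rowSums(hi, na.rm = TRUE)
  tcr <- rowSums(cr, na.rm = TRUE)

  qs <- function(x) quantile(x, c(0.05, 0.5, 0.95), names = FALSE, na.rm = TRUE)
  summary <- tibble::tibble(
    metal = metals,
    mean_HI = colMeans(hi),
    HI_p5 = apply(hi, 2, function(x) qs(x)[1]),
    HI_p50 = apply(hi, 2, function(x) qs(x)[2]),
    HI_p95 = apply(hi, 2, function(x) qs(x)[3]),
    p_HI_gt_1 = colMeans(hi > 1),
    mean_CR = colMeans(cr),
    CR_p5 = apply(cr, 2, function(x) if (all(is.na(x))) NA_real_ else qs(x)[1]),
    CR_p50 = apply(cr, 2, function(x) if (all(is.na(x))) NA_real_ else qs(x)[2]),
    CR_p95 = apply(cr, 2, function(x) if (all(is.na(x))) NA_real_ else qs(x)[3]),
    p_CR_gt_1e4 = colMeans(cr > 1e-4)
  )
  summary$share_THI_pct <- 100 * summary$mean_HI / sum(summary$mean_HI, na.rm = TRUE)
  summary$share_TCR_pct <- 100 * summary$mean_CR / sum(summary$mean_CR, na.rm = TRUE)

  totals <- tibble::tibble(
    population = population,
    mean_THI = mean(thi), THI_p5 = qs(thi)[1], THI_p50 = qs(thi)[2],
    THI_p95 = qs(thi)[3], p_THI_gt_1 = mean(thi > 1),
    mean_TCR = mean(tcr), TCR_p5 = qs(tcr)[1], TCR_p50 = qs(tcr)[2],
    TCR_p95 = qs(tcr)[3], p_TCR_gt_1e4 = mean(tcr > 1e-4)
  )

  structure(list(population = population, n = n, seed = seed,
                 hi = hi, cr = cr, thi = thi, tcr = tcr,
                 summary = summary, totals = totals),
            class = "hm_mc")
}

#' @export
print.hm_mc <- function(x, ...) {
  cat(sprintf("<Monte Carlo risk: %s, %d draws, seed %s>\n",
              x$population, x$n, x$seed %||% "random"))
  print(x$summary)
  print(x$totals)
  invisible(x)
}

draw_concentrations <- function(conc, n) {
  if (inherits(conc, "hm_survey")) {
    idx <- sample.int(nrow(conc), n, replace = TRUE)
    return(conc_matrix(conc)[idx, , drop = FALSE])
  }
  if (is.numeric(conc)) {
    conc <- lapply(conc, dist_point)
  }
  if (!is.list(conc) || is.null(names(conc))) {
    stopf("`conc` must be a survey, a named numeric vector or a named list of dist_spec")
  }
  check_metal_vocab(names(conc), "concentration")
  cols <- lapply(names(conc), function(m) {
    if (!is_dist_spec(conc[[m]])) stopf("invalid distribution spec for '%s'", m)
    sample_dist(conc[[m]], n)
  })
  do.call(cbind, setNames(cols, names(conc)))
}

#' Contribution shares of each metal to the total risk
#'
#' share_i = 100 * mean(HI_i) / sum_j mean(HI_j); shares sum to 100%.
#'
#' @param x An `hm_mc` result, or a named numeric vector of per-metal means.
#' @param what `"hi"` (shares of THI) or `"cr"` (shares of TCR); ignored for
#'   numeric input.
#' @return Tibble with `metal` and `share_pct`.
#' @examples
#' contribution_shares(c(Cr = 5.18e-2, As = 4.64e-2, Pb = 3.06e-2,
#'                       Hg = 6.79e-4, Cd = 6.45e-4))
#' @export
contribution_shares <- function(x, what = c("hi", "cr")) {
  what <- match.arg(what)
  means <- if (inherits(x, "hm_mc")) {
    m <- colMeans(if (what == "hi") x$hi else x$cr)
    m[!is.na(m)]
  } else {
    if (is.null(names(x))) stopf("`x` must be named by metal")
    x
  }
  if (length(means) < 2) stopf("contribution shares need at least two metals")
  tibble::tibble(metal = names(means),
                 share_pct = 100 * as.numeric(means) / sum(means))
}

#' Probability of exceeding a risk threshold
#'
#' The fraction of Monte Carlo draws strictly above `threshold`.
#'
#' @param x An `hm_mc` result or a numeric draw vector.
#' @param threshold Risk threshold (1 for THI/HI, 1e-4 for TCR/CR).
#' @param what Which draw vector of an `hm_mc` to use: `"thi"`, `"tcr"`,
#'   `"hi"` or `"cr"` (the latter two need `metal`).
#' @param metal Metal name for `what = "hi"` / `"cr"`.
#' @return A probability in `[0, 1]`.
#' @export
exceedance_probability <- function(x, threshold,
                                   what = c("thi", "tcr", "hi", "cr"),
                                   metal = NULL) {
  what <- match.arg(what)
  draws <- if (inherits(x, "hm_mc")) {
    if (what %in% c("hi", "cr")) {
      if (is.null(metal)) stopf("`metal` is required for what = '%s'", what)
      (if (what == "hi") x$hi else x$cr)[, metal]
    } else {
      if (what == "thi") x$thi else x$tcr
    }
  } else {
    x
  }
  mean(draws > threshold, na.rm = TRUE)
}
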