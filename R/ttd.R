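#' Target-organ toxicity dose (TTD) hazard assessment
#'
#' The TTD modification of the hazard index apportions the hazard of a metal
#' mixture over target organs: for every metal i and organ k with an
#' endpoint, HI_TTD(i,k) = ADD_ing(i) / TTD(i,k), and hazards are summed
#' dose-additively per organ (and per metal). Only the ingestion pathway
#' feeds the assessment by default, it being the dominant exposure route for
#' soil; other pathways can be added via `pathways`. Metals without endpoint
#' data (Hg in the bundled table) and absent metal-organ cells contribute
#' exactly zero.
#'
#' The grand total THI_TTD is identical whether accumulated metal-first or
#' organ-first (double-marginal conservation), and because each organ
#' endpoint is at most as large as the metal's chronic RfD, the per-metal
#' cumulative TTD hazard is at least the single-endpoint ingestion HI.
#'
#' @param dose_ing Named numeric vector of non-carcinogenic ingestion doses,
#'   mg/(kg d), one per metal.
#' @param ttd TTD endpoint table ([load_ttd_table()] format).
#' @param population Label carried into the result.
#' @return Object of class `hm_ttd`: `by_cell` (metal, organ, hi_ttd),
#'   `by_metal` and `by_organ` cumulative tibbles with contribution shares
#'   (%), and the grand total `thi_ttd`.
#' @examples
#' doses <- add_ingestion(c(As = 9.08, Cd = 0.36, Cr = 73.06, Pb = 28.14),
#'                        load_exposure_profile("children"))
#' ttd_hazard(doses, population = "children")
#' @export
ttd_hazard <- function(dose_ing, ttd = NULL, population = "children") {
  ttd <- ttd %||% load_ttd_table()
  if (!nrow(ttd)) stopf("TTD endpoint table is empty")
  if (is.null(names(dose_ing))) stopf("`dose_ing` must be named by metal")
  check_nonneg(dose_ing, "dose_ing")

  covered <- intersect(names(dose_ing), unique(ttd$metal))
  skipped <- setdiff(names(dose_ing), covered)
  if (length(skipped)) {
    warnf("no TTD endpoints for %s; excluded from THI_TTD",
          paste(skipped, collapse = ", "))
  }
  if (!length(covered)) stopf("no metal in `dose_ing` has TTD endpoints")

  cells <- ttd[ttd$metal %in% covered, ]
  cells$hi_ttd <- dose_ing[cells$metal] / cells$ttd

  by_metal <- cells |>
    dplyr::group_by(.data$metal) |>
    dplyr::summarise(hi_ttd = sum(.data$hi_ttd), .groups = "drop")
  by_organ <- cells |>
    dplyr::group_by(.data$organ) |>
    dplyr::summarise(hi_ttd = sum(.data$hi_ttd), .groups = "drop")
  thi_ttd <- sum(cells$hi_ttd)
  by_metal$share_pct <- 100 * by_metal$hi_ttd / thi_ttd
  by_organ$share_pct <- 100 * by_organ$hi_ttd / thi_ttd

  structure(list(by_cell = cells[, c("metal", "organ", "hi_ttd")],
                 by_metal = dplyr::arrange(by_metal, dplyr::desc(.data$hi_ttd)),
                 by_organ = dplyr::arrange(by_organ, dplyr::desc(.data$hi_ttd)),
                 thi_ttd = thi_ttd, population = population),
            class = "hm_ttd")
}

#' @export
print.hm_ttd <- function(x, ...) {
  cat(sprintf("<TTD hazard (%s): THI_TTD = %.3f>\n", x$population, x$thi_ttd))
  cat("by metal:\n"); print(x$by_metal)
  cat("by organ:\n"); print(x$by_organ)
  invisible(x)
}

#' TTD assessment of a concentration scenario
#'
#' Convenience wrapper: computes the non-carcinogenic doses for the chosen
#' pathways (ingestion only by default) and runs [ttd_hazard()].
#'
#' @param conc Named concentration vector, mg/kg.
#' @param population `"adults"` or `"children"`.
#' @param profile,ttd Optional overrides of the bundled tables.
#' @param pathways Pathways whose doses are summed before the TTD division.
#' @return An `hm_ttd` object.
#' @export
ttd_risk <- function(conc, population = c("children", "adults"),
                     profile = NULL, ttd = NULL, pathways = "ing") {
  population <- match.arg(population)
  profile <- profile %||% load_exposure_profile(population)
  bad <- setdiff(pathways, hm_pathways())
  if (length(bad)) stopf("unknown pathway '%s'", bad[1])
  dose <- Reduce(`+`, lapply(pathways, function(pw) {
    switch(pw,
           ing = add_ingestion(conc, profile),
           inh = add_inhalation(conc, profile),
           dermal = add_dermal(conc, profile))
  }))
  ttd_hazard(dose, ttd, population)
}

#' Amplification of the TTD hazard over the traditional hazard index
#'
#' Compares the multi-organ TTD assessment with the traditional
#' single-endpoint assessment of the same population: the ratio
#' THI_TTD / THI and the per-metal ratios HI_TTD / HI.
#'
#' @param ttd An `hm_ttd` result.
#' @param risk An `hm_risk` result ([deterministic_risk()]) containing the
#'   same population.
#' @return List with `thi_ratio` and a `by_metal` tibble of per-metal ratios
#'   (metals present in both assessments).
#' @export
ttd_vs_traditional <- function(ttd, risk) {
  stopifnot(inherits(ttd, "hm_ttd"), inherits(risk, "hm_risk"))
  if (!ttd$population %in% risk$populations) {
    stopf("`risk` contains no population '%s'", ttd$population)
  }
  bm <- risk$by_metal[risk$by_metal$population == ttd$population, ]
  if (length(unique(bm$scenario)) > 1) {
    stopf("`risk` must be a single-scenario assessment")
  }
  thi <- sum(bm$HI, na.rm = TRUE)
  if (thi <= 0) stopf("THI is zero; amplification ratio undefined")
  merged <- dplyr::inner_join(ttd$by_metal, bm[, c("metal", "HI")],
                              by = "metal")
  merged$ratio <- merged$hi_ttd / merged$HI
  list(thi_ratio = ttd$thi_ttd / thi,
       by_metal = merged[, c("metal", "hi_ttd", "HI", "ratio")])
}
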