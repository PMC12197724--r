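#' Deterministic health risk assessment
#'
#' Propagates soil concentrations through the three-pathway dose equations
#' and aggregates non-carcinogenic hazard quotients
#' (HI = sum over pathways of ADD/RfD, THI = sum over metals) and
#' carcinogenic risks (CR = sum over pathways of ADD x SF, TCR = sum over
#' metals). A metal/pathway cell with no RfD (or SF) in the toxicity table is
#' an absent parameter: it is reported as `NA`, contributes exactly zero to
#' the aggregates, and the skipped cells are reported once per run.
#' HI or THI above 1 flags a possible non-cancer risk; CR above 1e-4 is
#' conventionally unacceptable and below 1e-6 negligible.
#'
#' @param conc Either a named numeric vector of concentrations (mg/kg, one
#'   scenario, e.g. survey means) or an [as_survey] object (per-sample
#'   assessment).
#' @param populations Character subset of `c("adults", "children")`.
#' @param profiles Optional named list of exposure profiles; defaults to the
#'   bundled ones.
#' @param toxicity Optional RfD/SF table from [load_toxicity_table()].
#' @param quiet Suppress the absent-parameter report.
#' @return An object of class `hm_risk`: tibbles `by_pathway` (scenario,
#'   population, metal, pathway, add_nc, add_ca, hi, cr), `by_metal` and
#'   `totals` (THI, TCR and per-pathway sums).
#' @examples
#' conc <- c(As = 9.08, Cd = 0.36, Cr = 73.06, Hg = 0.13, Pb = 28.14)
#' risk <- deterministic_risk(conc)
#' risk$totals
#' @export
deterministic_risk <- function(conc, populations = c("adults", "children"),
                               profiles = NULL, toxicity = NULL,
                               quiet = FALSE) {
  populations <- match.arg(populations, several.ok = TRUE)
  toxicity <- toxicity %||% load_toxicity_table()
  profiles <- profiles %||% lapply(setNames(populations, populations),
                                   load_exposure_profile)

  C <- conc_matrix(conc)
  metals <- colnames(C)
  scen <- rownames(C)

  out <- lapply(populations, function(pop) {
    params <- dose_params(profiles[[pop]])
    cells <- risk_cells(C, params, toxicity)$by_pathway
    dplyr::mutate(cells, population = pop, .after = "scenario")
  })

  by_pathway <- dplyr::bind_rows(out)
  if (!quiet) report_absent(toxicity, metals)

  by_metal <- by_pathway |>
    dplyr::group_by(.data$scenario, .data$population, .data$metal) |>
    dplyr::summarise(
      HI = if (all(is.na(.data$hi))) NA_real_ else sum(.data$hi, na.rm = TRUE),
      CR = if (all(is.na(.data$cr))) NA_real_ else sum(.data$cr, na.rm = TRUE),
      .groups = "drop"
    )

  totals <- by_pathway |>
    dplyr::group_by(.data$scenario, .data$population) |>
    dplyr::summarise(
      THI = sum(.data$hi, na.rm = TRUE),
      TCR = sum(.data$cr, na.rm = TRUE),
      HI_ing = sum(.data$hi[.data$pathway == "ing"], na.rm = TRUE),
      HI_inh = sum(.data$hi[.data$pathway == "inh"], na.rm = TRUE),
      HI_dermal = sum(.data$hi[.data$pathway == "dermal"], na.rm = TRUE),
      CR_ing = sum(.data$cr[.data$pathway == "ing"], na.rm = TRUE),
      CR_inh = sum(.data$cr[.data$pathway == "inh"], na.rm = TRUE),
      CR_dermal = sum(.data$cr[.data$pathway == "dermal"], na.rm = TRUE),
      .groups = "drop"
    )

  structure(list(by_pathway = by_pathway, by_metal = by_metal,
                 totals = totals, populations = populations),
            class = "hm_risk")
}

#' @export
print.hm_risk <- function(x, ...) {
  cat(sprintf("<deterministic risk: %d scenario(s), populations %s>\n",
              length(unique(x$totals$scenario)),
              paste(x$populations, collapse = "/")))
  print(x$by_metal, n = 20)
  print(x$totals)
  invisible(x)
}

# named vector or survey -> scenario x metal matrix
conc_matrix <- function(conc) {
  if (inherits(conc, "hm_survey")) {
    m <- as.matrix(tibble::as_tibble(conc)[, survey_metals(conc)])
    rownames(m) <- conc$sample_id
    return(m)
  }
  if (is.matrix(conc)) {
    if (is.null(colnames(conc))) stopf("concentration matrix needs metal colnames")
    if (is.null(rownames(conc))) rownames(conc) <- sprintf("S%04d", seq_len(nrow(conc)))
    return(conc)
  }
  if (is.null(names(conc))) stopf("`conc` must be named by metal")
  check_metal_vocab(names(conc), "concentration")
  check_nonneg(conc, "conc")
  matrix(conc, nrow = 1, dimnames = list("mean", names(conc)))
}

tox_lookup <- function(toxicity, metals, pathway, what) {
  idx <- match(paste(metals, pathway), paste(toxicity$metal, toxicity$pathway))
  vals <- toxicity[[what]][idx]
  setNames(vals, metals)
}

# per-scenario, per-metal, per-pathway doses and risks for one population
risk_cells <- function(C, params, toxicity) {
  metals <- colnames(C)
  rows <- lapply(hm_pathways(), function(pw) {
    f_nc <- dose_factor(params, pw, "nc")
    f_ca <- dose_factor(params, pw, "ca")
    rfd <- tox_lookup(toxicity, metals, pw, "rfd")
    sf <- tox_lookup(toxicity, metals, pw, "sf")
    add_nc <- C * f_nc
    add_ca <- C * f_ca
    hi <- sweep(add_nc, 2, rfd, `/`)
    cr <- sweep(add_ca, 2, sf, `*`)
    tibble::tibble(
      scenario = rep(rownames(C), times = length(metals)),
      metal = rep(metals, each = nrow(C)),
      pathway = pw,
      add_nc = as.vector(add_nc), add_ca = as.vector(add_ca),
      hi = as.vector(hi), cr = as.vector(cr)
    )
  })
  list(by_pathway = dplyr::bind_rows(rows))
}

report_absent <- function(toxicity, metals) {
  tox <- toxicity[toxicity$metal %in% metals, ]
  no_rfd <- tox[is.na(tox$rfd), c("metal", "pathway")]
  no_sf <- tox[is.na(tox$sf), c("metal", "pathway")]
  msg <- c(
    if (nrow(no_rfd)) sprintf("no RfD (HI skipped): %s",
                              paste(no_rfd$metal, no_rfd$pathway, sep = "/",
                                    collapse = ", ")),
    if (nrow(no_sf)) sprintf("no SF (CR skipped): %s",
                             paste(no_sf$metal, no_sf$pathway, sep = "/",
                                   collapse = ", "))
  )
  if (length(msg)) message(paste(msg, collapse = "; "))
  invisible(NULL)
}

#' Non-carcinogenic and carcinogenic aggregation helpers
#'
#' `hazard_index()` sums per-pathway hazard quotients (ADD/RfD) over the
#' pathways with an RfD; `carcinogenic_risk()` sums ADD x SF over the
#' pathways with a slope factor. Both take a named-by-pathway dose vector
#' for one metal and the toxicity rows for that metal.
#'
#' @param doses Named numeric vector of doses, names among
#'   `ing`, `inh`, `dermal` (mg/kg/d; `nc`-averaged for `hazard_index`,
#'   `ca`-averaged for `carcinogenic_risk`).
#' @param toxicity RfD/SF table.
#' @param metal Metal name.
#' @return A single HI (or CR) value; `NA` if the metal has no RfD (SF) on
#'   any supplied pathway.
#' @examples
#' hazard_index(c(ing = 1.35e-5, inh = 1.44e-9, dermal = 5.4e-8),
#'              load_toxicity_table(), "As")
#' @export
hazard_index <- function(doses, toxicity, metal) {
  rfd <- tox_lookup(toxicity, rep(metal, length(doses)), names(doses), "rfd")
  q <- doses / rfd
  if (all(is.na(q))) {
    warnf("metal %s has no RfD on any pathway; excluded from THI", metal)
    return(NA_real_)
  }
  sum(q, na.rm = TRUE)
}

#' @rdname hazard_index
#' @export
carcinogenic_risk <- function(doses, toxicity, metal) {
  sf <- tox_lookup(toxicity, rep(metal, length(doses)), names(doses), "sf")
  r <- doses * sf
  if (all(is.na(r))) {
    warnf("metal %s has no slope factor on any pathway; excluded from TCR",
          metal)
    return(NA_real_)
  }
  sum(r, na.rm = TRUE)
}
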