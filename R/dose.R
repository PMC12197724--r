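#' Average daily dose equations
#'
#' The three USEPA exposure pathways from soil:
#' \deqn{ADD_{ing} = \frac{C \cdot R_{ing} \cdot EF \cdot ED}{BW \cdot AT} \times 10^{-6}}
#' \deqn{ADD_{inh} = \frac{C \cdot R_{inh} \cdot EF \cdot ED}{PEF \cdot BW \cdot AT}}
#' \deqn{ADD_{der} = \frac{C \cdot AF \cdot SA \cdot ABS \cdot EF \cdot ED}{BW \cdot AT} \times 10^{-6}}
#' with C in mg/kg soil and doses in mg/(kg body weight * day). The
#' averaging time AT is `AT_nc` for non-carcinogenic and `AT_ca` for
#' carcinogenic assessment; the bundled profiles set both to ED x 365 d,
#' which is the convention the reference hazard tables were derived under,
#' and either can be overridden in the exposure table.
#'
#' @param conc Soil concentration(s), mg/kg; a named numeric vector (one
#'   value per metal) or a numeric scalar.
#' @param profile An exposure profile from [load_exposure_profile()], or a
#'   named list of parameter values.
#' @param averaging `"nc"` or `"ca"`.
#' @return Dose(s) in mg/(kg d), same shape as `conc`.
#' @examples
#' add_ingestion(9.08, load_exposure_profile("adults"))
#' @name average_daily_dose
NULL

dose_params <- function(profile) {
  if (inherits(profile, "hm_profile")) profile_values(profile) else profile
}

required_dose_params <- function(pathway) {
  base <- c("EF", "ED", "BW")
  switch(pathway,
    ing = c("R_ing", base),
    inh = c("R_inh", "PEF", base),
    dermal = c("AF", "SA", "ABS", base)
  )
}

check_dose_params <- function(params, pathway, averaging) {
  need <- c(required_dose_params(pathway),
            if (averaging == "nc") "AT_nc" else "AT_ca")
  for (nm in need) {
    v <- params[[nm]]
    if (is.null(v)) stopf("missing exposure parameter '%s'", nm)
    if (any(!is.finite(v)) || any(v <= 0)) {
      stopf("exposure parameter '%s' must be strictly positive", nm)
    }
  }
  params
}

# per-unit-concentration dose factor; each parameter may be a scalar or a
# draw vector, so the same kernel serves the deterministic and Monte Carlo
# paths (and the degenerate-distribution equivalence is exact by construction)
dose_factor <- function(params, pathway = c("ing", "inh", "dermal"),
                        averaging = c("nc", "ca")) {
  pathway <- match.arg(pathway)
  averaging <- match.arg(averaging)
  p <- check_dose_params(params, pathway, averaging)
  at <- if (averaging == "nc") p$AT_nc else p$AT_ca
  switch(pathway,
    ing = p$R_ing * p$EF * p$ED / (p$BW * at) * 1e-6,
    inh = p$R_inh * p$EF * p$ED / (p$PEF * p$BW * at),
    dermal = p$AF * p$SA * p$ABS * p$EF * p$ED / (p$BW * at) * 1e-6
  )
}

#' @rdname average_daily_dose
#' @export
add_ingestion <- function(conc, profile, averaging = c("nc", "ca")) {
  check_nonneg(conc, "conc")
  conc * dose_factor(dose_params(profile), "ing", match.arg(averaging))
}

#' @rdname average_daily_dose
#' @export
add_inhalation <- function(conc, profile, averaging = c("nc", "ca")) {
  check_nonneg(conc, "conc")
  conc * dose_factor(dose_params(profile), "inh", match.arg(averaging))
}

#' @rdname average_daily_dose
#' @export
add_dermal <- function(conc, profile, averaging = c("nc", "ca")) {
  check_nonneg(conc, "conc")
  conc * dose_factor(dose_params(profile), "dermal", match.arg(averaging))
}
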