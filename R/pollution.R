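#' Single-factor pollution index
#'
#' PI = C / S, the ratio of a measured concentration to the regulatory
#' screening value for the sample's pH class. PI <= 1 is unpolluted,
#' 1 < PI <= 2 mild, 2 < PI <= 3 moderate and PI > 3 heavy pollution.
#'
#' @param conc Measured concentration, mg/kg (vectorised).
#' @param screening Screening value, mg/kg.
#' @return Numeric vector of PI values.
#' @examples
#' single_factor_index(0.36, 0.4)
#' @export
single_factor_index <- function(conc, screening) {
  check_positive(conc, "conc")
  check_positive(screening, "screening")
  conc / screening
}

#' Nemerow composite pollution index
#'
#' P_N = sqrt((mean(PI)^2 + max(PI)^2) / 2) over the per-metal single-factor
#' indices of one sample; the quadratic max term makes the worst pollutant
#' dominate.
#'
#' @param pi_values Positive per-metal PI values for one sample.
#' @return A single P_N value.
#' @examples
#' nemerow_index(c(0.9, 0.5))
#' @export
nemerow_index <- function(pi_values) {
  if (!length(pi_values)) stopf("`pi_values` must be non-empty")
  check_positive(pi_values, "pi_values")
  sqrt((mean(pi_values)^2 + max(pi_values)^2) / 2)
}

#' Geoaccumulation index
#'
#' Igeo = log2(C / (1.5 B)), where B is the geochemical background value and
#' the factor 1.5 absorbs natural variation from rock weathering. Igeo <= 0
#' indicates no anthropogenic enrichment.
#'
#' @param conc Measured concentration, mg/kg (vectorised).
#' @param background Background value, mg/kg.
#' @return Numeric vector of Igeo values.
#' @examples
#' geoaccumulation_index(0.13, 0.1)
#' @export
geoaccumulation_index <- function(conc, background) {
  check_positive(conc, "conc")
  check_positive(background, "background")
  log2(conc / (1.5 * background))
}

#' Pollution assessment of a whole survey
#'
#' Computes, for every sample and metal, PI against the pH-class screening
#' value and Igeo against the background value (both with classification
#' labels), the per-sample Nemerow index, and a survey-level summary:
#' min/max/mean/SD/CV per metal, exceedance rates against both the screening
#' values (per pH class and overall) and the background values, and a
#' survey-level P_N computed from the per-metal mean PIs.
#'
#' @param survey An [as_survey] object.
#' @param standards Optional list with `screening` and `background` tables
#'   (defaults to the bundled ones).
#' @param sd_denominator `"n-1"` (sample SD, default) or `"n"`.
#' @return A list of class `hm_pollution` with elements `by_sample` (long
#'   tibble: sample_id, metal, conc, ph_class, PI and label, Igeo and label),
#'   `nemerow` (per-sample P_N with label), `summary` (per-metal statistics
#'   and exceedance rates, %), `by_class` (per pH class screening exceedance,
#'   %), and `survey_pn`.
#' @export
assess_pollution <- function(survey, standards = NULL,
                             sd_denominator = c("n-1", "n")) {
  stopifnot(inherits(survey, "hm_survey"))
  sd_denominator <- match.arg(sd_denominator)
  standards <- standards %||% list(screening = load_screening_values(),
                                   background = load_background_values())
  long <- survey_long(survey)
  long$ph_class <- as.character(ph_class(long$pH))

  scr <- standards$screening
  bg <- standards$background
  long <- dplyr::left_join(long, scr, by = c("metal", "ph_class"))
  long <- dplyr::left_join(long, bg[, c("metal", "background")], by = "metal")

  pi_bands <- load_classification_bands("PI")
  igeo_bands <- load_classification_bands("Igeo")
  pn_bands <- load_classification_bands("PN")

  long$PI <- single_factor_index(long$conc, long$screening)
  long$PI_label <- classify_value(long$PI, pi_bands)
  long$Igeo <- geoaccumulation_index(long$conc, long$background)
  long$Igeo_label <- classify_value(long$Igeo, igeo_bands)

  nem <- long |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(PN = nemerow_index(.data$PI), .groups = "drop")
  nem$PN_label <- classify_value(nem$PN, pn_bands)

  sdf <- if (sd_denominator == "n-1") stats::sd else {
    function(x) sqrt(mean((x - mean(x))^2))
  }
  summary <- long |>
    dplyr::group_by(.data$metal) |>
    dplyr::summarise(
      n = dplyr::n(),
      min = min(.data$conc),
      max = max(.data$conc),
      mean = mean(.data$conc),
      sd = sdf(.data$conc),
      cv_pct = 100 * sdf(.data$conc) / mean(.data$conc),
      exceed_screening_pct = 100 * mean(.data$conc > .data$screening),
      exceed_background_pct = 100 * mean(.data$conc > .data$background),
      mean_PI = mean(.data$PI),
      mean_Igeo = mean(.data$Igeo),
      .groups = "drop"
    )

  by_class <- long |>
    dplyr::group_by(.data$metal, .data$ph_class) |>
    dplyr::summarise(n = dplyr::n(),
                     exceed_screening_pct = 100 * mean(.data$conc > .data$screening),
                     .groups = "drop")

  survey_pn <- nemerow_index(summary$mean_PI)

  structure(list(by_sample = long, nemerow = nem, summary = summary,
                 by_class = by_class, survey_pn = survey_pn,
                 survey_pn_label = classify_value(survey_pn, pn_bands),
                 mean_pn = mean(nem$PN)),
            class = "hm_pollution")
}

#' @export
print.hm_pollution <- function(x, ...) {
  cat(sprintf("<pollution assessment: %d samples x %d metals>\n",
              nrow(x$nemerow), nrow(x$summary)))
  print(x$summary)
  cat(sprintf("survey-level P_N (from mean PIs): %.3f (%s); mean per-sample P_N: %.3f\n",
              x$survey_pn, x$survey_pn_label, x$mean_pn))
  invisible(x)
}
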