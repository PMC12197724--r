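#' Bundled reference tables and their loaders
#'
#' The package ships, as plain CSV under `inst/extdata/`, every regulatory
#' and toxicological constant the pipeline needs:
#'
#' * `screening_values.csv` - GB 15618-2018 soil pollution risk screening
#'   values by metal and pH class (mg/kg);
#' * `soil_background.csv` - regional geochemical background values (mg/kg)
#'   and Hakanson toxic response factors;
#' * `survey_moments.csv` - per-metal min/max/mean/SD (mg/kg) and pH moments
#'   of the reference 740-sample survey, used to calibrate the synthetic
#'   generator and as the mean-concentration scenario;
#' * `exposure_parameters.csv` - exposure profiles for adults and children
#'   (point value plus optional distribution for the Monte Carlo engine);
#' * `toxicity_reference.csv` - per-metal, per-pathway chronic reference
#'   doses (RfD, mg/kg/d) and carcinogenic slope factors (SF, (mg/kg/d)^-1);
#'   blank cells are genuinely absent parameters, not zeros;
#' * `ttd_endpoints_calibrated.csv` - target-organ toxicity doses (mg/kg/d).
#'   These endpoints are a calibrated table constructed to be consistent with
#'   the per-metal and per-organ aggregate hazards of the reference survey,
#'   not a transcription of agency values, and are named accordingly;
#' * `classification_bands.csv` - right-closed classification bands for PI,
#'   P_N, Igeo, Er and RI.
#'
#' Each loader accepts a user CSV path replacing the bundled default; every
#' override is reported once via `message()`.
#'
#' @param path Optional path to a replacement CSV with the same columns.
#' @name reference_tables
NULL

load_ref <- function(path, default_file, what, quiet = FALSE) {
  if (is.null(path)) {
    read_ref_csv(extdata_path(default_file))
  } else {
    if (!file.exists(path)) stopf("%s table '%s' does not exist", what, path)
    if (!quiet) message(sprintf("using user-supplied %s table: %s", what, path))
    read_ref_csv(path)
  }
}

check_metal_vocab <- function(metals, what) {
  bad <- setdiff(unique(metals), hm_metals())
  if (length(bad)) {
    stopf("%s table has unknown metal(s) %s; accepted metals: %s",
          what, paste(bad, collapse = ", "), paste(hm_metals(), collapse = ", "))
  }
}

#' @rdname reference_tables
#' @export
load_screening_values <- function(path = NULL) {
  tbl <- load_ref(path, "screening_values.csv", "screening-value")
  need <- c("metal", "ph_class", "screening")
  if (!all(need %in% names(tbl))) {
    stopf("screening table must have columns %s", paste(need, collapse = ", "))
  }
  check_metal_vocab(tbl$metal, "screening")
  bad <- setdiff(unique(tbl$ph_class), ph_class_levels())
  if (length(bad)) {
    stopf("unknown pH class '%s'; accepted classes: %s", bad[1],
          paste(ph_class_levels(), collapse = ", "))
  }
  if (any(!is.finite(tbl$screening) | tbl$screening <= 0)) {
    stopf("screening values must be strictly positive")
  }
  full <- nrow(unique(tbl[, c("metal", "ph_class")]))
  if (full < length(hm_metals()) * length(ph_class_levels())) {
    stopf("screening table must cover all five metals in all four pH classes")
  }
  tbl
}

#' @rdname reference_tables
#' @export
load_background_values <- function(path = NULL) {
  tbl <- load_ref(path, "soil_background.csv", "background-value")
  need <- c("metal", "background", "toxic_response")
  if (!all(need %in% names(tbl))) {
    stopf("background table must have columns %s", paste(need, collapse = ", "))
  }
  check_metal_vocab(tbl$metal, "background")
  if (any(!is.finite(tbl$background) | tbl$background <= 0) ||
      any(!is.finite(tbl$toxic_response) | tbl$toxic_response <= 0)) {
    stopf("background and toxic response values must be strictly positive")
  }
  tbl
}

#' @rdname reference_tables
#' @export
load_survey_moments <- function(path = NULL) {
  tbl <- load_ref(path, "survey_moments.csv", "survey-moments")
  need <- c("variable", "min", "max", "mean", "sd")
  if (!all(need %in% names(tbl))) {
    stopf("moments table must have columns %s", paste(need, collapse = ", "))
  }
  if (any(tbl$min >= tbl$max)) stopf("moments table requires min < max")
  tbl
}

#' @rdname reference_tables
#' @param population `"adults"` or `"children"`.
#' @export
load_exposure_profile <- function(population = c("adults", "children"),
                                  path = NULL) {
  population <- match.arg(population)
  tbl <- load_ref(path, "exposure_parameters.csv", "exposure-parameter")
  tbl <- tbl[tbl$population == population, , drop = FALSE]
  if (!nrow(tbl)) stopf("no exposure parameters for population '%s'", population)
  if (any(!is.finite(tbl$value) | tbl$value <= 0)) {
    stopf("exposure parameter point values must be strictly positive (%s)",
          paste(tbl$parameter[!is.finite(tbl$value) | tbl$value <= 0],
                collapse = ", "))
  }
  abs_row <- tbl$value[tbl$parameter == "ABS"]
  if (length(abs_row) && (abs_row <= 0 || abs_row > 1)) {
    stopf("ABS must lie in (0, 1]")
  }
  structure(list(population = population, table = tbl),
            class = "hm_profile")
}

#' @export
print.hm_profile <- function(x, ...) {
  cat(sprintf("<exposure profile: %s>\n", x$population))
  print(x$table[, c("parameter", "unit", "value", "dist")], n = Inf)
  invisible(x)
}

# named list of point values
profile_values <- function(profile) {
  stopifnot(inherits(profile, "hm_profile"))
  setNames(as.list(profile$table$value), profile$table$parameter)
}

# named list of dist_spec (point spec when no distribution is declared)
profile_specs <- function(profile) {
  stopifnot(inherits(profile, "hm_profile"))
  tbl <- profile$table
  specs <- lapply(seq_len(nrow(tbl)), function(i) {
    row <- tbl[i, ]
    kind <- row$dist %||% "point"
    if (is.na(kind) || kind == "point") return(dist_point(row$value))
    lower <- if (is.na(row$lower)) -Inf else row$lower
    upper <- if (is.na(row$upper)) Inf else row$upper
    switch(kind,
      normal = dist_normal(row$p1, row$p2, lower, upper),
      lognormal = dist_lognormal(row$p1, row$p2, max(lower, 0), upper),
      uniform = dist_uniform(row$p1, row$p2),
      triangular = dist_triangular(row$p1, row$p2, row$p3),
      stopf("unknown distribution kind '%s' for parameter %s", kind,
            row$parameter)
    )
  })
  setNames(specs, tbl$parameter)
}

#' @rdname reference_tables
#' @export
load_toxicity_table <- function(path = NULL) {
  tbl <- load_ref(path, "toxicity_reference.csv", "toxicity")
  need <- c("metal", "pathway", "rfd", "sf")
  if (!all(need %in% names(tbl))) {
    stopf("toxicity table must have columns %s", paste(need, collapse = ", "))
  }
  check_metal_vocab(tbl$metal, "toxicity")
  bad <- setdiff(unique(tbl$pathway), hm_pathways())
  if (length(bad)) {
    stopf("unknown pathway '%s'; accepted pathways: %s", bad[1],
          paste(hm_pathways(), collapse = ", "))
  }
  if (any(tbl$rfd[!is.na(tbl$rfd)] <= 0) || any(tbl$sf[!is.na(tbl$sf)] <= 0)) {
    stopf("present RfD/SF values must be strictly positive")
  }
  tbl
}

#' @rdname reference_tables
#' @export
load_ttd_table <- function(path = NULL) {
  tbl <- load_ref(path, "ttd_endpoints_calibrated.csv", "TTD-endpoint")
  need <- c("metal", "organ", "ttd")
  if (!all(need %in% names(tbl))) {
    stopf("TTD table must have columns %s", paste(need, collapse = ", "))
  }
  check_metal_vocab(tbl$metal, "TTD")
  bad <- setdiff(unique(tbl$organ), hm_organs())
  if (length(bad)) {
    stopf("unknown organ '%s'; accepted organs: %s", bad[1],
          paste(hm_organs(), collapse = ", "))
  }
  if (any(!is.finite(tbl$ttd) | tbl$ttd <= 0)) {
    stopf("present TTD values must be strictly positive")
  }
  tbl
}

#' @rdname reference_tables
#' @param index One of `"PI"`, `"PN"`, `"Igeo"`, `"Er"`, `"RI"`.
#' @export
load_classification_bands <- function(index = NULL, path = NULL) {
  tbl <- load_ref(path, "classification_bands.csv", "classification-band")
  if (!is.null(index)) {
    tbl <- tbl[tbl$index == index, , drop = FALSE]
    if (!nrow(tbl)) stopf("no classification bands for index '%s'", index)
  }
  tbl
}

# label values against right-closed bands: value in (lower, upper]
classify_value <- function(x, bands) {
  breaks <- c(bands$lower[1], bands$upper)
  labs <- bands$label
  as.character(cut(x, breaks = breaks, labels = labs, right = TRUE,
                   include.lowest = TRUE))
}

#' Load the complete set of reference tables
#'
#' Convenience wrapper returning standards (screening, background, toxic
#' response), the two exposure profiles, the RfD/SF toxicity table, the TTD
#' endpoint table, classification bands and the reference survey moments,
#' each overridable by a user file.
#'
#' @param screening,background,exposure,toxicity,ttd,bands,moments Optional
#'   paths to replacement CSVs.
#' @return A named list with elements `screening`, `background`, `adults`,
#'   `children`, `toxicity`, `ttd`, `bands`, `moments`.
#' @export
load_reference_tables <- function(screening = NULL, background = NULL,
                                  exposure = NULL, toxicity = NULL,
                                  ttd = NULL, bands = NULL, moments = NULL) {
  list(
    screening = load_screening_values(screening),
    background = load_background_values(background),
    adults = load_exposure_profile("adults", exposure),
    children = load_exposure_profile("children", exposure),
    toxicity = load_toxicity_table(toxicity),
    ttd = load_ttd_table(ttd),
    bands = load_classification_bands(path = bands),
    moments = load_survey_moments(moments)
  )
}
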