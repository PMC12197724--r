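#' Soil survey objects
#'
#' A survey is a tibble with class `hm_survey`: one row per composite topsoil
#' sample, with a unique `sample_id`, optional `region` label and planar
#' `x`/`y` coordinates (pass-through metadata), a `pH` column in (0, 14) and
#' one concentration column per measured metal (mg/kg dry soil, strictly
#' positive). The metals present and the provenance (file path or
#' `"synthetic:<seed>"`) are carried as attributes.
#'
#' @param data A data frame with at least `pH` and one metal column.
#' @param provenance Free-text origin of the data.
#' @return An `hm_survey` tibble.
#' @export
as_survey <- function(data, provenance = "in-memory") {
  tbl <- tibble::as_tibble(data)
  if (!nrow(tbl)) stopf("a survey must contain at least one sample")
  metals <- intersect(hm_metals(), names(tbl))
  if (!length(metals)) {
    stopf("no metal concentration columns found; expected one or more of %s",
          paste(hm_metals(), collapse = ", "))
  }
  if (!"pH" %in% names(tbl)) stopf("missing required column: pH")
  if (!"sample_id" %in% names(tbl)) {
    tbl$sample_id <- sprintf("S%04d", seq_len(nrow(tbl)))
  }
  tbl$sample_id <- as.character(tbl$sample_id)
  dup <- tbl$sample_id[duplicated(tbl$sample_id)]
  if (length(dup)) stopf("duplicated sample_id: %s", dup[1])

  for (col in intersect(c("pH", "x", "y", metals), names(tbl))) {
    tbl[[col]] <- as.double(tbl[[col]])
  }
  bad_ph <- which(!is.finite(tbl$pH) | tbl$pH <= 0 | tbl$pH >= 14)
  if (length(bad_ph)) {
    stopf("sample %s: pH %.3g outside (0, 14)",
          tbl$sample_id[bad_ph[1]], tbl$pH[bad_ph[1]])
  }
  for (m in metals) {
    bad <- which(!is.finite(tbl[[m]]) | tbl[[m]] <= 0)
    if (length(bad)) {
      stopf("sample %s: non-positive %s concentration (%s mg/kg)",
            tbl$sample_id[bad[1]], m, format(tbl[[m]][bad[1]]))
    }
  }
  front <- intersect(c("sample_id", "region", "x", "y", "pH"), names(tbl))
  tbl <- tbl[, c(front, metals, setdiff(names(tbl), c(front, metals)))]
  structure(tbl, metals = metals, provenance = provenance,
            class = c("hm_survey", class(tbl)))
}

survey_metals <- function(survey) attr(survey, "metals")

#' @export
print.hm_survey <- function(x, ...) {
  cat(sprintf("<soil survey: %d samples, metals %s, provenance '%s'>\n",
              nrow(x), paste(survey_metals(x), collapse = "/"),
              attr(x, "provenance")))
  NextMethod()
}

#' Read a soil survey from a delimited file
#'
#' @param path CSV/TSV file, one row per sample.
#' @param schema Optional named character vector mapping standard column
#'   names to the file's column names, e.g.
#'   `c(pH = "soil_ph", As = "as_mg_kg")`; unmapped standard names are looked
#'   up directly.
#' @return An [as_survey] object; rows violating the invariants abort with a
#'   diagnostic naming the offending sample.
#' @export
read_survey <- function(path, schema = NULL) {
  if (!file.exists(path)) stopf("survey file '%s' does not exist", path)
  # base R parsing: correctly rounded doubles, so write/read round-trips
  # are bit-identical
  raw <- if (grepl("\\.tsv$", path)) {
    utils::read.delim(path, check.names = FALSE)
  } else {
    utils::read.csv(path, check.names = FALSE)
  }
  raw <- tibble::as_tibble(raw)
  if (!is.null(schema)) {
    miss <- schema[!schema %in% names(raw)]
    if (length(miss)) {
      stopf("schema error: column '%s' (mapped to %s) not present in file",
            miss[1], names(miss)[1])
    }
    names(raw)[match(schema, names(raw))] <- names(schema)
  }
  if (!"pH" %in% names(raw)) {
    stopf("schema error: required column 'pH' not found in '%s'", path)
  }
  as_survey(raw, provenance = path)
}

#' Write a survey back to CSV
#'
#' Numeric fields are written at full precision so that
#' `read_survey(write_survey(s))` round-trips bit-identically.
#'
#' @param survey An `hm_survey`.
#' @param path Output CSV path.
#' @export
write_survey <- function(survey, path) {
  stopifnot(inherits(survey, "hm_survey"))
  readr::write_csv(tibble::as_tibble(survey), path)
  invisible(path)
}

#' Classify soil pH into the screening-value classes
#'
#' The four classes of GB 15618-2018 partition (0, 14) with right-closed
#' boundaries, so `ph_class(5.5)` is `"<=5.5"` and `ph_class(6.5)` is
#' `"(5.5,6.5]"`.
#'
#' @param pH Numeric vector of pH values in (0, 14).
#' @return Factor with levels `<=5.5`, `(5.5,6.5]`, `(6.5,7.5]`, `>7.5`.
#' @examples
#' ph_class(c(5.5, 6.14, 8.06))
#' @export
ph_class <- function(pH) {
  if (any(!is.finite(pH) | pH <= 0 | pH >= 14)) {
    stopf("pH must lie in (0, 14)")
  }
  cut(pH, breaks = c(0, 5.5, 6.5, 7.5, 14), labels = ph_class_levels(),
      right = TRUE)
}

# long view: sample_id, pH, metal, conc
survey_long <- function(survey) {
  tidyr::pivot_longer(
    tibble::as_tibble(survey)[, c("sample_id", "pH", survey_metals(survey))],
    cols = dplyr::all_of(survey_metals(survey)),
    names_to = "metal", values_to = "conc"
  )
}
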