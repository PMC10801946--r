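# Cohort-level plumbing: data-frame <-> record conversion, batch
# classification with both engines, and the delimited-text readers/writers.

.cohort_columns <- c("id", "density_type", "mean_diameter",
                     "solid_component_diameter", "margin", "malignant_signs",
                     "benign_features", "endobronchial", "stability_months",
                     "course", "pathology", "pathology_subtype")

.split_tokens <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else strsplit(x, ";", fixed = TRUE)[[1]]
}

#' Convert between a cohort data frame and nodule records
#'
#' The tabular cohort schema mirrors the [nodule_record] fields, one row per
#' nodule; the list-valued fields (`malignant_signs`, `benign_features`) are
#' semicolon-joined tokens. These converters are exact inverses on valid
#' data.
#'
#' @param cohort data frame with the cohort columns.
#' @return `cohort_to_records()`: list of [nodule_record];
#'   `records_to_cohort()`: data frame.
#' @export
cohort_to_records <- function(cohort) {
  missing <- setdiff(.cohort_columns, names(cohort))
  if (length(missing))
    stop("cohort is missing columns: ", paste(missing, collapse = ", "))
  lapply(seq_len(nrow(cohort)), function(i) {
    nodule_record(
      id = cohort$id[i],
      density_type = cohort$density_type[i],
      mean_diameter = cohort$mean_diameter[i],
      solid_component_diameter = cohort$solid_component_diameter[i],
      margin = cohort$margin[i],
      malignant_signs = .split_tokens(cohort$malignant_signs[i]),
      benign_features = .split_tokens(cohort$benign_features[i]),
      endobronchial = isTRUE(cohort$endobronchial[i]),
      stability_months = cohort$stability_months[i],
      course = cohort$course[i],
      pathology = cohort$pathology[i],
      pathology_subtype = cohort$pathology_subtype[i]
    )
  })
}

#' @param records list of [nodule_record].
#' @rdname cohort_to_records
#' @export
records_to_cohort <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(
      id = r$id,
      density_type = r$density_type,
      mean_diameter = r$mean_diameter,
      solid_component_diameter = r$solid_component_diameter,
      margin = r$margin,
      malignant_signs = paste(r$malignant_signs, collapse = ";"),
      benign_features = paste(r$benign_features, collapse = ";"),
      endobronchial = r$endobronchial,
      stability_months = r$stability_months,
      course = r$course,
      pathology = r$pathology,
      pathology_subtype = r$pathology_subtype,
      stringsAsFactors = FALSE
    )
  }))
}

#' Classify a cohort with both rule engines
#'
#' Validates every record, runs the PNI-GARS and Lung-RADS engines and
#' appends the grade/category, screen label and PNI-GARS rule trace to the
#' cohort. Deterministic: identical inputs give identical outputs.
#'
#' @param cohort cohort data frame (see [cohort_to_records]).
#' @param systems which engines to run.
#' @return the cohort with added columns among `pni_grade`, `pni_screen`,
#'   `pni_trace`, `lungrads_category`, `lungrads_screen`.
#' @export
classify_cohort <- function(cohort, systems = c("pnigars", "lungrads")) {
  systems <- match.arg(systems, several.ok = TRUE)
  records <- cohort_to_records(cohort)
  if ("pnigars" %in% systems) {
    res <- lapply(records, classify_pnigars)
    cohort$pni_grade <- vapply(res, `[[`, "", "grade")
    cohort$pni_screen <- dichotomize_pni(cohort$pni_grade)
    cohort$pni_trace <- vapply(res, function(r) paste(r$trace, collapse = "|"), "")
  }
  if ("lungrads" %in% systems) {
    res <- lapply(records, classify_lungrads)
    cohort$lungrads_category <- vapply(res, `[[`, "", "category")
    cohort$lungrads_screen <- dichotomize_lungrads(cohort$lungrads_category)
  }
  cohort
}

#' Read and write cohort CSV files
#'
#' Fixed dialect for reproducibility: comma-delimited UTF-8 with a header
#' row, `.` decimal separator, semicolon-joined tokens in the list-valued
#' columns. Every row is validated on read; malformed rows are reported
#' with their line numbers.
#'
#' @param path file path.
#' @return `read_cohort()`: validated cohort data frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  missing <- setdiff(.cohort_columns, names(df))
  if (length(missing))
    stop("missing required columns: ", paste(missing, collapse = ", "))
  df$mean_diameter <- as.numeric(df$mean_diameter)
  df$solid_component_diameter <- suppressWarnings(as.numeric(df$solid_component_diameter))
  df$stability_months <- suppressWarnings(as.numeric(df$stability_months))
  df$endobronchial <- toupper(df$endobronchial) %in% c("TRUE", "T", "1", "YES")
  df$pathology_subtype[!nzchar(df$pathology_subtype)] <- NA_character_
  records <- cohort_to_records(df)
  errors <- character()
  for (i in seq_along(records)) {
    msg <- tryCatch({ validate_record(records[[i]]); NA_character_ },
                    error = function(e) conditionMessage(e))
    if (!is.na(msg)) errors <- c(errors, sprintf("row %d: %s", i + 1L, msg))
  }
  if (length(errors)) stop("invalid cohort rows:\n", paste(errors, collapse = "\n"))
  df
}

#' @param cohort cohort data frame.
#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}
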