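# Lung-RADS 2022 category assignment as exercised at a single screening
# baseline: size rules per density type, the 4X modifier, and the
# stability-based downgrade of category 3 / 4A nodules.

#' Baseline Lung-RADS 2022 category
#'
#' Category 1 for a definitely benign morphology (complete calcification or
#' fat component). Ground-glass nodules up to 30 mm are category 2
#' regardless of signs. Solid nodules: under 6 mm category 2, 6 to under
#' 8 mm category 3, 8 to under 15 mm 4A, 15 mm and over 4B. Part-solid
#' nodules: total diameter under 6 mm category 2; 6 mm and over with a solid
#' component under 6 mm category 3; solid component 6 to under 8 mm 4A;
#' 8 mm and over 4B. A category 3 or 4 nodule carrying an additional
#' suspicious finding from `x_triggers` becomes 4X. Perifissural and other
#' benign-appearing (but not fully calcified/fatty) nodules fall through to
#' the size rules, which for their typical sub-6-mm size yields category 2.
#'
#' @param record a validated [nodule_record].
#' @param x_triggers character vector of malignant-sign tokens that promote
#'   a category 3/4 nodule to 4X.
#' @return a Lung-RADS category (character, one of [lungrads_levels]).
#' @export
lungrads_baseline <- function(record,
                              x_triggers = c("spiculation", "enlarged_lymph_nodes",
                                             "ggn_doubling_1yr")) {
  if (any(record$benign_features %in% c("pure_calcification", "fat"))) {
    return("1")
  }
  d <- record$mean_diameter
  cat <- switch(record$density_type,
    GGN = "2",
    SN = if (d < 6) "2" else if (d < 8) "3" else if (d < 15) "4A" else "4B",
    PSN = {
      s <- record$solid_component_diameter
      if (d < 6) "2"
      else if (s < 6) "3"
      else if (s < 8) "4A"
      else "4B"
    }
  )
  if (cat %in% c("3", "4A", "4B") && any(record$malignant_signs %in% x_triggers)) {
    cat <- "4X"
  }
  cat
}

#' Stability downgrade of category 3 / 4A nodules
#'
#' A category 3 nodule documented stable for at least 6 months is downgraded
#' to category 2; a category 4A nodule stable for at least 3 months is
#' downgraded to category 3. One step per documented interval: a 4A nodule
#' does not fall straight to 2 however long the single interval. Categories
#' 1, 2, 4B and 4X are never downgraded.
#'
#' @param category a Lung-RADS category.
#' @param stability_months documented unchanged interval in months (`NA`
#'   means no documented stability).
#' @return the (possibly downgraded) category.
#' @export
lungrads_stability_downgrade <- function(category, stability_months) {
  if (!is.finite(stability_months)) return(category)
  if (category == "3" && stability_months >= 6) return("2")
  if (category == "4A" && stability_months >= 3) return("3")
  category
}

#' Classify one nodule with Lung-RADS 2022
#'
#' Baseline size/density category, 4X promotion, then the stability
#' downgrade when the follow-up course is documented unchanged. Growth
#' (course `"increased"`) is carried in the record but does not alter the
#' baseline category here, since classification is at a single pre-surgical
#' baseline.
#'
#' @inheritParams lungrads_baseline
#' @return list with `category` (character).
#' @examples
#' rec <- nodule_record("fig5", "PSN", 9.0, solid_component_diameter = 4.0,
#'                      stability_months = 16, course = "unchanged")
#' classify_lungrads(rec)$category  # "2"
#' @export
classify_lungrads <- function(record,
                              x_triggers = c("spiculation", "enlarged_lymph_nodes",
                                             "ggn_doubling_1yr")) {
  record <- validate_record(record)
  cat <- lungrads_baseline(record, x_triggers = x_triggers)
  if (identical(record$course, "unchanged")) {
    cat <- lungrads_stability_downgrade(cat, record$stability_months)
  }
  list(category = cat)
}

#' Dichotomize a Lung-RADS category into a screen label
#'
#' Categories 1 and 2 are a negative screen; categories 3, 4A, 4B and 4X
#' are positive.
#'
#' @param category character vector of Lung-RADS categories.
#' @return character vector, `"negative"` or `"positive"`.
#' @export
dichotomize_lungrads <- function(category) {
  ifelse(lungrads_rank(category) >= lungrads_rank("3"), "positive", "negative")
}
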