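# PNI-GARS grading engine: size-tier base grade, sign-driven upgrades,
# benign-feature downgrade, follow-up stability rules, screen dichotomization.

# Sign partition. "Special signs of early malignant lesions" climb the
# sub-level ladder one step each (two or more force grade IV); the remaining
# suspicious signs are strong enough to force grade IV on their own.
.pni_ladder_signs <- c("vacuole", "vascular_convergence", "solid_component_in_ggn",
                       "pleural_indentation", "lobulation_sign")
.pni_force_iv_signs <- c("spiculation", "ggn_doubling_1yr",
                         "ggn_density_above_minus600",
                         "enlarged_lymph_nodes", "shrunk_but_denser")

# Definitely benign morphologies (grade 0, classification stops there).
.pni_benign_definite <- c("pure_calcification", "fat", "spherical_atelectasis",
                          "perifissural")

#' Base PNI-GARS grade from size and density
#'
#' Size tiers (mean diameter, half-open intervals, upper bound inclusive):
#' micronodules of any density at 5 mm or less are grade I; (5, 8] mm grade
#' II; (8, 10] IIIa; (10, 20] IIIb; (20, 30] IIIc. A part-solid nodule whose
#' solid component exceeds 5 mm is grade IV outright. Endobronchial nodules
#' carry a grade III floor: IIIb when the size tier is (10, 20] mm, otherwise
#' at least IIIa.
#'
#' @param record a validated [nodule_record].
#' @return a PNI-GARS grade (character, one of [pni_grade_levels]).
#' @export
pni_base_grade <- function(record) {
  d <- record$mean_diameter
  g <- if (d <= 5) "I"
  else if (d <= 8) "II"
  else if (d <= 10) "IIIa"
  else if (d <= 20) "IIIb"
  else "IIIc"
  if (record$density_type == "PSN" && isTRUE(record$solid_component_diameter > 5)) {
    g <- pni_grade_levels[max(pni_grade_rank(g), pni_grade_rank("IV"))]
  }
  if (record$endobronchial) {
    floor_g <- if (d > 10 && d <= 20) "IIIb" else "IIIa"
    g <- pni_grade_levels[max(pni_grade_rank(g), pni_grade_rank(floor_g))]
  }
  g
}

#' Upgrade a grade for malignant imaging signs
#'
#' Special early-malignancy signs (vacuole, vascular convergence, a solid
#' component appearing in a GGN, pleural indentation, lobulation sign) move
#' the grade up one sub-level each on the ladder II -> IIIa -> IIIb -> IIIc
#' -> IV; two or more of them, or any of the stronger suspicious signs
#' (spiculation, GGN doubling within a year or density above -600 HU,
#' enlarged lymph nodes, shrinkage with rising density), force grade IV.
#' Grades below II are never upgraded by signs, and no grade exceeds IV.
#'
#' @param grade a PNI-GARS grade.
#' @param signs character vector of malignant-sign tokens.
#' @return the upgraded grade.
#' @export
pni_apply_malignant_signs <- function(grade, signs) {
  r <- pni_grade_rank(grade)
  if (r < pni_grade_rank("II")) return(grade)
  n_ladder <- sum(signs %in% .pni_ladder_signs)
  force_iv <- any(signs %in% .pni_force_iv_signs)
  if (force_iv || n_ladder >= 2) return("IV")
  if (n_ladder == 1) return(pni_grade_levels[min(r + 1L, pni_grade_rank("IV"))])
  grade
}

#' Downgrade a grade for benign periphery findings
#'
#' Satellite lesions in the same lobe (fibrosis, calcification, small
#' nodules, exudation, consolidation), or a clinical plus CT picture of
#' inflammation, decrease the grade by one level: IV -> IIIc -> IIIb ->
#' IIIa -> II -> I, with floor I (grade 0 is reserved for the enumerated
#' definitely benign morphologies).
#'
#' @param grade a PNI-GARS grade.
#' @param features character vector of benign-feature tokens.
#' @return the adjusted grade.
#' @export
pni_apply_benign_adjustment <- function(grade, features) {
  down <- "satellite_lesions" %in% features ||
    all(c("inflammation_clinical", "inflammation_ct") %in% features)
  if (!down) return(grade)
  r <- pni_grade_rank(grade)
  pni_grade_levels[max(r - 1L, pni_grade_rank("I"))]
}

#' Follow-up stability rule
#'
#' A solid nodule documented unchanged for at least 2 years (24 months), or
#' a sub-solid nodule (PSN/GGN) unchanged for at least 5 years (60 months),
#' or any nodule that decreased or disappeared during follow-up, is graded I.
#' Shorter stability leaves the grade untouched - in particular a part-solid
#' nodule stable for only months keeps its grade.
#'
#' @param record a validated [nodule_record].
#' @param grade the grade the stability rule would override.
#' @return grade `"I"` if a stability rule fires, otherwise `grade`.
#' @export
pni_apply_stability <- function(record, grade) {
  if (record$course %in% c("decreased", "disappeared")) return("I")
  m <- record$stability_months
  if (is.finite(m) && record$course == "unchanged") {
    need <- if (record$density_type == "SN") 24 else 60
    if (m >= need) return("I")
  }
  grade
}

#' Classify one nodule with PNI-GARS
#'
#' Full rule pipeline, in precedence order: (1) a definitely benign
#' morphology (pure calcification, fat component, spherical atelectasis,
#' perifissural nodule) is grade 0 and classification stops; (2) long-term
#' stability or regression grades I and stops; (3) base grade from size and
#' density; (4) malignant-sign upgrades; (5) benign periphery downgrade;
#' (6) endobronchial grade III floor. Definitely benign and long-stable
#' nodules can therefore never be upgraded by signs.
#'
#' @param record a [nodule_record] (validated internally).
#' @return list with `grade` (character) and `trace`, an ordered character
#'   vector of rule identifiers; replaying the trace from the base grade
#'   reproduces the final grade.
#' @examples
#' rec <- nodule_record("fig3a", "GGN", 9.5,
#'                      malignant_signs = "vascular_convergence")
#' classify_pnigars(rec)$grade  # "IIIb"
#' @export
classify_pnigars <- function(record) {
  record <- validate_record(record)
  trace <- character()
  if (any(record$benign_features %in% .pni_benign_definite)) {
    return(list(grade = "0", trace = "benign_definite->0"))
  }
  stab <- pni_apply_stability(record, NA_character_)
  if (identical(stab, "I")) {
    return(list(grade = "I", trace = "stability->I"))
  }
  g <- pni_base_grade(record)
  trace <- c(trace, paste0("base:", g))
  g2 <- pni_apply_malignant_signs(g, record$malignant_signs)
  if (!identical(g2, g)) trace <- c(trace, paste0("signs:", g2))
  g3 <- pni_apply_benign_adjustment(g2, record$benign_features)
  if (!identical(g3, g2)) trace <- c(trace, paste0("benign_adjust:", g3))
  g4 <- g3
  if (record$endobronchial) {
    floor_g <- if (record$mean_diameter > 10 && record$mean_diameter <= 20) "IIIb" else "IIIa"
    g4 <- pni_grade_levels[max(pni_grade_rank(g3), pni_grade_rank(floor_g))]
    if (!identical(g4, g3)) trace <- c(trace, paste0("endobronchial_floor:", g4))
  }
  list(grade = g4, trace = trace)
}

#' Dichotomize a PNI-GARS grade into a screen label
#'
#' Grades 0, I and II are a negative screen; grades III (all sub-levels) and
#' IV are positive.
#'
#' @param grade character vector of PNI-GARS grades.
#' @return character vector, `"negative"` or `"positive"`.
#' @export
dichotomize_pni <- function(grade) {
  ifelse(pni_grade_rank(grade) >= pni_grade_rank("IIIa"), "positive", "negative")
}
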