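# Domain model shared by the two rule engines, the statistics layer and I/O.

#' Controlled vocabularies
#'
#' Token sets used by the nodule record schema. `density_types` separates
#' solid (SN), part-solid (PSN) and ground-glass (GGN) nodules as seen in the
#' lung and mediastinal CT windows. `malignant_signs` are imaging findings
#' that raise suspicion; `benign_features` lower it or mark a definitely
#' benign morphology. The two vocabularies are disjoint.
#'
#' @format Character vectors of valid tokens.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
density_types <- c("SN", "PSN", "GGN")

#' @rdname vocabularies
#' @export
margin_types <- c("smooth", "partial_smooth", "lobulation", "short_spinous", "vague")

#' @rdname vocabularies
#' @export
malignant_signs <- c(
  "vacuole", "vascular_convergence", "solid_component_in_ggn",
  "spiculation", "pleural_indentation", "lobulation_sign",
  "ggn_doubling_1yr", "ggn_density_above_minus600",
  "enlarged_lymph_nodes", "shrunk_but_denser"
)

#' @rdname vocabularies
#' @export
benign_features <- c(
  "pure_calcification", "fat", "spherical_atelectasis", "perifissural",
  "satellite_lesions", "inflammation_clinical", "inflammation_ct"
)

#' @rdname vocabularies
#' @export
course_types <- c("unchanged", "decreased", "disappeared", "increased", "unknown")

#' Ordered grade and category scales
#'
#' PNI-GARS grades run 0 < I < II < IIIa < IIIb < IIIc < IV; Grade III is
#' subdivided by nodule size. Lung-RADS categories run 1 < 2 < 3 < 4A < 4B,
#' with 4X flagging additional suspicious findings on a category 3/4 nodule
#' (4X sits above 4B for dichotomization). Helper rank functions give the
#' position on each scale, which is what the engines use for comparisons,
#' upgrades and downgrades.
#'
#' @format Character vectors in scale order.
#' @name scales
NULL

#' @rdname scales
#' @export
pni_grade_levels <- c("0", "I", "II", "IIIa", "IIIb", "IIIc", "IV")

#' @rdname scales
#' @export
lungrads_levels <- c("1", "2", "3", "4A", "4B", "4X")

#' @param grade character vector of PNI-GARS grades.
#' @return integer rank on the scale (1 = lowest).
#' @rdname scales
#' @export
pni_grade_rank <- function(grade) {
  r <- match(grade, pni_grade_levels)
  if (anyNA(r)) stop("unknown PNI-GARS grade: ", paste(grade[is.na(r)], collapse = ", "))
  r
}

#' @param category character vector of Lung-RADS categories.
#' @rdname scales
#' @export
lungrads_rank <- function(category) {
  r <- match(category, lungrads_levels)
  if (anyNA(r)) stop("unknown Lung-RADS category: ", paste(category[is.na(r)], collapse = ", "))
  r
}

#' Construct a single nodule record
#'
#' One record holds the imaging features, follow-up history and pathology
#' truth of one pulmonary nodule - the unit classified by both rule engines.
#' Diameters are mean diameters (average of long and short axis on the lung
#' window) in millimetres, reported to one decimal. `solid_component_diameter`
#' is meaningful for part-solid nodules only. `stability_months` is the
#' longest documented unchanged follow-up interval.
#'
#' @param id opaque identifier.
#' @param density_type one of `"SN"`, `"PSN"`, `"GGN"`.
#' @param mean_diameter mean diameter in mm, in (0, 30].
#' @param solid_component_diameter solid-component diameter in mm (PSN only),
#'   or `NA`.
#' @param margin margin descriptor, one of [margin_types].
#' @param malignant_signs character vector drawn from [malignant_signs].
#' @param benign_features character vector drawn from [benign_features].
#' @param endobronchial logical; nodule located inside a bronchus.
#' @param stability_months longest documented unchanged interval in months,
#'   or `NA`.
#' @param course follow-up course, one of [course_types].
#' @param pathology `"benign"` or `"malignant"` (surgical truth).
#' @param pathology_subtype optional label (e.g. `"AIS"`, `"hamartoma"`).
#' @return a list of class `"nodule_record"`.
#' @examples
#' nodule_record("n1", "GGN", 9.5, malignant_signs = "vascular_convergence",
#'               pathology = "malignant")
#' @export
nodule_record <- function(id, density_type, mean_diameter,
                          solid_component_diameter = NA_real_,
                          margin = "smooth",
                          malignant_signs = character(),
                          benign_features = character(),
                          endobronchial = FALSE,
                          stability_months = NA_real_,
                          course = "unknown",
                          pathology = "benign",
                          pathology_subtype = NA_character_) {
  rec <- list(
    id = as.character(id),
    density_type = as.character(density_type),
    mean_diameter = as.numeric(mean_diameter),
    solid_component_diameter = as.numeric(solid_component_diameter),
    margin = as.character(margin),
    malignant_signs = as.character(malignant_signs),
    benign_features = as.character(benign_features),
    endobronchial = isTRUE(endobronchial),
    stability_months = as.numeric(stability_months),
    course = as.character(course),
    pathology = as.character(pathology),
    pathology_subtype = as.character(pathology_subtype)
  )
  class(rec) <- "nodule_record"
  rec
}

#' Validate a nodule record
#'
#' Enforces the cohort inclusion rules and schema invariants: mean diameter
#' in (0, 30] mm (nodules over 30 mm are out of the system's domain), a solid
#' component present if and only if the nodule is part-solid and strictly
#' smaller than the whole nodule, and all tokens drawn from the controlled
#' vocabularies.
#'
#' @param record a [nodule_record].
#' @return the record, unchanged, if valid; otherwise an error whose message
#'   starts with a reason code (`diameter_bound`, `solid_component`,
#'   `vocabulary`, ...).
#' @export
validate_record <- function(record) {
  fail <- function(code, msg) {
    stop(sprintf("[%s] record '%s': %s", code, record$id, msg), call. = FALSE)
  }
  if (!record$density_type %in% density_types)
    fail("vocabulary", paste("unknown density_type", record$density_type))
  d <- record$mean_diameter
  if (!is.finite(d) || d <= 0 || d > 30)
    fail("diameter_bound", sprintf("mean_diameter %.1f outside (0, 30] mm", d))
  s <- record$solid_component_diameter
  if (record$density_type == "PSN") {
    if (!is.finite(s))
      fail("solid_component", "PSN requires a solid_component_diameter")
    if (s <= 0 || s >= d)
      fail("solid_component",
           sprintf("solid component %.1f must lie in (0, %.1f)", s, d))
  } else if (is.finite(s)) {
    fail("solid_component", "solid_component_diameter only valid for PSN")
  }
  if (!record$margin %in% margin_types)
    fail("vocabulary", paste("unknown margin", record$margin))
  bad <- setdiff(record$malignant_signs, malignant_signs)
  if (length(bad)) fail("vocabulary", paste("unknown malignant sign:", paste(bad, collapse = ";")))
  bad <- setdiff(record$benign_features, benign_features)
  if (length(bad)) fail("vocabulary", paste("unknown benign feature:", paste(bad, collapse = ";")))
  if (!record$course %in% course_types)
    fail("vocabulary", paste("unknown course", record$course))
  if (!record$pathology %in% c("benign", "malignant"))
    fail("vocabulary", paste("unknown pathology", record$pathology))
  if (is.finite(record$stability_months) && record$stability_months < 0)
    fail("stability", "stability_months must be non-negative")
  record
}

#' @export
print.nodule_record <- function(x, ...) {
  cat(sprintf("<nodule %s> %s %.1f mm", x$id, x$density_type, x$mean_diameter))
  if (is.finite(x$solid_component_diameter))
    cat(sprintf(" (solid %.1f mm)", x$solid_component_diameter))
  if (length(x$malignant_signs))
    cat(" signs:", paste(x$malignant_signs, collapse = ";"))
  if (length(x$benign_features))
    cat(" benign:", paste(x$benign_features, collapse = ";"))
  cat(" |", x$pathology, "\n")
  invisible(x)
}
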