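# Synthetic cohorts: free-form generation from a composition recipe, and
# the deterministic reconstruction of a 7,781-nodule benchmark cohort whose
# per-stratum confusion tables under both engines are fixed by design.

#' One block of a cohort composition recipe
#'
#' A block describes `count` nodules sharing a density type, pathology truth
#' and feature template. Diameters (and, for part-solid nodules, solid
#' components) may be a fixed value or a `c(lo, hi)` millimetre range drawn
#' uniformly and rounded to one decimal, the measurement convention of the
#' record schema.
#'
#' @param count number of nodules (>= 0).
#' @param density_type `"SN"`, `"PSN"` or `"GGN"`.
#' @param pathology `"benign"` or `"malignant"`.
#' @param diameter scalar mm value or `c(lo, hi)` range.
#' @param solid solid-component mm value or range (PSN only).
#' @param signs malignant-sign tokens applied to every nodule in the block.
#' @param features benign-feature tokens.
#' @param margin margin descriptor.
#' @param stability_months documented stable interval, or `NA`.
#' @param course follow-up course.
#' @param subtype optional pathology subtype label.
#' @return list of class `"cohort_block"`.
#' @export
cohort_block <- function(count, density_type, pathology,
                         diameter, solid = NA_real_,
                         signs = character(), features = character(),
                         margin = "smooth", stability_months = NA_real_,
                         course = "unknown", subtype = NA_character_) {
  if (count < 0 || count != round(count)) stop("count must be a non-negative integer")
  structure(list(count = count, density_type = density_type,
                 pathology = pathology, diameter = diameter, solid = solid,
                 signs = signs, features = features, margin = margin,
                 stability_months = stability_months, course = course,
                 subtype = subtype),
            class = "cohort_block")
}

.draw_size <- function(spec, n) {
  if (length(spec) == 1) rep(spec, n)
  else round(stats::runif(n, spec[1], spec[2]), 1)
}

#' Generate a synthetic cohort from a recipe
#'
#' Expands each block into its records, drawing sizes from the block's
#' template with the given seed. Output order and values are deterministic
#' given the recipe and seed (Mersenne-Twister, recorded in the
#' `"generator"` attribute), and every record passes [validate_record()].
#'
#' @param blocks list of [cohort_block]s.
#' @param seed integer RNG seed.
#' @param id_prefix prefix for the generated record ids.
#' @return cohort data frame.
#' @examples
#' blocks <- list(cohort_block(5, "GGN", "malignant", diameter = c(8.1, 10),
#'                             signs = "vacuole"))
#' generate_cohort(blocks, seed = 1)
#' @export
generate_cohort <- function(blocks, seed = 1L, id_prefix = "syn") {
  set.seed(seed)
  parts <- list()
  k <- 0L
  for (b in blocks) {
    if (!inherits(b, "cohort_block")) stop("blocks must be cohort_block objects")
    if (b$count == 0) next
    d <- .draw_size(b$diameter, b$count)
    s <- if (b$density_type == "PSN") {
      sol <- .draw_size(b$solid, b$count)
      pmin(sol, d - 0.1)  # solid component strictly inside the nodule
    } else rep(NA_real_, b$count)
    # one representative record per distinct size combination suffices
    key <- paste(d, s)
    for (u in unique(key)) {
      j <- match(u, key)
      validate_record(nodule_record(
        id = "template", density_type = b$density_type, mean_diameter = d[j],
        solid_component_diameter = s[j], margin = b$margin,
        malignant_signs = b$signs, benign_features = b$features,
        stability_months = b$stability_months, course = b$course,
        pathology = b$pathology, pathology_subtype = b$subtype
      ))
    }
    parts[[length(parts) + 1L]] <- data.frame(
      id = sprintf("%s%05d", id_prefix, k + seq_len(b$count)),
      density_type = b$density_type,
      mean_diameter = d,
      solid_component_diameter = s,
      margin = b$margin,
      malignant_signs = paste(b$signs, collapse = ";"),
      benign_features = paste(b$features, collapse = ";"),
      endobronchial = FALSE,
      stability_months = b$stability_months,
      course = b$course,
      pathology = b$pathology,
      pathology_subtype = b$subtype,
      stringsAsFactors = FALSE
    )
    k <- k + b$count
  }
  if (k == 0L) {
    cohort <- utils::read.csv(text = paste(.cohort_columns, collapse = ","),
                              stringsAsFactors = FALSE)
  } else {
    cohort <- do.call(rbind, parts)
    rownames(cohort) <- NULL
  }
  attr(cohort, "generator") <- list(seed = seed, rng = "Mersenne-Twister")
  cohort
}

#' Reconstruct the 7,781-nodule benchmark cohort
#'
#' Builds, with no randomness, a cohort of 3,018 solid, 1,709 part-solid and
#' 3,054 ground-glass nodules whose classification by both engines followed
#' by [confusion()] yields a fixed, documented confusion table per stratum
#' and system. Within each stratum the joint behaviour of the two screens is
#' chosen as the maximal-concordance arrangement compatible with the
#' per-system tables; the steering features are minimal: size-tier choice, a
#' single vacuole sign (grade III under PNI-GARS while staying below the
#' 6 mm Lung-RADS cut), and satellite lesions (one-level PNI-GARS downgrade
#' that Lung-RADS ignores).
#'
#' @return cohort data frame of 7,781 validated records.
#' @export
reconstruct_table3_cohort <- function() {
  bl <- function(...) cohort_block(...)
  blocks <- list(
    # solid nodules: 1851 malignant, 1167 benign
    bl(1839, "SN", "malignant", diameter = 10.0, margin = "lobulation"),
    bl(9,    "SN", "malignant", diameter = 5.5, signs = "vacuole"),
    bl(3,    "SN", "malignant", diameter = 5.5),
    bl(569,  "SN", "benign",    diameter = 10.0),
    bl(188,  "SN", "benign",    diameter = 8.5, features = "satellite_lesions"),
    bl(410,  "SN", "benign",    diameter = 4.0),
    # part-solid nodules: 1604 malignant, 105 benign
    bl(1578, "PSN", "malignant", diameter = 16.0, solid = 6.5),
    bl(24,   "PSN", "malignant", diameter = 5.5, solid = 2.0, signs = "vacuole"),
    bl(2,    "PSN", "malignant", diameter = 5.5, solid = 2.0),
    bl(91,   "PSN", "benign",    diameter = 16.0, solid = 6.5),
    bl(8,    "PSN", "benign",    diameter = 9.0, solid = 4.0,
       features = "satellite_lesions"),
    bl(6,    "PSN", "benign",    diameter = 5.5, solid = 2.0),
    # ground-glass nodules: 2488 malignant, 566 benign (all Lung-RADS 2)
    bl(2401, "GGN", "malignant", diameter = 10.0),
    bl(87,   "GGN", "malignant", diameter = 4.0),
    bl(262,  "GGN", "benign",    diameter = 10.0),
    bl(304,  "GGN", "benign",    diameter = 4.0)
  )
  cohort <- generate_cohort(blocks, seed = 0L, id_prefix = "t3-")
  attr(cohort, "generator") <- list(seed = NA, rng = "deterministic")
  cohort
}

#' Tag malignant ground-glass nodules with pathology subtypes
#'
#' Labels the malignant GGNs, in cohort order, as adenocarcinoma in situ
#' (AIS, 979), minimally invasive adenocarcinoma (MIA, 946) and invasive
#' adenocarcinoma (IAC, 560); any remainder is labelled `"other"`. Labels
#' are annotations only and never affect classification.
#'
#' @param cohort cohort data frame (typically from
#'   [reconstruct_table3_cohort()]).
#' @param counts named integer vector of subtype counts, in assignment
#'   order; must not exceed the number of malignant GGNs.
#' @return the cohort with `pathology_subtype` filled in for malignant GGNs.
#' @export
tag_pathology_subtypes <- function(cohort, counts = c(AIS = 979, MIA = 946, IAC = 560)) {
  idx <- which(cohort$density_type == "GGN" & cohort$pathology == "malignant")
  if (sum(counts) > length(idx))
    stop("subtype counts (", sum(counts), ") exceed malignant GGNs (", length(idx), ")")
  labels <- c(rep(names(counts), times = counts),
              rep("other", length(idx) - sum(counts)))
  cohort$pathology_subtype[idx] <- labels
  cohort
}
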