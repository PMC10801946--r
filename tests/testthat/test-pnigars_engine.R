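test_that("base grade follows the size tiers with inclusive upper bounds", {
  cases <- list(
    list("SN", 4.0, NA, "I"), list("GGN", 5.0, NA, "I"), list("PSN", 5.0, 2.0, "I"),
    list("SN", 5.1, NA, "II"), list("SN", 8.0, NA, "II"),
    list("SN", 8.1, NA, "IIIa"), list("GGN", 9.5, NA, "IIIa"), list("SN", 10.0, NA, "IIIa"),
    list("SN", 10.1, NA, "IIIb"), list("SN", 14.9, NA, "IIIb"), list("SN", 20.0, NA, "IIIb"),
    list("SN", 20.1, NA, "IIIc"), list("GGN", 30.0, NA, "IIIc"),
    list("PSN", 9.0, 4.0, "IIIa"), list("PSN", 9.0, 6.0, "IV"),
    list("PSN", 16.0, 5.0, "IIIb"), list("PSN", 16.0, 5.1, "IV")
  )
  for (cs in cases) {
    rec <- nodule_record("x", cs[[1]], cs[[2]], solid_component_diameter = cs[[3]])
    expect_identical(pni_base_grade(validate_record(rec)), cs[[4]],
                     label = sprintf("%s %.1f mm", cs[[1]], cs[[2]]))
  }
})

test_that("special signs climb one sub-level each; two signs or a forcing sign give IV", {
  expect_identical(pni_apply_malignant_signs("IIIa", "vascular_convergence"), "IIIb")
  expect_identical(pni_apply_malignant_signs("II", "vacuole"), "IIIa")
  expect_identical(pni_apply_malignant_signs("IIIc", "pleural_indentation"), "IV")
  expect_identical(pni_apply_malignant_signs("IIIc", character()), "IIIc")
  expect_identical(
    pni_apply_malignant_signs("IIIb", c("vascular_convergence", "spiculation",
                                        "pleural_indentation")), "IV")
  expect_identical(pni_apply_malignant_signs("II", c("vacuole", "vascular_convergence")), "IV")
  expect_identical(pni_apply_malignant_signs("II", "spiculation"), "IV")
  expect_identical(pni_apply_malignant_signs("IV", "vacuole"), "IV")
  # micronodules are not upgraded by signs
  expect_identical(pni_apply_malignant_signs("I", "spiculation"), "I")
  expect_identical(pni_apply_malignant_signs("0", "vacuole"), "0")
})

test_that("benign periphery findings downgrade one level with floor I", {
  expect_identical(pni_apply_benign_adjustment("IIIa", "satellite_lesions"), "II")
  expect_identical(pni_apply_benign_adjustment("IIIb", character()), "IIIb")
  expect_identical(
    pni_apply_benign_adjustment("IIIb", c("inflammation_clinical", "inflammation_ct")),
    "IIIa")
  # one inflammation indicator alone is not enough
  expect_identical(pni_apply_benign_adjustment("IIIb", "inflammation_ct"), "IIIb")
  # exhaustive sweep: downgrade is one rank down, never below I
  for (g in pni_grade_levels) {
    out <- pni_apply_benign_adjustment(g, "satellite_lesions")
    expect_identical(pni_grade_rank(out),
                     max(pni_grade_rank(g) - 1L, pni_grade_rank("I")))
  }
})

test_that("stability rules grade long-stable or regressing nodules I", {
  sn <- nodule_record("s", "SN", 14.0, stability_months = 24, course = "unchanged")
  expect_identical(pni_apply_stability(sn, "IIIb"), "I")
  sn23 <- nodule_record("s", "SN", 14.0, stability_months = 23, course = "unchanged")
  expect_identical(pni_apply_stability(sn23, "IIIb"), "IIIb")
  psn <- nodule_record("p", "PSN", 9.0, solid_component_diameter = 4.0,
                       stability_months = 16, course = "unchanged")
  expect_identical(pni_apply_stability(psn, "IIIa"), "IIIa")
  psn5y <- nodule_record("p", "PSN", 9.0, solid_component_diameter = 4.0,
                         stability_months = 60, course = "unchanged")
  expect_identical(pni_apply_stability(psn5y, "IIIa"), "I")
  ggn <- nodule_record("g", "GGN", 12.0, course = "disappeared")
  expect_identical(pni_apply_stability(ggn, "IIIb"), "I")
})

test_that("full classification reproduces the worked figure cases", {
  fc <- figure_cases()
  expect_identical(classify_pnigars(fc$fig4)$grade, "0")
  expect_identical(classify_pnigars(fc$fig3a)$grade, "IIIb")
  expect_identical(classify_pnigars(fc$fig3c)$grade, "IV")
  expect_identical(classify_pnigars(fc$fig5)$grade, "IIIa")
})

test_that("precedence: definitely benign and long-stable nodules are never upgraded", {
  spiky_hamartoma <- nodule_record("x", "SN", 11.0,
                                   benign_features = "pure_calcification",
                                   malignant_signs = "spiculation")
  expect_identical(classify_pnigars(spiky_hamartoma)$grade, "0")
  stable_spiky <- nodule_record("y", "SN", 14.0, stability_months = 30,
                                course = "unchanged",
                                malignant_signs = "spiculation")
  expect_identical(classify_pnigars(stable_spiky)$grade, "I")
})

test_that("endobronchial nodules are floored at grade III", {
  small <- nodule_record("e1", "SN", 4.0, endobronchial = TRUE)
  expect_identical(classify_pnigars(small)$grade, "IIIa")
  medium <- nodule_record("e2", "SN", 12.0, endobronchial = TRUE)
  expect_identical(classify_pnigars(medium)$grade, "IIIb")
  # the floor re-applies after a benign downgrade
  sat <- nodule_record("e3", "SN", 9.0, endobronchial = TRUE,
                       benign_features = "satellite_lesions")
  expect_identical(classify_pnigars(sat)$grade, "IIIa")
})

test_that("dichotomization: grades 0/I/II negative, III and IV positive", {
  expect_identical(dichotomize_pni(c("0", "I", "II", "IIIa", "IIIb", "IIIc", "IV")),
                   c("negative", "negative", "negative",
                     "positive", "positive", "positive", "positive"))
})

test_that("grade is monotone in diameter on a 0.1 mm grid, other features fixed", {
  grid <- seq(0.5, 30, by = 0.1)
  for (dt in c("SN", "GGN")) {
    ranks <- vapply(grid, function(d) {
      pni_grade_rank(classify_pnigars(nodule_record("m", dt, d))$grade)
    }, integer(1))
    expect_true(all(diff(ranks) >= 0), label = paste("monotone", dt))
  }
  psn_grid <- seq(2.2, 30, by = 0.1)
  ranks <- vapply(psn_grid, function(d) {
    rec <- nodule_record("m", "PSN", d, solid_component_diameter = 2.0)
    pni_grade_rank(classify_pnigars(rec)$grade)
  }, integer(1))
  expect_true(all(diff(ranks) >= 0))
})

test_that("adding a malignant sign never lowers the grade; satellite lesions never raise it", {
  set.seed(11)
  for (i in 1:60) {
    d <- round(runif(1, 0.5, 30), 1)
    dt <- sample(c("SN", "GGN", "PSN"), 1)
    s <- if (dt == "PSN") round(runif(1, 0.1, d - 0.1), 1) else NA_real_
    base_signs <- sample(malignant_signs, sample(0:2, 1))
    rec <- nodule_record("p", dt, d, solid_component_diameter = s,
                         malignant_signs = base_signs)
    r0 <- pni_grade_rank(classify_pnigars(rec)$grade)
    extra <- sample(setdiff(malignant_signs, base_signs), 1)
    rec_plus <- nodule_record("p", dt, d, solid_component_diameter = s,
                              malignant_signs = c(base_signs, extra))
    expect_gte(pni_grade_rank(classify_pnigars(rec_plus)$grade), r0)
    rec_sat <- nodule_record("p", dt, d, solid_component_diameter = s,
                             malignant_signs = base_signs,
                             benign_features = "satellite_lesions")
    expect_lte(pni_grade_rank(classify_pnigars(rec_sat)$grade), r0)
  }
})

test_that("no trace exceeds grade IV, traces replay, and classification is deterministic", {
  set.seed(5)
  for (i in 1:80) {
    d <- round(runif(1, 0.5, 30), 1)
    dt <- sample(density_types, 1)
    s <- if (dt == "PSN") round(runif(1, 0.1, d - 0.1), 1) else NA_real_
    rec <- nodule_record("t", dt, d, solid_component_diameter = s,
                         malignant_signs = sample(malignant_signs, sample(0:3, 1)),
                         benign_features = sample(benign_features, sample(0:2, 1)),
                         endobronchial = runif(1) < 0.2)
    out1 <- classify_pnigars(rec)
    out2 <- classify_pnigars(rec)
    expect_identical(out1, out2)
    expect_lte(pni_grade_rank(out1$grade), pni_grade_rank("IV"))
    if (!out1$grade %in% c("0", "I") || grepl(":", out1$trace[length(out1$trace)])) {
      expect_identical(replay_trace(out1$trace), out1$grade)
    }
  }
})
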