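# Shared fixtures: the published per-stratum confusion tables, the worked
# figure cases, independent statistical oracles and random generators.

# Twelve TP/FN/FP/TN quadruples with the printed one-decimal percentages.
table3_rows <- function() {
  read.csv(text = "stratum,system,tp,fn,fp,tn,se,sp,ar
SN,lungrads,1839,12,757,410,99.4,35.1,74.5
SN,pnigars,1848,3,569,598,99.8,51.2,81.1
PSN,lungrads,1578,26,99,6,98.4,5.7,92.7
PSN,pnigars,1602,2,91,14,99.9,13.3,94.6
GGN,lungrads,0,2488,0,566,0,100,18.5
GGN,pnigars,2401,87,262,304,96.5,53.7,88.6
all,lungrads,3417,2526,856,982,57.5,53.4,56.5
all,pnigars,5851,92,922,916,98.5,49.8,87.0", stringsAsFactors = FALSE)
}

# Fully specified worked cases (hamartoma, two GGNs, stable PSN, stable SN).
figure_cases <- function() {
  list(
    fig4 = nodule_record("fig4", "SN", 11.0,
                         benign_features = c("pure_calcification", "fat"),
                         pathology = "benign", pathology_subtype = "hamartoma"),
    fig3a = nodule_record("fig3a", "GGN", 9.5,
                          malignant_signs = "vascular_convergence",
                          pathology = "malignant", pathology_subtype = "MIA"),
    fig3c = nodule_record("fig3c", "GGN", 11.4,
                          malignant_signs = c("vascular_convergence", "spiculation",
                                              "pleural_indentation"),
                          pathology = "malignant", pathology_subtype = "IAC"),
    fig5 = nodule_record("fig5", "PSN", 9.0, solid_component_diameter = 4.0,
                         stability_months = 16, course = "unchanged",
                         pathology = "malignant", pathology_subtype = "IAC"),
    fig6 = nodule_record("fig6", "SN", 14.9, stability_months = 5,
                         course = "unchanged",
                         pathology = "malignant", pathology_subtype = "IAC")
  )
}

# Two-sided Fisher p by direct hypergeometric enumeration (probability
# method): sum the probabilities of all tables with the observed margins
# that are no more probable than the observed table.
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  supp <- max(0, c1 - (n - r1)):min(r1, c1)
  logp <- lchoose(r1, supp) + lchoose(n - r1, c1 - supp) - lchoose(n, c1)
  p <- exp(logp)
  obs <- p[match(a, supp)]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

# Pearson statistic by expected-count summation (the defining formula).
pearson_sum_oracle <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# Pearson shortcut for a 2x2: n (ad - bc)^2 / (r1 r2 c1 c2).
pearson_shortcut <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Random 2x2 with all margins positive.
random_fourfold <- function(max_cell = 50) {
  repeat {
    t <- sample.int(max_cell, 4, replace = TRUE)
    m <- matrix(t, 2)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(t)
  }
}

# Small mixed synthetic cohort for I/O and pipeline tests.
mixed_blocks <- function() {
  list(
    cohort_block(8, "SN", "malignant", diameter = c(8.1, 20)),
    cohort_block(5, "SN", "benign", diameter = c(3, 5.9),
                 features = "satellite_lesions"),
    cohort_block(6, "PSN", "malignant", diameter = c(10, 16), solid = c(6, 8)),
    cohort_block(4, "GGN", "benign", diameter = c(5, 12), course = "unchanged",
                 stability_months = 12),
    cohort_block(3, "GGN", "malignant", diameter = c(8.1, 10), signs = "vacuole")
  )
}

replay_trace <- function(trace) {
  # trace entries are "rule:grade"; the final grade is the last entry's
  grades <- sub("^[^:]*:", "", trace)
  grades[length(grades)]
}
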