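scheme <- default_scheme()

test_that("scheme structure: item maxima, class bins, stratification", {
  # the published nominal maximum (47) is not reproducible from the
  # published per-item maxima, which sum to 41; the scheme stores both
  expect_equal(scheme$max_score, 41L)
  expect_equal(scheme$si_nominal_max, 47L)
  expect_equal(scheme$min_score, 1L)  # age at onset always grades >= 1
  expect_equal(scheme$class_bins$label,
               c("very_mild", "mild", "moderate", "severe", "very_severe"))
})

test_that("grade_item reproduces the published boundary resolutions", {
  cases <- list(
    # item, measurement, sex, expected
    list("MMT", 79, NA, 3L),          # "grade 3: 79-70"
    list("MMT", 100, NA, 0L),
    list("SIXMWT", 10, "F", 6L),      # "grade 6: <118"
    list("SIXMWT", 450, "M", 2L),
    list("SIXMWT", 535, "M", 1L),
    list("AAO", 50, NA, 1L),          # ">50" resolved as >=50
    list("AAO", 29, NA, 4L),          # "29-15" taken literally
    list("DFVC", 20, NA, 2L),         # shared edge, milder grade wins
    list("DFVC", 30.1, NA, 3L),       # rounds to 30, still grade 3
    list("DFVC", 31, NA, 4L),
    list("FVC", 80, NA, 0L),          # ">80" resolved as >=80
    list("VDD", 30, NA, 0L),          # "30-100" vs "20-30": milder wins
    list("VDD", 29.96, NA, 0L),       # rounds to 30.0
    list("BMI", 40, NA, 3L),          # "36-40" vs ">40"
    list("BMI", 24.95, NA, 1L),       # half-up to 25.0
    list("GSCG", 4, NA, 0L),
    list("GSCG", 22, NA, 4L)
  )
  for (cs in cases) {
    expect_equal(
      grade_item(scheme, cs[[1]], cs[[2]],
                 sex = if (!is.na(cs[[3]])) cs[[3]]),
      cs[[4]], ignore_attr = TRUE,
      label = sprintf("%s(%s)", cs[[1]], cs[[2]]))
  }
  expect_equal(grade_item(scheme, "BF", FALSE), 0L)
  expect_equal(grade_item(scheme, "BF", TRUE), 1L)
  expect_equal(grade_item(scheme, "IGG", 1200), 1L)
  expect_equal(grade_item(scheme, "IGG", 0), 0L)
})

test_that("grade_item error contract", {
  expect_error(grade_item(scheme, "SIXMWT", 300), "sex")
  expect_error(grade_item(scheme, "AAO", 0.2), "falls in 0 bins")
  expect_error(grade_item(scheme, "XYZ", 1), "unknown item")
  expect_error(grade_item(scheme, "VDD", NA), "missing")
  expect_warning(
    g <- grade_item(scheme, "VDD", NA, unavailable_to_zero = TRUE),
    "graded 0")
  expect_equal(g, 0L)
})

test_that("grading is monotone in each item's worsening direction", {
  for (item in c("AAO", "MMT", "GSCG", "FVC", "DFVC", "BMI", "VDD")) {
    rule <- scheme$items[[item]]
    bins <- rule$bins
    grid <- sort(unique(c(bins$lo[is.finite(bins$lo)],
                          bins$hi[is.finite(bins$hi)],
                          seq(min(bins$lo[is.finite(bins$lo)]),
                              max(bins$hi[is.finite(bins$hi)]),
                              length.out = 41))))
    g <- vapply(grid, function(v) grade_item(scheme, item, v), integer(1))
    worsening <- if (rule$direction == "higher_worse") g else rev(g)
    expect_true(all(diff(worsening) >= 0), label = paste("monotone", item))
  }
  for (sx in c("F", "M")) {
    grid <- seq(0, 650, by = 7)
    g <- vapply(grid, function(v) grade_item(scheme, "SIXMWT", v, sex = sx),
                integer(1))
    expect_true(all(diff(rev(g)) >= 0))
  }
})

test_that("grade_bmd matches all published composite grades", {
  expect_equal(grade_bmd(c(-2.9, -3, -3)), 2L)
  expect_equal(grade_bmd(c(-1.3, -1.5, -2.6)), 1L)  # one district <= -2.5
  expect_equal(grade_bmd(c(1.1, 2.2, 0.6)), 0L)
  expect_equal(grade_bmd(c(-0.8, -1.4, 0.2)), 1L)   # median above -1
  expect_equal(grade_bmd(c(-2.6, NA, NA)), 1L)
  expect_error(grade_bmd(c(NA, NA, NA)), "missing")
})

test_that("score_patient: worst-grade policy, exact columns, overrides", {
  ds <- table1_ds()
  t2 <- table2_fx()

  # not-performed spirometry takes the worst grade
  r <- ds$records[ds$records$patient_id == "F2II-4", ]
  g <- score_patient(scheme, r,
                     missing_reasons = c(delta_fvc = "not_performed"))
  expect_equal(unname(g$grades["DFVC"]), 4L)
  expect_equal(unname(g$provenance["DFVC"]), "missing_worst")

  # full column (computed path); IGG is 1 under the presence rule, which
  # is one of the documented departures from the printed matrix
  r12 <- ds$records[ds$records$patient_id == "F1II-12", ]
  g12 <- score_patient(scheme, r12)
  expect_equal(unname(g12$grades),
               c(2L, 3L, 3L, 1L, 0L, 3L, 1L, 0L, 0L, 0L, 1L, 1L, 1L, 0L))

  # an all-normal record grades 0 everywhere except age at onset
  g0 <- score_patient(scheme, make_record())
  expect_equal(unname(g0$grades["AAO"]), 1L)
  expect_true(all(g0$grades[setdiff(names(g0$grades), "AAO")] == 0L))

  # overrides replace the computed grade with provenance
  gov <- score_patient(scheme, r12, overrides = c(IGG = 0L))
  expect_equal(unname(gov$grades["IGG"]), 0L)
  expect_equal(unname(gov$provenance["IGG"]), "override")
  expect_error(score_patient(scheme, r12, overrides = c(VDD = 9L)),
               "out of range")
})

test_that("cohort regression: exact match set and exact mismatch set", {
  ds <- table1_ds()
  t2 <- table2_fx()
  computed <- score_cohort(scheme, ds)
  mm <- compare_grade_matrix(computed, t2$grades)
  want <- known_mismatch_cells()
  expect_equal(nrow(mm), nrow(want))
  expect_setequal(paste(mm$patient_id, mm$item),
                  paste(want$patient_id, want$item))
  # with the shipped overrides the printed matrix is reproduced exactly
  ov <- bundled_fixture("table2_overrides")
  expect_equal(nrow(compare_grade_matrix(score_cohort(scheme, ds, ov),
                                         t2$grades)), 0)
})

test_that("compute_severity_index sums exactly and classifies", {
  t2 <- table2_fx()
  r5 <- compute_severity_index(t2$grades[, "F1II-5"])
  expect_equal(r5$si, 23L)
  expect_equal(r5$severity_class, "moderate")
  expect_equal(r5$group, "M_S")

  # the printed SI row says 11 for F2II-1, but its own printed grades sum
  # to 12; the exact sum wins (one of two such columns, see vignette)
  r1 <- compute_severity_index(t2$grades[, "F2II-1"])
  expect_equal(r1$si, 12L)
  expect_equal(r1$severity_class, "mild")
  expect_equal(r1$group, "VM_M")

  zero <- compute_severity_index(
    stats::setNames(rep(0L, 14), rownames(t2$grades)))
  expect_equal(zero$si, 0L)
  expect_true(zero$flagged)
  expect_true(is.na(zero$severity_class))

  expect_error(compute_severity_index(c(AAO = 1L)), "missing item")

  # invariance under permutation of the grade map
  g <- t2$grades[, "F2II-5"]
  perm <- sample(seq_along(g))
  expect_equal(compute_severity_index(g[perm])$si,
               compute_severity_index(g)$si)
})

test_that("classify_severity boundaries", {
  expect_equal(classify_severity(c(1, 10, 11, 20, 21, 29, 30, 39, 40, 47)),
               c("very_mild", "very_mild", "mild", "mild", "moderate",
                 "moderate", "severe", "severe", "very_severe",
                 "very_severe"))
})

test_that("dichotomize reproduces the 6/5 split and degenerate cases", {
  t2 <- table2_fx()
  grp <- dichotomize(t2$si)
  expect_equal(unname(attr(grp, "sizes")), c(6L, 5L))
  expect_equal(unname(grp["F2II-5"]), "M_S")

  all5 <- dichotomize(stats::setNames(rep(5L, 4), paste0("P", 1:4)))
  expect_true(all(all5 == "VM_M"))
  expect_true(all(dichotomize(stats::setNames(1:3, paste0("P", 1:3)),
                              threshold = 0) == "M_S"))
  expect_error(dichotomize(integer(0)), "no severity")
})

test_that("scheme YAML round trip scores identically", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_scheme(scheme, tmp)
  sch2 <- read_scheme(tmp)
  ds <- table1_ds()
  expect_identical(score_cohort(sch2, ds), score_cohort(scheme, ds))
  # the shipped serialization stays in sync with the in-code default
  shipped <- read_scheme(system.file("extdata", "si_scheme.yaml",
                                     package = "lopdkit"))
  expect_identical(score_cohort(shipped, ds), score_cohort(scheme, ds))
})
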