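test_that("CHF index flags apply the strict sex-specific cutoffs", {
  # experimental-group mean profile: LAD and LVDD fire, LVEF does not
  f <- chf_index_flags(list(sex = "male", lad_mm = 40.05,
                            lvdd_mm = 56.05, lvef_pct = 60.09))
  expect_true(f$lad_positive)
  expect_true(f$lvdd_positive)
  expect_false(f$lvef_positive)
  expect_identical(f$n_positive_indices, 2L)
  expect_true(f$chf_ultrasound_positive)

  # boundary values: strict inequalities, all negative
  b <- chf_index_flags(list(sex = "male", lad_mm = 30, lvdd_mm = 55,
                            lvef_pct = 50))
  expect_false(b$lad_positive || b$lvdd_positive || b$lvef_positive)
  expect_false(b$chf_ultrasound_positive)

  # LVDD 51.35 mm: positive in a female, negative in a male
  pf <- list(sex = "female", lad_mm = 20, lvdd_mm = 51.35, lvef_pct = 60)
  pm <- list(sex = "male", lad_mm = 20, lvdd_mm = 51.35, lvef_pct = 60)
  expect_true(chf_index_flags(pf)$lvdd_positive)
  expect_false(chf_index_flags(pm)$lvdd_positive)

  # configurable combination rule
  expect_false(chf_index_flags(list(sex = "male", lad_mm = 40.05,
                                    lvdd_mm = 56.05, lvef_pct = 60.09),
                               rule_threshold = 3)$chf_ultrasound_positive)
  expect_error(chf_index_flags(list(sex = "male", lad_mm = 40)),
               "missing")
})

test_that("sarcopenia positivity is any-of with strict inequalities", {
  expect_true(sarcopenia_positive(list(sex = "male", grip_kg = 25)))
  expect_false(sarcopenia_positive(list(sex = "female", smi_kg_m2 = 5.5,
                                        grip_kg = 20, gait_m_s = 0.9)))
  expect_false(sarcopenia_positive(list(sex = "male", gait_m_s = 0.8)))
  expect_true(sarcopenia_positive(list(sex = "female", smi_kg_m2 = 5.3)))
  expect_error(sarcopenia_positive(list(sex = "male")), "at least one")
})

test_that("diagnose_cohort appends flags for every record", {
  ch <- sample_cohort(table2_cohort_params("experimental", 40, seed = 5))
  out <- diagnose_cohort(ch)
  expect_identical(nrow(out), 40L)
  expect_true(all(c("chf_ultrasound_positive", "sarcopenia_positive",
                    "n_positive_indices") %in% names(out)))
  i <- 17L
  expect_identical(out$chf_ultrasound_positive[i],
                   chf_index_flags(ch[i, ])$chf_ultrasound_positive)
})

test_that("concordance percentages reproduce the worked examples", {
  expect_identical(similarity_percent(215, 230), 93.5)
  expect_identical(similarity_percent(200, 230), 87.0)
  expect_identical(similarity_percent(230, 230), 100.0)
  expect_identical(proportion_percent(200, 259), 77.2)
  expect_identical(proportion_percent(215, 259), 83.0)
  expect_identical(proportion_percent(0, 259), 0.0)
  expect_error(similarity_percent(10, 0), ">= 1")
  expect_error(proportion_percent(10, 0), ">= 1")
  # monotone in the group count at fixed final count
  sims <- vapply(c(180, 200, 215, 230), similarity_percent,
                 numeric(1), final_chf = 230)
  expect_true(all(diff(sims) >= 0))
})

test_that("diagnosis tables enforce column sums and report concordance", {
  tab <- diagnosis_table(c("control", "experimental", "final"),
                         c(200, 215, 230), c(59, 44, 29))
  expect_identical(tab$cohort_total, rep(259L, 3))
  expect_error(diagnosis_table(c("a", "b"), c(10, 11), c(5, 5)),
               "cohort total")

  rep <- concordance_report(tab)
  expect_equal(rep$similarity_to_final_pct[rep$group == "experimental"],
               93.5)
  expect_equal(rep$similarity_to_final_pct[rep$group == "control"], 87.0)
  expect_equal(rep$chf_proportion_pct,
               c(77.2, 83.0, 88.8))
  expect_true(is.na(rep$similarity_to_final_pct[rep$group == "final"]))
  expect_error(concordance_report(tab, final_group = "nope"), "no group")

  # CHF and other-disease proportions sum to ~100 per column
  for (i in 1:3) {
    expect_lt(abs(proportion_percent(tab$chf_count[i], 259) +
                    proportion_percent(tab$other_count[i], 259) - 100),
              0.1 + 1e-9)
  }
})

test_that("group and count comparisons match hand calculations", {
  gc <- group_compare(1:5, 2:6)
  expect_equal(gc$statistic, -1, tolerance = 1e-12)
  expect_identical(gc$df, 8)

  same <- group_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(group_compare(c(1, 1), c(2, 2)), "zero variance")
  expect_error(group_compare(1, 1:3), "at least 2")

  cc <- count_compare(matrix(10, 2, 2))
  expect_equal(cc$statistic, 0)
  expect_equal(cc$p_value, 1)
  expect_error(count_compare(matrix(c(0, 0, 5, 5), 2, 2)), "margin")
  expect_error(count_compare(matrix(1:6, 2, 3)), "2 x 2")
})
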