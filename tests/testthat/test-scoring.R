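test_that("PRA worked examples categorize and aggregate correctly", {
  # moderate across the four numeric parameters, low systemic and smoking
  p <- make_patient(bop_percent = 24, n_ppd_ge5 = 7, bl_age_ratio = 0.59,
                    tooth_loss = 8, systemic_factor = FALSE,
                    smoking = "former_smoker")
  res <- compute_pra(p)
  expect_identical(unname(res$per_parameter[c("bop_percent", "n_ppd_ge5",
                                              "bl_age_ratio", "tooth_loss",
                                              "systemic_factor", "smoking")]),
                   c("moderate", "moderate", "moderate", "moderate", "low", "low"))
  expect_identical(res$overall, "moderate")
  expect_equal(res$n_low + res$n_moderate + res$n_high, 6)

  # two highs (>25% BOP, >8 deep sites) make the patient high risk
  res2 <- compute_pra(make_patient(bop_percent = 30, n_ppd_ge5 = 9))
  expect_identical(res2$overall, "high")
  expect_equal(res2$n_high, 2)

  # all parameters at their minima
  expect_identical(compute_pra(make_patient())$overall, "low")
})

test_that("PRA requires all six inputs", {
  p <- make_patient()
  p$smoking <- NULL
  expect_error(compute_pra(p), "smoking")
  p2 <- make_patient(bop_percent = NA)
  expect_error(compute_pra(p2), "bop_percent")
})

test_that("IRA worked examples, including the compliance flip to high risk", {
  p <- make_patient(bop_percent = 24, n_ppd_ge5 = 7, bl_age_ratio = 0.59,
                    history = TRUE, stage = "III", grade = "B", compliant = TRUE)
  impl <- make_implant()
  res <- compute_ira(p, impl)
  expect_identical(unname(res$per_parameter[.expected_ira <- c(
    "bop_percent", "n_ppd_ge5", "bl_age_ratio", "history", "susceptibility",
    "compliance", "rm_bone", "prosthesis_plaque")]),
    c("moderate", "high", "moderate", "moderate", "moderate", "low", "low", "low"))
  expect_identical(res$overall, "moderate")  # one high, several moderates
  expect_equal(res$n_low + res$n_moderate + res$n_high, 8)

  p$compliant <- FALSE  # second high-risk parameter
  expect_identical(compute_ira(p, impl)$overall, "high")

  expect_identical(compute_ira(make_patient(), impl)$overall, "low")
  expect_error(compute_ira(make_patient(), impl[0, ]), "implant")
})

test_that("IRA never assigns high to history nor moderate to compliance/RM-bone", {
  set.seed(11)
  impl_pool <- list(make_implant(), make_implant(implant_type = "bone_level"),
                    make_implant(fit = "poor_supramucosal"),
                    make_implant(plaque_sites_pi_gt1 = 5, cement_excess = TRUE))
  for (i in 1:50) {
    p <- make_patient(
      bop_percent = runif(1, 0, 100), n_ppd_ge5 = rpois(1, 6),
      bl_age_ratio = runif(1, 0, 2), history = runif(1) < 0.5,
      stage = sample(c("I", "II", "III", "IV"), 1),
      grade = sample(c("A", "B", "C"), 1), compliant = runif(1) < 0.5)
    res <- compute_ira(p, impl_pool[[sample(4, 1)]])
    expect_false(res$per_parameter[["history"]] == "high")
    expect_false(res$per_parameter[["compliance"]] == "moderate")
    expect_false(res$per_parameter[["rm_bone"]] == "moderate")
  }
})

test_that("case definition is the strict conjunction at the published thresholds", {
  expect_true(classify_peri_implantitis(6, TRUE, 3.0))
  expect_false(classify_peri_implantitis(7, FALSE, 5.0))
  expect_false(classify_peri_implantitis(5, TRUE, 5.0))
  expect_false(classify_peri_implantitis(6, TRUE, 2.9))
  expect_error(classify_peri_implantitis(NA, TRUE, 3), "present")
  expect_error(classify_peri_implantitis(-1, TRUE, 3), "non-negative")
})

test_that("patient-level classification is the OR over the patient's implants", {
  im <- rbind(make_implant("P1", "I1", max_ppd_mm = 3),
              make_implant("P1", "I2", max_ppd_mm = 7,
                           bop_or_suppuration = TRUE, bli_mm = 4),
              make_implant("P2", "I1", max_ppd_mm = 7, bli_mm = 4))
  ev <- classify_patients(im)
  expect_true(ev[["P1"]])
  expect_false(ev[["P2"]])  # deep pocket but no bleeding/suppuration
})

test_that("scoring-implant selection ranks RM-bone, then prosthesis, then id", {
  one <- make_implant("P1", "I1")
  expect_identical(select_scoring_implant(make_patient(), one)$implant_id, "I1")

  mixed <- rbind(make_implant("P1", "I1"),
                 make_implant("P1", "I2", implant_type = "bone_level"))
  expect_identical(select_scoring_implant(make_patient(), mixed)$implant_id, "I2")

  pros <- rbind(make_implant("P1", "I1", fit = "poor_supramucosal"),
                make_implant("P1", "I2"))
  expect_identical(select_scoring_implant(make_patient(), pros)$implant_id, "I1")

  ties <- rbind(make_implant("P1", "I2"), make_implant("P1", "I1"))
  expect_identical(select_scoring_implant(make_patient(), ties)$implant_id, "I1")
})

test_that("vectorized cohort scoring matches the per-patient scorers", {
  coh <- generate_cohort(cohort_config(n_patients = 40, seed = 3))
  scored <- score_cohort(coh$patients, coh$implants)
  for (i in c(1, 7, 20, 40)) {
    p <- as.list(coh$patients[i, ])
    impl <- coh$implants[coh$implants$patient_id == p$patient_id, ]
    expect_identical(scored$pra_category[i], compute_pra(p)$overall)
    expect_identical(scored$ira_category[i], compute_ira(p, impl)$overall)
  }
  expect_true(all(paste0("pra_", rule_table("PRA")$parameters) %in% names(scored)))
  expect_true(all(paste0("ira_", rule_table("IRA")$parameters) %in% names(scored)))
})
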