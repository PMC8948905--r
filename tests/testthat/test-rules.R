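test_that("numeric thresholds match the published rule tables, bounds closed", {
  cases <- list(
    # name, value, kind, expected
    list("BOP%", 30, "PRA", "high"),
    list("BOP%", 0, "PRA", "low"),
    list("BOP%", 9, "PRA", "low"),
    list("BOP%", 9.5, "PRA", "moderate"),   # between printed integer bounds
    list("BOP%", 25, "PRA", "moderate"),    # "10 to 25%" inclusive
    list("n_ppd_ge5", 7, "IRA", "high"),    # ">6" under IRA
    list("n_ppd_ge5", 7, "PRA", "moderate"),# "5 to 8" under PRA
    list("n_ppd_ge5", 8, "PRA", "moderate"),
    list("n_ppd_ge5", 9, "PRA", "high"),
    list("n_ppd_ge5", 2, "IRA", "low"),
    list("BL/age", 0.5, "IRA", "low"),      # "0 to 0.5" inclusive
    list("BL/age", 0.5, "PRA", "low"),
    list("BL/age", 1.01, "PRA", "high"),
    list("tooth_loss", 4, "PRA", "low"),
    list("tooth_loss", 8, "PRA", "moderate"),
    list("tooth_loss", 9, "PRA", "high")
  )
  for (cs in cases) {
    expect_identical(categorize_parameter(cs[[1]], cs[[2]], cs[[3]]), cs[[4]],
                     label = sprintf("%s=%s (%s)", cs[[1]], cs[[2]], cs[[3]]))
  }
})

test_that("categorical parameters map as defined", {
  expect_identical(categorize_parameter("smoking", "non_smoker", "PRA"), "low")
  expect_identical(categorize_parameter("smoking", "former_smoker", "PRA"), "low")
  expect_identical(categorize_parameter("smoking", "current_smoker", "PRA"), "moderate")
  expect_identical(categorize_parameter("smoking", "heavy_smoker", "PRA"), "high")
  expect_identical(categorize_parameter("systemic_factor", TRUE, "PRA"), "high")
  expect_identical(categorize_parameter("systemic_factor", FALSE, "PRA"), "low")
  expect_identical(categorize_parameter("history", TRUE, "IRA"), "moderate")
  expect_identical(categorize_parameter("history", FALSE, "IRA"), "low")
  expect_identical(categorize_parameter("compliance", TRUE, "IRA"), "low")
  expect_identical(categorize_parameter("compliance", FALSE, "IRA"), "high")
})

test_that("susceptibility staging/grading maps stage I low, grade C / stage IV high", {
  expect_identical(categorize_susceptibility("I", "A"), "low")
  expect_identical(categorize_susceptibility("I", "B"), "low")
  expect_identical(categorize_susceptibility("I", "C"), "low")
  expect_identical(categorize_susceptibility("II", "A"), "moderate")
  expect_identical(categorize_susceptibility("II", "B"), "moderate")
  expect_identical(categorize_susceptibility("II", "C"), "high")
  expect_identical(categorize_susceptibility("III", "B"), "moderate")
  expect_identical(categorize_susceptibility("III", "C"), "high")
  expect_identical(categorize_susceptibility("IV", "A"), "high")
  expect_identical(categorize_susceptibility("IV", "C"), "high")
  expect_identical(categorize_parameter("Periodontitis susceptibility", "III_C", "IRA"),
                   "high")
  expect_error(categorize_susceptibility("V", "A"), "stage")
})

test_that("RM-bone is two-level: implant type decides, measured <1.5 mm escalates", {
  expect_identical(categorize_rm_bone("tissue_level"), "low")
  expect_identical(categorize_rm_bone("tissue_level", NA), "low")
  expect_identical(categorize_rm_bone("tissue_level", 1.2), "high")
  expect_identical(categorize_rm_bone("tissue_level", 2.0), "low")
  expect_identical(categorize_rm_bone("bone_level"), "high")
  expect_identical(categorize_rm_bone("bone_level", 3), "high")
  expect_error(categorize_rm_bone("zygomatic"), "implant_type")
})

test_that("prosthesis/plaque score: high-risk features dominate supramucosal fit", {
  expect_identical(categorize_prosthesis(0), "low")
  expect_identical(categorize_prosthesis(3, "adequate", FALSE), "low")
  expect_identical(categorize_prosthesis(0, "poor_supramucosal"), "moderate")
  expect_identical(categorize_prosthesis(0, "poor_submucosal"), "high")
  expect_identical(categorize_prosthesis(4), "high")
  expect_identical(categorize_prosthesis(0, "adequate", TRUE), "high")
  expect_identical(categorize_prosthesis(5, "poor_supramucosal"), "high")
  expect_error(categorize_prosthesis(7), "0 and 6")
})

test_that("every admissible value maps to exactly one valid category", {
  for (kind in c("PRA", "IRA")) {
    tab <- rule_table(kind)
    grids <- list(bop_percent = seq(0, 100, by = 0.25),
                  n_ppd_ge5 = 0:60,
                  bl_age_ratio = seq(0, 3, by = 0.01))
    if (kind == "PRA") grids$tooth_loss <- 0:40
    for (nm in names(grids)) {
      cats <- categorize_parameter(nm, grids[[nm]], kind)
      expect_equal(length(cats), length(grids[[nm]]))
      expect_true(all(cats %in% risk_levels()),
                  label = sprintf("%s under %s total on its grid", nm, kind))
      # category is non-decreasing in the parameter value
      expect_true(all(diff(match(cats, risk_levels())) >= 0))
    }
  }
  for (s in c("I", "II", "III", "IV")) for (g in c("A", "B", "C")) {
    expect_true(categorize_susceptibility(s, g) %in% risk_levels())
  }
})

test_that("unknown parameters and out-of-domain values are rejected", {
  expect_error(categorize_parameter("tooth_loss", 3, "IRA"), "IRA")
  expect_error(categorize_parameter("sugar_intake", 3, "PRA"), "PRA")
  expect_error(categorize_parameter("BOP%", 130, "PRA"), "domain")
  expect_error(categorize_parameter("BOP%", -1, "IRA"), "domain")
  expect_error(categorize_parameter("n_ppd_ge5", -2, "PRA"), "domain")
  expect_error(categorize_parameter("smoking", "vaper", "PRA"), "smoking")
})

test_that("rule tables carry six PRA and eight IRA parameters", {
  expect_length(rule_table("PRA")$parameters, 6)
  expect_length(rule_table("IRA")$parameters, 8)
})
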