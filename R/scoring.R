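#' Aggregate per-parameter categories into an overall risk level
#'
#' A patient is high risk with at least two parameters in the high-risk
#' category; low risk with no high-risk parameter and at most one moderate;
#' moderate otherwise. The "otherwise" branch covers both at least two
#' moderates with at most one high, and the single-high-all-others-low
#' combination, which the IRA rules place in the moderate class and which
#' is applied to both scores.
#'
#' @param categories character vector of per-parameter risk categories
#'   (`"low"`, `"moderate"`, `"high"`).
#' @return A single overall category label.
#' @examples
#' aggregate_risk(rep("low", 6))                     # "low"
#' aggregate_risk(c("high", "high", rep("low", 4)))  # "high"
#' @export
aggregate_risk <- function(categories) {
  if (length(categories) == 0) stop("empty category list")
  categories <- as.character(risk_factor(categories))
  if (anyNA(categories)) stop("missing category")
  n_high <- sum(categories == "high")
  n_mod <- sum(categories == "moderate")
  if (n_high >= 2) "high"
  else if (n_high == 0 && n_mod <= 1) "low"
  else "moderate"
}

score_result <- function(score_kind, per_parameter) {
  per_parameter <- vapply(per_parameter, as.character, "")
  structure(list(
    score_kind = score_kind,
    per_parameter = per_parameter,
    overall = aggregate_risk(per_parameter),
    n_low = sum(per_parameter == "low"),
    n_moderate = sum(per_parameter == "moderate"),
    n_high = sum(per_parameter == "high")
  ), class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("<%s score> overall: %s (%d low / %d moderate / %d high)\n",
              x$score_kind, toupper(x$overall), x$n_low, x$n_moderate, x$n_high))
  for (p in names(x$per_parameter)) {
    cat(sprintf("  %-18s %s\n", p, x$per_parameter[[p]]))
  }
  invisible(x)
}

require_fields <- function(patient, fields, what) {
  for (f in fields) {
    v <- patient[[f]]
    if (is.null(v) || length(v) == 0 || all(is.na(v))) {
      stop(sprintf("%s: missing required field '%s'", what, f))
    }
  }
}

#' Compute the Periodontal Risk Assessment (PRA)
#'
#' Six parameters: full-mouth bleeding on probing percentage, number of
#' residual sites with probing depth >= 5 mm, radiographic bone loss of the
#' worst site divided by age (BL/age), teeth lost for periodontal reasons,
#' systemic/genetic status (diabetes or genetic factor), and smoking status.
#'
#' @param patient a named list or one-row data.frame with fields
#'   `bop_percent`, `n_ppd_ge5`, `bl_age_ratio`, `tooth_loss`,
#'   `systemic_factor` (logical) and `smoking` (status string).
#' @return A `score_result`: per-parameter categories, category counts and
#'   the aggregated overall risk.
#' @export
compute_pra <- function(patient) {
  if (is.data.frame(patient)) patient <- as.list(patient)
  require_fields(patient, .pra_params, "compute_pra")
  per <- list(
    bop_percent = categorize_parameter("bop_percent", patient$bop_percent, "PRA"),
    n_ppd_ge5 = categorize_parameter("n_ppd_ge5", patient$n_ppd_ge5, "PRA"),
    bl_age_ratio = categorize_parameter("bl_age_ratio", patient$bl_age_ratio, "PRA"),
    tooth_loss = categorize_parameter("tooth_loss", patient$tooth_loss, "PRA"),
    systemic_factor = categorize_parameter("systemic_factor", patient$systemic_factor, "PRA"),
    smoking = categorize_parameter("smoking", patient$smoking, "PRA")
  )
  score_result("PRA", per)
}

#' Compute the Implant Risk Assessment (IRA)
#'
#' Eight parameters: the three shared periodontal parameters (BOP%, sites
#' with probing depth >= 5 mm under stricter cut-offs, BL/age), history of
#' stage II-IV periodontitis (moderate at most), periodontitis
#' susceptibility from current staging/grading, compliance with maintenance
#' (two levels), the restoration-margin-to-bone parameter by implant type,
#' and the prosthesis/plaque score. For patients with several implants the
#' implant-level parameters come from the highest-risk implant
#' ([select_scoring_implant()]).
#'
#' @param patient a named list or one-row data.frame with fields
#'   `bop_percent`, `n_ppd_ge5`, `bl_age_ratio`, `history` (logical),
#'   `stage`, `grade`, `compliant` (logical), and either an `implants`
#'   element or the `implants` argument.
#' @param implants optional data.frame of the patient's implants (schema of
#'   [read_cohort()]); defaults to `patient$implants`.
#' @return A `score_result`.
#' @export
compute_ira <- function(patient, implants = NULL) {
  if (is.data.frame(patient)) patient <- as.list(patient)
  if (is.null(implants)) implants <- patient$implants
  if (is.null(implants) || nrow(implants) == 0) {
    stop("compute_ira: patient has no implant records")
  }
  require_fields(patient, c("bop_percent", "n_ppd_ge5", "bl_age_ratio",
                            "history", "stage", "grade", "compliant"),
                 "compute_ira")
  sel <- select_scoring_implant(patient, implants)
  per <- list(
    bop_percent = categorize_parameter("bop_percent", patient$bop_percent, "IRA"),
    n_ppd_ge5 = categorize_parameter("n_ppd_ge5", patient$n_ppd_ge5, "IRA"),
    bl_age_ratio = categorize_parameter("bl_age_ratio", patient$bl_age_ratio, "IRA"),
    history = categorize_parameter("history", patient$history, "IRA"),
    susceptibility = categorize_susceptibility(patient$stage, patient$grade),
    compliance = categorize_parameter("compliance", patient$compliant, "IRA"),
    rm_bone = categorize_rm_bone(sel$implant_type, sel$rm_bone_mm),
    prosthesis_plaque = categorize_prosthesis(sel$plaque_sites_pi_gt1,
                                              sel$fit, sel$cement_excess)
  )
  score_result("IRA", per)
}

#' Select the implant used for patient-level IRA scoring
#'
#' With multiple implants, the implant with the highest risk level is used:
#' implants are ranked by the restoration-margin-to-bone category first,
#' then by the prosthesis/plaque category, both under the
#' `low < moderate < high` order; ties break deterministically on the
#' smallest `implant_id`.
#'
#' @inheritParams compute_ira
#' @return The selected one-row implant data.frame.
#' @export
select_scoring_implant <- function(patient, implants = NULL) {
  if (is.null(implants)) {
    implants <- if (is.data.frame(patient)) attr(patient, "implants") else patient$implants
  }
  if (is.null(implants) || nrow(implants) == 0) stop("no implants to select from")
  rm_cat <- risk_rank(categorize_rm_bone(implants$implant_type, implants$rm_bone_mm))
  pros_cat <- risk_rank(categorize_prosthesis(implants$plaque_sites_pi_gt1,
                                              implants$fit, implants$cement_excess))
  ord <- order(-rm_cat, -pros_cat, as.character(implants$implant_id))
  implants[ord[1], , drop = FALSE]
}

#' Peri-implantitis case definition
#'
#' An implant is a peri-implantitis case when probing depth is at least
#' 6 mm with bleeding on probing or suppuration, and the radiographic bone
#' level is at least 3 mm apical to the coronal reference. A patient is a
#' case when any implant is.
#'
#' @param max_ppd_mm deepest probing depth at the implant, mm.
#' @param bop_or_suppuration logical.
#' @param bli_mm radiographic implant bone level, mm.
#' @return Logical vector.
#' @examples
#' classify_peri_implantitis(6, TRUE, 3)   # TRUE (boundary case)
#' classify_peri_implantitis(5, TRUE, 5)   # FALSE
#' @export
classify_peri_implantitis <- function(max_ppd_mm, bop_or_suppuration, bli_mm) {
  max_ppd_mm <- as.numeric(max_ppd_mm); bli_mm <- as.numeric(bli_mm)
  if (any(is.na(max_ppd_mm)) || any(is.na(bli_mm))) {
    stop("max_ppd_mm and bli_mm must be present")
  }
  if (any(max_ppd_mm < 0) || any(bli_mm < 0)) stop("depths must be non-negative")
  max_ppd_mm >= 6 & as.logical(bop_or_suppuration) & bli_mm >= 3
}

#' Patient-level event classification over an implant table
#'
#' @param implants implant data.frame with `patient_id`, `max_ppd_mm`,
#'   `bop_or_suppuration`, `bli_mm`.
#' @return Named logical vector keyed by patient id: TRUE when any implant
#'   meets the case definition.
#' @export
classify_patients <- function(implants) {
  case <- classify_peri_implantitis(implants$max_ppd_mm,
                                    implants$bop_or_suppuration,
                                    implants$bli_mm)
  tapply(case, implants$patient_id, any)
}

#' Score a whole cohort with PRA and IRA
#'
#' Vectorized scoring of a patient table plus its implant table. Appends
#' one category column per parameter (`pra_*`, `ira_*`) and the two overall
#' columns `pra_category` and `ira_category`.
#'
#' @param patients patient data.frame (schema of [read_cohort()]).
#' @param implants implant data.frame.
#' @param kinds which scores to compute, subset of `c("PRA", "IRA")`.
#' @return The patient data.frame with category columns appended.
#' @export
score_cohort <- function(patients, implants = NULL, kinds = c("PRA", "IRA")) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  out <- patients
  if ("PRA" %in% kinds) {
    out$pra_bop_percent <- categorize_parameter("bop_percent", patients$bop_percent, "PRA")
    out$pra_n_ppd_ge5 <- categorize_parameter("n_ppd_ge5", patients$n_ppd_ge5, "PRA")
    out$pra_bl_age_ratio <- categorize_parameter("bl_age_ratio", patients$bl_age_ratio, "PRA")
    out$pra_tooth_loss <- categorize_parameter("tooth_loss", patients$tooth_loss, "PRA")
    out$pra_systemic_factor <- categorize_parameter("systemic_factor", patients$systemic_factor, "PRA")
    out$pra_smoking <- categorize_parameter("smoking", patients$smoking, "PRA")
    cols <- paste0("pra_", .pra_params)
    out$pra_category <- apply(as.matrix(out[cols]), 1L, aggregate_risk)
  }
  if ("IRA" %in% kinds) {
    if (is.null(implants)) stop("IRA scoring needs the implant table")
    sel <- selected_implants(implants)
    idx <- match(as.character(patients$patient_id), as.character(sel$patient_id))
    if (anyNA(idx)) {
      stop("patients without implant records: ",
           paste(utils::head(patients$patient_id[is.na(idx)], 5), collapse = ", "))
    }
    sel <- sel[idx, , drop = FALSE]
    out$ira_bop_percent <- categorize_parameter("bop_percent", patients$bop_percent, "IRA")
    out$ira_n_ppd_ge5 <- categorize_parameter("n_ppd_ge5", patients$n_ppd_ge5, "IRA")
    out$ira_bl_age_ratio <- categorize_parameter("bl_age_ratio", patients$bl_age_ratio, "IRA")
    out$ira_history <- categorize_parameter("history", patients$history, "IRA")
    out$ira_susceptibility <- categorize_susceptibility(patients$stage, patients$grade)
    out$ira_compliance <- categorize_parameter("compliance", patients$compliant, "IRA")
    out$ira_rm_bone <- categorize_rm_bone(sel$implant_type, sel$rm_bone_mm)
    out$ira_prosthesis_plaque <- categorize_prosthesis(sel$plaque_sites_pi_gt1,
                                                       sel$fit, sel$cement_excess)
    cols <- paste0("ira_", .ira_params)
    out$ira_category <- apply(as.matrix(out[cols]), 1L, aggregate_risk)
  }
  out
}

# highest-risk implant per patient (vectorized select_scoring_implant)
selected_implants <- function(implants) {
  rm_cat <- risk_rank(categorize_rm_bone(implants$implant_type, implants$rm_bone_mm))
  pros_cat <- risk_rank(categorize_prosthesis(implants$plaque_sites_pi_gt1,
                                              implants$fit, implants$cement_excess))
  ord <- order(as.character(implants$patient_id), -rm_cat, -pros_cat,
               as.character(implants$implant_id))
  sorted <- implants[ord, , drop = FALSE]
  sorted[!duplicated(sorted$patient_id), , drop = FALSE]
}
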