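# External CSV schema <-> internal canonical codes
.smoking_codes <- c(non = "non_smoker", former = "former_smoker",
                    current = "current_smoker", heavy = "heavy_smoker")
.type_codes <- c(tissue = "tissue_level", bone = "bone_level")
.fit_codes <- c(adequate = "adequate", supra = "poor_supramucosal",
                sub = "poor_submucosal")

.patient_cols <- c("patient_id", "age_years", "bop_percent", "n_ppd_ge5",
                   "bl_age_ratio", "tooth_loss", "systemic_factor", "smoking",
                   "history", "stage", "grade", "compliant",
                   "followup_years", "event")
.implant_cols <- c("patient_id", "implant_id", "implant_type", "max_ppd_mm",
                   "bop_or_sup", "bli_mm", "rm_bone_mm",
                   "plaque_sites_pi_gt1", "fit", "cement_excess")

decode <- function(x, codes, what) {
  x <- as.character(x)
  out <- ifelse(x %in% names(codes), unname(codes[x]),
                ifelse(x %in% codes, x, NA))
  if (anyNA(out[!is.na(x)])) {
    bad <- unique(x[is.na(out) & !is.na(x)])
    stop(sprintf("unrecognized %s code(s): %s", what, paste(bad, collapse = ", ")))
  }
  out
}

# per-row domain checks; returns character vector of messages (empty = valid)
validate_patient_rows <- function(p) {
  msg <- rep("", nrow(p))
  add <- function(cond, text) {
    cond[is.na(cond)] <- TRUE
    msg[cond] <<- paste(msg[cond], text, sep = "; ")
  }
  add(p$bop_percent < 0 | p$bop_percent > 100, "bop_percent outside [0,100]")
  add(p$n_ppd_ge5 < 0, "negative n_ppd_ge5")
  add(p$bl_age_ratio < 0, "negative bl_age_ratio")
  add(p$tooth_loss < 0, "negative tooth_loss")
  add(p$age_years <= 0, "non-positive age_years")
  add(p$followup_years < 0, "negative followup_years")
  add(!p$stage %in% c("I", "II", "III", "IV"), "invalid stage")
  add(!p$grade %in% c("A", "B", "C"), "invalid grade")
  add(!p$smoking %in% .smoking_levels, "invalid smoking status")
  if (!is.null(p$cigarettes_per_day)) {
    add(p$smoking == "heavy_smoker" & !is.na(p$cigarettes_per_day) &
          p$cigarettes_per_day <= 19,
        "heavy smoker requires > 19 cigarettes/day")
  }
  sub("^; ", "", msg)
}

validate_implant_rows <- function(im) {
  msg <- rep("", nrow(im))
  add <- function(cond, text) {
    cond[is.na(cond)] <- TRUE
    msg[cond] <<- paste(msg[cond], text, sep = "; ")
  }
  add(im$max_ppd_mm < 0, "negative max_ppd_mm")
  add(im$bli_mm < 0, "negative bli_mm")
  add(!im$implant_type %in% c("tissue_level", "bone_level"), "invalid implant_type")
  add(!im$fit %in% .fit_levels, "invalid fit")
  add(im$plaque_sites_pi_gt1 < 0 | im$plaque_sites_pi_gt1 > 6,
      "plaque_sites_pi_gt1 outside 0..6")
  # rm_bone_mm may be blank (unmeasured)
  msg[!is.na(im$rm_bone_mm) & im$rm_bone_mm < 0] <-
    paste(msg[!is.na(im$rm_bone_mm) & im$rm_bone_mm < 0], "negative rm_bone_mm", sep = "; ")
  sub("^; ", "", msg)
}

#' Read a patient + implant cohort from CSV
#'
#' Reads the two-table cohort schema (one row per patient, one row per
#' implant), decodes the categorical short codes (`smoking`
#' non/former/current/heavy, `implant_type` tissue/bone, `fit`
#' adequate/supra/sub), enforces the domain invariants and drops invalid
#' rows with one warning per row naming the identifier. A missing
#' mandatory column is fatal; unknown extra columns are kept with a
#' warning.
#'
#' @param patient_csv,implant_csv file paths.
#' @return list of class `peri_cohort` with data.frames `patients` and
#'   `implants`; rejected-row messages are in `attr(, "rejected")`.
#' @export
read_cohort <- function(patient_csv, implant_csv) {
  p <- utils::read.csv(patient_csv, stringsAsFactors = FALSE)
  im <- utils::read.csv(implant_csv, stringsAsFactors = FALSE)
  miss_p <- setdiff(.patient_cols, names(p))
  if (length(miss_p)) stop("patient CSV missing column(s): ",
                           paste(miss_p, collapse = ", "))
  miss_i <- setdiff(setdiff(.implant_cols, "bop_or_sup"),
                    union(names(im), "bop_or_suppuration"))
  if (!("bop_or_sup" %in% names(im) || "bop_or_suppuration" %in% names(im))) {
    miss_i <- c(miss_i, "bop_or_sup")
  }
  if (length(miss_i)) stop("implant CSV missing column(s): ",
                           paste(miss_i, collapse = ", "))
  extra <- c(setdiff(names(p), c(.patient_cols, "cigarettes_per_day")),
             setdiff(names(im), c(.implant_cols, "bop_or_suppuration")))
  if (length(extra)) warning("unknown column(s) kept as-is: ",
                             paste(extra, collapse = ", "))

  p$smoking <- decode(p$smoking, .smoking_codes, "smoking")
  for (col in c("systemic_factor", "history", "compliant", "event")) {
    p[[col]] <- as.logical(p[[col]])
  }
  if ("bop_or_sup" %in% names(im)) {
    im$bop_or_suppuration <- as.logical(im$bop_or_sup)
    im$bop_or_sup <- NULL
  } else {
    im$bop_or_suppuration <- as.logical(im$bop_or_suppuration)
  }
  im$implant_type <- decode(im$implant_type, .type_codes, "implant_type")
  im$fit <- decode(im$fit, .fit_codes, "fit")
  im$cement_excess <- as.logical(im$cement_excess)
  im$rm_bone_mm <- suppressWarnings(as.numeric(im$rm_bone_mm))

  rejected <- character(0)
  pm <- validate_patient_rows(p)
  if (any(pm != "")) {
    bad <- which(pm != "")
    for (i in bad) {
      msg <- sprintf("patient %s rejected: %s", p$patient_id[i], pm[i])
      warning(msg, call. = FALSE)
      rejected <- c(rejected, msg)
    }
    p <- p[-bad, , drop = FALSE]
  }
  imsg <- validate_implant_rows(im)
  orphan <- !im$patient_id %in% p$patient_id
  if (any(imsg != "" & !orphan)) {
    bad <- which(imsg != "" & !orphan)
    for (i in bad) {
      msg <- sprintf("implant %s rejected: %s", im$implant_id[i], imsg[i])
      warning(msg, call. = FALSE)
      rejected <- c(rejected, msg)
    }
  }
  im <- im[imsg == "" & !orphan, , drop = FALSE]
  structure(list(patients = p, implants = im),
            class = "peri_cohort", rejected = rejected)
}

#' Write a cohort to the two-table CSV schema
#'
#' Inverse of [read_cohort()]: encodes the categorical columns back to
#' their short codes and writes `patients.csv` and `implants.csv`.
#'
#' @param cohort a `peri_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param dir output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- cohort$patients
  p$smoking <- names(.smoking_codes)[match(p$smoking, .smoking_codes)]
  p$systemic_factor <- as.integer(p$systemic_factor)
  p$history <- as.integer(p$history)
  p$compliant <- as.integer(p$compliant)
  p$event <- as.integer(p$event)
  im <- cohort$implants
  im$implant_type <- names(.type_codes)[match(im$implant_type, .type_codes)]
  im$fit <- names(.fit_codes)[match(im$fit, .fit_codes)]
  im$bop_or_sup <- as.integer(im$bop_or_suppuration)
  im$bop_or_suppuration <- NULL
  im$cement_excess <- as.integer(im$cement_excess)
  pf <- file.path(dir, "patients.csv"); imf <- file.path(dir, "implants.csv")
  utils::write.csv(p, pf, row.names = FALSE, na = "")
  utils::write.csv(im[, .implant_cols], imf, row.names = FALSE, na = "")
  invisible(c(patients = pf, implants = imf))
}

#' Risk-category distribution of a scored cohort
#'
#' @param scored data.frame from [score_cohort()].
#' @param kind `"PRA"` or `"IRA"`.
#' @return data.frame with `category`, `n`, `pct` (percentage, 2 dp).
#' @export
risk_distribution <- function(scored, kind = c("PRA", "IRA")) {
  kind <- match.arg(kind)
  col <- if (kind == "PRA") "pra_category" else "ira_category"
  cat_ <- factor(scored[[col]], levels = risk_levels())
  tab <- table(cat_)
  data.frame(category = names(tab), n = as.integer(tab),
             pct = round(100 * as.integer(tab) / nrow(scored), 2))
}

#' Diagnostic metric rows from published summary counts
#'
#' Reconstructs the 2x2 table from a validation's summary numbers
#' ([reconstruct_confusion()]) and returns it with its metrics: the
#' consistency check applied to a published report when patient-level
#' data are not available.
#'
#' @param n cohort size.
#' @param n_events events observed.
#' @param n_positive high-risk (test-positive) patients.
#' @param sensitivity printed sensitivity.
#' @return list with `confusion` and `metrics`.
#' @export
metrics_from_summary <- function(n, n_events, n_positive, sensitivity) {
  cm <- reconstruct_confusion(n, n_events, n_positive, sensitivity)
  list(confusion = cm, metrics = confusion_metrics(cm))
}

score_stats <- function(scored, kind) {
  col <- if (kind == "PRA") "pra_category" else "ira_category"
  cat_ <- scored[[col]]
  high <- cat_ == "high"
  time <- scored$followup_years
  event <- scored$event
  grp <- factor(cat_, levels = risk_levels())
  grp <- droplevels(grp)
  res <- list(distribution = risk_distribution(scored, kind))
  res$km <- try_stat(km_estimate(time, event, as.character(grp)))
  res$logrank <- if (nlevels(grp) >= 2) {
    try_stat(logrank_test(time, event, as.character(grp)))
  } else list(error = "fewer than two risk groups present")
  res$cox_high_vs_lowmod <- try_stat(cox_fit(time, event, high))
  res$roc <- try_stat(auc_ordinal(cat_, event))
  cm <- confusion_matrix(tp = sum(high & event), fp = sum(high & !event),
                         fn = sum(!high & event), tn = sum(!high & !event))
  res$confusion <- cm
  res$metrics <- suppressWarnings(confusion_metrics(cm))
  res
}

try_stat <- function(expr) {
  tryCatch(expr, error = function(e) list(error = conditionMessage(e)))
}

#' Run the full scoring and validation pipeline
#'
#' Reads (or simulates) a cohort, scores every patient with PRA and IRA,
#' takes the recorded peri-implantitis event and follow-up time (the
#' patient is the statistical unit throughout), and validates each score:
#' risk distribution, Kaplan-Meier curves per category, log-rank test
#' across categories, Cox hazard ratio for high versus the pooled
#' low/moderate group, ordinal ROC/AUC, the 2x2 table treating high risk
#' as test-positive with its metrics, and Cohen's kappa between the two
#' scores' high-risk calls.
#'
#' @param patient_csv,implant_csv input CSVs (schema of [read_cohort()]);
#'   mutually exclusive with `sim_config`.
#' @param sim_config a [cohort_config()] to simulate instead of reading.
#' @param out_dir optional directory; writes `scored.csv` and
#'   `report.json` when given.
#' @return list of class `validation_report`.
#' @export
run_pipeline <- function(patient_csv = NULL, implant_csv = NULL,
                         sim_config = NULL, out_dir = NULL) {
  from_files <- !is.null(patient_csv) || !is.null(implant_csv)
  if (from_files == !is.null(sim_config)) {
    stop("provide either the two CSV paths or a simulation config, not both")
  }
  cohort <- if (from_files) {
    if (is.null(patient_csv) || is.null(implant_csv)) {
      stop("both patient_csv and implant_csv are required")
    }
    read_cohort(patient_csv, implant_csv)
  } else {
    generate_cohort(sim_config)
  }
  scored <- score_cohort(cohort$patients, cohort$implants)
  n <- nrow(scored)
  n_events <- sum(scored$event)
  report <- list(
    n = n,
    n_events = n_events,
    incidence_pct = round(100 * n_events / n, 2),
    followup_years = list(mean = round(mean(scored$followup_years), 2),
                          range = range(scored$followup_years))
  )
  if (n_events == 0) {
    report$note <- "no events: survival and ROC sections unavailable"
    report$pra <- list(distribution = risk_distribution(scored, "PRA"))
    report$ira <- list(distribution = risk_distribution(scored, "IRA"))
  } else {
    report$pra <- score_stats(scored, "PRA")
    report$ira <- score_stats(scored, "IRA")
  }
  report$kappa_high_risk <- cohens_kappa(scored$pra_category == "high",
                                         scored$ira_category == "high")
  report <- structure(report, class = "validation_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(scored, file.path(out_dir, "scored.csv"), row.names = FALSE)
    write_report(report, file.path(out_dir, "report.json"))
  }
  attr(report, "scored") <- scored
  report
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> n = %d patients, %d events (%.2f%%)\n",
              x$n, x$n_events, x$incidence_pct))
  for (k in c("pra", "ira")) {
    s <- x[[k]]
    if (is.null(s$cox_high_vs_lowmod)) next
    cat(sprintf("  %s: high-risk %d/%d", toupper(k),
                s$distribution$n[s$distribution$category == "high"], x$n))
    if (is.null(s$cox_high_vs_lowmod$error)) {
      cat(sprintf("; HR %.2f (%.2f-%.2f)", s$cox_high_vs_lowmod$hr,
                  s$cox_high_vs_lowmod$ci_low, s$cox_high_vs_lowmod$ci_high))
    }
    if (is.null(s$roc$error)) cat(sprintf("; AUC %.3f", s$roc$auc))
    cat("\n")
  }
  cat(sprintf("  kappa (high-risk PRA vs IRA): %.3f\n", x$kappa_high_risk))
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' @param report a `validation_report` (or any list).
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass_deep(report), path, auto_unbox = TRUE,
                       digits = 10, na = "null", pretty = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}
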