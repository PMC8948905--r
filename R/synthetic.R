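#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the marginal composition of the study population at
#' score-calculation time: category probabilities are the published counts
#' over n = 73 (e.g. 61/73 compliant, 70/73 tissue-level-only, 65/73 with a
#' history of stage II-IV periodontitis), continuous parameters are
#' truncated normals matched to the published mean/SD (BOP% 24.29/21.25,
#' BL/age 0.59/0.23, age 60.08/7.96) and counts are negative binomials
#' matched to mean/SD (tooth loss 8.44/4.24, sites with PPD >= 5 mm
#' 7.85/11.41). Follow-up is administratively censored uniformly on a
#' 3 to 14 year window; events arrive with a constant annual hazard per
#' overall risk category (defaults 0.005 / 0.010 / 0.043 for
#' low / moderate / high).
#'
#' @param n_patients cohort size.
#' @param seed integer seed; the generator is deterministic given the
#'   config (the global RNG state is left untouched).
#' @param marginals named list of distribution specs; entries replace the
#'   defaults described above. Numeric specs: `list(dist = "truncnorm",
#'   mean=, sd=, lower=, upper=)` or `list(dist = "nbinom", mu=, sd=)`.
#'   Categorical/binary specs: a named probability vector summing to 1, or
#'   a single probability for binary fields.
#' @param hazard_by_category named annual event rates (per patient-year)
#'   for the three overall categories.
#' @param followup_window_years length-2 vector, censoring window in years
#'   (minimum 3: scores are calculated at least 3 years before the final
#'   examination).
#' @param implants_per_patient `list(min=, lambda=)`: count is
#'   `min + Poisson(lambda)`.
#' @param score_kind which score's overall category drives the hazard.
#' @param event_shape Weibull shape for event times; 1 (default) is the
#'   constant-hazard exponential model.
#' @param latent_correlation optional correlation matrix (Gaussian copula
#'   on the latent uniforms) over a subset of
#'   `c("age","bop_percent","n_ppd_ge5","bl_age_ratio","tooth_loss",
#'   "systemic_factor","smoking","history","susceptibility","compliant",
#'   "tissue_only","prosthesis")`; parameters are independent by default.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 73,
                          seed = 1L,
                          marginals = list(),
                          hazard_by_category = c(low = 0.005, moderate = 0.010,
                                                 high = 0.043),
                          followup_window_years = c(3, 14),
                          implants_per_patient = list(min = 1, lambda = 2.18),
                          score_kind = c("PRA", "IRA"),
                          event_shape = 1,
                          latent_correlation = NULL) {
  score_kind <- match.arg(score_kind)
  defaults <- list(
    age = list(dist = "truncnorm", mean = 60.08, sd = 7.96, lower = 30, upper = 95),
    bop_percent = list(dist = "truncnorm", mean = 24.29, sd = 21.25, lower = 0, upper = 100),
    n_ppd_ge5 = list(dist = "nbinom", mu = 7.85, sd = 11.41),
    bl_age_ratio = list(dist = "truncnorm", mean = 0.59, sd = 0.23, lower = 0, upper = Inf),
    tooth_loss = list(dist = "nbinom", mu = 8.44, sd = 4.24),
    systemic_factor = 3 / 73,
    smoking = c(non_smoker = 36, former_smoker = 20,
                current_smoker = 16, heavy_smoker = 1) / 73,
    history = 65 / 73,
    susceptibility = c(II_AB = 13, III_AB = 50, III_C = 6, IV = 4) / 73,
    compliant = 61 / 73,
    tissue_only = 70 / 73,
    prosthesis = c(low = 48, supra = 22, high_plaque = 3) / 73
  )
  unknown <- setdiff(names(marginals), names(defaults))
  if (length(unknown)) stop("unknown marginal(s): ", paste(unknown, collapse = ", "))
  defaults[names(marginals)] <- marginals
  for (nm in names(defaults)) {
    m <- defaults[[nm]]
    if (is.numeric(m) && !is.list(m)) {
      if (any(m < 0)) stop("negative probability in marginal '", nm, "'")
      if (length(m) > 1 && abs(sum(m) - 1) > 1e-8) {
        stop("probabilities of marginal '", nm, "' must sum to 1")
      }
      if (length(m) == 1 && m > 1) stop("probability of '", nm, "' exceeds 1")
    }
  }
  if (any(hazard_by_category < 0)) stop("hazard rates must be >= 0")
  if (length(followup_window_years) != 2 ||
      followup_window_years[1] < 3 ||
      followup_window_years[2] < followup_window_years[1]) {
    stop("followup_window_years must be (min, max) with min >= 3")
  }
  if (!all(risk_levels() %in% names(hazard_by_category))) {
    stop("hazard_by_category needs rates for low, moderate and high")
  }
  structure(list(n_patients = n_patients, seed = as.integer(seed),
                 marginals = defaults, hazard_by_category = hazard_by_category,
                 followup_window_years = followup_window_years,
                 implants_per_patient = implants_per_patient,
                 score_kind = score_kind, event_shape = event_shape,
                 latent_correlation = latent_correlation),
            class = "cohort_config")
}

# inverse-CDF sampling from one marginal given uniforms (copula-friendly)
sample_marginal <- function(spec, u) {
  if (is.list(spec)) {
    switch(spec$dist,
      truncnorm = {
        plo <- stats::pnorm(spec$lower, spec$mean, spec$sd)
        phi <- stats::pnorm(spec$upper, spec$mean, spec$sd)
        stats::qnorm(plo + u * (phi - plo), spec$mean, spec$sd)
      },
      nbinom = {
        v <- spec$sd^2
        if (v <= spec$mu) stop("nbinom marginal needs sd^2 > mu")
        size <- spec$mu^2 / (v - spec$mu)
        stats::qnbinom(u, size = size, mu = spec$mu)
      },
      stop("unknown distribution: ", spec$dist)
    )
  } else if (length(spec) == 1) {
    u < spec                                   # binary
  } else {
    names(spec)[findInterval(u, cumsum(spec), left.open = TRUE) + 1L]
  }
}

#' Sample follow-up time and event status for scored patients
#'
#' Event times are Weibull (exponential by default) with the annual rate
#' of the patient's overall risk category; administrative censoring is
#' uniform on the follow-up window. The event indicator is 1 when the
#' event time falls inside the observed window, and follow-up is the
#' minimum of the two times. Uses the current RNG state; vectorized over
#' patients.
#'
#' @param categories character vector of overall risk categories.
#' @param config a [cohort_config()].
#' @return data.frame with `followup_years` and `event` (logical).
#' @export
sample_event_times <- function(categories, config = cohort_config()) {
  rate <- unname(config$hazard_by_category[as.character(risk_factor(categories))])
  n <- length(rate)
  u <- stats::runif(n)
  # inverse-CDF Weibull with scale 1/rate; rate 0 => never
  t_event <- ifelse(rate > 0, (-log(u))^(1 / config$event_shape) / rate, Inf)
  t_cens <- stats::runif(n, config$followup_window_years[1],
                         config$followup_window_years[2])
  data.frame(followup_years = pmin(t_event, t_cens), event = t_event <= t_cens)
}

#' Generate a synthetic patient + implant cohort
#'
#' Draws patient-level score parameters from the configured marginals
#' (independently unless a copula correlation is supplied), builds an
#' implant table (implant types, prosthesis/plaque state), scores every
#' patient, samples follow-up and peri-implantitis events with
#' category-dependent hazards, and finally fills the implants'
#' follow-up clinical fields (probing depth, bleeding, bone level) so that
#' the patient-level case definition agrees with the sampled event flag.
#'
#' @param config a [cohort_config()].
#' @return A list of class `peri_cohort` with data.frames `patients` and
#'   `implants` in the CSV schema of [read_cohort()].
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 50, seed = 7))
#' nrow(coh$patients)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_patients
  m <- config$marginals
  latent <- c("age", "bop_percent", "n_ppd_ge5", "bl_age_ratio", "tooth_loss",
              "systemic_factor", "smoking", "history", "susceptibility",
              "compliant", "tissue_only", "prosthesis")
  U <- matrix(stats::runif(n * length(latent)), n, length(latent),
              dimnames = list(NULL, latent))
  R <- config$latent_correlation
  if (!is.null(R)) {
    vars <- colnames(R)
    if (is.null(vars) || !all(vars %in% latent)) {
      stop("latent_correlation must be a named correlation matrix over known parameters")
    }
    Z <- matrix(stats::rnorm(n * length(vars)), n, length(vars)) %*% chol(R)
    U[, vars] <- stats::pnorm(Z)
  }

  smoking <- sample_marginal(m$smoking, U[, "smoking"])
  cpd <- integer(n)
  cpd[smoking == "current_smoker"] <- sample(1:19, sum(smoking == "current_smoker"), TRUE)
  cpd[smoking == "heavy_smoker"] <- 20L + stats::rpois(sum(smoking == "heavy_smoker"), 6)
  susc <- sample_marginal(m$susceptibility, U[, "susceptibility"])
  stage <- c(II_AB = "II", III_AB = "III", III_C = "III", IV = "IV")[susc]
  grade <- ifelse(susc %in% c("II_AB", "III_AB"),
                  sample(c("A", "B"), n, TRUE),
                  ifelse(susc == "III_C", "C", sample(c("A", "B", "C"), n, TRUE)))

  patients <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    age_years = round(sample_marginal(m$age, U[, "age"]), 1),
    bop_percent = round(sample_marginal(m$bop_percent, U[, "bop_percent"]), 1),
    n_ppd_ge5 = sample_marginal(m$n_ppd_ge5, U[, "n_ppd_ge5"]),
    bl_age_ratio = round(sample_marginal(m$bl_age_ratio, U[, "bl_age_ratio"]), 3),
    tooth_loss = sample_marginal(m$tooth_loss, U[, "tooth_loss"]),
    systemic_factor = sample_marginal(m$systemic_factor, U[, "systemic_factor"]),
    smoking = smoking,
    cigarettes_per_day = cpd,
    history = sample_marginal(m$history, U[, "history"]),
    stage = unname(stage),
    grade = grade,
    compliant = sample_marginal(m$compliant, U[, "compliant"]),
    stringsAsFactors = FALSE
  )

  # implant table: counts, types, prosthesis/plaque state at score time
  n_impl <- config$implants_per_patient$min +
    stats::rpois(n, config$implants_per_patient$lambda)
  pid <- rep(patients$patient_id, n_impl)
  total <- sum(n_impl)
  first <- !duplicated(pid)
  implants <- data.frame(
    patient_id = pid,
    implant_id = paste0(pid, "-I", sequence(n_impl)),
    implant_type = "tissue_level",
    rm_bone_mm = NA_real_,
    plaque_sites_pi_gt1 = sample(0:3, total, TRUE, prob = c(0.5, 0.25, 0.15, 0.1)),
    fit = "adequate",
    cement_excess = FALSE,
    stringsAsFactors = FALSE
  )
  # patients with a bone-level implant get exactly one (first implant)
  bone_patient <- !sample_marginal(m$tissue_only, U[, "tissue_only"])
  implants$implant_type[first & bone_patient[match(pid, patients$patient_id)]] <- "bone_level"
  # worst prosthesis/plaque state per patient, placed on the first implant
  pros <- sample_marginal(m$prosthesis, U[, "prosthesis"])
  pros_by_impl <- pros[match(pid, patients$patient_id)]
  implants$fit[first & pros_by_impl == "supra"] <- "poor_supramucosal"
  hp <- first & pros_by_impl == "high_plaque"
  implants$plaque_sites_pi_gt1[hp] <- sample(4:6, sum(hp), TRUE, prob = c(0.6, 0.25, 0.15))

  # score, then draw follow-up and events from the category hazards
  scored <- score_cohort(patients, implants)
  category <- if (config$score_kind == "PRA") scored$pra_category else scored$ira_category
  fe <- sample_event_times(category, config)
  patients$followup_years <- round(fe$followup_years, 2)
  patients$event <- fe$event

  # follow-up clinical state consistent with the sampled events: cases get
  # one implant meeting the case definition, all other implants stay below
  event_by_impl <- patients$event[match(pid, patients$patient_id)]
  case_impl <- first & event_by_impl
  implants$max_ppd_mm <- sample(2:5, total, TRUE, prob = c(0.35, 0.35, 0.2, 0.1))
  implants$bop_or_suppuration <- stats::runif(total) < 0.25
  implants$bli_mm <- round(stats::runif(total, 0, 2.8), 1)
  implants$max_ppd_mm[case_impl] <- sample(6:9, sum(case_impl), TRUE,
                                           prob = c(0.5, 0.3, 0.15, 0.05))
  implants$bop_or_suppuration[case_impl] <- TRUE
  implants$bli_mm[case_impl] <- round(stats::runif(sum(case_impl), 3, 5.5), 1)

  structure(list(patients = patients, implants = implants, config = config),
            class = "peri_cohort")
}

#' @export
print.peri_cohort <- function(x, ...) {
  cat(sprintf("<peri_cohort> %d patients, %d implants, %d events (%.1f%%)\n",
              nrow(x$patients), nrow(x$implants), sum(x$patients$event),
              100 * mean(x$patients$event)))
  invisible(x)
}
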