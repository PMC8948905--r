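# Independent oracles coded from first principles; these deliberately do not
# share code with the package implementations they check.

# literal restatement of the overall-risk prose, case by case
aggregate_oracle <- function(cats) {
  nh <- sum(cats == "high"); nm <- sum(cats == "moderate")
  if (nh >= 2) return("high")                 # at least two high
  if (nh == 0 && nm <= 1) return("low")       # all low, or a single moderate
  if (nm >= 2 && nh <= 1) return("moderate")  # >= two moderate, <= one high
  if (nh == 1 && nm == 0) return("moderate")  # one high, all others low
  if (nh == 1 && nm == 1) return("moderate")  # one high + one moderate
  stop("unreachable combination")
}

# Efron log partial likelihood for a single binary covariate
efron_loglik <- function(beta, time, event, x) {
  r <- exp(beta * x)
  ll <- 0
  for (t in sort(unique(time[event]))) {
    D <- which(event & time == t)
    R <- which(time >= t)
    d <- length(D)
    sR <- sum(r[R]); sD <- sum(r[D])
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1) ll <- ll - log(sR - (l / d) * sD)
  }
  ll
}

# textbook two-group log-rank chi-square from the observed-minus-expected sums
logrank_oracle <- function(time, event, in_group1) {
  O <- E <- V <- 0
  for (t in sort(unique(time[event]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & in_group1)
    d <- sum(event & time == t); d1 <- sum(event & time == t & in_group1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# all-pairs Mann-Whitney count, ties scored one half
auc_bruteforce <- function(scores, outcome) {
  pos <- scores[outcome]; neg <- scores[!outcome]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# minimal complete records for the scorers
make_patient <- function(...) {
  p <- list(patient_id = "P1", age_years = 60, bop_percent = 5, n_ppd_ge5 = 0,
            bl_age_ratio = 0.2, tooth_loss = 0, systemic_factor = FALSE,
            smoking = "non_smoker", history = FALSE, stage = "I", grade = "A",
            compliant = TRUE, followup_years = 5, event = FALSE)
  mods <- list(...)
  p[names(mods)] <- mods
  p
}

make_implant <- function(patient_id = "P1", implant_id = "I1",
                         implant_type = "tissue_level", max_ppd_mm = 3,
                         bop_or_suppuration = FALSE, bli_mm = 1,
                         rm_bone_mm = NA_real_, plaque_sites_pi_gt1 = 0,
                         fit = "adequate", cement_excess = FALSE) {
  data.frame(patient_id = patient_id, implant_id = implant_id,
             implant_type = implant_type, max_ppd_mm = max_ppd_mm,
             bop_or_suppuration = bop_or_suppuration, bli_mm = bli_mm,
             rm_bone_mm = rm_bone_mm, plaque_sites_pi_gt1 = plaque_sites_pi_gt1,
             fit = fit, cement_excess = cement_excess,
             stringsAsFactors = FALSE)
}

enumerate_categories <- function(k) {
  as.matrix(expand.grid(rep(list(risk_levels()), k), stringsAsFactors = FALSE))
}
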