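#' Risk category levels
#'
#' The three ordered risk categories used by both scores, from lowest to
#' highest: `"low" < "moderate" < "high"`.
#'
#' @return Character vector of the three category labels in increasing order.
#' @export
risk_levels <- function() c("low", "moderate", "high")

#' Coerce to an ordered risk factor
#'
#' @param x character vector of category labels.
#' @return An ordered factor with levels `low < moderate < high`.
#' @export
risk_factor <- function(x) {
  x <- as.character(x)
  bad <- !is.na(x) & !x %in% risk_levels()
  if (any(bad)) {
    stop("unknown risk category: ", paste(unique(x[bad]), collapse = ", "))
  }
  factor(x, levels = risk_levels(), ordered = TRUE)
}

# integer rank of a category (low = 1, high = 3); NA passes through
risk_rank <- function(x) match(as.character(x), risk_levels())

.smoking_levels <- c("non_smoker", "former_smoker", "current_smoker", "heavy_smoker")
.stage_levels <- c("I", "II", "III", "IV")
.grade_levels <- c("A", "B", "C")
.fit_levels <- c("adequate", "poor_supramucosal", "poor_submucosal")

# Numeric parameter thresholds. Printed ranges are closed on the right
# ("0 to 9%", "0 to 0.5", "5 to 8"), so a value categorizes as the first
# category whose upper bound is >= the value: low on [0, b1], moderate on
# (b1, b2], high above b2. This also maps non-integer values falling
# between printed integer bounds (e.g. a BOP of 9.5%) to the next category
# up, the only reading under which the three ranges partition the domain.
.numeric_rules <- list(
  PRA = list(
    bop_percent  = list(breaks = c(9, 25),   domain = c(0, 100)),
    n_ppd_ge5    = list(breaks = c(4, 8),    domain = c(0, Inf)),
    bl_age_ratio = list(breaks = c(0.5, 1),  domain = c(0, Inf)),
    tooth_loss   = list(breaks = c(4, 8),    domain = c(0, Inf))
  ),
  IRA = list(
    bop_percent  = list(breaks = c(9, 25),   domain = c(0, 100)),
    n_ppd_ge5    = list(breaks = c(2, 6),    domain = c(0, Inf)),
    bl_age_ratio = list(breaks = c(0.5, 1),  domain = c(0, Inf))
  )
)

.pra_params <- c("bop_percent", "n_ppd_ge5", "bl_age_ratio", "tooth_loss",
                 "systemic_factor", "smoking")
.ira_params <- c("bop_percent", "n_ppd_ge5", "bl_age_ratio", "history",
                 "susceptibility", "compliance", "rm_bone", "prosthesis_plaque")

# display-name aliases accepted by categorize_parameter()
.param_aliases <- c(
  "bop"                          = "bop_percent",
  "bop%"                         = "bop_percent",
  "nbppd5mm"                     = "n_ppd_ge5",
  "nbofppd5mm"                   = "n_ppd_ge5",
  "ppd"                          = "n_ppd_ge5",
  "blage"                        = "bl_age_ratio",
  "toothloss"                    = "tooth_loss",
  "systemicstatus"               = "systemic_factor",
  "smokingstatus"                = "smoking",
  "historyofstageiiiiiandivperiodontitis" = "history",
  "periodontitissusceptibility"  = "susceptibility",
  "compliancelevel"              = "compliance",
  "rmbone"                       = "rm_bone",
  "prosthesisplaquescore"        = "prosthesis_plaque"
)

normalize_param <- function(name) {
  key <- gsub("[^a-z0-9]", "", tolower(name))
  if (key %in% names(.param_aliases)) return(unname(.param_aliases[key]))
  canon <- gsub("[^a-z0-9]", "", c(.pra_params, .ira_params))
  hit <- match(key, canon)
  if (!is.na(hit)) return(c(.pra_params, .ira_params)[hit])
  NA_character_
}

#' Rule table for a risk score
#'
#' Declarative encoding of the per-parameter categorization rules of the
#' PRA (six parameters) and the IRA (eight parameters). Numeric parameters
#' carry the two category break points (closed upper bounds of the low and
#' moderate ranges) and the admissible domain; categorical parameters carry
#' the category each level maps to.
#'
#' @param score_kind `"PRA"` or `"IRA"`.
#' @return A list with elements `score_kind`, `parameters` (in score order)
#'   and `rules`, a named list keyed by parameter.
#' @examples
#' rule_table("PRA")$parameters
#' @export
rule_table <- function(score_kind = c("PRA", "IRA")) {
  score_kind <- match.arg(score_kind)
  if (score_kind == "PRA") {
    rules <- c(.numeric_rules$PRA, list(
      systemic_factor = list(map = c("FALSE" = "low", "TRUE" = "high")),
      smoking = list(map = c(non_smoker = "low", former_smoker = "low",
                             current_smoker = "moderate", heavy_smoker = "high"))
    ))
    params <- .pra_params
  } else {
    rules <- c(.numeric_rules$IRA, list(
      # history of stage II-IV periodontitis: moderate at most, high never
      # allocated; compliance and RM-bone are two-level (no moderate)
      history = list(map = c("FALSE" = "low", "TRUE" = "moderate")),
      susceptibility = list(map = NULL),   # composite of stage and grade
      compliance = list(map = c("TRUE" = "low", "FALSE" = "high")),
      rm_bone = list(map = NULL),          # composite, see categorize_rm_bone
      prosthesis_plaque = list(map = NULL) # composite, see categorize_prosthesis
    ))
    params <- .ira_params
  }
  structure(list(score_kind = score_kind, parameters = params, rules = rules),
            class = "rule_table")
}

#' @export
print.rule_table <- function(x, ...) {
  cat(sprintf("<rule_table> %s score, %d parameters:\n  %s\n",
              x$score_kind, length(x$parameters),
              paste(x$parameters, collapse = ", ")))
  invisible(x)
}

categorize_numeric <- function(value, rule, name) {
  value <- as.numeric(value)
  bad <- !is.na(value) & (value < rule$domain[1] | value > rule$domain[2])
  if (any(bad)) {
    stop(sprintf("'%s' outside admissible domain [%s, %s]: %s", name,
                 rule$domain[1], rule$domain[2],
                 paste(utils::head(value[bad], 3), collapse = ", ")))
  }
  risk_levels()[findInterval(value, rule$breaks, left.open = TRUE) + 1L]
}

#' Categorize periodontitis susceptibility (stage and grade)
#'
#' Stage I is low risk; stage II or III with grade A or B is moderate;
#' grade C at stage II or above, and stage IV at any grade, are high.
#'
#' @param stage character vector, `"I"`..`"IV"`.
#' @param grade character vector, `"A"`..`"C"`.
#' @return Character vector of risk categories.
#' @export
categorize_susceptibility <- function(stage, grade) {
  stage <- as.character(stage); grade <- as.character(grade)
  if (any(!stage %in% .stage_levels)) stop("stage must be one of I, II, III, IV")
  if (any(!grade %in% .grade_levels)) stop("grade must be one of A, B, C")
  out <- rep("moderate", length(stage))
  out[stage == "I"] <- "low"
  out[stage == "IV" | (stage %in% c("II", "III") & grade == "C")] <- "high"
  out
}

#' Categorize the restoration-margin-to-bone parameter
#'
#' Tissue-level implants are low risk; bone-level implants, or a measured
#' restoration-margin-to-marginal-bone distance below 1.5 mm, are high.
#' There is no moderate category. An unmeasured distance (`NA`) on a
#' tissue-level implant stays low: implant type alone decides.
#'
#' @param implant_type `"tissue_level"` or `"bone_level"` (vector).
#' @param rm_bone_mm numeric vector of distances in mm, `NA` allowed.
#' @return Character vector of risk categories (`"low"` or `"high"`).
#' @export
categorize_rm_bone <- function(implant_type, rm_bone_mm = NA_real_) {
  implant_type <- as.character(implant_type)
  if (any(!implant_type %in% c("tissue_level", "bone_level"))) {
    stop("implant_type must be 'tissue_level' or 'bone_level'")
  }
  rm_bone_mm <- rep_len(as.numeric(rm_bone_mm), length(implant_type))
  high <- implant_type == "bone_level" | (!is.na(rm_bone_mm) & rm_bone_mm < 1.5)
  ifelse(high, "high", "low")
}

#' Categorize the prosthesis/plaque parameter
#'
#' High risk: submucosal poor fit, cement excess, or more than 3 implant
#' sites with Plaque Index > 1. Moderate: supramucosal poor fit (without a
#' high-risk feature). Low: fewer than 4 plaque sites, adequate fit, no
#' cement excess.
#'
#' @param plaque_sites_pi_gt1 integer count of implant sites (of the six
#'   probed) with Plaque Index > 1.
#' @param fit `"adequate"`, `"poor_supramucosal"` or `"poor_submucosal"`.
#' @param cement_excess logical.
#' @return Character vector of risk categories.
#' @export
categorize_prosthesis <- function(plaque_sites_pi_gt1, fit = "adequate",
                                  cement_excess = FALSE) {
  plaque <- as.numeric(plaque_sites_pi_gt1)
  if (any(is.na(plaque) | plaque < 0 | plaque > 6)) {
    stop("plaque_sites_pi_gt1 must be a count between 0 and 6 (six sites probed)")
  }
  fit <- as.character(fit)
  if (any(!fit %in% .fit_levels)) {
    stop("fit must be one of ", paste(.fit_levels, collapse = ", "))
  }
  n <- max(length(plaque), length(fit), length(cement_excess))
  plaque <- rep_len(plaque, n); fit <- rep_len(fit, n)
  cement <- rep_len(as.logical(cement_excess), n)
  out <- rep("low", n)
  out[fit == "poor_supramucosal"] <- "moderate"
  out[fit == "poor_submucosal" | cement | plaque > 3] <- "high"
  out
}

#' Categorize one score parameter
#'
#' Maps a single parameter value to its risk category under the PRA or the
#' IRA rule table. Vectorized over `value` for simple parameters. Composite
#' parameters take a list: `rm_bone` expects
#' `list(implant_type=, rm_bone_mm=)` (a bare character value is read as
#' the implant type), `susceptibility` expects `list(stage=, grade=)` (or a
#' string such as `"III_C"`), and `prosthesis_plaque` expects
#' `list(plaque_sites_pi_gt1=, fit=, cement_excess=)`.
#'
#' @param name parameter name; canonical identifiers
#'   (e.g. `"bop_percent"`) and display names (e.g. `"BOP%"`, `"BL/age"`)
#'   are both accepted.
#' @param value the parameter value (see Details above for composites).
#' @param score_kind `"PRA"` or `"IRA"`.
#' @return Risk category label(s): `"low"`, `"moderate"` or `"high"`.
#' @examples
#' categorize_parameter("BOP%", 30, "PRA")        # "high"
#' categorize_parameter("Nb of PPD >= 5 mm", 7, "IRA") # "high"
#' categorize_parameter("BL/age", 0.5, "IRA")     # "low"
#' @export
categorize_parameter <- function(name, value, score_kind = c("PRA", "IRA")) {
  score_kind <- match.arg(score_kind)
  tab <- rule_table(score_kind)
  param <- normalize_param(name)
  if (is.na(param) || !param %in% tab$parameters) {
    stop(sprintf("unknown %s parameter: '%s'", score_kind, name))
  }
  rule <- tab$rules[[param]]
  switch(param,
    bop_percent = ,
    n_ppd_ge5 = ,
    bl_age_ratio = ,
    tooth_loss = categorize_numeric(value, rule, param),
    systemic_factor = ,
    history = ,
    compliance = {
      v <- as.logical(value)
      if (any(is.na(v))) stop(sprintf("'%s' must be TRUE/FALSE", param))
      unname(rule$map[as.character(v)])
    },
    smoking = {
      v <- as.character(value)
      v[v %in% c("non", "never")] <- "non_smoker"
      v[v == "former"] <- "former_smoker"
      v[v %in% c("current", "smoker")] <- "current_smoker"
      v[v == "heavy"] <- "heavy_smoker"
      if (any(!v %in% .smoking_levels)) {
        stop("smoking must be one of ", paste(.smoking_levels, collapse = ", "))
      }
      unname(rule$map[v])
    },
    susceptibility = {
      if (is.character(value) && length(value) >= 1 && !is.list(value)) {
        parts <- strsplit(gsub("[ /]", "_", value), "_")
        stage <- vapply(parts, `[`, "", 1L)
        grade <- vapply(parts, function(p) if (length(p) > 1) p[2] else "A", "")
        categorize_susceptibility(stage, grade)
      } else {
        categorize_susceptibility(value$stage, value$grade)
      }
    },
    rm_bone = {
      if (is.character(value)) {
        categorize_rm_bone(value)
      } else {
        categorize_rm_bone(value$implant_type,
                           if (is.null(value$rm_bone_mm)) NA_real_ else value$rm_bone_mm)
      }
    },
    prosthesis_plaque = categorize_prosthesis(
      value$plaque_sites_pi_gt1,
      if (is.null(value$fit)) "adequate" else value$fit,
      if (is.null(value$cement_excess)) FALSE else value$cement_excess
    )
  )
}
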